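#' Per-family maximum sibling distance along the river
#'
#' For each full-sib family, the maximum over all member pairs of the
#' absolute difference in 1-D river coordinate (km along the channel).
#' Members without a coordinate are dropped from pairing and flagged.
#' Individuals sampled repeatedly contribute each capture location.
#'
#' @param families a \code{FamilySet}.
#' @param samples data.frame with \code{individual_id} and
#'   \code{river_km} (and optionally \code{capture_date}).
#' @return data.frame of class \code{FamilyDispersal}: family_id,
#'   n_members, birth_year (modal cohort), max_distance_km,
#'   n_missing_km.
#' @export
familyMaxDistance <- function(families, samples) {
  stopifnot(inherits(families, "FamilySet"))
  fam <- families$families
  rows <- lapply(split(fam, fam$family_id), function(f) {
    km <- samples$river_km[samples$individual_id %in% f$member]
    km <- km[is.finite(km)]
    n_missing <- sum(!f$member %in%
                       samples$individual_id[is.finite(samples$river_km)])
    dist <- if (length(km) >= 2) max(km) - min(km) else 0
    data.frame(family_id = f$family_id[1],
               n_members = length(unique(f$member)),
               birth_year = if ("modal_cohort" %in% colnames(f))
                 f$modal_cohort[1] else
                   as.numeric(names(sort(-table(f$cohort)))[1]),
               max_distance_km = dist, n_missing_km = n_missing,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("FamilyDispersal", class(out))
  out
}

#' Infer dispersal direction within full-sib families
#'
#' Per family with at least \code{min_members} members: each
#' later-sampled member is compared to earlier-sampled siblings; a lower
#' river km than an earlier sibling's is downstream movement, higher is
#' upstream. Families with both, or with no temporally ordered
#' displacement, are "unclear"; families sampled at a single site are
#' "none". Undated samples make the family "unclear", never guessed.
#' Larvae sampled away from an earlier sibling's site are read as
#' downstream-only movement.
#'
#' @param families a \code{FamilySet}.
#' @param samples data.frame with \code{individual_id},
#'   \code{river_km}, \code{capture_date}, and optionally
#'   \code{age_group} (0 with December capture = larva).
#' @param min_members minimum family size for direction inference
#'   (default 5).
#' @return data.frame: family_id, n_members, direction in
#'   \{none, downstream, upstream, unclear\}.
#' @export
inferDirection <- function(families, samples, min_members = 5) {
  stopifnot(inherits(families, "FamilySet"))
  fam <- families$families
  rows <- lapply(split(fam, fam$family_id), function(f) {
    res <- data.frame(family_id = f$family_id[1],
                      n_members = length(unique(f$member)),
                      direction = NA_character_,
                      stringsAsFactors = FALSE)
    if (res$n_members < min_members) return(res)
    s <- samples[samples$individual_id %in% f$member, , drop = FALSE]
    s <- s[is.finite(s$river_km), , drop = FALSE]
    if (!nrow(s)) { res$direction <- "unclear"; return(res) }
    if (length(unique(s$river_km)) == 1) {
      res$direction <- "none"; return(res)
    }
    if (any(is.na(s$capture_date))) {
      res$direction <- "unclear"; return(res)
    }
    s$capture_date <- as.Date(s$capture_date)
    # anchor at the family's earliest capture(s): later-sampled siblings
    # are read as having moved relative to that location
    anchor <- which(s$capture_date == min(s$capture_date))
    down <- up <- FALSE
    for (i in anchor) for (j in seq_len(nrow(s))) {
      if (s$capture_date[j] <= s$capture_date[i]) next
      larva_j <- as.integer(format(s$capture_date[j], "%m")) == 12
      if (s$river_km[j] < s$river_km[i]) down <- TRUE
      if (s$river_km[j] > s$river_km[i] && !larva_j) up <- TRUE
    }
    res$direction <- if (down && up) "unclear"
    else if (down) "downstream"
    else if (up) "upstream"
    else "unclear"
    res
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Flow and family-size model of sibling dispersal distance
#'
#' OLS of per-family maximum sibling distance on mean daily flow of the
#' family's birth year and on family size. Family size enters because
#' larger families are more likely to capture rare long-distance
#' movements.
#'
#' @param dispersals output of \code{\link{familyMaxDistance}} (needs
#'   \code{birth_year}).
#' @param flow data.frame with \code{date} and \code{discharge_ML_day}
#'   (daily series), or \code{year} and \code{discharge_ML_day} (yearly
#'   means).
#' @return list: \code{summary} (coefficients, per-coefficient p,
#'   overall p, adjusted R-squared), \code{data} (the merged model
#'   frame), \code{fit}.
#' @export
flowDispersalModel <- function(dispersals, flow) {
  if (nrow(dispersals) < 10) stop("need >= 10 families")
  if ("date" %in% colnames(flow)) {
    yr <- as.integer(format(as.Date(flow$date), "%Y"))
    fl <- tapply(flow$discharge_ML_day, yr, mean)
    flow <- data.frame(year = as.integer(names(fl)),
                       discharge_ML_day = as.numeric(fl))
  }
  d <- merge(dispersals, flow, by.x = "birth_year", by.y = "year")
  if (length(unique(d$discharge_ML_day)) < 2)
    stop("flow is constant across families; coefficient undefined")
  fit <- stats::lm(max_distance_km ~ discharge_ML_day + n_members,
                   data = d)
  list(summary = .lmSummary(fit), data = d, fit = fit)
}
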