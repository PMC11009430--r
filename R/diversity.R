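#' Individual heterozygosity (PHt)
#'
#' The proportion of heterozygous calls among non-missing loci, per
#' individual. Individuals with no non-missing calls are flagged and get
#' \code{NA} (and are excluded from any group means computed downstream).
#'
#' @param g a \linkS4class{SnpGeno}.
#' @return data.frame with \code{id}, \code{pht}, \code{n_loci} (number
#'   of non-missing calls).
#' @export
individualHeterozygosity <- function(g) {
  stopifnot(is(g, "SnpGeno"))
  m <- calls(g)
  n <- colSums(!is.na(m))
  het <- colSums(m == 1L, na.rm = TRUE)
  pht <- ifelse(n > 0, het / n, NA_real_)
  if (any(n == 0))
    warning(sum(n == 0), " individual(s) with all-missing calls flagged")
  data.frame(id = colnames(m), pht = pht, n_loci = n, row.names = NULL)
}

.standardizedGeno <- function(g) {
  m <- t(calls(g))  # individuals x loci
  mu <- colMeans(m, na.rm = TRUE)
  for (j in seq_len(ncol(m))) {
    nas <- is.na(m[, j])
    if (any(nas)) m[nas, j] <- mu[j]  # per-locus mean imputation
  }
  sdv <- apply(m, 2, stats::sd)
  keep <- sdv > 0
  scale(m[, keep, drop = FALSE])
}

#' Principal Coordinate Analysis of genotypes
#'
#' Classical PCoA (eigen-decomposition of the double-centred
#' squared-Euclidean distance matrix) on standardized genotype vectors,
#' with per-locus mean imputation of missing calls. With Euclidean
#' distances this equals a genotype PCA; axes are ordered by eigenvalue.
#'
#' @param g a \linkS4class{SnpGeno}.
#' @param k number of axes to return.
#' @return list of class \code{AncestryResult} with \code{coords}
#'   (individuals x k), \code{percent_var} (per returned axis) and
#'   \code{labels} (NULL until \code{\link{classifyAncestry}}).
#' @export
pcoaGenotypes <- function(g, k = 2) {
  stopifnot(is(g, "SnpGeno"))
  if (ncol(g) < 2) stop("need at least two individuals")
  X <- .standardizedGeno(g)
  mx <- min(nrow(X) - 1L, ncol(X))
  if (k > mx) {
    warning("k exceeds the rank of the data; truncated to ", mx)
    k <- mx
  }
  d2 <- as.matrix(stats::dist(X))^2
  n <- nrow(d2)
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% d2 %*% J
  e <- eigen(B, symmetric = TRUE)
  pos <- pmax(e$values, 0)
  coords <- e$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(pos[seq_len(k)]), k)
  rownames(coords) <- rownames(X)
  colnames(coords) <- paste0("PC", seq_len(k))
  out <- list(coords = coords,
              percent_var = 100 * pos[seq_len(k)] / sum(pos),
              labels = NULL)
  class(out) <- "AncestryResult"
  out
}

#' @export
print.AncestryResult <- function(x, ...) {
  cat(sprintf("AncestryResult: %d individuals, %d axes\n",
              nrow(x$coords), ncol(x$coords)))
  cat("  % variance:",
      paste(sprintf("%.1f", x$percent_var), collapse = ", "), "\n")
  if (!is.null(x$labels))
    print(table(x$labels$label))
  invisible(x)
}

#' Classify ancestry from PC1 against reference clusters
#'
#' Reference individuals of the two source populations define cluster
#' centres and SDs on PC1. An unlabelled individual is called
#' \code{admixed} iff its PC1 value lies between the two centres and more
#' than \code{m} SDs away from both; otherwise it is assigned the nearer
#' cluster. Classification is refused when the reference clusters are not
#' separated by at least \code{m} SDs of each on PC1.
#'
#' @param coords an \code{AncestryResult} from \code{\link{pcoaGenotypes}}.
#' @param reference_labels named character vector: known population
#'   ("target"/"source") for a subset of individuals.
#' @param m guard-band width in reference-cluster SDs (default 3).
#' @return the \code{AncestryResult} with a \code{labels} data.frame
#'   (id, label) and a \code{summary} list including the admixed count
#'   and percentage among non-reference individuals.
#' @export
classifyAncestry <- function(coords, reference_labels, m = 3) {
  stopifnot(inherits(coords, "AncestryResult"))
  pc1 <- coords$coords[, 1]
  refs <- reference_labels[names(reference_labels) %in% names(pc1)]
  pops <- unique(refs)
  if (length(pops) != 2)
    stop("both reference populations must be represented")
  cen <- vapply(pops, function(p) mean(pc1[names(refs)[refs == p]]),
                0)
  sds <- vapply(pops, function(p) {
    v <- stats::sd(pc1[names(refs)[refs == p]])
    if (is.na(v)) 0 else v
  }, 0)
  lo <- pops[which.min(cen)]; hi <- pops[which.max(cen)]
  gap <- cen[hi] - cen[lo]
  if (gap < m * (sds[lo] + sds[hi]))
    stop(sprintf(
      "reference clusters overlap on PC1 (gap %.2f < %.2f); classification refused",
      gap, m * (sds[lo] + sds[hi])))
  lab <- vapply(pc1, function(v) {
    inside <- v > cen[lo] & v < cen[hi]
    far <- abs(v - cen[lo]) > m * sds[lo] &
      abs(v - cen[hi]) > m * sds[hi]
    if (inside && far) "admixed"
    else if (abs(v - cen[lo]) <= abs(v - cen[hi])) lo else hi
  }, "")
  labels <- data.frame(id = names(pc1), label = unname(lab),
                       row.names = NULL)
  non_ref <- labels[!labels$id %in% names(refs), ]
  n_adm <- sum(non_ref$label == "admixed")
  coords$labels <- labels
  coords$summary <- list(
    centers = cen, sds = sds,
    n_admixed = n_adm, n_classified = nrow(non_ref),
    percent_admixed = admixedPercent(n_adm, nrow(non_ref)))
  coords
}

#' Admixed-proportion worked example helper
#'
#' Percentage of admixed individuals among classified fish, on the scale
#' a monitoring report prints (e.g. 2 of 446 gives 0.45).
#'
#' @param n_admixed admixed count.
#' @param n_total classified count.
#' @param digits rounding for presentation (default 2).
#' @return percentage, rounded.
#' @export
admixedPercent <- function(n_admixed, n_total, digits = 2) {
  round(100 * n_admixed / n_total, digits)
}

#' One-level analysis of molecular variance (AMOVA)
#'
#' Partitions squared-Euclidean genotype distances into among- and
#' within-group components (standard one-level AMOVA decomposition with
#' unequal group sizes) and reports the percent of molecular variance
#' among groups with a group-label permutation p-value.
#'
#' @param g a \linkS4class{SnpGeno}.
#' @param groups group label per individual.
#' @param n_perm number of permutations (>= 99).
#' @param seed permutation seed.
#' @return list: \code{percent_among}, \code{sigma} (variance
#'   components), \code{p} = (1 + #permutations with percent >=
#'   observed)/(n_perm + 1), \code{n_perm}.
#' @export
amovaOneLevel <- function(g, groups, n_perm = 999, seed = 1L) {
  stopifnot(is(g, "SnpGeno"))
  groups <- as.factor(groups)
  if (length(groups) != ncol(g))
    stop("one group label per individual required")
  tab <- table(groups)
  if (length(tab) < 2 || any(tab < 2))
    stop("need >= 2 groups with >= 2 members each")
  if (n_perm < 99) stop("n_perm < 99 refused")
  X <- .standardizedGeno(g)
  d2 <- as.matrix(stats::dist(X))^2
  N <- nrow(d2)

  comp <- function(grp) {
    tab <- table(grp)
    ss_t <- sum(d2) / (2 * N)
    ss_w <- 0
    for (lv in names(tab)) {
      idx <- which(grp == lv)
      ss_w <- ss_w + sum(d2[idx, idx]) / (2 * length(idx))
    }
    ss_a <- ss_t - ss_w
    df_a <- length(tab) - 1
    df_w <- N - length(tab)
    ms_a <- ss_a / df_a
    ms_w <- ss_w / df_w
    n0 <- (N - sum(tab^2) / N) / df_a
    sig_a <- max((ms_a - ms_w) / n0, 0)
    sig_w <- ms_w
    c(percent = 100 * sig_a / (sig_a + sig_w), sig_a = sig_a,
      sig_w = sig_w)
  }

  obs <- comp(groups)
  set.seed(seed)
  cnt <- 0L
  for (i in seq_len(n_perm)) {
    pm <- comp(sample(groups))
    if (pm[["percent"]] >= obs[["percent"]]) cnt <- cnt + 1L
  }
  list(percent_among = obs[["percent"]],
       sigma = c(among = obs[["sig_a"]], within = obs[["sig_w"]]),
       p = (cnt + 1) / (n_perm + 1), n_perm = n_perm)
}

.okFit <- function(x, min_distinct = 3) {
  v <- x[!is.na(x)]
  length(unique(v)) >= min_distinct
}

.lmSummary <- function(fit) {
  s <- summary(fit)
  co <- stats::coef(s)
  list(coefficients = co[, "Estimate"],
       p = co[-1, "Pr(>|t|)", drop = TRUE],
       adj_r_squared = s$adj.r.squared,
       overall_p = if (is.null(s$fstatistic)) NA_real_ else
         stats::pf(s$fstatistic[1], s$fstatistic[2], s$fstatistic[3],
                   lower.tail = FALSE))
}

#' Heterozygosity trend models (LM1a, LM1b, LM2, LM3, LM4)
#'
#' The monitoring regression suite on individual heterozygosity: LM1a
#' PHt ~ birth year; LM1b PHt ~ cohort (category) with one-way ANOVA and
#' all-pairs Tukey HSD; LM2 PHt ~ river km; LM3 PHt ~ age; LM4
#' age ~ river km. One row per genetic individual is expected (deduplicate
#' recaptures first).
#'
#' @param het output of \code{\link{individualHeterozygosity}}.
#' @param samples data.frame with \code{individual_id} (or \code{id}),
#'   \code{birth_year}, \code{river_km} and \code{age}.
#' @return named list of model summaries; each contains slope(s), p,
#'   adjusted R-squared; LM1b also has the ANOVA p and the Tukey table.
#' @export
diversityTrendModels <- function(het, samples) {
  idcol <- if ("individual_id" %in% colnames(samples)) "individual_id"
  else "id"
  d <- merge(het, samples, by.x = "id", by.y = idcol)
  d <- d[!duplicated(d$id), ]
  out <- list()
  if (!.okFit(d$birth_year))
    stop("fewer than 3 distinct birth years; fit refused")
  out$LM1a <- .lmSummary(stats::lm(pht ~ birth_year, data = d))
  av <- stats::aov(pht ~ factor(birth_year), data = d)
  out$LM1b <- list(
    anova_p = summary(av)[[1]][["Pr(>F)"]][1],
    tukey = stats::TukeyHSD(av)[[1]])
  if (!.okFit(d$river_km))
    stop("fewer than 3 distinct river positions; fit refused")
  out$LM2 <- .lmSummary(stats::lm(pht ~ river_km, data = d))
  if (!.okFit(d$age)) stop("fewer than 3 distinct ages; fit refused")
  out$LM3 <- .lmSummary(stats::lm(pht ~ age, data = d))
  out$LM4 <- .lmSummary(stats::lm(age ~ river_km, data = d))
  out
}
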