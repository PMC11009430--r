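#' @useDynLib genrescue, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Expected composite-LD r-squared under pure sampling noise
#'
#' The small-sample expectation of the composite-LD r-squared for a
#' sample of S individuals drawn from an effectively infinite, randomly
#' mating population: 1/S + 3.19/S^2 for S >= 30, else
#' 0.0018 + 0.907/S + 4.44/S^2.
#'
#' @param S (harmonic mean) number of individuals.
#' @return expected r-squared.
#' @export
expectedNullR2 <- function(S) {
  ifelse(S >= 30, 1 / S + 3.19 / S^2,
         0.0018 + 0.907 / S + 4.44 / S^2)
}

.nbFromR2prime <- function(r2p, S) {
  if (is.na(r2p) || r2p <= 0) return(Inf)
  # beyond the quadratic's range (very strong drift signal) the
  # discriminant goes negative; fall back to its boundary value so the
  # transform stays positive and monotone decreasing
  if (S >= 30) {
    disc <- max(1 / 9 - 2.76 * r2p, 0)
    (1 / 3 + sqrt(disc)) / (2 * r2p)
  } else {
    disc <- max(0.308^2 - 2.08 * r2p, 0)
    (0.308 + sqrt(disc)) / (2 * r2p)
  }
}

#' Effective number of breeders from the drift component of LD
#'
#' Inverts the drift signal r2' = r2 - E[r2|S] to an effective number of
#' breeders: (1/3 + sqrt(1/9 - 2.76 r2'))/(2 r2') for S >= 30,
#' (0.308 + sqrt(0.308^2 - 2.08 r2'))/(2 r2') otherwise. Non-positive
#' r2' gives Inf.
#'
#' @param r2prime bias-adjusted mean r-squared.
#' @param S harmonic-mean sample size.
#' @return effective number of breeders.
#' @export
nbFromLdSignal <- function(r2prime, S) {
  vapply(r2prime, .nbFromR2prime, 0, S = S)
}

#' Weighted mean composite-LD r-squared across locus pairs
#'
#' Applies the minor-allele-frequency screen (whole loci with overall
#' MAF below \code{p_crit} are ignored), then computes, for every
#' retained locus pair, the squared composite-LD correlation of genotype
#' counts over pairwise-complete individuals, weighting pairs by their
#' individual count.
#'
#' @param g a \linkS4class{SnpGeno}.
#' @param p_crit MAF cutoff (default 0.01).
#' @param min_n minimum complete individuals per pair (default 10).
#' @return list: \code{mean_r2}, \code{S} (harmonic-mean sample size),
#'   \code{n_pairs}, \code{n_loci} retained.
#' @export
meanLdR2 <- function(g, p_crit = 0.01, min_n = 10) {
  stopifnot(is(g, "SnpGeno"))
  ls <- locusSummary(g)
  keep <- !is.na(ls$maf) & ls$maf >= p_crit & ls$maf > 0
  if (sum(keep) < 2) stop("fewer than 2 loci pass the MAF screen")
  if (ncol(g) < 10) stop("need at least 10 individuals")
  res <- .ldR2Stats(t(calls(g)[keep, , drop = FALSE]),
                    jackknife = FALSE, min_n = min_n)
  res$n_loci <- sum(keep)
  res
}

#' LD-method effective number of breeders for a single cohort
#'
#' The single-sample linkage-disequilibrium estimator: the weighted mean
#' composite-LD r-squared is bias-adjusted by the sampling expectation
#' \code{\link{expectedNullR2}}, and the drift signal
#' r2' = r2 - E[r2|S] is inverted to
#' Nb = (1/3 + sqrt(1/9 - 2.76 r2'))/(2 r2') for S >= 30 (small-sample
#' constants 0.308, 2.08 otherwise). Non-positive r2' or a negative
#' discriminant yield an infinite estimate. The confidence interval is a
#' delete-one-individual jackknife on r2' (normal-theory interval mapped
#' through the monotone Nb transform).
#'
#' @param g a \linkS4class{SnpGeno} holding one cohort.
#' @param p_crit MAF cutoff (default 0.01).
#' @param jackknife compute the jackknife CI (default TRUE).
#' @param conf confidence level (default 0.95).
#' @param min_n minimum complete individuals per locus pair.
#' @return an \linkS4class{NbEstimate} (method "LD").
#' @export
ldNe <- function(g, p_crit = 0.01, jackknife = TRUE, conf = 0.95,
                 min_n = 10) {
  stopifnot(is(g, "SnpGeno"))
  ls <- locusSummary(g)
  keep <- !is.na(ls$maf) & ls$maf >= p_crit & ls$maf > 0
  if (sum(keep) < 2) stop("fewer than 2 loci pass the MAF screen")
  if (ncol(g) < 10) stop("need at least 10 individuals")
  res <- .ldR2Stats(t(calls(g)[keep, , drop = FALSE]),
                    jackknife = jackknife, min_n = min_n)
  S <- res$S
  r2p <- res$mean_r2 - expectedNullR2(S)
  nb <- .nbFromR2prime(r2p, S)
  ci <- c(NA_real_, NA_real_)
  if (jackknife) {
    jr2p <- res$jack_r2 - expectedNullR2(res$jack_S)
    jr2p <- jr2p[is.finite(jr2p)]
    nj <- length(jr2p)
    se <- sqrt((nj - 1) / nj * sum((jr2p - mean(jr2p))^2))
    z <- stats::qnorm(1 - (1 - conf) / 2)
    lo_r2p <- r2p - z * se
    hi_r2p <- r2p + z * se
    # Nb is decreasing in r2'
    ci <- c(.nbFromR2prime(hi_r2p, S), .nbFromR2prime(lo_r2p, S))
  }
  new("NbEstimate", method = "LD", nbHat = nb, ci = ci, S = S,
      pCrit = p_crit, nPairs = res$n_pairs, r2 = res$mean_r2)
}

.dyadCounts <- function(ids, fam_of, dam_of, sire_of) {
  # counts of pairs sharing a family / at least one parent among `ids`
  # (ids may repeat under bootstrap resampling)
  n <- length(ids)
  tot <- n * (n - 1) / 2
  pairsWithin <- function(lab) {
    lab <- lab[!is.na(lab)]
    tt <- table(lab)
    sum(tt * (tt - 1) / 2)
  }
  if (!is.null(dam_of)) {
    # identical resampled copies share both parents: counted once
    sd_ <- pairsWithin(dam_of[ids])
    ss_ <- pairsWithin(sire_of[ids])
    both <- pairsWithin(paste(dam_of[ids], sire_of[ids]))
    q <- (sd_ + ss_ - both) / tot
  } else {
    q <- pairsWithin(fam_of[ids]) / tot
  }
  q
}

#' Sibship-frequency effective number of breeders
#'
#' A moment analogue of the sibship-assignment method: with Q the
#' frequency of offspring dyads sharing at least one parent (full-sib
#' dyads plus shared-single-parent dyads over all pairs), equal sex
#' ratio and random mating give Q = 4/Nb - 4/Nb^2, inverted as
#' Nb = 2 (1 + sqrt(1 - Q)) / Q. Q = 0 yields an infinite estimate. The
#' confidence interval is a percentile bootstrap over offspring
#' (individuals resampled, dyads recounted).
#'
#' @param families a \code{FamilySet} for one cohort (inferred, or from
#'   \code{\link{truthFamilySet}}; parent identities are used when
#'   present, otherwise full-sib family labels), or a data.frame with
#'   columns member/dam/sire as returned by
#'   \code{\link{simulateIdealCohort}}.
#' @param n_offspring number of offspring the dyads were counted over.
#' @param n_bootstrap bootstrap replicates (>= 200).
#' @param seed bootstrap seed.
#' @param conf confidence level.
#' @return an \linkS4class{NbEstimate} (method "sibship"); slot \code{r2}
#'   holds Q-hat.
#' @export
sibshipNb <- function(families, n_offspring, n_bootstrap = 1000,
                      seed = 1L, conf = 0.95) {
  if (is.data.frame(families) &&
      all(c("member", "dam", "sire") %in% colnames(families))) {
    fam <- data.frame(
      family_id = paste(families$dam, families$sire),
      member = families$member, cohort = NA, support = 1,
      stringsAsFactors = FALSE)
    families <- structure(list(families = fam, parents = families,
                               duplicates = list(),
                               n_offspring = nrow(families)),
                          class = "FamilySet")
  }
  stopifnot(inherits(families, "FamilySet"))
  if (n_offspring < 10) stop("need at least 10 offspring")
  if (n_bootstrap < 200) stop("n_bootstrap < 200 refused")
  fam <- families$families
  members <- unique(fam$member)
  singles <- setdiff(seq_len(n_offspring), seq_along(members))
  ids_all <- c(members,
               sprintf(".single%04d", seq_len(n_offspring -
                                                length(members))))
  fam_of <- stats::setNames(rep(NA_character_, length(ids_all)), ids_all)
  fam_of[fam$member] <- fam$family_id
  # singletons are their own family (shared-parent pairs need >= 2 draws)
  un <- is.na(fam_of)
  fam_of[un] <- paste0(".solo", seq_len(sum(un)))
  dam_of <- sire_of <- NULL
  if (!is.null(families$parents)) {
    dam_of <- stats::setNames(families$parents$dam,
                              families$parents$member)[ids_all]
    sire_of <- stats::setNames(families$parents$sire,
                               families$parents$member)[ids_all]
    names(dam_of) <- names(sire_of) <- ids_all
    miss <- is.na(dam_of)
    dam_of[miss] <- paste0(".ud", seq_len(sum(miss)))
    miss <- is.na(sire_of)
    sire_of[miss] <- paste0(".us", seq_len(sum(miss)))
  }
  nbFromQ <- function(q) {
    if (is.na(q) || q <= 0) return(Inf)
    2 * (1 + sqrt(1 - q)) / q
  }
  q_hat <- .dyadCounts(ids_all, fam_of, dam_of, sire_of)
  nb <- nbFromQ(q_hat)
  set.seed(seed)
  qb <- replicate(n_bootstrap, {
    bs <- sample(ids_all, replace = TRUE)
    .dyadCounts(bs, fam_of, dam_of, sire_of)
  })
  nbb <- vapply(qb, nbFromQ, 0)
  a <- (1 - conf) / 2
  ci <- unname(stats::quantile(nbb, c(a, 1 - a), names = FALSE,
                               type = 1))
  new("NbEstimate", method = "sibship", nbHat = nb, ci = ci,
      S = n_offspring, pCrit = NA_real_,
      nPairs = n_offspring * (n_offspring - 1) / 2, r2 = q_hat)
}

#' Life-history adjustment of a single-cohort Nb estimate
#'
#' Single-cohort LD estimates from iteroparous, age-structured species
#' mix drift signal from the breeders of one cycle with the
#' per-generation effective size. The adjustment chain uses adult life
#' span AL and age at maturity alpha:
#' Nb_adj = Nb_hat / (1.03 - 0.245 log10(AL/alpha)), then
#' Ne_adj = Nb_adj / (0.485 + 0.758 log10(AL/alpha)). Interval endpoints
#' are transformed identically; infinite estimates stay infinite. Values
#' are kept as floats; round only at presentation
#' (\code{\link{nbTable}}).
#'
#' @param raw an \linkS4class{NbEstimate}.
#' @param lh a \linkS4class{LifeHistory} (default AL = 23, alpha = 3).
#' @return the estimate with adjusted slots filled.
#' @export
adjustNb <- function(raw, lh = lifeHistory()) {
  stopifnot(is(raw, "NbEstimate"), is(lh, "LifeHistory"))
  lr <- log10(lh@AL / lh@alpha)
  divisor_b <- 1.03 - 0.245 * lr
  if (divisor_b <= 0)
    stop(sprintf(
      "life-history divisor %.3f <= 0 (AL/alpha = %.1f too extreme)",
      divisor_b, lh@AL / lh@alpha))
  ratio <- 0.485 + 0.758 * lr
  raw@nbAdj <- raw@nbHat / divisor_b
  raw@neAdj <- raw@nbAdj / ratio
  raw@nbAdjCi <- raw@ci / divisor_b
  raw@neAdjCi <- raw@nbAdjCi / ratio
  raw@divisors <- c(divisor_b = divisor_b, ratio = ratio)
  raw
}

#' Presentation table for Nb estimates
#'
#' Rounds point estimates and intervals to integers, the way monitoring
#' reports print them.
#'
#' @param ... one or more \linkS4class{NbEstimate} objects, optionally
#'   named.
#' @return data.frame with method, Nb_hat, CI, Nb_adj, Ne_adj columns.
#' @export
nbTable <- function(...) {
  ests <- list(...)
  if (length(ests) == 1 && is.list(ests[[1]]) &&
      !is(ests[[1]], "NbEstimate"))
    ests <- ests[[1]]
  rnd <- function(x) ifelse(is.finite(x), round(x), Inf)
  do.call(rbind, lapply(seq_along(ests), function(i) {
    e <- ests[[i]]
    data.frame(
      cohort = if (!is.null(names(ests))) names(ests)[i] else
        as.character(i),
      method = e@method, Nb_hat = rnd(e@nbHat),
      ci_low = rnd(e@ci[1]), ci_high = rnd(e@ci[2]),
      Nb_adj = rnd(e@nbAdj), Ne_adj = rnd(e@neAdj),
      row.names = NULL)
  }))
}
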