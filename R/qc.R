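#' Standard locus and individual quality filters
#'
#' Applies the reduced-representation SNP panel filters in a fixed order:
#' (1) individuals by missingness, (2) loci by reproducibility, (3) loci
#' by missingness, (4) monomorphic loci, (5) one SNP per sequencing tag.
#' Defaults are the monitoring profile (individuals >30\% missing, locus
#' reproducibility <95\%, loci missing in >20\% of individuals); the
#' stricter parentage profile is reached by
#' \code{maxIndMissing = 0.2, minReproducibility = 0.99,
#' onePerTag = "best"}. Tag thinning keeps either a seeded random SNP per
#' tag or the SNP with the highest information-content score.
#'
#' @param g a \linkS4class{SnpGeno}.
#' @param maxIndMissing drop individuals with a larger missing fraction.
#' @param minReproducibility drop loci below this reproducibility.
#' @param maxLocusMissing drop loci with a larger missing fraction.
#' @param onePerTag "random" or "best" (requires an \code{info_score}
#'   locus column), or NA to skip tag thinning.
#' @param seed seed for the random tag draw.
#' @return list with the filtered \code{geno} and a \code{report}
#'   data.frame (step, removed, kind) in application order.
#' @export
standardFilters <- function(g, maxIndMissing = 0.3,
                            minReproducibility = 0.95,
                            maxLocusMissing = 0.2,
                            onePerTag = c("random", "best"),
                            seed = 1L) {
  stopifnot(is(g, "SnpGeno"))
  thr <- c(maxIndMissing, minReproducibility, maxLocusMissing)
  if (any(thr < 0 | thr > 1)) stop("thresholds must lie in [0, 1]")
  if (!is.na(onePerTag[1])) onePerTag <- match.arg(onePerTag)
  report <- data.frame(step = character(), removed = integer(),
                       kind = character())
  note <- function(step, removed, kind)
    rbind(report, data.frame(step = step, removed = removed, kind = kind))

  m <- calls(g)
  ind_miss <- colMeans(is.na(m))
  keep_ind <- ind_miss <= maxIndMissing
  report <- note("individual_missingness", sum(!keep_ind), "individuals")
  g <- g[, keep_ind]

  ld <- locusData(g)
  keep <- ld$reproducibility >= minReproducibility
  report <- note("reproducibility", sum(!keep), "loci")
  g <- g[keep, ]

  m <- calls(g)
  loc_miss <- rowMeans(is.na(m))
  keep <- loc_miss <= maxLocusMissing
  report <- note("locus_missingness", sum(!keep), "loci")
  g <- g[keep, ]

  ls <- locusSummary(g)
  keep <- !is.na(ls$maf) & ls$maf > 0
  report <- note("monomorphic", sum(!keep), "loci")
  g <- g[keep, ]

  if (!is.na(onePerTag[1])) {
    ld <- locusData(g)
    if (onePerTag == "best") {
      if (is.null(ld$info_score))
        stop("onePerTag='best' requires an info_score locus column")
      ord <- order(ld$tag_id, -ld$info_score)
    } else {
      set.seed(seed)
      ord <- sample(nrow(ld))
      ord <- ord[order(ld$tag_id[ord])]
    }
    keep_idx <- ord[!duplicated(ld$tag_id[ord])]
    keep <- sort(keep_idx)
    report <- note("one_per_tag", nrow(ld) - length(keep), "loci")
    g <- g[keep, ]
  }

  if (nrow(g) == 0)
    stop("all loci removed by the filter pipeline")
  list(geno = g, report = report)
}

#' Excess-heterozygosity locus filter
#'
#' Removes loci whose observed heterozygote proportion significantly
#' exceeds 0.5, the maximum expected for a biallelic locus under
#' Hardy-Weinberg equilibrium; such loci typically represent incorrectly
#' merged paralogous sequence tags. Per locus, a one-sided exact binomial
#' test of the heterozygote count against null proportion 0.5 over
#' non-missing calls; loci with p < alpha are removed. Loci with no
#' non-missing calls are skipped with a warning.
#'
#' @param g a \linkS4class{SnpGeno}.
#' @param alpha significance level (default 0.05).
#' @return list with filtered \code{geno} and \code{report} as in
#'   \code{\link{standardFilters}}.
#' @export
excessHetFilter <- function(g, alpha = 0.05) {
  stopifnot(is(g, "SnpGeno"))
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  m <- calls(g)
  n <- rowSums(!is.na(m))
  k <- rowSums(m == 1L, na.rm = TRUE)
  if (any(n == 0))
    warning(sum(n == 0), " locus/loci with zero non-missing calls skipped")
  # one-sided upper tail: P(X >= k | n, 0.5)
  p <- ifelse(n == 0, 1,
              stats::pbinom(k - 1L, n, 0.5, lower.tail = FALSE))
  keep <- p >= alpha
  report <- data.frame(step = "excess_heterozygosity",
                       removed = sum(!keep), kind = "loci")
  list(geno = g[keep, ], report = report)
}
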