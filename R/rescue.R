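#' Population inbreeding from the heterozygosity ratio
#'
#' F = 1 - PHt_target / PHt_source, treating the source population as
#' outbred (F_source = 0). A nonzero source inbreeding generalization is
#' available via \code{f_source}: F = 1 - (1 - f_source) *
#' PHt_target / PHt_source ... i.e. the source's own inbreeding inflates
#' the estimate; it is off (0) by default. A target more diverse than
#' the source returns 0 with a warning.
#'
#' @param pht_target mean PHt of the recipient population.
#' @param pht_source mean PHt of the (assumed outbred) source.
#' @param f_source inbreeding of the source population (default 0).
#' @return current inbreeding coefficient F.
#' @export
inbreedingFromHet <- function(pht_target, pht_source, f_source = 0) {
  if (pht_target <= 0 || pht_source <= 0)
    stop("PHt means must be positive")
  if (pht_target > pht_source) {
    warning("target is not less diverse than the source; F set to 0")
    return(0)
  }
  1 - (1 - f_source) * pht_target / pht_source
}

#' Migrant fraction needed to reach a target inbreeding level
#'
#' The fraction f of the augmented population that must derive from
#' unrelated, non-inbred migrants so that inbreeding falls from
#' F_current to F_target in the admixed generation:
#' f = 1 - sqrt(F_target / F_current). When the target is already met,
#' f = 0 with a note.
#'
#' @param f_current current population inbreeding.
#' @param f_target target inbreeding (default 0.1).
#' @return migrant fraction f in [0, 1).
#' @export
migrantFraction <- function(f_current, f_target = 0.1) {
  if (f_target <= 0 || f_current <= 0)
    stop("inbreeding coefficients must be positive")
  if (f_target >= f_current) {
    message("target inbreeding already met; zero migrants needed")
    return(0)
  }
  1 - sqrt(f_target / f_current)
}

#' Effective (and census) migrant numbers
#'
#' With the migrant fraction f and the local effective breeder base Nb,
#' the number of successfully breeding (effective) migrants is
#' N_m = f Nb / (1 - f), rounded to the nearest integer for reporting.
#' If an effective-to-census ratio Ne/N is supplied, the census number
#' to translocate is N_m / (Ne/N), also rounded.
#'
#' @param f migrant fraction, in (0, 1).
#' @param nb effective breeder base (> 0).
#' @param ne_over_n optional Ne/N ratio in (0, 1].
#' @return list: \code{n_m_effective}, \code{n_m_census} (NA without a
#'   ratio), and the unrounded \code{n_m_exact}.
#' @export
migrantsNeeded <- function(f, nb, ne_over_n = NULL) {
  if (f <= 0 || f >= 1)
    stop("migrant fraction must lie strictly between 0 and 1 ",
         "(f -> 1 implies an unbounded requirement)")
  if (nb <= 0) stop("breeder base must be positive")
  nm <- f * nb / (1 - f)
  census <- NA_real_
  if (!is.null(ne_over_n)) {
    if (ne_over_n <= 0 || ne_over_n > 1)
      stop("ne_over_n must lie in (0, 1]")
    # census scaling starts from the reported (rounded) effective count
    census <- round(round(nm) / ne_over_n)
  }
  list(n_m_effective = round(nm), n_m_census = census, n_m_exact = nm)
}

#' Expected effective breeders among translocated fish
#'
#' Scales per-year release counts by the effective-to-census ratio:
#' round(count x ratio) per year, summed.
#'
#' @param release_counts non-negative per-year release counts.
#' @param ne_over_n effective-to-census ratio in (0, 1].
#' @return list: \code{per_year} (integers), \code{total}.
#' @export
expectedEffectiveBreeders <- function(release_counts, ne_over_n) {
  if (any(release_counts < 0)) stop("release counts must be >= 0")
  if (ne_over_n <= 0 || ne_over_n > 1)
    stop("ne_over_n must lie in (0, 1]")
  per <- round(release_counts * ne_over_n)
  list(per_year = per, total = sum(per))
}

#' Build a genetic-rescue plan
#'
#' Chains the planning calculus: inbreeding from the heterozygosity
#' ratio, migrant fraction for the target inbreeding, effective migrants
#' against the breeder base, and optionally census migrants via the
#' Ne/N ratio.
#'
#' @param pht_target,pht_source mean PHt of recipient and source.
#' @param nb effective breeder base (e.g. mean of per-cohort adjusted LD
#'   estimates).
#' @param f_target target inbreeding (default 0.1).
#' @param ne_over_n optional Ne/N ratio for census scaling (e.g. 0.17).
#' @return a \linkS4class{RescuePlan}.
#' @examples
#' rescuePlan(0.089, 0.144, nb = 42, ne_over_n = 0.17)
#' @export
rescuePlan <- function(pht_target, pht_source, nb, f_target = 0.1,
                       ne_over_n = NULL) {
  f_cur <- inbreedingFromHet(pht_target, pht_source)
  f <- migrantFraction(f_cur, f_target)
  nm <- migrantsNeeded(f, nb, ne_over_n)
  new("RescuePlan", phtTarget = pht_target, phtSource = pht_source,
      fCurrent = f_cur, fTarget = f_target, migrantFraction = f,
      nbBase = nb, nmEffective = nm$n_m_effective,
      neOverN = if (is.null(ne_over_n)) NA_real_ else ne_over_n,
      nmCensus = if (is.null(ne_over_n)) NA_real_ else nm$n_m_census)
}

#' One-generation simulation check of a rescue plan
#'
#' Validates the planning algebra end to end on synthetic genotypes:
#' source-population allele frequencies are drawn from a Beta spectrum,
#' the recipient population's frequencies are drifted to the plan's
#' current inbreeding, local breeders and the plan's prescribed number
#' of effective migrants interbreed for one generation (each offspring
#' allele drawn from the mixed breeder pool), and the offspring
#' generation's inbreeding is recomputed from the PHt ratio against the
#' source.
#'
#' @param plan a \linkS4class{RescuePlan}.
#' @param n_loci loci to simulate (default 2000).
#' @param n_offspring offspring generation sample size (default 100).
#' @param freq_model Beta parameters of the source spectrum.
#' @param seed RNG seed.
#' @return list: \code{f_realized} (recomputed offspring F),
#'   \code{f_target}, \code{pht_offspring}, \code{pht_source},
#'   \code{n_migrants}, \code{n_local}.
#' @export
simulateRescueOutcome <- function(plan, n_loci = 2000,
                                  n_offspring = 100,
                                  freq_model = c(0.2, 0.2),
                                  seed = 1L) {
  stopifnot(is(plan, "RescuePlan"))
  set.seed(seed)
  p_src <- stats::rbeta(n_loci, freq_model[1], freq_model[2])
  p_src <- pmin(pmax(p_src, 1e-4), 1 - 1e-4)
  Fd <- plan@fCurrent
  nu <- 1 / Fd - 1
  p_tgt <- stats::rbeta(n_loci, p_src * nu, (1 - p_src) * nu)

  n_local <- max(2L, round(plan@nbBase))
  n_mig <- max(0L, round(plan@nmEffective))
  hw <- function(p, n)
    matrix(stats::rbinom(n * length(p), 1L, rep(p, n)) +
             stats::rbinom(n * length(p), 1L, rep(p, n)),
           nrow = length(p))
  pool <- cbind(hw(p_tgt, n_local), hw(p_src, n_mig))
  n_pool <- ncol(pool)
  off <- matrix(0L, n_loci, n_offspring)
  for (i in seq_len(n_offspring)) {
    pr <- sample(n_pool, 2)  # dam and sire from the mixed breeder pool
    off[, i] <- .gamete(pool[, pr[1]]) + .gamete(pool[, pr[2]])
  }
  pht_off <- mean(colMeans(off == 1L))
  pht_src_exp <- mean(2 * p_src * (1 - p_src))
  f_real <- 1 - pht_off / pht_src_exp
  list(f_realized = f_real, f_target = plan@fTarget,
       pht_offspring = pht_off, pht_source = pht_src_exp,
       n_migrants = n_mig, n_local = n_local)
}
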