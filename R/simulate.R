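#' Simulation configuration for the riverscape pedigree generator
#'
#' Builds and validates the configuration driving the synthetic-data
#' generator: a small riverine fish population with overlapping
#' generations, per-year breeder counts tied to river flow, polygamous
#' mating producing full-sib families, translocations from a genetically
#' diverse source population, rare cross-population matings, Gompertz
#' length-at-age with an optional heterozygosity-by-stress growth effect,
#' and flow-dependent 1-D dispersal along the river.
#'
#' Defaults emulate the monitored study system: seven sites along an
#' ~18 km regulated river reach, five cohort years (2016-2020) with mean
#' daily flows of 222, 97, 48, 52 and 130 ML/day, per-year breeder counts
#' highest in the high-flow year, ancestral allele frequencies drawn from
#' a U-shaped Beta spectrum with the source population lightly drifted
#' (mean PHt near 0.144) and the recipient heavily drifted (mean PHt near
#' 0.089, source/recipient ratio 1.62), 71 translocated fish over
#' 2017-2019, and an adult life span of 23 years with maturity at
#' 3 years.
#'
#' @param n_years number of breeding years simulated.
#' @param start_year first breeding (cohort) year.
#' @param sites data.frame with columns \code{name} and \code{river_km}
#'   (km from the most-downstream site, strictly increasing).
#' @param flow_by_year named numeric, yearly mean discharge (ML/day).
#' @param breeders_per_year named integer vector of per-year breeder
#'   counts, or \code{list(intercept=, slope=)} mapping flow linearly to a
#'   breeder count.
#' @param family_size_distribution \code{c(mean=, dispersion=)} of the
#'   negative-binomial family-size distribution (truncated to >= 2).
#' @param polygamy_rate fraction of extra polygamous families added on top
#'   of the one-family-per-breeder-pair base matching.
#' @param mating "family" (negative-binomial full-sib families; every
#'   selected breeder leaves offspring) or "random" (each offspring draws
#'   dam and sire independently; ideal random union used for estimator
#'   calibration).
#' @param n_offspring_per_year offspring count per year for
#'   \code{mating = "random"}.
#' @param n_founders number of founders of the recipient population.
#' @param site_fidelity probability that a family's sire is drawn from the
#'   same site as the dam (spawning-site fidelity).
#' @param n_loci number of biallelic SNP loci.
#' @param founder_allele_freq_model \code{c(shape1=, shape2=)} Beta
#'   parameters of the ancestral allele-frequency spectrum from which
#'   both populations drift independently (so F1 crosses recover
#'   ancestral heterozygosity and exceed both parental groups).
#' @param target_founder_inbreeding drift coefficient of the recipient
#'   population relative to the ancestor (each founder frequency is a
#'   Beta draw around the ancestral one with variance F p(1-p)).
#' @param source_founder_inbreeding drift coefficient of the source
#'   population relative to the ancestor.
#' @param source_heterozygosity_multiplier implied source/recipient PHt
#'   ratio before the site-level gradient; must equal
#'   (1 - source_founder_inbreeding) / (1 - target_founder_inbreeding)
#'   within 1e-6. With the default upstream gradient the realized
#'   source/recipient ratio is about 1.62 (PHt 0.144 vs 0.089).
#' @param upstream_inbreeding_gradient per-km drift coefficient applied
#'   to the starting allele frequencies of each site's founder breeding
#'   pool, so genetic diversity declines in the upstream direction
#'   (capped at 0.6).
#' @param founder_prehistory \code{c(nb=, generations=)}: recipient
#'   founders at each site descend from a small pool bred for this many
#'   generations at \code{nb} breeders, giving founders realistic
#'   within-site relatedness and variable individual inbreeding; NULL
#'   for independent Hardy-Weinberg founders.
#' @param translocation_schedule data.frame(year, count, site) of source
#'   fish releases, or NULL for none.
#' @param cross_population_mating_rate per-year probability that a live
#'   translocated fish breeds with a local partner.
#' @param dispersal_kernel \code{c(base_sd_km=, flow_coefficient=,
#'   downstream_bias_km=, stay_prob=)}; a juvenile stays at its natal
#'   site with probability \code{stay_prob}, otherwise draws one
#'   persistent displacement with SD
#'   \code{base_sd_km + flow_coefficient * flow} of the birth year,
#'   shifted downstream by \code{downstream_bias_km}.
#' @param growth \code{c(L_inf=, k=, t0=, noise_sd=)} Gompertz parameters
#'   (mm, per year, years, mm).
#' @param inbreeding_depression \code{list(stress_years=, slope=)}: birth
#'   years under stress and the growth penalty slope in mm per unit PHt.
#' @param missing_call_rate probability a genotype call is missing.
#' @param capture_prob \code{c(larva=, juvenile=, adult=)} yearly capture
#'   probabilities (juvenile = ages 1 to 4).
#' @param tag_duplicate_rate fraction of loci sharing a sequencing tag
#'   with another locus.
#' @param AL adult life span, years.
#' @param alpha age at maturity, years.
#' @param seed integer seed; all generator randomness derives from it.
#' @return a validated list of class \code{SimConfig}.
#' @export
simConfig <- function(n_years = 5,
                      start_year = 2016,
                      sites = data.frame(
                        name = c("Reservoir", "Condor", "Motherhole",
                                 "Vanitys", "Spur", "Pipeline", "Burkes"),
                        river_km = c(0, 3, 5, 8, 11, 14, 17)),
                      flow_by_year = c("2016" = 222, "2017" = 97,
                                       "2018" = 48, "2019" = 52,
                                       "2020" = 130),
                      breeders_per_year = c("2016" = 65, "2017" = 32,
                                            "2018" = 35, "2019" = 23,
                                            "2020" = 54),
                      family_size_distribution = c(mean = 5.3,
                                                   dispersion = 1.5),
                      polygamy_rate = 0.3,
                      mating = c("family", "random"),
                      n_offspring_per_year = 100,
                      n_founders = 160,
                      site_fidelity = 0.8,
                      n_loci = 2000,
                      founder_allele_freq_model = c(shape1 = 0.235,
                                                    shape2 = 0.235),
                      target_founder_inbreeding = 0.35,
                      source_founder_inbreeding = 0.1,
                      source_heterozygosity_multiplier =
                        (1 - source_founder_inbreeding) /
                        (1 - target_founder_inbreeding),
                      upstream_inbreeding_gradient = 0.012,
                      founder_prehistory = c(nb = 30, generations = 9),
                      translocation_schedule = data.frame(
                        year = c(2017, 2018, 2019),
                        count = c(31, 28, 12),
                        site = c("Pipeline", "Spur", "Vanitys")),
                      cross_population_mating_rate = 0.01,
                      dispersal_kernel = c(base_sd_km = 0.4,
                                           flow_coefficient = 0.012,
                                           downstream_bias_km = 0.8,
                                           stay_prob = 0.55),
                      growth = c(L_inf = 350, k = 0.6, t0 = 1.6,
                                 noise_sd = 8),
                      inbreeding_depression = list(stress_years = 2018,
                                                   slope = 250),
                      missing_call_rate = 0.02,
                      capture_prob = c(larva = 0.08, juvenile = 0.3,
                                       adult = 0.05),
                      tag_duplicate_rate = 0.1,
                      AL = 23, alpha = 3,
                      seed = 1L) {
  mating <- match.arg(mating)
  cfg <- list(n_years = n_years, start_year = start_year, sites = sites,
              flow_by_year = flow_by_year,
              breeders_per_year = breeders_per_year,
              family_size_distribution = family_size_distribution,
              polygamy_rate = polygamy_rate, mating = mating,
              n_offspring_per_year = n_offspring_per_year,
              n_founders = n_founders, site_fidelity = site_fidelity,
              n_loci = n_loci,
              founder_allele_freq_model = founder_allele_freq_model,
              target_founder_inbreeding = target_founder_inbreeding,
              source_founder_inbreeding = source_founder_inbreeding,
              source_heterozygosity_multiplier =
                source_heterozygosity_multiplier,
              upstream_inbreeding_gradient = upstream_inbreeding_gradient,
              founder_prehistory = founder_prehistory,
              translocation_schedule = translocation_schedule,
              cross_population_mating_rate = cross_population_mating_rate,
              dispersal_kernel = dispersal_kernel, growth = growth,
              inbreeding_depression = inbreeding_depression,
              missing_call_rate = missing_call_rate,
              capture_prob = capture_prob,
              tag_duplicate_rate = tag_duplicate_rate,
              AL = AL, alpha = alpha, seed = as.integer(seed))
  class(cfg) <- "SimConfig"
  validateSimConfig(cfg)
  cfg
}

#' Validate a SimConfig
#'
#' Checks the invariants of the simulation configuration: probabilities in
#' [0, 1], breeder counts >= 2, river coordinates non-negative and
#' strictly increasing, life-history ordering AL > alpha >= 1.
#'
#' @param cfg a \code{SimConfig}.
#' @return \code{cfg}, invisibly; errors on violation.
#' @export
validateSimConfig <- function(cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  probs <- c(cfg$cross_population_mating_rate, cfg$missing_call_rate,
             cfg$site_fidelity, cfg$capture_prob, cfg$polygamy_rate,
             cfg$tag_duplicate_rate)
  if (any(probs < 0 | probs > 1))
    stop("all probabilities must lie in [0, 1]")
  km <- cfg$sites$river_km
  if (any(km < 0) || any(diff(km) <= 0))
    stop("river_km must be non-negative and strictly increasing")
  if (is.numeric(cfg$breeders_per_year) &&
      any(cfg$breeders_per_year < 2))
    stop("breeder counts must be >= 2")
  for (fv in c(cfg$target_founder_inbreeding,
               cfg$source_founder_inbreeding))
    if (fv < 0 || fv >= 1)
      stop("founder inbreeding coefficients must lie in [0, 1)")
  mult <- (1 - cfg$source_founder_inbreeding) /
    (1 - cfg$target_founder_inbreeding)
  if (abs(cfg$source_heterozygosity_multiplier - mult) > 1e-6)
    stop("source_heterozygosity_multiplier must equal ",
         "(1 - source_founder_inbreeding)/(1 - target_founder_inbreeding)")
  if (cfg$alpha < 1 || cfg$AL <= cfg$alpha)
    stop("life history must satisfy AL > alpha >= 1")
  if (cfg$n_loci < 1) stop("n_loci must be >= 1")
  invisible(cfg)
}

.simYears <- function(cfg) seq(cfg$start_year, length.out = cfg$n_years)

.breederCount <- function(cfg, year) {
  b <- cfg$breeders_per_year
  if (is.list(b)) {
    fl <- cfg$flow_by_year[[as.character(year)]]
    n <- round(b$intercept + b$slope * fl)
  } else n <- b[[as.character(year)]]
  max(2L, as.integer(n))
}

.famSizes <- function(cfg, n) {
  fs <- cfg$family_size_distribution
  sz <- stats::rnbinom(n, mu = fs[["mean"]], size = fs[["dispersion"]])
  pmax(sz, 2L)
}

#' Simulate a riverscape pedigree with known ground truth
#'
#' Generates an age-structured pedigree over the configured years.
#' Breeders are drawn each year from all alive mature individuals
#' (iteroparous, overlapping generations; lifespan capped at AL years).
#' Under \code{mating = "family"} a random dam-sire matching guarantees
#' every selected breeder leaves offspring, polygamous extra families add
#' half-sib structure, and family sizes follow the configured truncated
#' negative binomial. Translocated source fish enter in scheduled years
#' and breed with a local partner with the configured probability,
#' producing admixed offspring. Cohort year is the calendar year of
#' spawning (November); sexes are simulated internally but never exported
#' to observation tables.
#'
#' @param config a \code{SimConfig}.
#' @return A \code{PedigreeTruth}: list with \code{individuals}
#'   (data.frame: id, dam, sire, birth_year, sex, population, natal_site,
#'   natal_km, translocated, founder), \code{breeders} (data.frame: year,
#'   n_breeders = true distinct parent count), and the \code{config}.
#' @export
simulatePedigree <- function(config) {
  validateSimConfig(config)
  set.seed(config$seed)
  sites <- config$sites
  y0 <- config$start_year

  nf <- config$n_founders
  founders <- data.frame(
    id = sprintf("T%04d", seq_len(nf)),
    dam = NA_character_, sire = NA_character_,
    birth_year = y0 - sample(seq(config$alpha, config$AL), nf,
                             replace = TRUE,
                             prob = 0.85^seq(0, config$AL - config$alpha)),
    sex = sample(c("F", "M"), nf, replace = TRUE),
    population = "target",
    natal_site = sample(sites$name, nf, replace = TRUE),
    translocated = FALSE, founder = TRUE,
    release_year = NA_integer_,
    stringsAsFactors = FALSE)
  founders$natal_km <- sites$river_km[match(founders$natal_site, sites$name)]

  inds <- founders
  breeders_truth <- data.frame(year = integer(), n_breeders = integer())
  migrant_counter <- 0L
  offspring_counter <- 0L

  newId <- function(n) {
    ids <- sprintf("O%05d", offspring_counter + seq_len(n))
    offspring_counter <<- offspring_counter + n
    ids
  }

  for (year in .simYears(config)) {
    ts <- config$translocation_schedule
    if (!is.null(ts) && year %in% ts$year) {
      row <- ts[ts$year == year, , drop = FALSE]
      for (i in seq_len(nrow(row))) {
        cnt <- row$count[i]
        mig <- data.frame(
          id = sprintf("S%04d", migrant_counter + seq_len(cnt)),
          dam = NA_character_, sire = NA_character_,
          birth_year = year - sample(seq(config$alpha, config$alpha + 5),
                                     cnt, replace = TRUE),
          sex = sample(c("F", "M"), cnt, replace = TRUE),
          population = "source",
          natal_site = row$site[i],
          natal_km = sites$river_km[match(row$site[i], sites$name)],
          translocated = TRUE, founder = TRUE,
          release_year = year,
          stringsAsFactors = FALSE)
        migrant_counter <- migrant_counter + cnt
        inds <- rbind(inds, mig)
      }
    }

    age <- year - inds$birth_year
    mature <- age >= config$alpha & age <= config$AL &
      inds$population == "target"
    dams_pool <- inds$id[mature & inds$sex == "F"]
    sires_pool <- inds$id[mature & inds$sex == "M"]

    fam <- NULL  # data.frame(dam, sire, size)
    if (config$mating == "family") {
      B <- .breederCount(config, year)
      nd <- ceiling(B / 2); ns <- floor(B / 2)
      if (nd > length(dams_pool) || ns > length(sires_pool))
        stop(sprintf(
          "year %d: breeder count %d exceeds available mature individuals (%d dams, %d sires)",
          year, B, length(dams_pool), length(sires_pool)))
      dams <- sample(dams_pool, nd)
      sires <- sample(sires_pool, ns)
      # base matching: every selected breeder gets at least one family
      npair <- max(nd, ns)
      pad <- function(v, n) c(sample(v),
                              if (n > length(v))
                                sample(v, n - length(v), replace = TRUE))
      base_d <- pad(dams, npair)
      base_s <- sample(pad(sires, npair))
      # spawning-site fidelity: prefer sires from the dam's site
      dam_site <- inds$natal_site[match(base_d, inds$id)]
      for (i in seq_along(base_s)) {
        if (stats::runif(1) < config$site_fidelity) {
          same <- sires[inds$natal_site[match(sires, inds$id)] ==
                          dam_site[i]]
          if (length(same)) base_s[i] <- sample(same, 1)
        }
      }
      # fidelity swaps can orphan sires; re-cover them so that exactly
      # the configured breeders leave offspring
      orphan <- setdiff(sires, base_s)
      if (length(orphan)) {
        base_d <- c(base_d, sample(dams, length(orphan), replace = TRUE))
        base_s <- c(base_s, orphan)
      }
      n_extra <- round(config$polygamy_rate * length(base_d))
      fam <- data.frame(dam = c(base_d,
                                sample(dams, n_extra, replace = TRUE)),
                        sire = c(base_s,
                                 sample(sires, n_extra, replace = TRUE)),
                        stringsAsFactors = FALSE)
      fam$size <- .famSizes(config, nrow(fam))
    } else {
      B <- .breederCount(config, year)
      nd <- ceiling(B / 2); ns <- floor(B / 2)
      if (nd > length(dams_pool) || ns > length(sires_pool))
        stop(sprintf(
          "year %d: breeder count %d exceeds available mature individuals (%d dams, %d sires)",
          year, B, length(dams_pool), length(sires_pool)))
      dams <- sample(dams_pool, nd)
      sires <- sample(sires_pool, ns)
      n_off <- config$n_offspring_per_year
      fam <- data.frame(dam = sample(dams, n_off, replace = TRUE),
                        sire = sample(sires, n_off, replace = TRUE),
                        stringsAsFactors = FALSE)
      fam$size <- 1L
    }

    # cross-population matings by translocated fish
    mig_alive <- inds$id[inds$translocated &
                           (year - inds$birth_year) >= config$alpha &
                           (year - inds$birth_year) <= config$AL &
                           inds$birth_year + config$alpha <= year]
    present <- inds$id[inds$translocated]
    ts_years <- if (is.null(config$translocation_schedule)) integer(0) else
      config$translocation_schedule$year
    mig_here <- intersect(mig_alive, present)
    if (length(mig_here)) {
      breeds <- mig_here[stats::runif(length(mig_here)) <
                           config$cross_population_mating_rate]
      for (mg in breeds) {
        sx <- inds$sex[match(mg, inds$id)]
        partners <- if (sx == "F") sires_pool else dams_pool
        if (!length(partners)) next
        n_part <- 1L + stats::rbinom(1, 1, 0.5)
        for (p in sample(partners, min(n_part, length(partners)))) {
          sz <- max(1L, stats::rnbinom(1, mu = 2, size = 1) + 1L)
          fam <- rbind(fam, data.frame(
            dam = if (sx == "F") mg else p,
            sire = if (sx == "F") p else mg,
            size = sz, stringsAsFactors = FALSE))
        }
      }
    }

    n_off <- sum(fam$size)
    off_dam <- rep(fam$dam, fam$size)
    off_sire <- rep(fam$sire, fam$size)
    dam_pop <- inds$population[match(off_dam, inds$id)]
    sire_pop <- inds$population[match(off_sire, inds$id)]
    pop <- ifelse(dam_pop == sire_pop & dam_pop == "target", "target",
                  ifelse(dam_pop == sire_pop, "source", "admixed"))
    natal_site <- inds$natal_site[match(off_dam, inds$id)]
    off <- data.frame(
      id = newId(n_off), dam = off_dam, sire = off_sire,
      birth_year = year,
      sex = sample(c("F", "M"), n_off, replace = TRUE),
      population = pop, natal_site = natal_site,
      natal_km = sites$river_km[match(natal_site, sites$name)],
      translocated = FALSE, founder = FALSE,
      release_year = NA_integer_,
      stringsAsFactors = FALSE)
    inds <- rbind(inds, off)
    breeders_truth <- rbind(breeders_truth, data.frame(
      year = year, n_breeders = length(unique(c(off_dam, off_sire)))))
  }

  ped <- list(individuals = inds, breeders = breeders_truth,
              config = config)
  class(ped) <- "PedigreeTruth"
  ped
}

#' @export
print.PedigreeTruth <- function(x, ...) {
  n <- nrow(x$individuals)
  cat(sprintf("PedigreeTruth: %d individuals (%d founders, %d translocated)\n",
              n, sum(x$individuals$founder),
              sum(x$individuals$translocated)))
  cat("  true breeders per year:",
      paste(sprintf("%d:%d", x$breeders$year, x$breeders$n_breeders),
            collapse = "  "), "\n")
  invisible(x)
}

.gamete <- function(g) {
  # one fair draw per locus from a {0,1,2} genotype vector
  out <- integer(length(g))
  out[g == 2L] <- 1L
  het <- which(g == 1L)
  if (length(het))
    out[het] <- stats::rbinom(length(het), 1L, 0.5)
  out
}

#' Mendelian gene drop over a simulated pedigree
#'
#' Founder genotypes are Hardy-Weinberg draws from population-specific
#' allele frequencies: an ancestral frequency per locus comes from the
#' configured Beta spectrum, and each population's founder frequency is
#' an independent Beta draw around it with variance F p(1-p) at its
#' configured founder inbreeding, so the recipient/source mean
#' heterozygosity ratio equals (1-F_target)/(1-F_source) and F1 crosses
#' recover ancestral heterozygosity, exceeding both parents. A positive
#' \code{upstream_inbreeding_gradient} additionally makes recipient
#' founders at upstream sites partially autozygous. Each offspring allele
#' is an independent fair draw of one of the corresponding parent's two
#' alleles. Missing calls are then injected at the configured rate.
#'
#' @param pedigree a \code{PedigreeTruth}.
#' @param config the \code{SimConfig} used to build it.
#' @return a \linkS4class{SnpGeno} with one column per pedigree
#'   individual; \code{colData} carries population and birth year.
#' @export
dropGenotypes <- function(pedigree, config = pedigree$config) {
  validateSimConfig(config)
  set.seed(config$seed + 1L)
  inds <- pedigree$individuals
  L <- config$n_loci
  if (L < 1) stop("locus count must be >= 1")

  ab <- config$founder_allele_freq_model
  p_anc <- stats::rbeta(L, ab[[1]], ab[[2]])
  p_anc <- pmin(pmax(p_anc, 1e-4), 1 - 1e-4)
  drift <- function(p, F) {
    if (F <= 0) return(p)
    nu <- 1 / F - 1
    stats::rbeta(length(p), p * nu, (1 - p) * nu)
  }
  p_src <- drift(p_anc, config$source_founder_inbreeding)
  p_tgt <- drift(p_anc, config$target_founder_inbreeding)

  # Recipient founders descend from small site-level breeding pools:
  # each site's pool starts from frequencies drifted in proportion to
  # its distance upstream (a stable diversity gradient along the river)
  # and is then bred for a few pre-history generations at a small
  # breeder number, so same-site founders are related and individual
  # inbreeding varies between founders and families.
  grad <- config$upstream_inbreeding_gradient
  ph <- config$founder_prehistory
  site_pool <- NULL
  if ((!is.null(ph) && ph[["nb"]] > 0) || grad > 0) {
    site_pool <- lapply(seq_len(nrow(config$sites)), function(si) {
      p_si <- drift(p_tgt, min(grad * config$sites$river_km[si], 0.6))
      Np <- max(if (!is.null(ph)) 2 * ph[["nb"]] else 0, 40,
                ceiling(1.5 * config$n_founders / nrow(config$sites)))
      pool <- matrix(stats::rbinom(L * Np, 2L, p_si), nrow = L)
      if (!is.null(ph) && ph[["nb"]] > 0) {
        nb_pre <- as.integer(ph[["nb"]])
        gameteM <- function(M)
          (M == 2L) + (M == 1L) *
          matrix(stats::rbinom(length(M), 1L, 0.5), nrow = nrow(M))
        for (gg in seq_len(ph[["generations"]])) {
          br <- sample(Np, nb_pre)
          dams <- br[seq_len(nb_pre / 2)]
          sires <- br[nb_pre / 2 + seq_len(nb_pre / 2)]
          pool <- gameteM(pool[, sample(dams, Np, replace = TRUE),
                               drop = FALSE]) +
            gameteM(pool[, sample(sires, Np, replace = TRUE),
                         drop = FALSE])
          storage.mode(pool) <- "integer"
        }
      }
      pool
    })
    names(site_pool) <- config$sites$name
    pool_used <- stats::setNames(rep(0L, nrow(config$sites)),
                                 config$sites$name)
  }

  G <- matrix(NA_integer_, nrow = L, ncol = nrow(inds),
              dimnames = list(NULL, inds$id))
  # founders first (pedigree rows are in generation order)
  ord <- order(!inds$founder)
  for (i in ord) {
    if (inds$founder[i]) {
      if (inds$population[i] == "source") {
        G[, i] <- stats::rbinom(L, 1L, p_src) +
          stats::rbinom(L, 1L, p_src)
      } else if (!is.null(site_pool)) {
        st <- inds$natal_site[i]
        k <- pool_used[[st]] %% ncol(site_pool[[st]]) + 1L
        pool_used[[st]] <- pool_used[[st]] + 1L
        G[, i] <- site_pool[[st]][, k]
      } else {
        G[, i] <- stats::rbinom(L, 1L, p_tgt) +
          stats::rbinom(L, 1L, p_tgt)
      }
    } else {
      gd <- G[, inds$dam[i]]
      gs <- G[, inds$sire[i]]
      if (anyNA(gd) || anyNA(gs))
        stop("every non-founder needs two genotyped parents in the pedigree")
      G[, i] <- .gamete(gd) + .gamete(gs)
    }
  }

  if (config$missing_call_rate > 0) {
    miss <- matrix(stats::runif(length(G)) < config$missing_call_rate,
                   nrow = L)
    G[miss] <- NA_integer_
  }

  n_tag <- max(1L, round(L * (1 - config$tag_duplicate_rate)))
  tag_id <- sprintf("tag%05d", sample(rep_len(seq_len(n_tag), L)))
  locus <- data.frame(
    locus_id = sprintf("L%05d", seq_len(L)),
    tag_id = tag_id,
    reproducibility = 1 - stats::rbeta(L, 1, 60),
    info_score = stats::runif(L),
    true_p_source = p_src, true_p_target = p_tgt)
  SnpGeno(G, locusData = locus,
          sampleData = data.frame(
            population = inds$population,
            birth_year = inds$birth_year,
            translocated = inds$translocated))
}

.gompertzLength <- function(age, growth) {
  growth[["L_inf"]] *
    exp(-exp(-growth[["k"]] * (age - growth[["t0"]])))
}

#' Render observation tables from a simulated pedigree
#'
#' Produces the observed sample table (capture events with site, river km,
#' date and total length) and a daily river-flow series. Larvae may be
#' sampled in December of their birth year; juveniles and adults in
#' February-March surveys of later years, so individuals can be captured
#' repeatedly. Each individual draws one persistent dispersal
#' displacement from its natal site (1-D along the river, biased
#' downstream, SD growing with the birth-year flow), applied to all
#' post-larval captures; larvae drift downstream only. Total length
#' follows the Gompertz curve plus, in stress years, a
#' heterozygosity-dependent growth term, plus Gaussian noise;
#' non-positive lengths are resampled.
#'
#' @param pedigree a \code{PedigreeTruth}.
#' @param config the \code{SimConfig} used to build it.
#' @param geno optional \linkS4class{SnpGeno} from
#'   \code{\link{dropGenotypes}}; required for a nonzero
#'   inbreeding-depression slope, since the growth term uses realized
#'   individual heterozygosity.
#' @param seed observation seed; defaults to an offset of the config
#'   seed. Re-rendering the same pedigree under different seeds redraws
#'   only the observation process (captures, dispersal, lengths).
#' @return list with \code{samples} (data.frame: sample_id, individual_id,
#'   population, site, river_km, capture_date, total_length_mm, age_true,
#'   birth_year_true) and \code{flow} (data.frame: date,
#'   discharge_ML_day).
#' @export
renderObservations <- function(pedigree, config = pedigree$config,
                               geno = NULL, seed = config$seed + 2L) {
  validateSimConfig(config)
  set.seed(seed)
  inds <- pedigree$individuals
  sites <- config$sites
  years <- .simYears(config)
  slope <- config$inbreeding_depression$slope
  stress <- config$inbreeding_depression$stress_years

  pht <- rep(0, nrow(inds))
  if (!is.null(geno)) {
    m <- calls(geno)[, inds$id, drop = FALSE]
    pht <- colSums(m == 1L, na.rm = TRUE) /
      pmax(colSums(!is.na(m)), 1L)
  } else if (any(slope != 0)) {
    warning("inbreeding_depression slope set but no genotypes supplied; ",
            "growth term dropped")
    slope <- 0
  }

  kern <- config$dispersal_kernel
  grw <- config$growth
  max_km <- max(sites$river_km)
  snap <- function(km) {
    km <- pmin(pmax(km, 0), max_km)
    mids <- head(sites$river_km, -1) + diff(sites$river_km) / 2
    sites$river_km[findInterval(km, c(-Inf, mids))]
  }

  # centre the heterozygosity effect within each stress cohort so the
  # cohort mean length stays on the growth curve
  pht_ctr <- pht
  for (sy in stress) {
    sel <- inds$birth_year == sy & !inds$founder
    if (any(sel)) pht_ctr[sel] <- pht[sel] - mean(pht[sel])
  }

  obs_idx <- which(!inds$founder | inds$translocated)
  n_obs <- length(obs_idx)
  by <- inds$birth_year[obs_idx]
  fl <- unname(config$flow_by_year[as.character(by)])
  fl[is.na(fl)] <- mean(config$flow_by_year)
  sd_km <- kern[["base_sd_km"]] + kern[["flow_coefficient"]] * fl
  # one persistent post-larval displacement per individual; most
  # juveniles never leave their natal pool
  stay_p <- if ("stay_prob" %in% names(kern)) kern[["stay_prob"]] else 0
  disp <- ifelse(stats::runif(n_obs) < stay_p, 0,
                 stats::rnorm(n_obs, -kern[["downstream_bias_km"]],
                              sd_km))
  larva_drift <- -abs(stats::rnorm(n_obs, 0, sd_km / 2)) *
    (stats::runif(n_obs) > stay_p)

  grid <- data.frame(
    oi = rep(seq_len(n_obs), each = length(years)),
    year = rep(years, n_obs))
  grid$by <- by[grid$oi]
  idx <- obs_idx[grid$oi]
  rel <- inds$release_year[idx]
  keep <- grid$year >= grid$by &
    (!inds$translocated[idx] | grid$year >= rel | is.na(rel))
  grid <- grid[keep, , drop = FALSE]
  idx <- obs_idx[grid$oi]

  is_larva <- grid$year == grid$by
  age <- ifelse(is_larva,
                as.numeric(as.Date(sprintf("%d-12-10", grid$by)) -
                             as.Date(sprintf("%d-11-15", grid$by))) /
                  365.25,
                as.numeric(as.Date(sprintf("%d-03-01", grid$year)) -
                             as.Date(sprintf("%d-11-15", grid$by))) /
                  365.25)
  cp <- ifelse(is_larva, config$capture_prob[["larva"]],
               ifelse(age <= 4, config$capture_prob[["juvenile"]],
                      config$capture_prob[["adult"]]))
  cp[inds$translocated[idx] & !is_larva] <-
    config$capture_prob[["adult"]]
  cp[age > config$AL] <- 0
  caught <- stats::runif(nrow(grid)) < cp
  grid <- grid[caught, , drop = FALSE]
  idx <- idx[caught]; is_larva <- is_larva[caught]; age <- age[caught]

  km <- snap(inds$natal_km[idx] +
               ifelse(is_larva, larva_drift[grid$oi], disp[grid$oi]))
  mu <- .gompertzLength(age, grw) +
    ifelse(inds$birth_year[idx] %in% stress,
           slope * pht_ctr[idx], 0)
  len <- mu + stats::rnorm(length(mu), 0, grw[["noise_sd"]])
  bad <- which(len <= 0)
  for (i in bad) {   # resample, never emit non-positive lengths
    for (k in 1:20) {
      len[i] <- mu[i] + stats::rnorm(1, 0, grw[["noise_sd"]])
      if (len[i] > 0) break
    }
    if (len[i] <= 0) len[i] <- max(mu[i], 1)
  }
  dates <- ifelse(is_larva, sprintf("%d-12-10", grid$by),
                  sprintf("%d-0%d-%02d", grid$year,
                          sample(2:3, nrow(grid), replace = TRUE),
                          sample(1:28, nrow(grid), replace = TRUE)))
  samples <- data.frame(
    sample_id = sprintf("smp%05d", seq_len(nrow(grid))),
    individual_id = inds$id[idx],
    population = inds$population[idx],
    site = sites$name[match(km, sites$river_km)],
    river_km = km,
    capture_date = dates,
    total_length_mm = len,
    age_true = age, birth_year_true = grid$by,
    stringsAsFactors = FALSE)
  samples <- samples[order(samples$capture_date,
                           samples$individual_id), ]
  samples$sample_id <- sprintf("smp%05d", seq_len(nrow(samples)))
  rownames(samples) <- NULL

  flow <- do.call(rbind, lapply(years, function(y) {
    dates <- seq(as.Date(sprintf("%d-01-01", y)),
                 as.Date(sprintf("%d-12-31", y)), by = "day")
    base <- config$flow_by_year[[as.character(y)]]
    season <- 1 + 0.35 * sin(2 * pi * (as.integer(format(dates, "%j")) -
                                         240) / 365)
    noise <- exp(stats::rnorm(length(dates), 0, 0.3))
    q <- base * season * noise
    q <- q * base / mean(q)
    data.frame(date = format(dates), discharge_ML_day = round(q, 2))
  }))

  list(samples = samples, flow = flow)
}

#' Discrete-generation ideal cohort for estimator calibration
#'
#' Simulates an isolated population of constant effective number of
#' breeders under the assumptions of the single-sample estimators: equal
#' sex ratio, random union of gametes, discrete generations. Founders
#' are Hardy-Weinberg draws from a Beta allele-frequency spectrum; each
#' generation, \code{nb} breeders (half dams, half sires) drawn from the
#' population produce the next generation by independent dam/sire draws
#' per offspring. Several generations let linkage disequilibrium at
#' unlinked loci reach its drift equilibrium, so the cohort carries the
#' full LD signal of \code{nb}. With \code{nb = Inf} a single huge
#' panmictic generation is returned (the null case of no drift signal).
#'
#' @param nb true effective number of breeders per generation (even), or
#'   \code{Inf} for the panmictic null.
#' @param n_offspring cohort sample size returned.
#' @param n_loci unlinked biallelic loci.
#' @param n_generations generations of breeding (default 4).
#' @param freq_model Beta parameters of the founder spectrum.
#' @param pop_size per-generation census size (default
#'   \code{max(2 nb, n_offspring, 100)}).
#' @param seed RNG seed.
#' @return list: \code{geno} (\linkS4class{SnpGeno} of the sampled
#'   cohort), \code{parents} (data.frame member/dam/sire of the sampled
#'   offspring, for truth-dyad counting), \code{nb_true}.
#' @export
simulateIdealCohort <- function(nb, n_offspring, n_loci,
                                n_generations = 4,
                                freq_model = c(0.3, 0.3),
                                pop_size = NULL, seed = 1L) {
  set.seed(seed)
  p <- stats::rbeta(n_loci, freq_model[1], freq_model[2])
  p <- pmin(pmax(p, 1e-4), 1 - 1e-4)
  if (!is.finite(nb)) {
    N <- max(n_offspring, 100)
    G <- matrix(stats::rbinom(n_loci * N, 2L, p), nrow = n_loci)
    sel <- sample(N, n_offspring)
    geno <- SnpGeno(G[, sel, drop = FALSE])
    return(list(geno = geno,
                parents = data.frame(member = sampleIds(geno),
                                     dam = NA, sire = NA),
                nb_true = Inf))
  }
  if (nb %% 2 != 0 || nb < 4) stop("nb must be an even number >= 4")
  N <- if (is.null(pop_size)) max(2 * nb, n_offspring, 100) else
    pop_size
  pop <- matrix(stats::rbinom(n_loci * N, 2L, p), nrow = n_loci)
  dam_of <- sire_of <- integer(N)
  for (gen in seq_len(n_generations)) {
    br <- sample(N, nb)
    dams <- br[seq_len(nb / 2)]
    sires <- br[nb / 2 + seq_len(nb / 2)]
    newpop <- matrix(0L, n_loci, N)
    dam_of <- sample(dams, N, replace = TRUE)
    sire_of <- sample(sires, N, replace = TRUE)
    for (i in seq_len(N))
      newpop[, i] <- .gamete(pop[, dam_of[i]]) +
        .gamete(pop[, sire_of[i]])
    pop <- newpop
  }
  sel <- sample(N, n_offspring)
  geno <- SnpGeno(pop[, sel, drop = FALSE])
  list(geno = geno,
       parents = data.frame(member = sampleIds(geno),
                            dam = paste0("d", dam_of[sel]),
                            sire = paste0("s", sire_of[sel]),
                            stringsAsFactors = FALSE),
       nb_true = nb)
}

#' Full-sib family set from pedigree truth
#'
#' Builds the ground-truth family structure for a set of individuals:
#' full-sib families (same dam and sire), parent-offspring pairs among the
#' given individuals, and the dyad count of pairs sharing at least one
#' parent. Used as the oracle for kinship-recovery tests and as input to
#' the sibship-frequency breeder estimator.
#'
#' @param pedigree a \code{PedigreeTruth}.
#' @param ids individual ids to restrict to (e.g. one cohort's offspring).
#' @return list of class \code{FamilySet} with \code{families}
#'   (data.frame: family_id, member, cohort, support), \code{parentage}
#'   (data.frame: offspring, parent), \code{duplicates} (empty),
#'   \code{n_offspring}, and \code{dyads} (full_sib, half_sib counts).
#' @export
truthFamilySet <- function(pedigree, ids) {
  inds <- pedigree$individuals
  sub <- inds[match(ids, inds$id), , drop = FALSE]
  key <- paste(sub$dam, sub$sire)
  fam_id <- as.integer(factor(key))
  families <- data.frame(family_id = sprintf("F%03d", fam_id),
                         member = sub$id, cohort = sub$birth_year,
                         support = 1, stringsAsFactors = FALSE)
  n <- nrow(sub)
  same_dam <- outer(sub$dam, sub$dam, "==")
  same_sire <- outer(sub$sire, sub$sire, "==")
  ut <- upper.tri(same_dam)
  fs <- sum(same_dam[ut] & same_sire[ut], na.rm = TRUE)
  hs <- sum(xor(same_dam[ut], same_sire[ut]), na.rm = TRUE)
  po <- which(outer(sub$id, sub$id, FUN = function(a, b) {
    inds$dam[match(b, inds$id)] == a | inds$sire[match(b, inds$id)] == a
  }), arr.ind = TRUE)
  parentage <- if (nrow(po)) data.frame(offspring = sub$id[po[, 2]],
                                        parent = sub$id[po[, 1]])
  else data.frame(offspring = character(), parent = character())
  out <- list(families = families, parentage = parentage,
              parents = data.frame(member = sub$id, dam = sub$dam,
                                   sire = sub$sire,
                                   stringsAsFactors = FALSE),
              duplicates = list(), n_offspring = n,
              dyads = c(full_sib = fs, half_sib = hs))
  class(out) <- "FamilySet"
  out
}

#' @export
print.FamilySet <- function(x, ...) {
  nf <- length(unique(x$families$family_id))
  cat(sprintf("FamilySet: %d families over %d individuals",
              nf, length(unique(x$families$member))))
  if (length(x$duplicates))
    cat(sprintf(", %d duplicate sets", length(x$duplicates)))
  cat("\n")
  invisible(x)
}
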