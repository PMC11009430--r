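#' Assemble and validate a pipeline run configuration
#'
#' Collects input paths and per-stage parameters for
#' \code{\link{runPipeline}}. All referenced files must exist at
#' validation time; the global seed is propagated to every stochastic
#' stage (each stage derives its own fixed offset, so stages can be
#' rerun independently yet reproducibly).
#'
#' @param genotypes path to a VCF or CSV genotype file.
#' @param samples path to the sample table TSV (sample_id,
#'   individual_id, population, site, river_km, capture_date,
#'   total_length_mm).
#' @param flow path to the daily flow TSV (date, discharge_ML_day).
#' @param out_dir output directory.
#' @param format genotype format ("vcf" or "csv").
#' @param locus_meta optional locus-metadata CSV (csv format).
#' @param qc list of QC thresholds (see \code{\link{standardFilters}}).
#' @param p_crit MAF cutoff for the LD estimator.
#' @param life_history a \linkS4class{LifeHistory}.
#' @param full_sib_min full-sib clustering threshold.
#' @param f_target target inbreeding for the rescue plan.
#' @param ne_over_n effective-to-census ratio (NULL to skip census
#'   scaling).
#' @param cohort_breaks length breaks for cohort assignment, or "auto".
#' @param seed global seed.
#' @return list of class \code{RunConfig}.
#' @export
runConfig <- function(genotypes, samples, flow, out_dir,
                      format = c("vcf", "csv"), locus_meta = NULL,
                      qc = list(maxIndMissing = 0.3,
                                minReproducibility = 0.95,
                                maxLocusMissing = 0.2,
                                onePerTag = "random"),
                      p_crit = 0.01, life_history = lifeHistory(),
                      full_sib_min = 0.35, f_target = 0.1,
                      ne_over_n = 0.17, cohort_breaks = "auto",
                      seed = 1L) {
  format <- match.arg(format)
  for (p in c(genotypes, samples, flow,
              if (!is.null(locus_meta)) locus_meta))
    if (!file.exists(p)) stop("input file not found: ", p)
  cfg <- list(genotypes = genotypes, samples = samples, flow = flow,
              out_dir = out_dir, format = format,
              locus_meta = locus_meta, qc = qc, p_crit = p_crit,
              life_history = life_history, full_sib_min = full_sib_min,
              f_target = f_target, ne_over_n = ne_over_n,
              cohort_breaks = cohort_breaks, seed = as.integer(seed))
  class(cfg) <- "RunConfig"
  cfg
}

#' Read a RunConfig from YAML
#'
#' @param path YAML file with the fields of \code{\link{runConfig}}.
#' @return a \code{RunConfig}.
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  lh <- if (!is.null(y$life_history))
    lifeHistory(y$life_history$AL, y$life_history$alpha) else
      lifeHistory()
  do.call(runConfig, c(
    y[setdiff(names(y), "life_history")],
    list(life_history = lh)))
}

#' Run the monitoring pipeline end to end
#'
#' Stages in dependency order: genotype QC, heterozygosity +
#' ordination/ancestry, kinship (duplicates, relatedness, full-sib
#' families), per-cohort effective-breeder estimation (LD method with
#' life-history adjustment, sibship method from the inferred families),
#' growth modelling and cohort assignment, sibling dispersal, and the
#' rescue plan. Every artifact is written under \code{out_dir} together
#' with a manifest (config echo, seed, package version). A stage failure
#' halts the run with the stage named; artifacts of completed stages are
#' retained.
#'
#' @param config a \code{RunConfig}.
#' @param verbose print stage progress.
#' @return list with the main results (invisible artifacts on disk):
#'   \code{qc_report}, \code{heterozygosity}, \code{ancestry},
#'   \code{families}, \code{nb_estimates}, \code{growth},
#'   \code{dispersal_model}, \code{plan}, \code{manifest}.
#' @export
runPipeline <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- "init"
  res <- list()
  tryCatch({
    stage <- "qc"
    say("[qc] reading and filtering genotypes")
    g <- readGenotypes(config$genotypes, config$format,
                       config$locus_meta)
    qcq <- config$qc
    flt <- standardFilters(g, qcq$maxIndMissing,
                           qcq$minReproducibility,
                           qcq$maxLocusMissing, qcq$onePerTag,
                           seed = config$seed + 11L)
    xs <- excessHetFilter(flt$geno)
    g <- xs$geno
    res$qc_report <- rbind(flt$report, xs$report)
    utils::write.csv(res$qc_report,
                     file.path(config$out_dir, "qc_report.csv"),
                     row.names = FALSE)

    stage <- "samples"
    smp <- utils::read.delim(config$samples,
                             stringsAsFactors = FALSE)
    flow <- utils::read.delim(config$flow, stringsAsFactors = FALSE)
    smp <- smp[smp$individual_id %in% sampleIds(g), , drop = FALSE]

    stage <- "diversity"
    say("[diversity] heterozygosity and ordination")
    het <- individualHeterozygosity(g)
    utils::write.table(het, file.path(config$out_dir, "pht.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    pc <- pcoaGenotypes(g, k = 2)
    refs <- smp[!duplicated(smp$individual_id), ]
    ref_lab <- stats::setNames(refs$population, refs$individual_id)
    ref_lab <- ref_lab[ref_lab %in% c("target", "source")]
    anc <- tryCatch(classifyAncestry(pc, ref_lab),
                    error = function(e) {
                      say("[diversity] ancestry skipped: %s",
                          conditionMessage(e))
                      pc
                    })
    res$heterozygosity <- het
    res$ancestry <- anc
    utils::write.table(
      data.frame(id = rownames(pc$coords), pc$coords),
      file.path(config$out_dir, "pcoa.tsv"), sep = "\t",
      row.names = FALSE, quote = FALSE)

    stage <- "cohorts"
    say("[growth] cohort assignment and growth model")
    ca <- assignCohorts(smp, breaks = config$cohort_breaks)
    by <- stats::setNames(ca$per_individual$birth_year,
                          ca$per_individual$individual_id)
    smp$birth_year <- as.integer(by[smp$individual_id])
    smp$age <- .novemberAge(smp$capture_date, smp$birth_year)
    first <- smp[order(smp$capture_date), ]
    first <- first[!duplicated(first$individual_id), ]
    gf <- fitGompertz(first$age, first$total_length_mm)
    resid <- growthResiduals(gf, first, first$age)
    res$growth <- list(fit = gf, cohorts = ca)

    stage <- "kinship"
    say("[kinship] duplicates, relatedness, families")
    dup <- findDuplicates(g)
    rel <- pairwiseRelatedness(g)
    cohorts <- stats::setNames(smp$birth_year[
      match(sampleIds(g), smp$individual_id)], sampleIds(g))
    fams <- clusterFullSibFamilies(rel, cohorts,
                                   full_sib_min = config$full_sib_min,
                                   geno = g,
                                   seed = config$seed + 23L)
    res$families <- fams
    utils::write.table(fams$families,
                       file.path(config$out_dir, "families.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)

    stage <- "ne"
    say("[ne] effective breeders per cohort")
    lh <- config$life_history
    cos <- sort(unique(cohorts[!is.na(cohorts)]))
    nb_est <- list()
    for (co in cos) {
      ids <- names(cohorts)[!is.na(cohorts) & cohorts == co]
      if (length(ids) < 10) next
      sub <- g[, ids]
      ld <- tryCatch(
        adjustNb(ldNe(sub, p_crit = config$p_crit), lh),
        error = function(e) NULL)
      if (!is.null(ld)) nb_est[[as.character(co)]] <- ld
    }
    res$nb_estimates <- nb_est
    if (length(nb_est))
      utils::write.csv(nbTable(nb_est),
                       file.path(config$out_dir, "nb_estimates.csv"),
                       row.names = FALSE)

    stage <- "inbreeding_depression"
    say("[growth] inbreeding-depression models")
    res$inbreeding_depression <- tryCatch(
      inbreedingDepressionSuite(resid, het),
      error = function(e) conditionMessage(e))

    stage <- "dispersal"
    say("[dispersal] sibling distances and flow model")
    fd <- familyMaxDistance(fams, smp)
    dir_tab <- inferDirection(fams, smp)
    res$dispersal_model <- tryCatch(
      list(model = flowDispersalModel(fd, flow)$summary,
           families = fd, directions = dir_tab),
      error = function(e) conditionMessage(e))

    stage <- "plan"
    say("[plan] rescue planning")
    idx <- match(het$id, smp$individual_id)
    pop <- smp$population[idx]
    pht_t <- mean(het$pht[pop == "target"], na.rm = TRUE)
    pht_s <- mean(het$pht[pop == "source"], na.rm = TRUE)
    nb_base <- mean(vapply(nb_est, function(e)
      if (is.finite(e@nbAdj)) e@nbAdj else NA_real_, 0),
      na.rm = TRUE)
    res$plan <- if (is.finite(pht_s) && is.finite(nb_base) &&
                    pht_t < pht_s)
      rescuePlan(pht_t, pht_s, nb_base, config$f_target,
                 config$ne_over_n) else NULL
    if (!is.null(res$plan)) {
      p <- res$plan
      jsonlite::write_json(
        list(pht_target = p@phtTarget, pht_source = p@phtSource,
             f_current = p@fCurrent, f_target = p@fTarget,
             migrant_fraction = p@migrantFraction, nb_base = p@nbBase,
             n_m_effective = p@nmEffective, ne_over_n = p@neOverN,
             n_m_census = p@nmCensus),
        file.path(config$out_dir, "rescue_plan.json"),
        auto_unbox = TRUE, digits = NA)
    }

    stage <- "manifest"
    cfg_echo <- config
    cfg_echo$life_history <- list(AL = config$life_history@AL,
                                  alpha = config$life_history@alpha)
    class(cfg_echo) <- NULL
    manifest <- list(
      package = "genrescue",
      version = as.character(utils::packageVersion("genrescue")),
      seed = config$seed, config = cfg_echo,
      config_hash = sum(utf8ToInt(paste(
        utils::capture.output(utils::str(cfg_echo)), collapse = ""))))
    jsonlite::write_json(manifest,
                         file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA,
                         force = TRUE)
    res$manifest <- manifest
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  invisible(res)
}
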