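#' Gompertz length-at-age
#'
#' L(t) = L_inf exp(-exp(-k (t - t0))): sigmoid growth with asymptote
#' L_inf (mm), rate k (per year) and inflection age t0 (years);
#' L(t0) = L_inf / e.
#'
#' @param age age in years.
#' @param L_inf,k,t0 curve parameters.
#' @return predicted total length, mm.
#' @export
gompertz <- function(age, L_inf, k, t0) {
  L_inf * exp(-exp(-k * (age - t0)))
}

#' Fit the Gompertz growth model
#'
#' Nonlinear least squares with multistart initialization: L_inf starts
#' from 1.2 x the maximum observed length (plus perturbations), k and t0
#' from a log-log linearized pass. Reports convergence and the residual
#' SD.
#'
#' @param ages ages in years.
#' @param lengths total lengths in mm.
#' @return list of class \code{GrowthFit}: \code{L_inf}, \code{k},
#'   \code{t0}, \code{residual_sd}, \code{converged}, \code{fit} (the
#'   nls object), \code{parameterization}.
#' @export
fitGompertz <- function(ages, lengths) {
  ok <- is.finite(ages) & is.finite(lengths)
  ages <- ages[ok]; lengths <- lengths[ok]
  if (length(ages) < 6 || length(unique(round(ages, 3))) < 2)
    stop("need >= 6 (age, length) points spanning >= 2 distinct ages")
  d <- data.frame(t = ages, L = lengths)

  linStart <- function(L_inf) {
    # log(-log(L/L_inf)) = -k t + k t0 for 0 < L < L_inf
    u <- d$L / L_inf
    use <- u > 0.01 & u < 0.99
    if (sum(use) < 2) return(NULL)
    z <- log(-log(u[use]))
    cf <- stats::coef(stats::lm(z ~ d$t[use]))
    k <- -cf[[2]]
    if (!is.finite(k) || k <= 0) return(NULL)
    c(L_inf = L_inf, k = k, t0 = cf[[1]] / k)
  }
  starts <- Filter(Negate(is.null),
                   lapply(max(d$L) * c(1.2, 1.5, 2.0, 1.05), linStart))
  starts <- c(starts, list(c(L_inf = max(d$L) * 1.2, k = 0.5,
                             t0 = stats::median(d$t))))
  best <- NULL; best_loss <- Inf
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(L ~ L_inf * exp(-exp(-k * (t - t0))),
                        data = d, start = as.list(st),
                        lower = c(L_inf = 1, k = 1e-4, t0 = -10),
                        control = minpack.lm::nls.lm.control(
                          maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      loss <- sum(stats::resid(fit)^2)
      if (loss < best_loss) { best <- fit; best_loss <- loss }
    }
  }
  if (is.null(best))
    stop(sprintf("Gompertz fit failed to converge (best loss %.1f)",
                 best_loss))
  cf <- stats::coef(best)
  out <- list(L_inf = cf[["L_inf"]], k = cf[["k"]], t0 = cf[["t0"]],
              residual_sd = stats::sd(stats::resid(best)),
              converged = TRUE, fit = best,
              parameterization = "L_inf*exp(-exp(-k*(t-t0)))")
  class(out) <- "GrowthFit"
  out
}

#' @export
print.GrowthFit <- function(x, ...) {
  cat(sprintf(
    "GrowthFit: L_inf = %.1f mm, k = %.3f /yr, t0 = %.2f yr (resid SD %.1f mm)\n",
    x$L_inf, x$k, x$t0, x$residual_sd))
  invisible(x)
}

#' Growth residuals against a fitted Gompertz curve
#'
#' Residual = observed length - predicted length at the individual's
#' age; positive values mean longer than average for the age. Individuals
#' without a length are excluded with a warning.
#'
#' @param fit a \code{GrowthFit}.
#' @param samples data.frame with \code{total_length_mm} and an id
#'   column (\code{individual_id} or \code{id}).
#' @param ages ages (years) aligned with \code{samples} rows.
#' @return data.frame: id, age, length, residual (and \code{cohort} if
#'   \code{samples} has a \code{birth_year} column).
#' @export
growthResiduals <- function(fit, samples, ages) {
  stopifnot(inherits(fit, "GrowthFit"))
  idcol <- if ("individual_id" %in% colnames(samples)) "individual_id"
  else "id"
  len <- samples$total_length_mm
  ok <- is.finite(len) & is.finite(ages)
  if (any(!ok))
    warning(sum(!ok), " individual(s) without length or age excluded")
  d <- data.frame(id = samples[[idcol]][ok], age = ages[ok],
                  length = len[ok])
  d$residual <- d$length - gompertz(d$age, fit$L_inf, fit$k, fit$t0)
  if ("birth_year" %in% colnames(samples))
    d$cohort <- samples$birth_year[ok]
  d
}

.novemberAge <- function(capture_date, birth_year) {
  as.numeric(as.Date(capture_date) -
               as.Date(sprintf("%d-11-15", birth_year))) / 365.25
}

#' Assign birth-year cohorts from capture date and length
#'
#' With explicit \code{breaks}, each capture window (calendar year of
#' capture) has length thresholds mapping total length to an age group;
#' with \code{breaks = "auto"}, valleys of a kernel-smoothed length
#' density per capture window propose the thresholds
#' (operator-reviewable). Birth year follows the November-spawning
#' convention: larvae sampled in December belong to the capture year's
#' cohort; fish sampled in the usual February-March window at age group
#' a (0 = young-of-year) were born in capture year - a - 1 ... i.e.
#' birth year = capture year - 1 - a for post-new-year sampling, capture
#' year - a for sampling in November/December. Individuals recaptured
#' across years must resolve to one birth year; inconsistencies are
#' reported, and ambiguous lengths (within \code{guard} mm of a break)
#' are labelled "uncertain", never guessed.
#'
#' @param samples data.frame with \code{individual_id},
#'   \code{capture_date} and \code{total_length_mm}.
#' @param breaks numeric vector of increasing length thresholds
#'   separating age groups 0, 1, 2, ... within a February-March capture
#'   window, or "auto".
#' @param guard half-width (mm) of the uncertainty band around each
#'   break (default 0: off).
#' @return list of class \code{CohortAssignment}: \code{assignments}
#'   data.frame (individual_id, sample_id, age_group, birth_year, rule),
#'   \code{per_individual} (consensus birth year + consistency flag),
#'   \code{breaks_used}, \code{consistency_rate}.
#' @export
assignCohorts <- function(samples, breaks = "auto", guard = 0) {
  need <- c("individual_id", "capture_date", "total_length_mm")
  if (!all(need %in% colnames(samples)))
    stop("samples must have columns: ", paste(need, collapse = ", "))
  d <- samples
  d$capture_date <- as.Date(d$capture_date)
  d$cap_year <- as.integer(format(d$capture_date, "%Y"))
  d$cap_month <- as.integer(format(d$capture_date, "%m"))

  auto <- identical(breaks, "auto")
  breaks_used <- list()
  getBreaks <- function(lens) {
    if (!auto) return(breaks)
    if (length(lens) < 10) return(numeric(0))
    dn <- stats::density(lens, bw = "SJ", n = 512)
    # interior local minima of the smoothed histogram
    y <- dn$y
    idx <- which(diff(sign(diff(y))) == 2) + 1
    dn$x[idx][dn$x[idx] > min(lens) & dn$x[idx] < max(lens)]
  }

  rows <- lapply(split(seq_len(nrow(d)), d$cap_year), function(ii) {
    sub <- d[ii, , drop = FALSE]
    feb <- sub$cap_month <= 6       # post-new-year sampling window
    br <- sort(getBreaks(sub$total_length_mm[feb]))
    breaks_used[[as.character(sub$cap_year[1])]] <<- br
    age_group <- findInterval(sub$total_length_mm, br)
    unc <- rep(FALSE, nrow(sub))
    if (guard > 0 && length(br))
      unc <- vapply(sub$total_length_mm,
                    function(l) any(abs(l - br) <= guard), TRUE)
    birth <- ifelse(feb, sub$cap_year - 1L - age_group,
                    sub$cap_year - age_group)
    # December larvae: same-year cohort regardless of breaks
    larva <- !feb & sub$cap_month == 12
    birth[larva] <- sub$cap_year[larva]
    age_group[larva] <- 0L
    data.frame(individual_id = sub$individual_id,
               sample_id = if ("sample_id" %in% colnames(sub))
                 sub$sample_id else NA_character_,
               age_group = ifelse(unc, NA_integer_, age_group),
               birth_year = ifelse(unc, NA_integer_, birth),
               rule = ifelse(larva, "december_larva",
                             ifelse(unc, "uncertain", "length_break")),
               stringsAsFactors = FALSE)
  })
  asg <- do.call(rbind, rows)
  rownames(asg) <- NULL

  per <- lapply(split(asg, asg$individual_id), function(a) {
    by <- a$birth_year[!is.na(a$birth_year)]
    data.frame(individual_id = a$individual_id[1],
               birth_year = if (length(by))
                 as.integer(names(sort(-table(by)))[1]) else NA_integer_,
               consistent = length(unique(by)) <= 1,
               n_captures = nrow(a), stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  rownames(per) <- NULL
  out <- list(assignments = asg, per_individual = per,
              breaks_used = breaks_used,
              consistency_rate = mean(per$consistent))
  class(out) <- "CohortAssignment"
  out
}

#' @export
print.CohortAssignment <- function(x, ...) {
  cat(sprintf("CohortAssignment: %d captures, %d individuals\n",
              nrow(x$assignments), nrow(x$per_individual)))
  print(table(birth_year = x$per_individual$birth_year))
  cat(sprintf("  recapture consistency: %.1f%%\n",
              100 * x$consistency_rate))
  invisible(x)
}

#' Inbreeding-depression regression suite (LM5, LM6, LMM6)
#'
#' LM5: one-way ANOVA of growth residuals on cohort (category) with
#' all-pairs Tukey HSD. LM6: OLS of residuals on individual
#' heterozygosity (PHt), pooled and per cohort. LMM6: random-intercept
#' model (birth year) with PHt as the fixed slope, fitted by REML; the
#' random effect's contribution is assessed by a likelihood-ratio
#' comparison of ML fits of LM6 vs LMM6. Cohorts with fewer than
#' \code{min_n} individuals are excluded from per-cohort fits with a
#' warning.
#'
#' @param residuals output of \code{\link{growthResiduals}} (one row per
#'   individual; must carry \code{cohort}).
#' @param het output of \code{\link{individualHeterozygosity}}.
#' @param min_n minimum per-cohort size (default 10).
#' @return list: \code{LM5} (anova p, percent variance explained, Tukey
#'   table), \code{LM6} (pooled summary), \code{LM6_per_cohort} (named
#'   list of summaries), \code{LMM6} (fixed slope, p, random-intercept
#'   SD), \code{lrt} (statistic, p).
#' @export
inbreedingDepressionSuite <- function(residuals, het, min_n = 10) {
  d <- merge(residuals, het, by = "id")
  d <- d[!is.na(d$cohort) & is.finite(d$pht), ]
  d <- d[!duplicated(d$id), ]
  if (length(unique(d$cohort)) < 2) stop("need >= 2 cohorts")
  d$cohort_f <- factor(d$cohort)

  av <- stats::aov(residual ~ cohort_f, data = d)
  ss <- summary(av)[[1]]
  tot <- sum(ss[["Sum Sq"]])
  lm5 <- list(anova_p = ss[["Pr(>F)"]][1],
              percent_variance = if (tot < 1e-10) 0 else
                100 * ss[["Sum Sq"]][1] / tot,
              tukey = stats::TukeyHSD(av)[[1]])

  lm6_fit <- stats::lm(residual ~ pht, data = d)
  lm6 <- .lmSummary(lm6_fit)

  sizes <- table(d$cohort)
  small <- names(sizes)[sizes < min_n]
  if (length(small))
    warning("cohort(s) with n < ", min_n, " excluded from per-cohort fits: ",
            paste(small, collapse = ", "))
  keep <- setdiff(names(sizes), small)
  per <- lapply(stats::setNames(keep, keep), function(co) {
    .lmSummary(stats::lm(residual ~ pht,
                         data = d[d$cohort == as.numeric(co), ]))
  })

  lmm6 <- tryCatch({
    lmm <- nlme::lme(residual ~ pht, random = ~ 1 | cohort_f, data = d,
                     method = "REML")
    sl <- summary(lmm)$tTable
    list(slope = sl["pht", "Value"], p = sl["pht", "p-value"],
         random_intercept_sd =
           as.numeric(nlme::VarCorr(lmm)["(Intercept)", "StdDev"]))
  }, error = function(e)
    list(slope = NA_real_, p = NA_real_,
         random_intercept_sd = NA_real_,
         note = paste("degenerate mixed model:",
                      conditionMessage(e))))
  lrt <- tryCatch({
    lmm_ml <- nlme::lme(residual ~ pht, random = ~ 1 | cohort_f,
                        data = d, method = "ML")
    stat <- 2 * (as.numeric(stats::logLik(lmm_ml)) -
                   as.numeric(stats::logLik(lm6_fit)))
    # null variance component lies on the boundary: halved chi-square(1)
    list(statistic = stat,
         p = 0.5 * stats::pchisq(stat, df = 1, lower.tail = FALSE))
  }, error = function(e)
    list(statistic = NA_real_, p = NA_real_))
  list(LM5 = lm5, LM6 = lm6, LM6_per_cohort = per, LMM6 = lmm6,
       lrt = lrt, n = nrow(d))
}
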