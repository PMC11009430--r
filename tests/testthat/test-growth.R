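test_that("noise-free Gompertz parameters are recovered to 4 significant figures", {
  ages <- seq(0.2, 8, length.out = 12)
  lens <- gompertz(ages, 350, 0.5, 1.2)
  fit <- fitGompertz(ages, lens)
  expect_equal(fit$L_inf, 350, tolerance = 1e-4)
  expect_equal(fit$k, 0.5, tolerance = 1e-4)
  expect_equal(fit$t0, 1.2, tolerance = 1e-4)
})

test_that("L_inf is recovered within 5 percent under 10 mm noise", {
  errs <- vapply(1:5, function(r) {
    set.seed(600 + r)
    ages <- runif(300, 0.2, 10)
    lens <- gompertz(ages, 350, 0.5, 1.2) + rnorm(300, 0, 10)
    abs(fitGompertz(ages, lens)$L_inf / 350 - 1)
  }, 0)
  expect_true(all(errs < 0.05))
})

test_that("degenerate age input refuses a growth fit", {
  expect_error(fitGompertz(rep(2, 10), rep(150, 10)), "distinct ages")
  expect_error(fitGompertz(1:3, c(10, 20, 30)), ">= 6")
})

test_that("growth residuals are zero on the curve and centred on the fit set", {
  ages <- seq(0.3, 9, length.out = 40)
  lens <- gompertz(ages, 350, 0.5, 1.2)
  fit <- fitGompertz(ages, lens)
  s <- data.frame(individual_id = paste0("f", 1:40),
                  total_length_mm = lens, birth_year = 2016)
  res <- growthResiduals(fit, s, ages)
  expect_true(all(abs(res$residual) < 1e-6 * 350))

  set.seed(61)
  lens2 <- lens + rnorm(40, 0, 8)
  fit2 <- fitGompertz(ages, lens2)
  s2 <- s; s2$total_length_mm <- lens2
  res2 <- growthResiduals(fit2, s2, ages)
  expect_lt(abs(mean(res2$residual)), 0.5)
})

test_that("cohort assignment follows the November spawning convention", {
  s <- data.frame(individual_id = c("a", "b", "c"),
                  sample_id = c("s1", "s2", "s3"),
                  capture_date = c("2018-12-10", "2019-02-20",
                                   "2019-02-20"),
                  total_length_mm = c(25, 40, 110))
  ca <- assignCohorts(s, breaks = c(80))
  by <- setNames(ca$assignments$birth_year,
                 ca$assignments$individual_id)
  expect_equal(unname(by["a"]), 2018)  # December larva
  expect_equal(unname(by["b"]), 2018)  # YOY caught in February
  expect_equal(unname(by["c"]), 2017)  # one length class older
})

test_that("auto length breaks assign most simulated ages correctly", {
  cfg <- simConfig(seed = 62, n_loci = 20,
                   translocation_schedule = NULL,
                   founder_prehistory = NULL,
                   inbreeding_depression = list(stress_years = 2018,
                                                slope = 0))
  ped <- simulatePedigree(cfg)
  obs <- renderObservations(ped, cfg)
  s <- obs$samples
  ca <- assignCohorts(s, breaks = "auto")
  truth <- unique(s[, c("individual_id", "birth_year_true")])
  merged <- merge(ca$per_individual, truth)
  acc <- mean(merged$birth_year == merged$birth_year_true,
              na.rm = TRUE)
  expect_gte(acc, 0.9)
  expect_gte(ca$consistency_rate, 0.95)
})

test_that("ambiguous lengths are labelled uncertain, never guessed", {
  s <- data.frame(individual_id = c("a", "b"),
                  sample_id = c("s1", "s2"),
                  capture_date = c("2019-02-20", "2019-02-20"),
                  total_length_mm = c(79, 120))
  ca <- assignCohorts(s, breaks = c(80), guard = 2)
  asg <- ca$assignments
  expect_equal(asg$rule[asg$individual_id == "a"], "uncertain")
  expect_true(is.na(asg$birth_year[asg$individual_id == "a"]))
  expect_equal(asg$rule[asg$individual_id == "b"], "length_break")
})

test_that("a perfectly collinear PHt-residual relationship is fit exactly", {
  set.seed(63)
  pht <- runif(80, 0.05, 0.15)
  resid <- data.frame(id = paste0("f", 1:80),
                      age = 1, length = 100,
                      residual = 100 * pht - 10,
                      cohort = rep(2016:2019, 20))
  het <- data.frame(id = paste0("f", 1:80), pht = pht, n_loci = 1000)
  suite <- suppressWarnings(inbreedingDepressionSuite(resid, het))
  expect_equal(unname(suite$LM6$coefficients["pht"]), 100,
               tolerance = 1e-8)
  expect_equal(unname(suite$LM6$coefficients["(Intercept)"]), -10,
               tolerance = 1e-8)
})

test_that("equal residuals across cohorts explain no variance in LM5", {
  resid <- data.frame(id = paste0("f", 1:40), age = 1, length = 100,
                      residual = 5, cohort = rep(2016:2019, 10))
  het <- data.frame(id = paste0("f", 1:40),
                    pht = runif(40, 0.05, 0.15), n_loci = 1000)
  suite <- suppressWarnings(inbreedingDepressionSuite(resid, het))
  expect_equal(suite$LM5$percent_variance, 0, tolerance = 1e-8)
})

test_that("the mixed-model slope lies between the per-cohort extremes", {
  set.seed(64)
  d <- do.call(rbind, lapply(2016:2019, function(y) {
    pht <- runif(60, 0.05, 0.15)
    slope <- switch(as.character(y), "2016" = 50, "2017" = 150,
                    "2018" = 250, "2019" = 100)
    data.frame(id = sprintf("f%d_%d", y, 1:60), pht = pht,
               residual = slope * (pht - 0.1) + rnorm(60, 0, 4),
               cohort = y)
  }))
  resid <- d[, c("id", "residual", "cohort")]
  resid$age <- 1; resid$length <- 100
  het <- d[, c("id", "pht")]; het$n_loci <- 1000
  suite <- suppressWarnings(inbreedingDepressionSuite(resid, het))
  per <- vapply(suite$LM6_per_cohort,
                function(x) unname(x$coefficients["pht"]), 0)
  expect_gte(suite$LMM6$slope, min(per) - 1e-6)
  expect_lte(suite$LMM6$slope, max(per) + 1e-6)
})
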