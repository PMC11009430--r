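mkFamilySet <- function(members, cohorts = NULL) {
  fam <- data.frame(family_id = "F001", member = members,
                    cohort = if (is.null(cohorts)) 2016 else cohorts,
                    support = 1, stringsAsFactors = FALSE)
  structure(list(families = fam, duplicates = list(),
                 parentage = data.frame(), n_offspring = length(members)),
            class = "FamilySet")
}

test_that("family maximum distance matches brute-force pair enumeration", {
  fs <- mkFamilySet(c("a", "b"))
  s <- data.frame(individual_id = c("a", "b"),
                  river_km = c(5.0, 14.7),
                  capture_date = c("2017-02-01", "2017-02-02"))
  fd <- familyMaxDistance(fs, s)
  expect_equal(fd$max_distance_km, 9.7)

  fs3 <- mkFamilySet(c("a", "b", "c"))
  s3 <- data.frame(individual_id = c("a", "b", "c"),
                   river_km = c(2, 5, 11),
                   capture_date = "2017-02-01")
  expect_equal(familyMaxDistance(fs3, s3)$max_distance_km,
               max(abs(outer(c(2, 5, 11), c(2, 5, 11), "-"))))

  # single-site family
  s0 <- data.frame(individual_id = c("a", "b"), river_km = c(8, 8),
                   capture_date = "2017-02-01")
  expect_equal(familyMaxDistance(fs, s0)$max_distance_km, 0)
})

test_that("adding members never decreases the maximum distance", {
  set.seed(71)
  km <- runif(10, 0, 17)
  for (n in 3:10) {
    fsa <- mkFamilySet(paste0("m", 1:(n - 1)))
    fsb <- mkFamilySet(paste0("m", 1:n))
    s <- data.frame(individual_id = paste0("m", 1:10), river_km = km,
                    capture_date = "2017-02-01")
    expect_gte(familyMaxDistance(fsb, s)$max_distance_km,
               familyMaxDistance(fsa, s)$max_distance_km)
  }
})

test_that("direction follows later-vs-earlier sibling positions", {
  fs <- mkFamilySet(paste0("m", 1:5))
  base <- data.frame(individual_id = paste0("m", 1:5),
                     river_km = c(10, 10, 10, 10, 4),
                     capture_date = c(rep("2017-02-01", 4),
                                      "2018-02-01"))
  expect_equal(inferDirection(fs, base)$direction, "downstream")

  up <- base; up$river_km[5] <- 14
  expect_equal(inferDirection(fs, up)$direction, "upstream")

  mixed <- base
  mixed$river_km <- c(10, 10, 10, 4, 14)
  mixed$capture_date <- c(rep("2017-02-01", 3), "2018-02-01",
                          "2018-02-01")
  expect_equal(inferDirection(fs, mixed)$direction, "unclear")

  # undated samples are never guessed
  und <- base; und$capture_date[5] <- NA
  expect_equal(inferDirection(fs, und)$direction, "unclear")

  # small families are not called
  fs2 <- mkFamilySet(paste0("m", 1:2))
  s2 <- base[1:2, ]
  expect_true(is.na(inferDirection(fs2, s2)$direction))
  expect_equal(inferDirection(fs2, s2, min_members = 2)$direction,
               "none")
})

test_that("direction labels are invariant to member ordering", {
  fs <- mkFamilySet(paste0("m", 1:5))
  s <- data.frame(individual_id = paste0("m", 1:5),
                  river_km = c(10, 10, 10, 10, 4),
                  capture_date = c(rep("2017-02-01", 4), "2018-02-01"))
  d1 <- inferDirection(fs, s)$direction
  d2 <- inferDirection(fs, s[5:1, ])$direction
  fs_r <- mkFamilySet(paste0("m", 5:1))
  d3 <- inferDirection(fs_r, s)$direction
  expect_equal(d1, d2)
  expect_equal(d1, d3)
})

test_that("a downstream-biased kernel yields mostly downstream families", {
  dirs <- do.call(rbind, lapply(72:74, function(seed) {
    cfg <- simConfig(seed = seed, n_loci = 10,
                     translocation_schedule = NULL,
                     founder_prehistory = NULL,
                     inbreeding_depression = list(stress_years = 2018,
                                                  slope = 0),
                     capture_prob = c(larva = 0.25, juvenile = 0.3,
                                      adult = 0.05),
                     dispersal_kernel = c(base_sd_km = 0.5,
                                          flow_coefficient = 0.004,
                                          downstream_bias_km = 1.2,
                                          stay_prob = 0.5))
    ped <- simulatePedigree(cfg)
    obs <- renderObservations(ped, cfg)
    off <- intersect(ped$individuals$id[!ped$individuals$founder],
                     obs$samples$individual_id)
    fs <- truthFamilySet(ped, off)
    inferDirection(fs, obs$samples)
  }))
  dirs <- dirs[!is.na(dirs$direction), ]
  expect_gte(nrow(dirs), 50)
  n_down <- sum(dirs$direction == "downstream")
  n_up <- sum(dirs$direction == "upstream")
  expect_gte(n_down, 2 * max(n_up, 1))
})

test_that("the flow model recovers exact linear coefficients on toy data", {
  fd <- data.frame(family_id = sprintf("F%02d", 1:15),
                   n_members = rep(c(2, 5, 8), 5),
                   birth_year = rep(2016:2020, each = 3),
                   max_distance_km = NA, n_missing_km = 0)
  flow <- data.frame(year = 2016:2020,
                     discharge_ML_day = c(222, 97, 48, 52, 130))
  fl <- flow$discharge_ML_day[match(fd$birth_year, flow$year)]
  fd$max_distance_km <- 0.5 + 0.01 * fl + 0.2 * fd$n_members
  res <- suppressWarnings(flowDispersalModel(fd, flow))  # exact fit
  expect_equal(unname(res$summary$coefficients["discharge_ML_day"]),
               0.01, tolerance = 1e-10)
  expect_equal(unname(res$summary$coefficients["n_members"]), 0.2,
               tolerance = 1e-10)
  expect_equal(res$summary$adj_r_squared, 1, tolerance = 1e-8)
})

test_that("constant flow across families refuses the model", {
  fd <- data.frame(family_id = sprintf("F%02d", 1:12), n_members = 3,
                   birth_year = 2016, max_distance_km = runif(12),
                   n_missing_km = 0)
  flow <- data.frame(year = 2016, discharge_ML_day = 100)
  expect_error(flowDispersalModel(fd, flow), "constant")
  expect_error(flowDispersalModel(fd[1:5, ], flow), ">= 10")
})
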