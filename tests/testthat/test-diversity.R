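test_that("PHt is the heterozygous fraction of non-missing calls", {
  m <- cbind(c(0L, 1L, 2L, 1L, NA),      # 2 het of 4 called
             c(0L, 0L, 2L, 2L, 0L))      # all homozygous
  g <- SnpGeno(m)
  het <- individualHeterozygosity(g)
  expect_equal(het$pht, c(0.5, 0))
  expect_equal(het$n_loci, c(4L, 5L))
  g2 <- SnpGeno(cbind(m, rep(NA_integer_, 5)))
  expect_warning(h2 <- individualHeterozygosity(g2), "all-missing")
  expect_true(is.na(h2$pht[3]))
})

test_that("PCoA gives identical coordinates to identical genotypes", {
  set.seed(3)
  m <- matrix(rbinom(200, 2, 0.4), nrow = 20)
  m <- cbind(m, m[, 1])   # duplicate of individual 1
  g <- SnpGeno(m)
  pc <- pcoaGenotypes(g, k = 2)
  expect_equal(pc$coords[1, ], pc$coords[ncol(m), ], tolerance = 1e-8)
  expect_true(all(diff(pc$percent_var) <= 1e-8))
  expect_lte(sum(pc$percent_var), 100 + 1e-8)
})

test_that("fixed differences separate populations on PC1 with F1s between", {
  set.seed(8)
  n <- 30
  a <- matrix(0L, 200, n); b <- matrix(2L, 200, n)
  f1 <- matrix(1L, 200, 4)
  noise <- matrix(rbinom(100 * (2 * n + 4), 2, 0.3), nrow = 100)
  g <- SnpGeno(rbind(cbind(a, b, f1), noise))
  pc <- pcoaGenotypes(g, k = 2)
  pc1 <- pc$coords[, 1]
  ga <- pc1[1:n]; gb <- pc1[n + 1:n]; gf <- pc1[2 * n + 1:4]
  if (mean(ga) > mean(gb)) { tmp <- ga; ga <- gb; gb <- tmp }
  expect_lt(max(ga), min(gf))
  expect_lt(max(gf), min(gb))
})

test_that("an unstructured sample has no dominant PCoA axis", {
  set.seed(13)
  p <- rbeta(1000, 1, 1)
  m <- matrix(rbinom(1000 * 100, 2, rep(p, 100)), nrow = 1000)
  pc <- pcoaGenotypes(SnpGeno(m), k = 2)
  expect_lt(pc$percent_var[1] / pc$percent_var[2], 2)
})

test_that("ancestry classification labels centers, hybrids and refuses overlap", {
  set.seed(21)
  coords <- list(coords = cbind(PC1 = c(rnorm(20, 0, 0.3),
                                        rnorm(20, 15, 0.3),
                                        7.5, 0.1, 14.9),
                                PC2 = rnorm(43)),
                 percent_var = c(30, 5), labels = NULL)
  rownames(coords$coords) <- paste0("i", 1:43)
  class(coords) <- "AncestryResult"
  refs <- setNames(rep(c("target", "source"), each = 20),
                   paste0("i", 1:40))
  res <- classifyAncestry(coords, refs)
  lab <- setNames(res$labels$label, res$labels$id)
  expect_equal(unname(lab["i41"]), "admixed")
  expect_equal(unname(lab["i42"]), "target")
  expect_equal(unname(lab["i43"]), "source")
  # overlapping references are refused
  bad <- coords
  bad$coords[, 1] <- rnorm(43, 0, 1)
  expect_error(classifyAncestry(bad, refs), "refused")
})

test_that("simulated F1s are nearly always called admixed", {
  cfg <- simConfig(n_years = 1, n_loci = 1000, n_founders = 80,
                   breeders_per_year = c("2016" = 10),
                   cross_population_mating_rate = 1,
                   translocation_schedule = data.frame(
                     year = 2016, count = 12, site = "Spur"),
                   founder_prehistory = NULL, seed = 17)
  ped <- simulatePedigree(cfg)
  g <- dropGenotypes(ped)
  pop <- ped$individuals$population
  expect_gte(sum(pop == "admixed"), 20)
  pc <- pcoaGenotypes(g, k = 2)
  refs <- setNames(ifelse(pop == "source", "source", "target"),
                   ped$individuals$id)[ped$individuals$founder]
  res <- classifyAncestry(pc, refs)
  lab <- setNames(res$labels$label, res$labels$id)
  f1 <- ped$individuals$id[pop == "admixed"]
  expect_gte(mean(lab[f1] == "admixed"), 0.95)
})

test_that("the admixed proportion prints as the field report does", {
  expect_equal(admixedPercent(2, 446), 0.45)
})

test_that("AMOVA attains 100 percent for fixed differences and is seed-stable", {
  g <- SnpGeno(cbind(matrix(0L, 40, 8), matrix(2L, 40, 8)))
  grp <- rep(c("a", "b"), each = 8)
  res <- amovaOneLevel(g, grp, n_perm = 99, seed = 1)
  expect_equal(res$percent_among, 100, tolerance = 1e-6)
  expect_equal(res$p, 1 / 100)
  res2 <- amovaOneLevel(g, grp, n_perm = 99, seed = 1)
  expect_identical(res, res2)
  expect_error(amovaOneLevel(g, grp, n_perm = 50), "n_perm")
})

test_that("AMOVA on a random split of a panmictic sample is near zero", {
  set.seed(5)
  p <- rbeta(300, 1, 1)
  m <- matrix(rbinom(300 * 60, 2, rep(p, 60)), nrow = 300)
  res <- amovaOneLevel(SnpGeno(m), rep(c("x", "y", "z"), each = 20),
                       n_perm = 99, seed = 3)
  expect_lt(res$percent_among, 2)
  expect_gt(res$p, 0.05)
})

test_that("heterozygosity trend models recover an exact linear gradient", {
  n <- 60
  km <- rep(seq(0, 17, length.out = 12), 5)
  pht <- 0.12 - 0.002 * km
  samples <- data.frame(individual_id = paste0("f", 1:n),
                        birth_year = rep(2016:2020, each = 12),
                        river_km = km,
                        age = rep(1:5, each = 12))
  het <- data.frame(id = paste0("f", 1:n), pht = pht, n_loci = 1000)
  mods <- suppressWarnings(diversityTrendModels(het, samples))  # exact fit
  expect_equal(unname(mods$LM2$coefficients["river_km"]), -0.002,
               tolerance = 1e-10)
  expect_equal(mods$LM2$adj_r_squared, 1, tolerance = 1e-8)
  expect_true(all(c("LM1a", "LM1b", "LM3", "LM4") %in% names(mods)))
  expect_true(is.matrix(mods$LM1b$tukey))
})

test_that("an upstream-declining breeder pool yields a negative PHt~km slope", {
  res <- vapply(1:6, function(r) {
    cfg <- simConfig(seed = 3000 + r, n_loci = 1500,
                     translocation_schedule = NULL)
    ped <- simulatePedigree(cfg)
    g <- dropGenotypes(ped)
    obs <- renderObservations(ped, cfg, geno = g)
    s <- obs$samples[!duplicated(obs$samples$individual_id), ]
    s$birth_year <- s$birth_year_true
    s$age <- s$age_true
    het <- individualHeterozygosity(g)
    m <- diversityTrendModels(het, s)
    c(slope = unname(m$LM2$coefficients["river_km"]),
      p = m$LM2$p[[1]])
  }, c(slope = 0, p = 0))
  # site-pool drift makes single realizations noisy; the signal must
  # dominate across replicates and never flip significantly positive
  expect_gte(sum(res["slope", ] < 0 & res["p", ] < 0.05), 4)
  expect_equal(sum(res["slope", ] > 0 & res["p", ] < 0.05), 0)
})
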