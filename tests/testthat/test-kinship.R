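test_that("a near-exact genotype copy is detected as a duplicate", {
  set.seed(41)
  m <- matrix(rbinom(400 * 20, 2, 0.4), nrow = 400)
  copy <- m[, 3]
  copy[sample(400, 20)] <- NA   # 5% of calls lost on recapture
  g <- SnpGeno(cbind(m, copy))
  res <- findDuplicates(g, min_match = 0.95)
  expect_equal(length(res$sets), 1)
  expect_setequal(res$sets[[1]],
                  c(sampleIds(g)[3], sampleIds(g)[21]))
})

test_that("full sibs are far less concordant than duplicates", {
  g <- sibPairs(50, 1000, "full", seed = 42)
  res <- findDuplicates(g, min_match = 0.995)
  expect_equal(length(res$sets), 0)
  m <- calls(g)
  i <- 1; j <- 2
  conc <- mean(m[, i] == m[, j])
  expect_lt(conc, 0.95)
})

test_that("pairs with too few comparable loci are excluded with a warning", {
  m <- matrix(rbinom(120 * 4, 2, 0.5), nrow = 120)
  m[1:80, 4] <- NA
  expect_warning(findDuplicates(SnpGeno(m), min_loci = 100),
                 "comparable loci")
  expect_error(findDuplicates(SnpGeno(m), min_match = 0.8),
               "min_match")
})

test_that("relatedness hits the expectation tiers for FS, HS and unrelated", {
  gf <- sibPairs(250, 2000, "full", seed = 43)
  rf <- pairwiseRelatedness(gf)$r
  idx <- cbind(seq(1, 499, 2), seq(2, 500, 2))
  expect_gt(mean(rf[idx]), 0.47)
  expect_lt(mean(rf[idx]), 0.53)
  expect_gt(min(diag(rf)), 0.9)

  gh <- sibPairs(250, 2000, "half", seed = 44)
  rh <- pairwiseRelatedness(gh)$r
  expect_gt(mean(rh[idx]), 0.22)
  expect_lt(mean(rh[idx]), 0.28)

  # non-paired individuals are unrelated: mean within +/-0.02 of zero
  ur <- rf
  ur[idx] <- NA; ur[idx[, 2:1]] <- NA
  diag(ur) <- NA
  expect_lt(abs(mean(ur, na.rm = TRUE)), 0.02)
})

test_that("monomorphic-only input refuses a relatedness estimate", {
  g <- SnpGeno(matrix(2L, 50, 6))
  expect_error(pairwiseRelatedness(g), "polymorphic")
})

test_that("a pair exactly at the threshold is included (closed threshold)", {
  r <- diag(4)
  r[1, 2] <- r[2, 1] <- 0.35
  r[3, 4] <- r[4, 3] <- 0.3499
  dimnames(r) <- list(letters[1:4], letters[1:4])
  rel <- structure(list(r = r, n_loci = matrix(1000, 4, 4)),
                   class = "RelatednessMatrix")
  fs <- clusterFullSibFamilies(rel, setNames(rep(2016, 4), letters[1:4]),
                               full_sib_min = 0.35, jitter_sd = 0,
                               n_replicates = 5, min_support = 3)
  fam <- fs$families
  expect_setequal(fam$member, c("a", "b"))
  expect_equal(length(unique(fam$family_id)), 1)
})

test_that("two disjoint simulated families are recovered exactly", {
  # build two 5-member families directly
  set.seed(46)
  p <- pmin(pmax(rbeta(2000, 0.5, 0.5), 0.01), 0.99)
  hw <- function() rbinom(2000, 1L, p) + rbinom(2000, 1L, p)
  gam <- function(g) {
    o <- integer(length(g)); o[g == 2L] <- 1L
    h <- g == 1L; o[h] <- rbinom(sum(h), 1L, 0.5); o
  }
  fam <- function() { d <- hw(); s <- hw()
    vapply(1:5, function(i) gam(d) + gam(s), integer(2000)) }
  # an unrelated background panel keeps allele frequencies estimable
  bg <- vapply(1:30, function(i) hw(), integer(2000))
  g <- SnpGeno(cbind(fam(), fam(), bg))
  rel <- pairwiseRelatedness(g)
  fs <- clusterFullSibFamilies(rel, setNames(rep(2016, 40),
                                             sampleIds(g)),
                               geno = g, seed = 3)
  fam_tab <- fs$families
  expect_equal(length(unique(fam_tab$family_id)), 2)
  split_ids <- split(fam_tab$member, fam_tab$family_id)
  expect_true(setequal(split_ids[[1]], sampleIds(g)[1:5]) ||
                setequal(split_ids[[1]], sampleIds(g)[6:10]))
  expect_setequal(unique(unlist(split_ids)), sampleIds(g)[1:10])
})

test_that("families spanning distant cohorts are flagged", {
  r <- diag(3)
  r[upper.tri(r)] <- 0.5; r[lower.tri(r)] <- 0.5
  dimnames(r) <- list(c("a", "b", "c"), c("a", "b", "c"))
  rel <- structure(list(r = r, n_loci = matrix(1000, 3, 3)),
                   class = "RelatednessMatrix")
  fs <- clusterFullSibFamilies(rel,
                               setNames(c(2016, 2016, 2019),
                                        c("a", "b", "c")),
                               jitter_sd = 0)
  expect_equal(length(fs$flagged), 1)
})

test_that("a true parent shows zero opposing homozygotes; unrelated candidates are rejected", {
  set.seed(47)
  L <- 2000
  p <- rep(0.3, L)
  hw <- function() rbinom(L, 1L, p) + rbinom(L, 1L, p)
  gam <- function(g) {
    o <- integer(length(g)); o[g == 2L] <- 1L
    h <- g == 1L; o[h] <- rbinom(sum(h), 1L, 0.5); o
  }
  dam <- hw(); sire <- hw(); unrel <- hw()
  off <- gam(dam) + gam(sire)
  offg <- SnpGeno(cbind(off), locusData = data.frame(
    locus_id = paste0("L", 1:L)))
  colnames(offg) <- "off1"
  cand <- SnpGeno(cbind(dam, unrel), locusData = data.frame(
    locus_id = paste0("L", 1:L)))
  res <- assignParentage(offg, cand, dropout = 0.01,
                         other_error = 0.001)
  expect_equal(res$parent, "dam")
  expect_equal(res$opposing_homozygotes, 0)
  # expected opposing-homozygote count for an unrelated candidate,
  # computed by brute force from the allele frequencies
  expected_oh <- sum(2 * p^2 * (1 - p)^2)
  oh_unrel <- sum((off == 0 & unrel == 2) | (off == 2 & unrel == 0))
  expect_gt(oh_unrel, 0.5 * expected_oh)
  expect_gt(oh_unrel, res$tolerance)
})

test_that("two offspring of one sampled parent are reported as half-sibs via it", {
  set.seed(48)
  L <- 2000
  p <- pmin(pmax(rbeta(L, 0.8, 0.8), 0.05), 0.95)
  hw <- function() rbinom(L, 1L, p) + rbinom(L, 1L, p)
  gam <- function(g) {
    o <- integer(length(g)); o[g == 2L] <- 1L
    h <- g == 1L; o[h] <- rbinom(sum(h), 1L, 0.5); o
  }
  shared <- hw()
  off1 <- gam(shared) + gam(hw())   # different unsampled second parents
  off2 <- gam(shared) + gam(hw())
  loc <- data.frame(locus_id = paste0("L", 1:L))
  offg <- SnpGeno(cbind(o1 = off1, o2 = off2), locusData = loc)
  cand <- SnpGeno(cbind(shared = shared, other = hw()),
                  locusData = loc)
  res <- assignParentage(offg, cand)
  expect_equal(res$parent, c("shared", "shared"))
})

test_that("parentage tolerance scales roughly linearly with locus count", {
  tols <- vapply(c(500, 1000, 2000), function(L) {
    qbinom(0.999, L, 0.011)
  }, 0)
  expect_gt(tols[2] / tols[1], 1.5)
  expect_lt(tols[2] / tols[1], 2.4)
  expect_gt(tols[3] / tols[2], 1.5)
  expect_lt(tols[3] / tols[2], 2.4)
})

test_that("full-sib vs half-sib log-likelihood ratio separates the truth", {
  gf <- sibPairs(40, 1500, "full", seed = 49)
  gh <- sibPairs(40, 1500, "half", seed = 50)
  lrf <- fullSibLogLR(gf)
  lrh <- fullSibLogLR(gh)
  idx <- cbind(seq(1, 79, 2), seq(2, 80, 2))
  expect_true(all(lrf[idx] > 0))
  expect_true(all(lrh[idx] < 0))
})
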