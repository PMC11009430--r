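.pairCounts <- function(m) {
  # number of pairwise-complete loci per pair of individuals
  M <- (!is.na(m)) * 1
  crossprod(M)
}

#' Detect duplicate genotypes (recaptures or identical twins)
#'
#' Pairs whose fraction of concordant calls over pairwise-complete loci is
#' at least \code{min_match} are merged into duplicate sets by transitive
#' closure. Pairs with fewer than \code{min_loci} comparable loci are
#' excluded with a warning.
#'
#' @param g a \linkS4class{SnpGeno}.
#' @param min_match concordance threshold, in (0.9, 1].
#' @param min_loci minimum comparable loci per pair (default 100).
#' @return list with \code{sets} (list of id vectors, one per duplicate
#'   set of size >= 2) and \code{pairs} (data.frame id1, id2,
#'   concordance, n_loci).
#' @export
findDuplicates <- function(g, min_match = 0.95, min_loci = 100) {
  stopifnot(is(g, "SnpGeno"))
  if (min_match <= 0.9 || min_match > 1)
    stop("min_match must lie in (0.9, 1]")
  m <- calls(g)
  n <- .pairCounts(m)
  eq <- matrix(0, ncol(m), ncol(m))
  for (v in 0:2) {
    Mv <- (!is.na(m) & m == v) * 1
    eq <- eq + crossprod(Mv)
  }
  conc <- eq / pmax(n, 1)
  ut <- which(upper.tri(conc), arr.ind = TRUE)
  few <- n[ut] < min_loci
  if (any(few))
    warning(sum(few), " pair(s) with < ", min_loci,
            " comparable loci excluded from duplicate detection")
  hit <- ut[!few & conc[ut] >= min_match, , drop = FALSE]
  ids <- colnames(m)
  pairs <- data.frame(id1 = ids[hit[, 1]], id2 = ids[hit[, 2]],
                      concordance = conc[hit],
                      n_loci = n[hit], row.names = NULL)
  sets <- list()
  if (nrow(pairs)) {
    gr <- igraph::graph_from_data_frame(pairs[, 1:2], directed = FALSE)
    cmp <- igraph::components(gr)
    sets <- split(names(cmp$membership), cmp$membership)
    names(sets) <- NULL
  }
  list(sets = sets, pairs = pairs)
}

#' Pairwise relatedness (allele-frequency-weighted estimator)
#'
#' A Queller-Goodnight-type moment estimator: with reference allele
#' frequencies p estimated from the sample,
#' r(i,j) = sum_l (x_il - 2 p_l)(x_jl - 2 p_l) / sum_l 2 p_l (1 - p_l)
#' over pairwise-complete loci. Expectation 0 for unrelated pairs, 0.25
#' for half-sibs, 0.5 for full-sibs and parent-offspring; the diagonal is
#' near 1 + F.
#'
#' @param g a \linkS4class{SnpGeno}.
#' @return list of class \code{RelatednessMatrix}: \code{r} (symmetric
#'   matrix), \code{n_loci} (comparable loci per pair); pairs with no
#'   shared loci are \code{NA}.
#' @export
pairwiseRelatedness <- function(g) {
  stopifnot(is(g, "SnpGeno"))
  ls <- locusSummary(g)
  poly <- !is.na(ls$maf) & ls$maf > 0
  if (!any(poly)) stop("no polymorphic loci; relatedness undefined")
  m <- calls(g)[poly, , drop = FALSE]
  p <- ls$p_alt[poly]
  w <- 2 * p * (1 - p)
  Z <- m - 2 * p           # recycled down columns (loci in rows)
  Z[is.na(m)] <- 0
  num <- crossprod(Z)
  M <- (!is.na(m)) * 1
  den <- crossprod(M * sqrt(w))  # sum of w over pairwise-complete loci
  n <- crossprod(M)
  r <- num / den
  r[n == 0] <- NA_real_
  out <- list(r = r, n_loci = n)
  class(out) <- "RelatednessMatrix"
  out
}

#' @export
print.RelatednessMatrix <- function(x, ...) {
  cat(sprintf("RelatednessMatrix: %d individuals\n", nrow(x$r)))
  off <- x$r[upper.tri(x$r)]
  cat(sprintf("  off-diagonal r: mean %.3f, range [%.3f, %.3f]\n",
              mean(off, na.rm = TRUE), min(off, na.rm = TRUE),
              max(off, na.rm = TRUE)))
  invisible(x)
}

#' Pairwise full-sib vs half-sib log-likelihood ratio
#'
#' For every pair of individuals, the log-likelihood ratio of the
#' full-sib hypothesis (IBD-sharing probabilities 1/4, 1/2, 1/4) against
#' the half-sib hypothesis (1/2, 1/2, 0), summed over pairwise-complete
#' loci under Hardy-Weinberg genotype probabilities at sample allele
#' frequencies. Positive values favour full sibs. With thousands of SNPs
#' the two hypotheses separate almost completely, which a scalar
#' relatedness threshold cannot do.
#'
#' @param g a \linkS4class{SnpGeno}.
#' @return symmetric matrix of log-likelihood ratios.
#' @export
fullSibLogLR <- function(g) {
  stopifnot(is(g, "SnpGeno"))
  ls <- locusSummary(g)
  poly <- !is.na(ls$maf) & ls$maf > 0
  m <- calls(g)[poly, , drop = FALSE]
  p <- pmin(pmax(ls$p_alt[poly], 1e-4), 1 - 1e-4)
  q <- 1 - p
  # genotype probabilities (HWE): 0, 1, 2 alt alleles
  P <- cbind(q^2, 2 * p * q, p^2)
  # T1[a+1][b+1] = P(g2 = b | g1 = a, share exactly one allele IBD):
  # the shared allele is a uniform draw from g1, the other a population
  # draw
  T1 <- list(
    list(q, p, rep(0, length(p))),                        # g1 = 0
    list(q / 2, 1 / 2, p / 2),                            # g1 = 1
    list(rep(0, length(p)), q, p))                        # g1 = 2
  lik <- function(k0, k1, k2, a, b) {
    k0 * P[, a + 1] * P[, b + 1] +
      k1 * P[, a + 1] * T1[[a + 1]][[b + 1]] +
      k2 * P[, a + 1] * (a == b)
  }
  n <- ncol(m)
  out <- matrix(0, n, n, dimnames = list(colnames(m), colnames(m)))
  Ib <- lapply(0:2, function(v) (!is.na(m) & m == v) * 1)
  for (a in 0:2) for (b in 0:2) {
    w <- log(pmax(lik(0.25, 0.5, 0.25, a, b), 1e-300)) -
      log(pmax(lik(0.5, 0.5, 0, a, b), 1e-300))
    out <- out + crossprod(Ib[[a + 1]] * w, Ib[[b + 1]])
  }
  (out + t(out)) / 2
}

.refineComponents <- function(memb, r, full_sib_min) {
  nxt <- max(memb) + 1L
  for (cm in unique(memb)) {
    idx <- which(memb == cm)
    if (length(idx) < 3) next
    rs <- r[idx, idx]
    rs[is.na(rs)] <- 0
    d <- stats::as.dist(pmax(0.5 - rs, 0))
    hc <- stats::hclust(d, method = "average")
    sub <- stats::cutree(hc, h = 0.5 - full_sib_min)
    if (max(sub) > 1) {
      for (s in unique(sub)) {
        memb[idx[sub == s]] <- nxt
        nxt <- nxt + 1L
      }
    }
  }
  memb
}

.componentsAtThreshold <- function(r, threshold) {
  adj <- !is.na(r) & r >= threshold   # closed threshold: ties included
  diag(adj) <- FALSE
  gr <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  igraph::components(gr)$membership
}

#' Cluster full-sib families from a relatedness matrix
#'
#' Builds a graph with edges where relatedness is at or above
#' \code{full_sib_min} (closed threshold) and takes connected components
#' as full-sib families. Replicate runs jitter the threshold and, when
#' the genotypes are supplied, recompute relatedness on a seeded random
#' subsample of loci; a pair's assignment is kept when it is found in at
#' least \code{min_support} of \code{n_replicates} runs. Connected
#' components are then refined by average-linkage clustering at the same
#' threshold, so a single noisy edge cannot chain two half-sib families
#' into one. Families are
#' annotated with their modal cohort; components mixing cohorts more than
#' one year apart are flagged (they may represent other relationships,
#' e.g. parent-offspring).
#'
#' @param rel a \code{RelatednessMatrix}.
#' @param cohorts named vector: cohort (birth year) per individual.
#' @param full_sib_min full-sib edge threshold (default 0.35).
#' @param half_sib_band lower edge of the half-sib band, below
#'   \code{full_sib_min} (default 0.15; reported, not clustered).
#' @param n_replicates number of replicate runs (default 5).
#' @param min_support minimum replicates supporting a pair (default 3).
#' @param jitter_sd SD of the threshold jitter across replicates.
#' @param geno optional \linkS4class{SnpGeno}; when given, each replicate
#'   recomputes relatedness on a random \code{subsample_frac} of loci,
#'   and edges must additionally pass the full-sib vs half-sib
#'   log-likelihood-ratio screen (\code{\link{fullSibLogLR}} > 0), which
#'   prevents strong half-sib pairs from bridging two true families.
#' @param subsample_frac locus fraction per replicate (default 0.8).
#' @param seed seed for the replicate jitters and subsamples.
#' @return a \code{FamilySet}: \code{families} data.frame (family_id,
#'   member, cohort, support = mean pair support within the family),
#'   \code{flagged} family ids spanning distant cohorts, plus the edge
#'   table.
#' @export
clusterFullSibFamilies <- function(rel, cohorts, full_sib_min = 0.35,
                                   half_sib_band = 0.15,
                                   n_replicates = 5, min_support = 3,
                                   jitter_sd = 0.02, geno = NULL,
                                   subsample_frac = 0.8, seed = 1L) {
  stopifnot(inherits(rel, "RelatednessMatrix"))
  if (half_sib_band >= full_sib_min)
    stop("half_sib_band must lie below full_sib_min")
  r <- rel$r
  ids <- colnames(r)
  set.seed(seed)
  support <- matrix(0L, nrow(r), ncol(r))
  for (k in seq_len(n_replicates)) {
    thr <- full_sib_min + stats::rnorm(1, 0, jitter_sd)
    rk <- r
    if (!is.null(geno)) {
      sub <- sort(sample(nrow(geno), round(subsample_frac * nrow(geno))))
      rk <- pairwiseRelatedness(geno[sub, ])$r
    }
    memb <- .componentsAtThreshold(rk, thr)
    same <- outer(memb, memb, "==")
    support <- support + (same & !is.na(rk) & rk >= half_sib_band)
  }
  base <- !is.na(r) & r >= full_sib_min & support >= min_support
  if (!is.null(geno)) base <- base & fullSibLogLR(geno) > 0
  diag(base) <- FALSE
  gr <- igraph::graph_from_adjacency_matrix(base, mode = "undirected")
  memb <- igraph::components(gr)$membership
  # single-linkage components can chain two half-sib families through
  # one noisy edge; refine each component by average linkage at the
  # same threshold (cross-family mean r sits near the half-sib tier)
  memb <- .refineComponents(memb, r, full_sib_min)
  fam <- split(ids, memb)
  fam <- fam[vapply(fam, length, 0L) >= 2]
  if (length(fam)) {
    ord <- order(-vapply(fam, length, 0L))
    fam <- fam[ord]
  }
  rows <- list(); flagged <- character()
  for (i in seq_along(fam)) {
    members <- fam[[i]]
    fid <- sprintf("F%03d", i)
    co <- cohorts[members]
    idx <- match(members, ids)
    sup <- support[idx, idx]
    rows[[i]] <- data.frame(
      family_id = fid, member = members,
      cohort = unname(co),
      support = mean(sup[upper.tri(sup)]) / n_replicates,
      stringsAsFactors = FALSE)
    known <- co[!is.na(co)]
    if (length(known) && diff(range(known)) > 1)
      flagged <- c(flagged, fid)
  }
  families <- if (length(rows)) do.call(rbind, rows) else
    data.frame(family_id = character(), member = character(),
               cohort = integer(), support = numeric())
  if (nrow(families)) {
    modal <- vapply(split(families$cohort, families$family_id),
                    function(co) {
                      co <- co[!is.na(co)]
                      if (!length(co)) return(NA_real_)
                      as.numeric(names(sort(-table(co)))[1])
                    }, 0)
    families$modal_cohort <- modal[families$family_id]
  }
  out <- list(families = families, flagged = flagged,
              duplicates = list(),
              parentage = data.frame(offspring = character(),
                                     parent = character()),
              n_offspring = length(ids),
              thresholds = c(full_sib_min = full_sib_min,
                             half_sib_band = half_sib_band))
  class(out) <- "FamilySet"
  out
}

#' Exclusion-based parentage assignment
#'
#' For each offspring-candidate pair, counts opposing-homozygote loci
#' (offspring 0 with candidate 2 or vice versa) over comparable loci. A
#' candidate is accepted as a parent when the count does not exceed the
#' binomial tolerance implied by the genotyping error model (allelic
#' dropout + other error) at that pair's locus count; among accepted
#' candidates the minimal-count one wins. Offspring with no accepted
#' candidate are reported with an unsampled parent.
#'
#' @param offspring a \linkS4class{SnpGeno} of potential offspring.
#' @param candidates a \linkS4class{SnpGeno} of candidate parents
#'   (same loci).
#' @param dropout allelic dropout rate, in [0, 0.1].
#' @param other_error other genotyping error rate, in [0, 0.1].
#' @param conf upper-tail probability bounding the tolerance
#'   (default 0.999).
#' @return data.frame: offspring, parent (NA if unsampled),
#'   opposing_homozygotes, n_loci, tolerance.
#' @export
assignParentage <- function(offspring, candidates, dropout = 0.01,
                            other_error = 0.001, conf = 0.999) {
  stopifnot(is(offspring, "SnpGeno"), is(candidates, "SnpGeno"))
  if (dropout < 0 || dropout > 0.1 || other_error < 0 ||
      other_error > 0.1)
    stop("error rates must lie in [0, 0.1]")
  shared <- intersect(locusData(offspring)$locus_id,
                      locusData(candidates)$locus_id)
  if (!length(shared)) stop("offspring and candidates share no loci")
  mo <- calls(offspring)[shared, , drop = FALSE]
  mc <- calls(candidates)[shared, , drop = FALSE]
  O0 <- (!is.na(mo) & mo == 0L) * 1; O2 <- (!is.na(mo) & mo == 2L) * 1
  C0 <- (!is.na(mc) & mc == 0L) * 1; C2 <- (!is.na(mc) & mc == 2L) * 1
  oh <- t(O0) %*% C2 + t(O2) %*% C0      # offspring x candidate
  n <- t((!is.na(mo)) * 1) %*% ((!is.na(mc)) * 1)
  O1 <- (!is.na(mo) & mo == 1L) * 1; C1 <- (!is.na(mc) & mc == 1L) * 1
  conc <- (t(O0) %*% C0 + t(O1) %*% C1 + t(O2) %*% C2) / pmax(n, 1)
  err <- dropout + other_error
  rows <- lapply(seq_len(ncol(mo)), function(i) {
    cand_oh <- oh[i, ]
    cand_n <- n[i, ]
    tol <- stats::qbinom(conf, cand_n, err)
    # a duplicate of the offspring (same id or same genotype) is not a parent
    same <- colnames(mc) == colnames(mo)[i] | conc[i, ] >= 0.995
    ok <- which(cand_oh <= tol & !same)
    if (length(ok)) {
      best <- ok[which.min(cand_oh[ok])]
      data.frame(offspring = colnames(mo)[i],
                 parent = colnames(mc)[best],
                 opposing_homozygotes = unname(cand_oh[best]),
                 n_loci = unname(cand_n[best]),
                 tolerance = unname(tol[best]),
                 stringsAsFactors = FALSE)
    } else
      data.frame(offspring = colnames(mo)[i], parent = NA_character_,
                 opposing_homozygotes = unname(min(cand_oh)),
                 n_loci = unname(cand_n[which.min(cand_oh)]),
                 tolerance = unname(tol[which.min(cand_oh)]),
                 stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
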