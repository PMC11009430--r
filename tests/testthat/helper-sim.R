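# Shared builders for small genotype fixtures and truth extraction.

tinyGeno <- function(m, ...) {
  SnpGeno(m, ...)
}

# gene-drop n_pairs sib pairs of a given relationship from fresh parents
# at Beta-distributed allele frequencies; returns a SnpGeno of 2*n_pairs
# columns ordered pair-wise
sibPairs <- function(n_pairs, n_loci, relationship = c("full", "half"),
                     seed = 1) {
  relationship <- match.arg(relationship)
  set.seed(seed)
  p <- rbeta(n_loci, 0.5, 0.5)
  p <- pmin(pmax(p, 0.01), 0.99)
  hw <- function() rbinom(n_loci, 1L, p) + rbinom(n_loci, 1L, p)
  gam <- function(g) {
    o <- integer(length(g)); o[g == 2L] <- 1L
    h <- g == 1L
    o[h] <- rbinom(sum(h), 1L, 0.5)
    o
  }
  cols <- vector("list", 2 * n_pairs)
  for (i in seq_len(n_pairs)) {
    d1 <- hw(); s1 <- hw()
    cols[[2 * i - 1]] <- gam(d1) + gam(s1)
    if (relationship == "full")
      cols[[2 * i]] <- gam(d1) + gam(s1)
    else
      cols[[2 * i]] <- gam(d1) + gam(hw())  # shared dam only
  }
  SnpGeno(do.call(cbind, cols))
}

# truth full-sib pair indicator matrices for a pedigree's offspring
truthPairs <- function(pedigree, ids) {
  sub <- pedigree$individuals[match(ids, pedigree$individuals$id), ]
  same_dam <- outer(sub$dam, sub$dam, "==")
  same_sire <- outer(sub$sire, sub$sire, "==")
  list(fs = same_dam & same_sire,
       hs = xor(same_dam, same_sire),
       ut = upper.tri(same_dam))
}

# pairwise precision/recall of a clustering against truth full-sib pairs
familyPairScores <- function(famset, pedigree, ids) {
  tp_ <- truthPairs(pedigree, ids)
  memb <- setNames(famset$families$family_id, famset$families$member)
  pred <- outer(memb[ids], memb[ids],
                function(a, b) !is.na(a) & !is.na(b) & a == b)
  ut <- tp_$ut
  tp <- sum(pred[ut] & tp_$fs[ut])
  fp <- sum(pred[ut] & !tp_$fs[ut])
  fn <- sum(!pred[ut] & tp_$fs[ut])
  c(precision = tp / max(tp + fp, 1), recall = tp / max(tp + fn, 1))
}
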