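#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @import SummarizedExperiment
NULL

#' SnpGeno: biallelic SNP genotypes with locus and sample metadata
#'
#' The central genotype container: a
#' \linkS4class{SummarizedExperiment} whose single assay \code{"calls"}
#' holds counts of the alternate allele (0, 1, 2 or \code{NA} for a missing
#' call), with loci in rows and individuals in columns. \code{rowData}
#' carries per-locus metadata (\code{locus_id}, \code{tag_id},
#' \code{reproducibility} and optionally \code{info_score}); \code{colData}
#' carries per-individual sample metadata.
#'
#' @slot ... inherited from \code{SummarizedExperiment}.
#' @aliases SnpGeno-class
#' @exportClass SnpGeno
setClass("SnpGeno", contains = "SummarizedExperiment")

.validSnpGeno <- function(object) {
  msg <- NULL
  if (!("calls" %in% assayNames(object)))
    msg <- c(msg, "assay 'calls' is required")
  else {
    m <- assay(object, "calls")
    v <- m[!is.na(m)]
    if (length(v) && !all(v %in% c(0L, 1L, 2L)))
      msg <- c(msg, "calls must be 0, 1, 2 or NA")
  }
  rd <- rowData(object)
  for (col in c("locus_id", "tag_id", "reproducibility"))
    if (!(col %in% colnames(rd)))
      msg <- c(msg, sprintf("rowData column '%s' is required", col))
  if ("locus_id" %in% colnames(rd) && anyDuplicated(rd$locus_id))
    msg <- c(msg, "locus_id values must be unique")
  if (ncol(object) && anyDuplicated(colnames(object)))
    msg <- c(msg, "sample ids must be unique")
  if ("reproducibility" %in% colnames(rd)) {
    rp <- rd$reproducibility
    if (any(rp < 0 | rp > 1, na.rm = TRUE))
      msg <- c(msg, "reproducibility must lie in [0, 1]")
  }
  if (is.null(msg)) TRUE else msg
}
setValidity("SnpGeno", .validSnpGeno)

#' Construct a SnpGeno object
#'
#' @param calls integer matrix of alternate-allele counts (loci x samples),
#'   entries 0/1/2/NA.
#' @param locusData data.frame of per-locus metadata. Must contain
#'   \code{locus_id}; \code{tag_id} defaults to \code{locus_id} and
#'   \code{reproducibility} to 1 when absent.
#' @param sampleData optional data.frame of per-sample metadata (one row per
#'   column of \code{calls}).
#' @return A \linkS4class{SnpGeno}.
#' @examples
#' g <- SnpGeno(matrix(c(0L, 1L, 2L, NA), 2, 2,
#'                     dimnames = list(NULL, c("s1", "s2"))),
#'              locusData = data.frame(locus_id = c("L1", "L2")))
#' nLoci(g)
#' @export
SnpGeno <- function(calls, locusData = NULL, sampleData = NULL) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (is.null(locusData))
    locusData <- data.frame(locus_id = paste0("L", seq_len(nrow(calls))))
  locusData <- as.data.frame(locusData)
  if (is.null(locusData$locus_id))
    locusData$locus_id <- paste0("L", seq_len(nrow(calls)))
  if (is.null(locusData$tag_id)) locusData$tag_id <- locusData$locus_id
  if (is.null(locusData$reproducibility)) locusData$reproducibility <- 1
  cn <- colnames(calls)
  if (is.null(cn) || any(is.na(cn) | cn == ""))
    colnames(calls) <- paste0("ind_", seq_len(ncol(calls)))
  rownames(calls) <- locusData$locus_id
  if (is.null(sampleData))
    sampleData <- DataFrame(row.names = colnames(calls))
  else {
    sampleData <- DataFrame(sampleData)
    rownames(sampleData) <- colnames(calls)
  }
  se <- SummarizedExperiment(assays = list(calls = calls),
                             rowData = DataFrame(locusData),
                             colData = sampleData)
  new("SnpGeno", se)
}

#' @describeIn SnpGeno genotype call matrix (loci x samples).
#' @param x,object a \code{SnpGeno}.
#' @export
calls <- function(x) assay(x, "calls")

#' @describeIn SnpGeno per-locus metadata as a data.frame.
#' @export
locusData <- function(x) as.data.frame(rowData(x))

#' @describeIn SnpGeno number of loci.
#' @export
nLoci <- function(x) nrow(x)

#' @describeIn SnpGeno number of individuals.
#' @export
nSamples <- function(x) ncol(x)

#' @describeIn SnpGeno sample identifiers.
#' @export
sampleIds <- function(x) colnames(x)

#' Per-locus summaries of a genotype matrix
#'
#' Call rate, allele frequency and minor-allele frequency per locus,
#' computed over non-missing calls.
#'
#' @param x a \code{SnpGeno}.
#' @return data.frame with \code{locus_id}, \code{call_rate}, \code{p_alt},
#'   \code{maf} and \code{n_called}.
#' @export
locusSummary <- function(x) {
  m <- calls(x)
  n_called <- rowSums(!is.na(m))
  p_alt <- rowSums(m, na.rm = TRUE) / (2 * pmax(n_called, 1L))
  p_alt[n_called == 0] <- NA_real_
  data.frame(locus_id = locusData(x)$locus_id,
             call_rate = n_called / ncol(m),
             p_alt = p_alt,
             maf = pmin(p_alt, 1 - p_alt),
             n_called = n_called,
             row.names = NULL)
}

setMethod("show", "SnpGeno", function(object) {
  cat(sprintf("SnpGeno: %d loci x %d individuals\n",
              nrow(object), ncol(object)))
  m <- assay(object, "calls")
  cat(sprintf("  missing calls: %.2f%%\n", 100 * mean(is.na(m))))
  pops <- colData(object)$population
  if (!is.null(pops))
    cat("  populations:",
        paste(sprintf("%s (%d)", names(table(pops)), table(pops)),
              collapse = ", "), "\n")
  invisible(NULL)
})

#' Life-history parameters for effective-size adjustment
#'
#' Adult life span (AL) and age at maturity (alpha), in years. These drive
#' the adjustment of single-cohort LD estimates to the effective number of
#' breeders per reproductive cycle and the per-generation effective size.
#' Defaults are the Macquarie perch values: AL = 23, alpha = 3.
#'
#' @slot AL adult life span, years.
#' @slot alpha age at maturity, years.
#' @aliases LifeHistory-class
#' @exportClass LifeHistory
setClass("LifeHistory", representation(AL = "numeric", alpha = "numeric"))

setValidity("LifeHistory", function(object) {
  if (object@alpha < 1) return("alpha must be >= 1")
  if (object@AL <= object@alpha) return("AL must exceed alpha")
  TRUE
})

#' @param AL adult life span in years.
#' @param alpha age at maturity in years.
#' @rdname LifeHistory-class
#' @export
lifeHistory <- function(AL = 23, alpha = 3) new("LifeHistory", AL = AL, alpha = alpha)

#' Single-cohort effective-number-of-breeders estimate
#'
#' Result container for the LD and sibship-frequency estimators, before and
#' after life-history adjustment. Point estimates and interval endpoints may
#' be \code{Inf} (no detectable drift signal).
#'
#' @slot method "LD" or "sibship".
#' @slot nbHat raw point estimate.
#' @slot ci length-2 numeric, confidence interval.
#' @slot S harmonic-mean sample size (LD) or number of offspring (sibship).
#' @slot pCrit minor-allele-frequency cutoff used (LD; NA for sibship).
#' @slot nPairs number of locus pairs (LD) or dyads (sibship).
#' @slot r2 weighted mean r-squared (LD) or sib-dyad frequency Q-hat (sibship).
#' @slot nbAdj adjusted effective number of breeders (NA until adjusted).
#' @slot neAdj adjusted per-generation effective size.
#' @slot nbAdjCi,neAdjCi adjusted interval endpoints.
#' @slot divisors named numeric: adjustment divisor and Nb/Ne ratio used.
#' @aliases NbEstimate-class
#' @exportClass NbEstimate
setClass("NbEstimate",
         representation(method = "character", nbHat = "numeric",
                        ci = "numeric", S = "numeric", pCrit = "numeric",
                        nPairs = "numeric", r2 = "numeric",
                        nbAdj = "numeric", neAdj = "numeric",
                        nbAdjCi = "numeric", neAdjCi = "numeric",
                        divisors = "numeric"),
         prototype(nbAdj = NA_real_, neAdj = NA_real_,
                   nbAdjCi = c(NA_real_, NA_real_),
                   neAdjCi = c(NA_real_, NA_real_),
                   divisors = c(divisor_b = NA_real_, ratio = NA_real_)))

setValidity("NbEstimate", function(object) {
  if (!object@method %in% c("LD", "sibship"))
    return("method must be 'LD' or 'sibship'")
  if (length(object@ci) != 2) return("ci must have two endpoints")
  if (is.finite(object@nbHat) && object@nbHat <= 0)
    return("a finite Nb estimate must be positive")
  TRUE
})

.fmtNb <- function(x) ifelse(is.finite(x), sprintf("%.1f", x), "Inf")

setMethod("show", "NbEstimate", function(object) {
  cat(sprintf("NbEstimate (%s method)\n", object@method))
  cat(sprintf("  Nb_hat = %s  [%s, %s]\n", .fmtNb(object@nbHat),
              .fmtNb(object@ci[1]), .fmtNb(object@ci[2])))
  if (object@method == "LD")
    cat(sprintf("  S = %.1f, P_crit = %s, locus pairs = %d\n", object@S,
                format(object@pCrit), as.integer(object@nPairs)))
  if (!is.na(object@nbAdj))
    cat(sprintf("  adjusted: Nb_adj = %s, Ne_adj = %s (divisor %.4f, ratio %.3f)\n",
                .fmtNb(object@nbAdj), .fmtNb(object@neAdj),
                object@divisors[["divisor_b"]], object@divisors[["ratio"]]))
  invisible(NULL)
})

#' Genetic-rescue plan
#'
#' Output of the migrant-number planning calculus: population inbreeding
#' estimated from the heterozygosity ratio against an assumed-outbred
#' source, the migrant fraction needed to reach the target inbreeding, and
#' the effective and census migrant numbers.
#'
#' @slot phtTarget,phtSource mean proportion of heterozygous loci per
#'   individual (PHt) in the recipient and source populations.
#' @slot fCurrent current population inbreeding coefficient.
#' @slot fTarget target inbreeding coefficient.
#' @slot migrantFraction fraction of the augmented population that must
#'   derive from migrants.
#' @slot nbBase effective breeder base of the recipient population.
#' @slot nmEffective effective migrants needed (rounded).
#' @slot neOverN effective-to-census ratio used for census scaling (NA if
#'   not requested).
#' @slot nmCensus census migrants needed (NA if no ratio supplied).
#' @aliases RescuePlan-class
#' @exportClass RescuePlan
setClass("RescuePlan",
         representation(phtTarget = "numeric", phtSource = "numeric",
                        fCurrent = "numeric", fTarget = "numeric",
                        migrantFraction = "numeric", nbBase = "numeric",
                        nmEffective = "numeric", neOverN = "numeric",
                        nmCensus = "numeric"))

setValidity("RescuePlan", function(object) {
  if (object@fCurrent < 0 || object@fCurrent >= 1)
    return("fCurrent must lie in [0, 1)")
  if (object@fTarget < 0 || object@fTarget >= 1)
    return("fTarget must lie in [0, 1)")
  if (object@nbBase <= 0) return("nbBase must be positive")
  TRUE
})

setMethod("show", "RescuePlan", function(object) {
  cat("RescuePlan\n")
  cat(sprintf("  PHt: target %.3f, source %.3f -> F_current = %.3f\n",
              object@phtTarget, object@phtSource, object@fCurrent))
  cat(sprintf("  F_target = %.3f -> migrant fraction f = %.3f\n",
              object@fTarget, object@migrantFraction))
  cat(sprintf("  breeder base Nb = %.1f -> %d effective migrants\n",
              object@nbBase, as.integer(object@nmEffective)))
  if (is.finite(object@nmCensus))
    cat(sprintf("  at Ne/N = %.2f -> %d census migrants\n",
                object@neOverN, as.integer(object@nmCensus)))
  invisible(NULL)
})
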