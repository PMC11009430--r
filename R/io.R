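#' Read a genotype matrix from VCF or CSV
#'
#' VCF input is parsed with \pkg{vcfR}; only biallelic records are
#' accepted (a multiallelic site aborts with the offending site named).
#' Genotypes are taken from the GT field and encoded as alternate-allele
#' counts; \code{"./."} becomes a missing call. CSV input expects a calls
#' matrix (rows = loci, first column \code{locus_id}, remaining columns =
#' samples, entries 0/1/2 or empty/NA) plus an optional locus-metadata CSV
#' with columns \code{locus_id}, \code{tag_id}, \code{reproducibility},
#' \code{info_score}.
#'
#' @param path file to read.
#' @param format "vcf" or "csv".
#' @param locus_meta optional path to the locus-metadata CSV (csv format
#'   only).
#' @return a \linkS4class{SnpGeno}; sample order as in the file.
#' @export
readGenotypes <- function(path, format = c("vcf", "csv"),
                          locus_meta = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "vcf") {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(v)
    if (is.null(dim(fix)))          # single-record file
      fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
    multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
    if (any(multi))
      stop("multiallelic site(s) not supported: ",
           paste(fix[multi, "CHROM"], fix[multi, "POS"],
                 sep = ":", collapse = ", "))
    gt <- vcfR::extract.gt(v, element = "GT")
    num <- matrix(NA_integer_, nrow(gt), ncol(gt),
                  dimnames = dimnames(gt))
    clean <- gsub("\\|", "/", gt)
    num[clean == "0/0"] <- 0L
    num[clean %in% c("0/1", "1/0")] <- 1L
    num[clean == "1/1"] <- 2L
    bad <- !is.na(clean) & !clean %in% c("0/0", "0/1", "1/0", "1/1",
                                         "./.")
    if (any(bad))
      stop("unparseable GT value(s): ",
           paste(unique(clean[bad]), collapse = ", "))
    ids <- if (!all(is.na(fix[, "ID"])) && !anyDuplicated(fix[, "ID"]))
      fix[, "ID"] else paste(fix[, "CHROM"], fix[, "POS"], sep = "_")
    if (anyDuplicated(colnames(gt)))
      stop("duplicate sample id(s): ",
           paste(unique(colnames(gt)[duplicated(colnames(gt))]),
                 collapse = ", "))
    return(SnpGeno(num, locusData = data.frame(locus_id = ids)))
  }
  df <- utils::read.csv(path, check.names = FALSE,
                        stringsAsFactors = FALSE)
  if (colnames(df)[1] != "locus_id")
    stop("csv genotypes must have 'locus_id' as the first column")
  if (anyDuplicated(colnames(df)[-1]))
    stop("duplicate sample id(s): ",
         paste(unique(colnames(df)[-1][duplicated(colnames(df)[-1])]),
               collapse = ", "))
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  bad <- which(!is.na(m) & !(m %in% 0:2), arr.ind = TRUE)
  if (nrow(bad))
    stop("invalid genotype call at data line ", bad[1, 1] + 1L,
         " (locus ", df$locus_id[bad[1, 1]], ")")
  meta <- data.frame(locus_id = df$locus_id)
  if (!is.null(locus_meta)) {
    lm_df <- utils::read.csv(locus_meta, stringsAsFactors = FALSE)
    meta <- merge(meta, lm_df, by = "locus_id", sort = FALSE)
    meta <- meta[match(df$locus_id, meta$locus_id), , drop = FALSE]
  }
  SnpGeno(m, locusData = meta)
}

#' Write genotypes as a plain-text VCF
#'
#' Minimal biallelic VCF (GT field only, \code{"./."} for missing calls),
#' written uncompressed so artifacts stay diffable.
#'
#' @param g a \linkS4class{SnpGeno}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeGenotypesVcf <- function(g, path) {
  m <- calls(g)
  gt <- matrix("./.", nrow(m), ncol(m))
  gt[!is.na(m) & m == 0L] <- "0/0"
  gt[!is.na(m) & m == 1L] <- "0/1"
  gt[!is.na(m) & m == 2L] <- "1/1"
  hdr <- c("##fileformat=VCFv4.2",
           "##source=genrescue",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", sampleIds(g)), collapse = "\t"))
  body <- paste("1", seq_len(nrow(m)), locusData(g)$locus_id, "A", "G",
                ".", "PASS", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write genotypes as a CSV matrix plus locus metadata
#'
#' @param g a \linkS4class{SnpGeno}.
#' @param path calls-matrix CSV path.
#' @param meta_path optional locus-metadata CSV path.
#' @return \code{path}, invisibly.
#' @export
writeGenotypesCsv <- function(g, path, meta_path = NULL) {
  df <- data.frame(locus_id = locusData(g)$locus_id, calls(g),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  if (!is.null(meta_path)) {
    keep <- intersect(c("locus_id", "tag_id", "reproducibility",
                        "info_score"), colnames(locusData(g)))
    utils::write.csv(locusData(g)[, keep, drop = FALSE], meta_path,
                     row.names = FALSE)
  }
  invisible(path)
}

#' Write the simulator outputs of one run to a directory
#'
#' Emits plain-text artifacts: genotypes as VCF and CSV, the sample table
#' and pedigree truth tables as TSV, the flow series as TSV, and the
#' configuration as YAML.
#'
#' @param pedigree a \code{PedigreeTruth}.
#' @param geno a \linkS4class{SnpGeno}.
#' @param obs output of \code{\link{renderObservations}}.
#' @param dir output directory (created if absent).
#' @return \code{dir}, invisibly.
#' @export
writeSimulation <- function(pedigree, geno, obs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeGenotypesVcf(geno, file.path(dir, "genotypes.vcf"))
  writeGenotypesCsv(geno, file.path(dir, "genotypes.csv"),
                    file.path(dir, "locus_meta.csv"))
  utils::write.table(obs$samples, file.path(dir, "samples.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(obs$flow, file.path(dir, "flow.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(pedigree$individuals,
                     file.path(dir, "pedigree_truth.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(pedigree$breeders,
                     file.path(dir, "breeders_truth.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  cfg <- pedigree$config
  cfg$sites <- as.list(cfg$sites)
  cfg$translocation_schedule <- as.list(cfg$translocation_schedule)
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(dir)
}
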