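#' GenotypeSet: integer-coded SNP calls for a set of samples
#'
#' A thin extension of [SummarizedExperiment::SummarizedExperiment] holding
#' one assay, `"calls"`, an integer matrix with SNPs as rows and samples as
#' columns. Calls use the coding `2 = AA`, `1 = AB`, `0 = BB`, `9 = missing`,
#' which all downstream modules (parentage, duplicate strings, sex check,
#' breed composition) share. `rowData` carries the SNP map (chromosome,
#' position, panel membership, PAR flag, cluster quality); `colData` carries
#' per-sample provenance (animal id, chip, dates) and QC state.
#'
#' @details Required `rowData` columns: `chromosome` (one of 1..29, X, Y,
#' MT), `position_bp` (positive integer, 1-based), `in_icbf800`,
#' `in_isag100`, `in_isag200`, `is_par`, `cluster_ok` (logical). `is_par`
#' may only be `TRUE` on chromosome X. Required `colData` columns:
#' `animal_id`; optional: `chip_name`, `sample_collection_date`,
#' `genotyping_date`, `valid` (one of valid/invalid/flagged/unresolved).
#'
#' @export
setClass("GenotypeSet", contains = "SummarizedExperiment")

CHROM_LEVELS <- c(as.character(1:29), "X", "Y", "MT")
VALID_STATES <- c("valid", "invalid", "flagged", "unresolved")
SNPMAP_COLS <- c("chromosome", "position_bp", "in_icbf800", "in_isag100",
                 "in_isag200", "is_par", "cluster_ok")

setValidity("GenotypeSet", function(object) {
  msg <- character()
  if (!"calls" %in% SummarizedExperiment::assayNames(object))
    return("assay 'calls' is required")
  m <- SummarizedExperiment::assay(object, "calls")
  if (!is.integer(m))
    msg <- c(msg, "assay 'calls' must be an integer matrix")
  bad <- m[!m %in% c(0L, 1L, 2L, 9L)]
  if (length(bad))
    msg <- c(msg, sprintf("calls outside {0,1,2,9}: first offending value %s",
                          bad[[1L]]))
  rd <- SummarizedExperiment::rowData(object)
  miss <- setdiff(SNPMAP_COLS, colnames(rd))
  if (length(miss))
    msg <- c(msg, paste0("rowData lacks column(s): ",
                         paste(miss, collapse = ", ")))
  if (all(c("chromosome", "is_par") %in% colnames(rd))) {
    if (!all(rd$chromosome %in% CHROM_LEVELS))
      msg <- c(msg, "unknown chromosome label in rowData")
    if (any(rd$is_par & rd$chromosome != "X"))
      msg <- c(msg, "is_par=TRUE on a non-X chromosome")
  }
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "duplicated snp_id in rownames")
  if (!"animal_id" %in% colnames(SummarizedExperiment::colData(object)))
    msg <- c(msg, "colData lacks column 'animal_id'")
  if (length(msg)) msg else TRUE
})

#' Construct a GenotypeSet
#'
#' @param calls integer matrix, SNPs x samples, values in \{0,1,2,9\};
#'   rownames are snp ids, colnames are sample ids.
#' @param snpMap data.frame or DataFrame of SNP metadata, one row per SNP
#'   in the same order as `calls` (see [GenotypeSet-class] for the
#'   required columns). If it has a `snp_id` column it is matched against
#'   `rownames(calls)`.
#' @param sampleData data.frame or DataFrame of per-sample metadata with at
#'   least `animal_id`; defaults to `animal_id == sample_id`.
#' @return A [GenotypeSet-class] object.
#' @examples
#' m <- matrix(c(2L, 1L, 0L, 9L), 2, 2,
#'             dimnames = list(c("s1", "s2"), c("a", "b")))
#' gs <- GenotypeSet(m, exampleSnpMap(2))
#' calls(gs)
#' @export
GenotypeSet <- function(calls, snpMap, sampleData = NULL) {
  if (!is.matrix(calls)) stop("'calls' must be a matrix")
  storage.mode(calls) <- "integer"
  snpMap <- S4Vectors::DataFrame(snpMap)
  if ("snp_id" %in% colnames(snpMap)) {
    if (is.null(rownames(calls))) rownames(calls) <- snpMap$snp_id
    if (!identical(as.character(snpMap$snp_id), rownames(calls)))
      stop("snpMap$snp_id does not match rownames(calls)")
    snpMap$snp_id <- NULL
  }
  rownames(snpMap) <- rownames(calls)
  if (is.null(sampleData)) {
    ids <- colnames(calls)
    if (is.null(ids)) ids <- character(0)
    sampleData <- S4Vectors::DataFrame(animal_id = ids, row.names = ids)
  } else {
    sampleData <- S4Vectors::DataFrame(sampleData)
    if (is.null(rownames(sampleData)) && "sample_id" %in% colnames(sampleData))
      rownames(sampleData) <- sampleData$sample_id
  }
  if (!"valid" %in% colnames(sampleData))
    sampleData$valid <- rep("valid", ncol(calls))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(calls = calls), rowData = snpMap, colData = sampleData)
  new("GenotypeSet", se)
}

#' @describeIn GenotypeSet integer call matrix (SNPs x samples)
#' @param x a GenotypeSet
#' @param ... unused
#' @export
setMethod("calls", "GenotypeSet", function(x, ...)
  SummarizedExperiment::assay(x, "calls"))

#' @describeIn GenotypeSet SNP map as a DataFrame (rowData)
#' @export
setMethod("snpMap", "GenotypeSet", function(x, ...)
  SummarizedExperiment::rowData(x))

#' @describeIn GenotypeSet per-sample metadata (colData)
#' @export
setMethod("sampleInfo", "GenotypeSet", function(x, ...)
  SummarizedExperiment::colData(x))

#' @describeIn GenotypeSet integer row indices of a named panel
#' @param panel one of "icbf800", "isag100", "isag200", "all"
#' @export
setMethod("panelIndex", "GenotypeSet", function(x, panel = "icbf800", ...) {
  rd <- SummarizedExperiment::rowData(x)
  switch(match.arg(panel, c("icbf800", "isag100", "isag200", "all")),
         icbf800 = which(rd$in_icbf800),
         isag100 = which(rd$in_isag100),
         isag200 = which(rd$in_isag200),
         all = seq_len(nrow(x)))
})

setMethod("show", "GenotypeSet", function(object) {
  rd <- SummarizedExperiment::rowData(object)
  cat("GenotypeSet with", nrow(object), "SNPs x", ncol(object), "samples\n")
  cat("  panel SNPs: icbf800 =", sum(rd$in_icbf800),
      "| isag200 =", sum(rd$in_isag200), "\n")
  cat("  chromosomes:",
      paste(unique(as.character(rd$chromosome)), collapse = " "), "\n")
  st <- table(SummarizedExperiment::colData(object)$valid)
  cat("  sample states:",
      paste(names(st), st, sep = "=", collapse = " "), "\n")
  invisible(NULL)
})

#' Minimal SNP map for examples and tests
#'
#' @param n number of autosomal panel SNPs to fabricate
#' @return DataFrame usable as the `snpMap` argument of [GenotypeSet()].
#' @export
exampleSnpMap <- function(n) {
  S4Vectors::DataFrame(
    chromosome = rep("1", n), position_bp = seq_len(n) * 1000L,
    in_icbf800 = rep(TRUE, n), in_isag100 = rep(FALSE, n),
    in_isag200 = rep(FALSE, n), is_par = rep(FALSE, n),
    cluster_ok = rep(TRUE, n),
    row.names = paste0("snp", seq_len(n)))
}
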