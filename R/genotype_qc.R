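#' Per-SNP call rates and the usable-SNP mask
#'
#' A SNP's call rate is the fraction of samples with a non-missing call.
#' SNPs with a cohort call rate below `snp_cr_min_for_use` (default 0.85)
#' are excluded from the per-animal call-rate denominator.
#'
#' @param x a [GenotypeSet-class] with at least one sample.
#' @param thresholds a [herdThresholds()] list.
#' @return list with `cr` (named numeric per SNP) and `usable` (logical).
#' @export
snpCallRates <- function(x, thresholds = herdThresholds()) {
  if (ncol(x) == 0) stop("no samples")
  m <- calls(x)
  cr <- rowMeans(m != 9L)
  list(cr = cr, usable = cr >= thresholds$snp_cr_min_for_use)
}

#' Per-animal call rate over usable SNPs
#'
#' Non-missing calls divided by the number of usable SNPs; a genotype
#' passes at a rate of 0.90 or higher (boundary inclusive).
#'
#' @param callsVec integer call vector for one sample.
#' @param usable logical usable-SNP mask from [snpCallRates()].
#' @param thresholds a [herdThresholds()] list.
#' @return list with `call_rate` and `pass`.
#' @export
animalCallRate <- function(callsVec, usable, thresholds = herdThresholds()) {
  if (!any(usable)) stop("usable-SNP mask is empty")
  cr <- sum(callsVec[usable] != 9L) / sum(usable)
  list(call_rate = cr, pass = cr >= thresholds$animal_cr_min)
}

#' Check that all three genotype classes are observed
#'
#' A valid genome-wide genotype shows AA, AB and BB; a missing class
#' (often BB) indicates a clustering or format failure.
#'
#' @param callsVec integer call vector.
#' @return list with `classes_present` (subset of c(0,1,2)) and `pass`.
#' @export
genotypeClassesPresent <- function(callsVec) {
  present <- sort(unique(callsVec[callsVec != 9L]))
  list(classes_present = present, pass = all(c(0L, 1L, 2L) %in% present))
}

#' Detect mixed genotype formats in raw allele data
#'
#' AB-declared data must only contain A/B (plus missing tokens); Top
#' ACTG-declared data must not contain B. Any violation (e.g. an
#' A/T call inside AB data) fails the check and lists the offending rows.
#'
#' @param raw data.frame with columns `sample_id`, `snp_id`, `allele1`,
#'   `allele2` as retained by the long-format reader (also accepts the
#'   `rows` field of a `herdqc_format_anomaly` condition).
#' @param declared `"AB"` or `"TOP"`.
#' @return list with `pass` and `offending` (data.frame of violating rows).
#' @export
detectMixedFormat <- function(raw, declared = c("AB", "TOP")) {
  declared <- match.arg(declared)
  alphabet <- if (declared == "AB") c("A", "B") else c("A", "C", "G", "T")
  ok <- raw$allele1 %in% c(alphabet, .missingTokens) &
        raw$allele2 %in% c(alphabet, .missingTokens)
  list(pass = all(ok), offending = raw[!ok, , drop = FALSE])
}

#' Genotype-class frequencies and the 20% rule
#'
#' Frequencies of AA, AB and BB over non-missing calls. Large-cohort
#' experience shows essentially no true genotype has any class below 20%,
#' so a genotype with `min(fAA, fAB, fBB)` strictly below
#' `geno_class_freq_min` is invalidated.
#'
#' @param callsVec integer call vector with at least one non-missing call.
#' @param thresholds a [herdThresholds()] list.
#' @return list with `freqs` (named fAA/fAB/fBB) and `pass`.
#' @export
classFrequencyCheck <- function(callsVec, thresholds = herdThresholds()) {
  obs <- callsVec[callsVec != 9L]
  if (!length(obs)) stop("no non-missing calls")
  f <- c(fAA = mean(obs == 2L), fAB = mean(obs == 1L), fBB = mean(obs == 0L))
  list(freqs = f, pass = min(f) >= thresholds$geno_class_freq_min)
}

#' Run the genotype QC pipeline
#'
#' Applies, per sample: the call-rate gate (over usable SNPs), the
#' genotype-class presence check, optionally the raw-format purity check,
#' and the genotype-class frequency rule. A genotype must pass all checks
#' to be used downstream; failing samples are marked `invalid` in the
#' returned object.
#'
#' @param x a [GenotypeSet-class].
#' @param raw optional raw allele table (long format) for the format
#'   purity check; when `NULL` the check passes vacuously.
#' @param declared raw allele format, `"AB"` or `"TOP"`.
#' @param thresholds a [herdThresholds()] list.
#' @param autosomes_only compute class frequencies over autosomal SNPs
#'   only (default `FALSE`: all non-missing calls, whose chrX share on a
#'   genome-wide chip is negligible).
#' @return list with `results` (data.frame: sample_id, call_rate, fAA,
#'   fAB, fBB, one logical column per check, `overall`) and `x`, the
#'   input with failing samples marked invalid.
#' @export
runGenotypeQC <- function(x, raw = NULL, declared = "AB",
                          thresholds = herdThresholds(),
                          autosomes_only = FALSE) {
  m <- calls(x)
  scr <- snpCallRates(x, thresholds)
  classMask <- if (autosomes_only)
    snpMap(x)$chromosome %in% as.character(1:29) else rep(TRUE, nrow(m))
  fmt_bad <- character()
  if (!is.null(raw)) {
    mf <- detectMixedFormat(raw, declared)
    fmt_bad <- unique(mf$offending$sample_id)
  }
  res <- lapply(seq_len(ncol(m)), function(j) {
    v <- m[, j]
    acr <- animalCallRate(v, scr$usable, thresholds)
    gcp <- genotypeClassesPresent(v)
    vc <- v[classMask]
    if (any(vc != 9L)) {
      cf <- classFrequencyCheck(vc, thresholds)
    } else {
      cf <- list(freqs = c(fAA = NA_real_, fAB = NA_real_, fBB = NA_real_),
                 pass = FALSE)
    }
    data.frame(sample_id = colnames(m)[j],
               call_rate = acr$call_rate,
               fAA = cf$freqs[["fAA"]], fAB = cf$freqs[["fAB"]],
               fBB = cf$freqs[["fBB"]],
               check_call_rate = acr$pass,
               check_classes_present = gcp$pass,
               check_format_pure = !(colnames(m)[j] %in% fmt_bad),
               check_class_freq = cf$pass,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$overall <- res$check_call_rate & res$check_classes_present &
    res$check_format_pure & res$check_class_freq
  st <- sampleInfo(x)$valid
  st[!res$overall] <- "invalid"
  SummarizedExperiment::colData(x)$valid <- st
  list(results = res, x = x)
}

#' Keep only samples that passed genotype QC
#'
#' @param x a [GenotypeSet-class] whose `valid` states were set by
#'   [runGenotypeQC()].
#' @return the subset of `x` with `valid == "valid"`.
#' @export
validSamples <- function(x) x[, sampleInfo(x)$valid == "valid"]
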