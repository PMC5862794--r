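#' Numeric constants of the QC and parentage pipelines
#'
#' Single home for every tunable threshold. Defaults follow the operating
#' rules of the national-herd pipeline the package implements:
#' \itemize{
#'   \item `animal_cr_min` (0.90): minimum per-animal call rate, inclusive.
#'   \item `snp_cr_min_for_use` (0.85): SNPs below this cohort call rate are
#'     excluded from the animal call-rate denominator.
#'   \item `geno_class_freq_min` (0.20): a genotype with any class (AA, AB,
#'     BB) frequency strictly below this is invalidated.
#'   \item `validate_max_mm` (4) / `fail_min_mm` (13): parentage validates
#'     at <= 4 panel mismatches (0.5% of 800), fails at >= 13 (> 1.5%);
#'     5-12 is the gray zone re-checked on all shared SNPs.
#'   \item `gray_full_snp_rate_max` (0.01): full-SNP misconcordance rate at
#'     or below which a gray-zone parentage validates.
#'   \item `predict_min_panel_calls` (600): minimum non-missing panel calls
#'     for an animal to enter the candidate table / give a verdict.
#'   \item `parent_age_gap_months` (15): a predicted parent must be at
#'     least this much older than the animal.
#'   \item `duplicate_identity_min` (0.99): genotype identity at or above
#'     which two samples are treated as the same animal's DNA.
#'   \item `block_size` (20) / `legacy_block_size` (50): duplicate-search
#'     block lengths over the 800-character panel string.
#'   \item `msm_flag_rate` (0.01): trio mating flagged when the rate of
#'     calf-AB with both parents same-homozygote exceeds this.
#'   \item `chry_female_max` (1) / `chry_male_min` (6): chrY called-SNP
#'     counts (out of 7) calling female / male.
#'   \item `chrx_male_het_max` (0.05) / `chrx_female_het_min` (0.15):
#'     chrX non-PAR heterozygosity thresholds.
#'   \item `par_snp_maf_min` (0.01), `par_snp_cr_min` (0.90): SNP filters
#'     applied before PAR determination.
#'   \item `par_male_het_min` (0.05): male het rate at which a chrX SNP is
#'     classified pseudoautosomal.
#'   \item `min_npar_calls` (20): minimum non-missing nPAR calls for a
#'     chrX sex verdict.
#'   \item `dam_offspring_flag_n` (2), `stockbull_offspring_flag_n` (5),
#'     `aibull_offspring_flag_n` (10), `offspring_fail_frac` (0.80):
#'     offspring-failure pattern flags per parent class.
#'   \item `dead_sample_days` (45): tissue collected more than this many
#'     days after recorded death raises a warning flag.
#'   \item `panel_maf_min` (0.25), `panel_cr_min` (0.90): hard filters for
#'     parentage-panel selection.
#'   \item `breed_min_ref` (25): minimum purebred reference animals per
#'     breed (desk-scale default).
#'   \item `breed_mismatch_tol` (0.40): largest tolerated absolute
#'     difference between a predicted and listed breed fraction.
#'   \item `breed_min_snps` (1000): minimum non-missing reference SNPs for
#'     a breed-composition estimate.
#' }
#'
#' @param ... name = value overrides of any default.
#' @return A named list with class `herd_thresholds`.
#' @examples
#' th <- herdThresholds(block_size = 50)
#' th$validate_max_mm
#' @export
herdThresholds <- function(...) {
  th <- list(
    animal_cr_min = 0.90,
    snp_cr_min_for_use = 0.85,
    geno_class_freq_min = 0.20,
    validate_max_mm = 4L,
    fail_min_mm = 13L,
    gray_full_snp_rate_max = 0.01,
    predict_min_panel_calls = 600L,
    parent_age_gap_months = 15L,
    duplicate_identity_min = 0.99,
    block_size = 20L,
    legacy_block_size = 50L,
    msm_flag_rate = 0.01,
    chry_female_max = 1L,
    chry_male_min = 6L,
    chrx_male_het_max = 0.05,
    chrx_female_het_min = 0.15,
    par_snp_maf_min = 0.01,
    par_snp_cr_min = 0.90,
    par_male_het_min = 0.05,
    min_npar_calls = 20L,
    dam_offspring_flag_n = 2L,
    stockbull_offspring_flag_n = 5L,
    aibull_offspring_flag_n = 10L,
    offspring_fail_frac = 0.80,
    dead_sample_days = 45L,
    panel_maf_min = 0.25,
    panel_cr_min = 0.90,
    breed_min_ref = 25L,
    breed_mismatch_tol = 0.40,
    breed_min_snps = 1000L)
  ov <- list(...)
  unknown <- setdiff(names(ov), names(th))
  if (length(unknown))
    stop("unknown threshold(s): ", paste(unknown, collapse = ", "))
  th[names(ov)] <- ov
  probs <- c("animal_cr_min", "snp_cr_min_for_use", "geno_class_freq_min",
             "gray_full_snp_rate_max", "duplicate_identity_min",
             "msm_flag_rate", "chrx_male_het_max", "chrx_female_het_min",
             "par_snp_maf_min", "par_snp_cr_min", "par_male_het_min",
             "offspring_fail_frac", "panel_maf_min", "panel_cr_min",
             "breed_mismatch_tol")
  for (p in probs)
    if (th[[p]] < 0 || th[[p]] > 1) stop("threshold ", p, " outside [0,1]")
  if (th$validate_max_mm >= th$fail_min_mm)
    stop("validate_max_mm must be below fail_min_mm")
  class(th) <- "herd_thresholds"
  th
}
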