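#' Per-SNP minor allele frequency
#'
#' `MAF = min(fA, 1 - fA)` with the allele-A frequency computed over
#' non-missing calls. An optional animal subset (e.g. the listed
#' purebreds of one breed) restricts the estimate.
#'
#' @param x a [GenotypeSet-class].
#' @param samples optional character vector of column names.
#' @return named numeric vector of MAFs (NA where no calls).
#' @export
computeMAF <- function(x, samples = NULL) {
  m <- calls(x)
  if (!is.null(samples)) m <- m[, samples, drop = FALSE]
  nA <- rowSums((m == 2L) * 2L + (m == 1L))
  nc <- rowSums(m != 9L)
  fA <- ifelse(nc > 0, nA / (2 * nc), NA)
  pmin(fA, 1 - fA)
}

#' Audit SNPs for parentage-panel eligibility
#'
#' @param x a [GenotypeSet-class] of a representative cohort.
#' @param thresholds a [herdThresholds()] list.
#' @return data.frame per SNP: maf, cr, cluster_ok, panel flags, and
#'   `eligible` (cluster_ok, CR >= panel_cr_min, MAF >= panel_maf_min).
#' @export
auditPanel <- function(x, thresholds = herdThresholds()) {
  rd <- snpMap(x)
  maf <- computeMAF(x)
  cr <- rowMeans(calls(x) != 9L)
  data.frame(snp_id = rownames(x),
             chromosome = as.character(rd$chromosome),
             position_bp = rd$position_bp,
             maf = maf, cr = cr, cluster_ok = rd$cluster_ok,
             in_isag100 = rd$in_isag100, in_isag200 = rd$in_isag200,
             eligible = rd$cluster_ok & !is.na(maf) &
               cr >= thresholds$panel_cr_min &
               maf >= thresholds$panel_maf_min &
               rd$chromosome %in% as.character(1:29),
             stringsAsFactors = FALSE)
}

#' Select a parentage panel
#'
#' Keeps every must-include SNP (typically the ISAG200 set) that passes
#' the hard filters — cluster quality, call rate at or above 0.90, MAF at
#' or above 0.25 — then fills the remaining slots with the eligible
#' candidates of highest MAF, ties broken by (chromosome, position).
#' Must-include SNPs failing the filters are excluded like any other.
#'
#' @param audit data.frame from [auditPanel()].
#' @param size panel size (e.g. 800).
#' @param must_include character vector of snp_ids given priority.
#' @return character vector of `size` selected snp_ids.
#' @export
selectPanel <- function(audit, size, must_include = character()) {
  elig <- audit[audit$eligible, , drop = FALSE]
  core <- elig$snp_id[elig$snp_id %in% must_include]
  if (length(core) > size) stop("must_include exceeds panel size")
  rest <- elig[!elig$snp_id %in% core, , drop = FALSE]
  need <- size - length(core)
  if (nrow(rest) < need)
    stop("only ", length(core) + nrow(rest),
         " eligible SNPs for a panel of ", size)
  o <- order(-rest$maf, match(rest$chromosome, CHROM_LEVELS),
             rest$position_bp)
  c(core, rest$snp_id[o][seq_len(need)])
}

#' Expected opposing-homozygote count for an unrelated pair
#'
#' At a SNP with allele frequency p (q = 1 - p), two unrelated
#' Hardy-Weinberg genotypes are opposing homozygotes with probability
#' 2 p^2 q^2; the expected mismatch count over a panel is the sum of
#' these terms.
#'
#' @param freqs vector of allele-A frequencies for the panel SNPs.
#' @return expected opposing-homozygote count.
#' @export
expectedUnrelatedMismatches <- function(freqs) {
  sum(2 * freqs^2 * (1 - freqs)^2)
}

#' Monte-Carlo power report for a parentage panel
#'
#' Simulates unrelated pairs (independent Hardy-Weinberg draws) and true
#' parent-offspring pairs (one transmitted allele plus one population
#' allele) at the panel's allele frequencies with a per-call error rate,
#' and reports the distribution of opposing-homozygote counts relative
#' to the validate (<=4) and fail (>=13) thresholds, alongside the
#' closed-form expectation for unrelated pairs.
#'
#' @param freqs allele-A frequencies of the panel SNPs.
#' @param error_rate per-call probability of recording a different
#'   genotype (uniform over the two wrong classes).
#' @param n_sims simulated pairs per relationship.
#' @param thresholds a [herdThresholds()] list.
#' @param seed RNG seed.
#' @return list with `unrelated` and `parent_offspring` summaries (mean
#'   mismatches, P(validate), P(fail), P(gray)), and
#'   `expected_unrelated_mean` from [expectedUnrelatedMismatches()].
#' @export
panelPowerReport <- function(freqs, error_rate = 0.002, n_sims = 1000L,
                             thresholds = herdThresholds(), seed = 1L) {
  set.seed(seed)
  J <- length(freqs)
  drawHW <- function() matrix(stats::rbinom(J * n_sims, 2, freqs),
                              nrow = J)
  addError <- function(g) {
    if (error_rate <= 0) return(g)
    hit <- matrix(stats::runif(length(g)) < error_rate, nrow = nrow(g))
    shift <- matrix(sample(1:2, length(g), replace = TRUE), nrow = nrow(g))
    g[hit] <- (g[hit] + shift[hit]) %% 3L
    g
  }
  mmCounts <- function(a, b) colSums((a == 2L & b == 0L) | (a == 0L & b == 2L))
  ## unrelated: two independent HWE genotypes
  u1 <- addError(drawHW()); u2 <- addError(drawHW())
  mm_u <- mmCounts(u1, u2)
  ## parent-offspring: child gets one allele from the parent genotype,
  ## one from the population
  par <- drawHW()
  transmitted <- matrix(stats::rbinom(J * n_sims, 1, par / 2), nrow = J)
  other <- matrix(stats::rbinom(J * n_sims, 1, freqs), nrow = J)
  child <- transmitted + other
  mm_p <- mmCounts(addError(par), addError(child))
  summ <- function(mm) list(
    mean_mismatches = mean(mm),
    p_validate = mean(mm <= thresholds$validate_max_mm),
    p_fail = mean(mm >= thresholds$fail_min_mm),
    p_gray = mean(mm > thresholds$validate_max_mm &
                  mm < thresholds$fail_min_mm))
  list(unrelated = summ(mm_u), parent_offspring = summ(mm_p),
       expected_unrelated_mean = expectedUnrelatedMismatches(freqs),
       mm_unrelated = mm_u, mm_parent_offspring = mm_p)
}
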