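#' Sex prediction from chromosome Y call counts
#'
#' Males carry Y, so Y-specific SNPs genotype in males and fail in
#' females. With the operational 7-SNP chrY set: 0-1 called = female,
#' 6-7 = male, 2-5 = ambiguous. For chips carrying a different number of
#' chrY SNPs the cutoffs scale proportionally (<=1/7 female, >=6/7 male).
#'
#' @param callsVec integer call vector for one sample.
#' @param chryIdx indices of chrY SNPs on this chip.
#' @param thresholds a [herdThresholds()] list.
#' @return list with `n_called` and `verdict` ("male"/"female"/
#'   "ambiguous"; NA when the chip has no chrY SNPs).
#' @export
predictSexY <- function(callsVec, chryIdx, thresholds = herdThresholds()) {
  if (!length(chryIdx))
    return(list(n_called = NA_integer_, verdict = NA_character_))
  n <- sum(callsVec[chryIdx] != 9L)
  k <- length(chryIdx)
  fmax <- thresholds$chry_female_max / 7
  mmin <- thresholds$chry_male_min / 7
  verdict <- if (n / k <= fmax) "female"
             else if (n / k >= mmin) "male" else "ambiguous"
  list(n_called = n, verdict = verdict)
}

#' Chromosome X non-PAR heterozygosity and sex verdict
#'
#' Het rate = nAB / (nAA + nAB + nBB) over non-PAR chrX SNPs. Males are
#' hemizygous there, so their apparent het rate is near zero: at or below
#' 5% calls male, at or above 15% female, between is ambiguous. Fewer
#' than `min_npar_calls` non-missing calls gives an ambiguous verdict
#' (too little data; highly inbred females can otherwise look male).
#'
#' @param callsVec integer call vector.
#' @param nparIdx indices of non-PAR chrX SNPs.
#' @param thresholds a [herdThresholds()] list.
#' @return list with `het`, `n_calls`, `verdict`.
#' @export
chrxNparHet <- function(callsVec, nparIdx, thresholds = herdThresholds()) {
  v <- callsVec[nparIdx]
  n <- sum(v != 9L)
  if (n < thresholds$min_npar_calls)
    return(list(het = NA_real_, n_calls = n, verdict = "ambiguous"))
  het <- sum(v == 1L) / n
  verdict <- if (het <= thresholds$chrx_male_het_max) "male"
             else if (het >= thresholds$chrx_female_het_min) "female"
             else "ambiguous"
  list(het = het, n_calls = n, verdict = verdict)
}

#' Combine the chrY and chrX sex verdicts
#'
#' Agreement reports that sex; one ambiguous verdict defers to the
#' other; both ambiguous stays ambiguous; opposite non-ambiguous verdicts
#' are a conflict requiring manual review (possible X0/XXY karyotype or a
#' sex-sorted-semen sample).
#'
#' @param verdict_y,verdict_x verdict strings (NA allowed for chips
#'   without the relevant SNPs).
#' @return one of "male", "female", "ambiguous", "conflict".
#' @export
combineSex <- function(verdict_y, verdict_x) {
  vy <- if (is.na(verdict_y)) "ambiguous" else verdict_y
  vx <- if (is.na(verdict_x)) "ambiguous" else verdict_x
  if (vy == vx) return(vy)
  if (vy == "ambiguous") return(vx)
  if (vx == "ambiguous") return(vy)
  "conflict"
}

#' Predict sex for every sample
#'
#' @param x a [GenotypeSet-class]; chrY SNPs and the chrX `is_par` flag
#'   are taken from its SNP map.
#' @param thresholds a [herdThresholds()] list.
#' @return data.frame: sample_id, n_chry_called, chrx_npar_het,
#'   verdict_y, verdict_x, combined.
#' @export
predictSex <- function(x, thresholds = herdThresholds()) {
  rd <- snpMap(x)
  chry <- which(rd$chromosome == "Y")
  npar <- which(rd$chromosome == "X" & !rd$is_par)
  m <- calls(x)
  out <- lapply(seq_len(ncol(m)), function(j) {
    y <- predictSexY(m[, j], chry, thresholds)
    xx <- chrxNparHet(m[, j], npar, thresholds)
    data.frame(sample_id = colnames(m)[j],
               n_chry_called = y$n_called, chrx_npar_het = xx$het,
               verdict_y = y$verdict, verdict_x = xx$verdict,
               combined = combineSex(y$verdict, xx$verdict),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Determine the pseudoautosomal region of chromosome X
#'
#' Uses samples of known sex. chrX SNPs failing the MAF (>= 0.01) or call
#' rate (>= 0.90) filters are excluded; among the rest, SNPs whose male
#' heterozygosity rate is at or above `par_male_het_min` are classified
#' pseudoautosomal, and the PAR interval is the longest positional run of
#' PAR-classified SNPs (male het in the true PAR runs around 24% against
#' about 0.2% in the hemizygous remainder, so the separation is wide).
#'
#' @param x a [GenotypeSet-class].
#' @param sex named character vector (by sample) of known sexes; at least
#'   `min_n` males and `min_n` females are required.
#' @param thresholds a [herdThresholds()] list.
#' @param min_n minimum count per sex (default 50).
#' @return list with `interval` (start_bp, end_bp; NULL when no SNP
#'   classifies as PAR), `snp_table` (per-SNP male het, classification),
#'   and the filter masks.
#' @export
determinePar <- function(x, sex, thresholds = herdThresholds(), min_n = 50L) {
  males <- names(sex)[sex == "male"]
  females <- names(sex)[sex == "female"]
  if (length(males) < min_n || length(females) < min_n)
    stop("need at least ", min_n, " known males and females")
  rd <- snpMap(x)
  xi <- which(rd$chromosome == "X")
  if (!length(xi)) stop("no chrX SNPs in the map")
  m <- calls(x)[xi, c(males, females), drop = FALSE]
  cr <- rowMeans(m != 9L)
  nA <- rowSums((m == 2L) * 2L + (m == 1L) * 1L)
  nTot <- rowSums(m != 9L) * 2L
  fA <- ifelse(nTot > 0, nA / nTot, NA)
  maf <- pmin(fA, 1 - fA)
  keep <- !is.na(maf) & maf >= thresholds$par_snp_maf_min &
    cr >= thresholds$par_snp_cr_min
  mm <- calls(x)[xi, males, drop = FALSE]
  called <- rowSums(mm != 9L)
  male_het <- ifelse(called > 0, rowSums(mm == 1L) / called, NA)
  cls <- rep("excluded", length(xi))
  cls[keep] <- ifelse(male_het[keep] >= thresholds$par_male_het_min,
                      "PAR", "nPAR")
  pos <- rd$position_bp[xi]
  o <- order(pos)
  tab <- data.frame(snp_id = rownames(x)[xi][o], position_bp = pos[o],
                    male_het = male_het[o], maf = maf[o], cr = cr[o],
                    class = cls[o], stringsAsFactors = FALSE)
  considered <- tab[tab$class != "excluded", , drop = FALSE]
  interval <- NULL
  if (any(considered$class == "PAR")) {
    r <- rle(considered$class == "PAR")
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- which(r$values)
    best <- runs[which.max(r$lengths[runs])]
    interval <- c(start_bp = considered$position_bp[starts[best]],
                  end_bp = considered$position_bp[ends[best]])
  }
  list(interval = interval, snp_table = tab)
}
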