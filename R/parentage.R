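#' Opposing-homozygote mismatches between two genotypes
#'
#' The only Mendelian impossibility testable on a duo: one individual AA
#' and the other BB at the same SNP. SNPs missing in either genotype are
#' excluded from the comparison; a heterozygous call can never mismatch.
#'
#' @param a,b integer call vectors aligned to the same SNP map.
#' @param idx integer indices of the SNPs to compare (e.g. the parentage
#'   panel); must be non-empty.
#' @return list with `n_compared` (both non-missing) and `n_mismatch`.
#' @export
countParentOffspringMismatches <- function(a, b, idx = seq_along(a)) {
  if (!length(idx)) stop("empty SNP index")
  a <- a[idx]; b <- b[idx]
  both <- a != 9L & b != 9L
  list(n_compared = sum(both),
       n_mismatch = sum(both & ((a == 2L & b == 0L) | (a == 0L & b == 2L))))
}

.verdictFromCounts <- function(mm, thresholds) {
  if (mm <= thresholds$validate_max_mm) "validated"
  else if (mm >= thresholds$fail_min_mm) "failed"
  else "gray"
}

#' Two-stage parentage validation of one candidate parent
#'
#' Stage one counts opposing homozygotes on the parentage panel: at most
#' 4 mismatches (0.5% of 800) validates, 13 or more (>1.5%) fails. The
#' gray zone of 5-12 is re-evaluated on all autosomal SNPs shared by the
#' pair: a full-SNP misconcordance rate at or below 1% validates
#' (`gray_validated`), above 1% fails (`gray_failed`). Sex chromosomes
#' are excluded from mismatch counting throughout — a sire and son are
#' legitimately opposing homozygotes on hemizygous chrX calls. Fewer
#' than `predict_min_panel_calls` mutually non-missing panel SNPs gives
#' `insufficient_data`.
#'
#' @param x a [GenotypeSet-class] containing both samples.
#' @param animalSample,parentSample column names (sample ids) in `x`.
#' @param role `"sire"` or `"dam"` (carried through to the result).
#' @param thresholds a [herdThresholds()] list.
#' @param panel panel name for stage one (default `"icbf800"`).
#' @return one-row data.frame: animal_id, candidate_id, role,
#'   n_compared_panel, n_mismatch_panel, full_snp_rate (NA unless gray),
#'   verdict.
#' @export
validateParent <- function(x, animalSample, parentSample, role = "sire",
                           thresholds = herdThresholds(),
                           panel = "icbf800") {
  pidx <- panelIndex(x, panel)
  a <- calls(x)[, animalSample]
  b <- calls(x)[, parentSample]
  pc <- countParentOffspringMismatches(a, b, pidx)
  full_rate <- NA_real_
  if (pc$n_compared < thresholds$predict_min_panel_calls) {
    verdict <- "insufficient_data"
  } else {
    verdict <- .verdictFromCounts(pc$n_mismatch, thresholds)
    if (verdict == "gray") {
      auto <- which(snpMap(x)$chromosome %in% as.character(1:29))
      fc <- countParentOffspringMismatches(a, b, auto)
      full_rate <- fc$n_mismatch / fc$n_compared
      verdict <- if (full_rate <= thresholds$gray_full_snp_rate_max)
        "gray_validated" else "gray_failed"
    }
  }
  data.frame(
    animal_id = as.character(sampleInfo(x)[animalSample, "animal_id"]),
    candidate_id = as.character(sampleInfo(x)[parentSample, "animal_id"]),
    sample_id = animalSample, candidate_sample = parentSample,
    role = role,
    n_compared_panel = pc$n_compared, n_mismatch_panel = pc$n_mismatch,
    full_snp_rate = full_rate, verdict = verdict,
    stringsAsFactors = FALSE)
}

#' Validate every listed parent of every genotyped animal
#'
#' @param x a QC-passed [GenotypeSet-class] (one sample per animal; see
#'   [buildCandidateTable()]).
#' @param animals animal metadata from [readAnimals()].
#' @param thresholds a [herdThresholds()] list.
#' @return data.frame of [validateParent()] rows, one per genotyped
#'   animal x genotyped listed parent.
#' @export
validateListedParents <- function(x, animals, thresholds = herdThresholds()) {
  byAnimal <- stats::setNames(colnames(x), sampleInfo(x)$animal_id)
  out <- list()
  for (j in seq_len(ncol(x))) {
    aid <- as.character(sampleInfo(x)$animal_id[j])
    if (!aid %in% rownames(animals)) next
    for (role in c("sire", "dam")) {
      pid <- animals[aid, paste0("listed_", role)]
      if (is.na(pid) || !pid %in% names(byAnimal)) next
      out[[length(out) + 1L]] <- validateParent(
        x, colnames(x)[j], byAnimal[[pid]], role, thresholds)
    }
  }
  if (!length(out)) return(emptyParentageFrame())
  do.call(rbind, out)
}

emptyParentageFrame <- function()
  data.frame(animal_id = character(), candidate_id = character(),
             sample_id = character(), candidate_sample = character(),
             role = character(), n_compared_panel = integer(),
             n_mismatch_panel = integer(), full_snp_rate = numeric(),
             verdict = character(), stringsAsFactors = FALSE)

#' Build the one-genotype-per-animal candidate table
#'
#' Every animal with a valid genotype and at least
#' `predict_min_panel_calls` (600) non-missing panel calls enters once;
#' when an animal has several valid genotypes the one with the most panel
#' calls wins, ties broken by the newest `genotyping_date`.
#'
#' @param x a [GenotypeSet-class] (QC applied; invalid samples ignored).
#' @param thresholds a [herdThresholds()] list.
#' @param panel panel name.
#' @return a [GenotypeSet-class] subset with one column per animal, plus
#'   `panel_calls` in its `colData`.
#' @export
buildCandidateTable <- function(x, thresholds = herdThresholds(),
                                panel = "icbf800") {
  x <- x[, sampleInfo(x)$valid == "valid"]
  pidx <- panelIndex(x, panel)
  pc <- colSums(calls(x)[pidx, , drop = FALSE] != 9L)
  keep <- pc >= thresholds$predict_min_panel_calls
  x <- x[, keep]; pc <- pc[keep]
  ci <- sampleInfo(x)
  gdate <- if ("genotyping_date" %in% colnames(ci))
    as.Date(ci$genotyping_date) else as.Date(rep(NA, ncol(x)))
  gnum <- as.numeric(gdate); gnum[is.na(gnum)] <- -Inf
  ord <- order(as.character(ci$animal_id), -pc, -gnum)
  first <- ord[!duplicated(as.character(ci$animal_id)[ord])]
  x <- x[, sort(first)]
  SummarizedExperiment::colData(x)$panel_calls <-
    pc[sort(first)]
  x
}

## chunked opposing-homozygote scan of one target against all table
## columns, dropping a column as soon as its running count exceeds maxmm
.panelScan <- function(P, v, maxmm, chunk = 100L) {
  n <- ncol(P)
  mm <- integer(n); cmp <- integer(n)
  active <- rep(TRUE, n)
  starts <- seq(1L, nrow(P), by = chunk)
  for (s in starts) {
    rows <- s:min(s + chunk - 1L, nrow(P))
    vi <- v[rows]
    sub <- P[rows, active, drop = FALSE]
    both <- (vi != 9L) & (sub != 9L)
    opp <- both & ((vi == 2L & sub == 0L) | (vi == 0L & sub == 2L))
    mm[active] <- mm[active] + colSums(opp)
    cmp[active] <- cmp[active] + colSums(both)
    active <- active & mm <= maxmm
    if (!any(active)) break
  }
  list(mm = mm, cmp = cmp, surviving = active)
}

.shiftMonths <- function(d, n) {
  lt <- as.POSIXlt(d)
  day <- lt$mday
  lt$mday <- 1L
  lt$mon <- lt$mon + n
  last <- as.POSIXlt(seq(as.Date(lt), by = "month", length.out = 2)[2] - 1)$mday
  lt$mday <- min(day, last)
  as.Date(lt)
}

#' Fast whole-table parent prediction for one animal
#'
#' Scans every other animal in the candidate table, abandoning a
#' candidate as soon as its opposing-homozygote count exceeds 12.
#' Survivors are filtered by age (a parent must be at least 15 months
#' older than the animal, which also removes the animal's own genotyped
#' progeny) and by sex (sire candidates male, dam candidates female).
#' Candidates in the 5-12 gray zone are confirmed on all shared SNPs at
#' the 1% misconcordance rule; all passing candidates are returned per
#' role.
#'
#' @param target animal_id present in the candidate table.
#' @param table candidate table from [buildCandidateTable()].
#' @param animals animal metadata from [readAnimals()].
#' @param thresholds a [herdThresholds()] list.
#' @param panel panel name.
#' @param chunk SNP chunk size for the early-termination scan (results
#'   are identical for any chunk size).
#' @return data.frame of [validateParent()]-shaped rows for every
#'   predicted sire/dam (verdict validated or gray_validated).
#' @export
predictParents <- function(target, table, animals,
                           thresholds = herdThresholds(),
                           panel = "icbf800", chunk = 100L) {
  aid <- as.character(sampleInfo(table)$animal_id)
  if (!target %in% aid) stop("target ", target, " not in candidate table")
  tj <- which(aid == target)
  pidx <- panelIndex(table, panel)
  P <- calls(table)[pidx, , drop = FALSE]
  sc <- .panelScan(P, P[, tj], maxmm = thresholds$fail_min_mm - 1L,
                   chunk = chunk)
  cand <- which(sc$surviving &
                sc$cmp >= thresholds$predict_min_panel_calls &
                seq_along(aid) != tj)
  if (!length(cand)) return(emptyParentageFrame())
  ## age rule: candidate DOB at or before target DOB minus 15 months
  tdob <- animals[target, "dob"]
  cutoff <- .shiftMonths(tdob, -thresholds$parent_age_gap_months)
  cdob <- animals[aid[cand], "dob"]
  cand <- cand[!is.na(cdob) & cdob <= cutoff]
  if (!length(cand)) return(emptyParentageFrame())
  out <- list()
  for (j in cand) {
    sex <- animals[aid[j], "recorded_sex"]
    role <- if (identical(sex, "male")) "sire"
            else if (identical(sex, "female")) "dam" else NA_character_
    if (is.na(role)) next
    r <- validateParent(table, colnames(table)[tj], colnames(table)[j],
                        role, thresholds, panel)
    if (r$verdict %in% c("validated", "gray_validated"))
      out[[length(out) + 1L]] <- r
  }
  if (!length(out)) return(emptyParentageFrame())
  do.call(rbind, out)
}

#' Trio mating validation: mating SNP misconcordances
#'
#' An MSM is a panel SNP where the calf is heterozygous while both
#' (individually validated) parents are homozygous for the same allele —
#' impossible for the listed mating. The trio is flagged for manual
#' review when the MSM rate over informative SNPs (all three non-missing)
#' exceeds 1%.
#'
#' @param x a [GenotypeSet-class] containing the three samples.
#' @param calfSample,sireSample,damSample column names in `x`.
#' @param thresholds a [herdThresholds()] list.
#' @param panel panel name.
#' @return one-row data.frame: animal_id, sire_id, dam_id, n_msm,
#'   n_informative, msm_rate, flagged.
#' @export
countMSM <- function(x, calfSample, sireSample, damSample,
                     thresholds = herdThresholds(), panel = "icbf800") {
  pidx <- panelIndex(x, panel)
  m <- calls(x)
  calf <- m[pidx, calfSample]; sire <- m[pidx, sireSample]
  dam <- m[pidx, damSample]
  inf <- calf != 9L & sire != 9L & dam != 9L
  msm <- inf & calf == 1L & sire == dam & sire %in% c(0L, 2L)
  n_inf <- sum(inf); n_msm <- sum(msm)
  rate <- if (n_inf) n_msm / n_inf else NA_real_
  data.frame(
    animal_id = as.character(sampleInfo(x)[calfSample, "animal_id"]),
    sire_id = as.character(sampleInfo(x)[sireSample, "animal_id"]),
    dam_id = as.character(sampleInfo(x)[damSample, "animal_id"]),
    n_msm = n_msm, n_informative = n_inf, msm_rate = rate,
    flagged = !is.na(rate) && rate > thresholds$msm_flag_rate,
    stringsAsFactors = FALSE)
}
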