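#' Run the full QC and parentage pipeline
#'
#' Wires the stages in their operational order: genotype QC first (a
#' genotype must pass every genotype-level check to be used downstream),
#' then parentage — validation of listed parents, whole-table parent
#' prediction for animals without two validated parents, trio mating
#' validation where both parents validated — then animal-level QC.
#' Disabling a stage never changes the outputs of the stages before it.
#'
#' @param x a [GenotypeSet-class] (e.g. from [readGenotypesMatrix()] or
#'   [simulateHerd()]).
#' @param animals metadata from [readAnimals()].
#' @param thresholds a [herdThresholds()] list.
#' @param ref optional `breed_reference` for the breed checks.
#' @param raw optional raw allele table for the format-purity check.
#' @param stages character subset of c("genotype_qc", "parentage",
#'   "animal_qc").
#' @param predict_unresolved run parent prediction for animals lacking
#'   two validated parents (the expensive stage on large herds).
#' @return list bundle: `genotype_qc`, `parentage` (validations,
#'   predictions, trios), `animal_qc`, `x` (final states), `config`.
#' @export
runPipeline <- function(x, animals, thresholds = herdThresholds(),
                        ref = NULL, raw = NULL,
                        stages = c("genotype_qc", "parentage", "animal_qc"),
                        predict_unresolved = FALSE) {
  bundle <- list(config = list(thresholds = unclass(thresholds),
                               stages = stages))
  if ("genotype_qc" %in% stages) {
    gq <- runGenotypeQC(x, raw = raw, thresholds = thresholds)
    bundle$genotype_qc <- gq$results
    x <- gq$x
  }
  xv <- x[, sampleInfo(x)$valid == "valid"]
  if ("parentage" %in% stages) {
    tab <- buildCandidateTable(xv, thresholds)
    val <- validateListedParents(tab, animals, thresholds)
    preds <- emptyParentageFrame()
    if (predict_unresolved) {
      ok2 <- vapply(split(val$verdict, val$animal_id), function(v)
        sum(v %in% c("validated", "gray_validated")) >= 2, FALSE)
      resolved <- names(ok2)[ok2]
      targets <- setdiff(as.character(sampleInfo(tab)$animal_id), resolved)
      pl <- lapply(targets, function(t)
        predictParents(t, tab, animals, thresholds))
      preds <- do.call(rbind, c(list(emptyParentageFrame()), pl))
    }
    trios <- list()
    for (a in unique(val$animal_id)) {
      rows <- val[val$animal_id == a, , drop = FALSE]
      sv <- rows[rows$role == "sire" &
                 rows$verdict %in% c("validated", "gray_validated"), ]
      dv <- rows[rows$role == "dam" &
                 rows$verdict %in% c("validated", "gray_validated"), ]
      if (nrow(sv) == 1 && nrow(dv) == 1)
        trios[[a]] <- countMSM(tab, rows$sample_id[1],
                               sv$candidate_sample, dv$candidate_sample,
                               thresholds)
    }
    bundle$parentage <- list(
      validations = val, predictions = preds,
      trios = if (length(trios)) do.call(rbind, trios) else NULL)
  }
  if ("animal_qc" %in% stages) {
    aq <- runAnimalQC(xv, animals, thresholds, ref)
    bundle$animal_qc <- aq
    sv <- sampleInfo(x)$valid
    names(sv) <- colnames(x)
    sv[rownames(aq$report)] <- aq$report$final_state
    upd <- aq$report$final_state
    names(upd) <- aq$report$sample_id
    sv[names(upd)] <- upd
    SummarizedExperiment::colData(x)$valid <-
      as.character(sv[colnames(x)])
    x <- x
  }
  bundle$x <- x
  bundle
}

#' Write a pipeline bundle as TSV reports
#'
#' One TSV per stage plus a per-sample JSON evidence ledger (when the
#' jsonlite package is available).
#'
#' @param bundle output of [runPipeline()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeReportBundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name) utils::write.table(
    df, file.path(dir, name), sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(bundle$genotype_qc)) wt(bundle$genotype_qc, "genotype_qc.tsv")
  if (!is.null(bundle$parentage)) {
    wt(bundle$parentage$validations, "parentage_validations.tsv")
    if (nrow(bundle$parentage$predictions))
      wt(bundle$parentage$predictions, "parentage_predictions.tsv")
    if (!is.null(bundle$parentage$trios))
      wt(bundle$parentage$trios, "trios.tsv")
  }
  if (!is.null(bundle$animal_qc)) {
    wt(bundle$animal_qc$report, "animal_qc.tsv")
    if (requireNamespace("jsonlite", quietly = TRUE))
      jsonlite::write_json(bundle$animal_qc$evidence,
                           file.path(dir, "evidence_ledger.json"),
                           auto_unbox = TRUE, null = "null")
  }
  invisible(dir)
}
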