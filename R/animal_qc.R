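#' Offspring-failure pattern flag for a parent genotype
#'
#' A parent genotype that looks clean can still be wrongly assigned; the
#' pattern of its genotyped offspring exposes this. A dam is flagged when
#' she has at least 2 genotyped offspring and all fail against her; a
#' stock bull at 5 or more offspring with at least 80% failing; an AI
#' sire at 10 or more with at least 80% failing.
#'
#' @param parent_id animal id of the parent.
#' @param parentage data.frame of parentage results (rows where
#'   `candidate_id == parent_id` are used; verdicts failed/gray_failed
#'   count as failures, validated/gray_validated as successes).
#' @param parent_class `"dam"`, `"stock_bull"` or `"ai_sire"`.
#' @param thresholds a [herdThresholds()] list.
#' @return list with `flag`, `n_offspring`, `n_fail`.
#' @export
offspringPatternCheck <- function(parent_id, parentage, parent_class,
                                  thresholds = herdThresholds()) {
  parent_class <- match.arg(parent_class, c("dam", "stock_bull", "ai_sire"))
  rows <- parentage[parentage$candidate_id == parent_id &
                    parentage$verdict %in%
                      c("validated", "gray_validated",
                        "failed", "gray_failed"), , drop = FALSE]
  n <- nrow(rows)
  n_fail <- sum(rows$verdict %in% c("failed", "gray_failed"))
  flag <- switch(parent_class,
    dam = n >= thresholds$dam_offspring_flag_n && n_fail == n && n > 0,
    stock_bull = n >= thresholds$stockbull_offspring_flag_n &&
      n_fail / n >= thresholds$offspring_fail_frac,
    ai_sire = n >= thresholds$aibull_offspring_flag_n &&
      n_fail / n >= thresholds$offspring_fail_frac)
  list(flag = isTRUE(flag), n_offspring = n, n_fail = n_fail)
}

#' Reset parentage verdicts that cite an invalidated genotype
#'
#' When a parent genotype is invalidated, every parentage verdict whose
#' evidence is that genotype is reset to `unresolved`; verdicts not
#' citing it are untouched.
#'
#' @param parentage data.frame of parentage results.
#' @param sample_id the invalidated genotype's sample id.
#' @return the data.frame with affected verdicts set to "unresolved".
#' @export
resetParentageForGenotype <- function(parentage, sample_id) {
  hit <- parentage$sample_id == sample_id |
    parentage$candidate_sample == sample_id
  parentage$verdict[hit] <- "unresolved"
  parentage
}

#' Post-death sample warning flag
#'
#' Tissue collected more than 45 days after the recorded death is
#' suspicious (strictly greater; day 45 itself is not flagged). AI sires
#' are exempt when the submitted sample is a semen straw. The flag never
#' invalidates on its own; it feeds duplicate resolution.
#'
#' @param collection_date,death_date Dates (NA allowed).
#' @param animal_class animal class string.
#' @param sample_type `"tissue"` or `"straw"`.
#' @param thresholds a [herdThresholds()] list.
#' @return TRUE when the flag raises.
#' @export
postDeathFlag <- function(collection_date, death_date,
                          animal_class = "commercial",
                          sample_type = "tissue",
                          thresholds = herdThresholds()) {
  if (is.na(collection_date) || is.na(death_date)) return(FALSE)
  if (identical(animal_class, "ai_sire") && identical(sample_type, "straw"))
    return(FALSE)
  as.numeric(collection_date - death_date) > thresholds$dead_sample_days
}

.evAgainstAnimal <- function(x, sample, animal_id, animals, thresholds,
                             ref = NULL, excluded = character()) {
  ## evidence of one genotype belonging to one animal, in priority order
  ev <- list()
  byAnimal <- stats::setNames(colnames(x), sampleInfo(x)$animal_id)
  byAnimal <- byAnimal[!byAnimal %in% excluded]
  ## 1) parentage against the animal's listed parents
  verdicts <- character()
  for (role in c("sire", "dam")) {
    pid <- animals[animal_id, paste0("listed_", role)]
    if (is.na(pid) || !pid %in% names(byAnimal)) next
    r <- validateParent(x, sample, byAnimal[[pid]], role, thresholds)
    verdicts <- c(verdicts, r$verdict)
  }
  ev$parentage <- if (!length(verdicts)) "ambiguous"
    else if (any(verdicts %in% c("validated", "gray_validated"))) "consistent"
    else if (all(verdicts %in% c("failed", "gray_failed"))) "inconsistent"
    else "ambiguous"
  ## 2) the animal's genotyped offspring against this genotype
  off <- rownames(animals)[!is.na(animals$listed_sire) &
                             animals$listed_sire == animal_id |
                           !is.na(animals$listed_dam) &
                             animals$listed_dam == animal_id]
  off <- off[off %in% names(byAnimal)]
  overd <- vapply(off, function(o) {
    role <- if (identical(animals[animal_id, "recorded_sex"], "male"))
      "sire" else "dam"
    validateParent(x, byAnimal[[o]], sample, role, thresholds)$verdict
  }, "")
  ev$offspring <- if (!length(overd)) "ambiguous"
    else if (any(overd %in% c("validated", "gray_validated"))) "consistent"
    else if (length(overd) >= 2 &&
             all(overd %in% c("failed", "gray_failed"))) "inconsistent"
    else "ambiguous"
  ## 3) predicted vs recorded sex
  sp <- predictSex(x[, sample, drop = FALSE], thresholds)
  rec <- animals[animal_id, "recorded_sex"]
  ev$sex <- if (!sp$combined %in% c("male", "female") ||
                !rec %in% c("male", "female")) "ambiguous"
    else if (sp$combined == rec) "consistent" else "inconsistent"
  ## 4) predicted vs listed breed composition
  if (!is.null(ref)) {
    est <- estimateBreedComposition(alignToReference(x, sample, ref), ref,
                                    thresholds)
    cmp <- compareToListed(est, animals[animal_id, "breed32"][[1]], ref,
                           thresholds)
    ev$breed <- switch(cmp, match = "consistent",
                       mismatch = "inconsistent", "ambiguous")
  } else ev$breed <- "ambiguous"
  ev
}

.coResident <- function(animals, id_a, id_b) {
  ha <- animals[id_a, "herds"][[1]]; hb <- animals[id_b, "herds"][[1]]
  if (!nrow(ha) || !nrow(hb)) return(NA)
  far <- as.Date("9999-12-31")
  for (i in seq_len(nrow(ha))) for (j in seq_len(nrow(hb))) {
    if (ha$herd_id[i] != hb$herd_id[j]) next
    ea <- if (is.na(ha$to_date[i])) far else ha$to_date[i]
    eb <- if (is.na(hb$to_date[j])) far else hb$to_date[j]
    if (ha$from_date[i] <= eb && hb$from_date[j] <= ea) return(TRUE)
  }
  FALSE
}

#' Resolve a duplicate or multi-genotype conflict from all evidence
#'
#' Two genotypes are in conflict (confirmed cross-animal duplicates, or
#' discordant genotypes recorded for one animal). Evidence is evaluated
#' in fixed priority — parentage against listed parents, offspring
#' validation, predicted versus recorded sex, predicted versus listed
#' breed — for every genotype-to-animal assignment. An attribution is
#' made only when exactly one assignment has no inconsistent evidence
#' and at least one positively consistent item; otherwise the genotypes
#' stay unresolved. Herd co-residence is reported: animals that never
#' shared a farm point to a lab rather than a farm error.
#'
#' @param x a [GenotypeSet-class].
#' @param sample_a,sample_b the conflicting sample ids.
#' @param animals metadata from [readAnimals()].
#' @param thresholds a [herdThresholds()] list.
#' @param ref optional `breed_reference` enabling the breed evidence.
#' @return list: `status` ("resolved"/"unresolved"), `attribution`
#'   (named vector sample -> animal_id, or NULL; an NA value means that
#'   genotype belongs to neither animal), `evidence` (per-assignment
#'   evidence tables), `co_resident`, `note`.
#' @export
resolveConflict <- function(x, sample_a, sample_b, animals,
                            thresholds = herdThresholds(), ref = NULL) {
  id_a <- as.character(sampleInfo(x)[sample_a, "animal_id"])
  id_b <- as.character(sampleInfo(x)[sample_b, "animal_id"])
  excl <- c(sample_a, sample_b)
  ok <- function(e) !any(unlist(e) == "inconsistent")
  supported <- function(e) any(unlist(e) == "consistent")
  ## same DNA under two animal labels: decide which animal it belongs to
  pid <- .pairIdentity(calls(x)[, sample_a], calls(x)[, sample_b],
                       panelIndex(x))
  if (id_a != id_b && !is.na(pid$identity) &&
      pid$identity >= thresholds$duplicate_identity_min) {
    ev <- list(
      dna_a = .evAgainstAnimal(x, sample_a, id_a, animals, thresholds,
                               ref, excl),
      dna_b = .evAgainstAnimal(x, sample_a, id_b, animals, thresholds,
                               ref, excl))
    fits <- c(a = ok(ev$dna_a) && supported(ev$dna_a),
              b = ok(ev$dna_b) && supported(ev$dna_b))
    co <- .coResident(animals, id_a, id_b)
    note <- if (identical(co, FALSE))
      "animals never co-resident: potential lab error" else ""
    if (sum(fits) == 1) {
      winner <- if (fits[["a"]]) id_a else id_b
      keep <- if (fits[["a"]]) sample_a else sample_b
      drop <- setdiff(excl, keep)
      attribution <- stats::setNames(c(winner, NA_character_),
                                     c(keep, drop))
      return(list(status = "resolved", attribution = attribution,
                  evidence = ev, co_resident = co, note = note))
    }
    return(list(status = "unresolved", attribution = NULL, evidence = ev,
                co_resident = co,
                note = if (nzchar(note)) note else "no unique fit"))
  }
  ev <- list(
    aa = .evAgainstAnimal(x, sample_a, id_a, animals, thresholds, ref, excl),
    bb = .evAgainstAnimal(x, sample_b, id_b, animals, thresholds, ref, excl),
    ab = .evAgainstAnimal(x, sample_a, id_b, animals, thresholds, ref, excl),
    ba = .evAgainstAnimal(x, sample_b, id_a, animals, thresholds, ref, excl))
  if (id_a == id_b) {
    ## one animal, two discordant genotypes: at most one can be its DNA
    fits <- c(a = ok(ev$aa) && supported(ev$aa),
              b = ok(ev$bb) && supported(ev$bb))
    if (sum(fits) == 1) {
      keep <- if (fits[["a"]]) sample_a else sample_b
      drop <- setdiff(excl, keep)
      attribution <- stats::setNames(c(id_a, NA_character_), c(keep, drop))
      return(list(status = "resolved", attribution = attribution,
                  evidence = ev, co_resident = TRUE, note = ""))
    }
    return(list(status = "unresolved", attribution = NULL, evidence = ev,
                co_resident = TRUE, note = "no unique fit"))
  }
  asis <- ok(ev$aa) && ok(ev$bb) && (supported(ev$aa) || supported(ev$bb))
  swap <- ok(ev$ab) && ok(ev$ba) && (supported(ev$ab) || supported(ev$ba))
  co <- .coResident(animals, id_a, id_b)
  note <- if (identical(co, FALSE))
    "animals never co-resident: potential lab error" else ""
  if (xor(asis, swap)) {
    attribution <- if (asis)
      stats::setNames(c(id_a, id_b), c(sample_a, sample_b)) else
      stats::setNames(c(id_b, id_a), c(sample_a, sample_b))
    list(status = "resolved", attribution = attribution, evidence = ev,
         co_resident = co, note = note)
  } else {
    list(status = "unresolved", attribution = NULL, evidence = ev,
         co_resident = co, note = if (nzchar(note)) note else
           "no unique consistent assignment")
  }
}

#' Run the animal-level QC pipeline
#'
#' For genotype-QC-passed samples, runs in order: duplicate discovery
#' and confirmation, multi-genotype reconciliation, sex check against
#' recorded sex, breed check against listed composition (when a
#' reference is supplied), parentage validation of listed parents,
#' offspring-pattern flags, and the post-death sample flag. All checks
#' run for every sample before any decision. Decision rule: a pedigree
#' animal with a breed mismatch is invalidated; confirmed unreconciled
#' duplicate or multi-genotype conflicts are invalid pending
#' [resolveConflict()] (which is attempted, and its attributions
#' applied); any other single failure only flags.
#'
#' @param x a [GenotypeSet-class] of QC-passed samples.
#' @param animals metadata from [readAnimals()].
#' @param thresholds a [herdThresholds()] list.
#' @param ref optional `breed_reference`.
#' @return list: `report` (per-sample data.frame with each check outcome
#'   and `final_state`), `parentage` (validation results), `duplicates`,
#'   `sex`, `resolutions`, `evidence` (per-sample log lines), and `x`
#'   with updated validity states.
#' @export
runAnimalQC <- function(x, animals, thresholds = herdThresholds(),
                        ref = NULL) {
  evlog <- stats::setNames(vector("list", ncol(x)), colnames(x))
  note <- function(s, m) evlog[[s]] <<- c(evlog[[s]], m)

  ## 1) duplicate check
  cand <- findDuplicateCandidates(x, thresholds = thresholds)
  dup <- confirmDuplicates(x, cand, thresholds, animals = animals)
  x <- dup$x
  dup_status <- stats::setNames(rep("clear", ncol(x)), colnames(x))
  for (k in seq_len(nrow(dup$results))) {
    r <- dup$results[k, ]
    if (r$status != "confirmed") next
    lab <- if (r$possible_twins) "possible_twins" else "duplicate"
    for (s in c(r$sample_a, r$sample_b)) {
      dup_status[s] <- lab
      note(s, sprintf("duplicate check: %s with %s (panel %.3f, full %.3f)",
                      lab, setdiff(c(r$sample_a, r$sample_b), s),
                      r$panel_identity, r$full_identity))
    }
  }

  ## 2) multi-genotype reconciliation
  multi_status <- stats::setNames(rep("single", ncol(x)), colnames(x))
  aid <- as.character(sampleInfo(x)$animal_id)
  conflict_pairs <- list()
  for (a in unique(aid[duplicated(aid)])) {
    rec <- reconcileMultiGenotypes(x, a, thresholds)
    ss <- colnames(x)[aid == a]
    multi_status[ss] <- rec$status
    for (s in ss) note(s, paste0("multi-genotype check: ", rec$status))
    if (rec$status == "conflict") {
      bad <- rec$pairs[!rec$pairs$concordant, , drop = FALSE]
      for (k in seq_len(nrow(bad)))
        conflict_pairs[[length(conflict_pairs) + 1L]] <-
          c(bad$sample_a[k], bad$sample_b[k])
    }
  }

  ## 3) sex check
  sexres <- predictSex(x, thresholds)
  rec_sex <- animals[aid, "recorded_sex"]
  sex_check <- ifelse(!sexres$combined %in% c("male", "female"),
                      sexres$combined,
                      ifelse(is.na(rec_sex) | !rec_sex %in%
                               c("male", "female"), "no_record",
                             ifelse(sexres$combined == rec_sex,
                                    "match", "mismatch")))
  names(sex_check) <- colnames(x)

  ## 4) breed check
  breed_check <- stats::setNames(rep("not_run", ncol(x)), colnames(x))
  if (!is.null(ref)) {
    for (j in seq_len(ncol(x))) {
      a <- aid[j]
      if (!a %in% rownames(animals)) next
      est <- estimateBreedComposition(
        alignToReference(x, colnames(x)[j], ref), ref, thresholds)
      breed_check[j] <- compareToListed(est, animals[a, "breed32"][[1]],
                                        ref, thresholds)
    }
  }

  ## 5) parentage validation of listed parents
  tab <- buildCandidateTable(x, thresholds)
  parentage <- validateListedParents(tab, animals, thresholds)
  par_check <- stats::setNames(rep("no_data", ncol(x)), colnames(x))
  for (k in seq_len(nrow(parentage))) {
    s <- parentage$sample_id[k]
    v <- parentage$verdict[k]
    cur <- par_check[s]
    par_check[s] <- if (v %in% c("failed", "gray_failed") ||
                        cur == "some_fail") "some_fail"
      else if (v %in% c("validated", "gray_validated")) "validated"
      else cur
  }

  ## 6) offspring pattern per parent genotype
  offspring_flag <- stats::setNames(rep(FALSE, ncol(x)), colnames(x))
  for (j in seq_len(ncol(x))) {
    a <- aid[j]
    if (!a %in% rownames(animals)) next
    cls <- if (identical(animals[a, "recorded_sex"], "female")) "dam"
           else if (identical(animals[a, "animal_class"], "ai_sire"))
             "ai_sire" else "stock_bull"
    chk <- offspringPatternCheck(a, parentage, cls, thresholds)
    offspring_flag[j] <- chk$flag
    if (chk$flag)
      note(colnames(x)[j],
           sprintf("offspring pattern: %d of %d genotyped offspring fail",
                   chk$n_fail, chk$n_offspring))
  }

  ## 7) post-death flag
  ci <- sampleInfo(x)
  coldate <- if ("sample_collection_date" %in% colnames(ci))
    as.Date(ci$sample_collection_date) else as.Date(rep(NA, ncol(x)))
  stype <- if ("sample_type" %in% colnames(ci))
    as.character(ci$sample_type) else rep("tissue", ncol(x))
  post_death <- vapply(seq_len(ncol(x)), function(j) {
    a <- aid[j]
    if (!a %in% rownames(animals)) return(FALSE)
    postDeathFlag(coldate[j], animals[a, "death_date"],
                  animals[a, "animal_class"], stype[j], thresholds)
  }, FALSE)
  names(post_death) <- colnames(x)

  ## decision rule
  final <- stats::setNames(rep("valid", ncol(x)), colnames(x))
  pedigree_animal <- aid %in% rownames(animals) &
    animals[aid, "animal_class"] == "pedigree"
  final[breed_check == "mismatch" & pedigree_animal] <- "invalid"
  conflicted <- dup_status == "duplicate" | multi_status == "conflict"
  final[conflicted] <- "unresolved"
  single_flag <- sex_check == "mismatch" | offspring_flag | post_death |
    par_check == "some_fail" | breed_check == "mismatch"
  final[final == "valid" & single_flag] <- "flagged"

  ## attempt resolution of conflicted pairs
  for (k in seq_len(nrow(dup$results))) {
    r <- dup$results[k, ]
    if (r$status == "confirmed" && !r$possible_twins &&
        as.character(sampleInfo(x)[r$sample_a, "animal_id"]) !=
        as.character(sampleInfo(x)[r$sample_b, "animal_id"]))
      conflict_pairs[[length(conflict_pairs) + 1L]] <-
        c(r$sample_a, r$sample_b)
  }
  resolutions <- list()
  for (pr in conflict_pairs) {
    res <- resolveConflict(x, pr[1], pr[2], animals, thresholds, ref)
    resolutions[[paste(pr, collapse = "|")]] <- res
    if (res$status == "resolved") {
      for (s in names(res$attribution)) {
        a_new <- res$attribution[[s]]
        if (is.na(a_new)) {
          final[s] <- "invalid"
          note(s, "conflict resolved: genotype does not belong to its animal")
        } else {
          SummarizedExperiment::colData(x)[s, "animal_id"] <- a_new
          final[s] <- "valid"
          note(s, paste0("conflict resolved: genotype attributed to ", a_new))
        }
      }
    } else {
      for (s in pr) note(s, paste0("conflict unresolved: ", res$note))
    }
  }

  SummarizedExperiment::colData(x)$valid <- final
  report <- data.frame(
    sample_id = colnames(x), animal_id = as.character(sampleInfo(x)$animal_id),
    dup_status = dup_status, multi_status = multi_status,
    sex_check = sex_check, breed_check = breed_check,
    parentage_check = par_check, offspring_flag = offspring_flag,
    post_death_flag = post_death, final_state = final,
    stringsAsFactors = FALSE, row.names = NULL)
  list(report = report, parentage = parentage, duplicates = dup$results,
       sex = sexres, resolutions = resolutions, evidence = evlog, x = x)
}
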