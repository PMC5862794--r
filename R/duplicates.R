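#' Encode a sample's panel genotype as a numeric string
#'
#' Character i is the call at panel position i, using `0` = BB, `1` = AB,
#' `2` = AA, `9` = missing — e.g. `"001290021"` for a 9-SNP panel.
#'
#' @param x a [GenotypeSet-class].
#' @param sample column name; when `NULL` all samples are encoded.
#' @param panel panel name.
#' @return named character vector of panel strings.
#' @export
encodePanelString <- function(x, sample = NULL, panel = "icbf800") {
  pidx <- panelIndex(x, panel)
  m <- calls(x)[pidx, , drop = FALSE]
  if (!is.null(sample)) m <- m[, sample, drop = FALSE]
  apply(m, 2, paste0, collapse = "")
}

#' Index panel strings by exact block content
#'
#' Splits each string into consecutive non-overlapping blocks of
#' `block_size` characters and groups samples whose substring for a block
#' is byte-identical (a missing `9` only matches another `9`). Two block
#' sizes are in operational use: 50 (16 blocks of an 800-SNP string) and
#' 20 (40 blocks), the smaller one tolerating more scattered missingness.
#'
#' @param strings named character vector from [encodePanelString()].
#' @param block_size block length; must divide the string length.
#' @return list keyed by `"<block>:<substring>"`, each element the
#'   character vector of samples sharing that block content.
#' @export
blockIndex <- function(strings, block_size) {
  L <- unique(nchar(strings))
  if (length(L) > 1) stop("panel strings of unequal length")
  if (L %% block_size != 0)
    stop("block_size ", block_size, " does not divide string length ", L)
  nblock <- L / block_size
  starts <- (seq_len(nblock) - 1L) * block_size + 1L
  keys <- unlist(lapply(seq_len(nblock), function(b)
    paste0(b, ":", substring(strings, starts[b], starts[b] + block_size - 1L))))
  samp <- rep(names(strings), times = nblock)
  split(samp, keys)
}

#' Find duplicate-sample candidates by block matching
#'
#' A pair of samples is a candidate when at least one block of their
#' panel strings matches exactly. Each unordered pair is reported once.
#'
#' @param x a [GenotypeSet-class].
#' @param block_size block length (default from `thresholds$block_size`).
#' @param thresholds a [herdThresholds()] list.
#' @param panel panel name.
#' @return data.frame with `sample_a`, `sample_b` (lexicographically
#'   ordered) and `n_matched_blocks`.
#' @export
findDuplicateCandidates <- function(x, block_size = NULL,
                                    thresholds = herdThresholds(),
                                    panel = "icbf800") {
  if (is.null(block_size)) block_size <- thresholds$block_size
  strings <- encodePanelString(x, panel = panel)
  idx <- blockIndex(strings, block_size)
  idx <- idx[lengths(idx) > 1]
  if (!length(idx))
    return(data.frame(sample_a = character(), sample_b = character(),
                      n_matched_blocks = integer(), stringsAsFactors = FALSE))
  pairs <- do.call(rbind, lapply(idx, function(s) {
    s <- sort(s)
    t(utils::combn(s, 2))
  }))
  key <- paste(pairs[, 1], pairs[, 2], sep = "\r")
  tab <- table(key)
  ab <- do.call(rbind, strsplit(names(tab), "\r", fixed = TRUE))
  out <- data.frame(sample_a = ab[, 1], sample_b = ab[, 2],
                    n_matched_blocks = as.integer(tab),
                    stringsAsFactors = FALSE)
  out[order(out$sample_a, out$sample_b), , drop = FALSE]
}

.pairIdentity <- function(a, b, idx) {
  a <- a[idx]; b <- b[idx]
  both <- a != 9L & b != 9L
  list(n = sum(both),
       identity = if (any(both)) mean(a[both] == b[both]) else NA_real_)
}

#' Confirm duplicate candidates SNP by SNP
#'
#' Candidates are compared on the panel with missing SNPs excluded, and
#' separately on all available SNPs. A pair is `confirmed` only when both
#' identities are at or above 99%; confirmed samples are set to
#' `unresolved` pending animal-level resolution. Confirmed pairs between
#' different animals sharing a dam and date of birth (within 7 days) are
#' labeled possible identical twins rather than errors.
#'
#' @param x a [GenotypeSet-class].
#' @param pairs data.frame from [findDuplicateCandidates()] (or any
#'   data.frame with `sample_a`/`sample_b`).
#' @param thresholds a [herdThresholds()] list.
#' @param panel panel name.
#' @param animals optional metadata for twin labeling.
#' @return list with `results` (sample_a, sample_b, panel_identity,
#'   full_identity, status, possible_twins) and `x` with updated states.
#' @export
confirmDuplicates <- function(x, pairs, thresholds = herdThresholds(),
                              panel = "icbf800", animals = NULL) {
  pidx <- panelIndex(x, panel)
  m <- calls(x)
  res <- lapply(seq_len(nrow(pairs)), function(k) {
    a <- m[, pairs$sample_a[k]]; b <- m[, pairs$sample_b[k]]
    pid <- .pairIdentity(a, b, pidx)
    if (!pid$n) stop("no mutually non-missing panel SNPs for pair ",
                     pairs$sample_a[k], " / ", pairs$sample_b[k])
    fid <- .pairIdentity(a, b, seq_along(a))
    confirmed <- pid$identity >= thresholds$duplicate_identity_min &&
      fid$identity >= thresholds$duplicate_identity_min
    data.frame(sample_a = pairs$sample_a[k], sample_b = pairs$sample_b[k],
               panel_identity = pid$identity, full_identity = fid$identity,
               status = if (confirmed) "confirmed" else "rejected",
               stringsAsFactors = FALSE)
  })
  res <- if (length(res)) do.call(rbind, res) else
    data.frame(sample_a = character(), sample_b = character(),
               panel_identity = numeric(), full_identity = numeric(),
               status = character(), stringsAsFactors = FALSE)
  res$possible_twins <- logical(nrow(res))
  if (!is.null(animals) && nrow(res)) {
    ai <- sampleInfo(x)
    for (k in which(res$status == "confirmed")) {
      ida <- as.character(ai[res$sample_a[k], "animal_id"])
      idb <- as.character(ai[res$sample_b[k], "animal_id"])
      if (ida != idb && ida %in% rownames(animals) &&
          idb %in% rownames(animals)) {
        same_dam <- identical(animals[ida, "listed_dam"],
                              animals[idb, "listed_dam"]) &&
          !is.na(animals[ida, "listed_dam"])
        close_dob <- !is.na(animals[ida, "dob"]) &&
          !is.na(animals[idb, "dob"]) &&
          abs(as.numeric(animals[ida, "dob"] - animals[idb, "dob"])) <= 7
        res$possible_twins[k] <- same_dam && close_dob
      }
    }
  }
  st <- sampleInfo(x)$valid
  hit <- colnames(x) %in%
    c(res$sample_a[res$status == "confirmed" & !res$possible_twins],
      res$sample_b[res$status == "confirmed" & !res$possible_twins])
  ## same-animal re-genotyping is legitimate: only cross-animal confirmed
  ## duplicates go to unresolved
  ai <- sampleInfo(x)
  cross <- rep(FALSE, ncol(x))
  for (k in which(res$status == "confirmed" & !res$possible_twins)) {
    if (!identical(as.character(ai[res$sample_a[k], "animal_id"]),
                   as.character(ai[res$sample_b[k], "animal_id"]))) {
      cross[colnames(x) %in% c(res$sample_a[k], res$sample_b[k])] <- TRUE
    }
  }
  st[hit & cross] <- "unresolved"
  SummarizedExperiment::colData(x)$valid <- st
  list(results = res, x = x)
}

#' Reconcile multiple genotypes recorded for one animal
#'
#' All pairs are compared on the panel and, when below the concordance
#' threshold there, on all shared SNPs. Any pair below 99% on both tiers
#' indicates the genotypes are not from the same animal: the animal is in
#' conflict and the involved genotypes are unresolved until animal-level
#' evidence resolves them. With three or more genotypes the pairwise
#' pattern identifies the odd one out.
#'
#' @param x a [GenotypeSet-class].
#' @param animal_id animal with two or more valid genotypes in `x`.
#' @param thresholds a [herdThresholds()] list.
#' @param panel panel name.
#' @return list with `status` ("consistent"/"conflict"), `pairs`
#'   (pairwise identities with a `concordant` flag), and `odd_one_out`
#'   (sample id or NA).
#' @export
reconcileMultiGenotypes <- function(x, animal_id,
                                    thresholds = herdThresholds(),
                                    panel = "icbf800") {
  samp <- colnames(x)[sampleInfo(x)$animal_id == animal_id &
                      sampleInfo(x)$valid %in% c("valid", "unresolved")]
  if (length(samp) < 2)
    stop("animal ", animal_id, " has fewer than 2 usable genotypes")
  pidx <- panelIndex(x, panel)
  m <- calls(x)
  cmb <- utils::combn(samp, 2)
  pairs <- lapply(seq_len(ncol(cmb)), function(k) {
    a <- m[, cmb[1, k]]; b <- m[, cmb[2, k]]
    pid <- .pairIdentity(a, b, pidx)
    fid <- .pairIdentity(a, b, seq_along(a))
    conc <- pid$identity >= thresholds$duplicate_identity_min ||
      fid$identity >= thresholds$duplicate_identity_min
    data.frame(sample_a = cmb[1, k], sample_b = cmb[2, k],
               panel_identity = pid$identity, full_identity = fid$identity,
               concordant = conc, stringsAsFactors = FALSE)
  })
  pairs <- do.call(rbind, pairs)
  status <- if (all(pairs$concordant)) "consistent" else "conflict"
  odd <- NA_character_
  if (status == "conflict" && length(samp) >= 3) {
    bad_count <- vapply(samp, function(s)
      sum(!pairs$concordant & (pairs$sample_a == s | pairs$sample_b == s)),
      0L)
    if (sum(bad_count == max(bad_count)) == 1 &&
        max(bad_count) == length(samp) - 1)
      odd <- samp[which.max(bad_count)]
  }
  list(status = status, pairs = pairs, odd_one_out = odd)
}
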