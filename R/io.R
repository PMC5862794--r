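#' Read a SNP map
#'
#' Tab-separated, one row per SNP, with header columns `snp_id`,
#' `chromosome` (1..29, X, Y, MT), `position_bp` (1-based), the panel
#' flags `in_icbf800`, `in_isag100`, `in_isag200`, `is_par`, `cluster_ok`,
#' and optionally `top_a`/`top_b` (the ACGT letters of the A and B alleles,
#' required only when genotype files arrive in Top allele format).
#'
#' @param path path to the TSV file.
#' @return A `DataFrame` sorted by (chromosome, position_bp) with `snp_id`
#'   as rownames, ready for [GenotypeSet()].
#' @export
readSnpMap <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(snp_id = "character",
                                         chromosome = "character"))
  need <- c("snp_id", SNPMAP_COLS)
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("SNP map lacks column(s): ", paste(miss, collapse = ", "))
  dup <- df$snp_id[duplicated(df$snp_id)]
  if (length(dup))
    stop("duplicated snp_id in SNP map: ", paste(unique(dup), collapse = ", "))
  if (!all(df$chromosome %in% CHROM_LEVELS))
    stop("unknown chromosome label: ",
         paste(unique(setdiff(df$chromosome, CHROM_LEVELS)), collapse = ", "))
  if (any(!is.finite(df$position_bp)) || any(df$position_bp <= 0))
    stop("position_bp must be a positive integer")
  for (fl in SNPMAP_COLS[-(1:2)]) df[[fl]] <- as.logical(df[[fl]])
  if (any(df$is_par & df$chromosome != "X"))
    stop("is_par=TRUE on a non-X chromosome")
  ord <- order(match(df$chromosome, CHROM_LEVELS), df$position_bp)
  df <- df[ord, , drop = FALSE]
  out <- S4Vectors::DataFrame(df[, setdiff(colnames(df), "snp_id"),
                                 drop = FALSE],
                              row.names = df$snp_id)
  out
}

#' @rdname readSnpMap
#' @param map a SNP map `DataFrame` (e.g. `snpMap(x)`).
#' @export
writeSnpMap <- function(map, path) {
  df <- data.frame(snp_id = rownames(map), as.data.frame(map),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## allele pair -> integer call, given the per-SNP A/B alphabet
.encodePair <- function(a1, a2) {
  nA <- (a1 == "A") + (a2 == "A")
  call <- rep(9L, length(a1))
  ok <- a1 %in% c("A", "B") & a2 %in% c("A", "B")
  call[ok] <- nA[ok]
  call
}

.missingTokens <- c("-", "--", "0", "")

#' Read long-format genotype calls
#'
#' CSV with columns `sample_id, snp_id, allele1, allele2`; missing alleles
#' are `-` or `--`. AB format codes (A,A) as 2 (AA), heterozygotes as 1,
#' (B,B) as 0. Top ACTG format is converted to AB via the `top_a`/`top_b`
#' columns of the SNP map; conversion refuses to run without them. Rows
#' whose `snp_id` is absent from the map are dropped and counted
#' (`metadata(x)$n_dropped_snp_rows`). Alleles outside the declared
#' format's alphabet raise a format-anomaly error (condition class
#' `herdqc_format_anomaly`) carrying the offending rows in its `rows`
#' field; see [detectMixedFormat()] for the non-throwing check.
#'
#' @param path CSV path.
#' @param map SNP map from [readSnpMap()].
#' @param fmt `"AB"` or `"TOP"`.
#' @param sampleData optional per-sample metadata.
#' @return A [GenotypeSet-class]; SNPs never observed for a sample are 9.
#' @export
readGenotypesLong <- function(path, map, fmt = c("AB", "TOP"),
                              sampleData = NULL) {
  fmt <- match.arg(fmt)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("sample_id", "snp_id", "allele1", "allele2")
  if (!all(need %in% colnames(df)))
    stop("long genotype file needs columns ", paste(need, collapse = ", "))
  known <- df$snp_id %in% rownames(map)
  n_dropped <- sum(!known)
  if (n_dropped)
    message(n_dropped, " row(s) with snp_id absent from the map dropped")
  df <- df[known, , drop = FALSE]
  alphabet <- if (fmt == "AB") c("A", "B") else c("A", "C", "G", "T")
  bad <- !(df$allele1 %in% c(alphabet, .missingTokens)) |
         !(df$allele2 %in% c(alphabet, .missingTokens))
  if (any(bad)) {
    rows <- df[bad, need, drop = FALSE]
    stop(errorCondition(
      sprintf("%d call(s) outside the %s alphabet (e.g., %s/%s at %s for %s)",
              sum(bad), fmt, rows$allele1[1], rows$allele2[1],
              rows$snp_id[1], rows$sample_id[1]),
      rows = rows,
      class = c("herdqc_format_anomaly", "error", "condition")))
  }
  a1 <- df$allele1; a2 <- df$allele2
  a1[a1 %in% .missingTokens] <- "-"
  a2[a2 %in% .missingTokens] <- "-"
  if (fmt == "TOP") {
    if (!all(c("top_a", "top_b") %in% colnames(map)))
      stop("TOP format requires 'top_a' and 'top_b' columns in the SNP map")
    ta <- map[df$snp_id, "top_a"]; tb <- map[df$snp_id, "top_b"]
    conv <- function(a, ta, tb) {
      out <- rep("-", length(a))
      out[a == ta] <- "A"; out[a == tb] <- "B"
      stray <- a != "-" & out == "-"
      if (any(stray))
        stop(errorCondition(
          sprintf("%d TOP allele(s) not matching the SNP's declared alleles",
                  sum(stray)),
          rows = df[stray, need, drop = FALSE],
          class = c("herdqc_format_anomaly", "error", "condition")))
      out
    }
    a1 <- conv(a1, ta, tb); a2 <- conv(a2, ta, tb)
  }
  samples <- unique(df$sample_id)
  m <- matrix(9L, nrow = nrow(map), ncol = length(samples),
              dimnames = list(rownames(map), samples))
  idx <- cbind(match(df$snp_id, rownames(map)),
               match(df$sample_id, samples))
  m[idx] <- .encodePair(a1, a2)
  gs <- GenotypeSet(m, map, sampleData)
  S4Vectors::metadata(gs)$n_dropped_snp_rows <- n_dropped
  gs
}

#' Read / write matrix-format genotypes
#'
#' TSV with `sample_id` as the first column and one column per SNP, in SNP
#' map order; cells are 0 (BB), 1 (AB), 2 (AA) or 9 (missing). A write
#' followed by a read reproduces the calls exactly.
#'
#' @param path TSV path.
#' @param map SNP map from [readSnpMap()].
#' @param sampleData optional per-sample metadata.
#' @return [GenotypeSet-class] for the reader; the writer returns `path`
#'   invisibly.
#' @export
readGenotypesMatrix <- function(path, map, sampleData = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (colnames(df)[1] != "sample_id")
    stop("first column must be 'sample_id'")
  snps <- colnames(df)[-1]
  if (!setequal(snps, rownames(map)))
    stop("column set differs from the SNP map (",
         length(setdiff(snps, rownames(map))), " unknown, ",
         length(setdiff(rownames(map), snps)), " absent)")
  df <- df[, c("sample_id", rownames(map)), drop = FALSE]
  m <- t(as.matrix(df[, -1, drop = FALSE]))
  storage.mode(m) <- "integer"
  colnames(m) <- df$sample_id
  bad <- which(!m %in% c(0L, 1L, 2L, 9L))
  if (length(bad)) {
    rc <- arrayInd(bad[1], dim(m))
    stop(sprintf("cell outside {0,1,2,9}: value %s at snp %s, sample %s",
                 m[bad[1]], rownames(m)[rc[1]], colnames(m)[rc[2]]))
  }
  GenotypeSet(m, map, sampleData)
}

#' @rdname readGenotypesMatrix
#' @param x a [GenotypeSet-class]
#' @export
writeGenotypesMatrix <- function(x, path) {
  m <- t(calls(x))
  ids <- colnames(x)
  if (is.null(ids)) ids <- character(0)
  df <- data.frame(sample_id = ids, m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read PLINK PED/MAP genotypes
#'
#' Supports the text PED dialect: six leading columns (family, sample id,
#' father, mother, sex, phenotype) followed by two alleles per SNP, `0`
#' meaning missing. Alleles may be A/B, or ACGT when the SNP map supplies
#' `top_a`/`top_b`. SNP order is taken from the `.map` file and must match
#' the supplied SNP map (SNPs absent from the map are dropped).
#'
#' @param ped_path,map_path paths to the `.ped` and `.map` files.
#' @param map SNP map from [readSnpMap()].
#' @param fmt allele alphabet, `"AB"` or `"TOP"`.
#' @return A [GenotypeSet-class] with `sample_id` from PED column 2.
#' @export
readPlinkPed <- function(ped_path, map_path, map, fmt = c("AB", "TOP")) {
  fmt <- match.arg(fmt)
  pm <- utils::read.table(map_path, stringsAsFactors = FALSE)
  snp_ids <- pm[[2]]
  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  toks <- strsplit(trimws(lines), "[ \t]+")
  nall <- lengths(toks) - 6L
  if (any(nall != 2L * length(snp_ids)))
    stop("PED line ", which(nall != 2L * length(snp_ids))[1],
         " has ", nall[nall != 2L * length(snp_ids)][1],
         " allele fields; expected ", 2L * length(snp_ids))
  keep <- snp_ids %in% rownames(map)
  if (!all(keep))
    message(sum(!keep), " PED SNP(s) absent from the map dropped")
  rows <- lapply(toks, function(tk) {
    al <- tk[-(1:6)]
    a1 <- al[c(TRUE, FALSE)][keep]
    a2 <- al[c(FALSE, TRUE)][keep]
    list(id = tk[2], a1 = a1, a2 = a2)
  })
  kept_ids <- snp_ids[keep]
  df <- data.frame(
    sample_id = rep(vapply(rows, `[[`, "", "id"), each = sum(keep)),
    snp_id = rep(kept_ids, length(rows)),
    allele1 = unlist(lapply(rows, `[[`, "a1")),
    allele2 = unlist(lapply(rows, `[[`, "a2")),
    stringsAsFactors = FALSE)
  tmp <- tempfile(fileext = ".csv")
  on.exit(unlink(tmp))
  utils::write.csv(df, tmp, row.names = FALSE)
  suppressMessages(readGenotypesLong(tmp, map, fmt = fmt))
}

#' Read animal metadata and pedigree
#'
#' CSV with columns `animal_id`, `recorded_sex` (male/female/unknown),
#' `dob`, `death_date` (ISO dates, blank when absent), `listed_sire`,
#' `listed_dam`, `animal_class` (commercial/pedigree/ai_sire/stock_bull),
#' `breed_composition` (breed fractions in 32nds, e.g. `"LM:24,AA:8"`;
#' parts may sum to less than 32, the remainder being unknown ancestry),
#' and optionally `herd_intervals`
#' (`"H1:2018-01-01:2019-05-01;H2:2019-05-02:"`, open-ended allowed).
#'
#' @param path CSV path.
#' @return data.frame with list-columns `breed32` (named integer vectors)
#'   and `herds` (data.frames herd_id/from_date/to_date).
#' @export
readAnimals <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("animal_id", "recorded_sex", "dob", "listed_sire", "listed_dam",
            "animal_class", "breed_composition")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("animal file lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$animal_id))
    stop("duplicated animal_id in animal file")
  df$dob <- as.Date(df$dob)
  df$death_date <- if ("death_date" %in% colnames(df))
    as.Date(ifelse(nzchar(df$death_date), df$death_date, NA)) else
    as.Date(rep(NA, nrow(df)))
  df$listed_sire[!nzchar(df$listed_sire)] <- NA
  df$listed_dam[!nzchar(df$listed_dam)] <- NA
  df$breed32 <- lapply(df$breed_composition, parseBreed32)
  df$herds <- if ("herd_intervals" %in% colnames(df))
    lapply(df$herd_intervals, parseHerdIntervals) else
    rep(list(emptyHerds()), nrow(df))
  overlap <- vapply(df$herds, function(h) {
    if (nrow(h) < 2) return(FALSE)
    o <- order(h$from_date)
    ends <- h$to_date[o]
    ends[is.na(ends)] <- as.Date("9999-12-31")
    any(h$from_date[o][-1] <= ends[-nrow(h)])
  }, FALSE)
  if (any(overlap))
    stop("overlapping herd intervals for animal(s): ",
         paste(df$animal_id[overlap], collapse = ", "))
  df$breed_composition <- NULL
  df$herd_intervals <- NULL
  rownames(df) <- df$animal_id
  df
}

#' @rdname readAnimals
#' @param animals an animal metadata data.frame as returned by
#'   [readAnimals()] or [simulateHerd()].
#' @export
writeAnimals <- function(animals, path) {
  df <- animals[, c("animal_id", "recorded_sex", "dob", "death_date",
                    "listed_sire", "listed_dam", "animal_class")]
  df$breed_composition <- vapply(animals$breed32, function(b)
    paste(names(b), b, sep = ":", collapse = ","), "")
  df$herd_intervals <- vapply(animals$herds, function(h) {
    if (!nrow(h)) return("")
    paste(paste(h$herd_id, h$from_date,
                ifelse(is.na(h$to_date), "", as.character(h$to_date)),
                sep = ":"), collapse = ";")
  }, "")
  df$listed_sire[is.na(df$listed_sire)] <- ""
  df$listed_dam[is.na(df$listed_dam)] <- ""
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

parseBreed32 <- function(s) {
  if (is.na(s) || !nzchar(s)) return(stats::setNames(integer(), character()))
  parts <- strsplit(strsplit(s, ",", fixed = TRUE)[[1]], ":", fixed = TRUE)
  v <- stats::setNames(vapply(parts, function(p) as.integer(p[2]), 0L),
                       vapply(parts, `[[`, "", 1))
  if (sum(v) > 32L) stop("breed composition parts exceed 32/32: ", s)
  v
}

parseHerdIntervals <- function(s) {
  if (is.na(s) || !nzchar(s)) return(emptyHerds())
  parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
  data.frame(
    herd_id = vapply(parts, `[[`, "", 1),
    from_date = as.Date(vapply(parts, `[[`, "", 2)),
    to_date = as.Date(vapply(parts, function(p)
      if (length(p) >= 3 && nzchar(p[3])) p[3] else NA_character_, "")),
    stringsAsFactors = FALSE)
}

emptyHerds <- function()
  data.frame(herd_id = character(), from_date = as.Date(character()),
             to_date = as.Date(character()), stringsAsFactors = FALSE)
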