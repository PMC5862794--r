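# shared fixture builders; everything is generated in code

# a GenotypeSet with n autosomal panel SNPs from a call matrix
toyGS <- function(m, sampleData = NULL) {
  if (is.null(rownames(m))) rownames(m) <- paste0("snp", seq_len(nrow(m)))
  map <- exampleSnpMap(nrow(m))
  rownames(map) <- rownames(m)
  GenotypeSet(m, map, sampleData)
}

# write a SNP map TSV and return its path
writeSnpMapFile <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

snpMapDf <- function(n, chromosome = "1", is_par = FALSE, top = FALSE) {
  df <- data.frame(
    snp_id = paste0("snp", seq_len(n)),
    chromosome = rep_len(chromosome, n),
    position_bp = seq_len(n) * 1000L,
    in_icbf800 = TRUE, in_isag100 = FALSE, in_isag200 = FALSE,
    is_par = rep_len(is_par, n), cluster_ok = TRUE,
    stringsAsFactors = FALSE)
  if (top) { df$top_a <- "A"; df$top_b <- "C" }
  df
}

# minimal animal metadata frame in readAnimals() shape
animalsDf <- function(ids, sex = "female", dob = as.Date("2015-01-01"),
                      sire = NA, dam = NA, class = "commercial",
                      breed = c(B1 = 32L)) {
  n <- length(ids)
  df <- data.frame(animal_id = ids,
                   recorded_sex = rep_len(sex, n),
                   dob = rep_len(dob, n),
                   death_date = as.Date(rep(NA, n)),
                   listed_sire = rep_len(as.character(sire), n),
                   listed_dam = rep_len(as.character(dam), n),
                   animal_class = rep_len(class, n),
                   stringsAsFactors = FALSE)
  df$breed32 <- rep(list(breed), n)
  df$herds <- rep(list(data.frame(herd_id = "H1",
                                  from_date = as.Date("2014-01-01"),
                                  to_date = as.Date(NA))), n)
  rownames(df) <- ids
  df
}

# one small herd shared by several test files (cached per session)
.small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulateHerd(simConfig(seed = 42, n_founders = 20,
                                       n_generations = 2, n_offspring = 40))
    cache
  }
})
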