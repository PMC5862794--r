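test_that("SNP map reader sorts, validates and flags PAR", {
  df <- snpMapDf(3)
  df$chromosome <- c("2", "1", "X")
  df$is_par[3] <- TRUE
  map <- readSnpMap(writeSnpMapFile(df))
  expect_equal(nrow(map), 3)
  expect_equal(as.character(map$chromosome), c("1", "2", "X"))
  expect_true(map["snp3", "is_par"])

  dup <- rbind(df, df[1, ])
  expect_error(readSnpMap(writeSnpMapFile(dup)), "snp1")  # names the offender
  bad <- df; bad$chromosome[1] <- "Z"
  expect_error(readSnpMap(writeSnpMapFile(bad)), "chromosome")
  neg <- df; neg$position_bp[1] <- -5L
  expect_error(readSnpMap(writeSnpMapFile(neg)), "position")
  par_auto <- df; par_auto$is_par <- TRUE
  expect_error(readSnpMap(writeSnpMapFile(par_auto)), "is_par")
})

test_that("long reader encodes AB calls and drops unknown SNPs", {
  map <- readSnpMap(writeSnpMapFile(snpMapDf(2)))
  csv <- tempfile(fileext = ".csv")
  write.csv(data.frame(sample_id = c("s1", "s1", "s1"),
                       snp_id = c("snp1", "snp2", "other"),
                       allele1 = c("A", "B", "A"),
                       allele2 = c("B", "B", "A")),
            csv, row.names = FALSE)
  expect_message(gs <- readGenotypesLong(csv, map), "dropped")
  expect_equal(unname(calls(gs)[, "s1"]), c(1L, 0L))
  expect_equal(S4Vectors::metadata(gs)$n_dropped_snp_rows, 1L)
})

test_that("AB data containing nucleotide alleles raises a format anomaly", {
  map <- readSnpMap(writeSnpMapFile(snpMapDf(2)))
  csv <- tempfile(fileext = ".csv")
  write.csv(data.frame(sample_id = "s1", snp_id = c("snp1", "snp2"),
                       allele1 = c("A", "A"), allele2 = c("A", "T")),
            csv, row.names = FALSE)
  cond <- tryCatch(readGenotypesLong(csv, map),
                   herdqc_format_anomaly = function(c) c)
  expect_s3_class(cond, "herdqc_format_anomaly")
  expect_equal(cond$rows$snp_id, "snp2")
  expect_equal(cond$rows$allele2, "T")
})

test_that("TOP format converts through the per-SNP allele table only", {
  map <- readSnpMap(writeSnpMapFile(snpMapDf(2, top = TRUE)))
  csv <- tempfile(fileext = ".csv")
  write.csv(data.frame(sample_id = "s1", snp_id = c("snp1", "snp2"),
                       allele1 = c("A", "C"), allele2 = c("C", "C")),
            csv, row.names = FALSE)
  gs <- readGenotypesLong(csv, map, fmt = "TOP")
  expect_equal(unname(calls(gs)[, "s1"]), c(1L, 0L))
  ## refuses without a TOP table
  map2 <- readSnpMap(writeSnpMapFile(snpMapDf(2)))
  expect_error(readGenotypesLong(csv, map2, fmt = "TOP"), "top_a")
})

test_that("matrix round-trip reproduces calls exactly", {
  set.seed(1)
  m <- matrix(sample(c(0L, 1L, 2L, 9L), 5 * 6, replace = TRUE), 6, 5,
              dimnames = list(paste0("snp", 1:6), paste0("s", 1:5)))
  map <- readSnpMap(writeSnpMapFile(snpMapDf(6)))
  gs <- GenotypeSet(m, map)
  path <- tempfile(fileext = ".tsv")
  writeGenotypesMatrix(gs, path)
  back <- readGenotypesMatrix(path, map)
  expect_identical(calls(back), calls(gs))

  ## bad cell is reported with coordinates
  lines <- readLines(path)
  lines[2] <- sub("\t[0129]", "\t3", lines[2])
  writeLines(lines, path)
  expect_error(readGenotypesMatrix(path, map), "snp")
})

test_that("matrix writer handles an empty record set", {
  map <- readSnpMap(writeSnpMapFile(snpMapDf(3)))
  gs <- GenotypeSet(matrix(integer(), 3, 0,
                           dimnames = list(paste0("snp", 1:3), NULL)), map)
  path <- tempfile(fileext = ".tsv")
  writeGenotypesMatrix(gs, path)
  expect_equal(nrow(read.delim(path)), 0)
  back <- readGenotypesMatrix(path, map)
  expect_equal(ncol(back), 0)
})

test_that("PLINK PED parsing matches the long-reader coding contract", {
  map <- readSnpMap(writeSnpMapFile(snpMapDf(2)))
  ped <- tempfile(fileext = ".ped")
  pmap <- tempfile(fileext = ".map")
  writeLines("fam a1 0 0 1 -9 A A B B", ped)
  writeLines(c("1 snp1 0 1000", "1 snp2 0 2000"), pmap)
  gs <- readPlinkPed(ped, pmap, map)
  expect_equal(unname(calls(gs)[, "a1"]), c(2L, 0L))

  writeLines("fam a1 0 0 1 -9 0 0 A B", ped)
  gs <- readPlinkPed(ped, pmap, map)
  expect_equal(unname(calls(gs)[, "a1"]), c(9L, 1L))

  writeLines("fam a1 0 0 1 -9 A A B", ped)
  expect_error(readPlinkPed(ped, pmap, map), "allele")
})

test_that("long-form and matrix-form presentations of the same data agree", {
  sim <- .small_sim()
  sub <- sim$x[1:40, 1:5]
  raw <- exportLongAlleles(sub)
  csv <- tempfile(fileext = ".csv"); tsv <- tempfile(fileext = ".tsv")
  write.csv(raw, csv, row.names = FALSE)
  writeGenotypesMatrix(sub, tsv)
  map <- snpMap(sub)
  g1 <- readGenotypesLong(csv, map)
  g2 <- readGenotypesMatrix(tsv, map)
  expect_identical(calls(g1)[, colnames(sub)], calls(g2)[, colnames(sub)])
})

test_that("GenotypeSet validity rejects bad calls and misplaced PAR flags", {
  m <- matrix(c(0L, 1L), 2, 1, dimnames = list(c("a", "b"), "s1"))
  expect_s4_class(toyGS(m), "GenotypeSet")
  m2 <- m; m2[1] <- 5L
  expect_error(toyGS(m2), "0,1,2,9")
  map <- exampleSnpMap(2); map$is_par[1] <- TRUE
  expect_error(GenotypeSet(m, map), "non-X")
})

test_that("animal metadata parses breed 32nds and herd intervals", {
  csv <- tempfile(fileext = ".csv")
  write.csv(data.frame(
    animal_id = c("A1", "A2"), recorded_sex = c("female", "male"),
    dob = c("2015-03-01", "2013-01-10"), death_date = c("", "2020-01-01"),
    listed_sire = c("A2", ""), listed_dam = c("", ""),
    animal_class = c("commercial", "ai_sire"),
    breed_composition = c("LM:24,AA:8", "CH:32"),
    herd_intervals = c("H1:2015-03-01:2016-01-01;H2:2016-01-02:", "")),
    csv, row.names = FALSE)
  an <- readAnimals(csv)
  expect_equal(an["A1", "breed32"][[1]], c(LM = 24L, AA = 8L))
  expect_equal(nrow(an["A1", "herds"][[1]]), 2)
  expect_true(is.na(an["A1", "death_date"]))
  expect_equal(an["A2", "death_date"], as.Date("2020-01-01"))
  expect_true(is.na(an["A2", "listed_sire"]))
})
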