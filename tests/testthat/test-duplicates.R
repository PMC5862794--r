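`%+%` <- function(a, b) paste0(a, b)

test_that("panel string encoding matches the documented worked example", {
  m <- matrix(c(0L, 0L, 1L, 2L, 9L, 0L, 0L, 2L, 1L), 9, 1,
              dimnames = list(paste0("snp", 1:9), "s1"))
  gs <- toyGS(m)
  expect_equal(unname(encodePanelString(gs, "s1")), "001290021")
  ## decode(encode(x)) == x on the panel
  dec <- as.integer(strsplit(encodePanelString(gs, "s1"), "")[[1]])
  expect_equal(dec, unname(m[, 1]))
  expect_equal(unname(encodePanelString(toyGS(matrix(9L, 9, 1,
    dimnames = list(paste0("snp", 1:9), "s1"))), "s1")),
    strrep("9", 9))
})

test_that("an 800-character string splits into 16 or 40 blocks", {
  s <- c(a = strrep("012", 266) %+% "01", b = strrep("9", 800))
  expect_equal(nchar(s[["a"]]), 800)
  idx50 <- blockIndex(s, 50)
  idx20 <- blockIndex(s, 20)
  block_nos <- function(i) unique(sub(":.*", "", names(i)))
  expect_length(block_nos(idx50), 16)
  expect_length(block_nos(idx20), 40)
  expect_error(blockIndex(s, 30), "divide")
})

test_that("block co-listing is exact string equality, missing included", {
  s1 <- strrep("0", 800)
  s2 <- s1
  substr(s2, 125, 125) <- "9"     # inside 50-block 3 and 20-block 7
  idx <- blockIndex(c(a = s1, b = s2), 50)
  together <- vapply(1:16, function(b) {
    grp <- idx[grepl(paste0("^", b, ":"), names(idx))]
    any(vapply(grp, function(g) all(c("a", "b") %in% g), FALSE))
  }, FALSE)
  expect_equal(which(!together), 3L)
})

test_that("scattered faults can hide from 50-blocks but not 20-blocks", {
  ## one discordant position per 50-block at offsets 25, 75, ..., 775:
  ## every 50-block differs, yet e.g. 20-block 1 (1-20) stays clean
  set.seed(21)
  J <- 800
  v <- sample(c(0L, 1L, 2L), J, replace = TRUE)
  w <- v
  bad <- seq(25, 775, by = 50)
  w[bad] <- 9L
  m <- cbind(s1 = v, s2 = w)
  rownames(m) <- paste0("snp", 1:J)
  gs <- toyGS(m)
  c50 <- findDuplicateCandidates(gs, block_size = 50)
  c20 <- findDuplicateCandidates(gs, block_size = 20)
  expect_equal(nrow(c50), 0)
  expect_equal(nrow(c20), 1)
  ## and the pair still confirms at >= 99% identity
  conf <- confirmDuplicates(gs, c20)
  expect_equal(conf$results$status, "confirmed")
  expect_equal(conf$results$panel_identity, 1)   # missing sites excluded
})

test_that("20-block candidates contain all 50-block candidates", {
  sim <- injectFaults(.small_sim(), n_duplicates = 6, seed = 9)
  c50 <- findDuplicateCandidates(sim$x, block_size = 50)
  c20 <- findDuplicateCandidates(sim$x, block_size = 20)
  key <- function(d) paste(d$sample_a, d$sample_b)
  expect_true(all(key(c50) %in% key(c20)))
})

test_that("injected duplicates are found and confirmed; unrelated pairs are not", {
  sim <- injectFaults(.small_sim(), n_duplicates = 6, seed = 9)
  cand <- findDuplicateCandidates(sim$x)
  conf <- confirmDuplicates(sim$x, cand, animals = sim$animals)
  got <- conf$results[conf$results$status == "confirmed", ]
  truthdup <- sim$truth$faults$duplicates
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  expect_setequal(key(got$sample_a, got$sample_b),
                  key(truthdup$original, truthdup$duplicate))
  ## candidate recall vs an exhaustive identity scan: every >=99%
  ## identical pair must be among the block candidates (candidates may
  ## additionally contain chance block matches between close relatives)
  pidx <- panelIndex(sim$x)
  m <- calls(sim$x)[pidx, ]
  n <- ncol(m)
  hits <- character()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    pi <- herdqc:::.pairIdentity(m[, i], m[, j], seq_len(nrow(m)))
    if (!is.na(pi$identity) && pi$identity >= 0.99)
      hits <- c(hits, paste(colnames(m)[i], colnames(m)[j]))
  }
  expect_true(all(hits %in% key(cand$sample_a, cand$sample_b)))
  expect_setequal(hits, key(got$sample_a, got$sample_b))
})

test_that("identity below 99% on either tier rejects the pair", {
  set.seed(31)
  J <- 1200
  v <- sample(c(0L, 1L, 2L), J, replace = TRUE)
  panel_flag <- c(rep(TRUE, 800), rep(FALSE, 400))
  mkgs <- function(w) {
    m <- cbind(s1 = v, s2 = w)
    rownames(m) <- paste0("snp", 1:J)
    map <- exampleSnpMap(J); map$in_icbf800 <- panel_flag
    rownames(map) <- rownames(m)
    GenotypeSet(m, map)
  }
  ## 95% identical on the panel
  w <- v; flip <- sample(800, 40); w[flip] <- (v[flip] + 1L) %% 3L
  pr <- data.frame(sample_a = "s1", sample_b = "s2")
  expect_equal(confirmDuplicates(mkgs(w), pr)$results$status, "rejected")
  ## identical panel but discordant full set: both tiers required
  w2 <- v; flip2 <- 800 + sample(400, 40); w2[flip2] <- (v[flip2] + 1L) %% 3L
  r <- confirmDuplicates(mkgs(w2), pr)$results
  expect_equal(r$panel_identity, 1)
  expect_lt(r$full_identity, 0.99)
  expect_equal(r$status, "rejected")
})

test_that("candidate discovery is order invariant", {
  sim <- injectFaults(.small_sim(), n_duplicates = 4, seed = 5)
  perm <- sample(ncol(sim$x))
  c1 <- findDuplicateCandidates(sim$x)
  c2 <- findDuplicateCandidates(sim$x[, perm])
  expect_equal(c1, c2, ignore_attr = TRUE)
})

test_that("multi-genotype reconciliation separates rechips from conflicts", {
  sim <- injectFaults(.small_sim(), n_duplicates = 3, seed = 13)
  dup <- sim$truth$faults$duplicates
  ## re-genotyped same animal: consistent
  rec <- reconcileMultiGenotypes(sim$x,
    as.character(sampleInfo(sim$x)[dup$original[1], "animal_id"]))
  expect_equal(rec$status, "consistent")
  ## graft an unrelated animal's genotype onto the same animal id
  x <- sim$x
  a1 <- dup$original[1]
  other <- setdiff(colnames(x), c(dup$original, dup$duplicate))[1]
  cd <- sampleInfo(x)
  cd[other, "animal_id"] <- cd[a1, "animal_id"]
  x2 <- GenotypeSet(calls(x), snpMap(x), cd)
  rec2 <- reconcileMultiGenotypes(x2,
    as.character(cd[a1, "animal_id"]))
  expect_equal(rec2$status, "conflict")
  ## unrelated-pair identity sits far below the threshold (~0.38 at
  ## panel MAFs near 0.45)
  badpair <- rec2$pairs[!rec2$pairs$concordant, ][1, ]
  expect_lt(badpair$panel_identity, 0.6)
  expect_gt(badpair$panel_identity, 0.2)
  ## three genotypes, one bad: odd one out identified
  expect_equal(rec2$odd_one_out, other)
})
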