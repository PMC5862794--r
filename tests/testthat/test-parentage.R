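test_that("opposing homozygotes are the only counted conflicts", {
  a <- c(2L, 1L, 2L, 0L, 9L, 2L)
  b <- c(0L, 0L, 2L, 2L, 2L, 9L)
  r <- countParentOffspringMismatches(a, b)
  expect_equal(r$n_compared, 4)   # two pairs have a missing side
  expect_equal(r$n_mismatch, 2)   # positions 1 (2/0) and 4 (0/2)
  ## symmetry
  r2 <- countParentOffspringMismatches(b, a)
  expect_equal(r, r2)
  ## a heterozygote never mismatches
  expect_equal(countParentOffspringMismatches(rep(1L, 5),
                                              c(0L, 1L, 2L, 0L, 2L))$n_mismatch,
               0)
  expect_error(countParentOffspringMismatches(a, b, integer()), "empty")
})

## builds a GenotypeSet whose panel mismatch/missing pattern is exact
pairGS <- function(n_panel = 800, n_extra = 400, panel_mm = 0,
                   extra_mm = 0) {
  J <- n_panel + n_extra
  base <- rep(1L, J)
  a <- base; b <- base
  if (panel_mm > 0) { a[seq_len(panel_mm)] <- 2L; b[seq_len(panel_mm)] <- 0L }
  if (extra_mm > 0) {
    i <- n_panel + seq_len(extra_mm)
    a[i] <- 2L; b[i] <- 0L
  }
  m <- cbind(child = a, parent = b)
  rownames(m) <- paste0("snp", seq_len(J))
  map <- exampleSnpMap(J)
  map$in_icbf800 <- c(rep(TRUE, n_panel), rep(FALSE, n_extra))
  rownames(map) <- rownames(m)
  GenotypeSet(m, map)
}

test_that("two-stage validation: <=4 validates, >=13 fails, 5-12 checks all SNPs", {
  expect_equal(validateParent(pairGS(panel_mm = 3), "child", "parent")$verdict,
               "validated")
  expect_equal(validateParent(pairGS(panel_mm = 4), "child", "parent")$verdict,
               "validated")
  expect_equal(validateParent(pairGS(panel_mm = 13), "child", "parent")$verdict,
               "failed")
  ## 8 panel mismatches, no extra: full rate 8/1200 = 0.0067 <= 1%
  r <- validateParent(pairGS(panel_mm = 8), "child", "parent")
  expect_equal(r$verdict, "gray_validated")
  expect_equal(r$full_snp_rate, 8 / 1200)
  ## 8 panel + 7 extra: 15/1200 = 0.0125 > 1%
  r2 <- validateParent(pairGS(panel_mm = 8, extra_mm = 7), "child", "parent")
  expect_equal(r2$verdict, "gray_failed")
  expect_gt(r2$full_snp_rate, 0.01)
})

test_that("insufficient panel overlap yields no verdict", {
  gs <- pairGS()
  m <- calls(gs)
  m[1:250, "parent"] <- 9L          # 550 shared panel calls < 600
  gs2 <- GenotypeSet(m, snpMap(gs))
  expect_equal(validateParent(gs2, "child", "parent")$verdict,
               "insufficient_data")
})

test_that("candidate table keeps one best genotype per animal", {
  J <- 800
  mkcol <- function(n_called) {
    v <- rep(1L, J); if (n_called < J) v[seq_len(J - n_called)] <- 9L; v
  }
  m <- cbind(s1 = mkcol(790), s2 = mkcol(640), s3 = mkcol(590))
  rownames(m) <- paste0("snp", 1:J)
  cd <- S4Vectors::DataFrame(animal_id = c("A1", "A1", "A2"),
                             genotyping_date = as.Date(c("2016-01-01",
                                                         "2017-01-01", NA)),
                             row.names = colnames(m))
  gs <- GenotypeSet(m, exampleSnpMap(J), cd)
  tab <- buildCandidateTable(gs)
  expect_equal(colnames(tab), "s1")      # 790 beats 640; A2 under 600 excluded
  expect_equal(unname(sampleInfo(tab)$panel_calls), 790)
  ## tie on calls -> newest genotyping date
  m2 <- cbind(s1 = mkcol(700), s2 = mkcol(700))
  rownames(m2) <- paste0("snp", 1:J)
  cd2 <- S4Vectors::DataFrame(animal_id = c("A1", "A1"),
                              genotyping_date = as.Date(c("2016-01-01",
                                                          "2017-06-01")),
                              row.names = colnames(m2))
  tab2 <- buildCandidateTable(GenotypeSet(m2, exampleSnpMap(J), cd2))
  expect_equal(colnames(tab2), "s2")
  ## empty input
  expect_equal(ncol(buildCandidateTable(gs[, 0])), 0)
})

test_that("trio MSM definition and flagging", {
  J <- 800
  mk <- function(calf, sire, dam) {
    m <- cbind(calf = calf, sire = sire, dam = dam)
    rownames(m) <- paste0("snp", 1:J)
    GenotypeSet(m, exampleSnpMap(J))
  }
  base <- rep(1L, J)
  ## calf AB, both parents AA at 5 SNPs -> 5 MSM
  calf <- base; sire <- base; dam <- base
  sire[1:5] <- 2L; dam[1:5] <- 2L
  r <- countMSM(mk(calf, sire, dam), "calf", "sire", "dam")
  expect_equal(r$n_msm, 5)
  expect_false(r$flagged)          # 5/800 < 1%... (0.625%)
  ## opposite homozygous parents is a valid mating, not an MSM
  sire2 <- base; dam2 <- base; sire2[1:5] <- 2L; dam2[1:5] <- 0L
  expect_equal(countMSM(mk(calf, sire2, dam2), "calf", "sire", "dam")$n_msm, 0)
  ## over 1% flags
  sire[1:10] <- 2L; dam[1:10] <- 2L
  expect_true(countMSM(mk(calf, sire, dam), "calf", "sire", "dam")$flagged)
  ## missing calls are not informative
  calf[6:800] <- 9L
  r2 <- countMSM(mk(calf, sire, dam), "calf", "sire", "dam")
  expect_equal(r2$n_informative, 5)
})

test_that("parent prediction recovers exactly the true parents in a gene drop", {
  sim <- .small_sim()
  gq <- runGenotypeQC(sim$x)
  tab <- buildCandidateTable(gq$x)
  ped <- sim$truth$pedigree
  aid <- as.character(sampleInfo(tab)$animal_id)
  ## pick generation-1 animals (their parents are genotyped founders, and
  ## they have genotyped offspring that the age rule must exclude)
  gen1 <- ped$animal_id[ped$generation == 1][1:12]
  for (a in gen1) {
    pr <- predictParents(a, tab, sim$animals)
    sires <- pr$candidate_id[pr$role == "sire"]
    dams <- pr$candidate_id[pr$role == "dam"]
    expect_equal(sires, ped$true_sire[ped$animal_id == a])
    expect_equal(dams, ped$true_dam[ped$animal_id == a])
  }
  expect_error(predictParents("nope", tab, sim$animals), "not in")
})

test_that("early-terminated scan equals an exhaustive oracle", {
  sim <- .small_sim()
  tab <- buildCandidateTable(runGenotypeQC(sim$x)$x)
  pidx <- panelIndex(tab)
  P <- calls(tab)[pidx, ]
  A <- P == 2L; B <- P == 0L; NM <- P != 9L
  mm_full <- crossprod(A, B) + crossprod(B, A)
  cmp_full <- crossprod(NM, NM)
  th <- herdThresholds()
  aid <- as.character(sampleInfo(tab)$animal_id)
  targets <- sample(seq_len(ncol(tab)), 25)
  for (tj in targets) {
    sc <- herdqc:::.panelScan(P, P[, tj], maxmm = th$fail_min_mm - 1L)
    keep <- sc$surviving & seq_len(ncol(P)) != tj &
      sc$cmp >= th$predict_min_panel_calls
    oracle <- mm_full[, tj] <= th$fail_min_mm - 1L &
      seq_len(ncol(P)) != tj & cmp_full[, tj] >= th$predict_min_panel_calls
    expect_equal(which(keep), unname(which(oracle)))
    expect_equal(sc$mm[keep], unname(mm_full[keep, tj]))
  }
  ## chunk size never changes the outcome
  tj <- targets[1]
  for (ch in c(37L, 100L, 800L)) {
    sc <- herdqc:::.panelScan(P, P[, tj], maxmm = 12L, chunk = ch)
    expect_equal(sc$surviving, herdqc:::.panelScan(P, P[, tj], 12L)$surviving)
  }
})

test_that("age and sex rules exclude progeny, young decoys and wrong roles", {
  sim <- .small_sim()
  tab <- buildCandidateTable(runGenotypeQC(sim$x)$x)
  ped <- sim$truth$pedigree
  animals <- sim$animals
  ## a generation-1 male with genotyped offspring in generation 2
  g1m <- ped$animal_id[ped$generation == 1 &
                       sim$truth$sex[ped$animal_id] == "male"]
  father <- g1m[vapply(g1m, function(a) any(ped$true_sire == a, na.rm = TRUE),
                       FALSE)][1]
  expect_false(is.na(father))
  pr <- predictParents(father, tab, animals)
  kids <- ped$animal_id[!is.na(ped$true_sire) & ped$true_sire == father]
  ## progeny (0 mismatches, negative age gap) never predicted as parents
  expect_false(any(kids %in% pr$candidate_id))
  ## a 14-month-older full sib with 0 mismatches is excluded by age:
  ## clone the father 14 months earlier
  m <- calls(tab)
  clone <- m[, colnames(tab)[sampleInfo(tab)$animal_id == father],
             drop = FALSE]
  colnames(clone) <- "S_decoy"
  gs2 <- GenotypeSet(cbind(m, clone), snpMap(tab),
                     rbind(sampleInfo(tab)[, c("animal_id"), drop = FALSE],
                           S4Vectors::DataFrame(animal_id = "DECOY",
                                                row.names = "S_decoy")))
  an2 <- rbind(animals, animals[father, ])
  rownames(an2)[nrow(an2)] <- "DECOY"
  an2["DECOY", "animal_id"] <- "DECOY"
  ## target: one of the father's kids; the decoy genotype is a copy of
  ## the father but dated only 14 months before the target
  kid <- kids[kids %in% as.character(sampleInfo(tab)$animal_id)][1]
  an2["DECOY", "dob"] <- seq(an2[kid, "dob"], by = "-14 months",
                             length.out = 2)[2]
  pr2 <- predictParents(kid, buildCandidateTable(gs2), an2)
  expect_false("DECOY" %in% pr2$candidate_id)
  expect_true(father %in% pr2$candidate_id)
})

test_that("unrelated-pair mismatch counts match the closed form", {
  set.seed(11)
  maf <- runif(800, 0.42, 0.50)
  p <- ifelse(runif(800) < 0.5, maf, 1 - maf)
  rep_ <- panelPowerReport(p, error_rate = 0, n_sims = 400, seed = 2)
  expected <- expectedUnrelatedMismatches(p)
  se <- sd(rep_$mm_unrelated) / sqrt(length(rep_$mm_unrelated))
  expect_lt(abs(rep_$unrelated$mean_mismatches - expected), 3 * se)
  ## error-free true parent-offspring pairs never mismatch
  expect_equal(rep_$parent_offspring$mean_mismatches, 0)
})
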