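parFrame <- function(parent, verdicts) {
  data.frame(animal_id = paste0("K", seq_along(verdicts)),
             candidate_id = parent,
             sample_id = paste0("SK", seq_along(verdicts)),
             candidate_sample = paste0("SP_", parent),
             role = "dam", n_compared_panel = 800L,
             n_mismatch_panel = 0L, full_snp_rate = NA_real_,
             verdict = verdicts, stringsAsFactors = FALSE)
}

test_that("offspring-failure patterns flag by parent class", {
  f2 <- parFrame("D1", c("failed", "failed"))
  expect_true(offspringPatternCheck("D1", f2, "dam")$flag)
  expect_false(offspringPatternCheck("D1",
    parFrame("D1", c("failed", "validated")), "dam")$flag)
  expect_false(offspringPatternCheck("D1",
    parFrame("D1", "failed"), "dam")$flag)          # n = 1 < 2
  ## stock bull: 4 of 5 failing is exactly 80%
  sb <- parFrame("B1", c(rep("failed", 4), "validated"))
  expect_true(offspringPatternCheck("B1", sb, "stock_bull")$flag)
  expect_false(offspringPatternCheck("B1",
    parFrame("B1", c(rep("failed", 3), rep("validated", 2))),
    "stock_bull")$flag)
  ## AI sire needs 10 offspring
  ai9 <- parFrame("A1", rep("failed", 9))
  expect_false(offspringPatternCheck("A1", ai9, "ai_sire")$flag)
  ai10 <- parFrame("A1", c(rep("failed", 8), rep("validated", 2)))
  expect_true(offspringPatternCheck("A1", ai10, "ai_sire")$flag)
})

test_that("invalidating a genotype resets exactly the verdicts citing it", {
  df <- rbind(parFrame("D1", c("validated", "failed")),
              parFrame("D2", "validated"))
  out <- resetParentageForGenotype(df, "SP_D1")
  expect_equal(out$verdict[out$candidate_sample == "SP_D1"],
               rep("unresolved", 2))
  expect_equal(out$verdict[out$candidate_sample == "SP_D2"], "validated")
})

test_that("post-death flag is strict at 45 days and exempts AI straws", {
  death <- as.Date("2020-01-01")
  expect_true(postDeathFlag(death + 46, death, "commercial"))
  expect_false(postDeathFlag(death + 45, death, "commercial"))
  expect_false(postDeathFlag(death + 200, death, "ai_sire", "straw"))
  expect_true(postDeathFlag(death + 200, death, "ai_sire", "tissue"))
  expect_false(postDeathFlag(as.Date(NA), death, "commercial"))
})

test_that("a clean herd passes animal QC with no flags", {
  sim <- simulateHerd(simConfig(seed = 77, n_founders = 12,
                                n_generations = 1, n_offspring = 20,
                                parent_misrecording = 0))
  aq <- runAnimalQC(sim$x, sim$animals)
  expect_true(all(aq$report$final_state == "valid"))
  expect_true(all(aq$report$dup_status == "clear"))
  expect_false(any(aq$report$offspring_flag))
})

test_that("a swapped dam/calf pair is re-attributed from parentage evidence", {
  sim <- simulateHerd(simConfig(seed = 101, n_founders = 20,
                                n_generations = 2, n_offspring = 40,
                                parent_misrecording = 0))
  ped <- sim$truth$pedigree
  ## a generation-2 calf and its genotyped dam
  calf <- ped$animal_id[ped$generation == 2][1]
  dam <- ped$true_dam[ped$animal_id == calf]
  s_calf <- paste0("S_", calf); s_dam <- paste0("S_", dam)
  cd <- sampleInfo(sim$x)
  cd[s_calf, "animal_id"] <- dam
  cd[s_dam, "animal_id"] <- calf
  x <- GenotypeSet(calls(sim$x), snpMap(sim$x), cd)
  res <- resolveConflict(x, s_calf, s_dam, sim$animals)
  expect_equal(res$status, "resolved")
  expect_equal(res$attribution[[s_calf]], calf)
  expect_equal(res$attribution[[s_dam]], dam)
})

test_that("a wrong-label duplicate is detected end to end and resolved", {
  sim <- simulateHerd(simConfig(seed = 55, n_founders = 20,
                                n_generations = 2, n_offspring = 40,
                                parent_misrecording = 0))
  simf <- injectFaults(sim, n_wrong_label = 1, seed = 3)
  wl <- simf$truth$faults$wrong_labels
  expect_equal(nrow(wl), 1)
  aq <- runAnimalQC(simf$x, simf$animals)
  rep_ <- aq$report
  victim <- wl$victim_sample; src <- wl$source_sample
  expect_equal(rep_$dup_status[rep_$sample_id == victim], "duplicate")
  key <- paste(sort(c(victim, src)), collapse = "|")
  res <- aq$resolutions[[key]]
  ## if the source animal has informative relatives the conflict resolves:
  ## the victim's genotype is not its animal's DNA
  if (!is.null(res) && res$status == "resolved") {
    expect_equal(rep_$final_state[rep_$sample_id == victim][1], "invalid")
    expect_equal(rep_$final_state[rep_$sample_id == src][1], "valid")
  } else {
    expect_true(all(rep_$final_state[rep_$sample_id %in%
                                       c(victim, src)] == "unresolved"))
  }
})

test_that("ambiguous-evidence conflicts stay unresolved", {
  ## two founder females, no genotyped relatives, same sex and breed:
  ## no evidence can separate them
  sim <- simulateHerd(simConfig(seed = 31, n_founders = 30,
                                n_generations = 1, n_offspring = 10,
                                parent_misrecording = 0))
  ped <- sim$truth$pedigree
  used <- unique(c(ped$true_sire, ped$true_dam))
  females <- ped$animal_id[ped$generation == 0 &
                           sim$truth$sex[ped$animal_id] == "female"]
  lonely <- setdiff(females, used)[1:2]
  expect_false(any(is.na(lonely)))
  s1 <- paste0("S_", lonely[1]); s2 <- paste0("S_", lonely[2])
  ## make s2 a copy of s1's DNA labeled as the other animal
  m <- calls(sim$x)
  m[, s2] <- m[, s1]
  x <- GenotypeSet(m, snpMap(sim$x), sampleInfo(sim$x))
  res <- resolveConflict(x, s1, s2, sim$animals)
  expect_equal(res$status, "unresolved")
})

test_that("single failures flag but never invalidate on their own", {
  sim <- simulateHerd(simConfig(seed = 19, n_founders = 12,
                                n_generations = 1, n_offspring = 20,
                                parent_misrecording = 0))
  simf <- injectFaults(sim, n_sex_mislabels = 2, seed = 4)
  aq <- runAnimalQC(simf$x, simf$animals)
  rep_ <- aq$report
  bad <- simf$truth$faults$sex_mislabels$animal_id
  rows <- rep_[rep_$animal_id %in% bad, ]
  expect_true(all(rows$sex_check == "mismatch"))
  expect_true(all(rows$final_state == "flagged"))
  expect_false(any(rep_$final_state == "invalid"))
})

test_that("re-running animal QC on a clean outcome is idempotent", {
  sim <- simulateHerd(simConfig(seed = 23, n_founders = 12,
                                n_generations = 1, n_offspring = 16,
                                parent_misrecording = 0))
  aq1 <- runAnimalQC(sim$x, sim$animals)
  aq2 <- runAnimalQC(aq1$x, sim$animals)
  expect_equal(aq1$report$final_state, aq2$report$final_state)
  expect_equal(aq1$report$sex_check, aq2$report$sex_check)
})
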