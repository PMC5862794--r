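#' Simulation configuration for a multi-breed pedigreed herd
#'
#' Defaults describe the study conditions the package is exercised
#' under: a parentage panel of 800 autosomal SNPs with minor allele
#' frequencies drawn Uniform(0.42, 0.50) (the high-MAF design of the
#' operational panel), extra non-panel autosomal SNPs for full-SNP
#' confirmation, a chromosome X with a distal pseudoautosomal tail, the
#' 7-SNP chromosome Y set, per-call error 0.2%, 1% missingness, and an
#' 8% listed-pedigree error rate (the middle of the 7-9% national range).
#'
#' @param seed integer RNG seed; fixed seed gives byte-identical output.
#' @param n_breeds number of breeds.
#' @param n_founders founders per breed (half male).
#' @param n_generations offspring generations.
#' @param n_offspring offspring per breed per generation.
#' @param n_panel autosomal parentage-panel SNPs.
#' @param n_extra extra autosomal (non-panel) SNPs.
#' @param n_chrx chromosome X SNPs.
#' @param par_frac fraction of chrX SNPs (distal, contiguous) that are
#'   pseudoautosomal.
#' @param n_chry chromosome Y SNPs.
#' @param fst breed divergence (Balding-Nichols Beta founder
#'   frequencies).
#' @param error_rate per-call probability of a wrong genotype class.
#' @param missing_rate per-call probability of no call.
#' @param parent_misrecording probability a listed parent is wrong.
#' @param panel_maf_range range the panel MAFs are drawn from.
#' @return list of class `sim_config`.
#' @export
simConfig <- function(seed = 1L, n_breeds = 3L, n_founders = 40L,
                      n_generations = 2L, n_offspring = 80L,
                      n_panel = 800L, n_extra = 400L, n_chrx = 150L,
                      par_frac = 0.10, n_chry = 7L, fst = 0.10,
                      error_rate = 0.002, missing_rate = 0.01,
                      parent_misrecording = 0.08,
                      panel_maf_range = c(0.42, 0.50)) {
  cfg <- as.list(environment())
  rates <- c("par_frac", "error_rate", "missing_rate", "parent_misrecording")
  for (r in rates)
    if (cfg[[r]] < 0 || cfg[[r]] > 1) stop(r, " outside [0,1]")
  class(cfg) <- "sim_config"
  cfg
}

## Balding-Nichols breed frequencies; clamped away from fixation so that
## every simulated SNP stays polymorphic within every breed (chips carry
## SNPs pre-filtered for informativeness)
.bnFreq <- function(p, fst) {
  if (fst <= 0) return(p)
  a <- p * (1 - fst) / fst
  b <- (1 - p) * (1 - fst) / fst
  pmin(pmax(stats::rbeta(length(p), a, b), 0.05), 0.95)
}

.simSnpTable <- function(cfg) {
  n_auto <- cfg$n_panel + cfg$n_extra
  auto_chr <- as.character(rep_len(1:29, n_auto))
  panel_flag <- rep(c(TRUE, FALSE), c(cfg$n_panel, cfg$n_extra))
  ## interleave panel/extra positions deterministically
  o <- order(auto_chr, seq_len(n_auto))
  n_par <- max(1L, round(cfg$n_chrx * cfg$par_frac))
  df <- data.frame(
    snp_id = c(sprintf("auto%04d", seq_len(n_auto)),
               sprintf("chrx%03d", seq_len(cfg$n_chrx)),
               sprintf("chry%02d", seq_len(cfg$n_chry))),
    chromosome = c(auto_chr, rep("X", cfg$n_chrx), rep("Y", cfg$n_chry)),
    position_bp = c(ave(seq_len(n_auto), auto_chr,
                        FUN = seq_along) * 100000L,
                    seq_len(cfg$n_chrx) * 100000L,
                    seq_len(cfg$n_chry) * 100000L),
    in_icbf800 = c(panel_flag, rep(FALSE, cfg$n_chrx + cfg$n_chry)),
    in_isag100 = FALSE, in_isag200 = FALSE,
    is_par = c(rep(FALSE, n_auto),
               seq_len(cfg$n_chrx) > cfg$n_chrx - n_par,
               rep(FALSE, cfg$n_chry)),
    cluster_ok = TRUE, stringsAsFactors = FALSE)
  df
}

#' Simulate a multi-breed pedigreed herd with complete truth
#'
#' Gene-drop simulation: per-breed founder allele frequencies derive
#' from shared base frequencies through a Balding-Nichols Beta draw;
#' founders are sampled in Hardy-Weinberg proportions and offspring
#' receive one Mendelian-sampled allele per parent, SNPs transmitted
#' independently. Chromosome X is hemizygous in males outside the PAR
#' (chips report the single allele as a homozygote); the PAR is
#' transmitted diploid in both sexes; chromosome Y is male-only. Per-call
#' error replaces a call with one of the two other classes; missingness
#' blanks calls. Listed parents are misrecorded at the configured rate by
#' substituting a random same-sex, age-eligible genotyped animal.
#'
#' @param cfg a [simConfig()].
#' @return list: `x` (a [GenotypeSet-class], one sample per animal),
#'   `animals` (metadata data.frame shaped like [readAnimals()] output),
#'   `truth` (ledger: true pedigree and sex, misrecorded parents,
#'   error-free call matrix, per-breed allele frequencies, sample map,
#'   faults so far).
#' @export
simulateHerd <- function(cfg = simConfig()) {
  set.seed(cfg$seed)
  snps <- .simSnpTable(cfg)
  J <- nrow(snps)
  is_auto <- snps$chromosome %in% as.character(1:29)
  is_x <- snps$chromosome == "X"
  is_y <- snps$chromosome == "Y"
  is_par <- snps$is_par
  is_npar_x <- is_x & !is_par
  diploid <- is_auto | is_par           # transmitted diploid in both sexes

  ## base allele frequencies
  base <- numeric(J)
  base[snps$in_icbf800] <- {
    maf <- stats::runif(cfg$n_panel, cfg$panel_maf_range[1],
                        cfg$panel_maf_range[2])
    flip <- stats::runif(cfg$n_panel) < 0.5
    ifelse(flip, maf, 1 - maf)
  }
  base[is_auto & !snps$in_icbf800] <- stats::runif(cfg$n_extra, 0.10, 0.90)
  base[is_par] <- stats::runif(sum(is_par), 0.10, 0.20)
  base[is_npar_x] <- stats::runif(sum(is_npar_x), 0.06, 0.94)
  base[is_y] <- stats::runif(sum(is_y), 0.30, 0.70)
  freqs <- sapply(seq_len(cfg$n_breeds), function(b) .bnFreq(base, cfg$fst))

  n_per_breed <- cfg$n_founders + cfg$n_generations * cfg$n_offspring
  n_total <- cfg$n_breeds * n_per_breed
  ids <- sprintf("A%05d", seq_len(n_total))
  A1 <- matrix(NA_integer_, J, n_total)
  A2 <- matrix(NA_integer_, J, n_total)
  sex <- character(n_total); breed <- integer(n_total)
  gen <- integer(n_total)
  sire <- rep(NA_character_, n_total); dam <- rep(NA_character_, n_total)

  k <- 0L
  for (b in seq_len(cfg$n_breeds)) {
    p <- freqs[, b]
    f_idx <- k + seq_len(cfg$n_founders)
    for (i in f_idx) {
      s <- if ((i - k) <= cfg$n_founders / 2) "male" else "female"
      sex[i] <- s; breed[i] <- b; gen[i] <- 0L
      A1[, i] <- stats::rbinom(J, 1, p)
      A2[, i] <- stats::rbinom(J, 1, p)
      if (s == "male") {
        A2[is_npar_x, i] <- NA_integer_           # one X
        A1[is_y, i] <- NA_integer_                # Y haplotype in A2
      } else {
        A1[is_y, i] <- NA_integer_; A2[is_y, i] <- NA_integer_
      }
    }
    prev <- f_idx
    for (g in seq_len(cfg$n_generations)) {
      o_idx <- k + cfg$n_founders + (g - 1L) * cfg$n_offspring +
        seq_len(cfg$n_offspring)
      msel <- prev[sex[prev] == "male"]
      fsel <- prev[sex[prev] == "female"]
      for (i in o_idx) {
        s_i <- sample(msel, 1L); d_i <- sample(fsel, 1L)
        sx <- sample(c("male", "female"), 1L)
        sex[i] <- sx; breed[i] <- b; gen[i] <- g
        sire[i] <- ids[s_i]; dam[i] <- ids[d_i]
        gd <- A1[, d_i] + ifelse(is.na(A2[, d_i]), A1[, d_i], A2[, d_i])
        gs <- A1[, s_i] + ifelse(is.na(A2[, s_i]), A1[, s_i], A2[, s_i])
        gd[is.na(gd)] <- 0L; gs[is.na(gs)] <- 0L   # chrY rows, overwritten
        from_dam <- stats::rbinom(J, 1, gd / 2)
        from_sire <- stats::rbinom(J, 1, gs / 2)
        a1 <- from_dam; a2 <- from_sire
        ## nPAR X: one maternal allele; paternal only for daughters
        a2[is_npar_x] <- if (sx == "female")
          A1[is_npar_x, s_i] else NA_integer_
        ## Y: paternal haplotype for sons
        a1[is_y] <- NA_integer_
        a2[is_y] <- if (sx == "male") A2[is_y, s_i] else NA_integer_
        A1[, i] <- a1; A2[, i] <- a2
      }
      prev <- o_idx
    }
    k <- k + n_per_breed
  }

  ## genotype calls: hemizygous single alleles reported as homozygotes
  g1 <- A1; g2 <- A2
  g1[is.na(g1)] <- g2[is.na(g1)]
  g2[is.na(g2)] <- g1[is.na(g2)]
  true_calls <- g1 + g2
  true_calls[is.na(true_calls)] <- 9L
  storage.mode(true_calls) <- "integer"
  dimnames(true_calls) <- list(snps$snp_id, paste0("S_", ids))

  obs <- .applyNoise(true_calls, cfg$error_rate, cfg$missing_rate)

  ## metadata
  ## generations two years apart with at most 120 days of within-cohort
  ## spread, so every true parent clears the 15-month age rule
  dob <- as.Date("2012-01-01") + gen * 730L + (seq_len(n_total) %% 120L)
  herd <- paste0("H", breed, "_", (seq_len(n_total) %% 5L) + 1L)
  listed_sire <- sire; listed_dam <- dam
  mis <- data.frame(animal_id = character(), role = character(),
                    true_parent = character(), listed_parent = character(),
                    stringsAsFactors = FALSE)
  nonf <- which(gen > 0L)
  hit <- nonf[stats::runif(length(nonf)) < cfg$parent_misrecording]
  for (i in hit) {
    role <- sample(c("sire", "dam"), 1L)
    want_sex <- if (role == "sire") "male" else "female"
    pool <- which(sex == want_sex & dob <= dob[i] - 456 & ids != ids[i])
    truep <- if (role == "sire") sire[i] else dam[i]
    pool <- pool[ids[pool] != truep]
    if (!length(pool)) next
    wrong <- ids[sample(pool, 1L)]
    if (role == "sire") listed_sire[i] <- wrong else listed_dam[i] <- wrong
    mis <- rbind(mis, data.frame(animal_id = ids[i], role = role,
                                 true_parent = truep, listed_parent = wrong,
                                 stringsAsFactors = FALSE))
  }

  breed_codes <- paste0("B", seq_len(cfg$n_breeds))
  animals <- data.frame(
    animal_id = ids, recorded_sex = sex, dob = dob,
    death_date = as.Date(rep(NA, n_total)),
    listed_sire = listed_sire, listed_dam = listed_dam,
    animal_class = ifelse(sex == "male" & gen == 0L, "stock_bull",
                          ifelse(sex == "male", "commercial", "commercial")),
    stringsAsFactors = FALSE)
  animals$breed32 <- lapply(breed, function(b)
    stats::setNames(32L, breed_codes[b]))
  animals$herds <- lapply(seq_len(n_total), function(i)
    data.frame(herd_id = herd[i], from_date = dob[i],
               to_date = as.Date(NA), stringsAsFactors = FALSE))
  rownames(animals) <- ids

  sampleData <- S4Vectors::DataFrame(
    animal_id = ids, chip_name = "sim_v1",
    sample_collection_date = dob + 30L,
    genotyping_date = dob + 60L,
    row.names = colnames(true_calls))
  x <- GenotypeSet(obs, .snpTableToMap(snps), sampleData)

  truth <- list(
    pedigree = data.frame(animal_id = ids, true_sire = sire,
                          true_dam = dam, generation = gen,
                          breed = breed_codes[breed],
                          stringsAsFactors = FALSE),
    sex = stats::setNames(sex, ids),
    misrecorded = mis,
    true_calls = true_calls,
    freqs = freqs,
    snps = snps,
    sample_map = data.frame(sample_id = colnames(true_calls),
                            true_animal_id = ids,
                            stringsAsFactors = FALSE),
    faults = list())
  list(x = x, animals = animals, truth = truth, config = cfg)
}

.snpTableToMap <- function(snps)
  S4Vectors::DataFrame(snps[, setdiff(colnames(snps), "snp_id"),
                            drop = FALSE],
                       row.names = snps$snp_id)

.applyNoise <- function(m, error_rate, missing_rate) {
  out <- m
  callable <- which(out != 9L)
  if (error_rate > 0 && length(callable)) {
    hit <- callable[stats::runif(length(callable)) < error_rate]
    out[hit] <- (out[hit] + sample(1:2, length(hit), replace = TRUE)) %% 3L
  }
  if (missing_rate > 0 && length(callable)) {
    drop <- callable[stats::runif(length(callable)) < missing_rate]
    out[drop] <- 9L
  }
  storage.mode(out) <- "integer"
  out
}

#' Inject labeled faults into a simulated herd
#'
#' Fault scenarios mirror the error taxonomy a national database sees:
#' the same animal sampled twice under different labels
#' (`n_duplicates`: a fresh sample is drawn from the animal's true
#' genotype with new error and missingness), two samples swapped between
#' animals (`n_swaps`, drawn from the same herd), and recorded sex
#' mislabeled (`n_sex_mislabels`). Every fault is appended to the truth
#' ledger.
#'
#' @param sim output of [simulateHerd()].
#' @param n_swaps,n_duplicates,n_sex_mislabels,n_wrong_label fault
#'   counts; a wrong label replaces one animal's sample with a fresh
#'   noisy copy of a same-herd animal's DNA (the classic mis-tagged
#'   collection device).
#' @param seed RNG seed for the fault draws.
#' @return `sim` with mutated `x`/`animals` and an updated ledger.
#' @export
injectFaults <- function(sim, n_swaps = 0L, n_duplicates = 0L,
                         n_sex_mislabels = 0L, n_wrong_label = 0L,
                         seed = 1L) {
  set.seed(seed)
  x <- sim$x; animals <- sim$animals; truth <- sim$truth
  cfg <- sim$config
  taken <- character()
  if (n_duplicates > 0) {
    cand <- setdiff(colnames(x), taken)
    pick <- sample(cand, n_duplicates)
    taken <- c(taken, pick)
    newcalls <- sapply(pick, function(s)
      .applyNoise(truth$true_calls[, s, drop = FALSE],
                  cfg$error_rate, cfg$missing_rate))
    colnames(newcalls) <- paste0(pick, "_dup")
    ci <- sampleInfo(x)[pick, , drop = FALSE]
    rownames(ci) <- colnames(newcalls)
    ## resubmitted under a different (bogus) sample label
    m2 <- cbind(calls(x), newcalls)
    cd <- rbind(sampleInfo(x), ci)
    x <- GenotypeSet(m2, snpMap(x), cd)
    truth$faults$duplicates <- data.frame(
      original = pick, duplicate = colnames(newcalls),
      stringsAsFactors = FALSE)
    truth$sample_map <- rbind(
      truth$sample_map,
      data.frame(sample_id = colnames(newcalls),
                 true_animal_id = as.character(ci$animal_id),
                 stringsAsFactors = FALSE))
  }
  if (n_swaps > 0) {
    cd <- sampleInfo(x)
    swaps <- data.frame(sample_a = character(), sample_b = character(),
                        stringsAsFactors = FALSE)
    avail <- setdiff(colnames(sim$x), taken)
    for (s in seq_len(n_swaps)) {
      if (length(avail) < 2) break
      a <- sample(avail, 1L)
      ha <- animals[as.character(cd[a, "animal_id"]), "herds"][[1]]$herd_id[1]
      herd_of <- vapply(as.character(cd[avail, "animal_id"]), function(id)
        animals[id, "herds"][[1]]$herd_id[1], "")
      mates <- avail[herd_of == ha & avail != a]
      if (!length(mates)) { avail <- setdiff(avail, a); next }
      b <- sample(mates, 1L)
      tmp <- cd[a, "animal_id"]
      cd[a, "animal_id"] <- cd[b, "animal_id"]
      cd[b, "animal_id"] <- tmp
      swaps <- rbind(swaps, data.frame(sample_a = a, sample_b = b,
                                       stringsAsFactors = FALSE))
      avail <- setdiff(avail, c(a, b)); taken <- c(taken, a, b)
    }
    SummarizedExperiment::colData(x)$animal_id <- cd$animal_id
    truth$faults$swaps <- swaps
  }
  if (n_wrong_label > 0) {
    cd <- sampleInfo(x)
    m <- calls(x)
    herd_of <- vapply(colnames(x), function(s)
      animals[as.character(cd[s, "animal_id"]),
              "herds"][[1]]$herd_id[1], "")
    wl <- data.frame(victim_sample = character(), source_sample = character(),
                     stringsAsFactors = FALSE)
    avail <- setdiff(colnames(sim$x), taken)
    for (s in seq_len(n_wrong_label)) {
      if (length(avail) < 2) break
      victim <- sample(avail, 1L)
      mates <- avail[herd_of[avail] == herd_of[victim] & avail != victim]
      if (!length(mates)) { avail <- setdiff(avail, victim); next }
      src <- sample(mates, 1L)
      m[, victim] <- .applyNoise(truth$true_calls[, src, drop = FALSE],
                                 cfg$error_rate, cfg$missing_rate)
      wl <- rbind(wl, data.frame(victim_sample = victim,
                                 source_sample = src,
                                 stringsAsFactors = FALSE))
      truth$sample_map$true_animal_id[
        truth$sample_map$sample_id == victim] <-
        as.character(cd[src, "animal_id"])
      avail <- setdiff(avail, c(victim, src)); taken <- c(taken, victim, src)
    }
    x <- GenotypeSet(m, snpMap(x), cd)
    truth$faults$wrong_labels <- wl
  }
  if (n_sex_mislabels > 0) {
    pick <- sample(rownames(animals), n_sex_mislabels)
    animals[pick, "recorded_sex"] <-
      ifelse(animals[pick, "recorded_sex"] == "male", "female", "male")
    truth$faults$sex_mislabels <- data.frame(animal_id = pick,
                                             stringsAsFactors = FALSE)
  }
  sim$x <- x; sim$animals <- animals; sim$truth <- truth
  sim
}

#' Export a herd's calls as a raw long-format allele table
#'
#' AB-format allele pairs per call, optionally corrupting a fraction of
#' rows to nucleotide symbols (the mixed-format failure mode the
#' genotype QC format check exists for).
#'
#' @param x a [GenotypeSet-class].
#' @param samples columns to export (default all).
#' @param corrupt_rate fraction of rows rewritten with T/G alleles.
#' @param seed RNG seed for the corruption draw.
#' @return data.frame `sample_id, snp_id, allele1, allele2`.
#' @export
exportLongAlleles <- function(x, samples = colnames(x), corrupt_rate = 0,
                              seed = 1L) {
  m <- calls(x)[, samples, drop = FALSE]
  df <- data.frame(
    sample_id = rep(samples, each = nrow(m)),
    snp_id = rep(rownames(m), length(samples)),
    call = as.vector(m), stringsAsFactors = FALSE)
  a <- list(`0` = c("B", "B"), `1` = c("A", "B"),
            `2` = c("A", "A"), `9` = c("-", "-"))
  df$allele1 <- vapply(as.character(df$call), function(g) a[[g]][1], "")
  df$allele2 <- vapply(as.character(df$call), function(g) a[[g]][2], "")
  if (corrupt_rate > 0) {
    set.seed(seed)
    nz <- which(df$call != 9L)
    hit <- nz[stats::runif(length(nz)) < corrupt_rate]
    df$allele2[hit] <- sample(c("T", "G"), length(hit), replace = TRUE)
  }
  df$call <- NULL
  df
}

#' Simulate genotypes from fixed per-breed allele frequencies
#'
#' Draws each genotype as Binomial(2, sum_k q_k P[j,k]) — an admixed
#' individual under the supervised-ancestry model — for parameter
#' recovery tests of the breed-composition estimator.
#'
#' @param P SNP x breed allele-A frequency matrix.
#' @param q ancestry fractions (recycled across individuals).
#' @param n number of individuals.
#' @param error_rate,missing_rate noise as in [simulateHerd()].
#' @return integer matrix SNP x n.
#' @export
simulateAdmixed <- function(P, q, n = 1L, error_rate = 0,
                            missing_rate = 0) {
  stopifnot(length(q) == ncol(P), abs(sum(q) - 1) < 1e-8)
  pA <- as.vector(P %*% q)
  m <- matrix(stats::rbinom(nrow(P) * n, 2, pA), nrow = nrow(P))
  storage.mode(m) <- "integer"
  rownames(m) <- rownames(P)
  .applyNoise(m, error_rate, missing_rate)
}
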