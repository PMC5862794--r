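---
title: "Methods: genotype and animal QC for national cattle SNP data"
author: "herdqc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genotype and animal QC for national cattle SNP data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(herdqc)
```

# Scope and data model

`herdqc` operates on integer-coded SNP calls — `2` = AA, `1` = AB,
`0` = BB, `9` = missing — held in a `GenotypeSet`, a
`SummarizedExperiment` with SNPs as rows and samples as columns. The
coding is shared by every module because the duplicate check works
directly on the concatenated digit string. The SNP map (`rowData`)
carries chromosome, 1-based position, parentage-panel membership, a
chromosome-X pseudoautosomal (PAR) flag and a cluster-quality flag.
Positions follow the UMD3.1 convention; AB coding is strand-free, and
Top-format input is converted only through an explicit per-SNP allele
table (`top_a`/`top_b`) — the readers refuse to guess strand. SNPs
present in a genotype file but absent from the map are dropped with a
count, because national databases mix chips and the pipeline operates
on the intersection.

All numeric constants live in one configuration object,
`herdThresholds()`; every rule below names its threshold there.

# Genotype QC

A genotype must pass four checks to be used downstream.

* **Call rate.** Pass at CR ≥ 0.90 (inclusive — the rule is stated with
  "≥"), computed over *usable* SNPs only: SNPs whose cohort call rate is
  below 0.85 are excluded from the denominator. The usable mask is
  recomputed from the supplied cohort rather than frozen from a
  database, because the package has no national database behind it;
  with cohorts of a few hundred samples or more the two coincide in
  practice. On very small cohorts a single bad sample can drag per-SNP
  rates below 0.85 and soften its own denominator — a known
  small-cohort artifact the tests avoid by using ≥ 20 samples.
* **Genotype classes.** All three classes AA/AB/BB must be observed;
  a record without BB (the classic clustering failure) fails.
* **Format purity.** AB-declared data containing C/T/G symbols (or
  Top-declared data containing B) fails; the long-format reader raises
  a structured `herdqc_format_anomaly` condition carrying the offending
  rows, and `detectMixedFormat()` is the non-throwing version.
* **Class frequency.** Fail when min(fAA, fAB, fBB) < 0.20, strictly —
  the boundary value 0.20 passes ("below" is strict). Frequencies are
  computed over all non-missing calls including chrX (whose share on a
  genome-wide chip is negligible); `autosomes_only = TRUE` restricts
  them. Empirically, genuine genotypes concentrate far from the 20%
  line, so the rule costs essentially nothing: on Hardy–Weinberg
  genotypes with MAF ~ U(0.3, 0.5) the expected class frequencies are
  (0.26, 0.47, 0.26) and more than 99% of simulated animals pass.

# Parentage

## Mismatch definition

A "mismatch" is an opposing homozygote — one individual AA, the other
BB. It is the only Mendelian impossibility testable on a duo and the
standard operationalization for exclusion-based verification.
Heterozygotes never conflict; SNPs missing in either member are
excluded from both numerator and denominator. Mismatch counting is
restricted to autosomes throughout: a sire and son are *legitimately*
opposing homozygotes at hemizygous chrX calls (the son's X is
maternal), so sex chromosomes carry no parentage information of this
kind.

## Two-stage validation

Stage one counts mismatches on the 800-SNP parentage panel: ≤ 4
validates, ≥ 13 fails. The apparent gap at exactly 4 in the rule's
usual phrasing ("fewer than 4 validates", gray zone "5–12") is resolved
in favour of validating at 4, consistent with observed validated-parent
distributions that include 4-mismatch validations. The gray zone 5–12
(0.5–1.5% of the panel) is re-scored on all shared autosomal SNPs: a
full-set misconcordance rate ≤ 1% validates, > 1% fails. A verdict can
only change between the panel stage and the full stage inside the gray
zone — outside it the full set is never consulted. Pairs sharing fewer
than 600 non-missing panel SNPs get `insufficient_data`; the absolute
thresholds 4/12 are kept as stated even when fewer than 800 panel SNPs
overlap, and `n_compared_panel` is always reported so users can audit
marginal overlaps.

## Whole-database prediction

The candidate table holds one genotype per animal — the one with the
most non-missing panel calls, ties broken by newest genotyping date —
for animals with ≥ 600 panel calls. Prediction scans the target against
every table row, abandoning a candidate as soon as its running
mismatch count exceeds 12; the chunked early-termination scan is
required (and property-tested) to return exactly the set an exhaustive
full count would. Survivors are filtered by age — a parent must be at
least 15 months older (6 months to puberty plus 9 months gestation),
expressed in calendar months, which also removes the target's own
genotyped progeny — and by sex (sire candidates male, dam candidates
female). Gray-zone survivors are confirmed at the full-SNP 1% rule with
the same ≥ 600-call overlap requirement as validation. Batching of the
scan is checkpointing only: results are identical for any chunk size.

All candidates passing these rules are returned. At gene-drop
conditions this is almost always exactly the true parent per slot, but
exclusion counting has a known residual weakness: a sufficiently
close relative (e.g. an ancestor reached through both parental lines in
an inbred pedigree) can occasionally pass the 1% full-set rule. The
package returns such co-candidates rather than silently picking one;
they are the reason the operational process re-checks gray-zone results
and prefers more SNPs.

## Trio mating validation

With both parents individually validated, a mating SNP misconcordance
(MSM) is a panel SNP where the calf is AB while sire and dam are
homozygous for the *same* allele (opposite homozygous parents make an
AB calf — a valid mating). The trio is flagged for manual review when
the MSM rate over informative SNPs (all three non-missing) exceeds 1%.
At a 0.2% per-call error rate a true trio accrues roughly half an MSM
on average across 800 SNPs, so the zero-MSM fraction the simulator
produces (~60%) is error-driven and the >1% flag essentially never
fires for true trios.

# Duplicate detection

The 800 panel calls are concatenated into a digit string
(e.g. `001290021`) and split into consecutive non-overlapping blocks —
operationally 40 blocks of 20 after experience showed that with 16
blocks of 50, scattered missingness can break *every* block of a true
duplicate. Block matching is byte equality: a missing `9` matches only
`9`. This is deliberate; its consequence — heavy
missingness suppresses candidates — is exactly the failure mode the
smaller blocks mitigate. Pairs sharing at least one exact block are
candidates; candidates are confirmed by SNP-by-SNP comparison (missing
excluded) on the panel *and* on all available SNPs, both at ≥ 99%
identity. Requiring both tiers is conjunctive; discordant tiers are
logged. An unrelated pair at panel MAFs near 0.45 agrees at ~38% of
SNPs, so the 99% line separates cleanly; the same-DNA identity is
about 1 − 2e ≈ 99.6% at call error e = 0.2%. Confirmed duplicates
between different animals that share a dam and a birth date within a
week are labeled possible identical twins — the one genuinely
unresolvable case — instead of errors.

Multiple genotypes recorded for one animal are reconciled the same way:
any pair below 99% on both tiers is a conflict, both genotypes are held
`unresolved`, and with three or more genotypes the pairwise pattern
identifies the odd one out by majority agreement.

# Sex prediction and the PAR

Chromosome Y: with the 7-SNP chrY set, 0–1 called SNPs → female, 6–7 →
male, 2–5 → ambiguous. For chips carrying a different number of chrY
SNPs the cutoffs scale proportionally (≤ 1/7, ≥ 6/7) — a design
generalization; the stated rule fixes only the 7-SNP case.

Chromosome X: heterozygosity over non-PAR SNPs, nAB / (nAA + nAB +
nBB): ≤ 5% → male, ≥ 15% → female, between → ambiguous. A verdict
requires at least 20 non-missing nPAR calls (a guard against highly
inbred females looking male on sparse data). The two verdicts combine
by agreement; one ambiguous defers to the other; opposing verdicts are
a conflict for manual review (possible X0/XXY, or a sex-sorted-semen
sample).

PAR determination uses samples of known sex: chrX SNPs are filtered at
MAF ≥ 0.01 and CR ≥ 0.90, a SNP is classified PAR when its male
heterozygosity is ≥ 0.05 (`par_male_het_min`, an artifact choice — the
operational description says only "high male heterozygosity"), and the
PAR interval is the longest positional run of PAR-classified SNPs.
Longest-run smoothing is our choice of the simplest consistent
spatial rule. In the simulator the male het separation (~22% PAR vs
~0.1% nPAR) recovers the boundary exactly.

# Breed composition

Supervised ancestry: with per-breed allele-A frequencies **P** fixed
from listed-purebred references, the allele dose of a test animal at
SNP j is Binomial(2, Σₖ qₖ P[j,k]) and the ancestry vector **q** on the
simplex is estimated by EM — each gene copy is attributed to breeds in
proportion to qₖP[j,k] (or qₖ(1 − P[j,k]) for B copies) and **q** is
re-estimated from the attributions. With **P** fixed the log-likelihood
is concave in **q**, EM is monotone (asserted every iteration in the
tests), and no block relaxation is needed. Frequencies are smoothed
with a 0.5 pseudocount per allele so off-reference animals keep finite
likelihoods; only autosomal SNPs are used; breeds with fewer than
`breed_min_ref` (default 25 — a desk-scale stand-in for the hundreds
used operationally) purebred references are dropped because small
reference breeds predict poorly. Convergence is a relative
log-likelihood change below 1e-7 or 2,000 iterations, both
configurable; the operational tool's settings are not public, so these
are package choices. Estimates need ≥ 1,000 overlapping SNPs, else
`unevaluable`.

Listed-vs-predicted comparison flags only gross conflicts: any breed
fraction differing from the listed value (in 32nds) by more than 0.40.
The categorical example motivating the check is "listed 100% one
breed, predicted 100% another"; 0.40 is an artifact default since no
numeric threshold is stated. Compositions involving breeds outside the
reference are `unevaluable` — such animals are predicted as an
arbitrary-looking mixture of reference breeds. Covariance PCA of the
reference (`referencePCA()`) is a diagnostic only.

# Animal QC orchestration

All checks run for every sample before any decision. The decision rule:
a *pedigree-class* animal with a breed mismatch is invalidated; a
confirmed unreconciled duplicate or multi-genotype conflict is invalid
pending resolution; every other single failure only flags — a sex
mismatch alone, for instance, may simply be a recording error.
Offspring-failure patterns flag a parent genotype: a dam with ≥ 2
genotyped offspring all failing, a stock bull with ≥ 5 and ≥ 80%
failing, an AI sire with ≥ 10 and ≥ 80% failing ("80%" is read as
≥ 80%: the section's thresholds are floors). Invalidating a parent
genotype resets exactly the parentage verdicts citing it. Tissue
sampled more than 45 days (strictly) after recorded death raises a
warning flag, except AI-sire straw samples.

Conflict resolution evaluates evidence in a fixed priority — parentage
against listed parents, offspring validation, predicted vs recorded
sex, predicted vs listed breed, herd co-residence — and attributes
genotypes only when exactly one assignment is consistent with all
non-ambiguous evidence. Two shapes are distinguished: *same DNA under
two labels* (which animal does the genotype belong to?) and *distinct
genotypes with swapped labels* (the dam/calf swap case, where each
genotype validates to the other animal's listed parents). Animals that
never co-resided point to a lab rather than farm error; this is logged,
not decisive. Geographic plausibility beyond herd co-residence would
need coordinates the data model does not carry. When breed and
duplicate evidence genuinely conflict, the pair stays unresolved rather
than guessed.

# Panel construction utilities

`selectPanel()` applies the hard filters — cluster quality, CR ≥ 0.90,
MAF ≥ 0.25 — keeps the passing must-include (ISAG-type) SNPs, and fills
remaining slots by descending MAF with a deterministic
(chromosome, position) tie-break. Filling by MAF is our reading of
"selected based on … MAF"; the exact operational ranking is not stated.
`panelPowerReport()` Monte-Carlos the opposing-homozygote distributions
for unrelated and true parent–offspring pairs; the unrelated mean has
the closed form Σ 2pᵢ²qᵢ² (≈ 98 mismatches for 800 SNPs at MAF
0.42–0.50), which the tests verify within Monte-Carlo error. It also
illustrates why low-density panels can validate wrong parents at a
fixed rate threshold: at 100 SNPs the acceptance region ≤ 1 mismatch is
reachable by unrelated pairs at low MAF, at 800 SNPs ≤ 8 is not.

# The herd simulator

`simulateHerd()` is a gene-drop: per-breed founder frequencies derive
from shared base frequencies through a Balding–Nichols Beta draw
(default Fst 0.1, clamped to [0.05, 0.95] so every SNP stays
polymorphic within every breed, as chip SNPs are pre-filtered to be),
founders are Hardy–Weinberg, and offspring receive one
Mendelian-sampled allele per parent with SNPs transmitted
independently — no recombination or linkage, which none of the checks
depend on. Defaults encode the study conditions: 800 panel SNPs with
MAF ~ U(0.42, 0.50), 400 extra autosomal SNPs, 150 chrX SNPs with a
distal 10% PAR, the 7 chrY SNPs, per-call error 0.2% (a call is
replaced by one of the two other classes), missingness 1%, and an 8%
listed-parent misrecording rate — the middle of the reported 7–9%
national range. Sex chromosomes are modelled structurally: males are
hemizygous outside the PAR (the chip reports the single allele as a
homozygote), the PAR is transmitted diploid in both sexes (an
approximation to X–Y PAR recombination), chrY is paternal and
male-only. PAR base frequencies are drawn U(0.10, 0.20) and non-PAR X
frequencies U(0.06, 0.94), so simulated male PAR heterozygosity lands
near the ~24% reported operationally and female nPAR heterozygosity in
the mid-30s. Generations are spaced two years apart with ≤ 120 days of
within-cohort spread, so every true parent clears the 15-month age
rule. `injectFaults()` adds labeled faults — duplicate submissions
(fresh error/missingness draws from the true genotype), same-herd
sample swaps, wrong-label submissions, sex mislabels — and
`exportLongAlleles()` can corrupt a fraction of allele rows into
nucleotide symbols to exercise the format check. Everything is recorded
in a truth ledger, so precision and recall of every detector are
computable exactly, and a fixed seed reproduces the herd byte for byte.

What the simulator does *not* emulate: linkage disequilibrium,
selection, assortative mating, platform-specific intensity artifacts,
and the long-tailed error structure of real labs. Passing tests
therefore demonstrate correctness of the decision logic under the
stated genetic model, not field performance; the operational
percentages from database-scale experience (validation rates, MSM
distributions) are functions of that real-world structure and are not
reproduced at desk scale.

# Problem sizes and numerical choices

The test and acceptance runs use a 1,000-animal four-breed herd for
parentage and sex (with an exhaustive-scan oracle over all ~500k
pairs computed by genotype-class cross-products), a 500-animal herd for
duplicate recall, 5,000 SNPs for breed-composition recovery, and 2,000
Monte-Carlo pairs for the closed-form mismatch check — sizes chosen so
each property is measured with comfortable margins in about a minute.
Ties are deterministic everywhere (candidate-table selection, panel
fill); mixture weights in the EM are clipped at 1e-12 from the simplex
boundary before logs; degenerate inputs (all-missing records, empty
panels, references with identical frequencies across breeds) return
explicit statuses rather than numbers.
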