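#' Build a breed reference of per-breed allele frequencies
#'
#' Reference animals must be listed purebred (32/32 of one breed).
#' Allele-A frequencies are estimated per breed per autosomal SNP with a
#' 0.5 pseudocount per allele, `P = (nA + 0.5) / (2 n_called + 1)`, so no
#' frequency is ever exactly 0 or 1 and off-reference genotypes keep a
#' finite likelihood. Breeds with fewer purebred references than
#' `breed_min_ref` are dropped with a warning — small reference breeds
#' predict poorly.
#'
#' @param x a [GenotypeSet-class] of reference animals.
#' @param animals animal metadata from [readAnimals()] (for `breed32`).
#' @param thresholds a [herdThresholds()] list.
#' @return list of class `breed_reference`: `P` (SNP x breed matrix of
#'   allele-A frequencies), `breeds`, `n_ref` (animals per breed),
#'   `snp_ids` (autosomal SNPs used).
#' @export
buildBreedReference <- function(x, animals, thresholds = herdThresholds()) {
  rd <- snpMap(x)
  auto <- which(rd$chromosome %in% as.character(1:29))
  if (!length(auto)) stop("no autosomal SNPs")
  aid <- as.character(sampleInfo(x)$animal_id)
  breed_of <- vapply(aid, function(a) {
    if (!a %in% rownames(animals)) return(NA_character_)
    b <- animals[a, "breed32"][[1]]
    if (length(b) == 1 && b == 32L) names(b) else NA_character_
  }, "")
  keep <- !is.na(breed_of)
  if (!any(keep)) stop("no listed-purebred reference animals")
  x <- x[auto, keep]; breed_of <- breed_of[keep]
  counts <- table(breed_of)
  low <- names(counts)[counts < thresholds$breed_min_ref]
  if (length(low))
    warning("breed(s) below the reference minimum dropped: ",
            paste(low, collapse = ", "))
  breeds <- sort(names(counts)[counts >= thresholds$breed_min_ref])
  if (!length(breeds)) stop("no breed meets the reference minimum")
  m <- calls(x)
  P <- sapply(breeds, function(b) {
    sub <- m[, breed_of == b, drop = FALSE]
    nA <- rowSums((sub == 2L) * 2L + (sub == 1L))
    nc <- rowSums(sub != 9L)
    (nA + 0.5) / (2 * nc + 1)
  })
  structure(list(P = P, breeds = breeds,
                 n_ref = as.integer(counts[breeds]),
                 snp_ids = rownames(x)),
            class = "breed_reference")
}

#' Estimate breed (ancestry) fractions for one genotype
#'
#' Supervised admixture model: with per-breed allele frequencies `P`
#' fixed, the allele-A dose at SNP j is Binomial(2, sum_k q_k P[j,k]),
#' and the ancestry vector `q` on the simplex is the only unknown. `q`
#' is maximized by EM — each of the two gene copies at a SNP is
#' attributed to a breed in proportion to `q_k P[j,k]` (A copies) or
#' `q_k (1 - P[j,k])` (B copies) and `q` is re-estimated from the
#' attributions. With `P` fixed the log-likelihood is concave in `q` and
#' non-decreasing at every step.
#'
#' @param callsVec integer call vector aligned to the reference's SNPs
#'   (use [alignToReference()] when the sample's map differs).
#' @param ref a `breed_reference` from [buildBreedReference()].
#' @param thresholds a [herdThresholds()] list.
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter iteration cap.
#' @return list of class `breed_estimate`: `q` (named fractions summing
#'   to 1), `loglik`, `loglik_trace`, `n_iter`, `converged`, `n_snps`,
#'   `flat` (TRUE when the design is uninformative: all breeds equally
#'   likely everywhere).
#' @export
estimateBreedComposition <- function(callsVec, ref,
                                     thresholds = herdThresholds(),
                                     tol = 1e-7, max_iter = 2000L) {
  obs <- which(callsVec != 9L)
  if (length(obs) < thresholds$breed_min_snps)
    return(structure(list(q = NULL, loglik = NA_real_,
                          loglik_trace = numeric(), n_iter = 0L,
                          converged = FALSE, n_snps = length(obs),
                          flat = NA, status = "unevaluable"),
                     class = "breed_estimate"))
  g <- callsVec[obs]
  P <- ref$P[obs, , drop = FALSE]
  K <- ncol(P)
  q <- rep(1 / K, K)
  ll_trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    pA <- as.vector(P %*% q)            # mixture allele-A frequency
    pA <- pmin(pmax(pA, 1e-12), 1 - 1e-12)
    ll <- sum(g * log(pA) + (2 - g) * log(1 - pA))
    ll_trace <- c(ll_trace, ll)
    if (is.finite(ll_old) &&
        abs(ll - ll_old) <= tol * (abs(ll_old) + 1e-12)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    ## E-step responsibilities summed over SNPs, per allele type
    wA <- sweep(P, 2, q, "*") / pA          # J x K
    wB <- sweep(1 - P, 2, q, "*") / (1 - pA)
    q <- as.vector(g %*% wA + (2 - g) %*% wB) / (2 * length(g))
    q <- q / sum(q)
  }
  flat <- max(apply(P, 1, function(r) diff(range(r)))) < 1e-10
  structure(list(q = stats::setNames(q, ref$breeds),
                 loglik = ll_trace[length(ll_trace)],
                 loglik_trace = ll_trace, n_iter = it,
                 converged = converged, n_snps = length(g),
                 flat = flat, status = "ok"),
            class = "breed_estimate")
}

#' Align a sample's calls to a breed reference's SNP set
#'
#' @param x a [GenotypeSet-class].
#' @param sample column name.
#' @param ref a `breed_reference`.
#' @return integer vector over the reference SNPs (9 where absent).
#' @export
alignToReference <- function(x, sample, ref) {
  v <- rep(9L, length(ref$snp_ids))
  hit <- ref$snp_ids %in% rownames(x)
  v[hit] <- calls(x)[ref$snp_ids[hit], sample]
  v
}

#' Compare a predicted breed composition with the listed one
#'
#' A gross conflict — any breed fraction differing from the listed value
#' by more than `breed_mismatch_tol` (default 0.40, i.e. the categorical
#' "listed 100% one breed, predicted 100% another" situation) — is a
#' mismatch. Compositions containing breeds outside the reference are
#' unevaluable: such animals get predicted as a seemingly arbitrary
#' mixture of reference breeds.
#'
#' @param estimate a `breed_estimate`.
#' @param breed32 named integer vector of listed 32nds (see
#'   [readAnimals()]).
#' @param ref the `breed_reference` used.
#' @param thresholds a [herdThresholds()] list.
#' @return "match", "mismatch", or "unevaluable".
#' @export
compareToListed <- function(estimate, breed32, ref,
                            thresholds = herdThresholds()) {
  if (is.null(estimate$q) || identical(estimate$status, "unevaluable"))
    return("unevaluable")
  if (!length(breed32)) return("unevaluable")
  if (any(!names(breed32) %in% ref$breeds)) return("unevaluable")
  listed <- stats::setNames(rep(0, length(ref$breeds)), ref$breeds)
  listed[names(breed32)] <- breed32 / 32
  if (max(abs(estimate$q - listed)) > thresholds$breed_mismatch_tol)
    "mismatch" else "match"
}

#' Principal components of a reference population (diagnostic)
#'
#' Covariance PCA of the centered genotype matrix; used to eyeball breed
#' separation and stray reference animals. Plays no role in decisions.
#'
#' @param x a [GenotypeSet-class].
#' @param n_pc number of components.
#' @return matrix of sample scores (samples x n_pc).
#' @export
referencePCA <- function(x, n_pc = 2L) {
  m <- calls(x)
  m[m == 9L] <- NA
  mu <- rowMeans(m, na.rm = TRUE)
  cm <- m - mu
  cm[is.na(cm)] <- 0
  p <- stats::prcomp(t(cm), center = FALSE)
  p$x[, seq_len(min(n_pc, ncol(p$x))), drop = FALSE]
}
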