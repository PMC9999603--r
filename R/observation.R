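# Observational model for lcNGS read counts. A locus observation for one
# person is a count vector c = (cA, cC, cG, cT). Given the true genotype
# g = (g1, g2), the heterozygote balance q is k/m with k ~ Binomial(m, 1/2),
# where m is the effective number of DNA templates founding PCR amplicons;
# conditional on q, reads fall in the four categories with probabilities
#   beta_i = (1 - e) * (q * I(g1 = i) + (1 - q) * I(g2 = i)) + e / 4,
# e being the per-read error probability. Low m produces skewed
# heterozygote balance and allelic drop-out; e produces drop-in reads.

#' Observational-model parameters
#'
#' @param m Effective number of PCR-founding DNA templates (integer >= 1).
#'   Low-quantity or degraded samples correspond to low `m`.
#' @param e Per-read error probability in `[0, 1)`; an error read reports
#'   each nucleotide with probability 1/4.
#' @return A list of class `kin_obs`.
#' @export
obs_params <- function(m = 10L, e = 0.02) {
  stopifnot(length(m) == 1L, m >= 1, m == as.integer(m), e >= 0, e < 1)
  structure(list(m = as.integer(m), e = as.numeric(e)), class = "kin_obs")
}

# the 10 unordered genotypes in canonical order
GENOTYPES <- cbind(
  g1 = c(1L, 1L, 1L, 1L, 2L, 2L, 2L, 3L, 3L, 4L),
  g2 = c(1L, 2L, 3L, 4L, 2L, 3L, 4L, 3L, 4L, 4L)
)

genotype_index <- function(a, b) {
  lo <- pmin(a, b); hi <- pmax(a, b)
  match(paste(lo, hi), paste(GENOTYPES[, 1], GENOTYPES[, 2]))
}

beta_vector <- function(q, g, e) {
  b <- rep(e / 4, 4)
  b[g[1]] <- b[g[1]] + (1 - e) * q
  b[g[2]] <- b[g[2]] + (1 - e) * (1 - q)
  b
}

#' Likelihood of a read-count vector given a genotype
#'
#' Finite mixture of multinomials over the binomial heterozygote-balance
#' states `q = k/m`, `k = 0..m`. Symmetric in the genotype order; an empty
#' observation (zero total reads) has likelihood 1 for every genotype.
#'
#' @param counts Length-4 vector of nonnegative integer read counts
#'   (A, C, G, T).
#' @param g Genotype as a length-2 vector of allele indices in 1..4.
#' @param obs A `kin_obs` parameter set.
#' @return The probability of `counts` given `g`.
#' @examples
#' read_likelihood(c(5, 0, 3, 0), c(1, 3), obs_params(m = 10, e = 0.02))
#' @export
read_likelihood <- function(counts, g, obs = obs_params()) {
  stopifnot(length(counts) == 4, all(counts >= 0), length(g) == 2,
            all(g %in% 1:4), inherits(obs, "kin_obs"))
  C <- sum(counts)
  if (C == 0) return(1)
  m <- obs$m; e <- obs$e
  lmult <- lgamma(C + 1) - sum(lgamma(counts + 1))
  pr <- 0
  for (k in 0:m) {
    b <- beta_vector(k / m, g, e)
    ll <- lmult + sum(ifelse(counts > 0, counts * log(b), 0))
    pr <- pr + stats::dbinom(k, m, 0.5) * exp(ll)
  }
  pr
}

# Vectorized engine path: counts is an (N x 4) matrix; returns an (N x 10)
# matrix of Pr(counts | genotype) including the multinomial coefficient.
read_likelihood_matrix <- function(counts, obs) {
  N <- nrow(counts)
  m <- obs$m; e <- obs$e
  Ctot <- rowSums(counts)
  lmult <- lgamma(Ctot + 1) - rowSums(lgamma(counts + 1))
  out <- matrix(0, N, 10)
  wk <- stats::dbinom(0:m, m, 0.5)
  for (gi in 1:10) {
    g <- GENOTYPES[gi, ]
    acc <- numeric(N)
    for (k in 0:m) {
      b <- beta_vector(k / m, g, e)
      pos <- b > 0
      ll <- counts[, pos, drop = FALSE] %*% log(b[pos])
      term <- exp(lmult + ll)
      if (any(!pos)) term[rowSums(counts[, !pos, drop = FALSE]) > 0] <- 0
      acc <- acc + wk[k + 1] * term
    }
    out[, gi] <- acc
  }
  out[Ctot == 0, ] <- 1
  out
}

#' Allelic drop-out probability
#'
#' Probability that all `d` reads at a heterozygous locus support only one
#' of the two true alleles (possibly plus error reads matching that allele):
#' `a_{m,d} = sum_k C(m,k) 2^-m [((1-e)k/m + e/4)^d + ((1-e)(1-k/m) + e/4)^d]`.
#' For a single read this is `1 - e/2` for every `m`.
#'
#' @param m Template-count parameter (vectorized).
#' @param d Allelic depth, number of reads (vectorized).
#' @param e Per-read error probability.
#' @return Drop-out probability `a_{m,d}`.
#' @examples
#' dropout_probability(10, 10, 0.02)
#' @export
dropout_probability <- function(m, d, e = 0.02) {
  stopifnot(all(d >= 1), all(m >= 1))
  n <- max(length(m), length(d))
  m <- rep_len(as.integer(m), n); d <- rep_len(d, n)
  vapply(seq_len(n), function(i) {
    k <- 0:m[i]
    w <- stats::dbinom(k, m[i], 0.5)
    sum(w * (((1 - e) * k / m[i] + e / 4)^d[i] + ((1 - e) * (1 - k / m[i]) + e / 4)^d[i]))
  }, numeric(1))
}

#' Expected per-read drop-in rate
#'
#' Expected proportion of reads reporting an allele absent from the
#' underlying genotype: an error read lands on one of the 3 absent alleles
#' at a homozygous locus and one of the 2 absent alleles at a heterozygous
#' one, so the rate is `hom_prop * 3e/4 + (1 - hom_prop) * 2e/4`.
#'
#' @param hom_prop Proportion of homozygous loci in the genome considered.
#' @param e Per-read error probability.
#' @return Expected drop-in rate per read.
#' @examples
#' dropin_rate(0.57, 0.02)  # 0.6425 * e
#' @export
dropin_rate <- function(hom_prop, e) {
  stopifnot(hom_prop >= 0, hom_prop <= 1)
  hom_prop * 3 * e / 4 + (1 - hom_prop) * 2 * e / 4
}

#' MAP genotype call from read counts
#'
#' Returns the genotype maximizing the product of its Hardy-Weinberg prior
#' (from the gamma-smoothed locus frequencies, without theta adjustment)
#' and the read-count likelihood. Ties are broken lexicographically in
#' (g1, g2).
#'
#' @inheritParams read_likelihood
#' @param f Length-4 locus frequency vector.
#' @param pop A `kin_pop` parameter set (used for gamma smoothing of `f`).
#' @return Length-2 integer vector `(g1, g2)` with `g1 <= g2`.
#' @export
call_genotype <- function(counts, f, obs = obs_params(), pop = pop_params()) {
  post <- genotype_posterior(matrix(counts, 1), matrix(f, 1), obs, pop)
  unname(GENOTYPES[which.max(post[1, ]), ])
}

# (N x 10) posterior-proportional matrix: HWE prior x likelihood
genotype_posterior <- function(counts, fmat, obs, pop) {
  fp <- fmat * (1 - pop$gamma) + matrix(pop$fbar * pop$gamma, nrow(fmat), 4, byrow = TRUE)
  prior <- fp[, GENOTYPES[, 1], drop = FALSE] * fp[, GENOTYPES[, 2], drop = FALSE]
  het <- GENOTYPES[, 1] != GENOTYPES[, 2]
  prior[, het] <- 2 * prior[, het]
  prior * read_likelihood_matrix(counts, obs)
}

# MAP call per row; ties broken by the canonical genotype order, which is
# lexicographic in (g1, g2)
call_genotype_matrix <- function(counts, fmat, obs, pop) {
  post <- genotype_posterior(counts, fmat, obs, pop)
  max.col(post, ties.method = "first")
}

#' Simulate read counts for one genotype
#'
#' Two-stage draw: heterozygote balance `q = k/m`, `k ~ Binomial(m, 1/2)`,
#' then `counts ~ Multinomial(depth, beta(q, g))`.
#'
#' @param g Genotype, length-2 vector of allele indices.
#' @param depth Total number of reads (>= 0).
#' @param obs A `kin_obs` parameter set.
#' @return Length-4 integer vector of read counts.
#' @export
simulate_reads <- function(g, depth, obs = obs_params()) {
  stopifnot(depth >= 0)
  if (depth == 0) return(integer(4))
  k <- stats::rbinom(1L, obs$m, 0.5)
  as.integer(stats::rmultinom(1L, depth, beta_vector(k / obs$m, g, obs$e)))
}
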