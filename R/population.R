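# Founder-allele population model: Dirichlet-multinomial with kinship
# parameter theta (Fst) and a small smoothing weight gamma pulling the
# locus frequencies f towards background nucleotide probabilities fbar.
# The joint law of the F founder alleles at a locus is exchangeable and is
# realized sequentially: given k previous draws of allele i among s draws,
# the next draw is allele i with probability
#   (theta * k + (1 - theta) * f'_i) / (1 + theta * (s - 1)),
# where f' = f * (1 - gamma) + gamma * fbar. With gamma = 0 this is the
# classical Fst sampling formula; theta = 0 is the Hardy-Weinberg limit of
# i.i.d. draws from f'.

#' Population-model parameters
#'
#' @param theta Kinship / fixation parameter (Fst), in `[0, 1)`. `theta = 0`
#'   is the Hardy-Weinberg limit.
#' @param gamma Smoothing weight in `[0, 1)` guarding against zero
#'   population frequencies.
#' @param fbar Background probabilities for A, C, G, T; defaults to uniform.
#' @return A list of class `kin_pop`.
#' @export
pop_params <- function(theta = 0.01, gamma = 0.001, fbar = rep(0.25, 4)) {
  stopifnot(theta >= 0, theta < 1, gamma >= 0, gamma < 1, length(fbar) == 4,
            all(fbar >= 0), abs(sum(fbar) - 1) < 1e-9)
  structure(list(theta = theta, gamma = gamma, fbar = as.numeric(fbar)), class = "kin_pop")
}

# gamma-smoothed frequency vector
smoothed_freq <- function(f, pop) f * (1 - pop$gamma) + pop$gamma * pop$fbar

#' Sequential founder-allele probability
#'
#' Probability that the next founder allele drawn at a locus is of type `i`,
#' given the counts of alleles already drawn.
#'
#' @param i Allele index 1..4 (A, C, G, T); may be a vector.
#' @param counts Length-4 vector of counts of alleles already drawn.
#' @param f Length-4 locus frequency vector (sums to 1).
#' @param pop A `kin_pop` parameter set.
#' @return Probability (vectorized over `i`); sums to 1 over `i = 1:4`.
#' @export
next_allele_prob <- function(i, counts, f, pop = pop_params()) {
  stopifnot(length(counts) == 4, all(counts >= 0), length(f) == 4)
  fp <- smoothed_freq(f, pop)
  s <- sum(counts)
  th <- pop$theta
  if (th == 0) return(fp[i])
  (th * counts[i] + (1 - th) * fp[i]) / (1 + th * (s - 1))
}

#' Joint probability of an ordered founder-allele assignment
#'
#' Product of sequential draw probabilities; by exchangeability of the
#' Dirichlet-multinomial the value does not depend on the order of the
#' sequence.
#'
#' @param alleles Integer vector of allele indices (1..4), one per founder
#'   allele at the locus.
#' @inheritParams next_allele_prob
#' @return Joint probability.
#' @export
founder_assignment_prob <- function(alleles, f, pop = pop_params()) {
  counts <- integer(4)
  pr <- 1
  for (a in alleles) {
    pr <- pr * next_allele_prob(a, counts, f, pop)
    counts[a] <- counts[a] + 1L
  }
  pr
}

#' Simulate founder alleles at a locus
#'
#' Sequential sampling from the model; uses R's global RNG stream.
#'
#' @param F_alleles Number of founder alleles to draw.
#' @inheritParams next_allele_prob
#' @return Integer vector of allele indices, length `F_alleles`.
#' @export
simulate_founder_alleles <- function(F_alleles, f, pop = pop_params()) {
  stopifnot(F_alleles >= 1)
  counts <- integer(4)
  out <- integer(F_alleles)
  for (j in seq_len(F_alleles)) {
    pr <- next_allele_prob(1:4, counts, f, pop)
    a <- sample.int(4L, 1L, prob = pr)
    out[j] <- a
    counts[a] <- counts[a] + 1L
  }
  out
}

# Vectorized founder-assignment probabilities used by the likelihood
# engine: `assign_mat` is an (n_assignments x F) matrix of allele indices
# and `fmat` an (N x 4) matrix of locus frequencies. Returns an
# (n_assignments x N) matrix of joint probabilities. The sequential-count
# coefficients depend only on the assignment prefix, not on the locus, so
# each row is a product over F factors linear in the smoothed frequencies.
founder_assignment_prob_matrix <- function(assign_mat, fmat, pop) {
  n_as <- nrow(assign_mat); Fn <- ncol(assign_mat); N <- nrow(fmat)
  fpm <- fmat * (1 - pop$gamma) + matrix(pop$fbar * pop$gamma, N, 4, byrow = TRUE)
  th <- pop$theta
  out <- matrix(1, n_as, N)
  if (Fn == 0L) return(out)
  counts <- matrix(0L, n_as, 4)
  for (j in seq_len(Fn)) {
    a <- assign_mat[, j]
    k <- counts[cbind(seq_len(n_as), a)]
    denom <- 1 + th * (j - 2)  # s = j - 1 previous draws
    # prob[i, locus] = (th*k_i + (1-th) * fp[locus, a_i]) / denom
    out <- out * (th * k + (1 - th) * t(fpm[, a, drop = FALSE])) / denom
    counts[cbind(seq_len(n_as), a)] <- k + 1L
  }
  out
}
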