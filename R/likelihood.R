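# Likelihood engine: per-locus IBD-code likelihoods and the symmetry-
# compressed Lander-Green forward pass over linked loci.
#
# Per locus, the probability of the observed data given an IBD code is a
# sum over joint assignments of nucleotides to the code's F founder-allele
# lineages: the exchangeable founder-model probability of the assignment
# times each typed person's observation likelihood given the genotype the
# assignment induces. The forward pass then runs over one representative
# inheritance pattern per symmetry class.

# per-person observation likelihood matrices (N x 10), one per typed person
person_likelihood_matrices <- function(data, typed, obs, called = FALSE,
                                       fmat = NULL, pop = NULL) {
  missing <- setdiff(typed, data$samples)
  if (length(missing)) stop("typed person(s) without data: ", paste(missing, collapse = ", "))
  lapply(typed, function(s) {
    m <- data$data[[s]]
    if (data$mode == "gl") {
      if (called) stop("genotype calling requires read counts, not genotype likelihoods")
      return(m)
    }
    if (called) {
      gi <- call_genotype_matrix(m, fmat, obs, pop)
      out <- matrix(0, nrow(m), 10)
      out[cbind(seq_len(nrow(m)), gi)] <- 1
      # a locus with no reads stays uninformative rather than asserting the
      # prior-maximal genotype
      out[rowSums(m) == 0, ] <- 1
      out
    } else {
      read_likelihood_matrix(m, obs)
    }
  })
}

#' Per-locus likelihood of an IBD code
#'
#' Computes, for every locus, the probability of the typed persons'
#' observations given that their allele slots are partitioned into
#' founder-allele lineages according to `labels`: a sum over the `4^F`
#' nucleotide assignments of the founder-model probability times the
#' product of the persons' observation likelihoods.
#'
#' @param labels Integer IBD-code label vector of length `2T`.
#' @param G_list List of `N x 10` observation-likelihood matrices, one per
#'   typed person in pedigree order.
#' @param fmat `N x 4` matrix of locus frequencies.
#' @param pop A `kin_pop` parameter set.
#' @return Numeric vector of length `N`.
#' @export
locus_code_likelihoods <- function(labels, G_list, fmat, pop = pop_params()) {
  Fn <- max(labels) + 1L
  Tn <- length(labels) %/% 2L
  stopifnot(length(G_list) == Tn)
  assign_mat <- as.matrix(expand.grid(rep(list(1:4), Fn), KEEP.OUT.ATTRS = FALSE))
  contrib <- founder_assignment_prob_matrix(assign_mat, fmat, pop)
  for (t in seq_len(Tn)) {
    a1 <- assign_mat[, labels[2L * t - 1L] + 1L]
    a2 <- assign_mat[, labels[2L * t] + 1L]
    gi <- genotype_index(a1, a2)
    contrib <- contrib * t(G_list[[t]])[gi, , drop = FALSE]
  }
  colSums(contrib)
}

# N x J matrix of class likelihoods; equal codes computed once and shared
class_likelihood_matrix <- function(pp, G_list, fmat, pop, cache = NULL) {
  keys <- pp$classes$code_str
  uk <- unique(keys)
  Lu <- lapply(uk, function(k) {
    if (!is.null(cache) && !is.null(cache[[k]])) return(cache[[k]])
    v <- locus_code_likelihoods(pp$classes$codes[[match(k, keys)]], G_list, fmat, pop)
    if (!is.null(cache)) cache[[k]] <- v
    v
  })
  do.call(cbind, Lu)[, match(keys, uk), drop = FALSE]
}

#' Compressed Lander-Green forward pass
#'
#' Runs the forward recursion over symmetry-class representatives: the
#' state vector `z` of length `J` starts at `1/2^K`, is multiplied
#' termwise by the class likelihoods at each locus, and is propagated
#' between loci by the evaluated transition matrix. `z` is rescaled by its
#' maximum at every locus with the log of the scale accumulated. The final
#' probability sums `z` over classes weighted by class sizes.
#'
#' @param Lmat `N x J` matrix of per-locus class likelihoods.
#' @param pp A `kin_preprocess` object.
#' @param pvec Recombination fractions between consecutive loci (length
#'   `N - 1`).
#' @return log10 of `Pr(data | pedigree)`; `-Inf` with attribute
#'   `impossible = TRUE` if the data annihilate every inheritance pattern.
#' @export
forward_log10_likelihood <- function(Lmat, pp, pvec) {
  N <- nrow(Lmat); J <- ncol(Lmat)
  stopifnot(J == pp$J, length(pvec) == max(N - 1L, 0L))
  z <- rep(1 / 2^pp$K, J)
  log10scale <- 0
  for (i in seq_len(N)) {
    z <- z * Lmat[i, ]
    if (i < N) {
      M <- evaluate_transition_matrix(pp$A, pvec[i])
      z <- as.numeric(M %*% z)
    }
    mx <- max(z)
    if (mx <= 0) {
      out <- -Inf
      attr(out, "impossible") <- TRUE
      return(out)
    }
    z <- z / mx
    log10scale <- log10scale + log10(mx)
  }
  log10(sum(pp$classes$sizes * z)) + log10scale
}

# single-(m,e) log10 likelihood of the data under one pedigree
pedigree_log10_once <- function(data, pp, markers, pop, obs, method, cache = NULL) {
  fmat <- as.matrix(markers[, c("fA", "fC", "fG", "fT")])
  G_list <- person_likelihood_matrices(
    data, pp$ped$typed, obs,
    called = (method == "called"), fmat = fmat, pop = pop
  )
  Lmat <- class_likelihood_matrix(pp, G_list, fmat, pop, cache = cache)
  if (method == "unlinked") {
    per_locus <- Lmat %*% pp$class_prior
    if (any(per_locus <= 0)) {
      out <- -Inf
      attr(out, "impossible") <- TRUE
      return(out)
    }
    sum(log10(per_locus))
  } else {
    forward_log10_likelihood(Lmat, pp, recombination_fractions(markers))
  }
}

#' log10 likelihood of observations under a pedigree
#'
#' `Pr(data | pedigree)` for linked SNPs, in log10. With parameter priors
#' (grids over `m` and/or `e`), the likelihood is the prior-weighted
#' mixture of the per-parameter likelihoods.
#'
#' @param data A `kin_data` object.
#' @param ped A `linkped` or a `kin_preprocess` object.
#' @param markers Marker tibble aligned with `data`.
#' @param pop A `kin_pop` parameter set.
#' @param obs A `kin_obs` parameter set (ignored where `prior` is given).
#' @param method `"full"` (linked, probabilistic), `"unlinked"` (product
#'   over loci), or `"called"` (MAP genotype calls, then linked).
#' @param m_prior,e_prior Optional named numeric vectors of prior weights:
#'   names are parameter values, entries are probabilities summing to 1.
#'   Defaults are point masses at `obs$m` and `obs$e`.
#' @param cache Optional environment for sharing per-code likelihoods
#'   across calls on the same data.
#' @return log10 likelihood (scalar).
#' @export
pedigree_log10_likelihood <- function(data, ped, markers, pop = pop_params(),
                                      obs = obs_params(),
                                      method = c("full", "unlinked", "called"),
                                      m_prior = NULL, e_prior = NULL, cache = NULL) {
  method <- match.arg(method)
  pp <- if (inherits(ped, "kin_preprocess")) ped else preprocess_pedigree(ped)
  if ((is.null(m_prior) && is.null(e_prior)) || data$mode == "gl") {
    return(pedigree_log10_once(data, pp, markers, pop, obs, method, cache = cache))
  }
  if (is.null(m_prior)) m_prior <- stats::setNames(1, obs$m)
  if (is.null(e_prior)) e_prior <- stats::setNames(1, obs$e)
  stopifnot(abs(sum(m_prior) - 1) < 1e-9, abs(sum(e_prior) - 1) < 1e-9)
  grid <- expand.grid(mi = seq_along(m_prior), ei = seq_along(e_prior))
  lls <- numeric(nrow(grid)); ws <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    o <- obs_params(as.numeric(names(m_prior))[grid$mi[i]],
                    as.numeric(names(e_prior))[grid$ei[i]])
    # cache is per-(m,e): person likelihoods differ across the grid
    lls[i] <- pedigree_log10_once(data, pp, markers, pop, o, method, cache = NULL)
    ws[i] <- m_prior[grid$mi[i]] * e_prior[grid$ei[i]]
  }
  mx <- max(lls)
  if (!is.finite(mx)) return(-Inf)
  log10(sum(ws * 10^(lls - mx))) + mx
}

#' Likelihood ratio between two pedigree hypotheses
#'
#' Computes `log10 Pr(data | ped1) - log10 Pr(data | ped2)` with either a
#' single parameter setting or a prior mixture over `m` and `e` (applied
#' identically to both hypotheses). Per-locus code likelihoods are shared
#' between hypotheses whose pedigrees induce the same IBD codes.
#'
#' @param data A `kin_data` object; must cover the typed persons of both
#'   pedigrees (same sample ids).
#' @param ped1,ped2 `linkped` or `kin_preprocess` objects for the two
#'   hypotheses (numerator and denominator).
#' @inheritParams pedigree_log10_likelihood
#' @param methods Character vector of methods to evaluate.
#' @return A `kin_lr` object: tibble with one row per method, columns
#'   `method`, `log10_lik1`, `log10_lik2`, `log10_lr`.
#' @examples
#' \donttest{
#' set.seed(1)
#' mk <- synth_marker_panel(100)
#' hs <- read_pedigree(system.file("extdata", "ped_halfsibs.ped", package = "kinlink"))
#' case <- simulate_case(hs, mk, depth_mean = 10, depth_sd = 2)
#' un <- unrelated_pedigree(hs$typed)
#' fit <- kin_lr(case$data, hs, un, mk, methods = c("full", "unlinked"))
#' glance(fit)
#' }
#' @export
kin_lr <- function(data, ped1, ped2, markers, pop = pop_params(), obs = obs_params(),
                   methods = "full", m_prior = NULL, e_prior = NULL) {
  pp1 <- if (inherits(ped1, "kin_preprocess")) ped1 else preprocess_pedigree(ped1)
  pp2 <- if (inherits(ped2, "kin_preprocess")) ped2 else preprocess_pedigree(ped2)
  t1 <- pp1$ped$typed; t2 <- pp2$ped$typed
  if (!setequal(t1, t2)) stop("the two pedigrees must reference the same typed sample ids")
  rows <- purrr::map(methods, function(meth) {
    cache <- if (identical(t1, t2)) new.env(parent = emptyenv()) else NULL
    l1 <- pedigree_log10_likelihood(data, pp1, markers, pop, obs, meth,
                                    m_prior = m_prior, e_prior = e_prior, cache = cache)
    l2 <- pedigree_log10_likelihood(data, pp2, markers, pop, obs, meth,
                                    m_prior = m_prior, e_prior = e_prior, cache = cache)
    tibble::tibble(method = meth, log10_lik1 = as.numeric(l1), log10_lik2 = as.numeric(l2),
                   log10_lr = as.numeric(l1) - as.numeric(l2))
  })
  structure(
    list(result = dplyr::bind_rows(rows),
         typed = t1,
         params = list(pop = pop, obs = obs, m_prior = m_prior, e_prior = e_prior),
         n_markers = nrow(markers)),
    class = "kin_lr"
  )
}

#' @export
print.kin_lr <- function(x, ...) {
  cat(sprintf("<kin_lr> %d markers, typed: %s\n", x$n_markers, paste(x$typed, collapse = ", ")))
  print(x$result)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a likelihood-ratio result
#'
#' @param x A `kin_lr` object.
#' @param ... Unused.
#' @return One row per (hypothesis, method) with the log10 likelihood.
#' @method tidy kin_lr
#' @export
tidy.kin_lr <- function(x, ...) {
  tidyr::pivot_longer(x$result, c("log10_lik1", "log10_lik2"),
                      names_to = "hypothesis", values_to = "log10_likelihood") |>
    dplyr::mutate(hypothesis = ifelse(.data$hypothesis == "log10_lik1", "ped1", "ped2")) |>
    dplyr::select("method", "hypothesis", "log10_likelihood")
}

#' @rdname tidy.kin_lr
#' @method glance kin_lr
#' @export
glance.kin_lr <- function(x, ...) {
  dplyr::select(x$result, "method", "log10_lr")
}
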