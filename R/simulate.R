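# Simulation of complete synthetic cases: founder alleles from the
# population model, gene dropping through the pedigree with linkage
# (inheritance bits form a Markov chain along each chromosome), allelic
# depths from a discretized Gamma law, and read counts from the
# observational model. All draws use R's global RNG stream, so a single
# set.seed() makes a whole case or study reproducible.

#' Drop founder alleles through a pedigree with linkage
#'
#' Draws, for every meiosis (including pruned ones: simulation needs real
#' transmissions), a chain of inheritance bits along the panel: the bit at
#' the first locus is uniform, and each subsequent bit flips with the
#' inter-locus recombination fraction, independently across meioses.
#' Founder alleles are then propagated by descent.
#'
#' @param ped A `linkped` object.
#' @param founder_alleles `F x N` integer matrix of founder-allele
#'   nucleotides (rows ordered founder-major: maternal then paternal allele
#'   of each founder in pedigree order), `N` = number of loci.
#' @param pvec Recombination fractions between consecutive loci.
#' @return List of per-person `2 x N` genotype matrices (maternal row
#'   first), named by person id.
#' @export
gene_drop <- function(ped, founder_alleles, pvec) {
  ml <- meiosis_list(ped)
  N <- ncol(founder_alleles)
  stopifnot(length(pvec) == max(N - 1L, 0L),
            nrow(founder_alleles) == 2L * length(ped$founders))
  n_mei <- nrow(ml$entries)
  bits <- matrix(0L, n_mei, N)
  if (n_mei > 0L && N > 0L) {
    bits[, 1] <- stats::rbinom(n_mei, 1L, 0.5)
    for (i in seq_len(N - 1L)) {
      flip <- stats::rbinom(n_mei, 1L, pvec[i])
      bits[, i + 1L] <- bitwXor(bits[, i], flip)
    }
  }
  per <- ped$persons
  idx <- stats::setNames(seq_len(nrow(per)), per$id)
  mat <- vector("list", nrow(per)); pat <- vector("list", nrow(per))
  fi <- match(ped$founders, per$id)
  for (k in seq_along(fi)) {
    mat[[fi[k]]] <- founder_alleles[2L * k - 1L, ]
    pat[[fi[k]]] <- founder_alleles[2L * k, ]
  }
  ent <- ml$entries
  for (j in seq_len(nrow(ent))) {
    ci <- idx[[ent$child[j]]]; pi <- idx[[ent$parent[j]]]
    b <- bits[j, ]
    transmitted <- ifelse(b == 0L, mat[[pi]], pat[[pi]])
    if (ent$side[j] == "father") pat[[ci]] <- transmitted else mat[[ci]] <- transmitted
  }
  out <- lapply(seq_len(nrow(per)), function(i) rbind(maternal = mat[[i]], paternal = pat[[i]]))
  names(out) <- per$id
  out
}

# founder alleles for all founders at all loci: one exchangeable sequence
# per locus, vectorized across loci
draw_founder_alleles <- function(n_founders, fmat, pop) {
  Fn <- 2L * n_founders
  N <- nrow(fmat)
  fp <- fmat * (1 - pop$gamma) + matrix(pop$fbar * pop$gamma, N, 4, byrow = TRUE)
  th <- pop$theta
  out <- matrix(0L, Fn, N)
  counts <- matrix(0, N, 4)
  for (j in seq_len(Fn)) {
    pr <- (th * counts + (1 - th) * fp) / (1 + th * (j - 2))
    u <- stats::runif(N) * rowSums(pr)
    cum <- pr[, 1]
    a <- rep(1L, N)
    for (i in 2:4) {
      a[u > cum] <- i
      cum <- cum + pr[, i]
    }
    out[j, ] <- a
    counts[cbind(seq_len(N), a)] <- counts[cbind(seq_len(N), a)] + 1
  }
  out
}

#' Allelic-depth model
#'
#' Depths are drawn per person and locus from a Gamma distribution with
#' the given mean and standard deviation (shape `mu^2/sd^2`, scale
#' `sd^2/mu`), rounded to the nearest integer with floor 0. Zero-depth
#' loci stay in the panel as uninformative observations.
#'
#' @param n Number of draws.
#' @param mean,sd Mean and standard deviation of the underlying Gamma.
#' @return Integer vector of depths.
#' @export
draw_depths <- function(n, mean = 10, sd = 2) {
  stopifnot(mean > 0, sd > 0)
  pmax(0L, as.integer(round(stats::rgamma(n, shape = mean^2 / sd^2, scale = sd^2 / mean))))
}

#' Simulate a complete lcNGS case
#'
#' Full generative pipeline: founder alleles from the population model,
#' gene dropping with linkage, Gamma-distributed allelic depths, and read
#' counts from the observational model, for every typed person.
#'
#' @param ped True pedigree (a `linkped`).
#' @param markers Marker tibble.
#' @param depth_mean,depth_sd Parameters of the depth model.
#' @param pop,obs Model parameter sets.
#' @return List with `data` (a `kin_data` in counts mode for the typed
#'   persons), `genotypes` (true `2 x N` genotype matrices per typed
#'   person) and `depths`.
#' @export
simulate_case <- function(ped, markers, depth_mean = 10, depth_sd = 2,
                          pop = pop_params(), obs = obs_params()) {
  fmat <- as.matrix(markers[, c("fA", "fC", "fG", "fT")])
  N <- nrow(fmat)
  founders <- draw_founder_alleles(length(ped$founders), fmat, pop)
  genos <- gene_drop(ped, founders, recombination_fractions(markers))
  counts <- list(); depths <- list()
  for (s in ped$typed) {
    d <- draw_depths(N, depth_mean, depth_sd)
    g <- genos[[s]]
    cm <- matrix(0L, N, 4, dimnames = list(markers$marker, c("A", "C", "G", "T")))
    for (i in which(d > 0L)) cm[i, ] <- simulate_reads(g[, i], d[i], obs)
    counts[[s]] <- cm
    depths[[s]] <- d
  }
  list(data = kin_data(counts, markers, "counts"),
       genotypes = genos[ped$typed], depths = depths)
}

#' Simulated method-comparison study
#'
#' Simulates `n_cases` cases under the related pedigree and `n_cases`
#' under unrelatedness (typed persons as mutually unrelated founders, same
#' locus-level theta coupling), and computes the log10 likelihood ratio in
#' favour of relatedness for each case with each requested method.
#'
#' @param ped_related Related-hypothesis pedigree (a `linkped`).
#' @param markers Marker tibble (see [synth_marker_panel()]).
#' @param n_cases Cases per hypothesis.
#' @param depth_mean,depth_sd Depth model parameters.
#' @param pop,obs Model parameters used both to simulate and to analyse.
#' @param methods Methods to evaluate (see [kin_lr()]).
#' @param analysis_pop Optional `kin_pop` used for analysis when it should
#'   differ from the simulation values (e.g. gamma robustness checks).
#' @param seed Integer seed for reproducibility.
#' @return A tibble of class `kin_study`: columns `case`, `related`
#'   (logical truth), `method`, `log10_lr`.
#' @export
run_study <- function(ped_related, markers, n_cases = 100, depth_mean = 10,
                      depth_sd = 2, pop = pop_params(), obs = obs_params(),
                      methods = c("full", "unlinked", "called"),
                      analysis_pop = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(analysis_pop)) analysis_pop <- pop
  pp_rel <- preprocess_pedigree(ped_related)
  pp_unrel <- preprocess_pedigree(unrelated_pedigree(ped_related$typed))
  rows <- list()
  for (truth in c(TRUE, FALSE)) {
    true_ped <- if (truth) ped_related else pp_unrel$ped
    for (cs in seq_len(n_cases)) {
      case <- simulate_case(true_ped, markers, depth_mean, depth_sd, pop, obs)
      fit <- kin_lr(case$data, pp_rel, pp_unrel, markers, analysis_pop, obs,
                    methods = methods)
      rows[[length(rows) + 1L]] <- dplyr::mutate(
        fit$result[, c("method", "log10_lr")],
        case = cs, related = truth, .before = 1
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("kin_study", class(out))
  out
}

#' ROC points and area for a study
#'
#' Sweeps the log10 LR cutoff over the observed values and reports false
#' and true positive rates; `roc_auc()` is the area under that curve
#' (equal to the probability that a related case outranks an unrelated
#' one, ties counted half).
#'
#' @param study A `kin_study` tibble.
#' @return `roc_points()`: tibble `method`, `cutoff`, `fpr`, `tpr`.
#' @export
roc_points <- function(study) {
  dplyr::group_by(study, .data$method) |>
    dplyr::group_modify(function(df, key) {
      cuts <- c(Inf, sort(unique(df$log10_lr), decreasing = TRUE), -Inf)
      tibble::tibble(
        cutoff = cuts,
        fpr = vapply(cuts, function(ct) mean(df$log10_lr[!df$related] >= ct), numeric(1)),
        tpr = vapply(cuts, function(ct) mean(df$log10_lr[df$related] >= ct), numeric(1))
      )
    }) |>
    dplyr::ungroup()
}

#' @rdname roc_points
#' @return `roc_auc()`: tibble `method`, `auc`.
#' @export
roc_auc <- function(study) {
  dplyr::group_by(study, .data$method) |>
    dplyr::summarise(auc = {
      x <- .data$log10_lr[.data$related]
      y <- .data$log10_lr[!.data$related]
      r <- rank(c(x, y))
      (sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2) / (length(x) * length(y))
    }) |>
    dplyr::ungroup()
}

#' Classification rates at LR cutoffs
#'
#' For each cutoff, the proportion of related cases with log10 LR above it
#' and of unrelated cases below it.
#'
#' @param study A `kin_study` tibble.
#' @param cutoffs Numeric vector of log10 LR cutoffs.
#' @return Tibble `method`, `cutoff`, `related_above`, `unrelated_below`.
#' @export
classification_rates <- function(study, cutoffs = seq(-4, 8, by = 0.5)) {
  dplyr::group_by(study, .data$method) |>
    dplyr::group_modify(function(df, key) {
      tibble::tibble(
        cutoff = cutoffs,
        related_above = vapply(cutoffs, function(ct) mean(df$log10_lr[df$related] > ct), numeric(1)),
        unrelated_below = vapply(cutoffs, function(ct) mean(df$log10_lr[!df$related] < ct), numeric(1))
      )
    }) |>
    dplyr::ungroup()
}

#' Plot a study
#'
#' `autoplot()` draws the ROC curves of all methods; `plot_lr_distribution()`
#' shows the per-method LR distributions by true relationship.
#'
#' @param object A `kin_study` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot kin_study
#' @export
autoplot.kin_study <- function(object, ...) {
  pts <- roc_points(object)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$fpr, y = .data$tpr, colour = .data$method)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted", colour = "grey") +
    ggplot2::labs(x = "False positive rate", y = "True positive rate", colour = "Method") +
    ggplot2::coord_equal()
}

#' @rdname autoplot.kin_study
#' @param study A `kin_study` tibble.
#' @export
plot_lr_distribution <- function(study) {
  ggplot2::ggplot(study, ggplot2::aes(x = .data$log10_lr,
                                      fill = ifelse(.data$related, "related", "unrelated"))) +
    ggplot2::geom_histogram(alpha = 0.6, position = "identity", bins = 40) +
    ggplot2::facet_wrap(ggplot2::vars(.data$method)) +
    ggplot2::labs(x = "log10 LR in favour of relatedness", fill = "Truth")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
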