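test_that("recombination fractions follow the Haldane map with chromosome breaks", {
  mk <- validate_markers(tibble::tibble(
    marker = c("a", "b", "c", "d"), chrom = c(1, 1, 1, 2),
    pos_cM = c(0, 0, 10, 5),
    fA = 0.4, fC = 0.3, fG = 0.2, fT = 0.1
  ))
  p <- recombination_fractions(mk)
  expect_equal(p[1], 0)
  expect_equal(p[2], 0.5 * (1 - exp(-0.2)))
  expect_equal(p[3], 0.5)
})

test_that("compressed forward equals uncompressed forward and the literal sum", {
  set.seed(51)
  pop <- pop_params(0.01, 0.001)
  obs <- obs_params(4, 0.02)
  # three loci for the small pedigrees, two for the 2^7 and 2^8 ones
  for (nm in FIXTURE_NAMES) {
    ped <- fixture_ped(nm)
    N <- if (meiosis_list(ped)$K > 6) 2L else 3L
    mk <- toy_markers(N, spacing_cM = 15)
    kd <- random_counts_data(ped, mk, lambda = 1.2)
    fmat <- as.matrix(mk[, c("fA", "fC", "fG", "fT")])
    pvec <- recombination_fractions(mk)
    ll <- pedigree_log10_likelihood(kd, ped, mk, pop, obs, "full")
    unc <- oracle_forward(ped, kd$data, fmat, pvec, pop, obs)
    brt <- oracle_brute(ped, kd$data, fmat, pvec, pop, obs)
    expect_equal(ll, log10(unc), tolerance = 1e-10, label = paste(nm, "uncompressed"))
    expect_equal(ll, log10(brt), tolerance = 1e-10, label = paste(nm, "brute"))
  }
})

test_that("forward probabilities are constant within symmetry classes", {
  set.seed(52)
  pop <- pop_params(0.02, 0.001)
  obs <- obs_params(3, 0.02)
  for (nm in c("halfsibs", "uncle_nephew", "incest")) {
    ped <- fixture_ped(nm)
    cl <- symmetry_classes(ped)
    mk <- toy_markers(3, spacing_cM = 20)
    kd <- random_counts_data(ped, mk)
    z <- oracle_forward_z(ped, kd$data, as.matrix(mk[, c("fA", "fC", "fG", "fT")]),
                          recombination_fractions(mk), pop, obs)
    for (j in seq_len(cl$J)) {
      vals <- z[cl$class_of == j]
      expect_lt(diff(range(vals)) / max(vals), 1e-12, label = paste(nm, "class", j))
    }
  }
})

test_that("free recombination reduces the forward pass to the unlinked product", {
  set.seed(53)
  # 100 loci on 100 different chromosomes: all inter-locus fractions are 0.5
  mk <- validate_markers(tibble::tibble(
    marker = sprintf("m%03d", 1:100), chrom = 1:100, pos_cM = 0,
    fA = 0.35, fC = 0.3, fG = 0.25, fT = 0.1
  ))
  for (nm in c("halfsibs", "second_cousins")) {
    ped <- fixture_ped(nm)
    kd <- random_counts_data(ped, mk, lambda = 2)
    full <- pedigree_log10_likelihood(kd, ped, mk, method = "full")
    unl <- pedigree_log10_likelihood(kd, ped, mk, method = "unlinked")
    expect_equal(full, unl, tolerance = 1e-10, label = nm)
  }
})

test_that("a single locus needs no transition model", {
  set.seed(54)
  ped <- fixture_ped("uncle_nephew")
  mk <- toy_markers(1)
  kd <- random_counts_data(ped, mk)
  full <- pedigree_log10_likelihood(kd, ped, mk, method = "full")
  unl <- pedigree_log10_likelihood(kd, ped, mk, method = "unlinked")
  expect_equal(full, unl, tolerance = 1e-12)
  # and equals the code-probability-weighted locus likelihood
  d <- ibd_distribution(ped)
  pop <- pop_params(); obs <- obs_params()
  manual <- sum(vapply(seq_len(nrow(d)), function(i) {
    d$prob[i] * oracle_locus_L(d$labels[[i]],
                               lapply(kd$data, function(cm) cm[1, ]),
                               unname(as.matrix(mk[, c("fA", "fC", "fG", "fT")])[1, ]),
                               pop, obs)
  }, numeric(1)))
  expect_equal(full, log10(manual), tolerance = 1e-12)
})

test_that("long panels run in log space and split across chromosomes", {
  set.seed(55)
  mk <- synth_marker_panel(10000)
  ped <- fixture_ped("halfsibs")
  case <- simulate_case(ped, mk, depth_mean = 4, depth_sd = 1)
  ll <- pedigree_log10_likelihood(case$data, ped, mk, method = "full")
  expect_true(is.finite(ll))
  # chromosome-wise products must reproduce the whole-genome run exactly,
  # because chromosome boundaries have free recombination
  parts <- vapply(unique(mk$chrom), function(ch) {
    sel <- mk$chrom == ch
    sub_mk <- mk[sel, ]
    sub <- kin_data(lapply(case$data$data, function(cm) cm[sel, , drop = FALSE]),
                    sub_mk, "counts")
    pedigree_log10_likelihood(sub, ped, sub_mk, method = "full")
  }, numeric(1))
  expect_equal(ll, sum(parts), tolerance = 1e-9)
})

test_that("externally supplied genotype likelihoods reproduce the read-count result", {
  set.seed(56)
  ped <- fixture_ped("halfsibs")
  mk <- toy_markers(12, spacing_cM = 8)
  kd <- random_counts_data(ped, mk)
  obs <- obs_params()
  gl <- lapply(kd$data, function(cm) kinlink:::read_likelihood_matrix(cm, obs))
  kd_gl <- kin_data(gl, mk, "gl")
  for (meth in c("full", "unlinked")) {
    expect_equal(
      pedigree_log10_likelihood(kd_gl, ped, mk, method = meth),
      pedigree_log10_likelihood(kd, ped, mk, method = meth),
      tolerance = 1e-12, label = meth
    )
  }
})

test_that("likelihood is invariant to marker-table row order and person relabelling", {
  set.seed(57)
  ped <- fixture_ped("uncle_nephew")
  mk <- synth_marker_panel(40)
  kd <- random_counts_data(ped, mk)
  ll <- pedigree_log10_likelihood(kd, ped, mk, method = "full")
  # shuffled marker table: validate_markers restores the sorted order, so
  # the original row-aligned counts still apply
  shuf <- sample(nrow(mk))
  mk2 <- suppressWarnings(validate_markers(tibble::as_tibble(mk)[shuf, ]))
  expect_equal(mk2$marker, mk$marker)
  kd2 <- kin_data(kd$data, mk2, "counts")
  expect_equal(pedigree_log10_likelihood(kd2, ped, mk2, method = "full"), ll)
  # consistent renaming of persons and samples changes nothing
  ren <- relabel_persons(ped, c(UN = "p1", NE = "p2"))
  kd3 <- kin_data(stats::setNames(kd$data, c("p1", "p2")), mk, "counts")
  expect_equal(pedigree_log10_likelihood(kd3, ren, mk, method = "full"), ll)
})

test_that("likelihood ratios are trivial on degenerate comparisons", {
  set.seed(58)
  ped <- fixture_ped("halfsibs")
  un <- unrelated_pedigree(ped$typed)
  mk <- synth_marker_panel(30)
  kd <- random_counts_data(ped, mk)
  self <- kin_lr(kd, ped, ped, mk)
  expect_equal(self$result$log10_lr, 0)
  empty <- kin_data(lapply(kd$data, function(cm) matrix(0L, nrow(cm), 4)), mk, "counts")
  fit <- kin_lr(empty, ped, un, mk, methods = c("full", "unlinked"))
  expect_equal(fit$result$log10_lr, c(0, 0), tolerance = 1e-9)
  expect_equal(fit$result$log10_lik1, c(0, 0), tolerance = 1e-9)
  expect_error(kin_lr(kd, ped, unrelated_pedigree(c("x", "y")), mk), "same typed")
})

test_that("genotype calling discards heterozygote ambiguity the full method keeps", {
  # single locus, true heterozygote with all reads from one allele: the
  # called method commits to a homozygote; the full likelihood stays
  # between the two certain-genotype extremes
  mk <- toy_markers(1, freqs = matrix(c(0.5, 0.5, 0, 0), 1))
  ped <- fixture_ped("halfsibs")
  counts <- list(CH1 = matrix(c(6L, 0L, 0L, 0L), 1), CH2 = matrix(c(6L, 0L, 0L, 0L), 1))
  kd <- kin_data(counts, mk, "counts")
  obs <- obs_params(m = 2, e = 0.02)
  full <- pedigree_log10_likelihood(kd, ped, mk, obs = obs, method = "full")
  called <- pedigree_log10_likelihood(kd, ped, mk, obs = obs, method = "called")
  # certain AA genotypes for both persons
  gl_hom <- matrix(0, 1, 10); gl_hom[1, 1] <- 1
  kd_hom <- kin_data(list(CH1 = gl_hom, CH2 = gl_hom), mk, "gl")
  hom <- pedigree_log10_likelihood(kd_hom, ped, mk, method = "full")
  expect_equal(called, hom, tolerance = 1e-12)
  # the full method's per-locus probability exceeds the hom-only term
  # because it also integrates the drop-out explanation
  expect_gt(full, called)
})

test_that("parameter priors mix likelihoods on the natural scale", {
  set.seed(59)
  ped <- fixture_ped("halfsibs")
  mk <- toy_markers(6, spacing_cM = 12)
  kd <- random_counts_data(ped, mk)
  l1 <- pedigree_log10_likelihood(kd, ped, mk, obs = obs_params(2, 0.02))
  l2 <- pedigree_log10_likelihood(kd, ped, mk, obs = obs_params(10, 0.02))
  mix <- pedigree_log10_likelihood(kd, ped, mk,
                                   m_prior = c("2" = 0.3, "10" = 0.7),
                                   e_prior = c("0.02" = 1))
  expect_equal(10^mix, 0.3 * 10^l1 + 0.7 * 10^l2, tolerance = 1e-12)
  # point-mass prior equals the plain call
  pt <- pedigree_log10_likelihood(kd, ped, mk, obs = obs_params(2, 0.02),
                                  m_prior = c("2" = 1))
  expect_equal(pt, l1, tolerance = 1e-12)
})
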