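# Independent oracles: direct summations that avoid the symmetry
# compression, the vectorized per-locus engine and the forward recursion.

# per-locus IBD-code likelihood by explicit nested summation over founder
# assignments, using only the scalar model functions
oracle_locus_L <- function(labels, counts_list, f, pop, obs) {
  Fn <- max(labels) + 1L
  grid <- as.matrix(expand.grid(rep(list(1:4), Fn)))
  tot <- 0
  for (i in seq_len(nrow(grid))) {
    a <- grid[i, ]
    pr <- founder_assignment_prob(a, f, pop)
    for (t in seq_along(counts_list)) {
      g <- c(a[labels[2 * t - 1] + 1], a[labels[2 * t] + 1])
      pr <- pr * read_likelihood(counts_list[[t]], g, obs)
    }
    tot <- tot + pr
  }
  tot
}

# N x 2^K matrix of per-pattern locus likelihoods via the oracle
oracle_pattern_L <- function(ped, counts, fmat, pop, obs) {
  pc <- kinlink:::all_pattern_codes(ped)
  N <- nrow(fmat)
  Lmat <- matrix(0, N, 2^pc$K)
  for (i in seq_len(N)) {
    byc <- vapply(names(pc$code_list), function(k) {
      oracle_locus_L(pc$code_list[[k]],
                     lapply(counts, function(cm) cm[i, ]),
                     unname(fmat[i, ]), pop, obs)
    }, numeric(1))
    Lmat[i, ] <- byc[pc$codes]
  }
  Lmat
}

# uncompressed forward pass over all 2^K inheritance patterns with full
# transition matrices; returns the final per-pattern joint probabilities
oracle_forward_z <- function(ped, counts, fmat, pvec, pop, obs) {
  pc <- kinlink:::all_pattern_codes(ped)
  K <- pc$K; npat <- 2^K
  pcnt <- kinlink:::popcount_table(K)
  Lmat <- oracle_pattern_L(ped, counts, fmat, pop, obs)
  z <- rep(1 / npat, npat)
  for (i in seq_len(nrow(fmat))) {
    z <- z * Lmat[i, ]
    if (i < nrow(fmat)) {
      p <- pvec[i]
      d <- outer(0:(npat - 1), 0:(npat - 1), function(a, b) pcnt[bitwXor(a, b) + 1])
      Tm <- p^d * (1 - p)^(K - d)
      z <- as.numeric(t(Tm) %*% z)
    }
  }
  z
}

oracle_forward <- function(ped, counts, fmat, pvec, pop, obs) {
  sum(oracle_forward_z(ped, counts, fmat, pvec, pop, obs))
}

# literal sum over all tuples (r_1, ..., r_N)
oracle_brute <- function(ped, counts, fmat, pvec, pop, obs) {
  pc <- kinlink:::all_pattern_codes(ped)
  K <- pc$K; npat <- 2^K; N <- nrow(fmat)
  pcnt <- kinlink:::popcount_table(K)
  Lmat <- oracle_pattern_L(ped, counts, fmat, pop, obs)
  tuples <- as.matrix(expand.grid(rep(list(0:(npat - 1)), N)))
  tot <- 0
  for (row in seq_len(nrow(tuples))) {
    r <- tuples[row, ]
    pr <- 1 / npat
    for (i in seq_len(N)) {
      pr <- pr * Lmat[i, r[i] + 1]
      if (i < N) {
        d <- pcnt[bitwXor(r[i], r[i + 1]) + 1]
        pr <- pr * pvec[i]^d * (1 - pvec[i])^(K - d)
      }
    }
    tot <- tot + pr
  }
  tot
}

# exhaustive search over the whole hyperoctahedral group (all coordinate
# permutations x all flip masks); feasible for K <= 5
oracle_orbits_exhaustive <- function(ped) {
  pc <- kinlink:::all_pattern_codes(ped)
  K <- pc$K
  code_id <- match(pc$codes, names(pc$code_list))
  npat <- 2^K
  if (K == 0) return(list(n_orbits = 1L, orbit_of = 1L))
  B <- kinlink:::pattern_bits_matrix(K)
  perms <- as.matrix(expand.grid(rep(list(1:K), K)))
  perms <- perms[apply(perms, 1, function(p) !anyDuplicated(p)), , drop = FALSE]
  parent <- seq_len(npat)
  find_root <- function(i) {
    while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }
    i
  }
  for (pi in seq_len(nrow(perms))) {
    for (mask in 0:(npat - 1)) {
      flip <- kinlink:::bit_vector(mask, K)
      img <- kinlink:::apply_isometry_all(B, perms[pi, ], flip, K) + 1L
      if (all(code_id[img] == code_id)) {
        for (r in seq_len(npat)) {
          a <- find_root(r); b <- find_root(img[r])
          if (a != b) parent[b] <- a
        }
      }
    }
  }
  root <- vapply(seq_len(npat), find_root, integer(1))
  list(n_orbits = length(unique(root)), orbit_of = match(root, unique(root)))
}
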