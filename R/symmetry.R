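# Symmetry compression of the inheritance-pattern hypercube.
#
# The forward pass over linked loci works on the 2^K inheritance patterns.
# Any permutation g of the hypercube that (1) preserves the IBD-code map h
# and (2) preserves Hamming distances maps the forward probabilities onto
# themselves, so patterns in a common orbit always carry equal probability
# and one representative per orbit suffices. Every Hamming isometry of the
# K-cube is a coordinate permutation followed by coordinate flips (the
# hyperoctahedral group), so the search space is pairs (perm, flip mask).

# ---- low-level pattern helpers (patterns are integers 0 .. 2^K-1, -------
# ---- coordinate 1 is the most significant bit) ---------------------------

pattern_bits_matrix <- function(K) {
  npat <- 2L^K
  if (K == 0L) return(matrix(integer(0), nrow = 1L, ncol = 0L))
  vapply(1:K, function(j) bitwAnd(bitwShiftR(0:(npat - 1L), K - j), 1L), integer(npat))
}

popcount_table <- function(K) {
  if (K == 0L) return(0L)
  x <- 0:(2L^K - 1L)
  n <- integer(length(x))
  while (any(x > 0L)) {
    n <- n + bitwAnd(x, 1L)
    x <- bitwShiftR(x, 1L)
  }
  n
}

# apply isometry (perm, flip) to all patterns at once; returns image integers.
# Action on a pattern vector r: coordinate j of r is written to coordinate
# perm[j] of the image, then flipped if flip[perm[j]] == 1.
apply_isometry_all <- function(B, perm, flip, K) {
  npat <- nrow(B)
  img <- integer(npat)
  for (j in seq_len(K)) {
    bit <- bitwXor(B[, j], flip[perm[j]])
    img <- img + bit * 2L^(K - perm[j])
  }
  img
}

# ---- isometry search -----------------------------------------------------

#' IBD-preserving isometries of the inheritance-pattern hypercube
#'
#' Finds every map `g` of the `2^K` inheritance patterns that is a Hamming
#' isometry (a coordinate permutation composed with coordinate flips) and
#' satisfies `h(g(r)) = h(r)` for every pattern `r`, where `h` is the IBD
#' code map of the pedigree. The search assigns the permutation one
#' coordinate at a time and prunes a partial assignment as soon as the
#' multiset of IBD codes in some source slice of the cube differs from its
#' image slice; a surviving complete assignment is a verified isometry.
#'
#' @param ped A `linkped` object.
#' @param max_K Capacity guard on the number of retained meioses.
#' @return List with `isometries` (list of `list(perm, flip)`), `codes`
#'   (IBD-code id per pattern), `code_list`, `K`.
#' @export
ibd_isometries <- function(ped, max_K = 12L) {
  pc <- all_pattern_codes(ped)
  K <- pc$K
  if (K > max_K) stop("K = ", K, " exceeds max_K = ", max_K)
  code_id <- match(pc$codes, names(pc$code_list))
  iso <- find_isometries_codes(code_id, K)
  list(isometries = iso, codes = code_id, code_list = pc$code_list, K = K)
}

# core search given integer code ids per pattern
find_isometries_codes <- function(code_id, K) {
  if (K == 0L) return(list(list(perm = integer(0), flip = integer(0))))
  B <- pattern_bits_matrix(K)
  nc <- max(code_id)
  npat <- length(code_id)
  found <- list()

  recurse <- function(perm, flip, srckey, tgtkey, used, depth) {
    if (depth > K) {
      found[[length(found) + 1L]] <<- list(perm = perm, flip = flip)
      return(invisible())
    }
    w <- 2L^(depth - 1L)
    for (jp in which(!used)) {
      for (b in 0:1) {
        sk <- srckey + B[, depth] * w
        tk <- tgtkey + bitwXor(B[, jp], b) * w
        nb <- 2L^depth * nc
        if (identical(
          tabulate(sk * nc + code_id, nbins = nb),
          tabulate(tk * nc + code_id, nbins = nb)
        )) {
          perm2 <- perm; perm2[depth] <- jp
          flip2 <- flip; flip2[jp] <- b
          used2 <- used; used2[jp] <- TRUE
          recurse(perm2, flip2, sk, tk, used2, depth + 1L)
        }
      }
    }
    invisible()
  }
  recurse(integer(K), integer(K), integer(npat), integer(npat), logical(K), 1L)
  found
}

# ---- orbits --------------------------------------------------------------

#' Symmetry classes of inheritance patterns
#'
#' Partitions the `2^K` inheritance patterns into orbits of the full group
#' of IBD-preserving Hamming isometries (see [ibd_isometries()]). All
#' members of an orbit share one IBD code; computations over linked loci
#' need only one representative per orbit.
#'
#' @param ped A `linkped` object.
#' @param max_K Capacity guard on `K`.
#' @return An object of class `kin_classes`: list with `K`, `J`, `reps`
#'   (pattern integers, lexicographic minima), `rep_bits` (printed bit
#'   strings), `sizes`, `class_of` (class index per pattern), `codes`
#'   (integer label vector per class), `code_str`, and `n_isometries`.
#' @export
symmetry_classes <- function(ped, max_K = 12L) {
  found <- ibd_isometries(ped, max_K = max_K)
  K <- found$K
  npat <- 2L^K
  parent <- seq_len(npat)
  find_root <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (K > 0L) {
    B <- pattern_bits_matrix(K)
    for (g in found$isometries) {
      img <- apply_isometry_all(B, g$perm, g$flip, K) + 1L
      for (r in seq_len(npat)) {
        a <- find_root(r); b <- find_root(img[r])
        if (a != b) parent[b] <- a
      }
    }
  }
  root <- vapply(seq_len(npat), find_root, integer(1))
  # representative = lexicographically smallest pattern = smallest integer
  # (coordinate 1 is the most significant bit); classes ordered by repr.
  rep_of <- stats::ave(seq_len(npat) - 1L, root, FUN = min)
  reps <- sort(unique(rep_of))
  class_of <- match(rep_of, reps)
  sizes <- tabulate(class_of, nbins = length(reps))
  code_keys <- names(found$code_list)
  class_code_id <- found$codes[reps + 1L]
  structure(
    list(
      K = K,
      J = length(reps),
      reps = reps,
      rep_bits = vapply(reps, function(r) pattern_string(bit_vector(r, K)), character(1)),
      sizes = sizes,
      class_of = class_of,
      codes = unname(found$code_list[class_code_id]),
      code_str = code_keys[class_code_id],
      n_isometries = length(found$isometries)
    ),
    class = "kin_classes"
  )
}

#' @export
print.kin_classes <- function(x, ...) {
  cat(sprintf(
    "<kin_classes> K = %d meioses, %d patterns in J = %d classes (%d isometries)\n",
    x$K, 2L^x$K, x$J, x$n_isometries
  ))
  df <- tibble::tibble(
    class = seq_len(x$J), representative = x$rep_bits,
    size = x$sizes, ibd_code = x$code_str
  )
  print(df, n = min(nrow(df), 25L))
  invisible(x)
}

# ---- transition polynomials ----------------------------------------------

#' Integer coefficients of the compressed transition polynomials
#'
#' Entry `A[j, k, r + 1]` counts the members of class `k` at Hamming
#' distance `r` from the representative of class `j`. The compressed
#' transition probability from the representative of class `j` into class
#' `k` is the polynomial `sum_r A[j,k,r+1] p^r (1-p)^(K-r)` in the
#' inter-locus recombination fraction `p`; rows of the evaluated matrix sum
#' to one.
#'
#' @param classes A `kin_classes` object.
#' @return Integer array of dimension `J x J x (K + 1)`.
#' @export
transition_coefficients <- function(classes) {
  stopifnot(inherits(classes, "kin_classes"))
  K <- classes$K; J <- classes$J
  A <- array(0L, dim = c(J, J, K + 1L))
  if (K == 0L) {
    A[1, 1, 1] <- 1L
    return(A)
  }
  pc <- popcount_table(K)
  for (j in seq_len(J)) {
    d <- pc[bitwXor(0:(2L^K - 1L), classes$reps[j]) + 1L]
    # cross-tabulate class membership against distance from representative j
    A[j, , ] <- as.integer(table(
      factor(classes$class_of, levels = seq_len(J)),
      factor(d, levels = 0:K)
    ))
  }
  A
}

#' Evaluate the compressed transition matrix at a recombination fraction
#'
#' @param A Coefficient tensor from [transition_coefficients()].
#' @param p Recombination fraction in `[0, 0.5]` (0.5 across chromosome
#'   boundaries or at infinite genetic distance).
#' @return A `J x J` row-stochastic matrix `M*`; the compressed forward
#'   update is `z <- M* %*% z`.
#' @export
evaluate_transition_matrix <- function(A, p) {
  stopifnot(is.numeric(p), length(p) == 1L, p >= 0, p <= 1)
  K <- dim(A)[3] - 1L
  w <- p^(0:K) * (1 - p)^(K - (0:K))
  J <- dim(A)[1]
  M <- matrix(0, J, J)
  for (r in 0:K) M <- M + A[, , r + 1L] * w[r + 1L]
  M
}

# ---- preprocessing driver ------------------------------------------------

#' Preprocess a pedigree for linked-locus likelihood computations
#'
#' Runs the complete pedigree preprocessing: meiosis-list construction and
#' pruning, IBD-code enumeration, symmetry subdivision of the `2^K`
#' inheritance patterns, and the integer coefficient tensor of the
#' compressed transition polynomials. The result contains everything the
#' likelihood engine needs and can be serialized with [write_preprocess()].
#'
#' @param ped A `linkped` object.
#' @param max_K Capacity guard on the number of retained meioses.
#' @return An object of class `kin_preprocess`: list with `ped`, `K`, `J`,
#'   `classes` (a `kin_classes`), `A` (transition coefficient tensor), and
#'   `code_prob` (prior probability of each class's IBD code, summed over
#'   the classes sharing it).
#' @examples
#' ped <- read_pedigree(system.file("extdata", "ped_halfsibs.ped", package = "kinlink"))
#' pp <- preprocess_pedigree(ped)
#' pp
#' @export
preprocess_pedigree <- function(ped, max_K = 12L) {
  stopifnot(inherits(ped, "linkped"))
  classes <- symmetry_classes(ped, max_K = max_K)
  structure(
    list(
      ped = ped,
      K = classes$K,
      J = classes$J,
      classes = classes,
      A = transition_coefficients(classes),
      class_prior = classes$sizes / 2^classes$K
    ),
    class = "kin_preprocess"
  )
}

#' @export
print.kin_preprocess <- function(x, ...) {
  cat(sprintf(
    "<kin_preprocess> %d typed persons, K = %d, J = %d classes, %d distinct IBD codes\n",
    length(x$ped$typed), x$K, x$J, length(unique(x$classes$code_str))
  ))
  invisible(x)
}

#' Serialize / restore a preprocessing result
#'
#' Writes the symmetry subdivision and transition coefficients to JSON so
#' repeated likelihood runs on the same pedigree can skip preprocessing.
#'
#' @param pp A `kin_preprocess` object.
#' @param path Output (input) file path.
#' @return `read_preprocess()` returns a `kin_preprocess` (without the
#'   original `ped`, which is stored as its person table).
#' @export
write_preprocess <- function(pp, path) {
  stopifnot(inherits(pp, "kin_preprocess"))
  obj <- list(
    persons = pp$ped$persons,
    K = pp$K,
    J = pp$J,
    class_sizes = pp$classes$sizes,
    representatives = pp$classes$rep_bits,
    ibd_codes = pp$classes$codes,
    code_probabilities = pp$class_prior,
    A_tensor = pp$A
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_preprocess
#' @export
read_preprocess <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  ped <- pedigree(obj$persons)
  K <- as.integer(obj$K); J <- as.integer(obj$J)
  codes <- obj$ibd_codes
  if (is.matrix(codes)) codes <- lapply(seq_len(nrow(codes)), function(i) as.integer(codes[i, ]))
  A <- array(as.integer(obj$A_tensor), dim = c(J, J, K + 1L))
  classes <- structure(
    list(
      K = K, J = J,
      reps = strtoi(gsub("[()]", "", obj$representatives), base = 2L),
      rep_bits = obj$representatives,
      sizes = as.integer(obj$class_sizes),
      class_of = NULL,
      codes = codes,
      code_str = vapply(codes, format_ibd_code, character(1)),
      n_isometries = NA_integer_
    ),
    class = "kin_classes"
  )
  if (K == 0L) classes$reps <- 0L
  structure(
    list(ped = ped, K = K, J = J, classes = classes, A = A,
         class_prior = as.numeric(obj$code_probabilities)),
    class = "kin_preprocess"
  )
}
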