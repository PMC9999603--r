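#' Construct a pedigree of tested and untested persons
#'
#' A pedigree is an ordered list of persons, each either a founder (both
#' parents unknown) or a non-founder (both parents in the pedigree). The
#' order of the rows is meaningful: it is the fixed person ordering used to
#' canonicalize IBD codes, and the order of the typed persons is the order
#' in which their allele pairs appear in every IBD code.
#'
#' A person listed with exactly one known parent is completed by inserting a
#' new untyped founder as the missing parent (one per such person, named
#' `<id>/f` or `<id>/m`), so that sketches of pedigrees can be written
#' tersely. Two children sharing only one named parent are therefore
#' half-siblings unless the second parent is named explicitly.
#'
#' @param df Data frame with columns `id`, `father`, `mother`, `typed`.
#'   Unknown parents are written `"0"`, `NA` or `""`. `typed` is logical or
#'   0/1.
#' @return An object of class `linkped`: a list with elements `persons`
#'   (a tibble in pedigree order), `typed` (character vector of typed ids in
#'   order) and `founders` (character vector).
#' @examples
#' ped <- pedigree(data.frame(
#'   id = c("M", "C1", "C2"), father = c("0", "0", "0"),
#'   mother = c("0", "M", "M"), typed = c(0, 1, 1)
#' ))
#' ped
#' @export
pedigree <- function(df) {
  stopifnot(is.data.frame(df), all(c("id", "father", "mother", "typed") %in% names(df)))
  per <- tibble::tibble(
    id = as.character(df$id),
    father = as.character(df$father),
    mother = as.character(df$mother),
    typed = parse_typed(df$typed)
  )
  per$father[is.na(per$father) | per$father %in% c("0", "")] <- NA_character_
  per$mother[is.na(per$mother) | per$mother %in% c("0", "")] <- NA_character_
  if (anyDuplicated(per$id)) {
    stop("duplicated person id(s): ", paste(unique(per$id[duplicated(per$id)]), collapse = ", "))
  }
  # auto-complete single-parent entries with a fresh untyped founder spouse
  add <- list()
  for (i in seq_len(nrow(per))) {
    fa <- per$father[i]; mo <- per$mother[i]
    if (is.na(fa) && !is.na(mo)) {
      fa <- paste0(per$id[i], "/f")
      per$father[i] <- fa
      add[[length(add) + 1L]] <- fa
    } else if (!is.na(fa) && is.na(mo)) {
      mo <- paste0(per$id[i], "/m")
      per$mother[i] <- mo
      add[[length(add) + 1L]] <- mo
    }
  }
  if (length(add)) {
    per <- dplyr::bind_rows(
      tibble::tibble(id = unlist(add), father = NA_character_, mother = NA_character_, typed = FALSE),
      per
    )
  }
  miss <- setdiff(stats::na.omit(c(per$father, per$mother)), per$id)
  if (length(miss)) stop("parent id(s) not in pedigree: ", paste(miss, collapse = ", "))
  if (!any(per$typed)) stop("pedigree has no typed person")
  idx <- stats::setNames(seq_len(nrow(per)), per$id)
  # acyclicity: every person must reach founders by parent links
  depth <- rep(NA_integer_, nrow(per))
  get_depth <- function(i, seen) {
    if (!is.na(depth[i])) return(depth[i])
    if (seen[i]) stop("pedigree contains a parent cycle involving ", per$id[i])
    seen[i] <- TRUE
    fa <- per$father[i]
    d <- if (is.na(fa)) 0L else {
      1L + max(get_depth(idx[[fa]], seen), get_depth(idx[[per$mother[i]]], seen))
    }
    depth[i] <<- d
    d
  }
  for (i in seq_len(nrow(per))) get_depth(i, rep(FALSE, nrow(per)))
  structure(
    list(
      persons = per,
      typed = per$id[per$typed],
      founders = per$id[is.na(per$father)]
    ),
    class = "linkped"
  )
}

parse_typed <- function(x) {
  if (is.logical(x)) return(x)
  x <- trimws(as.character(x))
  out <- x %in% c("1", "TRUE", "true", "T")
  bad <- !x %in% c("0", "1", "TRUE", "FALSE", "true", "false", "T", "F")
  if (any(bad)) stop("typed flag must be 0/1: got ", paste(unique(x[bad]), collapse = ", "))
  out
}

#' Read a pedigree from a FAM-like text file
#'
#' One person per line, whitespace separated: `id father mother typed`,
#' with `0` for an unknown parent and `typed` 0/1. Line order defines the
#' fixed person ordering (see [pedigree()]). Lines starting with `#` are
#' ignored.
#'
#' @param path Path to the pedigree file.
#' @return A `linkped` object.
#' @export
read_pedigree <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop("empty pedigree file: ", path)
  parts <- strsplit(lines, "[[:space:]]+")
  bad <- which(lengths(parts) != 4L)
  if (length(bad)) stop("malformed pedigree line(s): ", paste(bad, collapse = ", "))
  m <- do.call(rbind, parts)
  pedigree(data.frame(
    id = m[, 1], father = m[, 2], mother = m[, 3], typed = m[, 4],
    stringsAsFactors = FALSE
  ))
}

#' Relabel persons in a pedigree
#'
#' Renames person ids (e.g. to match the sample ids carried by the data)
#' without changing structure or ordering.
#'
#' @param ped A `linkped` object.
#' @param mapping Named character vector: `c(old_id = "new_id", ...)`.
#' @return A `linkped` with ids replaced.
#' @export
relabel_persons <- function(ped, mapping) {
  stopifnot(inherits(ped, "linkped"), length(names(mapping)) == length(mapping))
  sub <- function(x) ifelse(x %in% names(mapping), unname(mapping[x]), x)
  per <- ped$persons
  per$id <- sub(per$id)
  per$father <- ifelse(is.na(per$father), NA, sub(per$father))
  per$mother <- ifelse(is.na(per$mother), NA, sub(per$mother))
  pedigree(per)
}

#' Pedigree of unrelated typed persons
#'
#' Each person is a typed founder; no meioses, a single empty inheritance
#' pattern, and an all-distinct IBD code.
#'
#' @param ids Character vector of person ids.
#' @return A `linkped` object.
#' @export
unrelated_pedigree <- function(ids) {
  pedigree(data.frame(id = ids, father = "0", mother = "0", typed = 1))
}

#' @export
print.linkped <- function(x, ...) {
  ml <- meiosis_list(x)
  cat(sprintf(
    "<linkped> %d persons (%d founders), %d typed: %s\n",
    nrow(x$persons), length(x$founders), length(x$typed),
    paste(x$typed, collapse = ", ")
  ))
  cat(sprintf("  %d meioses retained after pruning (K = %d)\n", ml$K, ml$K))
  invisible(x)
}

#' Ordered meiosis list of a pedigree
#'
#' Lists the parent-child transmissions whose grand-maternal/grand-paternal
#' outcome can affect which alleles are identical by descent among typed
#' persons. One bit per retained meiosis gives the inheritance pattern; the
#' list length is `K`, so there are `2^K` inheritance patterns.
#'
#' A meiosis `(child, parent)` is pruned when the parent is an untyped
#' founder with a single child: whichever of that parent's two alleles is
#' transmitted, the allele is unique to the child's lineage, so the bit
#' cannot change any IBD relation among typed persons. The retained meioses
#' are ordered depth-first over persons in pedigree order, with each
#' person's father-side meiosis before the mother-side one.
#'
#' @param ped A `linkped` object.
#' @return A list with `entries` (tibble `child`, `parent`, `side`,
#'   `pruned`), covering all meioses with a `pruned` flag, and `K`, the
#'   number of retained meioses.
#' @export
meiosis_list <- function(ped) {
  stopifnot(inherits(ped, "linkped"))
  per <- ped$persons
  idx <- stats::setNames(seq_len(nrow(per)), per$id)
  n_children <- table(factor(c(per$father, per$mother), levels = per$id))
  is_founder <- is.na(per$father)
  prune_parent <- is_founder & !per$typed & as.integer(n_children) == 1L
  names(prune_parent) <- per$id

  child <- character(0); parent <- character(0); side <- character(0)
  visited <- rep(FALSE, nrow(per))
  visit <- function(i) {
    if (visited[i]) return(invisible())
    visited[i] <<- TRUE
    fa <- per$father[i]
    if (!is.na(fa)) {
      visit(idx[[fa]]); visit(idx[[per$mother[i]]])
      child <<- c(child, per$id[i], per$id[i])
      parent <<- c(parent, fa, per$mother[i])
      side <<- c(side, "father", "mother")
    }
    invisible()
  }
  for (i in seq_len(nrow(per))) visit(i)
  pruned <- if (length(parent)) unname(prune_parent[parent]) else logical(0)
  list(
    entries = tibble::tibble(child = child, parent = parent, side = side, pruned = pruned),
    K = sum(!pruned)
  )
}

#' Founder-allele descent of the typed allele slots under one inheritance
#' pattern
#'
#' Each typed person contributes two allele slots (maternal then paternal).
#' Given a bit per retained meiosis (0 = the child received the parent's
#' maternal allele, 1 = the paternal one), every slot descends from a unique
#' founder allele; slots are identical by descent exactly when they descend
#' from the same founder allele. Pruned meioses are resolved with a fixed
#' default bit; the induced partition of typed slots does not depend on that
#' default.
#'
#' @param ped A `linkped` object.
#' @param pattern Integer 0/1 vector of length `K` (see [meiosis_list()]).
#' @param default_bit Bit used for pruned meioses (0 or 1).
#' @return Integer vector of length `2T`: founder-allele id per typed slot,
#'   person-major, maternal slot first.
#' @export
allele_descent <- function(ped, pattern, default_bit = 0L) {
  ml <- meiosis_list(ped)
  if (length(pattern) != ml$K) stop("pattern length ", length(pattern), " != K = ", ml$K)
  descent_from_bits(ped, ml, fill_bits(ml, pattern, default_bit))
}

# expand a length-K pattern to bits for every meiosis (pruned ones get `default`)
fill_bits <- function(ml, pattern, default = 0L) {
  bits <- rep(as.integer(default), nrow(ml$entries))
  bits[!ml$entries$pruned] <- as.integer(pattern)
  bits
}

# resolve founder-allele ids of all typed slots given bits for all meioses
descent_from_bits <- function(ped, ml, bits) {
  per <- ped$persons
  idx <- stats::setNames(seq_len(nrow(per)), per$id)
  mat <- rep(NA_integer_, nrow(per))  # founder-allele id of maternal slot
  pat <- rep(NA_integer_, nrow(per))
  fnd <- which(is.na(per$father))
  mat[fnd] <- seq_along(fnd) * 2L - 1L
  pat[fnd] <- seq_along(fnd) * 2L
  ent <- ml$entries
  for (j in seq_len(nrow(ent))) {
    ci <- idx[[ent$child[j]]]; pi <- idx[[ent$parent[j]]]
    transmitted <- if (bits[j] == 0L) mat[pi] else pat[pi]
    if (ent$side[j] == "father") pat[ci] <- transmitted else mat[ci] <- transmitted
  }
  ti <- idx[ped$typed]
  out <- integer(2L * length(ti))
  out[seq_along(ti) * 2L - 1L] <- mat[ti]
  out[seq_along(ti) * 2L] <- pat[ti]
  out
}

#' Canonical IBD code of a typed-slot partition
#'
#' Encodes which of the `2T` typed allele slots (maternal, paternal per
#' typed person, persons in pedigree order) are identical by descent, as a
#' vector of subset labels. Labels are consecutive integers from 0. Between
#' two subsets, the one appearing alone in the earliest person that contains
#' exactly one of them gets the smaller label (ties, which can only arise
#' when two subsets occur in exactly the same persons, are broken by first
#' slot index); finally the two labels within each person's pair are swapped
#' if needed so the first is not larger.
#'
#' @param slots Integer vector of length `2T`: any labelling of the slots in
#'   which equal values mean identical by descent (e.g. [allele_descent()]).
#' @return Integer vector of length `2T`, the canonical IBD code.
#' @export
ibd_code <- function(slots) {
  n <- length(slots)
  stopifnot(n >= 2L, n %% 2L == 0L)
  subs <- match(slots, unique(slots))      # subsets numbered by first slot occurrence
  nsub <- max(subs)
  np <- n %/% 2L
  person <- rep(seq_len(np), each = 2L)
  # occurrence matrix: subset x person
  occ <- matrix(FALSE, nsub, np)
  occ[cbind(subs, person)] <- TRUE
  # rank subsets: lexicographically by occurrence vector (presence earlier is
  # smaller), tie-broken by first slot index
  first_slot <- match(seq_len(nsub), subs)
  key <- apply(occ, 1L, function(z) paste(ifelse(z, "0", "1"), collapse = ""))
  rank <- order(key, first_slot)
  lab <- integer(nsub); lab[rank] <- seq_len(nsub) - 1L
  code <- lab[subs]
  for (p in seq_len(np)) {
    i <- 2L * p - 1L
    if (code[i] > code[i + 1L]) code[c(i, i + 1L)] <- code[c(i + 1L, i)]
  }
  code
}

format_ibd_code <- function(code) paste0("(", paste(code, collapse = ", "), ")")

# IBD code (as integer vector) for every inheritance pattern 0..2^K-1.
# Returns list(codes = character vector indexed by pattern+1, code_list =
# named list of unique codes).
all_pattern_codes <- function(ped, default_bit = 0L) {
  ml <- meiosis_list(ped)
  K <- ml$K
  if (K > 16L) stop("K = ", K, " exceeds the enumeration guard (16)")
  npat <- 2L^K
  codes <- character(npat)
  code_list <- list()
  for (r in 0:(npat - 1L)) {
    pattern <- bit_vector(r, K)
    code <- ibd_code(descent_from_bits(ped, ml, fill_bits(ml, pattern, default_bit)))
    key <- format_ibd_code(code)
    codes[r + 1L] <- key
    if (is.null(code_list[[key]])) code_list[[key]] <- code
  }
  list(codes = codes, code_list = code_list, K = K)
}

# integer -> 0/1 vector of length K, bit 1 = most significant (leftmost)
bit_vector <- function(x, K) {
  if (K == 0L) return(integer(0))
  as.integer(bitwAnd(bitwShiftR(x, (K - 1L):0), 1L))
}

pattern_string <- function(bits) paste0("(", paste(bits, collapse = ""), ")")

#' Exact IBD-code distribution of a pedigree
#'
#' Enumerates all `2^K` inheritance patterns with equal probability and
#' tallies the induced IBD codes. Probabilities are exact dyadic rationals
#' (`count / 2^K`), hence represented exactly in double precision.
#'
#' @param ped A `linkped` object.
#' @return A tibble with columns `code` (printed form), `labels`
#'   (list-column of integer label vectors) and `prob`, sorted by
#'   decreasing probability then code.
#' @examples
#' ped <- read_pedigree(system.file("extdata", "ped_halfsibs.ped", package = "kinlink"))
#' ibd_distribution(ped)
#' @export
ibd_distribution <- function(ped) {
  pc <- all_pattern_codes(ped)
  tab <- table(pc$codes)
  keys <- names(tab)
  out <- tibble::tibble(
    code = keys,
    labels = unname(pc$code_list[keys]),
    prob = as.numeric(tab) / 2^pc$K
  )
  dplyr::arrange(out, dplyr::desc(.data$prob), .data$code)
}
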