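# Marker panel handling. A panel is a tibble with one row per SNP:
# marker id, chromosome, genetic map position in centiMorgans, and the four
# nucleotide frequencies fA, fC, fG, fT. Physical coordinates are never
# used; linkage enters only through cM distances.

MARKER_COLS <- c("marker", "chrom", "pos_cM", "fA", "fC", "fG", "fT")

#' Read and validate a marker definition table
#'
#' Tab-separated table with header columns `marker chrom pos_cM fA fC fG fT`.
#' Rows are sorted by (chromosome, position); a warning is issued if the
#' input was unsorted. Frequency vectors off the simplex by at most `1e-6`
#' are renormalized; larger violations are rejected with their line number.
#'
#' @param path Path to the TSV file.
#' @return A tibble of markers (class `kin_markers`).
#' @export
read_marker_table <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(MARKER_COLS, names(df))
  if (length(missing)) stop("marker table lacks column(s): ", paste(missing, collapse = ", "))
  validate_markers(df[MARKER_COLS])
}

#' @rdname read_marker_table
#' @param df A data frame with the marker table columns.
#' @export
validate_markers <- function(df) {
  df <- tibble::as_tibble(df)
  fs <- as.matrix(df[, c("fA", "fC", "fG", "fT")])
  if (any(fs < 0)) stop("negative allele frequency at line(s): ",
                        paste(which(apply(fs < 0, 1, any)), collapse = ", "))
  dev <- abs(rowSums(fs) - 1)
  bad <- which(dev > 1e-6)
  if (length(bad)) stop("allele frequencies do not sum to 1 at line(s): ",
                        paste(bad, collapse = ", "))
  fs <- fs / rowSums(fs)
  df[, c("fA", "fC", "fG", "fT")] <- fs
  if (anyDuplicated(df$marker)) stop("duplicated marker id(s)")
  ord <- order(df$chrom, df$pos_cM)
  if (!identical(ord, seq_len(nrow(df)))) {
    warning("marker table was not sorted by (chrom, pos_cM); sorting")
    df <- df[ord, ]
  }
  class(df) <- c("kin_markers", class(df))
  df
}

#' Write a marker table
#'
#' @param markers A marker tibble.
#' @param path Output TSV path.
#' @export
write_marker_table <- function(markers, path) {
  readr::write_tsv(tibble::as_tibble(markers)[MARKER_COLS], path, progress = FALSE)
  invisible(path)
}

#' Inter-locus recombination fractions from genetic positions
#'
#' Haldane map function for a Poisson crossover model:
#' `p = (1 - exp(-2 d)) / 2` with `d` the inter-marker distance in Morgans.
#' Across chromosome boundaries the fraction is 0.5 (free recombination);
#' markers at identical positions get 0.
#'
#' @param markers Marker tibble sorted by (chrom, pos_cM).
#' @return Numeric vector of length `nrow(markers) - 1`.
#' @export
recombination_fractions <- function(markers) {
  n <- nrow(markers)
  if (n < 2L) return(numeric(0))
  if (!identical(order(markers$chrom, markers$pos_cM), seq_len(n))) stop("markers must be sorted")
  d_morgan <- diff(markers$pos_cM) / 100
  same_chr <- markers$chrom[-1] == markers$chrom[-n]
  if (any(d_morgan[same_chr] < 0)) stop("positions decrease within a chromosome")
  p <- (1 - exp(-2 * d_morgan)) / 2
  p[!same_chr] <- 0.5
  p
}

# sex-averaged genetic lengths (cM) of the 22 autosomes, approximately a
# 35-Morgan genome
CHROM_CM <- c(278, 263, 224, 214, 209, 194, 187, 169, 167, 174, 161,
              176, 131, 125, 132, 134, 129, 124, 110, 108, 62, 72)

#' Generate a synthetic SNP panel
#'
#' Draws marker positions uniformly over 22 autosomes with genetic lengths
#' matching a standard ~35 Morgan autosomal map, in proportion to
#' chromosome length. Each SNP is biallelic over two distinct random
#' nucleotides with minor-allele frequency uniform on (0.3, 0.5), emulating
#' forensic kinship panels, which select SNPs for high minor-allele
#' frequency across populations to maximize informativeness.
#'
#' @param n_markers Number of SNPs (the full reference panel scale is 3929).
#' @return A `kin_markers` tibble. Uses the global RNG stream.
#' @export
synth_marker_panel <- function(n_markers = 3929) {
  stopifnot(n_markers >= 22L)
  n_chr <- pmax(1L, as.integer(stats::rmultinom(1, n_markers, CHROM_CM / sum(CHROM_CM))))
  # rounding pmax may overshoot by a few markers; trim deterministically
  while (sum(n_chr) > n_markers) n_chr[which.max(n_chr)] <- n_chr[which.max(n_chr)] - 1L
  rows <- list()
  for (ch in seq_along(CHROM_CM)) {
    pos <- sort(stats::runif(n_chr[ch], 0, CHROM_CM[ch]))
    rows[[ch]] <- tibble::tibble(chrom = ch, pos_cM = pos)
  }
  df <- dplyr::bind_rows(rows)
  n <- nrow(df)
  pair <- t(vapply(seq_len(n), function(i) sample.int(4L, 2L), integer(2)))
  maf <- stats::runif(n, 0.3, 0.5)
  p1 <- ifelse(stats::runif(n) < 0.5, maf, 1 - maf)
  fs <- matrix(0, n, 4)
  fs[cbind(seq_len(n), pair[, 1])] <- p1
  fs[cbind(seq_len(n), pair[, 2])] <- 1 - p1
  out <- tibble::tibble(
    marker = sprintf("snp%05d", seq_len(n)),
    chrom = df$chrom, pos_cM = df$pos_cM,
    fA = fs[, 1], fC = fs[, 2], fG = fs[, 3], fT = fs[, 4]
  )
  validate_markers(out)
}
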