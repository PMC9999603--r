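# Per-sample per-marker observations. The engine accepts two
# representations: raw A/C/G/T read counts (an N x 4 matrix per sample), or
# externally supplied genotype likelihoods (an N x 10 matrix per sample
# over the unordered genotypes in canonical order; see GENOTYPES). A
# missing marker for a sample is uninformative: zero counts / unit
# likelihoods.

#' Assemble a read-data object
#'
#' @param data Named list (one element per sample) of matrices with
#'   `nrow(markers)` rows: 4 columns of read counts (`mode = "counts"`) or
#'   10 columns of genotype likelihoods (`mode = "gl"`).
#' @param markers The marker tibble the rows are aligned to.
#' @param mode `"counts"` or `"gl"`.
#' @return A list of class `kin_data`.
#' @export
kin_data <- function(data, markers, mode = c("counts", "gl")) {
  mode <- match.arg(mode)
  stopifnot(is.list(data), length(names(data)) == length(data))
  want <- if (mode == "counts") 4L else 10L
  for (s in names(data)) {
    if (!is.matrix(data[[s]]) || ncol(data[[s]]) != want || nrow(data[[s]]) != nrow(markers)) {
      stop("data for sample ", s, " must be a ", nrow(markers), " x ", want, " matrix")
    }
  }
  structure(list(data = data, samples = names(data), markers = markers$marker, mode = mode),
            class = "kin_data")
}

#' @export
print.kin_data <- function(x, ...) {
  cat(sprintf("<kin_data> %d samples x %d markers, mode = %s\n",
              length(x$samples), length(x$markers), x$mode))
  invisible(x)
}

#' Read a read-count table
#'
#' Tab-separated with header `sample marker nA nC nG nT`. Markers not
#' present for a sample get zero counts (uninformative).
#'
#' @param path Path to the TSV file.
#' @param markers Marker tibble defining row order.
#' @return A `kin_data` object in counts mode.
#' @export
read_read_counts <- function(path, markers) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("sample", "marker", "nA", "nC", "nG", "nT")
  missing <- setdiff(need, names(df))
  if (length(missing)) stop("read-count table lacks column(s): ", paste(missing, collapse = ", "))
  unknown <- setdiff(unique(df$marker), markers$marker)
  if (length(unknown)) stop("read-count table references unknown marker(s): ",
                            paste(utils::head(unknown, 5), collapse = ", "))
  out <- list()
  for (s in unique(df$sample)) {
    sub <- df[df$sample == s, ]
    m <- matrix(0L, nrow(markers), 4, dimnames = list(markers$marker, c("A", "C", "G", "T")))
    ri <- match(sub$marker, markers$marker)
    cnt <- as.matrix(sub[, c("nA", "nC", "nG", "nT")])
    storage.mode(cnt) <- "integer"
    m[ri, ] <- cnt
    out[[s]] <- m
  }
  kin_data(out, markers, "counts")
}

#' Write a read-count table
#'
#' @param data A `kin_data` object in counts mode.
#' @param markers Marker tibble.
#' @param path Output TSV path.
#' @export
write_read_counts <- function(data, markers, path) {
  stopifnot(inherits(data, "kin_data"), data$mode == "counts")
  rows <- purrr::map(data$samples, function(s) {
    m <- data$data[[s]]
    tibble::tibble(sample = s, marker = markers$marker,
                   nA = m[, 1], nC = m[, 2], nG = m[, 3], nT = m[, 4])
  })
  readr::write_tsv(dplyr::bind_rows(rows), path, progress = FALSE)
  invisible(path)
}

NUCS <- c("A", "C", "G", "T")

#' Read observations from a VCF
#'
#' In `"AD"` mode the per-sample allelic depths are mapped to A/C/G/T read
#' counts through the record's REF/ALT nucleotides. In `"PL"` mode the
#' Phred-scaled genotype likelihoods are converted to linear scale and
#' placed on the corresponding unordered nucleotide genotypes (all other
#' genotypes get likelihood 0), then renormalized to maximum 1. Records are
#' joined to the marker table by the ID column.
#'
#' @param path Path to a VCF file.
#' @param markers Marker tibble; VCF records with IDs not in the table are
#'   dropped with a message.
#' @param field `"AD"` or `"PL"`.
#' @return A `kin_data` object (counts mode for AD, gl mode for PL).
#' @export
read_vcf_data <- function(path, markers, field = c("AD", "PL")) {
  field <- match.arg(field)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  ids <- fix[, "ID"]
  keep <- ids %in% markers$marker
  if (!all(keep)) message(sum(!keep), " VCF record(s) not in the marker table; dropped")
  gt <- vcfR::extract.gt(v, element = field)
  samples <- colnames(gt)
  ri <- match(ids, markers$marker)
  out <- list()
  for (s in samples) {
    m <- if (field == "AD") {
      matrix(0L, nrow(markers), 4, dimnames = list(markers$marker, NUCS))
    } else {
      matrix(1, nrow(markers), 10)
    }
    for (i in which(keep)) {
      alleles <- c(fix[i, "REF"], strsplit(fix[i, "ALT"], ",")[[1]])
      ai <- match(alleles, NUCS)
      val <- gt[i, s]
      if (is.na(val)) next
      nums <- suppressWarnings(as.numeric(strsplit(val, ",")[[1]]))
      if (field == "AD") {
        for (a in seq_along(ai)) {
          if (!is.na(ai[a]) && a <= length(nums) && !is.na(nums[a])) {
            m[ri[i], ai[a]] <- m[ri[i], ai[a]] + as.integer(nums[a])
          }
        }
      } else {
        # PL order: genotypes (a,b), a <= b, ordered by b then a (VCF spec)
        gl <- rep(0, 10)
        idx <- 0L
        for (b in seq_along(ai)) {
          for (a in 1:b) {
            idx <- idx + 1L
            if (idx <= length(nums) && !is.na(nums[idx]) && !is.na(ai[a]) && !is.na(ai[b])) {
              gl[genotype_index(ai[a], ai[b])] <- 10^(-nums[idx] / 10)
            }
          }
        }
        if (max(gl) > 0) m[ri[i], ] <- gl / max(gl)
      }
    }
    out[[s]] <- m
  }
  kin_data(out, markers, if (field == "AD") "counts" else "gl")
}
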