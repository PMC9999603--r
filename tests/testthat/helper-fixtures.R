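# shared fixtures: the five example pedigrees and small synthetic inputs

fixture_ped <- function(name) {
  read_pedigree(system.file("extdata", paste0("ped_", name, ".ped"), package = "kinlink"))
}

FIXTURE_NAMES <- c("halfsibs", "uncle_nephew", "two_uncles", "incest", "second_cousins")

# small marker tibble with n loci on one chromosome, fixed spacing in cM
toy_markers <- function(n, spacing_cM = 10, freqs = NULL) {
  if (is.null(freqs)) {
    freqs <- matrix(rep(c(0.4, 0.3, 0.2, 0.1), n), n, 4, byrow = TRUE)
  }
  validate_markers(tibble::tibble(
    marker = sprintf("m%03d", seq_len(n)),
    chrom = 1L,
    pos_cM = (seq_len(n) - 1) * spacing_cM,
    fA = freqs[, 1], fC = freqs[, 2], fG = freqs[, 3], fT = freqs[, 4]
  ))
}

# random read counts for the typed persons of a pedigree
random_counts_data <- function(ped, markers, lambda = 1.5) {
  counts <- lapply(ped$typed, function(s) {
    matrix(stats::rpois(nrow(markers) * 4, lambda), nrow(markers), 4)
  })
  names(counts) <- ped$typed
  kin_data(counts, markers, "counts")
}
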