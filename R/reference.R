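#' Mitochondrial genome length (rCRS numbering)
#'
#' The canonical human mitochondrial reference is 16,569 bp long; all profile
#' coordinates in this package are 1-based positions on that circle, used
#' linearly (no wrap-around).
#'
#' @export
MT_GENOME_LENGTH <- 16569L

#' Hypervariable segment windows used in forensic control-region typing
#'
#' HV1 spans positions 16,024-16,365 and HV2 spans 73-340.
#'
#' @return A coverage data frame with columns `start` and `end`.
#' @export
hv_windows <- function() {
  seq_ranges(c(73L, 16024L), c(340L, 16365L))
}

#' Deterministic synthetic stand-in for the mitochondrial reference
#'
#' The real reference sequence is not redistributed with the package; this
#' generator produces a fixed pseudo-random 16,569-base sequence (always the
#' same, independent of the session RNG) that plays the role of the reference
#' in examples, tests and synthetic data. Any analysis of real profiles should
#' supply the true reference via [read_reference_fasta()].
#'
#' @param length Sequence length; defaults to the mitochondrial genome length.
#' @return Character vector of single bases (A/C/G/T) of the given length.
#' @export
synthetic_reference <- function(length = MT_GENOME_LENGTH) {
  # simple multiplicative congruential stream so the sequence is frozen
  # regardless of the caller's RNG state
  m <- 2147483647
  a <- 48271
  x <- 20240101
  out <- character(length)
  bases <- c("A", "C", "G", "T")
  draws <- numeric(length)
  for (i in seq_len(length)) {
    x <- (a * x) %% m
    draws[i] <- x
  }
  out <- bases[(draws %% 4) + 1]
  out
}

#' Read a reference sequence from FASTA
#'
#' @param path Path to a FASTA file; the first record is used.
#' @return Character vector of single upper-case bases.
#' @export
read_reference_fasta <- function(path) {
  dna <- ape::read.FASTA(path)
  if (length(dna) < 1L) stop("no sequences in FASTA file: ", path)
  toupper(as.character(dna)[[1L]])
}

#' Write a reference sequence to FASTA
#'
#' @param reference Character vector of single bases.
#' @param path Output path.
#' @param name Sequence name for the FASTA header.
#' @export
write_reference_fasta <- function(reference, path, name = "reference") {
  seqs <- list(tolower(reference))
  names(seqs) <- name
  ape::write.FASTA(ape::as.DNAbin(seqs), path)
  invisible(path)
}
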