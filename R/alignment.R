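#' Build a multiple alignment from reference-coded profiles
#'
#' Because profiles are coded as differences to a shared reference, a
#' multiple alignment needs no aligner: over a common window every sample's
#' sequence is the reference substring with its differences applied, and the
#' union of observed insertion slots (position, index) across samples defines
#' extra columns, filled with `-` for samples lacking that insertion.
#' Deletions stay as gap columns.
#'
#' @param profiles List of `mt_profile` objects, all covering the window.
#' @param reference Reference sequence (character vector of bases).
#' @param window Coverage table (or range spec string); may have several
#'   ranges, which are concatenated.
#' @return Character matrix (samples x columns) with sample ids as rownames.
#' @export
profiles_to_alignment <- function(profiles, reference, window) {
  if (is.character(window)) window <- parse_range_spec(window)
  ids <- vapply(profiles, function(p) p$sample_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate sample ids in profile set")
  for (p in profiles) {
    if (!ranges_contain(p$coverage, window)) {
      stop("window not covered by profile ", p$sample_id)
    }
  }
  # union of insertion slots across samples, in coordinate order
  ins_all <- do.call(rbind, lapply(profiles, function(p) {
    v <- p$variants
    v <- v[v$kind == "insertion" & positions_in_ranges(window, v$position), ,
           drop = FALSE]
    v[, c("position", "insert_index"), drop = FALSE]
  }))
  slots <- unique(ins_all)
  slots <- slots[order(slots$position, slots$insert_index), , drop = FALSE]
  positions <- ranges_positions(window)
  # column layout: each reference position, then its insertion slots
  col_pos <- positions
  col_ins <- rep(0L, length(positions))
  if (nrow(slots) > 0L) {
    for (r in rev(seq_len(nrow(slots)))) {
      at <- max(which(col_pos == slots$position[r] & col_ins <
                        slots$insert_index[r]))
      col_pos <- append(col_pos, slots$position[r], after = at)
      col_ins <- append(col_ins, slots$insert_index[r], after = at)
    }
  }
  ncol <- length(col_pos)
  aln <- matrix("-", length(profiles), ncol, dimnames = list(ids, NULL))
  ref_cols <- col_ins == 0L
  for (i in seq_along(profiles)) {
    p <- profiles[[i]]
    row <- character(ncol)
    row[ref_cols] <- reference[col_pos[ref_cols]]
    row[!ref_cols] <- "-"
    v <- p$variants
    v <- v[positions_in_ranges(window, v$position), , drop = FALSE]
    for (j in seq_len(nrow(v))) {
      col <- which(col_pos == v$position[j] &
                     col_ins == (if (v$kind[j] == "insertion")
                       v$insert_index[j] else 0L))
      row[col] <- switch(v$kind[j], substitution = v$base[j],
                         insertion = v$base[j], deletion = "-")
    }
    aln[i, ] <- row
  }
  aln
}

#' Write an alignment to FASTA
#' @param alignment Character matrix with taxon rownames.
#' @param path Output path.
#' @export
write_alignment_fasta <- function(alignment, path) {
  seqs <- lapply(seq_len(nrow(alignment)), function(i)
    tolower(alignment[i, ]))
  names(seqs) <- rownames(alignment)
  ape::write.FASTA(ape::as.DNAbin(seqs), path)
  invisible(path)
}

#' Read an alignment from FASTA
#' @param path FASTA path (equal-length sequences).
#' @return Character matrix (upper case) with taxon rownames.
#' @export
read_alignment_fasta <- function(path) {
  dna <- ape::read.FASTA(path)
  chars <- lapply(as.character(dna), toupper)
  lens <- lengths(chars)
  if (length(unique(lens)) != 1L) stop("sequences differ in length: ", path)
  out <- do.call(rbind, chars)
  rownames(out) <- names(dna)
  out
}
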