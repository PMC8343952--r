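#' Parse a single variant token in forensic rCRS-difference nomenclature
#'
#' Recognised forms: substitutions (`"73G"`), insertions (`"315.1C"` — the
#' `.1` is the insert index after the anchor position) and deletions
#' (`"249DEL"`, with `"249-"` accepted as an input dialect). Bases are
#' normalised to upper case; `N` denotes a missing base and is excluded from
#' matching downstream.
#'
#' @param token Variant token string.
#' @return A one-row data frame with columns `position`, `kind`
#'   (`"substitution"`, `"insertion"` or `"deletion"`), `insert_index`
#'   (0 for non-insertions), `base` (`NA` for deletions) and the canonical
#'   `token`.
#' @export
parse_variant <- function(token) {
  tok <- trimws(token)
  if (length(tok) != 1L || is.na(tok) || !nzchar(tok)) {
    stop("malformed variant token: ", deparse(token))
  }
  sub_m <- regexec("^([0-9]+)([ACGTNacgtn])$", tok)[[1L]]
  ins_m <- regexec("^([0-9]+)\\.([0-9]+)([ACGTNacgtn])$", tok)[[1L]]
  del_m <- regexec("^([0-9]+)(DEL|del|Del|-)$", tok)[[1L]]
  mk <- function(position, kind, insert_index, base) {
    if (position < 1L || position > MT_GENOME_LENGTH) {
      stop("variant position outside 1..", MT_GENOME_LENGTH, ": ", tok)
    }
    canonical <- switch(kind,
      substitution = paste0(position, base),
      insertion = paste0(position, ".", insert_index, base),
      deletion = paste0(position, "DEL"))
    data.frame(position = position, kind = kind,
               insert_index = insert_index, base = base,
               token = canonical, stringsAsFactors = FALSE)
  }
  if (sub_m[1L] != -1L) {
    g <- regmatches(tok, list(sub_m))[[1L]]
    return(mk(as.integer(g[2L]), "substitution", 0L, toupper(g[3L])))
  }
  if (ins_m[1L] != -1L) {
    g <- regmatches(tok, list(ins_m))[[1L]]
    k <- as.integer(g[3L])
    if (k < 1L) stop("insertion index must be >= 1: ", tok)
    return(mk(as.integer(g[2L]), "insertion", k, toupper(g[4L])))
  }
  if (del_m[1L] != -1L) {
    g <- regmatches(tok, list(del_m))[[1L]]
    return(mk(as.integer(g[2L]), "deletion", 0L, NA_character_))
  }
  stop("malformed variant token: ", tok)
}

#' Parse several variant tokens at once
#' @param tokens Character vector of tokens (may be empty).
#' @return Variant table (zero or more rows) sorted by position and
#'   insert index.
#' @export
parse_variants <- function(tokens) {
  tokens <- tokens[nzchar(trimws(tokens))]
  if (length(tokens) == 0L) return(empty_variant_table())
  out <- do.call(rbind, lapply(tokens, parse_variant))
  out[order(out$position, out$insert_index), , drop = FALSE]
}

empty_variant_table <- function() {
  data.frame(position = integer(0), kind = character(0),
             insert_index = integer(0), base = character(0),
             token = character(0), stringsAsFactors = FALSE)
}

#' Construct a mitochondrial DNA profile (mitotype)
#'
#' A profile is a sample's set of differences to the reference over a declared
#' coverage. Invariants enforced: every variant lies inside the coverage, at
#' most one substitution/deletion per position, insertions unique per
#' (position, index), variants stored sorted.
#'
#' @param sample_id Sample identifier.
#' @param coverage A [seq_ranges()] coverage table (or a range spec string).
#' @param variants A variant table from [parse_variants()] (or a character
#'   vector of tokens).
#' @return An object of class `mt_profile`.
#' @export
mt_profile <- function(sample_id, coverage, variants = character(0)) {
  if (is.character(coverage)) coverage <- parse_range_spec(coverage)
  if (is.character(variants)) variants <- parse_variants(variants)
  variants <- variants[order(variants$position, variants$insert_index), ,
                       drop = FALSE]
  rownames(variants) <- NULL
  outside <- !positions_in_ranges(coverage, variants$position)
  if (any(outside)) {
    stop("variant(s) outside declared range for sample ", sample_id, ": ",
         paste(variants$token[outside], collapse = ", "))
  }
  nonins <- variants[variants$kind != "insertion", , drop = FALSE]
  if (anyDuplicated(nonins$position)) {
    stop("multiple substitutions/deletions at one position for sample ",
         sample_id)
  }
  ins <- variants[variants$kind == "insertion", , drop = FALSE]
  if (anyDuplicated(paste(ins$position, ins$insert_index))) {
    stop("duplicate insertion slot for sample ", sample_id)
  }
  structure(list(sample_id = sample_id, coverage = coverage,
                 variants = variants),
            class = "mt_profile")
}

#' @export
print.mt_profile <- function(x, ...) {
  cat("<mt_profile> ", x$sample_id, "  range ", format_range_spec(x$coverage),
      "\n  ", if (nrow(x$variants)) paste(x$variants$token, collapse = " ")
             else "(reference over declared range)", "\n", sep = "")
  invisible(x)
}

#' Parse one EMPOP-style profile record
#'
#' Record fields (whitespace-delimited): sample id, range specification, then
#' zero or more variant tokens.
#'
#' @param record A single delimited line, or a character vector of fields.
#' @return An `mt_profile`.
#' @export
parse_profile <- function(record) {
  fields <- if (length(record) == 1L) {
    strsplit(trimws(record), "[ \t]+")[[1L]]
  } else {
    record
  }
  fields <- fields[nzchar(fields)]
  if (length(fields) < 2L) stop("profile record needs id and range: ", record)
  mt_profile(fields[1L], parse_range_spec(fields[2L]),
             if (length(fields) > 2L) fields[-(1:2)] else character(0))
}

#' Variant tokens of a profile, optionally restricted to a window
#'
#' @param profile An `mt_profile`.
#' @param window Optional coverage table; only variants anchored inside are
#'   returned.
#' @param drop_n Drop variants whose base is `N` (treated as missing data).
#' @return Character vector of canonical tokens.
#' @export
profile_tokens <- function(profile, window = NULL, drop_n = TRUE) {
  v <- profile$variants
  if (!is.null(window) && nrow(v) > 0L) {
    v <- v[positions_in_ranges(window, v$position), , drop = FALSE]
  }
  if (drop_n && nrow(v) > 0L) {
    v <- v[is.na(v$base) | v$base != "N", , drop = FALSE]
  }
  v$token
}

#' Restrict a profile to a window
#'
#' The profile's coverage is intersected with the window and variants outside
#' the intersection are dropped. Ranges are adjusted this way before database
#' searches so that query and database records are compared over commonly
#' available data. An empty intersection is returned as an explicitly flagged
#' empty-coverage profile (`attr(., "empty_coverage")`), never silently.
#'
#' @param profile An `mt_profile`.
#' @param window Coverage table (or range spec string).
#' @return The restricted `mt_profile`.
#' @export
restrict_profile <- function(profile, window) {
  if (is.character(window)) window <- parse_range_spec(window)
  cov <- ranges_intersect(profile$coverage, window)
  v <- profile$variants
  if (nrow(v) > 0L) {
    v <- v[positions_in_ranges(cov, v$position), , drop = FALSE]
    rownames(v) <- NULL
  }
  out <- structure(list(sample_id = profile$sample_id, coverage = cov,
                        variants = v), class = "mt_profile")
  attr(out, "empty_coverage") <- nrow(cov) == 0L
  out
}

#' Symmetric difference between two profiles over a window
#'
#' Counts the variant tokens present in exactly one of the two profiles within
#' the window; zero differences means the two haplotypes match over the
#' window. `N` bases are treated as missing and excluded. Both profiles must
#' fully cover the window.
#'
#' @param a,b `mt_profile` objects.
#' @param window Coverage table (or range spec string).
#' @return List with `variants` (character vector of differing tokens) and
#'   `count`.
#' @export
profile_diff <- function(a, b, window) {
  if (is.character(window)) window <- parse_range_spec(window)
  if (!ranges_contain(a$coverage, window)) {
    stop("window not covered by profile ", a$sample_id)
  }
  if (!ranges_contain(b$coverage, window)) {
    stop("window not covered by profile ", b$sample_id)
  }
  ta <- profile_tokens(a, window)
  tb <- profile_tokens(b, window)
  d <- c(setdiff(ta, tb), setdiff(tb, ta))
  list(variants = sort(d), count = length(d))
}

#' Reconstruct the nucleotide sequence of a profile over a window
#'
#' Applies the profile's differences to the reference substring: substitutions
#' replace the reference base, deletions become the gap character `-`, and
#' insertions are appended after their anchor position in insert-index order.
#' Keeping deletions as gaps (rather than removing the column) means all
#' sequences rebuilt over a common window stay alignable once insertion
#' columns are expanded across samples (see [profiles_to_alignment()]).
#'
#' @param profile An `mt_profile`.
#' @param reference Reference sequence as a character vector of single bases.
#' @param window A single-range window (one row of a coverage table), which
#'   must lie inside the profile's coverage.
#' @return Character scalar (sequence over the window).
#' @export
profile_to_sequence <- function(profile, reference, window) {
  if (is.character(window)) window <- parse_range_spec(window)
  if (!ranges_contain(profile$coverage, window)) {
    stop("window not covered by profile ", profile$sample_id)
  }
  pieces <- character(0)
  for (i in seq_len(nrow(window))) {
    pos <- window$start[i]:window$end[i]
    seq <- reference[pos]
    v <- profile$variants
    v <- v[v$position >= window$start[i] & v$position <= window$end[i], ,
           drop = FALSE]
    subs <- v[v$kind == "substitution", , drop = FALSE]
    seq[match(subs$position, pos)] <- subs$base
    dels <- v[v$kind == "deletion", , drop = FALSE]
    seq[match(dels$position, pos)] <- "-"
    ins <- v[v$kind == "insertion", , drop = FALSE]
    if (nrow(ins) > 0L) {
      ins <- ins[order(ins$position, ins$insert_index), , drop = FALSE]
      # walk from the last slot backwards, always appending right after the
      # anchor: earlier slots then push later ones into index order
      for (j in rev(seq_len(nrow(ins)))) {
        at <- match(ins$position[j], pos)
        seq <- append(seq, ins$base[j], after = at)
      }
    }
    pieces <- c(pieces, paste(seq, collapse = ""))
  }
  paste(pieces, collapse = "")
}

#' Read an EMPOP-style profile table
#'
#' Tab-separated with header columns `sample_id`, `range`, `variants`
#' (space-separated tokens, possibly empty) and optionally `population` and
#' `origin`.
#'
#' @param path Path to the TSV file.
#' @return List with `profiles` (list of `mt_profile`) and the raw `table`.
#' @export
read_profile_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("sample_id", "range")
  if (!all(need %in% names(tab))) {
    stop("profile table must have columns sample_id and range: ", path)
  }
  if (!"variants" %in% names(tab)) tab$variants <- ""
  tab$variants[is.na(tab$variants)] <- ""
  profiles <- lapply(seq_len(nrow(tab)), function(i) {
    toks <- strsplit(trimws(tab$variants[i]), "[ \t]+")[[1L]]
    mt_profile(tab$sample_id[i], parse_range_spec(tab$range[i]), toks)
  })
  list(profiles = profiles, table = tab)
}

#' Write profiles to an EMPOP-style table
#'
#' @param profiles List of `mt_profile` objects.
#' @param path Output TSV path.
#' @param population Optional population label (recycled) written as a column.
#' @param origin Optional origin annotation column.
#' @export
write_profile_table <- function(profiles, path, population = NULL,
                                origin = NULL) {
  tab <- data.frame(
    sample_id = vapply(profiles, function(p) p$sample_id, character(1)),
    range = vapply(profiles, function(p) format_range_spec(p$coverage),
                   character(1)),
    variants = vapply(profiles, function(p) paste(p$variants$token,
                                                  collapse = " "),
                      character(1)),
    stringsAsFactors = FALSE)
  if (!is.null(population)) tab$population <- population
  if (!is.null(origin)) tab$origin <- origin
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
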