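#' Build a set of reference coordinate ranges
#'
#' Ranges are 1-based, inclusive, in rCRS numbering. The result is sorted and
#' validated: ranges must be non-overlapping and lie within 1..16,569.
#'
#' @param start,end Integer vectors of equal length.
#' @return Data frame with columns `start`, `end`, sorted by `start`.
#' @export
seq_ranges <- function(start, end) {
  start <- as.integer(start)
  end <- as.integer(end)
  if (length(start) != length(end)) stop("start and end lengths differ")
  if (length(start) == 0L) {
    return(structure(data.frame(start = integer(0), end = integer(0)),
                     class = c("seq_ranges", "data.frame")))
  }
  if (any(is.na(start)) || any(is.na(end))) stop("NA in range bounds")
  if (any(start < 1L) || any(end > MT_GENOME_LENGTH)) {
    stop("range bounds outside 1..", MT_GENOME_LENGTH)
  }
  if (any(start > end)) stop("range start exceeds end")
  o <- order(start)
  start <- start[o]; end <- end[o]
  if (length(start) > 1L && any(start[-1L] <= end[-length(end)])) {
    stop("ranges overlap")
  }
  structure(data.frame(start = start, end = end),
            class = c("seq_ranges", "data.frame"))
}

#' Parse a range specification string
#'
#' Accepts forms like `"16024-16365;73-340"`; single positions (`"263"`) are
#' treated as one-base ranges.
#'
#' @param spec Range specification string.
#' @return A [seq_ranges()] coverage table.
#' @export
parse_range_spec <- function(spec) {
  spec <- trimws(spec)
  if (identical(spec, "") || is.na(spec)) stop("empty range specification")
  parts <- strsplit(spec, ";", fixed = TRUE)[[1L]]
  parts <- trimws(parts)
  parts <- parts[nzchar(parts)]
  if (length(parts) == 0L) stop("empty range specification")
  m <- regmatches(parts, regexec("^([0-9]+)(?:-([0-9]+))?$", parts))
  bad <- vapply(m, function(x) length(x) == 0L, logical(1))
  if (any(bad)) stop("malformed range token(s): ", paste(parts[bad], collapse = ", "))
  start <- vapply(m, function(x) as.integer(x[2L]), integer(1))
  end <- vapply(m, function(x) {
    if (nzchar(x[3L])) as.integer(x[3L]) else as.integer(x[2L])
  }, integer(1))
  seq_ranges(start, end)
}

#' Format a coverage table back into a range specification string
#' @param ranges A coverage table from [seq_ranges()].
#' @return String such as `"73-340;16024-16365"`.
#' @export
format_range_spec <- function(ranges) {
  if (nrow(ranges) == 0L) return("")
  paste(sprintf("%d-%d", ranges$start, ranges$end), collapse = ";")
}

#' Intersect two coverage tables
#' @param a,b Coverage tables.
#' @return Coverage table of the intersection (possibly empty).
#' @export
ranges_intersect <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L) return(seq_ranges(integer(0), integer(0)))
  starts <- integer(0); ends <- integer(0)
  for (i in seq_len(nrow(a))) {
    s <- pmax(a$start[i], b$start)
    e <- pmin(a$end[i], b$end)
    keep <- s <= e
    starts <- c(starts, s[keep]); ends <- c(ends, e[keep])
  }
  seq_ranges(starts, ends)
}

#' Is every position of `inner` covered by `outer`?
#' @param inner,outer Coverage tables.
#' @return Logical scalar; an empty `inner` is trivially contained.
#' @export
ranges_contain <- function(outer, inner) {
  if (nrow(inner) == 0L) return(TRUE)
  isect <- ranges_intersect(outer, inner)
  sum(isect$end - isect$start + 1L) == sum(inner$end - inner$start + 1L)
}

#' Are these positions inside the coverage?
#' @param ranges Coverage table.
#' @param positions Integer vector of positions.
#' @return Logical vector.
#' @export
positions_in_ranges <- function(ranges, positions) {
  if (length(positions) == 0L) return(logical(0))
  if (nrow(ranges) == 0L) return(rep(FALSE, length(positions)))
  vapply(positions, function(p) any(p >= ranges$start & p <= ranges$end),
         logical(1))
}

#' Total number of reference positions covered
#' @param ranges Coverage table.
#' @return Integer count.
#' @export
ranges_width <- function(ranges) {
  if (nrow(ranges) == 0L) return(0L)
  sum(ranges$end - ranges$start + 1L)
}

#' All covered reference positions, in order
#' @param ranges Coverage table.
#' @return Integer vector.
#' @export
ranges_positions <- function(ranges) {
  if (nrow(ranges) == 0L) return(integer(0))
  unlist(lapply(seq_len(nrow(ranges)), function(i) ranges$start[i]:ranges$end[i]),
         use.names = FALSE)
}
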