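#' A labelled haplotype database
#'
#' A collection of mtDNA profiles carrying one shared population label,
#' supporting range-adjusted match counting.
#'
#' @param profiles List of `mt_profile` objects.
#' @param population Population label shared by all records.
#' @param origin Optional character vector of per-record origin annotations.
#' @return Object of class `haplotype_db`.
#' @export
haplotype_db <- function(profiles, population, origin = NULL) {
  if (!is.null(origin) && length(origin) != length(profiles)) {
    stop("origin annotation length must match number of profiles")
  }
  structure(list(profiles = profiles, population = population,
                 origin = origin, n = length(profiles)),
            class = "haplotype_db")
}

#' @export
print.haplotype_db <- function(x, ...) {
  cat("<haplotype_db> population=", x$population, ", n=", x$n, "\n", sep = "")
  invisible(x)
}

#' Load a haplotype database from an EMPOP-style table
#'
#' Reads the profile TSV of [read_profile_table()]; if a `population` column
#' is present all rows must agree, otherwise the label must be supplied.
#'
#' @param path TSV path.
#' @param population Population label (required if the table has none).
#' @return A `haplotype_db`.
#' @export
read_haplotype_db <- function(path, population = NULL) {
  parsed <- read_profile_table(path)
  tab <- parsed$table
  if ("population" %in% names(tab)) {
    pops <- unique(tab$population)
    if (length(pops) != 1L) stop("table mixes population labels: ", path)
    if (is.null(population)) population <- pops
  }
  if (is.null(population)) stop("no population label available for ", path)
  haplotype_db(parsed$profiles, population,
               origin = if ("origin" %in% names(tab)) tab$origin else NULL)
}

#' Range-adjusted haplotype match counting
#'
#' A database record is *comparable* when its coverage fully contains the
#' comparison window; `n` counts comparable records and `x` counts comparable
#' records identical to the query over the window (zero symmetric
#' difference). Records with partial window coverage are dropped from `n`
#' by default, which keeps `x` values comparable across records; the
#' alternative of intersecting the window per record is available with
#' `partial = "intersect"`.
#'
#' @param query Query `mt_profile`; must cover the window.
#' @param db A `haplotype_db`.
#' @param window Coverage table (or range spec string).
#' @param partial `"drop"` (default) or `"intersect"`.
#' @return List with `x` and `n`.
#' @export
range_adjusted_match_count <- function(query, db, window,
                                       partial = c("drop", "intersect")) {
  partial <- match.arg(partial)
  if (is.character(window)) window <- parse_range_spec(window)
  if (!ranges_contain(query$coverage, window)) {
    stop("window not covered by query ", query$sample_id)
  }
  qt <- sort(profile_tokens(query, window))
  x <- 0L; n <- 0L
  for (rec in db$profiles) {
    if (ranges_contain(rec$coverage, window)) {
      n <- n + 1L
      if (identical(sort(profile_tokens(rec, window)), qt)) x <- x + 1L
    } else if (partial == "intersect") {
      w <- ranges_intersect(rec$coverage, window)
      if (nrow(w) == 0L) next
      n <- n + 1L
      if (profile_diff(query, rec, w)$count == 0L) x <- x + 1L
    }
  }
  if (n == 0L) {
    stop("no comparable records in population ", db$population,
         " for the requested window")
  }
  list(x = x, n = n)
}

#' Augmented-count haplotype match probability
#'
#' The frequency of a haplotype observed `x` times among `n` comparable
#' database records is estimated with the augmented count `(x + 1) / (n + 1)`,
#' which never returns zero for unobserved haplotypes.
#'
#' @param x Match count, `0 <= x <= n`.
#' @param n Comparable-record count, `n >= 1`.
#' @return The probability `(x + 1) / (n + 1)`.
#' @export
augmented_probability <- function(x, n) {
  if (any(n < 1L)) stop("n must be >= 1")
  if (any(x < 0L) || any(x > n)) stop("x must satisfy 0 <= x <= n")
  (x + 1) / (n + 1)
}

#' Two-population haplotype probability contrast
#'
#' Computes range-adjusted match counts of the query in two reference
#' databases, converts them to augmented-count probabilities, and reports
#' their ratio and the population with the larger probability. Equal
#' probabilities are reported as an explicit `"tie"`, never broken silently.
#'
#' @param query Query `mt_profile`.
#' @param db_a,db_b `haplotype_db` objects (A is the likelihood-ratio
#'   numerator).
#' @param window Coverage table (or range spec string).
#' @param partial Passed to [range_adjusted_match_count()].
#' @return One-row data frame with columns `sample_id`, `x_a`, `n_a`, `p_a`,
#'   `x_b`, `n_b`, `p_b`, `lr`, `winner`.
#' @export
population_contrast <- function(query, db_a, db_b, window,
                                partial = c("drop", "intersect")) {
  partial <- match.arg(partial)
  a <- range_adjusted_match_count(query, db_a, window, partial)
  b <- range_adjusted_match_count(query, db_b, window, partial)
  p_a <- augmented_probability(a$x, a$n)
  p_b <- augmented_probability(b$x, b$n)
  winner <- if (p_a > p_b) db_a$population else if (p_b > p_a) {
    db_b$population
  } else "tie"
  data.frame(sample_id = query$sample_id,
             x_a = a$x, n_a = a$n, p_a = p_a,
             x_b = b$x, n_b = b$n, p_b = p_b,
             lr = p_a / p_b, winner = winner,
             stringsAsFactors = FALSE)
}

#' Contrast a set of queries against two reference populations
#'
#' @param queries List of `mt_profile` objects.
#' @param db_a,db_b `haplotype_db` objects.
#' @param window Coverage table (or range spec string).
#' @param partial Passed through to [population_contrast()].
#' @return Data frame, one row per query.
#' @export
contrast_report <- function(queries, db_a, db_b, window,
                            partial = c("drop", "intersect")) {
  partial <- match.arg(partial)
  do.call(rbind, lapply(queries, population_contrast,
                        db_a = db_a, db_b = db_b, window = window,
                        partial = partial))
}

#' Convert an mtDNA copy-number concentration to cell equivalents
#'
#' DNA extracts from degraded skeletal material are quantified as mtDNA
#' copies per microlitre; dividing by the assumed per-cell mtDNA copy number
#' (default 250) expresses the yield as nuclear-cell equivalents.
#'
#' @param copies_per_ul Non-negative mtDNA copy concentration.
#' @param copies_per_cell Assumed copies per cell; must be positive.
#' @return Cell equivalents.
#' @export
copies_to_cell_equivalents <- function(copies_per_ul, copies_per_cell = 250) {
  if (any(copies_per_cell <= 0)) stop("copies_per_cell must be positive")
  if (any(copies_per_ul < 0)) stop("copies_per_ul must be non-negative")
  copies_per_ul / copies_per_cell
}
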