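# multi-copy loci stored as ordered (ascending) pairs
PAIR_LOCI <- list(DYS385 = c("DYS385a", "DYS385b"),
                  DYF387S1 = c("DYF387S1a", "DYF387S1b"))

#' Construct a Y-STR haplotype
#'
#' Alleles are repeat counts (decimal microvariants such as 14.2 allowed),
#' keyed by marker name. Multi-copy loci (DYS385a/b, DYF387S1a/b) are stored
#' as ordered pairs: when both members are typed their values are sorted
#' ascending, so haplotypes are invariant to the reported pair order.
#' Untyped markers are simply absent.
#'
#' @param sample_id Sample identifier.
#' @param alleles Named numeric vector of allele values (> 0).
#' @return Object of class `ystr_haplotype`.
#' @export
ystr_haplotype <- function(sample_id, alleles) {
  alleles <- unlist(alleles)
  if (is.null(names(alleles)) || any(!nzchar(names(alleles)))) {
    stop("alleles must be a named vector")
  }
  if (anyDuplicated(names(alleles))) stop("duplicate marker names")
  if (any(alleles <= 0)) stop("allele values must be positive")
  for (pair in PAIR_LOCI) {
    if (all(pair %in% names(alleles))) {
      vals <- sort(unname(alleles[pair]))
      alleles[pair] <- vals
    }
  }
  structure(list(sample_id = sample_id, alleles = alleles),
            class = "ystr_haplotype")
}

#' @export
print.ystr_haplotype <- function(x, ...) {
  cat("<ystr_haplotype> ", x$sample_id, "  ",
      paste(names(x$alleles), x$alleles, sep = "=", collapse = " "),
      "\n", sep = "")
  invisible(x)
}

#' Define a named marker panel
#' @param name Panel name.
#' @param loci Character vector of unique marker names, in panel order.
#' @return Object of class `marker_panel`.
#' @export
marker_panel <- function(name, loci) {
  if (anyDuplicated(loci)) stop("panel loci must be unique")
  structure(list(name = name, loci = loci), class = "marker_panel")
}

#' The 12-locus extended Cohen Modal Haplotype panel
#'
#' DYS19, DYS388, DYS390, DYS391, DYS392, DYS393, DYS385a/b, DYS389I,
#' DYS389II, DYS426 and DYS439 (DYS389II stored as reported, not
#' DYS389I-subtracted).
#'
#' @return A `marker_panel` of 12 loci.
#' @export
cmh12_panel <- function() {
  marker_panel("CMH12", c("DYS19", "DYS388", "DYS390", "DYS391", "DYS392",
                          "DYS393", "DYS385a", "DYS385b", "DYS389I",
                          "DYS389II", "DYS426", "DYS439"))
}

#' A 27-locus commercial Y-STR kit panel fixture
#'
#' The marker list of a widely used 27-locus forensic Y-STR multiplex
#' (as published in the kit documentation). It types 10 of the 12 extended
#' CMH loci; DYS388 and DYS426 are not included and must be typed in
#' separate assays.
#'
#' @return A `marker_panel` of 27 loci.
#' @export
yfiler_plus_panel <- function() {
  marker_panel("YfilerPlus27", c(
    "DYS576", "DYS389I", "DYS635", "DYS389II", "DYS627", "DYS460",
    "DYS458", "DYS19", "YGATAH4", "DYS448", "DYS391", "DYS456", "DYS390",
    "DYS438", "DYS392", "DYS518", "DYS570", "DYS437", "DYS385a", "DYS385b",
    "DYS449", "DYS393", "DYS439", "DYS481", "DYF387S1a", "DYF387S1b",
    "DYS533"))
}

#' Parse a hyphenated 12-locus CMH-style haplotype string
#'
#' Strings such as `"14-16-23-10-11-12-13/15-13-30-11-12"` list eleven
#' hyphen-separated fields, with the DYS385a/b pair written `a/b`. The field
#' order is taken to be the CMH locus list order: DYS19, DYS388, DYS390,
#' DYS391, DYS392, DYS393, DYS385a/b, DYS389I, DYS389II, DYS426, DYS439.
#' (The order is a documented assumption; it is consistent with the
#' reference and all neighbour haplotypes handled by this package.)
#'
#' @param s Haplotype string.
#' @param sample_id Sample id for the resulting haplotype.
#' @return A `ystr_haplotype` over the 12 CMH loci.
#' @export
parse_cmh_string <- function(s, sample_id = s) {
  fields <- strsplit(trimws(s), "-", fixed = TRUE)[[1L]]
  if (length(fields) != 11L) {
    stop("expected 11 hyphen-separated fields (pair locus as a/b): ", s)
  }
  pair <- strsplit(fields[7L], "/", fixed = TRUE)[[1L]]
  if (length(pair) != 2L) stop("field 7 must be the DYS385 pair a/b: ", s)
  vals <- suppressWarnings(as.numeric(c(fields[1:6], pair, fields[8:11])))
  if (any(is.na(vals))) stop("non-numeric allele in: ", s)
  loci <- c("DYS19", "DYS388", "DYS390", "DYS391", "DYS392", "DYS393",
            "DYS385a", "DYS385b", "DYS389I", "DYS389II", "DYS426", "DYS439")
  ystr_haplotype(sample_id, stats::setNames(vals, loci))
}

#' The extended Cohen Modal Haplotype reference
#'
#' The 12-locus reference haplotype 14-16-23-10-11-12-13/15-13-30-11-12
#' (see [parse_cmh_string()] for the locus order).
#'
#' @return A `ystr_haplotype`.
#' @export
cmh_reference <- function() {
  parse_cmh_string("14-16-23-10-11-12-13/15-13-30-11-12", "CMH")
}

#' Mismatches of a haplotype against the Cohen Modal Haplotype
#'
#' Each CMH locus typed in the haplotype is compared to the reference; the
#' DYS385a/b pair is compared as a multiset (each differing member counts as
#' one mismatch). `compared` counts loci entering the comparison and
#' `missing = 12 - compared` counts untyped CMH loci.
#'
#' @param h A `ystr_haplotype`.
#' @param reference Reference haplotype (default [cmh_reference()]).
#' @return List with `mismatches`, `compared`, `missing`.
#' @export
cmh_mismatch_count <- function(h, reference = cmh_reference()) {
  panel <- cmh12_panel()$loci
  ref <- reference$alleles
  obs <- h$alleles
  mismatches <- 0L; compared <- 0L
  handled <- character(0)
  for (pair in PAIR_LOCI) {
    pair_in_panel <- intersect(pair, panel)
    if (length(pair_in_panel) == 0L) next
    handled <- c(handled, pair_in_panel)
    typed <- pair_in_panel[pair_in_panel %in% names(obs)]
    if (length(typed) == 0L) next
    ov <- sort(unname(obs[typed]))
    rv <- sort(unname(ref[pair_in_panel]))
    compared <- compared + length(ov)
    if (length(ov) == length(rv)) {
      mismatches <- mismatches + sum(ov != rv)
    } else {
      # single typed member: match it against the closer reference member
      mismatches <- mismatches + as.integer(!any(rv == ov))
    }
  }
  singles <- setdiff(panel, handled)
  for (loc in singles) {
    if (!loc %in% names(obs)) next
    compared <- compared + 1L
    if (obs[[loc]] != ref[[loc]]) mismatches <- mismatches + 1L
  }
  list(mismatches = mismatches, compared = compared,
       missing = length(panel) - compared)
}

#' Classify a haplotype relative to the Cohen Modal Haplotype
#'
#' `full_match`: all 12 loci typed and identical to the reference.
#' `close_neighbour`: between 1 and `neighbour_max` mismatches with at most
#' 2 untyped loci. `insufficient`: fewer than 10 loci typed. Everything else
#' is `other`.
#'
#' @param h A `ystr_haplotype`.
#' @param neighbour_max Largest mismatch count still called a neighbour.
#' @return One of `"full_match"`, `"close_neighbour"`, `"insufficient"`,
#'   `"other"`.
#' @export
classify_cmh <- function(h, neighbour_max = 3L) {
  m <- cmh_mismatch_count(h)
  if (m$mismatches == 0L && m$missing == 0L) return("full_match")
  if (m$compared < 10L) return("insufficient")
  if (m$mismatches >= 1L && m$mismatches <= neighbour_max && m$missing <= 2L) {
    return("close_neighbour")
  }
  "other"
}

#' Loci of a target panel covered by another panel
#'
#' @param panel The typing panel actually run.
#' @param target The panel of interest (e.g. the 12 CMH loci).
#' @return Number of target loci present in `panel`.
#' @export
panel_coverage <- function(panel, target) {
  length(intersect(target$loci, panel$loci))
}

#' Score a haplotype against haplogroup reference sets
#'
#' A transparent frequency-based scorer (in place of black-box haplogroup
#' predictors): for each haplogroup reference set, the score is the mean over
#' shared typed loci of the add-one-smoothed empirical frequency of the
#' observed allele, `(count + 1) / (n + 1)`. Sets are ranked by score; when
#' the top two scores differ by less than 5\% relative, the prediction is
#' reported as `"ambiguous"`.
#'
#' @param h A `ystr_haplotype`.
#' @param refsets Named list: haplogroup name -> list of `ystr_haplotype`.
#' @param ambiguity_margin Relative margin below which the call is
#'   ambiguous.
#' @return List with `predicted` (name or `"ambiguous"`) and `scores`
#'   (data frame ranked by descending score).
#' @export
ystr_assign <- function(h, refsets, ambiguity_margin = 0.05) {
  if (length(refsets) == 0L || is.null(names(refsets))) {
    stop("refsets must be a non-empty named list")
  }
  scores <- vapply(names(refsets), function(g) {
    set <- refsets[[g]]
    if (length(set) == 0L) stop("empty reference set: ", g)
    shared <- intersect(names(h$alleles),
                        unique(unlist(lapply(set, function(r)
                          names(r$alleles)))))
    if (length(shared) == 0L) {
      stop("no shared typed loci with reference set ", g)
    }
    per_locus <- vapply(shared, function(loc) {
      vals <- unlist(lapply(set, function(r) r$alleles[[loc]]))
      vals <- vals[!is.na(vals)]
      (sum(vals == h$alleles[[loc]]) + 1) / (length(vals) + 1)
    }, numeric(1))
    mean(per_locus)
  }, numeric(1))
  ranked <- data.frame(haplogroup = names(scores), score = unname(scores),
                       stringsAsFactors = FALSE)
  ranked <- ranked[order(-ranked$score, ranked$haplogroup), , drop = FALSE]
  rownames(ranked) <- NULL
  predicted <- ranked$haplogroup[1L]
  if (nrow(ranked) > 1L) {
    rel <- (ranked$score[1L] - ranked$score[2L]) / ranked$score[1L]
    if (rel < ambiguity_margin) predicted <- "ambiguous"
  }
  list(predicted = predicted, scores = ranked)
}

#' Read a Y-STR haplotype table
#'
#' TSV with a `sample_id` column and one column per marker; pair loci may be
#' given either as separate `DYS385a`/`DYS385b` columns or as a combined
#' `DYS385` column with values `"a,b"`. Empty cells are untyped markers.
#'
#' @param path TSV path.
#' @return List of `ystr_haplotype` objects.
#' @export
read_ystr_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character", check.names = FALSE)
  if (!"sample_id" %in% names(tab)) stop("need a sample_id column: ", path)
  markers <- setdiff(names(tab), "sample_id")
  lapply(seq_len(nrow(tab)), function(i) {
    alleles <- numeric(0)
    for (m in markers) {
      cell <- trimws(tab[[m]][i])
      if (!nzchar(cell) || is.na(cell)) next
      if (grepl(",", cell, fixed = TRUE)) {
        vals <- as.numeric(strsplit(cell, ",", fixed = TRUE)[[1L]])
        alleles[paste0(m, c("a", "b"))] <- vals
      } else {
        alleles[m] <- as.numeric(cell)
      }
    }
    ystr_haplotype(tab$sample_id[i], alleles)
  })
}

#' Write Y-STR haplotypes to a table
#'
#' @param haplotypes List of `ystr_haplotype` objects.
#' @param path Output TSV path.
#' @export
write_ystr_table <- function(haplotypes, path) {
  markers <- unique(unlist(lapply(haplotypes, function(h) names(h$alleles))))
  tab <- data.frame(sample_id = vapply(haplotypes, function(h) h$sample_id,
                                       character(1)),
                    stringsAsFactors = FALSE)
  for (m in markers) {
    tab[[m]] <- vapply(haplotypes, function(h) {
      if (m %in% names(h$alleles)) format(h$alleles[[m]]) else ""
    }, character(1))
  }
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' CMH classification report for a set of haplotypes
#'
#' @param haplotypes List of `ystr_haplotype` objects.
#' @param neighbour_max Passed to [classify_cmh()].
#' @return Data frame with columns `sample_id`, `mismatches`, `compared`,
#'   `missing`, `class`.
#' @export
cmh_report <- function(haplotypes, neighbour_max = 3L) {
  rows <- lapply(haplotypes, function(h) {
    m <- cmh_mismatch_count(h)
    data.frame(sample_id = h$sample_id, mismatches = m$mismatches,
               compared = m$compared, missing = m$missing,
               class = classify_cmh(h, neighbour_max),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
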