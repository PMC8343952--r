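#' Build a haplogroup diagnostic-variant tree
#'
#' The tree is a rooted hierarchy of named haplogroups; each node carries the
#' diagnostic variants acquired on the branch leading into it (tokens in the
#' same nomenclature as profiles). The cumulative diagnostic set of a node is
#' the union along the root-to-node path.
#'
#' @param table Data frame with columns `name`, `parent` (empty or `NA` for
#'   the root) and `diagnostics` (space-separated variant tokens, possibly
#'   empty).
#' @return Object of class `haplogroup_tree`.
#' @export
haplogroup_tree <- function(table) {
  need <- c("name", "parent", "diagnostics")
  if (!all(need %in% names(table))) {
    stop("haplogroup table needs columns name, parent, diagnostics")
  }
  table$parent[is.na(table$parent)] <- ""
  table$diagnostics[is.na(table$diagnostics)] <- ""
  if (anyDuplicated(table$name)) stop("duplicate haplogroup names")
  roots <- table$name[table$parent == ""]
  if (length(roots) != 1L) stop("tree must have exactly one root")
  known <- c("", table$name)
  if (!all(table$parent %in% known)) {
    stop("unknown parent(s): ",
         paste(setdiff(table$parent, known), collapse = ", "))
  }
  idx <- stats::setNames(seq_len(nrow(table)), table$name)
  depth <- integer(nrow(table))
  cumulative <- vector("list", nrow(table))
  resolve <- function(i, seen = character(0)) {
    if (!is.null(cumulative[[i]])) return(cumulative[[i]])
    if (table$name[i] %in% seen) stop("cycle in haplogroup tree at ",
                                      table$name[i])
    own <- strsplit(trimws(table$diagnostics[i]), "[ \t]+")[[1L]]
    own <- own[nzchar(own)]
    own <- if (length(own)) parse_variants(own)$token else character(0)
    if (table$parent[i] == "") {
      depth[i] <<- 0L
      cumulative[[i]] <<- own
    } else {
      p <- idx[[table$parent[i]]]
      up <- resolve(p, c(seen, table$name[i]))
      depth[i] <<- depth[p] + 1L
      cumulative[[i]] <<- union(up, own)
    }
    cumulative[[i]]
  }
  for (i in seq_len(nrow(table))) resolve(i)
  structure(list(table = table, index = idx, depth = depth,
                 cumulative = cumulative, root = roots),
            class = "haplogroup_tree")
}

#' @export
print.haplogroup_tree <- function(x, ...) {
  cat("<haplogroup_tree> ", nrow(x$table), " haplogroups, root=", x$root,
      "\n", sep = "")
  invisible(x)
}

#' Read a haplogroup tree from a TSV file
#'
#' @param path TSV with header `name`, `parent`, `diagnostics`.
#' @return A `haplogroup_tree`.
#' @export
read_haplogroup_tree <- function(path) {
  haplogroup_tree(utils::read.delim(path, stringsAsFactors = FALSE,
                                    colClasses = "character"))
}

#' The synthetic haplogroup tree shipped with the package
#'
#' A small curated fixture with invented (synthetic) control-region
#' diagnostics: it covers the fine subclades reported for the case samples
#' (K1a1b1a, K2a2a1, H3p, HV1b2, I1c1a, J1c14, V7a, X2b7), their ancestors,
#' and several other common European clades used by the second synthetic
#' reference population. It is a stand-in for a full phylogenetic import,
#' which is a documented extension point.
#'
#' @return A `haplogroup_tree`.
#' @export
lineagekit_haplogroup_tree <- function() {
  read_haplogroup_tree(system.file("extdata", "haplogroups_synthetic.tsv",
                                   package = "lineagekit", mustWork = TRUE))
}

#' Cumulative diagnostic variants of a haplogroup
#' @param tree A `haplogroup_tree`.
#' @param name Haplogroup name.
#' @return Character vector of canonical variant tokens.
#' @export
cumulative_diagnostics <- function(tree, name) {
  i <- tree$index[[name]]
  if (is.null(i)) stop("unknown haplogroup: ", name)
  tree$cumulative[[i]]
}

#' Names of a haplogroup and all its descendants
#' @param tree A `haplogroup_tree`.
#' @param name Haplogroup name.
#' @return Character vector including `name` itself.
#' @export
haplogroup_descendants <- function(tree, name) {
  if (is.null(tree$index[[name]])) stop("unknown haplogroup: ", name)
  out <- name
  frontier <- name
  while (length(frontier) > 0L) {
    kids <- tree$table$name[tree$table$parent %in% frontier]
    out <- c(out, kids)
    frontier <- kids
  }
  out
}

#' Assign a profile to a haplogroup
#'
#' Every node is scored against the observed variants: `matched` counts
#' expected diagnostics observed, `missing` counts expected diagnostics whose
#' position lies inside the profile's coverage but which are not observed,
#' and `score = matched - missing`. Diagnostics at positions outside the
#' coverage contribute to neither term. The best node is the score maximiser;
#' ties are broken toward the deeper (more derived) node and then
#' lexicographically, matching the forensic practice of reporting the finest
#' supportable subclade. Observed variants expected by no node on the best
#' path are reported as `private` but do not enter the score.
#'
#' @param profile An `mt_profile` with non-empty coverage.
#' @param tree A `haplogroup_tree`.
#' @param match_weight,missing_weight Unit costs of the score (defaults 1
#'   and 1).
#' @return List with `best`, `score`, `matched`, `missing`, `private` and a
#'   `runners_up` data frame ranked by (score desc, depth desc, name asc).
#' @export
assign_haplogroup <- function(profile, tree, match_weight = 1,
                              missing_weight = 1) {
  if (!inherits(tree, "haplogroup_tree")) stop("tree must be a haplogroup_tree")
  if (nrow(tree$table) == 0L) stop("empty haplogroup tree")
  if (nrow(profile$coverage) == 0L) stop("profile has empty coverage")
  observed <- profile_tokens(profile)
  nms <- tree$table$name
  matched <- integer(length(nms))
  missing <- integer(length(nms))
  for (i in seq_along(nms)) {
    expected <- tree$cumulative[[i]]
    if (length(expected) == 0L) next
    # tokens are canonical, so the leading digits are the anchor position
    pos <- as.integer(sub("^([0-9]+).*$", "\\1", expected))
    in_cov <- positions_in_ranges(profile$coverage, pos)
    exp_cov <- expected[in_cov]
    matched[i] <- sum(exp_cov %in% observed)
    missing[i] <- length(exp_cov) - matched[i]
  }
  score <- match_weight * matched - missing_weight * missing
  ranking <- data.frame(name = nms, score = score, matched = matched,
                        missing = missing, depth = tree$depth,
                        stringsAsFactors = FALSE)
  ranking <- ranking[order(-ranking$score, -ranking$depth, ranking$name), ,
                     drop = FALSE]
  rownames(ranking) <- NULL
  best <- ranking[1L, ]
  private <- length(setdiff(observed,
                            cumulative_diagnostics(tree, best$name)))
  list(best = best$name, score = best$score, matched = best$matched,
       missing = best$missing, private = private, runners_up = ranking)
}

#' Haplogroup relative-frequency profile of a database
#'
#' Assigns every record of the database and reports, for each requested
#' haplogroup, the fraction of records assigned to it or to one of its
#' descendants; mass not captured by any requested group is reported as
#' `other`. With disjoint requested clades the frequencies plus `other`
#' sum to one.
#'
#' @param db A `haplotype_db`.
#' @param tree A `haplogroup_tree`.
#' @param groups Non-empty character vector of haplogroup names.
#' @return Data frame with columns `group` and `frequency`, ending with the
#'   `other` row.
#' @export
haplogroup_frequency_profile <- function(db, tree, groups) {
  if (length(groups) == 0L) stop("groups must be non-empty")
  unknown <- setdiff(groups, tree$table$name)
  if (length(unknown) > 0L) {
    stop("unknown haplogroup name(s): ", paste(unknown, collapse = ", "))
  }
  best <- vapply(db$profiles,
                 function(p) assign_haplogroup(p, tree)$best, character(1))
  member_sets <- lapply(groups, haplogroup_descendants, tree = tree)
  counts <- vapply(member_sets, function(s) sum(best %in% s), integer(1))
  captured <- best %in% unique(unlist(member_sets))
  out <- data.frame(group = c(groups, "other"),
                    frequency = c(counts, sum(!captured)) / db$n,
                    stringsAsFactors = FALSE)
  out
}
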