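#' Validated configuration for a full analysis run
#'
#' Collects everything a run needs: the synthetic study spec (or databases
#' loaded from files), the comparison window, stage toggles and stage
#' parameters. Unknown arguments are rejected.
#'
#' @param spec A `synthetic_spec` (default study conditions with the given
#'   seed).
#' @param window Comparison window coverage table (default HV1 + HV2).
#' @param query_population Population the case queries are drawn from.
#' @param contrast_order Length-2 character vector: numerator and
#'   denominator populations of the likelihood ratio.
#' @param k_queries Number of case queries.
#' @param phylo_per_population Reference records subsampled per population
#'   for the phylogeographic stage (the study-scale analysis also worked on
#'   a representative subset).
#' @param phylo_max_sweeps Branch-length sweeps per fitting round in the
#'   phylogenetic stage.
#' @param neighbour_max CMH neighbour threshold.
#' @param theta Fixed G+C content for the T92 stage (estimated when `NULL`).
#' @param kappa_init Initial transition/transversion ratio.
#' @param stages Named logical vector enabling `contrast`, `haplogroup`,
#'   `phylo` and `ystr`.
#' @param out_dir Optional output directory for the machine-readable report.
#' @param seed Integer seed governing every stage.
#' @return Object of class `run_config`.
#' @export
run_config <- function(spec = NULL, window = hv_windows(),
                       query_population = "ashkenazi_like",
                       contrast_order = c("ashkenazi_like", "polish_like"),
                       k_queries = 10L, phylo_per_population = 12L,
                       phylo_max_sweeps = 2L, neighbour_max = 3L,
                       theta = NULL, kappa_init = 4,
                       stages = c(contrast = TRUE, haplogroup = TRUE,
                                  phylo = TRUE, ystr = TRUE),
                       out_dir = NULL, seed = 1L) {
  if (is.null(spec)) spec <- default_synthetic_spec(seed = seed)
  if (!inherits(spec, "synthetic_spec")) stop("spec must be a synthetic_spec")
  if (is.character(window)) window <- parse_range_spec(window)
  stage_names <- c("contrast", "haplogroup", "phylo", "ystr")
  full <- stats::setNames(rep(TRUE, 4L), stage_names)
  if (!all(names(stages) %in% stage_names)) {
    stop("unknown stage name(s): ",
         paste(setdiff(names(stages), stage_names), collapse = ", "))
  }
  full[names(stages)] <- stages
  if (length(contrast_order) != 2L ||
      !all(contrast_order %in% names(spec$populations))) {
    stop("contrast_order must name two populations of the spec")
  }
  if (!query_population %in% names(spec$populations)) {
    stop("unknown query population: ", query_population)
  }
  if (k_queries < 1L) stop("k_queries must be >= 1")
  structure(list(spec = spec, window = window,
                 query_population = query_population,
                 contrast_order = contrast_order,
                 k_queries = as.integer(k_queries),
                 phylo_per_population = as.integer(phylo_per_population),
                 phylo_max_sweeps = as.integer(phylo_max_sweeps),
                 neighbour_max = as.integer(neighbour_max),
                 theta = theta, kappa_init = kappa_init, stages = full,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full lineage-marker analysis
#'
#' Executes the stages in fixed order — simulate, database contrast,
#' haplogroup assignment and frequency profiling, phylogeographic clustering,
#' CMH scoring — and assembles a per-query case report. A failure in one
#' query is collected in the error section without aborting the others.
#' Reruns with the same configuration and seed are identical.
#'
#' @param config A [run_config()].
#' @return Object of class `case_report`: list with `queries` (data frame),
#'   `frequency_profiles`, `tree` (newick string or `NA`), `errors` and
#'   `meta`. Written to `config$out_dir` as JSON/CSV when set.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) stop("config must be a run_config")
  spec <- config$spec
  pops <- config$contrast_order
  errors <- list()
  note_error <- function(stage, id, e) {
    errors[[length(errors) + 1L]] <<- list(stage = stage, sample = id,
                                           message = conditionMessage(e))
  }

  mt_a <- generate_mt_population(spec, pops[1L])
  mt_b <- generate_mt_population(spec, pops[2L])
  case <- generate_case_set(spec, config$query_population,
                            k = config$k_queries)
  queries <- case$truth
  k <- nrow(queries)

  # --- database contrast -------------------------------------------------
  if (config$stages[["contrast"]]) {
    cr <- lapply(seq_len(k), function(i) {
      tryCatch(population_contrast(case$profiles[[i]], mt_a$db, mt_b$db,
                                   config$window),
               error = function(e) { note_error("contrast",
                                                queries$sample_id[i], e)
                                     NULL })
    })
    got <- !vapply(cr, is.null, logical(1))
    contrast <- if (any(got)) do.call(rbind, cr[got]) else NULL
    if (!is.null(contrast)) {
      queries <- merge(queries, contrast, by = "sample_id", sort = FALSE)
    }
  } else {
    queries$winner <- "skipped"
  }

  # --- haplogroup assignment and frequency profiles ----------------------
  freq_profiles <- NULL
  if (config$stages[["haplogroup"]]) {
    queries$mt_haplogroup_call <- vapply(seq_len(k), function(i) {
      tryCatch(assign_haplogroup(case$profiles[[i]], spec$tree)$best,
               error = function(e) { note_error("haplogroup",
                                                queries$sample_id[i], e)
                                     NA_character_ })
    }, character(1))
    groups <- sort(unique(unlist(lapply(spec$populations,
                                        function(p) names(p$mt_freqs)))))
    freq_profiles <- lapply(list(mt_a$db, mt_b$db), function(db) {
      out <- haplogroup_frequency_profile(db, spec$tree, groups)
      out$population <- db$population
      out
    })
    freq_profiles <- do.call(rbind, freq_profiles)
  } else {
    queries$mt_haplogroup_call <- "skipped"
  }

  # --- phylogeographic clustering ----------------------------------------
  tree_newick <- NA_character_
  tree_loglik <- NA_real_
  if (config$stages[["phylo"]]) {
    res <- tryCatch({
      set.seed(derive_seed(config$seed, "phylo_subsample"))
      m <- config$phylo_per_population
      pick_a <- sample(seq_along(mt_a$db$profiles), min(m, mt_a$db$n))
      pick_b <- sample(seq_along(mt_b$db$profiles), min(m, mt_b$db$n))
      refs <- c(mt_a$db$profiles[pick_a], mt_b$db$profiles[pick_b])
      labels <- stats::setNames(
        rep(pops, c(length(pick_a), length(pick_b))),
        vapply(refs, `[[`, character(1), "sample_id"))
      aln <- profiles_to_alignment(c(refs, case$profiles), spec$reference,
                                   config$window)
      dm <- build_distance_matrix(aln, theta = config$theta)
      cands <- list(build_tree(dm, "NJ"), build_tree(dm, "BioNJ"))
      fit <- select_topology(cands, aln, theta = config$theta,
                             kappa = config$kappa_init, max_rounds = 1L,
                             max_sweeps = config$phylo_max_sweeps)
      report <- clade_label_report(fit, labels, queries$sample_id)
      list(tree = ape::write.tree(fit), loglik = attr(fit, "logLik"),
           report = report)
    }, error = function(e) { note_error("phylo", NA_character_, e); NULL })
    if (!is.null(res)) {
      tree_newick <- res$tree
      tree_loglik <- res$loglik
      names(res$report)[names(res$report) == "query"] <- "sample_id"
      names(res$report)[names(res$report) == "call"] <- "clade_call"
      queries <- merge(queries, res$report, by = "sample_id", sort = FALSE)
    }
  } else {
    queries$clade_call <- "skipped"
  }

  # --- Y-STR / CMH --------------------------------------------------------
  if (config$stages[["ystr"]]) {
    cmh <- cmh_report(case$ystr, config$neighbour_max)
    names(cmh)[names(cmh) == "class"] <- "cmh_class"
    queries <- merge(queries, cmh[, c("sample_id", "mismatches",
                                      "cmh_class")],
                     by = "sample_id", sort = FALSE)
    ys_a <- generate_ystr_population(spec, pops[1L])
    ys_b <- generate_ystr_population(spec, pops[2L])
    all_y <- c(ys_a$haplotypes, ys_b$haplotypes)
    all_truth <- rbind(ys_a$truth, ys_b$truth)
    refsets <- split(all_y, all_truth$haplogroup)
    queries$y_haplogroup_call <- vapply(seq_len(k), function(i) {
      tryCatch(ystr_assign(case$ystr[[i]], refsets)$predicted,
               error = function(e) { note_error("ystr",
                                                queries$sample_id[i], e)
                                     NA_character_ })
    }, character(1))
  } else {
    queries$cmh_class <- "skipped"
    queries$y_haplogroup_call <- "skipped"
  }

  report <- structure(list(
    queries = queries,
    frequency_profiles = freq_profiles,
    tree = tree_newick,
    tree_logLik = tree_loglik,
    errors = errors,
    meta = list(seed = config$seed,
                populations = pops,
                query_population = config$query_population,
                n_per_population = spec$n_per_population,
                k_queries = config$k_queries,
                window = format_range_spec(config$window),
                stages = as.list(config$stages))),
    class = "case_report")
  if (!is.null(config$out_dir)) write_case_report(report, config$out_dir)
  report
}

#' @export
print.case_report <- function(x, ...) {
  cat("<case_report> ", nrow(x$queries), " queries; stages: ",
      paste(names(x$meta$stages)[unlist(x$meta$stages)], collapse = ", "),
      "\n", sep = "")
  if (length(x$errors)) cat("  ", length(x$errors), " stage error(s)\n")
  invisible(x)
}

#' Write a case report to disk
#'
#' Canonical JSON plus CSV side-car tables and the newick tree. Files are
#' written atomically (temp file then rename).
#'
#' @param report A `case_report`.
#' @param dir Output directory (created if needed).
#' @export
write_case_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  atomically <- function(path, writer) {
    tmp <- paste0(path, ".tmp")
    writer(tmp)
    file.rename(tmp, path)
  }
  atomically(file.path(dir, "report.json"), function(p) {
    jsonlite::write_json(unclass(report), p, auto_unbox = TRUE, digits = NA,
                         na = "null", dataframe = "rows")
  })
  atomically(file.path(dir, "queries.csv"), function(p) {
    utils::write.csv(report$queries, p, row.names = FALSE)
  })
  if (!is.null(report$frequency_profiles)) {
    atomically(file.path(dir, "haplogroup_frequencies.csv"), function(p) {
      utils::write.csv(report$frequency_profiles, p, row.names = FALSE)
    })
  }
  if (!is.na(report$tree)) {
    atomically(file.path(dir, "tree.nwk"), function(p) {
      writeLines(report$tree, p)
    })
  }
  invisible(dir)
}
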