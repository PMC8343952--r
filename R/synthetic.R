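#' Derive a reproducible sub-seed for a named generation stage
#'
#' All randomness in the synthetic generators flows from one base seed;
#' each stage (population, case set, subsampling) uses a sub-seed derived
#' deterministically from the base seed and the stage tag, so stages are
#' independent and reproducible regardless of call order.
#'
#' @param seed Integer base seed.
#' @param tag Stage tag string.
#' @return Integer sub-seed in [0, 2^31).
#' @export
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 10007 + h) %% 2147483647)
}

#' Specification of a synthetic two-population study
#'
#' Defines two reference populations with distinct haplogroup frequency
#' spectra over a shared founder set, the per-lineage private-variant rate,
#' Y-STR founders with a stepwise mutation rate, and the reference sequence.
#' All generators take their conditions from such a spec.
#'
#' @param populations Named list; each element has `mt_freqs` (named
#'   frequency vector over founder names, summing to 1) and `y_freqs`
#'   (named frequency vector over Y-STR founder names).
#' @param founders Named list of `mt_profile` founder haplotypes.
#' @param tree The `haplogroup_tree` the founders were derived from (used to
#'   keep private variants off diagnostic positions).
#' @param lambda_private Poisson mean of private control-region substitutions
#'   per sampled lineage.
#' @param n_per_population Records generated per reference population.
#' @param ystr_founders Named list of `ystr_haplotype` founders.
#' @param mu_smm Per-locus single-step mutation probability in [0, 0.5].
#' @param reference Reference sequence (character vector of bases).
#' @param seed Integer base seed.
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(populations, founders, tree, lambda_private,
                           n_per_population, ystr_founders, mu_smm,
                           reference, seed = 1L) {
  for (pop in names(populations)) {
    p <- populations[[pop]]
    if (abs(sum(p$mt_freqs) - 1) > 1e-12) {
      stop("mt frequency vector of ", pop, " does not sum to 1")
    }
    if (!all(names(p$mt_freqs) %in% names(founders))) {
      stop("unknown founder in mt_freqs of ", pop)
    }
    if (abs(sum(p$y_freqs) - 1) > 1e-12) {
      stop("y frequency vector of ", pop, " does not sum to 1")
    }
    if (!all(names(p$y_freqs) %in% names(ystr_founders))) {
      stop("unknown founder in y_freqs of ", pop)
    }
  }
  if (lambda_private < 0) stop("lambda_private must be >= 0")
  if (mu_smm < 0 || mu_smm > 0.5) stop("mu_smm must lie in [0, 0.5]")
  if (n_per_population < 1L) stop("n_per_population must be >= 1")
  structure(list(populations = populations, founders = founders, tree = tree,
                 lambda_private = lambda_private,
                 n_per_population = as.integer(n_per_population),
                 ystr_founders = ystr_founders, mu_smm = mu_smm,
                 reference = reference, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Default synthetic two-population study specification
#'
#' Mirrors the qualitative structure of a forensic two-population ancestry
#' contrast: population `ashkenazi_like` concentrates its haplogroup
#' spectrum on eight fine subclades (named after lineages reported in
#' Ashkenazi mtDNA surveys), while `polish_like` concentrates on other
#' common European clades, with 5\% spectral overlap. Defaults: 500 records
#' per population, 0.05 expected private control-region substitutions per
#' lineage (young subclades: most members carry the modal motif unchanged),
#' Y-STR founders at the Cohen Modal Haplotype and a well-separated second
#' haplotype, and a per-locus stepwise mutation probability of 0.02.
#'
#' @param seed Integer base seed.
#' @param n_per_population Records per population.
#' @param lambda_private Private-variant Poisson mean.
#' @param mu_smm Y-STR per-locus stepwise mutation probability.
#' @return A `synthetic_spec`.
#' @export
default_synthetic_spec <- function(seed = 1L, n_per_population = 500L,
                                   lambda_private = 0.05, mu_smm = 0.02) {
  tree <- lineagekit_haplogroup_tree()
  coverage <- hv_windows()
  founder_names <- c("K1a1b1a", "K2a2a1", "H3p", "HV1b2", "I1c1a", "J1c14",
                     "V7a", "X2b7", "U5a1", "U5b1b", "T2b", "H1", "W6",
                     "N1b")
  founders <- lapply(founder_names, function(nm) {
    toks <- cumulative_diagnostics(tree, nm)
    pos <- vapply(toks, function(t) parse_variant(t)$position, integer(1))
    mt_profile(paste0("founder_", nm), coverage,
               toks[positions_in_ranges(coverage, pos)])
  })
  names(founders) <- founder_names
  ystr_founders <- list(
    J_like = parse_cmh_string("14-16-23-10-11-12-13/15-13-30-11-12",
                              "founder_J_like"),
    R1a_like = parse_cmh_string("16-12-25-11-11-13-11/14-13-31-12-10",
                                "founder_R1a_like"))
  populations <- list(
    ashkenazi_like = list(
      mt_freqs = c(K1a1b1a = 0.20, K2a2a1 = 0.15, H3p = 0.125,
                   HV1b2 = 0.125, I1c1a = 0.10, J1c14 = 0.10, V7a = 0.10,
                   X2b7 = 0.10),
      y_freqs = c(J_like = 0.6, R1a_like = 0.4)),
    polish_like = list(
      mt_freqs = c(U5b1b = 0.25, U5a1 = 0.20, T2b = 0.20, H1 = 0.15,
                   W6 = 0.10, N1b = 0.05, K1a1b1a = 0.05),
      y_freqs = c(J_like = 0.1, R1a_like = 0.9)))
  synthetic_spec(populations, founders, tree, lambda_private,
                 n_per_population, ystr_founders, mu_smm,
                 synthetic_reference(), seed)
}

diagnostic_positions <- function(tree) {
  toks <- unique(unlist(tree$cumulative))
  if (length(toks) == 0L) return(integer(0))
  sort(unique(vapply(toks, function(t) parse_variant(t)$position,
                     integer(1))))
}

draw_private_tokens <- function(n_variants, candidates, reference) {
  if (n_variants == 0L) return(character(0))
  pos <- sample(candidates, n_variants)
  vapply(pos, function(p) {
    base <- sample(setdiff(c("A", "C", "G", "T"), reference[p]), 1L)
    paste0(p, base)
  }, character(1))
}

#' Generate a synthetic mtDNA reference population
#'
#' Each record draws a founder haplogroup from the population's frequency
#' vector, copies the founder profile, and adds a Poisson number of private
#' substitutions at uniformly chosen covered positions, avoiding every
#' diagnostic position of the haplogroup tree (so the generating haplogroup
#' stays recoverable). Deterministic under the derived seed.
#'
#' @param spec A `synthetic_spec`.
#' @param population Population name in `spec$populations`.
#' @param n Number of records (defaults to `spec$n_per_population`).
#' @param seed Optional override of the derived sub-seed.
#' @return List with `db` (a `haplotype_db`) and `truth` (data frame
#'   `sample_id`, `haplogroup`).
#' @export
generate_mt_population <- function(spec, population, n = NULL, seed = NULL) {
  if (!population %in% names(spec$populations)) {
    stop("unknown population: ", population)
  }
  if (is.null(n)) n <- spec$n_per_population
  if (is.null(seed)) seed <- derive_seed(spec$seed, paste0("mt:", population))
  set.seed(seed)
  freqs <- spec$populations[[population]]$mt_freqs
  picks <- sample(names(freqs), n, replace = TRUE, prob = freqs)
  coverage <- spec$founders[[1L]]$coverage
  candidates <- setdiff(ranges_positions(coverage),
                        diagnostic_positions(spec$tree))
  profiles <- vector("list", n)
  for (i in seq_len(n)) {
    founder <- spec$founders[[picks[i]]]
    k <- stats::rpois(1L, spec$lambda_private)
    k <- min(k, length(candidates))
    toks <- c(founder$variants$token,
              draw_private_tokens(k, candidates, spec$reference))
    profiles[[i]] <- mt_profile(sprintf("%s_%04d", population, i),
                                founder$coverage, toks)
  }
  list(db = haplotype_db(profiles, population),
       truth = data.frame(sample_id = vapply(profiles, `[[`, character(1),
                                             "sample_id"),
                          haplogroup = picks, stringsAsFactors = FALSE))
}

#' Generate a synthetic Y-STR population
#'
#' Each draw copies a founder haplotype chosen from the population's Y
#' frequency vector and mutates every allele (pair members independently)
#' by one repeat with probability `mu_smm`, direction by fair coin — the
#' stepwise mutation model. Deterministic under the derived seed.
#'
#' @param spec A `synthetic_spec`.
#' @param population Population name.
#' @param n Number of haplotypes (defaults to `spec$n_per_population`).
#' @param seed Optional override of the derived sub-seed.
#' @return List with `haplotypes` (list of `ystr_haplotype`) and `truth`
#'   (data frame `sample_id`, `haplogroup`).
#' @export
generate_ystr_population <- function(spec, population, n = NULL,
                                     seed = NULL) {
  if (!population %in% names(spec$populations)) {
    stop("unknown population: ", population)
  }
  if (is.null(n)) n <- spec$n_per_population
  if (is.null(seed)) seed <- derive_seed(spec$seed, paste0("y:", population))
  set.seed(seed)
  freqs <- spec$populations[[population]]$y_freqs
  picks <- sample(names(freqs), n, replace = TRUE, prob = freqs)
  haps <- vector("list", n)
  for (i in seq_len(n)) {
    alleles <- spec$ystr_founders[[picks[i]]]$alleles
    mut <- stats::runif(length(alleles)) < spec$mu_smm
    if (any(mut)) {
      step <- ifelse(stats::runif(sum(mut)) < 0.5, -1, 1)
      alleles[mut] <- alleles[mut] + step
    }
    haps[[i]] <- ystr_haplotype(sprintf("%s_y%04d", population, i), alleles)
  }
  list(haplotypes = haps,
       truth = data.frame(sample_id = vapply(haps, `[[`, character(1),
                                             "sample_id"),
                          haplogroup = picks, stringsAsFactors = FALSE))
}

#' Generate a synthetic case set of queries
#'
#' Draws `k` samples from the named population's generative process (both an
#' mtDNA profile and a Y-STR haplotype per sample) and records the truth
#' labels for recovery scoring.
#'
#' @param spec A `synthetic_spec`.
#' @param population Source population name.
#' @param k Number of queries (>= 1).
#' @param seed Optional override of the derived sub-seed.
#' @return List with `profiles`, `ystr` and `truth` (data frame `sample_id`,
#'   `population`, `mt_haplogroup`, `y_haplogroup`).
#' @export
generate_case_set <- function(spec, population, k = 10L, seed = NULL) {
  if (k < 1L) stop("k must be >= 1")
  if (is.null(seed)) {
    seed <- derive_seed(spec$seed, paste0("case:", population))
  }
  mt <- generate_mt_population(spec, population, n = k, seed = seed)
  ys <- generate_ystr_population(spec, population, n = k,
                                 seed = derive_seed(seed, "case_y"))
  profiles <- mt$db$profiles
  ids <- sprintf("case_%02d", seq_len(k))
  for (i in seq_len(k)) {
    profiles[[i]]$sample_id <- ids[i]
    ys$haplotypes[[i]]$sample_id <- ids[i]
  }
  list(profiles = profiles, ystr = ys$haplotypes,
       truth = data.frame(sample_id = ids, population = population,
                          mt_haplogroup = mt$truth$haplogroup,
                          y_haplogroup = ys$truth$haplogroup,
                          stringsAsFactors = FALSE))
}
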