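#' Tamura 3-parameter model parameters
#'
#' The T92 substitution model distinguishes transitions from transversions
#' (rate ratio `kappa`) and accounts for G+C content `theta`: stationary
#' frequencies are `piG = piC = theta/2` and `piA = piT = (1-theta)/2`. The
#' rate matrix is normalised to one expected substitution per unit branch
#' length, and its eigendecomposition is cached for transition probabilities.
#'
#' @param theta G+C content, in (0, 1).
#' @param kappa Transition/transversion rate ratio, > 0.
#' @return Object of class `t92_params` with elements `theta`, `kappa`, `pi`
#'   (stationary frequencies in A, C, G, T order) and the cached spectral
#'   decomposition of the rate matrix.
#' @export
t92_params <- function(theta, kappa = 4) {
  if (theta <= 0 || theta >= 1) stop("theta must lie in (0, 1)")
  if (kappa <= 0) stop("kappa must be positive")
  pi <- c(A = (1 - theta) / 2, C = theta / 2, G = theta / 2,
          T = (1 - theta) / 2)
  Q <- t92_rate_matrix(theta, kappa)
  # reversible model: symmetrise with sqrt(pi) for a stable eigendecomposition
  d <- sqrt(pi)
  S <- diag(d) %*% Q %*% diag(1 / d)
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  structure(list(theta = theta, kappa = kappa, pi = pi, Q = Q,
                 evals = e$values,
                 right = diag(1 / d) %*% e$vectors,
                 left = t(e$vectors) %*% diag(d)),
            class = "t92_params")
}

#' T92 instantaneous rate matrix (unit expected rate)
#'
#' @param theta G+C content.
#' @param kappa Transition/transversion rate ratio.
#' @return 4x4 matrix in A, C, G, T order with unit expected substitution
#'   rate at stationarity.
#' @export
t92_rate_matrix <- function(theta, kappa) {
  bases <- c("A", "C", "G", "T")
  pi <- c((1 - theta) / 2, theta / 2, theta / 2, (1 - theta) / 2)
  purine <- c(TRUE, FALSE, TRUE, FALSE)
  Q <- matrix(0, 4, 4, dimnames = list(bases, bases))
  for (i in 1:4) for (j in 1:4) {
    if (i == j) next
    Q[i, j] <- pi[j] * if (purine[i] == purine[j]) kappa else 1
  }
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))
  Q / mu
}

#' T92 transition probability matrix
#'
#' @param params A [t92_params()] object.
#' @param t Branch length (expected substitutions per site, >= 0).
#' @return 4x4 matrix `P` with `P[i, j] = Pr(j at the end | i at the start)`.
#' @export
t92_transition_probs <- function(params, t) {
  if (t < 0) stop("branch length must be non-negative")
  P <- params$right %*% (exp(params$evals * t) * params$left)
  # clamp tiny negative round-off
  P[P < 0] <- 0
  dimnames(P) <- list(names(params$pi), names(params$pi))
  P
}

#' Pairwise Tamura 3-parameter distance
#'
#' With `h = 2 theta (1 - theta)`, transition fraction `P` and transversion
#' fraction `Q` over the compared sites, the distance is
#' `d = -h log(1 - P/h - Q) - (1 - h)/2 * log(1 - 2 Q)`.
#' Sites where either sequence carries a gap, `N`, or any non-ACGT symbol are
#' excluded (pairwise deletion).
#'
#' @param s1,s2 Sequences as character vectors of single bases or single
#'   strings of equal length.
#' @param theta G+C content used for `h`.
#' @return Distance in substitutions per site.
#' @export
t92_distance <- function(s1, s2, theta) {
  s1 <- split_seq(s1); s2 <- split_seq(s2)
  if (length(s1) != length(s2)) stop("sequences differ in length")
  ok <- s1 %in% c("A", "C", "G", "T") & s2 %in% c("A", "C", "G", "T")
  if (!any(ok)) stop("no comparable sites between the two sequences")
  a <- s1[ok]; b <- s2[ok]
  purine <- function(x) x %in% c("A", "G")
  diff <- a != b
  ts <- diff & (purine(a) == purine(b))
  P <- mean(ts)
  Q <- mean(diff & !ts)
  h <- 2 * theta * (1 - theta)
  arg1 <- 1 - P / h - Q
  arg2 <- 1 - 2 * Q
  if (arg1 <= 0 || arg2 <= 0) {
    stop("T92 distance undefined (saturated divergence): P=", signif(P, 4),
         " Q=", signif(Q, 4))
  }
  -h * log(arg1) - (1 - h) / 2 * log(arg2)
}

split_seq <- function(s) {
  if (length(s) == 1L && nchar(s) > 1L) s <- strsplit(s, "")[[1L]]
  toupper(s)
}

#' Estimate G+C content from an alignment
#'
#' @param alignment Character matrix (taxa x sites) over A, C, G, T, `-`, N.
#' @return Fraction of G+C among unambiguous bases.
#' @export
estimate_theta <- function(alignment) {
  v <- toupper(as.vector(alignment))
  acgt <- v[v %in% c("A", "C", "G", "T")]
  if (length(acgt) == 0L) stop("alignment has no unambiguous bases")
  mean(acgt %in% c("G", "C"))
}

#' Pairwise T92 distance matrix for an alignment
#'
#' `theta` is by default estimated once from the whole alignment (a single
#' shared value); per-pair estimation is available with
#' `theta_policy = "pairwise"`. Sites with gaps or Ns are excluded per pair
#' (pairwise deletion) or, with `complete_deletion = TRUE`, columns carrying
#' any ambiguity are removed once for all pairs.
#'
#' @param alignment Character matrix with taxon rownames.
#' @param theta Optional fixed G+C content; overrides estimation.
#' @param theta_policy `"global"` (default) or `"pairwise"`.
#' @param complete_deletion Drop ambiguous columns globally before computing.
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
build_distance_matrix <- function(alignment, theta = NULL,
                                  theta_policy = c("global", "pairwise"),
                                  complete_deletion = FALSE) {
  theta_policy <- match.arg(theta_policy)
  if (nrow(alignment) < 2L) stop("need at least two taxa")
  if (complete_deletion) {
    keep <- apply(alignment, 2, function(col)
      all(toupper(col) %in% c("A", "C", "G", "T")))
    alignment <- alignment[, keep, drop = FALSE]
  }
  n <- nrow(alignment)
  taxa <- rownames(alignment)
  if (is.null(taxa)) taxa <- paste0("t", seq_len(n))
  dm <- matrix(0, n, n, dimnames = list(taxa, taxa))
  global_theta <- if (!is.null(theta)) theta else estimate_theta(alignment)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    th <- if (theta_policy == "global") global_theta else {
      estimate_theta(alignment[c(i, j), , drop = FALSE])
    }
    d <- tryCatch(t92_distance(alignment[i, ], alignment[j, ], th),
                  error = function(e) {
                    stop("pair ", taxa[i], " / ", taxa[j], ": ",
                         conditionMessage(e), call. = FALSE)
                  })
    dm[i, j] <- d; dm[j, i] <- d
  }
  dm
}

state_index <- c(A = 1L, C = 2L, G = 3L, T = 4L)

# 4 x sites partial-likelihood matrix for one leaf sequence; gaps/N/other
# symbols contribute likelihood 1 in every state (missing data)
leaf_partials <- function(seq) {
  L <- matrix(1, 4L, length(seq))
  known <- seq %in% names(state_index)
  if (any(known)) {
    cols <- which(known)
    L[, cols] <- 0
    L[cbind(state_index[seq[known]], cols)] <- 1
  }
  L
}

compress_patterns <- function(alignment) {
  key <- apply(alignment, 2, paste, collapse = "\r")
  first <- !duplicated(key)
  weights <- as.vector(table(factor(key, levels = key[first])))
  list(alignment = alignment[, first, drop = FALSE], weights = weights)
}

#' Log-likelihood of an alignment on a tree under T92
#'
#' Felsenstein's pruning algorithm over alignment columns: partial
#' likelihoods are propagated from the leaves to an arbitrary root with the
#' T92 transition probabilities, and the root vector is contracted with the
#' stationary frequencies. Gap and `N` states are treated as missing data
#' (partial likelihood one in every state). Identical columns are collapsed
#' into weighted patterns; per-column rescaling guards against underflow.
#'
#' @param tree An `ape::phylo` tree whose tip labels equal the alignment's
#'   row names; branch lengths in substitutions per site.
#' @param alignment Character matrix (taxa x sites).
#' @param params A [t92_params()] object.
#' @return Log-likelihood (numeric scalar).
#' @export
t92_log_likelihood <- function(tree, alignment, params) {
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch length")
  alignment <- toupper(alignment)
  if (!setequal(tree$tip.label, rownames(alignment))) {
    stop("tree tips and alignment taxa differ")
  }
  cp <- compress_patterns(alignment)
  aln <- cp$alignment; w <- cp$weights
  S <- ncol(aln)
  if (S == 0L) return(0)
  tree <- stats::reorder(tree, "postorder")
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  partials <- vector("list", n_node)
  logscale <- matrix(0, 1L, S)
  scale_acc <- rep(0, S)
  for (i in seq_len(n_tip)) {
    partials[[i]] <- leaf_partials(aln[tree$tip.label[i], ])
  }
  node_scale <- vector("list", n_node)
  for (i in seq_len(n_tip)) node_scale[[i]] <- rep(0, S)
  parents <- tree$edge[, 1L]; children <- tree$edge[, 2L]
  for (k in seq_along(parents)) {
    p <- parents[k]; ch <- children[k]
    P <- t92_transition_probs(params, tree$edge.length[k])
    contrib <- P %*% partials[[ch]]
    if (is.null(partials[[p]])) {
      partials[[p]] <- contrib
      node_scale[[p]] <- node_scale[[ch]]
    } else {
      partials[[p]] <- partials[[p]] * contrib
      node_scale[[p]] <- node_scale[[p]] + node_scale[[ch]]
      mx <- apply(partials[[p]], 2, max)
      mx[mx == 0] <- 1
      partials[[p]] <- sweep(partials[[p]], 2, mx, "/")
      node_scale[[p]] <- node_scale[[p]] + log(mx)
    }
  }
  root <- parents[length(parents)]
  site_l <- as.vector(params$pi %*% partials[[root]])
  sum(w * (log(site_l) + node_scale[[root]]))
}

#' Optimise branch lengths by coordinate-wise scalar search
#'
#' Each branch in turn is optimised with a bounded one-dimensional search
#' (on [0, 10] substitutions per site) holding the others fixed; sweeps
#' repeat until the log-likelihood gain falls below `tol` or `max_sweeps` is
#' reached. The log-likelihood never decreases across sweeps.
#'
#' @param tree `ape::phylo` starting tree.
#' @param alignment Character matrix.
#' @param params A [t92_params()] object.
#' @param max_sweeps Maximum number of passes over all branches.
#' @param tol Convergence threshold on the log-likelihood gain per sweep.
#' @param upper Upper bound per branch.
#' @return The tree with optimised `edge.length` and a `logLik` attribute.
#' @export
optimize_branch_lengths <- function(tree, alignment, params,
                                    max_sweeps = 20L, tol = 1e-6,
                                    upper = 10) {
  alignment <- toupper(alignment)
  ll <- t92_log_likelihood(tree, alignment, params)
  for (sweep in seq_len(max_sweeps)) {
    for (k in seq_along(tree$edge.length)) {
      f <- function(x) {
        tree$edge.length[k] <- x
        t92_log_likelihood(tree, alignment, params)
      }
      opt <- stats::optimize(f, c(0, upper), maximum = TRUE, tol = 1e-8)
      if (opt$objective >= f(tree$edge.length[k])) {
        tree$edge.length[k] <- opt$maximum
      }
    }
    new_ll <- t92_log_likelihood(tree, alignment, params)
    gain <- new_ll - ll
    ll <- new_ll
    if (gain < tol) break
  }
  attr(tree, "logLik") <- ll
  tree
}

#' Optimise the transition/transversion ratio
#'
#' Scalar maximisation of the log-likelihood over `kappa` in a bounded
#' interval, holding the tree fixed.
#'
#' @param tree `ape::phylo` tree with branch lengths.
#' @param alignment Character matrix.
#' @param theta G+C content.
#' @param interval Search interval for `kappa`.
#' @return List with `kappa` and `logLik`.
#' @export
optimize_kappa <- function(tree, alignment, theta, interval = c(0.1, 100)) {
  f <- function(k) t92_log_likelihood(tree, alignment, t92_params(theta, k))
  opt <- stats::optimize(f, interval, maximum = TRUE, tol = 1e-4)
  list(kappa = opt$maximum, logLik = opt$objective)
}

#' Fit branch lengths and kappa on a fixed topology
#'
#' Alternates branch-length sweeps with scalar `kappa` optimisation until the
#' joint log-likelihood gain is below `tol` (at most `max_rounds` rounds).
#'
#' @param tree Starting `ape::phylo` tree.
#' @param alignment Character matrix.
#' @param theta G+C content (estimated from the alignment when `NULL`).
#' @param kappa Initial transition/transversion ratio.
#' @param optimize_kappa Also optimise `kappa` (default TRUE).
#' @param max_rounds,tol Outer-loop controls.
#' @param max_sweeps Branch sweeps per round.
#' @return List with `tree` (branch lengths optimised, `logLik` attribute),
#'   `params` and `logLik`.
#' @export
fit_t92 <- function(tree, alignment, theta = NULL, kappa = 4,
                    optimize_kappa = TRUE, max_rounds = 5L, tol = 1e-4,
                    max_sweeps = 20L) {
  alignment <- toupper(alignment)
  if (is.null(theta)) theta <- estimate_theta(alignment)
  params <- t92_params(theta, kappa)
  ll <- -Inf
  for (round in seq_len(max_rounds)) {
    tree <- optimize_branch_lengths(tree, alignment, params,
                                    max_sweeps = max_sweeps)
    new_ll <- attr(tree, "logLik")
    if (optimize_kappa) {
      ok <- optimize_kappa(tree, alignment, theta)
      if (ok$logLik > new_ll) {
        params <- t92_params(theta, ok$kappa)
        new_ll <- ok$logLik
      }
    }
    if (new_ll - ll < tol) { ll <- new_ll; break }
    ll <- new_ll
  }
  attr(tree, "logLik") <- ll
  list(tree = tree, params = params, logLik = ll)
}

#' Select the topology with the superior log-likelihood
#'
#' Each candidate topology (typically the NJ and BioNJ starting trees) is
#' fitted with [fit_t92()] and the candidate with the highest optimised
#' log-likelihood is returned; exact ties keep the first candidate in input
#' order (with a message).
#'
#' @param candidates Non-empty list of `ape::phylo` trees.
#' @param alignment Character matrix.
#' @param theta,kappa,... Passed to [fit_t92()].
#' @return The winning tree with `logLik` and `params` attributes.
#' @export
select_topology <- function(candidates, alignment, theta = NULL, kappa = 4,
                            ...) {
  if (length(candidates) == 0L) stop("no candidate topologies")
  fits <- lapply(candidates, fit_t92, alignment = alignment, theta = theta,
                 kappa = kappa, ...)
  lls <- vapply(fits, function(f) f$logLik, numeric(1))
  best <- which.max(lls)
  if (sum(lls == lls[best]) > 1L) {
    message("log-likelihood tie between candidate topologies; keeping the ",
            "first in input order")
    best <- which(lls == lls[best])[1L]
  }
  out <- fits[[best]]$tree
  attr(out, "logLik") <- fits[[best]]$logLik
  attr(out, "params") <- fits[[best]]$params
  out
}

#' Simulate sequences under the T92 model along a tree
#'
#' Used to validate distance and likelihood machinery: a root sequence is
#' drawn from the stationary distribution and evolved along each branch with
#' the exact T92 transition probabilities.
#'
#' @param tree Rooted or unrooted `ape::phylo` tree with branch lengths.
#' @param sites Number of independent sites.
#' @param params A [t92_params()] object.
#' @param seed Optional integer seed for reproducibility.
#' @return Character matrix (tips x sites).
#' @export
simulate_t92_alignment <- function(tree, sites, params, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  bases <- names(params$pi)
  tree <- stats::reorder(tree, "postorder")
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  root <- tree$edge[nrow(tree$edge), 1L]
  states <- matrix(NA_integer_, n_node, sites)
  states[root, ] <- sample.int(4L, sites, replace = TRUE, prob = params$pi)
  # walk edges root-to-tips (reverse postorder)
  for (k in rev(seq_len(nrow(tree$edge)))) {
    p <- tree$edge[k, 1L]; ch <- tree$edge[k, 2L]
    P <- t92_transition_probs(params, tree$edge.length[k])
    for (s in 1:4) {
      idx <- which(states[p, ] == s)
      if (length(idx)) {
        states[ch, idx] <- sample.int(4L, length(idx), replace = TRUE,
                                      prob = P[s, ])
      }
    }
  }
  out <- matrix(bases[states[seq_len(n_tip), , drop = FALSE]], n_tip, sites)
  rownames(out) <- tree$tip.label
  out
}
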