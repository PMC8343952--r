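# shared fixtures and independent oracles, built in code at test time

REF <- synthetic_reference()

# independent brute-force T92 log-likelihood: rate matrix built from the model
# definition, matrix exponential via scaling-and-squaring on a Taylor series
# (no eigendecomposition), likelihood by exhaustive summation over all
# internal-node state assignments
bf_rate_matrix <- function(theta, kappa) {
  pi <- c((1 - theta) / 2, theta / 2, theta / 2, (1 - theta) / 2)
  purine <- c(TRUE, FALSE, TRUE, FALSE)
  Q <- matrix(0, 4, 4)
  for (i in 1:4) for (j in 1:4) {
    if (i != j) Q[i, j] <- pi[j] * if (purine[i] == purine[j]) kappa else 1
  }
  diag(Q) <- -rowSums(Q)
  Q / (-sum(pi * diag(Q)))
}

bf_expm <- function(M) {
  nrm <- max(abs(M))
  s <- max(0L, ceiling(log2(max(nrm, 1e-300))) + 4L)
  A <- M / 2^s
  P <- diag(4)
  term <- diag(4)
  for (k in 1:18) {
    term <- term %*% A / k
    P <- P + term
  }
  for (k in seq_len(s)) P <- P %*% P
  P
}

bf_t92_loglik <- function(tree, aln, theta, kappa) {
  pi <- c((1 - theta) / 2, theta / 2, theta / 2, (1 - theta) / 2)
  Q <- bf_rate_matrix(theta, kappa)
  tree <- reorder(tree, "postorder")
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  Pm <- lapply(tree$edge.length, function(t) bf_expm(Q * t))
  root <- tree$edge[nrow(tree$edge), 1L]
  internals <- sort(unique(tree$edge[, 1L]))
  code <- c(A = 1L, C = 2L, G = 3L, T = 4L)
  total <- 0
  for (site in seq_len(ncol(aln))) {
    obs <- toupper(aln[, site])
    site_sum <- 0
    grid <- do.call(expand.grid, rep(list(1:4), length(internals)))
    for (g in seq_len(nrow(grid))) {
      states <- integer(n_node)
      states[internals] <- as.integer(grid[g, ])
      lik <- pi[states[root]]
      ok <- TRUE
      for (e in seq_len(nrow(tree$edge))) {
        p <- tree$edge[e, 1L]; ch <- tree$edge[e, 2L]
        if (ch <= n_tip) {
          b <- obs[match(tree$tip.label[ch], rownames(aln))]
          if (b %in% names(code)) {
            lik <- lik * Pm[[e]][states[p], code[[b]]]
          } # gap/N: sum over child states = 1, contributes factor 1
        } else {
          lik <- lik * Pm[[e]][states[p], states[ch]]
        }
        if (lik == 0) { ok <- FALSE; break }
      }
      if (ok) site_sum <- site_sum + lik
    }
    total <- total + log(site_sum)
  }
  total
}

# random test alignment over A/C/G/T with occasional gaps and Ns
random_alignment <- function(n_taxa, sites, gap_frac = 0.05) {
  m <- matrix(sample(c("A", "C", "G", "T"), n_taxa * sites, replace = TRUE),
              n_taxa, sites)
  n_special <- rbinom(1, n_taxa * sites, gap_frac)
  if (n_special > 0) {
    idx <- sample(length(m), n_special)
    m[idx] <- sample(c("-", "N"), n_special, replace = TRUE)
  }
  rownames(m) <- paste0("t", seq_len(n_taxa))
  m
}

# Kimura 2-parameter distance, written independently of t92_distance
k2p_distance <- function(s1, s2) {
  ok <- s1 %in% c("A", "C", "G", "T") & s2 %in% c("A", "C", "G", "T")
  a <- s1[ok]; b <- s2[ok]
  pur <- function(x) x %in% c("A", "G")
  d <- a != b
  P <- mean(d & (pur(a) == pur(b)))
  Q <- mean(d & (pur(a) != pur(b)))
  -0.5 * log(1 - 2 * P - Q) - 0.25 * log(1 - 2 * Q)
}

# small toy haplogroup tree used across haplogrouping tests
toy_hg_tree <- function() {
  haplogroup_tree(data.frame(
    name = c("root", "A", "A1", "A1a", "B", "B1"),
    parent = c("", "root", "A", "A1", "root", "B"),
    diagnostics = c("", "100T 200C", "150G", "210A 220G", "300A 310C",
                    "320T"),
    stringsAsFactors = FALSE))
}

# profile covering the whole control-region windows with the given tokens
cr_profile <- function(id, tokens = character(0)) {
  mt_profile(id, seq_ranges(c(73, 16024), c(340, 16365)), tokens)
}

# profile covering positions 1..1000 (toy tree positions)
toy_profile <- function(id, tokens = character(0)) {
  mt_profile(id, seq_ranges(1, 1000), tokens)
}
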