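test_that("the T92 distance matches direct evaluation and its K2P limit", {
  s <- c("A", "C", "G", "T", "A", "C", "G", "T")
  expect_equal(t92_distance(s, s, 0.4), 0)

  # P = 0.1, Q = 0.05, theta = 0.4 (h = 0.48): frozen from independent
  # arithmetic on the distance formula
  s1 <- paste(rep("A", 20), collapse = "")
  s2 <- paste(c(rep("G", 2), rep("C", 1), rep("A", 17)), collapse = "")
  expect_equal(t92_distance(s1, s2, 0.4), 0.17084431313498982,
               tolerance = 1e-12)

  # theta = 1/2 collapses T92 onto Kimura's two-parameter distance
  set.seed(9)
  for (i in 1:100) {
    a <- sample(c("A", "C", "G", "T"), 60, replace = TRUE)
    b <- a
    mut <- sample(60, 6)
    b[mut] <- sample(c("A", "C", "G", "T"), 6, replace = TRUE)
    d1 <- t92_distance(a, b, 0.5)
    expect_equal(d1, k2p_distance(a, b), tolerance = 1e-12)
  }
})

test_that("ambiguous sites are excluded and saturation raises an error", {
  a <- c("A", "A", "-", "N", "C")
  b <- c("A", "G", "C", "C", "C")
  # only 3 comparable sites; one transition
  h <- 2 * 0.4 * 0.6
  expect_equal(t92_distance(a, b, 0.4), -h * log(1 - (1 / 3) / h),
               tolerance = 1e-12)
  expect_error(t92_distance(c("A", "A"), c("G", "G"), 0.4), "saturated")
  expect_error(t92_distance(c("-", "N"), c("A", "C"), 0.4), "comparable")
})

test_that("distance matrices equal the element-wise pairwise oracle", {
  set.seed(31)
  # related rows: a shared ancestral sequence with a few mutations per taxon
  anc <- sample(c("A", "C", "G", "T"), 300, replace = TRUE)
  aln <- t(vapply(1:5, function(i) {
    s <- anc
    mut <- sample(300, 25)
    s[mut] <- sample(c("A", "C", "G", "T"), 25, replace = TRUE)
    s[sample(300, 8)] <- sample(c("-", "N"), 8, replace = TRUE)
    s
  }, character(300)))
  rownames(aln) <- paste0("t", 1:5)
  dm <- build_distance_matrix(aln)
  th <- estimate_theta(aln)
  for (i in 1:4) for (j in (i + 1):5) {
    expect_equal(dm[i, j], t92_distance(aln[i, ], aln[j, ], th),
                 tolerance = 1e-14)
    expect_equal(dm[i, j], dm[j, i])
  }
  expect_true(all(diag(dm) == 0))

  same <- matrix(rep(c("A", "C", "G", "T"), 3), nrow = 3, ncol = 4,
                 byrow = TRUE, dimnames = list(c("a", "b", "c"), NULL))
  expect_true(all(build_distance_matrix(same, theta = 0.5) == 0))

  two <- aln[1:2, , drop = FALSE]
  expect_equal(build_distance_matrix(two, theta = 0.4)[1, 2],
               t92_distance(aln[1, ], aln[2, ], 0.4))
})

test_that("pruning handles missing data and degenerate trees exactly", {
  par <- t92_params(0.4, 4)
  tr <- ape::read.tree(text = "((a:0.1,b:0.2):0.05,c:0.1,d:0.3);")
  aln_n <- matrix("N", 4, 1, dimnames = list(c("a", "b", "c", "d"), NULL))
  expect_equal(t92_log_likelihood(tr, aln_n, par), 0)

  star0 <- ape::read.tree(text = "(a:0,b:0,c:0);")
  aln_c <- matrix("C", 3, 1, dimnames = list(c("a", "b", "c"), NULL))
  expect_equal(t92_log_likelihood(star0, aln_c, par),
               log(par$pi[["C"]]), tolerance = 1e-12)
})

test_that("pruning equals brute-force state enumeration on small trees", {
  set.seed(77)
  par_sets <- list(c(0.4, 4), c(0.55, 2))
  tr4 <- ape::read.tree(text = "((a:0.12,b:0.31):0.08,(c:0.2,d:0.05):0.1);")
  tr5 <- ape::read.tree(
    text = "((a:0.1,b:0.2):0.06,(c:0.15,(d:0.3,e:0.07):0.12):0.04);")
  for (ps in par_sets) {
    par <- t92_params(ps[1], ps[2])
    for (tr in list(tr4, tr5)) {
      aln <- random_alignment(length(tr$tip.label), 4, gap_frac = 0.15)
      rownames(aln) <- tr$tip.label
      expect_equal(t92_log_likelihood(tr, aln, par),
                   bf_t92_loglik(tr, aln, ps[1], ps[2]),
                   tolerance = 1e-9)
    }
  }
})

test_that("pruning agrees with an independent likelihood implementation", {
  skip_if_not_installed("phangorn")
  set.seed(13)
  tr <- ape::rtree(6, br = function(n) runif(n, 0.02, 0.3))
  par <- t92_params(0.5, 3)
  aln <- simulate_t92_alignment(tr, 300, par, seed = 5)
  fit <- phangorn::pml(tr, phangorn::phyDat(aln), model = "K80",
                       Q = c(1, 3, 1, 1, 3, 1))
  expect_equal(t92_log_likelihood(tr, aln, par), fit$logLik,
               tolerance = 1e-8)
})

test_that("branch optimisation is monotone and recovers the 2-taxon MLE", {
  par <- t92_params(0.4, 4)
  tr <- ape::read.tree(text = "(A:0.02,B:0.02);")
  aln <- simulate_t92_alignment(tr, 3000,
                                t92_params(0.4, 4), seed = 21)
  ll0 <- t92_log_likelihood(tr, aln, par)
  opt <- optimize_branch_lengths(tr, aln, par)
  expect_gte(attr(opt, "logLik"), ll0)
  d_analytic <- t92_distance(aln["A", ], aln["B", ], 0.4)
  expect_lt(abs(sum(opt$edge.length) - d_analytic), 1e-3)

  # an already-optimal tree is a fixed point (within tolerance)
  opt2 <- optimize_branch_lengths(opt, aln, par)
  expect_equal(attr(opt2, "logLik"), attr(opt, "logLik"), tolerance = 1e-5)
  expect_equal(sum(opt2$edge.length), sum(opt$edge.length),
               tolerance = 1e-4)
})

test_that("pairwise distance estimates track true path lengths", {
  # parameter recovery: 6 taxa, theta = 0.4, kappa = 4, 5000 sites
  set.seed(55)
  tr <- ape::rtree(6, br = function(n) runif(n, 0.01, 0.08))
  par <- t92_params(0.4, 4)
  aln <- simulate_t92_alignment(tr, 5000, par, seed = 56)
  dm <- build_distance_matrix(aln, theta = 0.4)
  true_d <- ape::cophenetic.phylo(tr)
  taxa <- rownames(true_d)
  for (i in 1:5) for (j in (i + 1):6) {
    td <- true_d[i, j]
    if (td <= 0.3) {
      expect_lt(abs(dm[taxa[i], taxa[j]] - td), 0.1 * td)
    }
  }
})

test_that("topology selection maximises the optimised log-likelihood", {
  # strongly separated 4-taxon data: the generating topology must win
  gen <- ape::read.tree(text = "((a:0.05,b:0.05):0.6,(c:0.05,d:0.05):0.6);")
  par <- t92_params(0.45, 4)
  aln <- simulate_t92_alignment(gen, 800, par, seed = 31)
  swap <- ape::read.tree(text = "((a:0.1,c:0.1):0.1,(b:0.1,d:0.1):0.1);")
  best <- select_topology(list(swap, gen), aln, theta = 0.45)
  expect_equal(ape::dist.topo(ape::unroot(best), ape::unroot(gen)), 0,
               ignore_attr = TRUE)
  # annotated score is the likelihood of the returned tree
  expect_equal(attr(best, "logLik"),
               t92_log_likelihood(best, aln, attr(best, "params")),
               tolerance = 1e-9)
  single <- select_topology(list(gen), aln, theta = 0.45)
  expect_equal(ape::dist.topo(ape::unroot(single), ape::unroot(gen)), 0,
               ignore_attr = TRUE)
})
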