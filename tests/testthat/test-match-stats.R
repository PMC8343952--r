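test_that("augmented counting follows (x+1)/(n+1) with its bounds", {
  expect_equal(augmented_probability(0, 945), 1 / 946)
  expect_equal(augmented_probability(2, 744), 3 / 745)
  expect_equal(augmented_probability(5, 5), 1)
  expect_error(augmented_probability(3, 2))
  expect_error(augmented_probability(0, 0))
  expect_error(augmented_probability(-1, 5))
})

test_that("augmented probability is monotone in x and in n", {
  n <- 100
  p <- augmented_probability(0:n, n)
  expect_true(all(diff(p) > 0))
  x <- 7
  ns <- x:500
  pn <- vapply(ns, function(n) augmented_probability(x, n), numeric(1))
  expect_true(all(diff(pn) <= 0))
})

test_that("range-adjusted matching counts comparable and matching records", {
  w <- seq_ranges(73, 340)
  q <- cr_profile("q", c("73G", "263G"))

  same <- haplotype_db(lapply(1:5, function(i)
    cr_profile(paste0("r", i), c("73G", "263G"))), "P")
  expect_equal(range_adjusted_match_count(q, same, w), list(x = 5L, n = 5L))

  priv <- cr_profile("priv", c("73G", "263G", "111T"))
  expect_equal(range_adjusted_match_count(priv, same, w)$x, 0L)

  # mixed coverage: 2 of 4 records cover the window, 1 of those matches
  mixed <- haplotype_db(list(
    cr_profile("m1", c("73G", "263G")),
    cr_profile("m2", c("73G", "150T")),
    mt_profile("m3", "100-340", c("263G")),
    mt_profile("m4", "16024-16365")), "P")
  expect_equal(range_adjusted_match_count(q, mixed, w),
               list(x = 1L, n = 2L))

  expect_error(range_adjusted_match_count(q, same, seq_ranges(1, 50)),
               "not covered")
  hv1_only <- haplotype_db(list(mt_profile("h", "16024-16365")), "P")
  expect_error(range_adjusted_match_count(q, hv1_only, w), "no comparable")
})

test_that("match counting equals an exhaustive pairwise diff scan", {
  set.seed(101)
  w <- seq_ranges(73, 340)
  toks <- c("73G", "111T", "150C", "263G", "300A")
  for (rep in 1:5) {
    db_profiles <- lapply(1:30, function(i) {
      cr_profile(paste0("r", i),
                 sample(toks, sample(0:3, 1)))
    })
    db <- haplotype_db(db_profiles, "P")
    q <- cr_profile("q", sample(toks, sample(0:3, 1)))
    got <- range_adjusted_match_count(q, db, w)
    oracle_x <- sum(vapply(db_profiles, function(r)
      profile_diff(q, r, w)$count == 0L, logical(1)))
    expect_equal(got$x, oracle_x)
    expect_equal(got$n, 30L)
  }
})

test_that("shrinking the window never decreases the match count", {
  set.seed(202)
  big <- seq_ranges(73, 340)
  small <- seq_ranges(73, 200)
  toks <- c("80C", "120T", "180G", "250A", "300T")
  db <- haplotype_db(lapply(1:40, function(i)
    cr_profile(paste0("r", i), sample(toks, sample(0:3, 1)))), "P")
  for (rep in 1:10) {
    q <- cr_profile("q", sample(toks, sample(0:2, 1)))
    x_big <- range_adjusted_match_count(q, db, big)$x
    x_small <- range_adjusted_match_count(q, db, small)$x
    expect_gte(x_small, x_big)
  }
})

test_that("the two-population contrast reports probabilities and winner", {
  w <- seq_ranges(73, 340)
  q <- cr_profile("q", "73G")
  db_a <- haplotype_db(c(list(cr_profile("a0", "73G")),
                         lapply(1:8, function(i)
                           cr_profile(paste0("a", i), "150T"))), "A")
  db_b <- haplotype_db(lapply(1:9, function(i)
    cr_profile(paste0("b", i), "263G")), "B")
  res <- population_contrast(q, db_a, db_b, w)
  expect_equal(res$p_a, 0.2)
  expect_equal(res$p_b, 0.1)
  expect_equal(res$lr, 2)
  expect_equal(res$winner, "A")

  # identical databases: explicit tie, lr exactly one
  db_b2 <- haplotype_db(db_a$profiles, "B")
  res2 <- population_contrast(q, db_a, db_b2, w)
  expect_equal(res2$lr, 1)
  expect_equal(res2$winner, "tie")

  rep <- contrast_report(list(q, cr_profile("q2", "263G")), db_a, db_b, w)
  expect_equal(nrow(rep), 2L)
  expect_equal(rep$winner[2L], "B")
})

test_that("copy-number concentrations convert to cell equivalents", {
  expect_equal(copies_to_cell_equivalents(4000, 250), 16)
  expect_equal(copies_to_cell_equivalents(0, 250), 0)
  expect_equal(copies_to_cell_equivalents(70, 250), 0.28)
  expect_error(copies_to_cell_equivalents(100, 0))
  expect_error(copies_to_cell_equivalents(-5, 250))
})
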