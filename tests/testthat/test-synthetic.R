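test_that("zero private-variant rate reproduces founders verbatim", {
  spec <- default_synthetic_spec(seed = 3, n_per_population = 40,
                                 lambda_private = 0)
  gen <- generate_mt_population(spec, "polish_like")
  for (i in seq_along(gen$db$profiles)) {
    founder <- spec$founders[[gen$truth$haplogroup[i]]]
    expect_equal(sort(gen$db$profiles[[i]]$variants$token),
                 sort(founder$variants$token))
  }
})

test_that("a degenerate frequency vector yields a single founder", {
  spec <- default_synthetic_spec(seed = 4, n_per_population = 30)
  spec$populations$polish_like$mt_freqs <-
    c(U5b1b = 1, U5a1 = 0, T2b = 0, H1 = 0, W6 = 0, N1b = 0, K1a1b1a = 0)
  gen <- generate_mt_population(spec, "polish_like")
  expect_true(all(gen$truth$haplogroup == "U5b1b"))
})

test_that("founder draws respect the frequency spectrum", {
  # two-founder 0.7/0.3 spectrum at n = 1000: counts inside the central
  # 99% binomial band around 700/300
  spec <- default_synthetic_spec(seed = 5, n_per_population = 1000)
  spec$populations$ashkenazi_like$mt_freqs <-
    c(K1a1b1a = 0.7, K2a2a1 = 0.3, H3p = 0, HV1b2 = 0, I1c1a = 0,
      J1c14 = 0, V7a = 0, X2b7 = 0)
  gen <- generate_mt_population(spec, "ashkenazi_like")
  k <- sum(gen$truth$haplogroup == "K1a1b1a")
  band <- qbinom(c(0.005, 0.995), 1000, 0.7)
  expect_gte(k, band[1])
  expect_lte(k, band[2])
})

test_that("generation is fully deterministic under the spec seed", {
  spec <- default_synthetic_spec(seed = 6, n_per_population = 25)
  g1 <- generate_mt_population(spec, "ashkenazi_like")
  g2 <- generate_mt_population(spec, "ashkenazi_like")
  expect_identical(g1$truth, g2$truth)
  expect_identical(lapply(g1$db$profiles, `[[`, "variants"),
                   lapply(g2$db$profiles, `[[`, "variants"))
  c1 <- generate_case_set(spec, "ashkenazi_like", k = 5)
  c2 <- generate_case_set(spec, "ashkenazi_like", k = 5)
  expect_identical(c1$truth, c2$truth)
})

test_that("private variants avoid diagnostic positions", {
  spec <- default_synthetic_spec(seed = 8, n_per_population = 60,
                                 lambda_private = 2)
  gen <- generate_mt_population(spec, "ashkenazi_like")
  diag_pos <- sort(unique(vapply(
    unlist(spec$tree$cumulative), function(t) parse_variant(t)$position,
    integer(1))))
  for (i in seq_along(gen$db$profiles)) {
    founder <- spec$founders[[gen$truth$haplogroup[i]]]
    private <- setdiff(gen$db$profiles[[i]]$variants$token,
                       founder$variants$token)
    if (length(private) > 0L) {
      pos <- vapply(private, function(t) parse_variant(t)$position,
                    integer(1))
      expect_false(any(pos %in% diag_pos))
    }
  }
})

test_that("zero stepwise mutation reproduces Y-STR founders exactly", {
  spec <- default_synthetic_spec(seed = 9, n_per_population = 30,
                                 mu_smm = 0)
  gen <- generate_ystr_population(spec, "ashkenazi_like")
  for (i in seq_along(gen$haplotypes)) {
    founder <- spec$ystr_founders[[gen$truth$haplogroup[i]]]
    expect_equal(gen$haplotypes[[i]]$alleles, founder$alleles)
  }
  # a population founded on the CMH with mu = 0 is all full matches
  spec$populations$ashkenazi_like$y_freqs <- c(J_like = 1, R1a_like = 0)
  gen_j <- generate_ystr_population(spec, "ashkenazi_like")
  classes <- vapply(gen_j$haplotypes, classify_cmh, character(1))
  expect_true(all(classes == "full_match"))
})

test_that("stepwise mutation is directionally symmetric", {
  spec <- default_synthetic_spec(seed = 10, n_per_population = 10000,
                                 mu_smm = 0.3)
  spec$populations$ashkenazi_like$y_freqs <- c(J_like = 1, R1a_like = 0)
  gen <- generate_ystr_population(spec, "ashkenazi_like")
  founder <- spec$ystr_founders$J_like$alleles
  # DYS392 is a single-copy locus so pair re-sorting cannot mask direction
  deltas <- vapply(gen$haplotypes, function(h)
    h$alleles[["DYS392"]] - founder[["DYS392"]], numeric(1))
  se <- sd(deltas) / sqrt(length(deltas))
  expect_lt(abs(mean(deltas)), 3 * se + 1e-12)
})

test_that("invalid specifications are rejected", {
  spec <- default_synthetic_spec(seed = 2, n_per_population = 10)
  bad <- spec$populations
  bad$ashkenazi_like$mt_freqs[1] <- bad$ashkenazi_like$mt_freqs[1] + 0.1
  expect_error(synthetic_spec(bad, spec$founders, spec$tree, 0.1, 10,
                              spec$ystr_founders, 0.02, spec$reference),
               "sum to 1")
  expect_error(default_synthetic_spec(lambda_private = -1), "lambda")
  expect_error(default_synthetic_spec(mu_smm = 0.9), "mu_smm")
  expect_error(generate_mt_population(spec, "nowhere"), "unknown population")
  expect_error(generate_case_set(spec, "ashkenazi_like", k = 0), "k must")
})
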