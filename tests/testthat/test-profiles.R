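test_that("variant tokens parse to their encoded fields", {
  v <- parse_variant("73G")
  expect_equal(v$position, 73L)
  expect_equal(v$kind, "substitution")
  expect_equal(v$base, "G")

  v <- parse_variant("315.1C")
  expect_equal(v$position, 315L)
  expect_equal(v$kind, "insertion")
  expect_equal(v$insert_index, 1L)
  expect_equal(v$base, "C")

  v <- parse_variant("249DEL")
  expect_equal(v$position, 249L)
  expect_equal(v$kind, "deletion")
  expect_true(is.na(v$base))

  # deletion dialect and case normalisation on read; DEL on output
  expect_equal(parse_variant("249-")$token, "249DEL")
  expect_equal(parse_variant("73g")$token, "73G")
})

test_that("the parser rejects exactly the tokens outside the grammar", {
  bad <- c("G73", "73", "", "73GG", "315.0C", "0A", "16570A", "73.1",
           "DEL249", "73 G", "-73", "73..1C")
  for (tok in bad) expect_error(parse_variant(tok), info = tok)

  # fuzz: random strings either parse to a canonical round-trip or error
  set.seed(42)
  alphabet <- c(0:9, "A", "C", "G", "T", ".", "-", "X", "g")
  for (i in 1:200) {
    tok <- paste(sample(alphabet, sample(1:6, 1), replace = TRUE),
                 collapse = "")
    res <- tryCatch(parse_variant(tok), error = function(e) NULL)
    if (!is.null(res)) {
      expect_match(res$token, "^[0-9]+(\\.[0-9]+)?([ACGTN]|DEL)$")
      # re-parsing the canonical token is stable
      expect_identical(parse_variant(res$token), res)
    }
  }
})

test_that("profile records parse and enforce range containment", {
  p <- parse_profile("S1 16024-16365;73-340")
  expect_s3_class(p, "mt_profile")
  expect_equal(nrow(p$variants), 0L)
  expect_equal(format_range_spec(p$coverage), "73-340;16024-16365")

  p2 <- parse_profile("S2 73-340 73G 263G")
  expect_equal(p2$variants$token, c("73G", "263G"))

  expect_error(parse_profile("S3 73-340 16126C"), "16126C")
  expect_error(mt_profile("dup", "73-340", c("100T", "100C")), "multiple")
})

test_that("sequence reconstruction applies differences to the reference", {
  cov <- seq_ranges(73, 340)
  empty <- mt_profile("e", cov)
  expect_equal(profile_to_sequence(empty, REF, cov),
               paste(REF[73:340], collapse = ""))

  sub <- mt_profile("s", cov, "73G")
  expect_equal(profile_to_sequence(sub, REF, seq_ranges(73, 75)),
               paste(c("G", REF[74:75]), collapse = ""))

  del <- mt_profile("d", cov, "249DEL")
  expect_equal(profile_to_sequence(del, REF, seq_ranges(248, 250)),
               paste(c(REF[248], "-", REF[250]), collapse = ""))

  ins <- mt_profile("i", cov, c("315.1C", "315.2A"))
  out <- profile_to_sequence(ins, REF, seq_ranges(314, 316))
  expect_equal(out, paste(c(REF[314], REF[315], "C", "A", REF[316]),
                          collapse = ""))

  expect_error(profile_to_sequence(sub, REF, seq_ranges(50, 80)),
               "not covered")
})

test_that("restriction adjusts coverage, filters variants, is idempotent", {
  p <- cr_profile("q", c("73G", "263G", "16126C"))
  hv1 <- seq_ranges(16024, 16365)
  r <- restrict_profile(p, hv1)
  expect_equal(r$variants$token, "16126C")
  expect_false(attr(r, "empty_coverage"))

  r2 <- restrict_profile(r, hv1)
  expect_equal(r2$variants, r$variants)
  expect_equal(r2$coverage, r$coverage)

  disjoint <- restrict_profile(p, seq_ranges(5000, 6000))
  expect_true(attr(disjoint, "empty_coverage"))
  expect_equal(nrow(disjoint$coverage), 0L)
})

test_that("profile differences are symmetric, zero on identity", {
  w <- seq_ranges(73, 340)
  p <- cr_profile("p", c("73G", "263G"))
  q <- cr_profile("q", c("73G", "263G", "150T"))
  expect_equal(profile_diff(p, p, w)$count, 0L)
  expect_equal(profile_diff(p, q, w)$count, 1L)
  expect_equal(profile_diff(p, q, w)$variants,
               profile_diff(q, p, w)$variants)
  # restriction never creates differences inside the window
  expect_equal(profile_diff(p, restrict_profile(p, w), w)$count, 0L)
  # N bases are missing data, not differences
  pn <- cr_profile("pn", c("73G", "263G", "155N"))
  expect_equal(profile_diff(p, pn, w)$count, 0L)
  expect_error(profile_diff(p, cr_profile("short"), seq_ranges(1, 50)),
               "not covered")
})

test_that("profile tables round-trip through TSV", {
  profs <- list(cr_profile("a", c("73G", "315.1C")), cr_profile("b"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_profile_table(profs, path, population = "pop1")
  back <- read_profile_table(path)
  expect_equal(length(back$profiles), 2L)
  expect_equal(back$profiles[[1L]]$variants$token, c("73G", "315.1C"))
  expect_equal(unique(back$table$population), "pop1")
  db <- read_haplotype_db(path)
  expect_equal(db$population, "pop1")
  expect_equal(db$n, 2L)
})
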