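test_that("the CMH reference matches itself and printed neighbours score 2 and 3", {
  ref <- cmh_reference()
  m <- cmh_mismatch_count(ref)
  expect_equal(m, list(mismatches = 0L, compared = 12L, missing = 0L))
  expect_equal(classify_cmh(ref), "full_match")

  n1 <- parse_cmh_string("14-15-23-10-11-12-13/15-13-30-11-13", "n1")
  n2 <- parse_cmh_string("14-16-23-10-11-12-13/17-13-31-11-11", "n2")
  expect_equal(cmh_mismatch_count(n1)$mismatches, 2L)
  expect_equal(cmh_mismatch_count(n2)$mismatches, 3L)
  expect_equal(classify_cmh(n1), "close_neighbour")
  expect_equal(classify_cmh(n2), "close_neighbour")
})

test_that("pair loci compare as multisets, invariant to input order", {
  a <- ystr_haplotype("a", c(DYS385a = 15, DYS385b = 13, DYS19 = 14))
  b <- ystr_haplotype("b", c(DYS385a = 13, DYS385b = 15, DYS19 = 14))
  expect_equal(a$alleles, b$alleles)
  expect_equal(cmh_mismatch_count(a)$mismatches,
               cmh_mismatch_count(b)$mismatches)
  # both pair members equal the reference pair {13, 15}
  expect_equal(cmh_mismatch_count(a)$mismatches, 0L)
})

test_that("mismatch accounting always totals twelve loci", {
  set.seed(91)
  ref <- cmh_reference()
  for (i in 1:25) {
    keep <- sample(names(ref$alleles), sample(1:12, 1))
    alleles <- ref$alleles[keep] +
      sample(c(-1, 0, 1), length(keep), replace = TRUE)
    h <- ystr_haplotype("h", alleles)
    m <- cmh_mismatch_count(h)
    matches <- m$compared - m$mismatches
    expect_equal(m$mismatches + matches + m$missing, 12L)
    expect_equal(m$missing, 12L - length(keep))
  }
})

test_that("classification thresholds and monotonicity hold", {
  ref <- cmh_reference()
  few <- ystr_haplotype("few", ref$alleles[1:4])
  expect_equal(classify_cmh(few), "insufficient")

  far <- ystr_haplotype("far", ref$alleles + 2)
  expect_equal(classify_cmh(far), "other")

  # adding a typed matching locus never moves a haplotype away from
  # full_match (rank: insufficient < other < close_neighbour < full_match)
  rank <- function(cls) match(cls, c("insufficient", "other",
                                     "close_neighbour", "full_match"))
  set.seed(92)
  for (i in 1:25) {
    keep <- sample(names(ref$alleles), sample(1:11, 1))
    alleles <- ref$alleles[keep] +
      sample(c(-1, 0, 1), length(keep), replace = TRUE,
             prob = c(0.15, 0.7, 0.15))
    h <- ystr_haplotype("h", alleles)
    add <- sample(setdiff(names(ref$alleles), keep), 1)
    h2 <- ystr_haplotype("h2", c(alleles, ref$alleles[add]))
    expect_gte(rank(classify_cmh(h2)), rank(classify_cmh(h)))
  }
})

test_that("panel coverage counts shared loci", {
  cmh <- cmh12_panel()
  expect_equal(panel_coverage(cmh, cmh), 12L)
  expect_equal(panel_coverage(yfiler_plus_panel(), cmh), 10L)
  expect_equal(panel_coverage(marker_panel("x", c("DYS999")), cmh), 0L)
  # the two CMH loci absent from the 27-locus kit are DYS388 and DYS426
  expect_equal(setdiff(cmh$loci, yfiler_plus_panel()$loci),
               c("DYS388", "DYS426"))
})

test_that("the frequency scorer ranks the generating reference set first", {
  ref <- cmh_reference()
  other <- ystr_haplotype("o", ref$alleles + 5)
  refsets <- list(J = lapply(1:20, function(i)
    ystr_haplotype(paste0("j", i), ref$alleles)),
    R = lapply(1:20, function(i)
      ystr_haplotype(paste0("r", i), other$alleles)))
  res <- ystr_assign(ref, refsets)
  expect_equal(res$predicted, "J")
  expect_equal(res$scores$haplogroup[1L], "J")

  # identical reference sets cannot be told apart
  same <- list(A = refsets$J, B = refsets$J)
  expect_equal(ystr_assign(ref, same)$predicted, "ambiguous")

  expect_error(ystr_assign(ref, list()), "named list")
})

test_that("stepwise-mutation draws are assigned back to their haplogroup", {
  spec <- default_synthetic_spec(seed = 23, n_per_population = 150)
  a <- generate_ystr_population(spec, "ashkenazi_like")
  b <- generate_ystr_population(spec, "polish_like")
  all_h <- c(a$haplotypes, b$haplotypes)
  truth <- rbind(a$truth, b$truth)
  refsets <- split(all_h, truth$haplogroup)
  case <- generate_ystr_population(spec, "ashkenazi_like", n = 50,
                                   seed = 12345)
  pred <- vapply(case$haplotypes, function(h)
    ystr_assign(h, refsets)$predicted, character(1))
  expect_gte(mean(pred == case$truth$haplogroup), 0.9)
})

test_that("Y-STR tables round-trip and reports summarise classes", {
  ref <- cmh_reference()
  n1 <- parse_cmh_string("14-15-23-10-11-12-13/15-13-30-11-13", "n1")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_ystr_table(list(ref, n1), path)
  back <- read_ystr_table(path)
  expect_equal(back[[1L]]$alleles, ref$alleles)
  expect_equal(back[[2L]]$alleles, n1$alleles)

  rep <- cmh_report(list(ref, n1))
  expect_equal(rep$class, c("full_match", "close_neighbour"))
  expect_equal(rep$mismatches, c(0L, 2L))
})
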