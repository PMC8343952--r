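#!/usr/bin/env Rscript
# Step 1 — simulate the two reference populations and the case set.
#
# The study design: two reference panels with distinct haplogroup spectra
# (an "Ashkenazi-like" panel concentrated on eight fine subclades and a
# "Polish-like" panel concentrated on other common European clades, 5%
# spectral overlap), 500 records each, plus ten case queries drawn from the
# Ashkenazi-like population. Everything is written in the same TSV formats
# the pipeline reads back.

suppressMessages(library(lineagekit))
seed <- 1L
dir.create("results", showWarnings = FALSE)

spec <- default_synthetic_spec(seed = seed)
a <- generate_mt_population(spec, "ashkenazi_like")
b <- generate_mt_population(spec, "polish_like")
case <- generate_case_set(spec, "ashkenazi_like", k = 10)

write_profile_table(a$db$profiles, "results/db_ashkenazi_like.tsv",
                    population = "ashkenazi_like")
write_profile_table(b$db$profiles, "results/db_polish_like.tsv",
                    population = "polish_like")
write_profile_table(case$profiles, "results/case_profiles.tsv")
write_ystr_table(case$ystr, "results/case_ystr.tsv")
write.csv(rbind(a$truth, b$truth), "results/reference_truth.csv",
          row.names = FALSE)
write.csv(case$truth, "results/case_truth.csv", row.names = FALSE)
write_reference_fasta(spec$reference, "results/reference_synthetic.fasta",
                      name = "synthetic_mt_reference")

counts <- table(c(a$truth$haplogroup, b$truth$haplogroup),
                rep(c("ashkenazi_like", "polish_like"), each = 500))
cat("Simulated", a$db$n + b$db$n, "reference records (seed", seed, ")\n")
cat("Founder haplogroup counts per population:\n")
print(counts)
cat("Case queries:", nrow(case$truth), "drawn from ashkenazi_like\n")
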