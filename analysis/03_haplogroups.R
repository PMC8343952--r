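#!/usr/bin/env Rscript
# Step 3 — haplogroup assignment and relative-frequency profiles.
#
# Every case query and reference record is assigned to the best-scoring
# haplogroup of the diagnostic-variant tree; the per-population frequency
# profiles show how the case haplogroups separate the two panels.

suppressMessages(library(lineagekit))

tree <- lineagekit_haplogroup_tree()
case <- read_profile_table("results/case_profiles.tsv")$profiles
db_a <- read_haplotype_db("results/db_ashkenazi_like.tsv")
db_b <- read_haplotype_db("results/db_polish_like.tsv")

calls <- data.frame(
  sample_id = vapply(case, `[[`, character(1), "sample_id"),
  haplogroup = vapply(case, function(p) assign_haplogroup(p, tree)$best,
                      character(1)))
write.csv(calls, "results/case_haplogroups.csv", row.names = FALSE)
cat("Case haplogroup calls:\n")
print(calls)

groups <- c("K1a1b1a", "K2a2a1", "H3p", "HV1b2", "I1c1a", "J1c14", "V7a",
            "X2b7", "U5a1", "U5b1b", "T2b", "H1", "W6", "N1b")
freq <- do.call(rbind, lapply(list(db_a, db_b), function(db) {
  out <- haplogroup_frequency_profile(db, tree, groups)
  out$population <- db$population
  out
}))
write.csv(freq, "results/haplogroup_frequencies.csv", row.names = FALSE)
cat("\nRelative frequencies of the case-associated subclades:\n")
case_groups <- groups[1:8]
sub <- freq[freq$group %in% case_groups, ]
print(tapply(sub$frequency, sub$population, sum))
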