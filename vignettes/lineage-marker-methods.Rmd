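---
title: "Methods: lineage-marker ancestry assessment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lineage-marker ancestry assessment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lineagekit)
```

This vignette is the package's own account of its models and the design
choices behind them: what each stage computes, which parameters matter and
why their defaults are what they are, what the synthetic generator does and
does not emulate, and the known limitations.

## Mitotypes as reference-coded profiles

Forensic mtDNA data are exchanged as *differences to the rCRS* over declared
sequence ranges, not as raw sequences. A profile (`mt_profile`) is a sample
id, a sorted set of variants — substitutions (`73G`), insertions (`315.1C`,
the `.1` indexing the slot after the anchor) and deletions (`249DEL`; the
`-` dialect is accepted on input) — and a coverage given as non-overlapping
1-based inclusive ranges on the 16,569-bp mitochondrial reference, used
linearly (the analyses here involve only the control region and linearly
coded mitogenomes, so circular wrap-around is deliberately unsupported).
`N` bases denote missing information and are excluded from matching and
distances.

Two conventions are worth stating because the field does not fix them:

- **Insertion placement is taken literally.** Insertions around the
  homopolymeric stretches (309/315, 16193) are kept at their reported
  (position, index) slots; no phylogenetic realignment of indels is
  attempted. Users comparing data from sources with different conventions
  should normalise upstream.
- **Alignment without an aligner.** Since every profile is coded against
  the same reference, a multiple alignment over a common window is obtained
  by applying each profile's differences to the reference substring and
  expanding the union of observed insertion slots into shared columns
  (gap-filled where absent); deletions stay as gap columns. This makes the
  phylogenetic stage independent of any alignment heuristic.

## Database matching and the two-population contrast

A database record is *comparable* to a query over a window only when its
coverage contains the window entirely; `n` counts comparable records, `x`
counts those identical to the query there (zero symmetric difference). This
"drop partially covering records" rule is the conservative reading of
range-adjusted searching: the alternative — intersecting the window per
record — keeps more records but makes their match counts incomparable, so
it is available (`partial = "intersect"`) but not the default. The same
reasoning governs mixed-resolution panels (e.g. one panel lacking HVS-III):
the comparison window is shrunk to what both sides cover, rather than
trimming the database.

The haplotype frequency estimate is the augmented count
$(x + 1)/(n + 1)$ — never zero for unobserved haplotypes, exactly 1 when
every record matches. The contrast of two populations is the ratio of these
probabilities, reported in user-declared numerator/denominator order, with
an explicit `"tie"` category when the probabilities are equal (ties are
never silently broken, because with equal panel sizes an unmatched query is
genuinely uninformative). No confidence intervals or substructure
corrections are applied: the estimator is the plain augmented count by
design.

## Haplogroup assignment

The haplogroup engine is a transparent diagnostic-variant scorer, not a
re-implementation of any curated service. A haplogroup tree carries, per
node, the variants acquired on its incoming branch; the expected set of a
node is the union along the root path. For a profile,

- `matched` = expected diagnostics observed,
- `missing` = expected diagnostics whose position the profile covers but
  does not show,
- `score = matched − missing`, with unit weights (configurable); private
  variants are reported but unscored, since a private variant is evidence
  of lineage depth, not of misassignment.

Diagnostics at uncovered positions count for neither term, so partial
profiles are never penalised for what they could not see. Ties go to the
deeper node, then alphabetically — matching the forensic practice of
reporting the finest supportable subclade. The shipped tree
(`inst/extdata/haplogroups_synthetic.tsv`) is a small curated fixture with
*synthetic* diagnostics covering the case-relevant fine subclades, their
ancestors and several other common European clades; importing a full
phylogenetic reference is an extension point, not a dependency.

## The Tamura 3-parameter stage

The phylogeographic analysis uses the T92 substitution model throughout: it
distinguishes transitions from transversions (ratio $\kappa$) and models
base composition through the G+C content $\theta$ (stationary frequencies
$\pi_G = \pi_C = \theta/2$). With $h = 2\theta(1-\theta)$ and transition /
transversion fractions $P, Q$ over compared sites, the pairwise distance is

$$d = -h \ln\!\left(1 - P/h - Q\right) - \tfrac{1}{2}(1-h)\ln(1 - 2Q).$$

At $\theta = 1/2$ this is exactly Kimura's two-parameter distance. Choices
and their rationale:

- $\theta$ is estimated **once from the whole alignment** (default), since
  mitochondrial windows share composition; per-pair estimation is a flag.
- Sites with gaps or `N` in either sequence are excluded per pair
  (pairwise deletion, default) or globally (complete deletion, by flag).
- A distance whose logarithm argument is non-positive is a **saturation
  error naming the pair**, never infinity — saturated control-region pairs
  indicate an input problem in this application.
- No rate heterogeneity (+G) is modelled: the model is plain T92.

Starting topologies come from neighbour-joining (classic Q criterion, via
`ape::nj`) and BioNJ. BioNJ is implemented in the package in double
precision (Gascuel's variance-weighted reduction, variances initialised to
the distances, pair selection by the Q criterion, reduction weight
$\lambda$ clamped to $[0,1]$): both methods then reduce additive matrices
exactly, which the tests verify to $10^{-9}$. Negative branch-length
estimates are clamped to zero with a warning.

The log-likelihood is computed by Felsenstein pruning with per-column
rescaling and weighted site patterns; gaps and `N` are missing data
(partial likelihood one in every state), so an all-missing column
contributes exactly zero log-likelihood. Transition probabilities come from
the spectral decomposition of the reversible rate matrix, normalised to one
expected substitution per unit branch length. Branch lengths are optimised
coordinate-wise (bounded scalar search on $[0, 10]$ substitutions/site,
sweeps until the gain drops below $10^{-6}$ or 20 sweeps), and $\kappa$ by
scalar search on $[0.1, 100]$ (initial value 4), alternating with branch
sweeps. Candidate topologies are exactly the NJ and BioNJ trees — no
NNI/SPR search, mirroring an initial-trees-then-pick-the-better-likelihood
procedure; a heuristic search would be an extension point.

Per query, the clade report takes the smallest non-trivial containing clade
(the query's immediate ancestor), tallies the population labels of its
co-members and calls the majority, `"mixed"` on a balanced split,
`"unresolved"` when all co-members are themselves unlabelled queries.

## Y-STR scoring

The extended Cohen Modal Haplotype is fixed at 12 loci; the hyphenated
string `14-16-23-10-11-12-13/15-13-30-11-12` is mapped to the locus list
order DYS19, DYS388, DYS390, DYS391, DYS392, DYS393, DYS385a/b, DYS389I,
DYS389II, DYS426, DYS439 — an explicitly documented assumption (the
hyphen notation itself does not name loci), consistent with every haplotype
handled here. DYS389II is stored as reported by kits (not
DYS389I-subtracted). Multi-copy loci are compared as multisets, so the
reported order of a pair never matters. Classification: `full_match` (all
12 typed, 0 mismatches), `close_neighbour` (1–`neighbour_max` mismatches,
at most 2 untyped; the neighbour threshold defaults to 3 and is
configurable, since "close neighbour" has no universal cutoff),
`insufficient` (fewer than 10 typed), otherwise `other`.

The Y haplogroup scorer is deliberately simple and transparent — the mean,
over shared typed loci, of the add-one-smoothed empirical frequency of the
observed allele in each reference set, with an explicit `"ambiguous"` call
when the top two scores are within 5% relative — in place of proprietary
predictors whose internals cannot be reproduced.

## The synthetic study generator

The generator emulates the statistical structure the analysis assumes: two
reference populations with distinct haplogroup frequency spectra over a
shared founder set, and case queries drawn from one of them. Defaults (the
study conditions for all end-to-end tests):

- **Populations.** `ashkenazi_like` concentrates on eight fine subclades
  (K1a1b1a, K2a2a1, H3p, HV1b2, I1c1a, J1c14, V7a, X2b7; frequencies
  0.20/0.15/0.125/0.125/0.10/0.10/0.10/0.10); `polish_like` concentrates on
  U5b1b, U5a1, T2b, H1, W6, N1b (0.25/0.20/0.20/0.15/0.10/0.05) with 5%
  mass on K1a1b1a. Spectral overlap is thus 5% — fine subclades that are
  frequent in one population and rare in the other.
- **Panel sizes.** 500 records per population and 10 case queries — large
  enough for stable frequency contrasts, small enough that every test and
  script runs in minutes on one CPU (the vignette-level phylogenetic stage
  additionally subsamples 12 records per population, as a study at this
  scale would work with a representative mitogenome subset).
- **Private variation.** Each record adds Poisson(λ = 0.05) private
  substitutions at uniform covered positions, never on a diagnostic
  position. Fine subclades are young: most members carry the modal
  control-region motif unchanged, which is also what makes forensic
  database searches of such haplotypes productive. λ is per lineage over
  HV1+HV2, in expected substitutions.
- **Y-STR.** Founders at the CMH (`J_like`) and a well-separated haplotype
  (`R1a_like`, most loci differing); each locus mutates ±1 repeat with
  probability μ = 0.02 per draw (single-step model, fair direction), a
  deliberately generous per-generation-scale rate that still keeps founder
  recovery above 90%.
- **Determinism.** All draws flow from one integer seed through named
  sub-seeds per stage (`derive_seed`), so any stage can be regenerated
  independently and byte-identically.

What the generator does **not** emulate: coalescent genealogy within
haplogroups (records are independent draws around founders), recurrent or
back mutation, locus-specific Y-STR mutation rates, heteroplasmy, and
database curation artefacts. Passing end-to-end tests therefore show that
the *pipeline* recovers the structure it assumes — they are not evidence
about any real population, and real reference panels (with their own
coverage quirks and shared ancestry) remain harder than this synthetic
setting. The shipped 16,569-bp reference sequence is likewise a
deterministic synthetic stand-in; analyses of real profiles must load the
true reference FASTA.

## Numerical and degenerate-input choices

- Augmented counting requires $n \ge 1$; an empty comparable set is an
  explicit error naming the failing population, not a probability.
- Restriction to a disjoint window yields a flagged empty-coverage profile
  rather than a silent empty object.
- Likelihood rescaling is per column at every internal join, so hundreds of
  taxa do not underflow; site patterns are collapsed with weights.
- Branch optimisation never accepts a decrease (each scalar step keeps the
  better of old and new), so the log-likelihood trace is monotone by
  construction.
- With many identical sequences (common in control-region data), distance
  matrices are highly degenerate: NJ/BioNJ then resolve zero-length
  polytomies arbitrarily and may propose slightly negative branches, which
  are clamped to zero with a warning. Clade calls for queries inside such
  polytomies can be `"unresolved"`; this is reported, not hidden.

## Known limitations

- The haplogroup fixture is synthetic; results on real data require a real
  diagnostic table (same TSV format).
- Clade-label calls summarise local tree structure only; they are not a
  formal assignment test.
- The two-population contrast compares exactly two panels; multi-population
  contrasts are compositions of pairwise ones.
- Heteroplasmy codes, sequence-to-profile alignment and variant calling
  from reads are out of scope: profiles are the input format.
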