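---
title: "Methods: branch-specific substitution rates and deviation tests"
author: "apeClock"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: branch-specific substitution rates and deviation tests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apeClock)
```

## The model

`apeClock` tests the molecular-clock null model of protein evolution on
four ape species. The tree is fixed:
`((Human,Chimpanzee)Internal, Gorilla, Gibbon)`. Five branches carry
substitutions: the four tips and the internal branch subtending
human+chimpanzee. With no outgroup, the deeper internal branch (the
human+chimp+gorilla stem) cannot be polarised and is absorbed into the
gibbon branch — every gibbon-branch quantity in this package implicitly
contains it.

The unit of observation is an ortholog family: four homologous proteins,
one per species, aligned and reduced to gap-free conserved blocks. The
kept-column count `L` (*alignment overlap*) is the denominator of all
per-site statistics. Columns are classified by their residue pattern; a
*branch-specific substitution* is a column explained by exactly one event:
three identical residues and one deviant (a tip branch), or
human = chimpanzee differing from gorilla = gibbon (the internal branch).
Columns requiring two or more events — phylogenetically inconsistent
two-state patterns, three-state patterns, and four-state ("no identity")
columns — are tallied but never attributed to a branch. This is
deliberately conservative: convergent substitution is negligible at these
divergences, and inconsistent patterns mostly reflect incomplete lineage
sorting or introgression, which would bias rate estimates if forced onto
branches. Consistent three-state columns (e.g. a human=chimp pair with
gorilla and gibbon each unique) are also excluded from branch counts even
though they admit a parsimonious placement, because the branch-specific
definition requires a single substitution per column; the package's
aggregate accounting (branch-specific = species-specific + internal) is
only consistent under that exclusion.

Per family, the per-branch counts `n_b` give

* `% substitutions per site` = `100 n / L`,
* Poisson-corrected branch lengths `PC_b = -ln(1 - n_b / L)`, the standard
  multiple-hit correction (always `>= n_b / L`; undefined when `n_b = L`,
  in which case the family is excluded with a logged saturation error
  rather than clamped — such saturation cannot occur at ape divergences on
  any family long enough to pass the block filter),
* relative branch lengths `n_b / N` with `N = sum(n_b)`, at the dataset
  level the branch's share of all branch-specific substitutions.

The *mean tree* is the per-branch arithmetic mean of `PC_b` over families
with `N >= 1`; zero-substitution families carry no branch-length
information and are excluded (their number is reported separately).

## The two deviation tests

**RF score Z-test.** A family's branch-length-aware Robinson–Foulds score
against the mean tree is the L1 distance
`z_i = sum_b |PC_b - PCbar_b|`. Its variance is estimated by a column
bootstrap: each of `B = 1000` replicates resamples the family's `L` kept
columns with replacement, reclassifies them and recomputes `z_ib`;
`V(z_i)` is the sample variance with the `B - 1` denominator. The mean
tree is held fixed across replicates: it is estimated from thousands of
families, so its own resampling variance is negligible next to the
single-family variance. Because `z_ib` depends on a replicate only through
its per-branch counts, the bootstrap is drawn directly as a multinomial
over the six column classes (five branches + everything else), which is
distributionally identical to resampling column indices and considerably
faster. Replicates that saturate a branch (`n_b = L`) are discarded and
counted; a family with more than 10 % discarded replicates is aborted.
`Z = z_i / sqrt(V)` is referred to the standard normal, two-sided (the
question is "different from the average", not "larger"), and
Benjamini–Hochberg FDR is applied across families. Degenerate families
with `V = 0` get `p = 1` when `z_i = 0` and are flagged untestable
otherwise, never assigned `p = 0`.

**Multinomial branch test.** The RF score cannot distinguish a uniformly
fast family from a lineage-specific burst. For that, each family's `N`
branch-specific events are compared with a conditional null: `S = 100000`
multinomial draws of `N` events over the five branches, with probabilities
equal to the dataset-level relative branch lengths. The null depends only
on `N`, so it is built once per distinct `N` and cached. Per branch, the
two-tailed empirical rank p-value is
`p = min(1, 2 min(Pr[X <= n_b], Pr[X >= n_b]))`, the observed value
included in both tails — the standard doubling convention; the smallest
attainable p is `1/S`. Bonferroni correction for the five branches tested
per family is applied as a fixed threshold comparison,
`p < 0.05 / 5 = 0.01`, not as p-value multiplication. Direction is the
sign of `n_b - N p_b`.

A consequence of conditioning on `N` worth knowing: a genuine burst on one
branch inflates `N`, which deflates every other branch's conditional
expectation `N p_b`. Families with a strong burst therefore often carry a
legitimate *slower* flag on the longest other branch (mostly gibbon). This
is not a false positive — it mirrors the published observation of dozens
of families slow on gibbon and fast elsewhere — and the package's recovery
test accordingly demands that *faster* flags land only on the shifted
branch.

## The simulator and what it does (not) emulate

`simulateFamily()` draws an ancestral protein (uniform over the 20
residues), then gives every column x branch an independent substitution
event with probability `rate_b x multiplier x fold`. Internal-branch
events replace the human and chimpanzee residues identically; tip events
replace the tip's current residue with a uniformly chosen different one,
so multiple hits on a column produce inconsistent and no-identity patterns
naturally, with no separate homoplasy knob. Ground truth records the event
matrix and the per-branch count of columns hit by exactly one branch.

Default parameters are the study conditions of the genome-wide ape
dataset: branch rates equal to the aggregate per-site substitution
frequencies (0.0027, 0.0026, 0.0009, 0.0036, 0.0134 for human,
chimpanzee, internal, gorilla, gibbon), and a gamma-distributed per-family
rate multiplier with mean 1. The gamma *shape defaults to 2* (CV ≈ 0.7):
the real data show most substituted families departing significantly from
the mean tree, so family-rate heterogeneity must be substantial; shape 2
reproduces that qualitative regime while keeping rates positive and
unimodal. `familyShape = Inf` disables heterogeneity for calibration
tests. Ancestral lengths are uniform on 100–1000 residues (the real
families average ≈ 580). Indels are single-species deletion runs with
geometric length of mean 3, started per column with probability
`indelRate`; they exist to exercise the gap-removal filter, not to model
real indel processes. Episodic shifts multiply one branch's rate by
`episodicFold` in a designated fraction of families.

The simulator deliberately does **not** model amino-acid exchangeability
(replacements are uniform over the 19 alternatives — the statistics
measure identity only), codon structure, selection, alignment error, or
rate variation across sites within a family. Passing tests on synthetic
data therefore validate the counting, correction and testing machinery,
not the realism of any biological rate model; on real data the block
filter and the inconsistent-category exclusions are the guards against
alignment artefacts.

Toy genome pairs for the orthology stage are single-chromosome gene orders
with planted non-overlapping inversions (3–6 genes, flipped strand) and
tandem duplicates (adjacent co-located copy with a slightly weaker
homology hit), plus a complete hit table for all true pairs.

## Orthology calling choices

The collinearity caller is a deterministic single-pass chainer, not a
scored dynamic program: anchors (homology hits mapped to gene ranks) are
sorted by query rank within each chromosome pair and scanned once per
orientation; a chain extends while both genomes advance by at most
`maxGap + 1` ranks in the chain's orientation, a violating anchor closes
the chain, and chains shorter than `minGenes` are dropped. Defaults
`minGenes = 3`, `maxGap = 2`. A second hit of an already-chained gene
(rank step 0) is skipped rather than allowed to sever the chain, so
tandem-duplicate anchors do not fragment blocks. Downstream pair vetting
only uses block membership and size, which this chainer reproduces; block
scores and e-values are out of scope.

Pair parsing applies, in order: identity retention (global
Needleman–Wunsch with BLOSUM62, gap open 10, extension 0.5, identity =
identical positions / alignment length, threshold 95 %); removal when
either gene has a *strictly* higher bitscore hit to a third gene (ties do
not remove — the conservative reading of "better"); larger-block
resolution for genes in two blocks (ties keep the first encountered and
are flagged in the output); and tandem-duplicate removal (two same-species
hits from one query at rank distance <= 1). Families are the intersection
of the three human-pivot pair lists.

## Block filter conventions

With exactly four sequences and both the conserved and flanking minima
equal to four, "conserved" collapses to "all four residues identical and
non-gap", and the flanking rule becomes "blocks start and end on conserved
columns". The filter removes every gap-containing column (splitting the
alignment there), removes maximal runs of more than 2 consecutive
non-conserved columns within each gap-free segment (splitting further),
trims segment ends to conserved columns, and drops blocks shorter than 10
columns. The published tool's exact treatment of a non-conserved column
adjacent to a removed gap column is not fully specified by its parameter
list; this reconstruction resolves it by evaluating non-conserved runs
within gap-free segments, so divergence at block margins is possible in
principle. The filter is idempotent, and block boundaries guarantee that
no run of three or more non-conserved columns survives concatenation.
Kept columns are reported 1-based in all tables.

Families with `L = 0` (non-overlapping) are excluded from all downstream
statistics; families with `0 < L < 50` are retained.

## Numerical and reproducibility choices

* All report rounding follows the conventional table precision (4 decimals
  for relative lengths, 2 for percentages, 3 for per-Mya and mean-tree PC
  lengths); internal computation is full precision. The per-Mya column is
  computed from the full-precision per-site rate before rounding — with
  the published totals this yields 0.036 for the internal branch where
  rounding first would give 0.037.
* Branch times (6.65, 6.65, 2.41, 9.06, 31.24 Mya) are a shipped
  configuration profile from TimeTree, not estimates.
* Every stochastic stage takes a seed; per-family and per-N seeds are
  derived deterministically from the master seed, so datasets, bootstraps
  and nulls are bit-reproducible and families are reproducible
  individually.
* The two-tailed empirical p cannot go below `1/S`; at the default
  `S = 100000` this is far below the 0.01 threshold.

## Problem sizes used in the validation suite

The test suite validates the statistical guarantees at desk scale, chosen
so the whole suite runs in well under a minute per heavy check: the
null-vs-binomial oracle on the full grid `N = 1..100` x 5 branches at
`S = 100000`; type-I control on 2,000 clock families of 500 residues
(family-wise flag rate at the 0.01 threshold bounded by 0.06); and
recovery of a 10-fold episodic shift on 300 gorilla-shifted families of
500 residues, requiring at least 80 % correct-branch faster flags among
families with `N >= 20` and wrong-branch faster flags at the null level.
For the recovery test the null probabilities are passed as the clock
relative branch lengths rather than re-estimated from the half-episodic
toy dataset: at genome scale the episodic subset is a negligible fraction
of the aggregate, but in a deliberately enriched simulation it would
contaminate the null.

## Known limitations

* The orthology module consumes gene orders and precomputed homology hits;
  it does not run BLAST or select isoforms from real annotation files
  (alignment production for real families is likewise upstream of this
  package).
* The inconsistent-site categories flag incomplete lineage sorting or
  introgression but the package makes no attempt to assign causes.
* The multinomial test conditions on `N`, so its "slower" calls on long
  branches partly reflect bursts elsewhere in the same family (see above);
  interpret direction jointly across branches.
* Mean-tree values are family averages and depend on the exact family set;
  they are reported, not asserted against any external reference.
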