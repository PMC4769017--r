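---
title: "Activation-loop motif discovery and evolution statistics: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Activation-loop motif discovery and evolution statistics: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mapkloop)
```

## The problem

MAPK catalytic domains share two strongly conserved stretches flanking the
activation segment: the catalytic-loop motif `H-R-D-L-K-P-N` on the
N-terminal side and the APE-region motif `T-R-W-Y-R-A-P` on the C-terminal
side. Between them sits the phospho-acceptor triplet — canonically T-E-Y or
T-G-Y in fungi — whose dual phosphorylation activates the kinase. `mapkloop`
locates those anchors in unaligned protein sequences, extracts the triplet,
classifies it against a motif catalog, and provides the two statistics most
often used to characterise the evolution of the resulting gene family on
amino-acid alignments: Tajima's test of neutrality and Tajima's
relative-rate test.

## Pattern engine

Patterns use PROSITE syntax: dash-separated elements that are literal
residues, `[..]` ambiguity sets, `{..}` exclusions, or `x` wildcards, each
optionally repeated `(i)` times or over a range `(i,j)`. Parsing is strict —
unbalanced brackets, empty sets and inverted ranges are reported with their
character offset — and every pattern re-serialises to a canonical form
(sorted set members, unit repeats omitted), so catalogs round-trip through
text configs.

Matching reports *every* span that satisfies the pattern, 1-based inclusive,
sorted by start and then by length. Two semantics matter:

* **Mismatch counting is per fixed-length element position.** A fixed repeat
  such as `A(3)` is expanded into three unit elements, each of which can be
  violated independently; a violated element costs one unit of the budget.
  Wildcards cannot be violated, and variable-range elements (`x(2,4)`) must
  match exactly — a mismatch inside a stretch of unknown length has no
  well-defined register.
* For one span reachable through several registers, the minimal mismatch
  count is reported.

During development the zero-mismatch engine was checked against an
exhaustive substring oracle driven by independently rendered regular
expressions; that check is frozen as a property test.

## Anchoring and triplet extraction

`find_kinase_domain()` matches both anchors with a per-anchor mismatch
budget (default 2 violated elements) and pairs each N-anchor hit with its
nearest downstream C-anchor hit that leaves room for a triplet. Within the
open region between a pair, triplet candidates are positions `i` with
`residue(i)` in the allowed first-residue set and `residue(i+2) = Y`; the
third position is always the phospho-acceptor tyrosine, so it is fixed,
while the first position defaults to `{T, S, K}` — every catalogued motif
begins with one of these — and can be widened to all 20 residues for
exploratory scans.

Several candidates can occur in one loop. The selection rule is: prefer
candidates whose *gap* (residues strictly between the triplet end and the
C-anchor start) falls inside the catalog's offset window, default 4–14
residues, a heuristic reflecting how close the T-x-Y sits to the APE region
in kinase domains; among those take the candidate closest to the C anchor;
if none is in the window, take the closest overall; break remaining ties
leftmost. The window and the rule are deliberate conventions — motif
databases do not define how to reduce multiple candidate triplets to one —
and both are configurable through `anchor_catalog()`.

When a protein carries more than one anchored domain, all are reported and
the pair with the fewest total anchor mismatches (then leftmost) is flagged
primary.

## Consensus annotation

`consensus_annotation()` implements the common two-level consensus
convention for alignment figures: per column, the frequency of the most
frequent non-gap residue over the non-gap entries is mapped to `high`
(default ≥ 90%), `low` (≥ 50%) or `none`. Gaps are excluded from the
denominator — consensus is a statement about the residues present — and
ties go to the alphabetically smallest residue so output is deterministic.
All-gap columns are `none`.

## Tajima's test of neutrality

For `m ≥ 4` aligned sequences, let `S` be the number of segregating sites,
`p_s = S/n`, and `k̄` the mean number of pairwise differences. With
`a₁ = Σ_{i=1}^{m−1} 1/i`, `a₂ = Σ 1/i²`,
`b₁ = (m+1)/(3(m−1))`, `b₂ = 2(m²+m+3)/(9m(m−1))`,
`c₁ = b₁ − 1/a₁`, `c₂ = b₂ − (m+2)/(a₁m) + a₂/a₁²`,
`e₁ = c₁/a₁`, `e₂ = c₂/(a₁²+a₂)`:

```
D = (k̄ − S/a₁) / sqrt(e₁ S + e₂ S (S − 1))
```

Conventions, chosen to match how the statistic is reported for protein
alignments:

* **Gap handling.** `k̄` uses pairwise deletion (each pair compared over
  the sites where both carry a residue); `S` is counted per column over the
  non-missing residues. The ambiguity codes X, B and Z are treated as
  missing, the conservative reading. A complete-deletion mode and a
  per-column coverage pre-filter (`min_coverage = 0.95` drops columns with
  more than 5% missing entries) are available.
* **Per-site quantities.** `π = k̄/n` and `Θ = p_s/a₁` are per-site; the
  sign of D is therefore determined by whether `π` exceeds `Θ` — positive
  when intermediate-frequency variation is in excess, negative when rare
  variation is.
* **Summary entry point.** `tajima_d_from_summary(m, S, n, pi)` recomputes
  D from published summary rows with `k̄ = π·n`; when a table prints `p_s`
  but not `n`, the site count is reconstructed as `n = round(S/p_s)`.
* Degenerate inputs error: `m < 4` (the variance coefficients need four
  sequences) and `S = 0` (the statistic is undefined).

The implementation is tested against a brute-force oracle that re-derives
everything by direct enumeration of pairs and columns on small random
alignments (1000 draws with `m ≤ 6`, `n ≤ 12`, with and without gaps).

## Tajima's relative-rate test

For three sequences — ingroup A and B, outgroup C — the columns surviving
complete deletion partition exhaustively into: identical in all three;
unique difference in A (`B = C ≠ A`); unique in B; unique in C; and fully
divergent. Rate equality of A and B is tested by

```
χ² = (n_A − n_B)² / (n_A + n_B),  df = 1
```

on the unique-difference counts, with the upper-tail probability from the
χ² distribution (for df 1 this equals `erfc(sqrt(x/2))`). When
`n_A + n_B = 0` there is no information about rates; the package returns
χ² = 0, p = 1 with an explicit flag rather than an error, since the
situation is legitimate for identical sequences.

## Neighbor joining

`p_distance_matrix()` derives per-pair p-distances from the same
pairwise-difference machinery, and `nj_tree()` wraps standard neighbor
joining, clamping the occasional negative branch length to zero and
emitting newick. This is plumbing: it gives downstream group assignment
(clade labels A–D for `summarize_by_group()`) something to operate on, but
group labels themselves are always assigned by the caller — model-based
phylogenetics is out of this package's scope.

## Synthetic data: what it emulates, and what it does not

`gen_kinase_cohort()` builds proteins as
`background + N-anchor + loop + triplet + spacer + C-anchor + background`,
with the spacer length drawn inside the offset window and the loop and
spacer free of tyrosine so the planted triplet is the unique candidate;
anchor mutations are planted on request. Composed records are rejected and
redrawn if the anchors are findable anywhere except the planted spans at a
mismatch budget of 2, so recovery by a scanner with at least the
generator's budget is exact by construction. The default cohort
(`default_cohort()`) covers all nine novel motifs in the divisions where
they occur, alongside the canonical TEY/TGY repertoire, with one to four
MAPKs per species.

`gen_alignment()` mutates a uniform random ancestral sequence independently
per sequence per site (a star genealogy): each site substitutes with the
given probability to one of the 19 alternative residues.
`gen_triple()` constructs three-sequence alignments column-category by
column-category, then shuffles columns; the relative-rate partition of the
output equals the requested one exactly, which is how published count
partitions are turned into runnable inputs.

Limitations to keep in mind when interpreting green tests: backgrounds are
compositionally uniform (real proteomes are not), there is no indel
process, no among-site rate variation, and the star genealogy is not a
coalescent. Passing tests demonstrate the correctness of the machinery on
data whose ground truth is known, not the sensitivity or specificity of the
scan on real proteomes.

### The neutral null for D under a star genealogy

A star genealogy is not neutral-equilibrium data: at low substitution rates
every substitution is private to one lineage, mimicking a population
expansion and biasing D negative, while near saturation recurrent
substitution pushes D positive. The rate at which the two estimators agree
in expectation solves

```
p_diff(r) = p_poly(r, m) / a₁
p_diff = 1 − (1−r)² − r²/19        (expected pairwise difference per site)
p_poly = 1 − (1−r)^m − 19(r/19)^m  (probability a column is polymorphic)
```

`star_neutral_rate(m)` finds this crossing numerically; it is the
star-genealogy analogue of mutation-drift equilibrium. The neutrality
property test simulates 200 replicates at `m = 10`, `n = 300` sites and the
calibrated rate (≈ 0.159) and checks that the mean of D lies within three
standard errors of zero. These sizes keep the whole suite fast while
leaving the standard error of the mean near 0.01, small enough to detect a
meaningful bias.

## Numerical and interface choices

* All reported coordinates are 1-based inclusive; motif labels are stored
  undelimited (`TEY`) and may be rendered dashed only in display.
* Catalog order for report columns is TEY, TGY, remaining canonical
  motifs, then the novel motifs; species rows follow first appearance.
* Paralog suffixes (-A, -B, ...) follow appearance order within a species.
* Verification tolerances against printed reference values: |ΔD| ≤ 1e-3,
  |Δχ²| ≤ 5e-3 (two printed decimals), |Δp| ≤ 1e-4, |ΔΘ| ≤ 1e-5 — the
  precision limits of the printed values themselves.
* Generators take an explicit integer seed and are pure functions of
  (arguments, seed); identical seeds give byte-identical output.
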