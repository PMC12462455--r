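---
title: "Methods: IBD sharing statistics, permutation nulls, and pedigree simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: IBD sharing statistics, permutation nulls, and pedigree simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleoibd)
```

# The analysis problem

Allele-frequency statistics (PCA, f-statistics, qpAdm) resolve ancestry on
the scale of millennia, but they cannot tell whether two groups that carry
the *same* ancestry profile were one mate-exchanging community or two
parallel ones — nor whether a cultural transition was carried by migrants
or adopted in place. Identity-by-descent (IBD) segments can: a block of,
say, 20 cM shared by two individuals implies a common ancestor only a
handful of generations back. `paleoibd` implements the statistics layer on
top of called IBD segments for exactly these questions: within- versus
between-group enrichment, local continuity versus replacement across a
transition, differential source-group contribution, geographically
stratified sharing contrasts, and pairwise kinship.

# Segment handling

**Input contract.** One row per called block per unordered pair:
ids (canonicalized lexicographically), autosome, genetic start/end
(half-open, cM), length, SNP count, and IBD state (`IBD1` = one shared
haplotype, `IBD2` = both). No physical coordinates are needed anywhere.

**Merging.** Haplotype-HMM callers for ancient DNA report a single merged
block where a pedigree simulator reports abutting IBD1/IBD2 runs.
`merge_adjacent_states()` therefore joins same-pair, same-chromosome runs
whose gap is at most `gap_tol_cM` (default 0, i.e. strict adjacency — no
gap tolerance is published for this step, so the conservative choice is the
default and the knob is exposed). Merged state is IBD1 if any constituent
was IBD1; SNP counts are summed; overlaps merge with a warning since
double-counted SNPs cannot be disentangled.

**Filtering.** Retention requires `length ≥ 12 cM` *and*
`n_snps/length ≥ 220 per cM`. Both comparisons are inclusive. The length
boundary is stated both as "longer than 12 cM" and "at least 12 cM" in the
literature this mirrors; we implement the inclusive reading (the
operational, Methods-style phrasing) and expose both thresholds. The 12 cM
floor is a false-positive guard for imputed 1240K-panel genomes; the
density floor removes blocks supported by too few markers.

**Matrix.** The pairwise matrix holds the total retained length per pair,
zero diagonal, symmetric; all group statistics divide by the number of
*possible* pairs, so non-sharing pairs count as zeros. This makes the means
population quantities rather than properties of the sharing subgraph.

# The three permutation tests

All three use the empirical p-value `p = #(null ≥ observed)/N` with ties
counted and **no** `(k+1)/(N+1)` smoothing, and the observed labeling is
not force-included in the null. This convention is required for the
exhaustive test (whose null is the complete assignment space) and keeps the
Monte-Carlo tests consistent with it. Permutations are independent uniform
draws from the relabeling space (not guaranteed distinct) — standard
Monte-Carlo practice. Fixed seeds give bit-identical nulls; exhaustive
enumeration is seed-independent.

1. **Label shuffle** (`label_shuffle_test`): statistic
   `(w₁ + w₂)/2 − b`. Under the null that group labels are arbitrary,
   relabeling individuals while keeping the matrix intact preserves the
   exchangeable structure.
2. **Continuity** (`continuity_test`): on the source × successor
   sub-matrix, statistic `(FcSc/FcSo)/(FeSc/FeSo)`. Permuting *columns*
   (successor individuals) between Sc and So keeps each successor's sharing
   profile intact and asks whether the focal-region successors are
   special specifically in their sharing with focal-region sources.
3. **Contribution** (`contribution_test`): statistic `FeS/FcS` over all
   successors; *rows* (source individuals) are reassigned, exhaustively
   when `C(n, k)` is feasible (165 for the 11-row, k = 3 design). A zero
   denominator is replaced by 0.01 cM, and such permutations stay in the
   p-value count (they are flagged via the `extreme` field, which callers
   may exclude from plots — never from inference).

**Numerical conventions.** Ratios of sparse Poisson-like sums are wild;
the 0.01 cM substitution bounds them without discarding permutations. The
granularity of p is 1/N, so α = 0.05 decisions need N ≥ a few hundred; the
test suite uses N = 200–400 per synthetic cohort (scaled down from the
conventional 10,000 purely for CI budget) and the package defaults remain
10,000.

# Proximity contrasts

Pairs are classified with coordinates, not labels: two sites belong to the
same geographic area iff their great-circle distance (haversine,
R = 6371 km) is ≤ 200 km (inclusive). *Mortuary proximity* = same burial
tradition, different areas, at least one member from the focal region;
*geographic proximity* = different traditions, same area, both members in
the focal region; everything else is excluded. Region labels enter only
through focal membership, so mislabelled regions cannot silently change
the distance logic.

The two pair sets are compared by a two-sided Wilcoxon rank-sum test on
per-pair sums (or maxima), zeros included by default so the pair universe
is label-defined (a `include_zero = FALSE` flag provides the
positive-pairs-only variant; the published violin plots are ambiguous on
this point, so both are first-class). Because IBD values are zero-inflated,
ties are the rule, and the classical exact distribution is undefined; we
compute an exact tie-aware two-sided p by dynamic programming over doubled
midranks when both sets have ≤ 12 values, else the tie- and
continuity-corrected normal approximation. The exact branch reproduces
`stats::wilcox.test(exact = TRUE)` to 1e-12 on tie-free data. Note that
"exact ≈ approximate within 0.01" holds only loosely at these sizes: the
measured tie-free discrepancy at 12 + 12 reaches ≈ 0.011 (and more under
heavy ties), which is a property of the normal approximation itself; the
test suite asserts 0.02.

# Kinship

**pmr.** For pseudo-haploid genotypes (one sampled allele per site,
the standard representation at < 1× coverage), the pairwise mismatch rate
over jointly covered sites has expectation `2·E[p(1−p)]` for unrelated
pairs and drops proportionally to the kinship coefficient. The baseline is
the mode of a Gaussian-kernel density (Silverman bandwidth, 512-point
grid) across all pairs: close relatives are rare enough that they do not
move the mode, so no curated unrelated set is required. The coefficient is
`1 − pmr/baseline`; degree bins sit at the geometric midpoints
`2^{-1.5}, 2^{-2.5}, 2^{-3.5}, 2^{-4.5}` between the expected coefficients
1/2, 1/4, 1/8, 1/16 — the midpoints are our choice (standard binning
practice; the source method states only the 3/4, 7/8, 15/16 pmr fractions)
and are configurable. Pairs with fewer than 5,000 overlapping sites (our
default; unstated in the source) are down-called to `low-confidence`.

**Envelopes.** Degree calls from total IBD alone saturate beyond the 3rd
degree; the joint (total cM, number of segments) separates further. The
pedigree simulator generates 100 replicates per relationship, merged and
filtered identically to real data, and a bivariate normal is fitted per
relationship. Classification ranks relationships by log-likelihood and
reports every relationship within 2 log-units of the best (interval calls
such as "4th–5th degree"); a point outside every envelope's 99.9%
Mahalanobis region is called beyond 5th degree. The likelihood rule
replaces the visual scatter-cloud comparison so the call is testable; a
tiny covariance ridge handles degenerate clouds (parent–child has constant
total).

# Pedigree simulator

Gene dropping with explicit haplotype mosaics. Crossovers per chromosome
follow a stationary gamma-renewal process with shape ν and mean
inter-crossover distance 100 cM; ν = 1 is the Poisson/Haldane case and the
default, because the interference parameters of the simulator we stand in
for are not published — ν is exposed, and ν ≈ 10 reproduces the strong
underdispersion typical of interference fits. The default map is a bundled
sex-averaged autosomal length table (≈ 3546 cM total); sex-specific maps
can be supplied as two-length columns. This is deliberately simpler than a
position-level sex-specific map: validation is by Mendelian closed forms
(parent–child covers the map exactly; siblings: 75% any-IBD, 25% IBD2;
each added meiosis halves expected sharing across the 14 relationships),
not by replica-exactness to any particular published run.

The 14 relationships span degrees 1–7: parent–child, siblings;
grandparent–grandchild, avuncular, half-siblings, double first cousins;
first/second/third full cousins; half first/second cousins; and the lineal
great-grandparent, great-great-grandparent and third-great-grandparent
pairs (the "3rd–5th degree great-grandparent" series is mapped to these
lineal pedigrees). Simulated segments get
`n_snps = round(length × 300/cM)`, so the 220/cM density filter is
length-driven, matching the effective behaviour on the 1240K panel.

# Synthetic cohorts

The generator states a world and stays there: per-pair retained-segment
counts are Poisson with a symmetric group-pair intensity matrix λ; lengths
are `12 + Exp(mean 8)` cM (so the expected per-pair total is 20λ cM —
analytically convenient, and the rank/ratio-based tests are insensitive to
the exact law); chromosomes are drawn proportional to map length,
positions uniformly. Defaults λ_within = 2, λ_between = 0.5. The presets
encode the three competing demographic readings: `coexistence` (11 + 15
sympatric individuals, within ≫ between), `replacement` (Fc 3 / Fe 8 /
Sc 6 / So 9 with successor sharing independent of source region — a true
null for the continuity and contribution tests), and `continuity`
(the same but the Fc–Sc cell raised threefold). Site coordinates are fixed
per group (Orkhon-valley central site, an eastern and a northern site).
Genotypes are pseudo-haploid draws at Beta(0.8, 0.8) allele frequencies;
planted relatives copy alleles at their kinship coefficient rate and
receive pedigree-simulated segments.

What a green test does establish: the statistics, their permutation nulls,
and the calibration/power behaviour under the stated world. What it does
not: robustness to features of real ancient-DNA data the generator omits —
phasing/imputation error structure, coverage-correlated false IBD, uneven
temporal sampling, or spatial autocorrelation beyond the three fixed
sites.

# Known limitations

* The permutation tests condition on the observed matrix; they do not
  model call uncertainty in the segments themselves.
* The continuity and contribution statistics are ratios of means over very
  small groups (3–9 individuals in the motivating design); their nulls are
  well-defined, but power is intrinsically limited and single individuals
  can dominate (the motivating analysis itself flags one such case).
* The envelope classifier assumes bivariate normality of (sum, count);
  for very distant relationships the mass at zero makes the envelope
  unusable and it is excluded from ranking rather than modelled.
* pmr-based kinship saturates beyond the 3rd degree; envelope-based calls
  take over there but carry simulation-model assumptions (map, ν).
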