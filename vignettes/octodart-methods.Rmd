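---
title: "Methods: dominant-marker analysis for octoploid DArT/DArTseq panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dominant-marker analysis for octoploid DArT/DArTseq panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octodart)
```

## The problem

Cultivated strawberry (*Fragaria × ananassa*) is an allo-octoploid
(2n = 8x = 56). Array- and sequencing-based DArT genotyping scores
restriction fragments as dominant presence/absence (0/1) bands, which
side-steps the ambiguity of calling allele dosage in a polyploid but
forces every downstream method to work on dominant calls. `octodart`
implements the complete analysis chain for such data:

* a **filtering and classification cascade** that reduces raw binary SNP
  allele scorings from an F1 mapping population to a set of single-dose
  (simplex) markers suitable for pseudo-testcross linkage mapping;
* **diversity and structure statistics** for cultivar panels scored with
  dominant markers (PIC, call rate/reproducibility, Nei–Li
  restriction-fragment distances, neighbour-joining with bootstrap, PCoA,
  and the Evanno ΔK model-selection statistic);
* **two-point linkage, LOD grouping and map summaries**;
* a **synteny comparison** of an octoploid genetic map against a diploid
  reference genome (chromosome concordance, coordinate scaling, inversion
  detection);
* **seeded simulators** of an octoploid F1 cross and of a structured
  diversity panel, so every stage is testable against known truth.

## Segregation model and the classification cascade

Under a pseudo-testcross design, two heterozygous parents are crossed and
each parent's markers are mapped against the other's null background.
We assume strict **disomic inheritance**: each marker dose resides on one
homologous pair within one sub-genome, so each dose transmits like a
diploid heterozygote. The expected band-presence fractions in the F1 are:

| class | parental pattern (P1,P2) | presence : absence |
|---|---|---|
| simplex testcross | (1,0) or (0,1) | 1:1 |
| simplex intercross | (1,1) | 3:1 |
| duplex (one parent) | (1,0) | 3:1 |
| triplex (one parent) | (1,0) | 7:1 |
| two+ doses, both parents | (1,1) | 7:1, 13:3, 15:1 |

Because SNPs in a polyploid may sit on different sub-genomes, each SNP is
expanded into its two binary **allele scorings** (`expand_alleles()`), and
the cascade operates on alleles throughout. `run_cascade()` applies, in
order:

1. **Monomorphic filter** — all non-missing progeny calls equal.
2. **Missing-data filter** — more than `floor(0.10 n)` missing progeny
   calls, a missing parental call, or both parents scoring 0. The 10%
   threshold counts progeny only (at n = 94 that is "more than nine
   lines"); parents are covered by their own rule.
3. **Segregation classification** (`classify_segregation()`): the simplex
   ratio implied by the parental pattern is χ²-tested (1 df, no continuity
   correction). If p ≥ `alpha_simplex` (default 0.001) the allele is
   simplex; otherwise the multiplex ratios compatible with the pattern are
   tested and the allele is multiplex if any fits at `alpha_multiplex`
   (default 0.01), else distorted. Testing simplex first reflects that
   multiplex and distorted classes are defined as departures from the
   simplex expectation; the multiplex ratio set is configurable because
   published enumerations of octoploid ratios vary.
4. **Row-sum (depth) filter** — intercross (3:1) markers are less
   informative than testcross markers (both parental genotypes contribute
   the band), so only those whose allele row sum — the total sequencing
   read count supporting the allele — reaches `min_row_sum` (default 600)
   are kept.
5. **Redundancy collapse** — pairwise call similarity over jointly scored
   progeny; pairs above 0.99, and exactly complementary pairs from the two
   alleles of one SNP (both simplex in the same sub-genome), collapse to
   the representative with fewer missing calls (ties by ID). Similarity is
   computed with pairwise deletion and is not assessed below an overlap of
   20 progeny, since ">0.99 similar" is meaningless on a handful of calls.

`cascade_report()` reconciles all stage counts (kept + removed = input at
every stage, by construction) and derives percentages on their
conventional denominators, rounded to one decimal.

## Diversity statistics

**PIC.** For a dominant biallelic marker with band frequency *f*,
PIC = 1 − f² − (1−f)² = 2f(1−f), bounded by 0.5 — a dominant marker can
never be as informative as a codominant one. `pic_summary()` reports the
per-marker values, the mean, and the conventional bins (<0.10, 0.10–0.30,
0.30–0.40, 0.40–0.50).

**Nei–Li distance.** Shared restriction fragments estimate divergence: for
a pair of accessions, F = 2·n_xy/(n_x + n_y) over markers scored in both.
We use the fragment-mode relation F = G⁴/(3 − 2G), solved for the
per-site retention G by damped fixed-point iteration
G ← ½[G + (F(3 − 2G))^¼] from G₀ = F^¼ to |ΔG| < 1e-12, and
D = −(2/r)·ln G with r the restriction-site length (default 6, the PstI
recognition site that generates DArT fragments; r is exposed because
halving/doubling r rescales D exactly). F = 1 gives D = 0; F = 0 is
saturated and flagged (optionally capped); a pair with no bands at all is
undefined. Missing calls are handled by pairwise deletion, matching the
practice of keeping markers with scattered missing values in panel
analyses.

**Neighbour joining.** Saitou–Nei agglomeration with the Q-criterion,
written here rather than delegated so that tie-breaking (smallest leaf
label pair) and negative-branch bookkeeping are fully specified: negative
length estimates are clamped to zero in the output (PHYLIP-compatible)
with raw values kept in an attribute. On an additive matrix the generating
tree is recovered exactly; tests cross-check against an independent NJ
implementation and against brute-force quartet resolution. Bootstrap
supports (`bootstrap_support()`) resample marker columns, rebuild distance
and tree, and count unrooted bipartitions of the original tree; degenerate
replicates (saturated distances) are dropped and the effective count
reported. Rooting is by a named outgroup accession
(`root_phylogram()`), with a midpoint-style fallback.

**PCoA.** Classical Gower scaling of −½D² (via `stats::cmdscale`), axes
ordered by eigenvalue, percent variance computed over positive eigenvalues
only; negative eigenvalues (non-Euclidean inputs) are reported but carry
no coordinates. "Standardized covariance" variants used by some desktop
packages are not reconstructed; classical PCoA is the documented,
reproducible choice.

**ΔK.** `delta_k()` consumes a table of replicate log-probabilities L(K)
from any model-based clustering program (the Bayesian clustering itself is
out of scope) and computes
ΔK = |L̄(K+1) − 2L̄(K) + L̄(K−1)| / sd(L(K)), undefined at the endpoints;
zero replicate variance at an interior K is a hard error, since the
divisor is then meaningless. `simulate_loglik_curves()` provides a
piecewise-linear-plus-noise test substrate with a knee at a known K.

## Linkage

For two testcross markers from the same parent, `two_point()` estimates
rf = min(d, n−d)/n from the mismatch count d, with coupling/repulsion
phase, and the standard LOD k·log₁₀(2rf) + (n−k)·log₁₀(2(1−rf)).
`independence_lod()` is the G²-based LOD (G²/(2 ln 10)) on the 2×2 progeny
table, usable for any pair, including across parents — under the
pseudo-testcross model, cross-parent testcross pairs share no meioses, so
only the independence form is meaningful there. The two statistics
coincide exactly when both markers segregate exactly 1:1 and differ
slightly otherwise. Pairs with fewer than 20 jointly scored progeny are
not computed (unstable estimates). `group_markers()` takes the
single-linkage transitive closure over pairs with LOD above the threshold
(default 5); marker ordering within groups is deliberately not
implemented — maximum-likelihood ordering belongs to dedicated mapping
software and orders are accepted as input. `map_stats()` summarises a map:
per-group lengths (max − min position), spacings, and gaps above a
threshold (default 8 cM). Because "average marker distance" is ambiguous,
both total-length/markers and the mean adjacent interval are reported.

## Synteny

Linkage groups named by Roman homoeology-group prefix (I-1 … VII-4) are
expected on the diploid reference pseudochromosome of the same number;
`chromosome_concordance()` reports the discordant fraction over markers
with both coordinates. For co-plotting, physical Mb are multiplied by 4
(`scale_physical()`), reflecting that four homoeologous octoploid maps in
cM span roughly four times the diploid physical scale.
`detect_rearrangements()` orders anchored markers by cM (ties by bp, then
ID), takes the longest strictly increasing and decreasing subsequences of
bp as the candidate colinear backbones, keeps the longer (orientation
flag, ties favour forward), and reports off-backbone markers as
rearrangement candidates. Runs of ≥3 consecutive candidates that are
internally monotone against the backbone are flagged as inverted blocks
and extended over flanking markers that continue the reversed trend (an
inversion endpoint can legitimately lie on the backbone). Kendall τ per
linkage group summarises overall colinearity. Single-marker long-range
discrepancies remain candidates — assembly error versus transposition is
not decidable from marker order alone.

## The simulators: what they emulate, and what they do not

`simulate_octoploid_cross()` generates parental and progeny calls under
the disomic model above. Simplex (testcross and intercross) markers are
placed on linkage groups (default 5 groups of 80 cM) and recombine by the
Haldane map function, with each dose phased at random onto one homologue;
intercross markers recombine independently in the two parents. Duplex and
triplex markers are simulated as 2–3 independent unlinked doses, since
multi-dose markers do not enter the mapping set. Genotyping error is a
symmetric 0↔1 flip (the simplest mechanism that produces the spurious
double-crossover artifacts seen in dense maps), applied after inheritance
to parents and progeny alike; missing calls are thinned at the configured
rate (default 10%). Read depth per allele is lognormal
(meanlog 5.9, sdlog 0.8), independent of genotype — chosen so that
roughly a quarter of intercross alleles clear the 600-read default, the
retention scale typical of this assay; depth is genuinely
genotype-independent in expectation only for presence alleles, a
simplification.

Defaults follow the reference study design where stated: 94 progeny, a
62-accession panel scored for 603 markers, 20 replicate runs over K = 1–10
for ΔK. The panel simulator uses a hierarchical band-frequency model
(ancestral frequency uniform on [0.05, 0.95], per-subpopulation uniform
divergence of ±0.3 clamped to [0.01, 0.99], Dirichlet admixture for a
configurable fraction of accessions). What the simulators do **not**
emulate: polysomic or mixed inheritance, linkage between multiplex doses,
segregation-distorting selection, depth–genotype correlation, and
non-random missingness. Passing tests therefore demonstrate correctness
of the statistical machinery under the stated model, not robustness to
every pathology of real octoploid data.

## Numerical choices and degenerate inputs

* χ² tests use the exact 1-df upper tail; the test suite verifies
  agreement with the closed-form complementary-error-function tail to
  1e-10 over statistics in [0, 50].
* The retention solve is damped to guarantee convergence for all
  F ∈ (0, 1]; the residual |G⁴ − F(3−2G)| is checked in tests.
* NJ ties are broken by the smallest representative-label pair;
  group numbering in `group_markers()` is by size then smallest member —
  all outputs are deterministic for a given seed.
* All-missing markers are *not* monomorphic; they fall to the
  missing-data filter. A parental pattern (0,0) reaching the classifier is
  an internal error (the missing filter owns that rule).
* Saturated (F = 0) distances refuse tree building unless capped — a
  silent large constant would distort branch lengths unannounced.
* Degenerate ΔK divisors (zero replicate variance), sub-overlap marker
  pairs, and empty dosage-class configurations all raise informative
  errors rather than returning numbers.

## Problem sizes used in the test suite

Tests run the full chain at deliberately modest sizes chosen to make
binomial sampling error negligible where a proportion is asserted
(n = 10,000 progeny for segregation fractions), and at study scale
(n = 94) where the claim is about recovery rates: 4,000 classified
markers for the ≥99% class-recovery check, 100 simulated curve sets for
ΔK knee recovery, 200 random additive trees for NJ exactness, and
500-replicate-scale LOD grouping and LIS enumerations. These sizes are the
package's validation design; all complete in seconds.

## Known limitations

Dominant markers cannot distinguish duplex-intercross configurations from
simplex-intercross by ratio alone at n = 94 except through the parental
pattern; the cascade classifies by pattern first for this reason. The
Nei–Li fragment model assumes independent fragment loss across sites; the
exact variant used by legacy restriction-distance software (sites- vs
fragments-mode, rate heterogeneity) is not fully documented, so the
fragment-mode formula is exposed with r configurable and any alternative
must preserve the limiting behaviours (F = 1 → D = 0, monotone in F).
Marker ordering within linkage groups and Bayesian admixture inference
are out of scope by design.
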