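---
title: "Methods: founder-haplotype decay, core-haplotype detection and allele age estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: founder-haplotype decay, core-haplotype detection and allele age estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`foundertrace` analyses a founder mutation through the haplotype it drags
along: all carrier chromosomes descend from one ancestral chromosome, and
recombination trims the shared flanking haplotype a little more each
generation. This vignette explains the models behind each stage, the
parameters that matter, what the synthetic-data generator does and does not
emulate, and the numerical and design choices a maintainer should know about.

## Coordinates and interval conventions

All physical positions are 1-based GRCh37. Interval length is the
**difference** `end − start`, not `end − start + 1`: published boundary
coordinates of conserved windows reproduce their published kb/Mb lengths only
under the difference convention (e.g. `41487451 − 41223094 = 264357` prints
as "264.4 kb"). Formatting helpers round kb and Mb to one decimal and
approximate kb to the nearest 10 kb. The chromosome 17 length defaults to the
GRCh37 value 81,195,210 bp and is overridable everywhere it is used, because
published genetic-distance work rarely states which total length was assumed.

Genetic positions come from a HapMap-format recombination map
(position, rate in cM/Mb, cumulative cM): positions between map points are
interpolated linearly, positions beyond the ends are extrapolated with the
terminal interval rates (floored at 0 cM below the map start). PLINK `.map`
files are accepted, with zero cM columns filled by interpolation or by a
constant rate (1 cM/Mb by default).

## Quality control

Markers and samples are filtered with the thresholds standard in SNP-array
founder studies: sample call rate ≥ 0.95, marker call rate ≥ 0.95, minor
allele frequency **strictly above** 0.05 (the exclusion is inclusive,
`MAF ≤ 0.05`), and an exact Hardy–Weinberg test at `p ≤ 1e-5`. Rules are
evaluated in the order call rate → MAF → HWE and only the first triggering
rule is recorded per marker, so QC reports are unambiguous. The order is an
artifact decision; the thresholds are the binding contract.

The HWE test is the exact conditional test: given the sample size and allele
counts, the heterozygote count follows the Levene–Haldane distribution

$$P(n_{Aa} = h \mid n, n_A) = \frac{n!\,2^h}{n_{AA}!\,h!\,n_{aa}!}
  \cdot \frac{n_A!\,n_a!}{(2n)!},$$

and the two-sided p-value sums the probabilities of all configurations no
more likely than the observed one (with a `1 + 1e-9` relative tolerance on
the equality comparison, the usual guard against floating-point ties).
Probabilities are computed on the log scale and normalised, which is stable
for the sample sizes arrays produce. HWE is computed on all samples pooled
unless the caller restricts the input; whether the original studies used
controls only is typically unstated.

## Core haplotype and shared segments

The focal mutation is usually known from clinical testing and is **not** an
array marker, so all detection is anchored at the nearest flanking markers
and extends outward:

* `find_core_haplotype()` extends left and right while every
  mutation-bearing haplotype carries the same allele (at most
  `max_mismatch_haps` deviating haplotypes per marker, default 0). The
  boundaries are the last conserved markers; the length is the distance
  between them, equivalently the sum of the one-sided distances — the
  classic "sum of the distance to the last marker on either side" rule used
  to size conserved founder haplotypes.
* `pairwise_shared_segment()` does the same for one pair of haplotypes with a
  total opposing-allele budget (`max_mismatches`). With a positive budget the
  two sides compete for it; the implementation walks markers outward in
  order of genetic distance from the focal position (left first on exact
  ties) and closes a side at its last matching marker once accepting the next
  mismatch there would exceed the remaining budget. This rule is local,
  deterministic and side-symmetric; with the default budget 0 it reduces to
  "stop at the first opposing allele", which is the definition used
  everywhere downstream.

Missing alleles follow a declared policy: `"ignore"` (default — the
haplotype simply does not vote at that marker, which mimics what manual
alignment of QC-passed array data does), `"mismatch"` (conservative:
missingness breaks identity), or `"impute-consensus"`. Degenerate geometries
are handled explicitly: a focal position beyond the typed region on one side
produces a one-sided core with a warning; a side whose first flanking marker
already fails identity degenerates to the focal position itself.

Carrier grouping (`group_haplotypes()`) is single-linkage clustering with an
edge wherever a pair shares at least `min_shared_cM`; connected components
are the "mutation haplotypes". Cluster labels are assigned by each cluster's
smallest member id so output is stable under input order. Single linkage is
an artifact decision — it matches how IBD studies informally group carriers,
and it is transparent; its known failure mode (a recent recombinant carrier
with a very short retained segment becomes a singleton) is real and visible
rather than hidden by an averaging rule.

For real diploid data without per-chromosome mutation flags,
`assign_carrier_haplotypes()` picks, for each known carrier sample, the
haplotype agreeing with the current carrier consensus at more markers,
iterating consensus and selection to a fixed point (≤ 10 iterations, ties
keep the first haplotype). Synthetic data always carries truth flags.

## Distances and the UPGMA tree

The genetic distance between two carriers is the chromosome length minus the
length they share around the mutation, in bp by default (the Mb-scale
narrative of founder studies) with a cM mode available — which units the
published analyses used is usually not stated, so both are provided. UPGMA
is implemented directly: iterative merging of the closest pair with
size-weighted average linkage, node heights at half the merge distance, and
deterministic tie-breaking by the lexicographically smallest pair of cluster
labels. The result is returned as an `ape` `phylo` object, ultrametric by
construction (verified to 1e-9 in the tests, which also check agreement with
`phangorn::upgma` and a brute-force oracle that recomputes cluster distances
as means over the original matrix). Bootstrap support over marker resampling
is deliberately not bundled: the published procedure ("1000 replications" in
an alignment tool) is not described in enough detail to replicate, and a
resampling wrapper is easy to write around `all_shared_segments()`.

## Allele age estimation

### Model

Under a **star genealogy**, every carrier chromosome descends independently
from the founder through `g` meioses. The retained ancestral segment on one
side of the mutation then ends at the nearest of `g` independent
recombination opportunities, so its genetic extent `x` (in Morgans) is
Exponential with rate `g`. An extent that runs to the edge of the typed
window is **censored**: only the survivor probability `exp(−g x)` is known.
The log-likelihood over extents is

$$\ell(g) = k \ln g - g \sum_i x_i,$$

with `k` the number of uncensored one-sided extents and the sum over all
extents including censored ones at their censoring bound.

* `moment_age()` returns the closed-form MLE `ĝ = k / Σx` with the exact
  chi-square interval `[χ²₀.₀₂₅(2k), χ²₀.₉₇₅(2k)] / (2Σx)` from the gamma
  distribution of the total. With `k = 0` only an upper bound is returned,
  with a warning.
* `mcmc_age()` samples the posterior under a uniform prior on `g`
  (default `Uniform(1, 500)` generations — the published analyses state no
  prior, so a wide flat one is the neutral choice). The sampler is
  Metropolis–Hastings on `log g` with the Jacobian term included so the
  prior really is flat on `g`; the Gaussian step size is adapted during
  burn-in toward an acceptance rate of 0.2–0.5 and frozen afterwards so the
  post-burn-in chain satisfies detailed balance. Defaults are 1,000,000
  iterations with 100,000 burn-in, the configuration used in published
  founder-dating runs; because the no-growth likelihood reduces to the two
  sufficient statistics `(k, Σx)`, a million iterations cost seconds.
* **Growth correction** (optional, via a `demographic_model`): in a
  population growing at per-generation rate `d`, a random carrier lineage
  coalesces into the founder lineage more recently than `g`, with depth
  `t = g − T`, `T ~ Exponential(d)` truncated to `[0, g]`. The per-extent
  density integrates over `t` by Gauss–Legendre quadrature (≥ 64 nodes,
  enforced). This is a first-order stand-in for a full intra-allelic
  coalescent: the dedicated dating tools model the joint genealogy and
  marker frequencies, but their internal equations are not published, so
  this package states its approximation instead of pretending to replicate
  theirs. Reproducing any specific published posterior is out of scope — it
  would also require the original genotypes, which were never deposited.

The demographic arithmetic is exposed directly: `growth_rate()` implements
`d = ln(P_t/P_o)/g` (the displayed equation — worked expressions in the
founder-dating literature sometimes drop the "ln" typographically, but only
the logarithm reproduces their own numerical results, e.g.
`ln(51e6/1000)/26.05 = 0.42`); `years_to_generations()` and
`generations_to_years()` convert at 20 years per generation by default; and
`carrier_chromosome_fraction()` implements only the definitional
`f = prevalence × share / 2` — published `f` values whose derivations are
not shown are treated as config inputs, never re-derived.

### Measuring extents

`extract_extents()` measures, per carrier chromosome, the genetic distance
from the focal position to the last marker matching the ancestral reference
before the first opposing marker on each side. The reference is the
simulation founder, a `core_haplotype` consensus (completed by the panel
consensus outside the core), or `consensus_haplotype()` — the per-marker
majority across carriers. Two practical controls matter:

* **Dating window** (`window_bp`, default the whole map; the pipeline
  defaults to the 4.35-Mb window chr17:39,040,105–43,387,103, which brackets
  the recombination margins of the major mutation haplotypes). Extents that
  reach the window edge are censored, and the likelihood handles them
  exactly; ignoring censoring would bias ages upward.
* **Mismatch budget** (`max_mismatches`, default 0). On a dense map a single
  genotyping error truncates an extent long before the true recombination
  breakpoint: at one marker per 5 kb and a 0.2% per-allele error rate, the
  first miscall appears after ~2.5 Mb on average, competing with the true
  signal and inflating `ĝ` severely. A budget of 2 lets the scan step over
  isolated miscalls (the chance that background alleles produce runs past
  3 opposing markers is negligible), which is the package's substitute for
  the curated low-density marker panels such studies genotype by design.
  Estimator-recovery tests run on error-free panels with budget 0, isolating
  the estimator from this orthogonal robustness concern.

Extent measurement is quantised to the marker grid (it stops at the last
*matching marker*, understating the true breakpoint by up to one marker
interval) and can overshoot by chance background matches (~1–2 markers at
array MAFs). At the default density these two biases are a fraction of a
percent of `1/g` and largely cancel; they are visible only in the tests'
tolerances.

## Ancestry summarisation

Chromosome-level ancestry of one haplotype weights each marker's local
ancestry call by the interval between the midpoints to its neighbouring
markers. The first interval starts at the chromosome origin (coordinate 0)
and the last ends at the chromosome length, so the weights sum exactly to
the chromosome length and fractions sum to 1 within 1e-12 — the natural
closure of the midpoint rule, whose published phrasing covers only internal
midpoints. A useful internal identity follows and is tested: per-marker
carrier fractions averaged with the midpoint weights equal the mean
chromosome-level fraction over the same haplotypes.

Carriers and non-carriers are compared per sample (the mean of a sample's
two haplotype fractions; per-haplotype comparison is available behind a
flag — which aggregation published analyses used is unstated) with the
pooled-variance Student's *t* test by default, Welch by flag, reporting
mean ± SD per group. Zero-variance degeneracies are resolved before
delegation to `stats::t.test` (equal means → `t = 0, p = 1`; unequal means →
the `p → 0` limit with a warning).

## The synthetic-data generator

`simulate_carrier_panel()` generates the structure the analysis assumes,
no more:

* A random marker map (default one marker per ~5 kb over a 20-Mb window
  around the *BRCA1* locus, constant 1 cM/Mb), background allele frequencies
  with MAF uniform on (0.05, 0.5).
* One founder haplotype drawn from the background model, carrying the
  mutation at the focal position (default chr17:41,244,000 — an approximate
  in-gene position; the exact coordinate is immaterial to the simulation).
* Per carrier chromosome, one-sided retained extents drawn
  `Exponential(rate = g_true)` in Morgans, truncated (and flagged censored)
  at the region edges; founder alleles are copied on the retained interval,
  background alleles drawn outside. Defaults `g_true = 26`, 32 carriers and
  150 controls emulate a Colombia-like carrier series at desk scale;
  `g_true = 100` gives the Iberia-like regime. Sample sizes are scale
  choices, not contracts — the binding parameters are the rates.
* Genotyping error flips alleles independently (default 0.002) and
  missingness masks them (default 0.01), after the truth record snapshots
  the clean panel.
* Optional **two-lineage** mode: a second founder shares the first founder's
  alleles in a ~264-kb core window around the mutation and carries an
  independent background elsewhere — an early recombination event onto
  another chromosome, the structure behind "two main mutation haplotypes".
* Optional **growth mode** draws lineage depths `g − T`,
  `T ~ Exponential(d)` truncated to `[0, g]`, the same approximation the
  MCMC growth correction integrates over; by default depths are fixed at
  `g_true` (the star genealogy the moment estimator inverts).

What it does **not** emulate — and therefore what passing tests do not show
about real data: background linkage disequilibrium (sites are independent,
which makes false haplotype sharing *less* likely than in real array data at
these MAFs, a conservative null for the detection stages; a hook accepts
user-supplied background haplotypes for LD-aware checks), phasing error
beyond the mismatch budgets, recurrent mutation, selection, and population
structure among controls. A full forward simulation is out of scope by
design.

Determinism: every generator takes a seed and is bit-reproducible; the
pipeline fans one global seed out to per-stage child seeds through the fixed
affine map `stage_seed(seed, k) = (seed × 48271 + k) mod (2³¹ − 1)`, so each
stage can be rerun in isolation.

## Numerical choices and degenerate inputs

* Exact-test tie comparison uses a `1 + 1e-9` relative tolerance; UPGMA tie
  detection uses `1e-12` relative tolerance, then the label rule.
* The MCMC errors (naming the iteration's state) on non-finite likelihoods
  rather than silently rejecting, and errors upfront if the prior excludes
  all mass.
* Retained-interval arithmetic in the simulator includes a `1e-9` cM
  tolerance so censored intervals still include their edge markers despite
  floating-point rounding.
* Empty genotype tables, all-zero HWE counts, single-marker ancestry tracks,
  identical haplotype ids in a pairwise query, all-censored extent sets and
  degenerate zero-variance *t* tests each have an explicit, warned behaviour
  rather than an error where a defensible value exists.

## Problem sizes used by the test and acceptance suites

The suites exercise: 200 random small panels (≤ 10 haplotypes × ≤ 50
markers) against brute-force oracles; the exhaustive HWE sweep over all
genotype triples with n ≤ 25; UPGMA against oracles on 4–8-leaf matrices;
estimator recovery at `g = 26` and `g = 100` with 200 carriers × 20 seeds
and 50,000-iteration MCMC runs; and ancestry power/calibration studies over
20 and 100 seeds. These sizes give stable verdicts (binomial bounds are
stated next to each stochastic assertion) while the whole suite stays fast
enough to run routinely.

## Known limitations

* The star genealogy ignores shared internal branches of the true
  intra-allelic genealogy; with strong growth the approximation is good
  (genealogies are near-star), with weak growth it understates uncertainty.
  The growth correction adjusts lineage depths, not genealogy shape.
* Single-linkage grouping isolates recent recombinants (short retained
  segments) as singletons instead of forcing them into a lineage.
* The LD-free background makes chance sharing conservative but also makes
  consensus-based references slightly "too easy"; on real data the
  mismatch budget and the dating window do the equivalent work.
* Ancestry summarisation consumes local-ancestry calls; it does not infer
  them.
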