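---
title: "Methods: population structure and temperature-gated larval drift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population structure and temperature-gated larval drift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models implemented in **skagerrak**, the
assumptions behind them, the parameters that matter, and the design
choices made where several defensible options existed. The setting is the
connectivity question for invasive Pacific oysters (*Crassostrea gigas*)
across a marine dispersal barrier such as the Skagerrak: genetics asks
whether recipient-coast populations descend from donor-coast ones; drift
simulation asks whether the physics and thermal biology even permit the
crossing.

## 1. The genotype container

All genetics functions work on a `genotype_tbl`: a long tibble with one
row per individual per locus and the two allele labels as integer fragment
sizes in bp. Two conventions are enforced at construction:

* **Missingness is per-genotype, never per-allele.** A half-call (one
  allele scored, one absent) is not a biologically meaningful state for a
  diploid codominant marker; it is coerced to missing with a warning.
* **Population and locus order is first-appearance order**, and every
  report preserves it, so tables read in the same order the sampling
  design was laid out.

Allele labels are kept as raw fragment sizes rather than recoded indices
so that private-allele comparisons remain meaningful across populations
and files. GenePop (3-digit default on write) and a two-columns-per-locus
delimited layout are supported for exchange; both round-trip losslessly
up to GenePop's lack of a separate population-label field (labels are
taken from the last individual of each `POP` block, the common
convention).

## 2. Diversity statistics

For each population × locus with $N$ gene copies ($N = 2 \times$ called
individuals, so missing data shrinks $N$):

* $H_O$ — fraction of called individuals with two different alleles.
* $H_E = 1 - \sum_i p_i^2$, with Nei's small-sample correction
  $N/(N-1)$ reported alongside. Published tables rarely state which
  estimator they print, so both columns are always emitted; per-population
  summaries conventionally use the unbiased one, pooled per-locus panels
  the uncorrected one.
* Rarefied allelic richness
  $A_R(g) = \sum_i \left[1 - \binom{N - N_i}{g} / \binom{N}{g}\right]$,
  the expected number of distinct alleles in a subsample of $g$ gene
  copies. Rarefaction is at the gene-copy level and the default $g$ is the
  per-locus minimum $N$ across populations — the convention of rarefaction
  tools in this field — so a small sample (here, the 12-individual
  westernmost population) does not depress comparisons. The tests verify
  $A_R$ against exhaustive subsample enumeration for $N \le 12$.
* Private alleles are raw presence/absence counts (alleles seen in exactly
  one group and nowhere else), not rarefied: the pooled donor-vs-recipient
  comparison in this design is a raw count, and rarefying it would change
  its meaning. Any disjoint grouping of populations is accepted, so both
  per-location and pooled-coast counts come from the same operation.

## 3. Equilibrium tests and the multiple-testing threshold

**Hardy–Weinberg.** The exact test orders genotype arrays by their
conditional probability given the allele counts (the classical
"exact" criterion, two-sided by construction), estimated by Monte Carlo:
the $2n$ observed gene copies are repeatedly shuffled into $n$ random
diploid pairings and the p-value is the smoothed proportion of
arrangements no more probable than the observed one,
$(1 + \text{hits})/(\text{steps} + 1)$. Ordering by conditional
probability rather than by heterozygote deficit matches the default
behaviour of the standard population-genetics packages this workflow
mirrors. Monomorphic cells return `NA` ("not testable" rather than
"in equilibrium"). Default 100,000 arrangements in production runs;
calibration tests use fewer since the binomial noise floor, not Monte
Carlo error, dominates there.

**Linkage disequilibrium.** The association statistic is the G-statistic
of the two-locus genotype contingency table; the null is built by
permuting one locus's single-locus genotypes across individuals, which
preserves both margins exactly. Same smoothed p-value; 10,000 permutations
by default.

**Benjamini–Yekutieli threshold.** Families of tests are flagged at
$\alpha / \sum_{i=1}^{k} 1/i$, the FDR-controlling threshold valid under
arbitrary dependence — appropriate here because tests at the same locus
across populations, or sharing a locus within a population, are anything
but independent. The family size $k$ counts defined tests only (an `NA`
from a monomorphic cell is not a test). For the canonical LD family of 15
locus pairs × 6 samples, $k = 90$ gives a threshold of 0.00984 at five
decimals. Star levels (5%, 1%, 0.1%) are each computed through the same
B-Y adjustment.

## 4. Between-population structure

**Chord distance.** Per locus,
$d_\ell = \frac{2}{\pi}\sqrt{2\,(1 - \sum_a \sqrt{x_a y_a})}$ on the union
of observed alleles. Multi-locus combination is the arithmetic mean of
$d_\ell$ by default; the root-mean-square variant is available behind a
flag because historical implementations disagree and the difference is
second-order for the weakly differentiated data this workflow targets. A
locus with zero gene copies in either population of a pair is dropped
from that pair's average with a warning rather than imputed.

**Neighbour joining and bootstrap.** NJ is delegated to `ape::nj()`
(Saitou–Nei, deterministic); negative branch lengths — possible on
non-additive inputs — are clamped to zero with the deficit moved to the
adjacent branch, so additive matrices are reproduced exactly and the
clamp never fires on them. Supports come from resampling loci with
replacement (2000 replicates by default), recomputing the chord matrix
and tree each time, and counting how often each internal bipartition of
the point-estimate tree recurs. Support is attached to the point tree's
splits, not to a consensus tree, matching the usual "splits above 70% are
significant" reading; the 0.70 rule is a convention, flagged as such.
With a handful of loci the bootstrap distribution is coarse — supports
move in steps of roughly $1/\text{loci}$ choose patterns — which is a
property of the design, not the estimator.

**PCoA.** Classical metric scaling (`stats::cmdscale` behind the module
surface): double-centre $-D^2/2$, eigendecompose, scale eigenvectors by
root eigenvalues. Percent variance is reported over positive eigenvalues
only; chord matrices are near-Euclidean so negative eigenvalues are tiny,
but the convention matters for reporting.

**Weir–Cockerham θ.** The 1984 variance-components estimator, multiallelic
and multi-locus as a ratio of sums: per allele and locus, components $a$
(among populations), $b$ (among individuals within populations) and $c$
(within individuals) are formed from per-population sample sizes, allele
frequencies and observed heterozygote frequencies;
$\hat\theta = \sum a / \sum (a+b+c)$. Missing genotypes reduce per-locus
sample sizes; a locus untyped in one population is excluded for that
pair; weakly differentiated pairs may give slightly negative estimates,
reported untruncated since the interesting values here sit near zero
(0.002–0.05). The test suite checks the implementation against an
independent derivation — a nested ANOVA of gene-copy indicator variables —
to $10^{-10}$, and recovers the F-model's simulated $F$ within ±15% at
$F \in \{0.02, 0.05, 0.1\}$ ($n = 50$, 6 loci, 100 replicates).

**Permutation test.** Individuals (whole multilocus genotypes) are pooled
and relabelled preserving sample sizes, 10,000 times by default, with the
$+1$-smoothed p-value. Pairs are tested independently with no across-pair
correction, mirroring how pairwise tables are conventionally starred. One
subtlety the tests document: with very small samples a permutation can
recreate the original split exactly, tying the maximal statistic, so the
minimal p-value $1/(\text{reps}+1)$ is only attained when
$\binom{n_1+n_2}{n_1}$ is large.

## 5. The drift model

Larvae are passive super-individuals on a single surface layer: no
vertical behaviour, no random walk, no mortality other than the thermal
gates — deliberately, so the temperature signal is isolated and every
trajectory is bit-reproducible. Positions advance by explicit Euler
(default `dt` = 3600 s; RK4 behind a flag) on bilinearly interpolated
velocities; near land, interpolation weights are restricted to water
cells and renormalised. The development clock accumulates
$\max(T - T_{\text{base}}, 0)\,dt/86400$ degree-days from the pre-step
position; $T_{\text{base}}$ defaults to 0 °C since the empirical
"recruitment degree-day" requirement is quoted as a plain cumulative sum,
and every acceptance property either holds for any base or states it.

A step that would enter a land cell is a **coast contact**: the larva
sticks at its last water position (no resuspension) and is classified
immediately — `LANDED_SURVIVED` iff degree-days ≥ 225 **and** landing-site
temperature ≥ 18 °C, both inclusive; otherwise `LANDED_FAILED`. Leaving
the domain or exceeding the maximum pelagic duration (default 60 days)
expires the larva. Survived landings are binned on a half-open,
axis-aligned 50 km grid anchored at the domain origin, and counted inside
named regions by point-in-polygon.

Euler is first-order: halving `dt` roughly halves the position error on
smooth fields (verified on a gyre), and on uniform flow the scheme is
exact — the analytic crossing fixture (255 km in exactly 10 days at a
constant 25 °C) must land with exactly 250 degree-days.

## 6. What the synthetic generators emulate — and what they do not

**Genotypes.** The F-model draws ancestral frequencies per locus from a
flat Dirichlet, then population frequencies from
$\text{Dirichlet}(p_0 (1-F)/F)$, then genotypes under within-population
HWE. Its virtue is that $F$ *is* the θ estimand, giving clean recovery
targets; its limits are equally clear: no mutation model (no stepwise
microsatellite ladder), no null alleles or scoring error, no inbreeding
unless injected via `make_hwe_violating_population()` (which distorts
heterozygote probability by a factor $1 - F_{IS}$). The study-shaped
stand-in `simulate_study_genotypes()` copies the published *design* —
six samples of 12 and 5 × 50 individuals, six loci with the panel's
fragment-size ranges and total allele counts, exactly three individuals
untyped at each of the two incompletely amplifying loci, and one
strongly diverged westernmost population ($F = 0.05$ vs 0.01) — so that
report shapes and counting logic can be exercised at full scale. Its
allele-level content is synthetic: statistics that depend on which
alleles the real oysters carried (private-allele totals, specific θ
values) will differ from the published ones, and passing tests on it
demonstrate correct counting, not agreement with the real supplementary
data.

**Ocean scenarios.** A rectangular basin (200 × 252 km, 4 km cells,
6-hourly fields over 80 days) with land strips on the donor (south) and
recipient (north) coasts and open east/west walls. Currents come from a
discrete stream function differentiated centrally, so the discrete
divergence vanishes identically — a property the tests assert. The
default "channel" pattern $v(x) = v_0 \sin(\pi x / L_x)$ crosses fastest
mid-basin (10-day transit by default) and is stagnant at the edges,
giving each scenario a natural mix of fast landers, slow landers and
expiries. Temperature is baseline 19 °C + a 1.5 °C seasonal cosine
peaking mid-August + a −0.01 °C/km northward gradient + a scenario
offset; the presets move *only* the offset (cold −4, moderate +1.5,
warm +6 °C), so, as in the real contrast between 1990s and 2000s
summers, temperature — not circulation — is the single cause of
between-year differences. Under these values the cold preset never
reaches the 18 °C gate anywhere (zero settlement), the warm preset's
fastest crossings arrive with ≈ 250 degree-days, and the moderate preset
splits: mid-basin larvae arrive too fast to reach 225 degree-days while
slower flanks succeed. The generator does not attempt real Skagerrak
bathymetry, stratification, tides or wind events; absolute landed counts
are therefore scenario properties, not predictions, and are never
compared against published hindcast-driven counts.

## 7. Problem sizes, tolerances and degenerate inputs

* Monte-Carlo defaults (100,000 HWE arrangements, 10,000 LD and F_ST
  permutations, 2000 bootstrap replicates) are production settings;
  the test suite and the acceptance script scale effort to the precision
  each check needs — e.g. 1000 HWE arrangements per fixture when the
  quantity under test is a rejection *rate* over 200 fixtures, whose
  binomial noise dwarfs the Monte-Carlo error.
* Calibration checks accept rates inside the 99% binomial band around the
  nominal α; θ recovery is checked to ±15% relative, reflecting F-model
  sampling noise at 6 loci.
* Exact oracles are held to 10⁻⁹ (rarefaction vs enumeration,
  interpolation vs dense oracle, PCoA planar recovery) or 10⁻¹⁰–10⁻¹²
  (θ vs ANOVA components, NJ on additive matrices).
* Degenerate inputs are defined, not patched over: all-missing cells give
  `NA` statistics; monomorphic cells give `NA` tests; a population
  untyped at a locus drops that locus pairwise (chord, θ) with a warning;
  `F = 0` in the generator copies ancestral frequencies exactly rather
  than dividing by zero; single-locus tables refuse to bootstrap.
* Every stochastic stage takes a seed, derived from one root seed per
  workflow run, and seeded helpers restore the caller's RNG state, so
  pipelines are byte-reproducible and stages can be re-run independently.

## 8. Known limitations

Beyond the generator limits above: the HWE test is Monte-Carlo only (no
complete enumeration for multiallelic tables); no null-allele or
large-allele-dropout screening is included (upstream QC in the original
workflows); ordination is PCoA only (no discriminant analysis); the drift
model has no behaviour, mortality or vertical structure by design; and
NetCDF ingestion is not built in — fields enter through the in-memory
constructor, from whatever source the user parses.
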