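---
title: "From molecular phenotypes to genetic maps: models and choices"
author: "phenomarker"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From molecular phenotypes to genetic maps: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenomarker)
```

## The idea

In a segregating population derived from two inbred parents (here mainly
selfed recombinant inbred lines, RILs), a molecular phenotype — a
transcript, protein or metabolite level — that is controlled by a single
major QTL separates into one cluster per genotype class. Measured across
the population it shows a clearly bimodal (RIL, backcross) or trimodal
(F2) distribution. Such a phenotype *is* a genetic marker in disguise:
assign each individual to the mixture component it most probably belongs
to, and you have genotype calls at the (initially unknown) locus driving
the trait. With tens of thousands of phenotypes measured at once, enough
of them segregate this way to saturate a sparse genetic map, or to build
one from nothing.

`phenomarker` implements that conversion and everything around it: the
mixture modeling, the statistical filters that weed out phenotypes which
would make unreliable markers, interval mapping to place the survivors,
linkage-group machinery for de novo maps, error detection and imputation,
and readers/writers for the rotated-CSV (`csvr`) cross format and GFF3 so
results drop straight into the R/qtl ecosystem and genome browsers.

## Pipeline and models

### Preprocessing

`transform_values()` offers the transforms customary for expression-like
data (`log`, `sqrt`, `reciprocal`, `probit`, `logit`), with hard domain
checks — silently producing `NaN` would corrupt every later step. When
replicated parental measurements exist (at least three per parent),
`select_parental_differential()` keeps phenotypes that differ between the
parents by a Welch *t*-test. Welch rather than pooled-variance because
the parents are different genotypes and nothing guarantees equal
variances. No multiple-testing correction is applied by default — the
selection is a computational pre-filter, not an inference, and a
too-aggressive correction only costs candidate markers; `bonferroni` and
`BH` are available. Replicates are pooled across environments by
default; a phenotype whose parental contrast flips sign across
environments is invisible to the pooled test, which is exactly the kind
of environment-sensitive trait the later QC filters are designed to
remove anyway. The degenerate zero-variance case is defined rather than
an error: equal means give p = 1, unequal means p = 0 with a
`degenerate` flag.

### Mixture model

`fit_mixture()` fits a k-component Gaussian mixture by EM (k = 2 for
RIL/backcross, 3 for F2). Choices that matter:

* **Initialization.** Component *j* starts at the `(j - 0.5)/k` sample
  quantile — deterministic, scale-equivariant — plus seeded jittered
  restarts. All starts run a short, capped EM and only the best
  continues to convergence (the classic short-run strategy: restarts
  matter early, ridge-crawling only needs doing once).
* **Free variances** by default, with a floor of `1e-6` times the total
  variance to stop a component collapsing onto a single point.
  Expression classes often differ in spread; an equal-variance switch
  exists.
* **Convergence** when the log-likelihood gain per iteration drops below
  `tol` (`1e-8`). On unimodal data EM crawls a ridge for thousands of
  iterations, hence the generous `max_iter = 5000`.

The log-likelihood is non-decreasing across iterations within a run — a
guarantee of EM that the tests assert on every fit.

### Which phenotypes qualify as markers

Two filters sit between a fitted mixture and a candidate marker:

* **Multimodality** (`test_multimodality()`): a parametric-bootstrap
  likelihood-ratio test of k components against one Gaussian, p-value
  `(1 + #(LR* >= LR)) / (n_boot + 1)`. The LR is computed by the *same*
  fixed-effort EM on the observed data as on every bootstrap sample.
  That exchangeability is what keeps the test calibrated at finite
  computational effort; using a better-converged fit on the observed
  side only would bias the test liberal. Defaults: `alpha = 0.05`,
  `n_boot = 99`.
* **Segregation** (`test_segregation()`): the mixing proportions must
  sit within `max_deviation` (default 0.1) of the expected segregation
  ratio — 1:1 for RIL/backcross, 1:2:1 for F2. A bimodal phenotype with
  80:20 proportions is not segregating as a single Mendelian locus.

Power is worth stating honestly. At n ≈ 148 the bootstrap LRT selects
essentially 100 % of phenotypes whose genotype classes are 8 residual
standard deviations apart, ~95 % at 4 sd, ~80 % at 3 sd — and only a few
percent at 2 sd, where the mixture density is still unimodal. No
calibrated test can do much better at that separation; the method is
built for phenotypes with *major* QTL, and its published applications
select on the order of 10 % of differentially expressed probes. Passing
the test suite therefore says the selection machinery is calibrated and
powerful where the signal supports it, not that weak-effect phenotypes
are recoverable.

### Genotype calling

`call_genotypes()` assigns each individual to the highest-posterior
component if that posterior reaches the threshold (default 0.8; ties are
always missing). For F2, when the top posterior falls short but exactly
one component can be excluded (posterior below `1 - threshold`), a
semi-informative call `notA`/`notH`/`notB` records the partial
information; on csvr output these map to the standard dominant-marker
codes `C` (not A) and `D` (not B), while `notH` has no csvr code and is
written as missing. With parental data, `label_parental_origin()` maps
the extreme components to whichever parent's mean is nearer; without it,
component order fixes provisional labels and the per-phenotype phase is
arbitrary — resolved later by the mirrored-group merge.

### Two-point linkage and de novo maps

`estimate_rf()` estimates the recombination fraction between two call
vectors: for RIL/backcross the discordant fraction capped at 0.5, with
`LOD = n log10 2 + k log10 r + (n - k) log10 (1 - r)`; for F2 by
maximizing the 9-cell joint-table likelihood numerically. For selfed
RILs the observed discordance `R` is the *expanded* fraction; it is
de-expanded to the meiotic `r = R / (2 (1 - R))` only when distances are
computed. `form_linkage_groups()` then takes the single-linkage
transitive closure over pairs with `rf <= 0.35` and `LOD >= 6`
(conventional grouping defaults).

Without parental labels each phenotype's A/B labels are arbitrary, so
every chromosome splits into two repulsion-phase groups — capped rf of
0.5 makes opposite-phase markers look unlinked. `merge_mirrored_groups()`
finds group pairs in strong negative correlation, inverts one side and
merges. The statistic is the **minimum** pairwise call correlation
between the two groups, not the mean: on a 100 cM chromosome most
marker pairs are far apart and nearly uncorrelated, so a mean dilutes
toward zero precisely for the whole- and half-chromosome groups that
must merge, while a true mirrored pair always contains near-perfect
antagonists. At ~150 individuals a spurious correlation of magnitude
0.7 (the default threshold) is a many-sigma event, so the minimum is
safe from noise. A group negatively correlated with two partners is only
an error when those partners also mirror *each other* (no consistent
phase exists); a group mirroring several same-phase fragments of one
chromosome merges greedily, most negative pair first.
`build_denovo_map()` iterates group → merge → regroup until the phase
flips stabilize, because each flip can make formerly repulsion-hidden
linkage visible. Merging happens before ordering: ordering is only
meaningful once a group contains a whole chromosome in one phase.

`order_markers()` orders each group by greedy insertion minimizing the
sum of adjacent recombination fractions, refined by exhaustive ripple
over sliding windows (default width 6) until no improvement; orders are
canonicalized reversal-wise. Exhaustive search (the test oracle) is used
only for groups of at most 8 markers. `estimate_map()` converts
adjacent-pair rf through Haldane or Kosambi (`d = 25 ln((1+2r)/(1-2r))`,
the default, as partial interference fits real data better) and
accumulates positions from 0; un-estimable gaps get the chromosome's
mean gap and a flag. With a physical-position table,
`name_and_orient_chromosomes()` names each group by the majority
physical chromosome of its markers (a tie is an error; trans-eQTL-driven
markers are expected dissenters) and flips groups whose cM order
anti-correlates with bp order.

### Genome scans and marker QC

`scan_one()` performs Haley–Knott regression: at each grid position the
trait is regressed on the expected genotype given the markers
(`LOD = (n/2) log10(RSS0/RSS1)`), with the environment as an additive
covariate when present. Genotype probabilities come from
`calc_genoprob()`, a forward–backward HMM along each chromosome with
Haldane transitions (RIL-expanded for selfed RILs) and an emission model
in which any call is wrong with probability `error_prob`. Conditioning
on all markers rather than the flanking pair matters once derived
markers enter a map: a miscalled genotype is out-voted by its neighbors
instead of being trusted verbatim. The default `error_prob = 1e-4` suits
curated markers; ~0.01–0.02 suits markers derived from mixture
posteriors at the default calling threshold. With `error_prob = 0` the
scan LOD at a marker equals the closed-form marker-regression LOD
exactly, which the tests verify against an independent least-squares
oracle.

`scan_two()` fits, for every pair of positions (including across
chromosomes), the additive model `y ~ g1 + g2` and the full model with
interaction, both on additive genotype coding. Two summaries feed QC:
the maximum interaction LOD (full − additive; epistasis evidence) and
the second-QTL LOD (best additive pair − best single; multiple-QTL
evidence). `test_gxe()` compares `y ~ g + env` against `y ~ g * env` at
the marker nearest the single-QTL peak.

`classify_candidate()` applies the published filter thresholds —
environment interaction at LOD ≥ 7.5, multiple QTL at LOD > 15 (taken as
the second-QTL LOD; the additive-vs-best-single contrast is what "a
second QTL" means operationally), epistasis at LOD ≥ 7.5, and a
significant QTL at LOD > 5 — with precedence gxe → multi-QTL →
epistatic → no-QTL → single-QTL, and a configurable action (remove or
flag).

A design point: `scan_candidates()` interval-maps the candidate's
**call dosage**, not the raw phenotype. The calls are what will enter
the map, so their cosegregation behavior is the quantity under test —
and because sub-threshold individuals are missing rather than miscalled,
the call trait localizes far more sharply than the phenotype (placement
peaks land within a few cM of truth even for moderate effects). An
epistatic trait whose calls follow the XOR of two loci, or a
multi-QTL trait whose calls chimerize two chromosomes, shows up directly
in these scans. Raw values are the fallback when no calls exist.

### Saturation and error handling

`saturate_map()` scans each candidate on the original map, keeps
single-QTL survivors, inserts each at its peak position (marker id
`m_<phenotype>`), re-estimates the map, and removes candidates that
duplicate another marker (rf = 0; the duplicate with the higher peak
LOD wins) or sit within `colocate_tol` (0.5 cM) of an original marker.
QC runs on the *original* map, before any placement. The telescoping
`SaturationReport` accounts for every phenotype from input to final
marker. Call errors in derived markers inflate adjacent recombination
estimates, so some map expansion after saturation is expected — the
phenomenon is visible in real applications of this class of method too —
which is why placement accuracy should be judged in the original map's
coordinates rather than after re-estimation.

`detect_double_recombinants()` flags calls that disagree with both
flanking markers inside a `window_cm` (default 10 cM) window — at short
distances a double crossover is far less likely than a genotyping
error. Correction (setting flagged calls missing) is off by default.
`fill_missing()` imputes missing calls from the HMM posterior given the
flanking markers, leaving exact ties missing, and reports the imputed
fraction prominently: imputed genotypes are inferences, not
observations.

`theoretical_resolution(n)` returns `100/n` cM — one expected
recombination per 100 meioses sets the spacing a population of `n`
individuals can resolve; with 148 individuals that is 0.68 cM.

## The synthetic-data generator

`simulate_study()` emulates the study design this class of method is
used on: 148 selfed RILs, five 100 cM chromosomes with markers every
10 cM, four environments in balanced blocks, parents measured twice per
environment (8 replicates pooled — comfortably above the 3-replicate
floor of the t-test). Genotypes follow the Markov chain implied by
Haldane distances (RIL-expanded; F2 as two independent gamete chains),
so simulated recombination is interference-free.

Phenotype classes (`simulate_phenotypes()`), with effects in units of
the residual sd (default effect 2, residual sd 1):

* `clean_local` / `clean_distant` — one QTL of size `effect` at a map
  marker; the local variant's physical position is its QTL marker's,
  the distant variant's lies elsewhere (cis vs trans eQTL).
* `gxe` — effect `+effect/2` in half the environments, `−effect/2` in
  the other half. Marginally this trait has *no* QTL and equal pooled
  parental means: it is invisible to the parental t-test, not usefully
  bimodal, and the QC step removes it either as a genotype-by-environment
  interaction (when the interaction LOD clears 7.5) or as showing no
  QTL. Both outcomes are correct — the trait carries no usable marker
  information — so removal, not the specific label, is what the tests
  assert.
* `epistatic` — a main effect plus an equal-size interaction with an
  unlinked locus: bimodal, segregating 1:1, parentally differential —
  a convincing fake whose calls follow the XOR of two loci. The
  two-locus interaction scan is the only filter that catches it.
* `multi_qtl` — two additive QTL on different chromosomes.
* `no_qtl` — noise.

Parental replicates are generated from the same class model with all-A
and all-B genotypes per environment, so every class's parental contrast
(or lack of it) is inherited rather than asserted.

What the generator does *not* emulate: probe-level microarray noise,
batch effects, non-Gaussian residuals, segregation distortion, linked
QTL pairs, or residual heterozygosity in the RILs. Tests passing on
these simulations show the algorithms are correct under the model's own
assumptions; they do not certify performance on data that violates
them.

## Problem sizes and numerical choices

The test-suite and acceptance experiments run at the population size the
method targets (148–150 individuals, 5 chromosomes) with phenotype
panels of 50–150 and two-QTL scans on a 10 cM pair grid — large enough
to measure power and calibration, small enough to run interactively.
Where an experiment needs a *saturating* marker supply (the LOD-gain
comparison), it uses 150 major-effect (4 sd) local-eQTL phenotypes over
a hidden 2.5 cM truth grid; at the default 2 sd supply only a handful of
candidates pass selection on a 500 cM map, which is enough to test
placement accuracy but not to move genome-wide QTL power. The classical
trait used in that comparison carries a 2 sd QTL, a deliberately strong
"showcase" phenotype: with a 1 sd trait the before/after difference is
dominated by sampling noise.

Other numerics: the EM variance floor (`1e-6` of total variance); LOD
values clamped at 0; bootstrap p-values use the `+1` convention so p = 0
is impossible; map functions invert each other to machine precision and
`rf >= 0.5` is an error (unlinked pairs have no distance); rf estimates
from fewer than 2 joint observations are `NA` and the pair is treated as
unlinked; marker orders are canonicalized so reversal-equivalent
solutions compare equal; seeds propagate from a single integer through
every stochastic step, so any result in this package is reproducible
from `(inputs, seed)`.

## Known limitations

* Diploid inbred crosses only (`riself`, `bc`, `f2`); no outbred or
  polyploid designs, no sex-specific maps.
* The two-QTL scan uses additive genotype coding for all cross types;
  the full 8-df F2 two-locus model is not implemented.
* Phenotypes with no major QTL yield no markers — the method cannot
  manufacture signal, only harvest it.
* Marker ordering is heuristic (greedy + ripple); for pathological rf
  matrices the global optimum is not guaranteed.
* Sample mix-up detection between genotype and phenotype data is out of
  scope; dedicated tools exist for that step.
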