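---
title: "Fine-scale ancestry estimation: models, parameters and design choices"
author: "finescale authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fine-scale ancestry estimation: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Within a single country, subpopulations differentiate at the level of
F\_ST ~ 0.002–0.007 — far below what genotype-frequency methods resolve
comfortably, but well within reach of haplotype-based models, which exploit
the co-inheritance of alleles along chromosomes. `finescale` implements a
complete within-country ancestry workflow: it constructs geographically
anchored reference groups from phased genotype panels, expresses each
individual's genome as a mixture over those groups (an *ancestry profile*,
a point on the simplex), validates how far back in time a single
foreign ancestor remains detectable, and tracks how the profiles of birth
cohorts change over the 20th century — the kind of signal left by war-time
evacuations and urbanization.

All stages run end to end on synthetic data generated by the package
itself, so every claim the test suite makes is checked against a known
truth.

## The haplotype-copying painter

The core statistic is produced by a Li–Stephens copying model
(`paint_recipient()`). Each recipient haplotype is modelled as a mosaic of
the donor haplotypes: the hidden state at a site is the donor haplotype
being copied; between adjacent sites the chain stays on its donor with
probability `exp(-n d / H)` (`d` = inter-site distance in cM, `H` = number
of donor haplotypes, `n` = the switch rate), otherwise it switches to a
uniformly chosen donor. The emission matches the donor allele with
probability `1 - M`. The forward–backward recursion yields, per donor
*unit* (an individual, or a basis population):

* the expected **chunk count** — the expected number of maximal
  same-unit runs, computed from the pairwise posterior transition terms
  (a switch *into* a unit always passes through the uniform part of the
  transition kernel, which is what makes the per-unit aggregation exact);
* the expected **copied length** in cM — the posterior unit mass weighted
  by half-interval site lengths, so per chromosome the lengths sum exactly
  to the chromosome's map span per haplotype.

The painter deliberately runs with fixed parameters, a uniform donor
prior, and no EM re-estimation. This keeps it exactly checkable: on
instances with up to 4 sites and 3 donors the test suite verifies the
recursion against a brute-force sum over all hidden-state paths to 1e-10.

**Parameters.** The defaults `n = 3720.27`, `M = 0.00014` correspond to a
dense genotyping-chip regime (one variant per ~0.015 cM). The effective
quantity is the per-interval switch intensity `n d / H`; at the package's
synthetic density (one variant per ~0.5 cM) the equivalent behaviour
requires a much smaller rate, and the pipeline default is `switch_rate =
50`, `mutation_prob = 1e-4` (`run_config()`). Both are plain arguments
everywhere.

## Coancestry, tree, and reference-group selection

Painting every reference candidate against all others (leave-self-out)
gives a square **coancestry matrix** of expected chunk counts with a zero
diagonal. `build_population_tree()` row-normalizes it and applies Ward
(`ward.D2`) agglomeration on Euclidean distances between the profiles —
a deterministic stand-in for an MCMC partition model that preserves the
interface the selection procedure needs: a merge tree that can be cut at
any level K into nested populations.

`select_reference_groups()` then runs the iterative identity-proportion
procedure:

1. cut the tree at `K_start`;
2. estimate leave-one-out ancestry profiles of all candidates against the
   current populations;
3. per population, compute the *identity proportion* — the mean
   own-population proportion of its members;
4. drop every population below 50% identity and repeat from 2 until
   nothing is dropped;
5. drop members whose own-group proportion falls below a threshold
   (0.95 is the conventional choice for a 2-group reference set, 0.70 for
   finer sets);
6. drop geographic outliers, automated here as members farther than a
   configurable distance (default 150 km) from their group's
   coordinate-wise median.

Identity proportions are computed from leave-one-out profiles; including
the member in its own group mean would inflate self-copying and hence
identity. The full audit trail (identities per round, every exclusion) is
returned and `replay_reference_audit()` reconstructs the final groups from
it exactly — the suite asserts this replay is lossless.

Individual copyvectors are painted once against the full candidate set
and reused across the loop's iterations; dropping a population changes the
group means, not the paintings.

## Ancestry profiles

`estimate_profile()` expresses a target copyvector (aggregated to a fixed
basis of donor populations — by default a level-20 tree cut, truncated to
the number of candidates) as a convex combination of the reference groups'
mean copyvectors. The default estimator minimizes the squared error
subject to non-negativity and sum-to-one. With at most 20 groups the
problem is solved *exactly* by enumerating support sets and solving each
equality-constrained system through its KKT conditions; the suite checks
the solution against a 0.001-step grid search. An MCMC variant (posterior
mean under a multinomial likelihood of basis chunk counts with a symmetric
Dirichlet prior, Metropolis-within-Gibbs) is provided for fidelity to the
sampling-based convention, with iteration counts scaled to desk size; it
is not the default because the deterministic estimator is reproducible and
fast, and the quantity of interest is a point estimate.

Small estimated proportions are not reliable evidence of ancestry; the
shrink rule (`shrink_profile()`) zeroes entries strictly below 5% and
rescales the remainder. Entries exactly at the threshold survive. If every
entry is below the threshold the largest single entry is kept — a profile
must remain a profile.

Reference members are always estimated leaving themselves out of their
group mean (`leave_one_out_profiles()`, using the exact deflation
`(n m - x)/(n - 1)`); other individuals are estimated against full groups.

## The pedigree simulator

`sample_gamete()` draws crossovers between adjacent loci with the Haldane
(no-interference) probability `r = (1 - exp(-2 d_M)) / 2`, `d_M` the map
distance in Morgans, and picks the starting haplotype fairly; chromosomes
are independent. `simulate_descendant()` wires `2^G` ancestors into a full
binary pedigree, simulates the meioses generation by generation from the
eldest ancestors down, and tracks each ancestor's realized share of the
final genome by recombining an ancestor-label payload alongside the
alleles. Shares are **cM-weighted** (half-interval weights), not
site-counted: that matches the recombination process and is invariant to
marker density. At G = 1 each parent contributes exactly one half; at
depth G the expected share of any single ancestor is `1/2^G`
(6.25% at G = 4, 3.13% at G = 5), which the simulation suite verifies
within three Monte-Carlo standard errors.

Scenario machinery (`run_scenario()`) draws all `2^G` ancestors from one
pool ("All-X") or all but one ("Almost-X"), estimates each simulated
individual's profile, and records estimates next to realized truth
fractions; 20 replicates per scenario is the convention. Single-origin
classification uses the second-largest All-X component value as the
threshold (the 95% quantile at n = 20).

## The synthetic-data generator

The generator is the package's study system, and its defaults are fixed
study conditions, not tuning knobs:

* **Differentiation.** Ancestral allele frequencies are Uniform(0.05,
  0.95); population frequencies follow the Balding–Nichols Beta
  distribution with parameter `fst_to_root` (default 0.05, the value the
  validation suites use throughout).
* **Founder pools realize their frequencies exactly.** Each population
  has a pool of founder haplotypes (default 30) whose allele counts are
  the rounded expectation under the population frequency, assigned to
  random founders. Differentiation between populations is therefore
  governed by the Beta draw alone: a small pool does not add drift on
  top of the nominal F. Realized pairwise Hudson F\_ST on two `F = 0.05`
  populations lands within ±10–30% of 0.05 across seeds.
* **Haplotypes are founder mosaics.** A sampled haplotype copies founder
  segments of mean length 5 cM (`founder_segment_cm`), the stationary
  outcome of several generations of recombination inside the pool. This
  spreads relatedness evenly across a population. An earlier design that
  built each haplotype from a single meiosis of two founders concentrated
  sharing in sib-like pairs, and those pairs — not the populations — were
  what a Ward tree split first; the mosaic design removes that artifact
  while keeping the shared-segment signal the copying model needs.
* **Geography and cohorts.** Birth places are isotropic normal scatter
  around each population's centre on a planar km grid (all distances in
  the package are Euclidean on that grid); birth years are uniform over
  1923–1987.
* The default desk-scale genome is 4 chromosomes of 50 cM at 1 cM/Mb with
  400 variants; `default_genetic_map()` offers a 22-chromosome, ~3000 cM
  genome when a genome-wide shape matters.

What the generator does **not** emulate: coalescent depth structure,
mutation, background relatedness gradients, uneven chip ascertainment.
Passing tests therefore demonstrate the *procedures* are correct and
recover planted truth under the stated model — they do not certify
accuracy magnitudes on real cohort data.

`plant_admixed_individuals()` appends individuals simulated from
pedigrees whose ancestor slots are drawn (without replacement within one
individual) from named populations, recording true origins and realized
fractions — the substrate for identifiability tests and for the planted
migration-pulse analysis.

## Temporal analyses

* `loess_curves()` fits a degree-2 local regression (span 0.5) of each
  profile component on birth year and renormalizes the smoothed components
  to the simplex at every grid year (raw fits are returned alongside,
  since per-component smoothing does not preserve the simplex by itself).
  Confidence bands are pointwise normal approximations,
  fit ± 1.96 × SE.
* `profile_entropy()` is Shannon entropy in bits, `-sum p log2 p`; zero
  for a single-source profile, `log2 k` for a uniform one.
* `heterogeneity_slope()` regresses yearly entropy on year, weighting each
  year by its sample count; the period split puts the boundary year 1950
  in the *pre* period.
* `pairwise_fst()` is the Hudson ratio-of-averages estimator with
  standard errors from a delete-one block jackknife over chromosomes;
  monomorphic sites drop out of both sums.
* `municipal_average()` weights every individual's profile by the inverse
  squared distance to each municipality centre, flooring distances at
  5 km so near-centre individuals cannot dominate; all individuals
  contribute to all municipalities (a cutoff radius is available as an
  explicit deviation for very large cohorts).

### Detecting a planted migration pulse

The acceptance analysis plants a pulse: individuals born before a
configured onset year are single-origin; those born at or after it carry
one parent from the source population. The onset estimate is the first
grid year at which the LOESS curve of the source component crosses the
midpoint between its pre-pulse baseline and post-pulse plateau (means over
the years at least a decade away from onset on either side). With one
individual per year over 1923–1987 the estimate lands within ±2 years of
the planted onset — a scaled-down analogue of dating a historical
migration from cohort profiles.

## Numerical choices and degenerate inputs

* Forward–backward is scaled per site; a NaN in the forward pass is an
  error rather than a silent fallback. A zero-cM-span chromosome is a
  single block (copied length 0).
* Neighbor counting uses a closed boundary (distance exactly equal to the
  radius counts); outlier flagging uses a strict inequality at its
  threshold. Both conventions are documented at the function level and
  pinned by tests.
* The Hardy–Weinberg filter uses the exact conditional (Levene–Haldane)
  test computed by full enumeration in log space, so the 1e-6 threshold
  is meaningful at any sample size; ties in the tail sum are absorbed
  with a 1e-12 relative slack.
* The simplex solver declares a model degenerate when all group vectors
  are identical and returns a uniform profile with a warning instead of an
  arbitrary vertex.
* `spatial_thin()` recomputes neighbor counts after every single removal
  (the stated loop implies it); batch recomputation would remove more
  points than necessary in dense clusters.
* Sample-level QC bounds on the inbreeding coefficient are ±0.04 by
  default — the dense-chip convention. The end-to-end pipeline exposes the
  bound in its config and defaults to ±0.25 because the sampling noise of
  F scales as `1/sqrt(L)` and at a few hundred variants the chip bound
  would reject typical individuals.
* One global seed fans out to fixed per-stage seeds in `run_pipeline()`,
  so any stage is reproducible in isolation; the manifest records md5
  checksums of every artifact.

## Problem sizes

The validation suites run at desk scale, chosen once: two populations of
24–52 individuals, 400 variants on 4 × 50 cM chromosomes for structure
recovery; 2,000 variants and 100 diploids per population for the F\_ST
comparison; 400 pedigree replicates for the `1/2^G` expectations; 50
random seeds for the thinning invariants. At these sizes the full test
suite completes in well under a minute of compute.

## Known limitations

* The painter's fixed-parameter, uniform-prior design underestimates
  minor ancestry components at pedigree depths G ≥ 3 (the estimates remain
  correctly ordered, which is what the identifiability analysis needs).
* Ward clustering is a deterministic surrogate; it preserves the tree
  interface but not the likelihood semantics of the MCMC partition model
  it stands in for.
* Identity proportions from leave-one-out profiles are slightly
  conservative relative to full-group profiles.
* Geodesic geometry, population-density rasters, sex-specific maps,
  crossover interference and the X chromosome are out of scope.
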