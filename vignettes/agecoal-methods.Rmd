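---
title: "Coalescence rates from dated mutation sharing: models and choices"
author: "agecoal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coalescence rates from dated mutation sharing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`agecoal` estimates the coalescence rate through time between a *target*
and a *reference* set of chromosomes, using only whether mutations carried
by the reference are shared by the target. The anchor is a collection of
mutations dated with a genome-wide genealogy: each carries an age interval
given by the times of the nodes below and above the branch it maps to, and
the mutation's age is taken uniform on that branch (neutrality).

Under the infinite-sites assumption, a derived allele of age $a$ carried
by a reference chromosome is shared by the target chromosome exactly when
the two lineages coalesced more recently than $a$. With a
piecewise-constant coalescence rate $\lambda(t)$ and the coalescence
forbidden before $t_0$ (the older of the two sample ages, for ancient
samples),

$$ P(\text{shared} \mid a, \lambda) \;=\; 1 - \exp\!\Big( -\int_{t_0}^{a}
\lambda(s)\, ds \Big). $$

The likelihood multiplies this over sites, over homologous chromosomes in
both sets (so no phasing is needed), and — for read-level input — over
reads, and is maximised over the per-epoch rates by an EM algorithm in
which the pair's latent coalescence time plays the role of the missing
data. The complete-data statistics are, per epoch, the expected number of
coalescence events and the expected waiting time (exposure); the M-step is
the occurrence/exposure ratio, as in any piecewise-exponential model.
Inverse rates $1/(2\lambda_e)$ are reported as diploid effective
population sizes.

Sites fixed and derived in every sample of the dating genealogy must be
included, because external samples can coalesce onto the root branch;
their age is capped by the TMRCA to an outgroup, 10 million years for
human–chimpanzee, which is also the grid's final boundary `tOut`.

## Time grid and units

All internal computation is in generations; years enter only at I/O,
converted with a configurable generation time (default 28 years). Mutation
rates are quoted per generation while epochs are usually quoted in years
before present, so the conversion must live in one place — the
`TimeGrid`. The default grid has one linear bin up to 1,000 generations
followed by 28 log-spaced bins up to `tOut`, mirroring the log-scale time
axis on which such rates are plotted. The original implementation's grid
is not published; this default is the package's own choice.

## Binned likelihood: why ages are integrated within bins

The EM consumes only the number of shared and not-shared observations per
time bin and per genomic block, so its cost is independent of genome
length and sample count. Two conventions are offered for where a binned
observation "lives" in time:

* `binAges = "uniform"` (default): the observation's age is uniform over
  its bin, and the per-bin sharing probability and E-step expectations are
  integrated analytically (closed forms exist because the hazard is
  constant within a bin). Since branch mass genuinely is uniform on a
  linear scale, this is exact in aggregate, and wide bins stay unbiased.
* `binAges = "midpoint"`: all of a bin's mass sits at the bin midpoint.
  Cheaper, and it matches textbook closed forms (with all counts in one
  bin of midpoint $a$, the single-epoch MLE is
  $-\log(n/(s+n))/(a - t_0)$), but it is measurably biased once bins span
  a few-fold range in time: in the infinite-data limit on a six-epoch grid
  we observed per-epoch biases up to ~15%, oscillating in sign between
  neighbouring epochs. A geometric-mean representative age is worse still,
  because age mass is uniform on a *linear* scale within a bin.

A second, independent conditioning choice matters more than either: if the
count grid and the rate grid coincide and are coarse, each epoch's rate is
recovered by sequentially deconvolving a survival curve from as many
proportions as epochs, and noise compounds multiplicatively from epoch to
epoch (a factor ~2–3 per epoch). Binning the counts on a finer grid while
constraining the rates to coarser epochs (`rateGrid=`) gives the fit
within-epoch age resolution and removes that amplification; the M-step
simply pools events and exposures across the fine bins of an epoch. This
is the recommended way to run the estimator, and what the package's own
validation does (six rate epochs, five geometric count bins per epoch).

## EM mechanics

* **Acceleration.** The fraction of missing information here is large and
  plain EM can crawl for thousands of iterations along flat ridges. Each
  cycle therefore takes two EM steps and attempts a SQUAREM-style
  extrapolation, kept only if it does not lower the observed
  log-likelihood; the recorded trace is thus non-decreasing by
  construction.
* **Stopping.** Iteration stops when the relative log-likelihood change
  falls below `tol` (default 1e-8) *and* rates are stable (relative
  per-epoch change below 1e-6, judged against the dominant rate so epochs
  pinned at a boundary cannot stall the test), or when the likelihood has
  been flat for eight consecutive cycles — residual drift is then along a
  ridge the data cannot resolve.
* **Boundaries.** Rates are clipped to `[0, rateCap]` (default 1 per
  generation, a bound that keeps the M-step finite under degenerate
  all-shared data). While any shared mass exists, rates are floored at
  1e-15 so that a boundary epoch cannot assign probability zero to an
  observed sharing event in a bootstrap resample. Epochs with negligible
  exposure inherit the neighbouring estimated rate, so curves remain
  defined through data-sparse epochs.
* **Initialisation.** A flat curve at the single-epoch MLE, found by
  bracketed one-dimensional search of the same binned likelihood.
* **Shared singletons.** A mutation that is a singleton in the dating
  genealogy and is observed shared must be older than the coalescence of
  target, reference and the carrier, which biases its age upward relative
  to uniform. The binned statistics keep shared-singleton mass in a
  separate matrix; the EM treats the pooled mass as a latent-age mixture
  whose prior profile is the uniform interval mass and whose posterior is
  re-tilted by the current per-bin sharing probability each iteration.
  This is a pooled approximation of per-mutation re-sampling (the
  published recipe is in unpublished supplementary material);
  `dropSharedSingletons = TRUE` excludes the mass instead.
* **Observations inconsistent with the sample ages** — shared mutations
  whose whole age interval predates $t_0$ — indicate dating or sequencing
  error; the model gives them probability zero, so they are dropped and
  counted in `diagnostics$droppedBelowT0`.

## Read-level input

Low-coverage and ancient samples enter as per-read pileups at the dated
sites. A read is accepted when its mapping quality exceeds 30, its length
exceeds 34 bp, it has fewer than three mismatches, and the site is at
least two bases from the read end; sites showing more than two distinct
alleles are skipped. Each passing target read contributes one observation
weighted by the reference's carried-copy weight (derived dosage, or
derived-supporting read count when the reference is also a pileup) — the
likelihood multiplies across reads and read pairs. Multiplying across
reads double-counts non-independent evidence at high coverage;
`maxReadsPerSite` can cap it, with no cap as the default. The
transversion-only mode (`filterTransversions()`) is the mitigation for
ancient-DNA deamination damage; no explicit damage model is fitted.
Coverage masks pass sites with depth at least 5 and below twice the mean
genomic coverage, and are expressed in BED convention.

## The synthetic generator

`simulatePair()` / `simulatePairs()` draw a pair coalescence time from the
true piecewise-exponential hazard, then lay down Poisson mutation
complements: private to the reference lineage with mean
$\mu L (T - t_{\mathrm{ref}})$ and uniform true ages below $T$, and shared
ancestral-lineage mutations with mean $\mu L (t_{\mathrm{out}} - T)$ above
$T$; draws beyond the cap are truncated at $t_{\mathrm{out}}$ and carry no
shared sites. Fixed-site augmentation for real tables follows the same
Poisson law with mean $\mu l (t_{\mathrm{out}} - t_{\mathrm{sample}})$,
positions drawn uniformly with replacement and repeats collapsed (a
two-state model: a second hit at a derived fixed site leaves the observed
state unchanged, so the appended count follows the Poisson-occupancy law
$\mathrm{Binomial}(l, 1 - e^{-m/l})$ rather than the raw Poisson — a
~0.24% deflection at the densities we test).

Dating noise is emulated by reporting the interval
$[a(1-h),\, a(1+h)]$ around the true age (exact ages via a vanishing
interval at $h = 0$). Note this centred emission contradicts the
estimator's uniform-age assumption — the true age is the interval's
centre, not uniform — so $h > 0$ tests robustness to a genuinely
misspecified dating model; with $h = 0.3$ we observe systematic per-epoch
errors up to roughly +20% in low-rate epochs adjacent to high-rate ones.

What the generator does *not* emulate: recombination within a region
(each region has a single coalescence time; independence across regions
stands in for linkage blocks), gene conversion, biased ancestral-allele
polarisation, deamination-like asymmetric errors (reads flip to a uniform
different base), and real genealogy-inference dating error beyond the
interval widths. Passing tests therefore demonstrate correctness of the
estimator under its own assumptions and robustness to coverage and
interval noise — not immunity to the systematic artefacts of real data.

### Validation scale

The package's statistical validation uses a six-epoch alternating
(zigzag) history with boundaries at 800, 4,000, 12,000, 36,000 and
108,000 generations below the outgroup cap and rates
$(1.2, 0.6, 0.9, 0.15, 0.18, 0.03)\times 10^{-4}$ per generation:
per-epoch hazards stay within a factor ~10 so every epoch retains
surviving lineages. Recovery runs use $2\times 10^5$ independent regions
at 8 dated mutations per generation of time depth (at least ~6,400
expected observations in the narrowest epoch) — precision is governed by
the number of independent coalescence draws, not by mutation count alone,
because all mutations of a region share one coalescence time. The
low-coverage comparison uses thirty 20 Mb blocks with 100 block-bootstrap
replicates, requiring overlapping 95% intervals wherever an epoch expects
at least 100 read observations.

## Downstream statistics

* **Integrated rates** over a window in years are
  $\sum_e \lambda_e\, |{\rm bin}_e \cap {\rm window}|$ — expected
  coalescences, not time-averaged rates; the choice only rescales the
  mixture design matrix and response jointly, leaving coefficients'
  interpretation intact.
* **Directional-migration mixtures** fit a focal integrated-rate profile
  against surrogate-source profiles by non-negative least squares
  (Lawson–Hanson, KKT verified to 1e-8), with entry-resampling bootstrap
  (1,000 replicates, 2.5/97.5 percentiles). The construction of the focal
  profile from recently coalesced lineages requires genealogy inference
  and is accepted as input. An optional user-supplied affine rescaling
  can reconcile rate levels between estimators; none is applied by
  default.
* **PCA** on epoch-wise rate matrices mean-imputes missing entries,
  drops constant columns, standardises columns to mean 0 / sd 1 and uses
  `prcomp`.

## Mutation-spectrum statistics

Trinucleotide classes are strand-collapsed to a pyrimidine centre
(96 classes). The CpG-context exclusion removes 20 classes, leaving 76;
the published account states only the counts, and natural symmetric
definitions ("either allele creates CG on either strand") flag 23–24
classes, so the shipped rule `pulse20` is an explicit reconstruction
constrained to the printed counts: ancestral CpG (central C with right
flank G; 12), derived CpG (T>C with right flank G; 4), and derived CpG on
the opposite strand (T>G with left flank C; 4). The rule is pluggable.

A class's relative rate per epoch divides its opportunity-normalised,
age-binned mutation density by the mean over the 76 retained classes,
cancelling shared temporal trends; singletons and terminal-branch
mutations are excluded (with `carrierCount == 1` as the terminal proxy
when no flag is supplied — the same set, with a warning). The integrated
mutation intensity (IMI) scales the curve to mean 1 over 0.1–1 My (before
the signature of interest), then integrates the excess over 14 ky–1 My in
log10 time; epochs missing at the recent end take the earliest available
value, the published treatment of samples older than 14 ky. A constant
curve has an IMI of exactly 0 (the scaling divides equals by equals).

For samples too shallow for curves, the TCC>TTC proportion counts dated
sites with at least four reads, at least four derived-supporting reads,
and branch upper age below 100 ky, relative to all non-CpG C>T
transitions, with a 10 Mb block bootstrap.

## Known limitations

* The likelihood multiplies over sites that share latent coalescence
  times, i.e. it is a composite likelihood: point estimates are
  consistent, but naive information-based intervals would be too narrow —
  hence the block bootstrap.
* Rate estimates in epochs where few lineage pairs remain uncoalesced are
  intrinsically noisy, and the oldest epochs are informative only through
  the outgroup-capped fixed sites.
* The shared-singleton treatment is a pooled approximation; the
  rescaling between genealogy-based and sharing-based rate levels is not
  implemented (the published account defers it to supplementary
  material).
* `importTreeTables()` consumes tskit-style node/edge/site/mutation
  tables dumped to text; it does not read native `.trees` files.
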