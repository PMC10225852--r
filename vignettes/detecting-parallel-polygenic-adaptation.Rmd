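---
title: "Detecting parallel polygenic adaptation from temporal allele-frequency covariance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting parallel polygenic adaptation from temporal allele-frequency covariance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Polygenic adaptation moves a trait by small coordinated frequency shifts at
many loci. No single locus sweeps, so outlier scans have little power. When
two populations face the same novel pressure — here, the historical template
is trans-Atlantic cod under twentieth-century fishing — a shared polygenic
response leaves a subtler fingerprint: allele-frequency *changes* over time
covary positively across the populations, genome-wide. This package
implements that test for the five-cohort sampling design (population A
sampled once historically and twice contemporaneously, population B once
historically and once contemporaneously), together with the simulation
machinery needed to ask whether neutral demography or background selection
could fake the signal.

## The statistic

For two comparisons with per-locus allele-frequency-change vectors
$\Delta s_1$ and $\Delta s_2$ over a common locus set,

$$\mathrm{ConvCor}(\Delta s_1, \Delta s_2) =
  \frac{\operatorname{cov}(\Delta s_1, \Delta s_2)}
       {\sqrt{\operatorname{var}(\Delta s_1)\,\operatorname{var}(\Delta s_2)}},$$

i.e. the Pearson correlation of paired per-locus changes. Some write-ups
print the denominator as the raw variance product without the square root
while still describing (and bounding) the quantity as a correlation; we
implement the Pearson form as the statistic — it is the only reading under
which the reported magnitudes (a shared-baseline control near 0.5 or 0.7)
are attainable — and expose the literal unbounded form behind
`conv_cor(..., literal = TRUE)` purely for audit. Similarly, whether
changes should be mean-centred is not decidable from the usual
descriptions; we centre (sample moments, $n-1$ denominators) by default and
provide `centered = FALSE` for comparison. Genome-wide mean change is tiny
in practice, so the two agree closely.

Four canonical comparisons are computed (`canonical_convcors()`):
cross-population tests ConvCor_1 and ConvCor_2 (population B's temporal
change against each of population A's two temporal changes), the positive
control ConvCor_3 (population A's two changes, which share the historic
baseline sample), and the negative control ConvCor_4 (B's change against
the A-modern-to-A-modern "change", which is nearly pure sampling noise).
Under the null, ConvCor_3 converges to
$\sigma^2_0 / (\sigma^2_0 + \sigma^2_1) = 0.5$ when baseline and terminal
sampling variances are equal and drift between the two modern samples is
negligible — a useful internal calibration check, verified both in closed
form on the synthetic generator and in forward simulations.

Uncertainty comes from a percentile bootstrap over loci (default 100
resamples, 95% level): loci are the resampling unit, paired changes are
resampled together, and degenerate (zero-variance) resamples are redrawn up
to a bounded retry count so NaNs never contaminate the percentile ordering.
BCa was not used: at genome-wide locus counts the plain percentile
interval is already stable to the third decimal, and the replicate count
and level are configurable where more is wanted.

## Filtering and frequencies

The ingestion path mirrors the standard temporal-genomics hygiene for
mixed historic/modern data: genotype calls with Phred-scaled quality below
30 are masked (`mask_low_quality()`; strictly `GQ < 30` is removed); loci
are screened for missingness in a designated *reference* cohort — the one
with the worst missing-data profile — keeping loci strictly below 40%
missing there and applying that subset to every cohort; loci must be
biallelic with minor allele frequency at least 0.05. Boundary conventions
follow the protocol wording: *less than* 40% and *less than* 0.05 are
strict removals. The MAF is pooled across all sampled individuals by
default (the same filter a simulated sample set receives); a per-cohort
mode exists. Frequencies are plain sample proportions over non-missing
calls — no shrinkage or genotype-likelihood estimation — and each pairwise
change vector uses the complete-case locus intersection for that
comparison rather than a global five-cohort intersection (this maximizes
loci per comparison; a global-intersection run can be obtained by
pre-subsetting). Internally coordinates are converted at the boundaries:
VCF positions are 1-based, BED intervals 0-based half-open.

## F_ST

`wc_fst()` implements the Weir & Cockerham (1984) two-population diploid
estimator from its variance components $a$, $b$, $c$, with the genome-wide
summary as the weighted ratio of sums $\sum a / \sum(a+b+c)$ — the
"weighted F_ST" of the standard command-line tools — and the unweighted
mean of per-locus ratios reported alongside. Negative per-locus estimates
are retained in the sums. Temporal F_ST treats the two time points of one
population as the two "populations". Loci need at least two called
individuals per cohort to contribute. The implementation is validated
against an independent scalar transcription of the published component
formulas and through a VCF export/re-read round trip.

## The forward simulator

`run_scenario()` is a discrete-generation Wright–Fisher forward simulator
with a sparse genome representation (per-haplotype sorted sets of mutation
ids — the only feasible contract at these mutation counts), written in
C++. The life cycle per generation: fitness evaluation, fitness-weighted
parent sampling within each subpopulation (two distinct parents per
offspring), meiosis with Poisson($Lr$) crossovers at uniform positions,
Poisson($L\mu$) new mutations per gamete (typed, and recorded in a
registry with origin generation and origin subpopulation), then post-split
migration in which each offspring independently relocates with probability
$m$. Census offspring counts follow the demographic schedule exactly;
realized island sizes fluctuate only by the binomial migrant counts, which
are not rebalanced.

The default demography encodes the cod template: ancestral $N_e = 7000$,
burn-in 57 400 generations, a split into two subpopulations that grow to
$N_e = 35\,000$ over 6530 generations, migration $10^{-2}$–$10^{-6}$, a
5 Mb chromosome with $r = 1.5\times10^{-7}$ and $\mu = 1.64\times10^{-8}$
per base per generation, and five cohorts of 20 diploids (subpop1 at 6525,
subpop2 at 6530, and three samples at 6540 generations post-split).

Design choices where the source description was genuinely open:

* **Reproduction model.** Demographies like this one are sometimes run in
  non-Wright-Fisher engines with explicit survival and fecundity; those
  schedules change the mapping from census size to per-tick drift. We use
  strict WF with one generation per time step: every quantity the
  analysis consumes (F_ST, convergence correlations, variant ages and
  frequencies) is controlled by $N_e$, $\mu$, $r$, $m$, $s$, which WF
  matches by construction at the nominal generation count — see
  *Limitations* for what this choice does to absolute drift.
* **Growth law.** "Grew at a constant rate" is read as a constant
  multiplicative rate: $N(t) = N_{\mathrm{anc}} g^t$ with
  $g = (N_{\mathrm{final}}/N_{\mathrm{anc}})^{1/T}$; a linear mode is one
  flag away. Exponential growth is the natural reading and the common
  default for post-bottleneck expansion.
* **Split initialization.** Each subpopulation starts at
  $N_{\mathrm{anc}}$ (drawn from the ancestor) and grows five-fold; the
  description fixes only the endpoints.
* **Stabilizing-selection width.** The QTL fitness function
  $w = \exp(-(z - z_{\mathrm{opt}})^2 / 2\omega^2)$ needs a width that is
  rarely pinned down in applications. Default
  $\omega = 5$ (phenotype units), so one heterozygous unit-effect QTL
  costs about 2% fitness; it is config-exposed.
* **Mutation stacking.** Multiple hits at one base stay distinct registry
  records; export emits one record per derived allele, so a stacked site
  appears as split records sharing a position, is flagged multi-allelic on
  both the write and read paths, and is removed by the standard biallelic
  filter.

The three-type mutation model draws each new mutation as neutral,
recessive deleterious ($h = 0$; $-s \sim$ Gamma with mean 0.05 and shape
0.5, fitness factor $\max(1+s, 0)$ when homozygous, multiplicative across
loci) or a QTL (additive effect $\sim N(0, 1)$, phenotype
$z = \sum \mathrm{dosage} \times \beta$, Gaussian stabilizing selection
toward 0) with equal probabilities.

## Rescaling

`rescale_scenario()` applies the standard population-rescaling protocol:
sizes and generation counts divided by $Q$ (rounded), $\mu$, $r$, $m$ and
selection coefficients multiplied by $Q$, preserving $\theta = 4N\mu$,
$\rho = 4Nr$, $Nm$ and $Ns$; QTL effect variance is unchanged while
$\omega$ is divided by $\sqrt{Q}$ so the log-fitness load per phenotype
unit scales with $Q$ like any other selection coefficient. A guard refuses
rescaled sizes below 50. The desk profile (`desk_scenario()`) additionally
cuts the chromosome to 0.5 Mb with $r$ raised ten-fold first, preserving
chromosome-level $\rho$. All replicated analyses in this package use
$Q = 50$, $L = 5\times10^5$ and 3–5 replicates per scenario; one desk
replicate takes a few seconds, a full scenario a couple of minutes on one
core, which is what makes replicated grids routine on a laptop.

Three rescaling artifacts are worth naming precisely, because they bound
what desk-scale numbers can and cannot reproduce:

1. **Sample-time collapse.** At $Q = 50$ the 6525/6530/6540 sampling
   generations all round to the final generation, so "historic" and
   "contemporary" cohorts become independent draws from the same
   generation. This is benign here — at full scale the drift across those
   5–15 generations is itself negligible (temporal F_ST ≈ 0, which is
   also the finding for the real populations) — and it is exactly what
   makes ConvCor_3 ≈ 0.5 and ConvCor_4 ≈ 0 hold.
2. **Truncated frequency spectrum.** New mutations enter at frequency
   $1/(2N/Q)$, $Q$ times higher than at full scale, and the equilibrium
   spectrum loses its rare tail below that bound. Quantities conditioned
   on frequency thresholds inherit a systematic $Q$-dependence: young
   (post-split) mutations reach "common" frequencies (> 0.05) far more
   often than at full scale, deflating the share of common variants that
   predates the split, while the per-type fractions of segregating
   variants predating the split and their conditional mean frequencies
   are inflated. Runs at $Q = 100$ versus $Q = 50$ confirm the monotone
   trend toward the full-scale values as $Q$ decreases. Desk-scale
   origin-epoch numbers should therefore be read as qualitative
   (ordering and magnitudes), not as point reproductions.
3. **Strong-coefficient flooring.** Scaled deleterious coefficients
   (mean $-0.05 Q$) frequently exceed $|s| = 1$, so homozygotes floor at
   fitness 0: the scaled deleterious class behaves like recessive
   lethals. This preserves the qualitative purging of shared deleterious
   variation but compresses the fitness-effect spectrum.

## Limitations

The WF generation-per-tick substitution produces *more* drift per nominal
generation than a non-WF engine with overlapping generations would; our
neutral spatial F_ST at the lowest migration rates (~0.17–0.21 weighted,
after MAF filtering) accordingly sits above what an overlapping-generations
engine run at the same nominal generation count would produce (roughly
0.08–0.12 for an effective generation time near two ticks), while matching
this simulator's own coalescent expectation ($1 - \pi_w/\pi_b$) to a few
percent. Comparisons
across migration rates, the near-zero temporal F_ST, and all
convergence-correlation behaviour are unaffected. The simulator also uses
a single chromosome with uniform recombination, no gene conversion, no age
structure and no variable recombination map; linkage disequilibrium
heterogeneity (e.g. inside inversions) is outside its scope.

## The synthetic generator

`synth_generate()` is the fast statistical stand-in used to test and
calibrate every statistics module in milliseconds: independent loci, a
MAF-truncated $1/x$ initial spectrum shared by both populations,
deterministic shared-direction selection shifts
$s \cdot \beta \cdot p(1-p)$ (clamped to $[0,1]$ with clamps counted),
binomial drift with $2N_e$ draws, and binomial sampling noise with
$2 \times 20$ chromosomes per cohort. The two modern cohorts of population
A are drawn zero drift-generations apart — in the cod design the two
modern samples lie a few years apart against a ~10-year generation time —
which is precisely what makes ConvCor_4 a negative control. What it deliberately lacks: linkage (loci independent),
realistic site-frequency spectra, migration coupling, and missing data.
Passing tests on synthetic data therefore demonstrate the statistical
machinery (centring, calibration, monotonicity, seeding), not robustness
to the LD and ascertainment structure of real genomes — that is what the
forward simulator and the filtering tests are for.

`evaluate_detection()` operationalizes the inference rule "the 95%
bootstrap interval excludes zero" and reports its Monte-Carlo type-I error
and power; on nulls of 1000–2000 loci the rule holds its nominal level
within binomial error.

## Reproducibility

Every stochastic stage takes a seed; one root seed is fanned out to named
child streams (`child_seeds()`), so the bootstrap, the simulator and the
synthetic generator are independently reproducible, and identical seeds
give bit-identical outputs (asserted in the test suite). The numbered
scripts under `analysis/` regenerate all tables in `results/`, and
`scripts/acceptance.R` recomputes the headline simulation quantities from
scratch.
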