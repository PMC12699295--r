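---
title: "Models and methods behind ctcfdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ctcfdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific problem

CTCF marks the boundaries of chromatin loops, but boundary strength varies
widely between sites with similar CTCF occupancy.  A state-centric view
resolves this: a DNA-bound CTCF molecule is not a static footprint but an
ensemble of conformations in which blocks of its eleven zinc fingers (ZFs)
wrap and unwrap from the motif on the millisecond timescale — the same
timescale on which an extruding cohesin complex traverses the CTCF
footprint.  Whether cohesin is captured or slips through then depends on
which conformation it encounters, so boundary permeability is encoded in
the composition of the ensemble, which chromatin context (motif sequence,
CpG methylation, partners such as PDS5A) can tune.

`ctcfdyn` implements the quantitative machinery for four experimental
views of this ensemble, together with synthetic-data generators that
emulate each experiment with known ground truth:

* **footprint** — single-read GpC methyltransferase footprints at CTCF
  motifs (NOMe-seq–style): read classification, per-ZF protection, ZF
  co-binding, ChIP stratification and correlation.
* **trace_hmm** — optical-tweezers DNA-unzipping traces: hidden Markov
  segmentation of fork-position fluctuations into conformational states,
  with occupancies, lifetimes and transition rates.
* **kymo** — kymograph-derived single-particle trajectories on DNA: 1D
  diffusion, binding dwell survival, colocalization and bounce/dock
  encounter outcomes, nearest-motif positions.
* **rupture** — irreversible unzipping: force-rip detection, N-/C-terminal
  assignment, and two-component decomposition of rupture-force
  distributions.

Because the raw experimental datasets are not redistributable, every
quantitative claim the package makes about itself is a parameter-recovery
statement: generators are calibrated to published summary values, and the
analyses must recover those values from raw synthetic observations.  The
test suite and `scripts/acceptance.R` are exactly these checks.

# Coordinate conventions

Motif-relative positions are signed integers with 0 at the motif center
(rounded down for even-length motifs; BED input is 0-based half-open) and
negative coordinates on the N-terminal-protein side.  The default ZF map
tiles `[-16, +16]` bp with eleven 3-bp windows ordered ZF11..ZF1 from
negative to positive, so ZF1–2 sit at the C-terminal end of the motif and
ZF9–11 at the N-terminal end; flanking nucleosome-depleted-region (NDR)
windows at `[-60, -20]` and `[+20, +60]` bp serve as the accessibility
reference.  The exact ZF register in vivo is uncertain at the 1–2 bp
level, so `zf_map()` is a replaceable table rather than a constant.
Minus-strand motifs are handled by mirroring (`orient_calls()`); all
per-ZF statistics are invariant under a strand flip plus mirror, which the
test suite asserts.

# The footprint model

## Generator

`gen_methyl_reads()` draws each read's archetype from a four-class
mixture — `ctcf_full` (all ZF windows protected), `ctcf_partial` (core
ZFs 3–8 protected, each peripheral ZF independently protected with its
own probability), `nucleosomal` (147-bp window protected), `unbound`
(nothing protected) — and then applies a two-parameter labeling model:
accessible GpCs are methylated with `label_efficiency` (default 0.85) and
protected GpCs with `background_methylation` (default 0.05); calls drop
to missing with `missing_rate` (default 0.05).  Published work does not
report enzyme efficiencies, so these defaults were fixed once at values
typical for exogenous GpC methyltransferase labeling and are exposed in
the configuration.

GpC sites sit on a regular 3-bp grid over `[-120, +120]` bp.  A grid is a
deliberate simplification — the analysis depends only on call positions —
and 3 bp is the one spacing that puts exactly one site in every 3-bp ZF
window; a 4-bp grid leaves ZF4 and ZF8 entirely siteless, which would
make per-ZF protection undefined there.  Real data instead has
sequence-determined, irregular GpC placement with a GpC-poor ZF5 triplet;
the generator does not emulate sequence, so ZF5 exclusion is available as
an analysis option (`exclude_zf`) rather than emerging from the data.

## Classification

A read is summarized by three methylated fractions over called sites:
core (ZF3–8 windows), pooled NDRs, and a broad 147-bp window.  Defaults:
`ctcf_bound` when core ≤ 0.2 and NDR ≥ 0.6; `nucleosomal` when broad
≤ 0.2 and NDR < 0.6; otherwise `unbound`; reads lacking a called site in
the core or either NDR are `unclassifiable` with a reason.  The
thresholds separate the generator archetypes nearly perfectly and are
configurable, since the exact published rule is not in the main text of
the source literature.  One known consequence of the 0.2 core cut: with
six core sites and 5% background methylation, about 3% of genuine CTCF
reads show two or more background-methylated core calls and fall through
to `unbound`, so recovered CTCF fractions run ~1.5 percentage points
below truth — well inside the tolerances used here.

## The protected fraction is estimated, not counted

The strict sub-label (`protected` = zero methylated calls in every ZF
window) is reported per read, but it is a biased estimator of the fully
protected fraction: with eleven windows and 5% background, only
`0.95^11 ≈ 0.57` of truly protected reads survive the strict rule.
`estimate_protected_fraction()` therefore defaults to a model-based
estimator.  Labeling rates are first estimated from sites whose state is
known in every CTCF-bound read — core ZF windows (protected) and NDR
sites (accessible) — using *truncated* binomial maximum likelihood,
because the classification itself selects reads with low core and high
NDR methylation and would otherwise bias both rates.  An EM algorithm
then fits a two-population model to the per-read peripheral-ZF
methylation counts: fully protected reads emit at the background rate in
every window, partially protected reads carry independent per-ZF binding
probabilities.  One numerical caveat drove the implementation: the
likelihood ridge between the mixture weight and the per-ZF probabilities
is nearly flat, so the EM is stopped on parameter change rather than
log-likelihood gain, and the bootstrap restarts warm-start from the full
fit.

## Stratification and correlation

Decile stratification by ChIP score ranks motifs with ties broken by
motif id (reproducibility), summarizes each cluster × decile cell by the
median with a percentile-bootstrap CI (10,000 resamples over motifs by
default), and compares the 1st and 10th deciles with a two-tailed
Mann–Whitney test (`stats::wilcox.test`, exact for small samples, checked
against an in-repo full-enumeration oracle).  No multiple-testing
correction is applied across ZF clusters, matching the raw two-tailed
p-value convention of the source analyses.  Pearson correlations between
per-motif per-ZF inaccessibility and ChIP scores use the t-approximation
for p-values and mask zero-variance columns.

# The conformational-ensemble model

## Generator

The hidden conformation path is a strictly sequential (birth–death)
continuous-time Markov chain over four states; `gen_fork_trace()`
simulates it by the Gillespie algorithm (exact exponential event times),
snapshots the state on the sampling grid, and adds Gaussian emission
noise per state.  Exact event-time simulation avoids the discrete-time
approximation bias that a per-frame jump simulation would put into
lifetime recovery.  Emission means and SDs for the four conformations
are the published mapped positions: −27.1 ± 5.5, −15.5 ± 5.7, −3.0 ± 5.7
and +20.1 ± 11.4 bp from the motif center.

`ensemble_rate_matrix()` builds the generator from a stationary
distribution plus lifetimes of states 1..K−1; flux balance on a sequential
chain fixes the last lifetime and requires every edge flux to be
positive, which tightly constrains admissible combinations.  Published
per-condition numbers cover conformation II and III occupancies and
conformation II lifetimes (insulator 76%, 5.8 ms; consensus 82%, 9.6 ms;
methylated insulator II 52% / III 47%); the sparse states I and IV and
the other lifetimes are not printed per condition, so realistic
millisecond values satisfying flux feasibility were fixed once in
`ctcf_conditions()`: insulator WT `(8, 76, 13, 3)%` with lifetimes
`(1.0, 5.8, 2.0)` ms; consensus `(3, 82, 11, 4)%`, `(1.5, 9.6, 1.4)` ms;
methylated `(1.2, 51.5, 46.5, 0.8)%`, `(1.0, 5.8, 5.8)` ms (the printed
52/47 after rounding); insulator+PDS5A `(5, 83, 9, 3)%`.  The default
5 kHz sampling resolves the shortest of these lifetimes with ≥ 5 samples.

## HMM fitting and decoding

`fit_hmm()` is Baum–Welch EM with Gaussian emissions (forward–backward in
C++ with per-sample scaling), kmeans++-style mean initialization, 10
restarts by default keeping the best likelihood, an SD floor of 10⁻⁶ of
the data range, and restart-level rejection of degenerate states
(vanishing expected counts).  States are always reported in ascending
mean order.  Multiple traces are fitted jointly by accumulating
sufficient statistics per trace, so transitions never bridge trace
boundaries; fitting per trace and pooling summaries is equally available.
Model size is chosen by BIC with `p = K² + 2K − 1` free parameters, ties
toward smaller K.  The per-iteration log-likelihood is recorded and its
monotonicity asserted in tests; the forward likelihood and Viterbi path
are verified against brute-force path enumeration on short traces.

## Occupancies, lifetimes, rates

Occupancy is the per-state fraction of Viterbi-decoded samples.  Two
lifetime estimators are reported, and they answer different questions:

* *Dwell-based* (`ensemble_stats()`): mean Viterbi dwell duration with
  boundary-truncated dwells excluded (truncation biases lifetimes
  downward).  At the study's signal-to-noise ratio — neighboring states
  ~2 SD apart with millisecond dwells — Viterbi decoding absorbs a
  substantial share of brief excursions, so these dwell means run tens of
  percent *above* the true lifetimes.  They are kept as the descriptive
  statistic of the decoded path.
* *Model-based* (`model_lifetimes()`): the continuous-time generator is
  recovered from the fitted per-sample transition matrix as
  `Q = logm(A)/Δt` (eigendecomposition; fallback `(A − I)/Δt` flagged if
  `A` has complex or non-positive eigenvalues) and the lifetime is
  `−1/Q_kk`.  The matrix logarithm also undoes the discretization bias of
  the naive linear conversion, which hides round trips completed within
  one sample interval.  This estimator is consistent for the simulated
  CTMC and is the package's headline lifetime.

Transition rates from the decoded path are `k_ij = (transitions i→j) /
(time in i)`; expressed as a generator `k_ii = −Σ_{j≠i} k_ij`.
`sequentiality_score()` reports the fraction of transitions with
`|Δstate| = 1`; decoding errors create apparent skips, so scores slightly
below 1 are expected even for strictly sequential generators.

Bound-region segmentation (`segment_bound_region()`) cuts the trace into
fixed windows (default 0.2 s), takes an upper quantile of window
variances as the unbound reference, and marks windows below
`var_ratio_threshold` (default 0.5) of it as bound, with a minimum run
length of 5 windows.  Force-to-bp calibration is an affine map by
default, with any strictly monotone user map accepted; the exact
published conversion is in unavailable methods material, so the affine
stand-in is flagged in output metadata.

# The kymograph model

Particles diffuse on a 1D substrate with step variance `2DΔt`, reflecting
boundaries, Gaussian localization error (default 0.05 kb), and an
optional static site where encounters dock with probability `dock_prob`
(immobilization for an exponential lifetime) or bounce (reflection).
`estimate_diffusion()` fits `MSD(τ) = 2Dτ + 2σ_loc²` over the first 4
lags of overlapping displacements by weighted least squares with weights
`(n − lag)/lag` — an approximation to the inverse variance of the
overlapping-pair MSD estimator (simple OLS is the fallback).  Negative
fitted D clips to 0 with a flag.  Dwell survival uses the empirical 1-CDF,
switching to Kaplan–Meier (`survival::survfit`) when any event is flagged
censored; the median is the smallest time with survival ≤ 0.5 (so for
`{1,2,3,4,5}` the median is 3).  Its confidence interval is the exact
distribution-free order-statistic interval when nothing is censored —
chosen after measuring that a percentile bootstrap of a 22-event median
covers the truth only ~90% of the time at nominal 95%, while the
order-statistic interval covers ~98% — and a percentile bootstrap of the
Kaplan–Meier median under censoring.  Colocalization uses a 0.3-kb distance threshold — a stand-in for
the diffraction limit — bridging single-frame gaps; encounters dock when
their longest contact reaches 10 s (the published contrast is transient
bouncing versus > 60 s docking; no cut is named, so the threshold is
configurable and reported).  Bypass events (crossing the target while not
in contact) are counted and expected to be zero.

# The rupture model

`gen_unzip_curve()` writes a noisy baseline (default 13 pN, a typical
naked-DNA unzipping plateau) with sawtooth rips: a linear ramp over ~6 bp
to the event's rupture force, collapsing back to baseline within 2 bp.
`detect_rips()` subtracts a rolling-median baseline (31 bp), keeps local
maxima whose excess reaches 2 pN and that collapse within 3 bp, and
merges peaks closer than 5 bp — window choices matched to the sharpness
of discrete rips in unzipping data and all configurable.

Rupture forces are summarized as mean ± SE (the convention of the source
figures).  The two-population decomposition is a two-component Gaussian
mixture fitted by EM with 20 quantile-grid-initialized restarts and a
BIC comparison against a single Gaussian; the published high-force call
method is not described in the main text of the source literature, so
this mixture-with-BIC-guard is the package's formalization.  Component
variances are tied (`variance_model = "equal"`) by default: the
calibrated components have nearly equal SDs (~2.6 and ~2.8 pN, obtained
from the printed standard errors as `SE·√n`), and equal-variance EM is
markedly more stable when one component holds only ~10 of 83 events,
avoiding spurious solutions that capture a few extreme points with a tiny
variance.  With those calibrated parameters the components overlap at
~3σ, which puts ~4 percentage points of sampling noise on the fitted
weight at n = 83 — single-dataset weights scatter accordingly, and the
package's recovery checks therefore average over seeded replicates.
`ks_two_sample()` computes the exact two-tailed p by full enumeration for
n + m ≤ 12 (the cost boundary where enumeration stays trivial) and the
asymptotic Kolmogorov distribution with effective size `nm/(n+m)` above.

# What the generators do and do not emulate

The generators reproduce the *statistical* structure the analyses consume:
class mixtures, per-ZF protection probabilities, sequential four-state
kinetics with Gaussian emissions, Brownian motion with localization
error, two-component force mixtures with quota or Bernoulli component
sampling (quota — exactly `round(w·n)` high events — is the default so
fraction-recovery tests are exact).  They deliberately do not emulate:
nanopore signal or methylation-caller error structure, sequence-derived
GpC placement, trap mechanics or worm-like-chain elasticity,
force-dependent kinetics, image formation or spot detection, or
heavy-tailed emission noise.  Passing tests therefore demonstrate that
the estimators are correct and well-calibrated under the stated models,
not that those models capture every artifact of real instruments.

# Problem sizes and reproducibility

The shipped checks use sizes chosen to put Monte-Carlo error comfortably
inside each tolerance while keeping a full run on one CPU in minutes:
60-s traces at 5 kHz (300,000 samples; 1–10 traces per condition),
10,000 reads for classification, 3,000 motifs × 20 reads for per-ZF
protection, 50 trajectories × 200 frames for diffusion, 83 quota-sampled
rupture events (the published n).  Every random draw flows from a single
integer seed; the pipeline (`run_pipeline()`) stamps each artifact with
the package version, seed and a hash of the scientific configuration, and
rerunning an identical configuration reproduces the report byte for
byte.

# Known limitations

* The EM protected-fraction estimator assumes independent peripheral-ZF
  binding within partially protected reads; block-correlated dissociation
  (which the co-binding analysis is designed to detect) would make it an
  approximation.
* Viterbi-dwell lifetimes are upward-biased at ≤ 2σ state separation;
  use `model_lifetimes()` for kinetics.
* BIC state selection on very long traces is insensitive to states below
  ~0.5% occupancy; fitting with a fixed K from replicate-level evidence
  is the supported alternative.
* The mixture weight at n ≈ 80 with 3σ-separated components is noisy by
  nature (~4 pp SD); report it with its uncertainty, not as a point fact.
* The kymograph generator treats docking as perfect immobilization and
  ignores photobleaching, so dwell censoring must be flagged by the
  caller if trace ends are informative.
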