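# ctcfdyn

Single-molecule analysis of CTCF conformational dynamics and chromatin
boundary footprints.

CTCF sets the boundaries of cohesin-extruded chromatin loops, yet sites
with similar CTCF occupancy insulate very differently.  `ctcfdyn`
implements the quantitative analyses behind a state-centric explanation:
a DNA-bound CTCF is an ensemble of conformations — blocks of its eleven
zinc fingers (ZFs) wrapping and unwrapping the motif on the millisecond
timescale — and boundary permeability reflects the composition of that
ensemble.  The package covers four experimental views of the ensemble and
ships synthetic-data generators with known ground truth for each, so
every estimator is testable end to end by parameter recovery:

| arm | data | what it computes |
|---|---|---|
| footprint | per-read GpC methylation calls at CTCF motifs | read classes (CTCF-bound / nucleosomal / unbound), per-ZF protection `1 − methylated fraction`, fully vs partially protected fractions, ZF co-binding `P(ZF_j | ZF_i)`, ChIP-decile stratification (Mann–Whitney), per-ZF ChIP correlation |
| trace_hmm | unzipping fork-position traces | Gaussian-emission HMM (Baum–Welch, C++ core), BIC state selection, Viterbi paths, state→bp mapping, occupancies, lifetimes, transition rates, sequentiality |
| kymo | kymograph particle trajectories | MSD-based 1D diffusion `MSD(τ) = 2Dτ + 2σ²`, dwell survival (Kaplan–Meier aware), colocalization, bounce/dock outcomes, nearest-motif positions |
| rupture | unzipping force–position curves | force-rip detection, N-/C-terminal region assignment, mean ± SE summaries, two-component Gaussian mixture with BIC guard, two-sample K-S test (exact for n+m ≤ 12) |

The core models in one line each: conformations form a strictly
sequential four-state continuous-time Markov chain with Gaussian
emissions at mapped fork positions (−27.1, −15.5, −3.0, +20.1 bp from
the motif center); footprint reads are a four-archetype mixture observed
through a two-parameter labeling channel (accessible GpCs methylated with
efficiency ~0.85, protected with background ~0.05); particles diffuse
with step variance `2DΔt` under localization noise; rupture forces are a
two-component Gaussian mixture.

## Worked example

Simulate one unzipping trace at the wild-type insulator condition,
refit the conformational ensemble, and read off its composition:

```r
library(ctcfdyn)

cond <- ctcf_conditions()$insulator_wt
g <- gen_fork_trace(trace_sim_config(cond$means_bp, cond$sds_bp,
                                     cond$rate_matrix,
                                     duration_s = 60, seed = 11))
fit <- fit_hmm(g$trace$value, K = 4, n_restarts = 3, seed = 1)
fit
#> Gaussian-emission HMM with 4 states on 300000 samples
#>   means (bp): -27.09, -15.52, -2.991, 20.16
#>   sds   (bp): 5.507, 5.712, 5.714, 11.28
#>   logLik: -999236.2  BIC: 1998763

path <- viterbi_decode(fit, g$trace$value, sample_rate_hz = 5000)
ensemble_stats(path)$per_state$occupancy
#> [1] 0.07089000 0.77076000 0.12803667 0.03031333
model_lifetimes(fit, 5000)$lifetimes_ms
#> [1] 1.013880 5.898127 1.966088 2.144460
```

The fitted means land on the four conformational positions within a
fraction of a bp; conformation II (N-terminal ZFs released) dominates
with ~77% occupancy and a ~6 ms lifetime — the millisecond-scale
exchange that puts the ensemble on the timescale of cohesin passage.
Viterbi-path dwell means overestimate lifetimes at this signal-to-noise
ratio, so kinetics come from `model_lifetimes()` (matrix logarithm of
the fitted transition matrix); the vignette explains the estimator
choice.

A configuration-driven run of all four arms (simulate → analyze →
report):

```sh
Rscript inst/scripts/ctcfdyn.R --config inst/extdata/demo_config.yaml
```

writes TSV artifacts plus `report.json`, each stamped with the package
version, seed and config hash; rerunning the same config reproduces the
report byte for byte.

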