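# bindnet

Graph-theoretic analysis of task EEG functional connectivity across the
adult lifespan, built around a visual short-term memory **binding**
(change-detection) paradigm: two conditions (shapes alone vs.
colour–shape conjunctions), 48 test trials each, 1000-ms test-locked
epochs from a 30-channel 10–20 montage at 256 Hz.

The package implements the full analysis chain as composable, tested
functions, plus a synthetic-data module that generates complete cohorts
with known ground truth so every stage can be validated without any
recorded data:

1. **Synthesis** — screened cohorts (ages 20–81, MMSE ≥ 27, BDI ≤ 17),
   paradigm trial sequences, and phase-coupled multichannel epochs with
   age-dependent coupling (`simulate_cohort()`, `simulate_trials()`,
   `simulate_epochs()`), written as EDF files.
2. **Artifact screening** — the four classic criteria (±70 µV amplitude,
   50 µV/ms step, 50 µV per 200 ms, minimum 0.5 µV activity per 100 ms)
   applied per epoch and channel (`reject_epochs()`).
3. **Connectivity** — the weighted phase lag index
   `wPLI = |E[Im X]| / E[|Im X|]` estimated in 1-Hz bands at centers
   1–48 Hz and averaged into delta/theta/alpha/beta/gamma matrices
   (`wpli_spectrum()`, `aggregate_band()`).
4. **Graphs** — 55% proportional thresholding, then characteristic path
   length, global efficiency, betweenness, Onnela weighted clustering,
   Louvain modules, participation-coefficient hubness, and small-world
   ratios `γ = L/L_rand`, `λ = C/C_rand`, `σ = γ/λ` against a 30-node
   ring-lattice reference (the customary Watts–Strogatz convention is a
   switch away).
5. **Statistics** — penalized cubic-regression-spline additive models of
   age (basis dimension 10 for cognitive, 12 for graph outcomes; REML),
   and an age-partialled Pearson correlation screen under
   Benjamini–Hochberg FDR with a moderate-effect cut (|r| > 0.400).

The methods vignette (`vignettes/eeg-network-aging.Rmd`) documents the
models, the estimator's numerical choices, and what the synthetic data
do and do not emulate.

## Worked example

```r
library(bindnet)

# one synthetic subject, one condition
ep <- simulate_epochs(list(age = 30), "shape",
                      default_coupling_profile(), n_epochs = 40, seed = 1)
ep
#> epoch_array: S000 / shape - 40 epochs x 30 channels x 256 samples @ 256 Hz

clean <- reject_epochs(ep)$epochs
spec  <- wpli_spectrum(clean)              # 48 matrices, 1-48 Hz
alpha <- aggregate_band(spec, "alpha")
round(alpha["Pz", "P3"], 2)                # a coupled pair at age 30
#> [1] 0.4

g  <- threshold_proportional(alpha, 0.55)
g
#> thresholded_graph: 30 nodes, 239 edges (proportion 0.55)
small_world(g)
#> small_world_result (as_printed): L=1.4506 C=0.5400 L_rand=1.4506 C_rand=0.7003
#>   gamma=1.0000 lambda=0.7711 sigma=1.2968
```

At 55% density the binarized graph and its lattice reference both have
diameter 2, so `gamma` is 1 and `sigma` is carried by the clustering
ratio — see the vignette for why.

## The study workflow

The numbered scripts under `analysis/` run the full study on a
synthetic 39-subject cohort (seed-deterministic, ~2 minutes):

```sh
Rscript analysis/01_simulate.R     --seed 1 --outdir results/study
Rscript analysis/02_preprocess.R   --outdir results/study
Rscript analysis/03_connectivity.R --outdir results/study
Rscript analysis/04_graph.R        --outdir results/study
Rscript analysis/05_stats.R        --outdir results/study
```

Stage 5 prints the demographic table, the outcomes with significant age
effects and the correlation report. Under the default coupling profile
(posterior alpha coupling declining after age 50), the run reproduces
the designed pattern: the flagged graph outcomes are exclusively
alpha-band metrics, e.g.

```
11 of 52 outcomes show a significant age effect (p < 0.05):
               outcome  edf F_value p_value
             acc_shape 2.78   22.13 0.0e+00
   cc_mean_alpha_shape 2.55    6.24 1.4e-03
 cc_mean_alpha_binding 1.00   17.38 1.8e-04
     cpl_alpha_binding 2.66    4.29 1.0e-02
 ...
correlation screen: 60 candidate pairs, 2 reported (|r| > 0.400, q < 0.05)
             metric       score      r  q_bh
 geff_alpha_binding acc_binding  0.460 0.046
  cpl_alpha_binding acc_binding -0.458 0.046
```

Every stage reads only the files of its predecessors, so any stage can
be rerun in isolation; `run_pipeline(run_config(...))` does the same
in one call and writes a manifest with MD5 digests and stage timings.

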