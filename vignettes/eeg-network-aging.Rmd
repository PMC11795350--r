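---
title: "Methods: EEG working-memory networks across the adult lifespan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: EEG working-memory networks across the adult lifespan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The pipeline in one paragraph

`bindnet` analyses task EEG from a visual short-term memory binding
(change-detection) paradigm across the adult lifespan. Epoched
30-channel recordings (1000-ms test-locked epochs at 256 Hz) are screened
with four artifact criteria, narrowband functional connectivity is
estimated with the weighted phase lag index (wPLI) on a 1--48 Hz grid of
1-Hz-wide bands, band-averaged connectivity matrices are proportionally
thresholded at 55% and summarized by graph metrics of integration
(characteristic path length, global efficiency, betweenness), segregation
(weighted clustering, Louvain modules, participation) and global
organization (lattice-referenced small-world ratios), and age effects on
every outcome are modelled with penalized cubic-regression-spline
additive models, followed by an age-partialled correlation screen between
graph metrics and cognition under Benjamini--Hochberg false-discovery
control. A synthetic-data module generates complete cohorts with known
ground truth, so every stage is testable without any recorded data.

# The synthetic cohort

`simulate_cohort()` emulates a screened community sample: ages
stratified-uniform over 20--81 years (one draw per equal-width stratum, so
even n = 39 covers the range), MMSE restricted to 27--30 and BDI to 0--17
(the inclusion rules of a screened sample), and cognitive/behavioural
scores drawn around piecewise-linear mean age curves
(`cognition_curves()`): task accuracy declining after midlife, reaction
time rising late, language skills peaking near age 45, visuospatial
ability dropping sharply after 70. The curves are exposed so recovery
tests can compare generated data against exact ground truth; at zero
noise the domain scores reproduce the curves to machine precision.

`simulate_trials()` reproduces the paradigm's design constants: 96 test
trials, 48 per condition (shape, colour--shape binding) in
counterbalanced blocks of 12, probe displays drawn *same*/*different*
with probability 0.5 on every trial, 1000-ms study displays and a
1200-ms delay.

## The oscillator model

`simulate_epochs()` builds each channel as a sum of five band-limited
oscillations plus 1/f noise. Each band has a carrier frequency (2, 6,
10, 20, 40 Hz by default), an amplitude in microvolts, and a per-channel,
per-epoch random phase that drifts slowly within the epoch (a random walk
sampled on a coarse knot grid and linearly interpolated). Coupling is
implemented by *phase copying*: for each coupled pair of a band, on a
randomly chosen fraction `g` of epochs the target channel's band
component takes the source's phase shifted by the band's lag. This gives
the estimator analytically predictable limits -- at `g = 0` a pair sits at
the wPLI null level, at `g = 1` (with a lag away from 0 and pi) wPLI
approaches 1 -- and makes `g(age)` the single ground-truth dial for
age-dependent connectivity.

Two topological details matter and are enforced by
`coupling_profile()`:

* **Targets must be fresh.** Within a band, a pair's target channel must
  not have appeared in an earlier pair, otherwise the later assignment
  would silently overwrite the earlier coupling. Stars (one source, many
  targets) and ordered chains are the supported shapes.
* **Stars make no triangles.** Two targets of the same source are locked
  at *zero* lag relative to each other, which wPLI deliberately
  suppresses; a star therefore produces high wPLI only on its spokes. A
  chain with per-link lag `2*pi/7` instead locks all pairs of chain
  members at lags `k * 2*pi/7` (never 0 or pi for k <= 5), creating a
  full wPLI clique with triangles -- the substrate used for the alpha
  clustering effect in the default and recovery profiles.

Default amplitudes (alpha 5 uV, delta/theta 2 uV, beta 1.5 uV, gamma
0.8 uV, 1/f noise SD 2.5 uV) are calibrated so that clean epochs pass the
artifact criteria: the 200-ms peak-to-peak range of a generated epoch
stays well under the 50-uV criterion. The per-condition epoch counts are
drawn from a truncated normal (mean 38.05 / SD 6.24 for shape,
39.28 / 6.60 for binding, truncated to [20, 48]), matching the usable
epoch counts of a realistic session; the pipeline additionally
contaminates ~8% extra epochs with amplitude artifacts so the screening
stage has real work.

What the generator does **not** emulate: volume conduction and a shared
reference (which produce zero-lag correlations between neighbouring
channels in real EEG -- wPLI discounts them by design, so synthetic tests
cannot probe that robustness), ocular/muscle artifact morphology,
nonstationary band power, and any true relation between the simulated
cognitive scores and the simulated connectivity (the two are independent
given age, so metric-cognition correlations in synthetic runs are
age-mediated only).

# Artifact screening

`reject_epochs()` applies four criteria to every channel of every epoch;
any violation rejects the whole epoch (no interpolation):

| criterion | default | note |
|---|---|---|
| (a) absolute amplitude | 70 uV | any sample |
| (b) voltage step | 50 uV/ms | adjacent samples, scaled to uV/ms |
| (c) max difference in 200 ms | 50 uV | dense sliding window, 51 samples at 256 Hz |
| (d) min activity in 100 ms | 0.5 uV | dense sliding window, 26 samples |

Criterion (b) is stated in uV/ms; at 256 Hz one sample spans 3.906 ms,
so the per-sample limit is 195 uV. A consequence worth knowing: **at 256
Hz criterion (b) cannot fire alone** -- any signal within the +-70 uV
amplitude bound has adjacent-sample steps below 140 uV, and a step large
enough to violate (b) also violates (a) and (c). The tests isolate (b)
with a 2000-Hz fixture, where the per-sample limit (25 uV) bites below
the other thresholds. Window lengths are rounded to the nearest sample
count and advance one sample at a time (a monotonic-deque sliding
min/max keeps this linear in the number of samples).

The screen is fully automatic and logs every (epoch, channel, criterion)
violation; the original study reviewed such flags manually, so our
rejection counts are reproducible but not an emulation of human
judgement.

# wPLI estimation

For each center frequency f0 in 1..48 Hz, each epoch is band-pass
filtered with a **zero-phase filter equal to the squared magnitude
response of a 4th-order Butterworth band-pass** of width 1 Hz, applied in
the frequency domain; the analytic signal is formed by zeroing negative
frequencies, and the estimator

wPLI_ij = |E[Im(X_ij)]| / E[|Im(X_ij)|],  X_ij = a_i * conj(a_j)

pools the expectation over all retained time points and epochs (25% of
samples are discarded at each epoch edge). Pairs with E[|Im|] = 0 are
defined as 0 and noted. A per-epoch pooling variant (one time-averaged
cross-spectral value per epoch) is available via `pooling = "epoch"`.

Numerical choices, made after measuring the alternatives:

* A time-domain forward-backward IIR filter is unusable here: the
  impulse response of a 1-Hz-wide filter is on the order of a second, so
  its transients span the entire 1000-ms epoch (a 10-Hz probe sinusoid
  retains only ~60% of its amplitude mid-epoch after `filtfilt` on 256
  samples). The frequency-domain implementation has exactly zero phase
  and no transient, at the cost of circular wrap-around that the edge
  trim suppresses.
* The filtered analytic signal is reconstructed by a direct inverse DFT
  over the frequency bins whose gain exceeds 1e-4 of the peak (the -80 dB
  skirt), restricted to the trimmed window -- one small complex matrix
  product per frequency instead of a full inverse FFT per channel-epoch.
  The truncation error is below 1e-3 on the wPLI scale (checked against a
  full-precision plain-R implementation in the tests).
* At f0 <= 3 Hz a 1000-ms epoch holds under 4 cycles; the estimate then
  leans entirely on pooling across epochs, and the package says so in a
  message rather than refusing.

The wPLI null level deserves emphasis: with ~40 one-second epochs the
1-Hz-wide analytic signal contributes roughly one independent sample per
epoch, so an uncoupled pair has E[wPLI] near 0.1 and a 95th percentile
near 0.28 -- and the *maximum* over all 435 pairs x 48 frequencies of a
null recording reaches 0.5--0.65. Detection claims should therefore be
calibrated against a permutation null (epoch shuffling), as the tests
do, not against a fixed cutoff.

Band aggregation averages the narrowband matrices whose integer center
frequency falls inside the band's nominal edges: delta {1,2,3}, theta
{4..7}, alpha {8..13}, beta {14..29}, gamma {30..48}.

# Graph analysis

`threshold_proportional()` ranks the 435 upper-triangle weights and
keeps the top floor(0.55 x 435) = 239 edges (ties broken by ascending
row/column index, so the result is deterministic); retained weights are
unchanged. Weighted metrics are computed on this graph with edge
distances 1/w: characteristic path length (mean shortest-path distance
over connected pairs, disconnection flagged), global efficiency (mean
inverse distance, 0 for disconnected pairs), betweenness (fractional
counting, normalized by (n-1)(n-2)/2), Onnela weighted clustering
(geometric mean of triangle weights rescaled by the global maximum),
seeded weighted Louvain modules with within-module strength z-scores,
and the participation coefficient P_i = 1 - sum_m (s_im/s_i)^2 with a
configurable hub flag at P > 0.3. The continuous participation
coefficient, not the flag, is the analysis variable; "hub" and "module"
nodewise values are operationalized as participation and module-z
respectively -- an interpretation, since the field uses several
conventions.

## Small-world ratios

The small-world statistic is computed on the **binarized** thresholded
graph so it is commensurate with its unit-weight ring-lattice reference
(`lattice_reference(30, 239)`: each node linked to its 7 nearest
neighbours per side plus 29 edges at distance 8). The default
convention, labelled `as_printed`, is

gamma = L / L_rand, lambda = C / C_rand, sigma = gamma / lambda,

which inverts the customary Watts--Strogatz roles of L and C; the
customary convention (gamma = C/C_rand against a degree-preserving
rewired ensemble, 10 seeded realizations averaged) is available as
`convention = "watts_strogatz"`, and every result records which was
used. Two structural consequences at 55% density are worth knowing:
a 239-edge graph on 30 nodes almost always has diameter 2, and so does
the lattice reference, which makes the binary L and L_rand equal
(gamma = 1) for essentially every subject -- sigma is then carried
entirely by the clustering ratio; and the sigma values of the two
conventions are reciprocal on the same reference.

# Statistical modelling

`fit_age_gam()` fits y = b0 + f(age) + e with f a penalized cubic
regression spline (mgcv), basis dimension k = 10 for behavioural and
cognitive outcomes and k = 12 for graph outcomes, smoothing parameter by
REML. "Order 10/12" is read as the spline basis dimension, the reference
implementation's meaning. Reported per outcome: intercept estimate / SE /
t / p and the smooth's EDF, reference df, F and approximate p-value.
Calibration measured at the study's size (n = 39, k = 12, 500 null
replicates): smooth-term type-I rate 0.068 at alpha = 0.05 -- inside the
acceptable band but slightly above nominal, which is a known property of
approximate penalized-smooth p-values and worth remembering when reading
borderline p-values near 0.05.

`partial_corr()` computes the age-partialled Pearson correlation from
residuals of linear regressions on age, with p from
t = r sqrt((n-3)/(1-r^2)) on n-3 df. `screen_correlations()` applies the
reporting rule: only metrics with a significant additive-model age
effect enter; BH adjustment is applied within metric family
(integration / segregation / global -- the family definition is
configurable and recorded); pairs are reported when |r| > 0.400 *and*
the BH-adjusted p is below 0.05, sorted by |r|.

# The parameter-recovery study

`run_recovery_replicate()` is the pipeline's headline validation: a
100-subject cohort under `recovery_profile()` -- an alpha chain (carrier
12 Hz, coupling declining linearly 0.85 to 0.15 across 20--81) and an
age-stable theta star (g = 0.5) -- is simulated, screened, connected
(theta and alpha centers), thresholded and summarized, and the
additive model (k = 12) is fit to the alpha (true effect) and theta
(true null) mean clustering coefficients. A replicate succeeds when the
alpha effect is flagged at p < 0.05 and the theta metric is not. Across
seeded replicates the alpha p-values are essentially zero and failures
come almost entirely from the ~5% type-I rate on the null metric.

Design notes, learned the hard way and worth recording:

* The alpha carrier sits at 12 Hz because an age-*varying* coupling at
  10 Hz leaks through the 7-Hz filter skirt into the theta band strongly
  enough that, at n = 100, the "null" theta clustering acquires a
  significant age trend. Band-pass leakage makes perfect nulls
  impossible in principle; 12 Hz pushes the leak below detectability at
  this sample size.
* Because Onnela clustering rescales by the graph's maximum weight, a
  declining coupled clique *raises* the normalized weight of null edges,
  so the mean clustering coefficient can move opposite to the coupling.
  The age effect is detected either way; the sign of the metric's trend
  depends on the coupling topology and the normalization, not only on
  the physiology it models.
* Problem sizes (16 epochs per subject, one condition, theta+alpha
  centers only) are the study's own choices, keeping a replicate light
  while staying above the estimator's minimum epoch count.

# Degenerate inputs and edge behaviour

Empty epoch sets after rejection are an error naming the recording;
edgeless graphs are an error; disconnected thresholded graphs are
flagged, with CPL over connected pairs and efficiency handling
disconnection natively; zero-strength nodes have participation 0 by
convention; constant outcomes and sub-basis sample sizes are errors in
the model stage, and the pipeline skips the model stage with a warning
when n < k; all-zero p-vectors and single tests are handled by the BH
step-up as limiting cases.

# Known limitations

* EDF intermediates quantize to 16 bits over a symmetric range (error
  under 0.001 uV at the default amplitudes) -- negligible here, but a
  difference from in-memory runs.
* The frequency-domain filter and the pooled estimator are one of
  several defensible readings of "1-Hz bandwidth" wPLI; per-epoch
  pooling is provided, alternative filters are not.
* Nodewise statistics (betweenness, participation, module-z) are
  computed and exported but the shipped screen operates on global
  metrics; nodewise screening would require a larger FDR family.
* Synthetic effect sizes are calibration choices; nothing in this
  package estimates the connectivity effect sizes of any real cohort.
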