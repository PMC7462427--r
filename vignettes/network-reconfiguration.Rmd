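---
title: "Dynamic network reconfiguration from perturbational EEG: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic network reconfiguration from perturbational EEG: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netreconf)
```

## The problem

A single pulse of focal neurostimulation transiently perturbs ongoing
cortical dynamics. If ongoing activity is organized into frequency-specific
communities of regions — sets of sources that share an oscillatory rhythm —
then a pulse should reorganize those communities, and the reorganization
can be quantified by comparing dynamic community structure before and
after the pulse. `netreconf` implements that analysis chain for
region-by-time-by-trial source data:

1. **Connectivity.** Trial-consistency phase coupling (debiased weighted
   phase lag index, dwPLI) between all region pairs, in tapered sliding
   windows spanning the peri-stimulus epoch, averaged into frequency
   bands.
2. **Dynamic communities.** Each band's windowed connectivity matrices
   form the layers of a multilayer network; a Louvain-style greedy
   optimizer maximizes multilayer modularity with ordinal interlayer
   coupling, run as a seeded ensemble with a medoid consensus.
3. **Scale selection.** The structural (γ) and temporal (ω) resolution
   parameters are calibrated by sweeping a grid and maximizing the gap
   between observed modularity and that of an edge-shuffled null.
4. **Reconfiguration metrics.** Node flexibility and pairwise allegiance,
   computed separately on the pre- and post-pulse window blocks of one
   whole-epoch partition, summarized per community and against distance
   from the stimulation site, with t tests and Bonferroni /
   Benjamini–Yekutieli control.

Because no public dataset accompanies the method, the package ships a
synthetic generator that plants exactly the statistical structure the
analysis assumes, so every stage can be validated end-to-end against
known ground truth.

## Connectivity model

For regions $a,b$, window $w$, frequency $f$ and trials $j = 1 \dots J$,
let $X_j = F_a F_b^{*}$ be the tapered cross-spectrum and
$I_j = \mathrm{Im}(X_j)$. The estimator is

$$\mathrm{dwPLI} = \frac{\sum_{j \ne k} I_j I_k}{\sum_{j \ne k} |I_j I_k|}
 = \frac{(\sum_j I_j)^2 - \sum_j I_j^2}{(\sum_j |I_j|)^2 - \sum_j I_j^2},$$

the debiased square-root weighted phase lag index. It uses only the
imaginary cross-spectrum, so zero-lag coupling (volume-conduction-like
mixing) contributes nothing; the ordered-pair form removes the positive
bias of the squared-sum estimator at finite trial counts, so independent
signals give 0 in expectation at any $J$. A pair whose imaginary parts
vanish identically has a $0/0$ denominator; we define the value as 0 and
flag it rather than guessing.

Windowing defaults (all overridable in `window_spec()`): 0.5-s
single-taper Hanning windows, zero-padded to a 0.5-Hz grid over
2–25 Hz, window centers 5 samples apart at 128 Hz (≈39 ms), retained
over ±1 s around the pulse — 25 pre-pulse windows, the pulse-centered
window, 25 post-pulse windows. The taper length is a compromise: long
enough to separate the alpha (8–12 Hz) and beta (13–20 Hz) bands, short
enough that 25 windows tile one second of data. A DPSS multitaper option
(`taper = "dpss"`) exists for broader-band smoothing; per-trial
cross-spectra are pooled over tapers before the imaginary-part products.
Band averages are arithmetic means over bins in the closed band, so
12.5 Hz belongs to neither default band. Negative dwPLI values are kept
at this stage.

## Multilayer modularity

With layer adjacency $A_{ijs}$ (dwPLI, negatives clipped to zero — the
Newman–Girvan null assumes nonnegative weights; the clip count is
recorded), strengths $k_{is}$, layer totals $2m_s$ and assignment
$g_{is}$:

$$Q = \frac{1}{2\mu}\sum_{ijs}\left[A_{ijs} - \gamma\,
  \frac{k_{is}k_{js}}{2m_s}\right]\delta(g_{is},g_{js})
  + \frac{1}{2\mu}\sum_{i,s}2\,\omega\,\delta(g_{is},g_{i,s\pm1}),$$

with $2\mu$ the total intra- plus interlayer weight. Interlayer coupling
is ordinal (each node to its own copy in adjacent layers only),
following standard temporal-network practice; all-to-all coupling is not
offered. Diagonal null terms are included, so the all-in-one partition
of a single layer scores exactly 0.

The optimizer (C++ core) sweeps node-layer tuples in seeded random
order, moving each to the community of maximal strictly positive gain,
then aggregates communities into super-nodes and repeats. It is
deterministic given its seed and guarantees a local maximum: no single
tuple move can improve the final $Q$. Because the heuristic is
stochastic across seeds, the final structure is taken from an ensemble
(default 100 runs, run $k$ seeded `base_seed + k`). The consensus is the
medoid — the member with the largest mean pairwise z-scored Rand
similarity to the others, ties broken by higher $Q$ then lower seed.
When run-to-run agreement is high (the regime these analyses operate
in; the ensemble records the agreement fraction), the choice of
consensus rule is inconsequential, which the tests assert. "Static"
band communities used for community-level summaries come from the
pre-pulse layers only (modal label per node across layers), so they are
unbiased by the stimulation.

## Scale selection

The shuffled null permutes each layer's upper-triangle weights uniformly
(independently per layer, preserving the layer's weight multiset and
hence its total and mean), destroying correlational structure while
keeping the weight distribution and its temporal profile. For each
$(\gamma, \omega)$ cell, each subject contributes mean observed $Q$ and
mean null $Q$ over optimizer runs (one shuffled realization per subject
per cell by default); `select_scale()` takes the argmax of the mean
difference, breaking ties toward smaller $\omega$ then smaller
$\gamma$. On structureless networks the expected difference is zero —
a calibration property the tests verify over 50 seeds.

`modularity_params()` defaults to $\gamma = 1.025$, $\omega = 9$, the
scale calibrated on peri-stimulus source-space EEG by this procedure.
The scale is a property of the dataset, not of the method: on the
package's synthetic generator the same sweep selects $\gamma = 1$,
$\omega = 1$ (shipped as `example_params()`, recomputed by the
acceptance script). The synthetic ensembles are cleaner and more
stationary than EEG, so they calibrate to weaker temporal coupling;
analyses of the generator's output should use the scale its own sweep
selects, exactly as one would for any new dataset.

## Reconfiguration metrics

For a partition over $L$ layers, node flexibility is
$\xi_i = g_i/(L-1)$ with $g_i$ the number of community changes between
consecutive layers; allegiance $P_{ij}$ is the fraction of layers in
which $i$ and $j$ share a label (diagonal 1). We normalize the
co-assignment count by $L$, which keeps $P \le 1$; a literal
$L-1$ mode is available (`normalization = "transitions"`). Both metrics
are computed twice on the *same* whole-epoch partition — once on the 25
pre-pulse layers, once on the 25 post-pulse layers, the pulse window
excluded — so community label identity is consistent across the pulse.
Signed (post − pre) and absolute differences are both emitted;
summaries use the absolute change, but the signed tables are retained
because increases and decreases are scientifically distinct.

Distance summaries use the Euclidean distance between a community's
centroid (mean member coordinate, meters) and the stimulation-site
node; site allegiance change averages $|\Delta P|$ between each
community's members and the site node (the site excluded from its own
community's average). Node selection takes nodes at or above the 85th
percentile of the change score, with the threshold computed by linear
interpolation between order statistics (type-7 quantile) and returned
for plotting. Homologous left/right stimulation conditions are merged
by elementwise averaging (`average_lr()`).

Statistics are classical: two-sided one-sample / paired t tests
(zero-variance samples flagged as degenerate rather than assigned
extreme p values), Bonferroni with a strict threshold ($0.05/10 =
0.005$ for the ten pairwise contrasts among five communities), and
Benjamini–Yekutieli FDR (valid under arbitrary dependence) applied
within each band's edge matrix. Corrected and uncorrected flags are
both reported.

## The synthetic generator

`sim_config()` + `generate_trials()` emulate source-localized
peri-stimulus data: 68 regions at 128 Hz over a ±2.5-s epoch by
default. Per band and trial, every planted community shares one
band-limited source (white noise through a zero-phase Butterworth
band-pass — second-order sections run forward and backward, fourth-order
magnitude response — with 1 s of padding absorbing transients and the
circular wrap of the FFT-implemented fractional delays); each member
receives the source delayed by its `lag_cycles` at the band center
frequency, scaled by `coupling`, plus independent Gaussian noise. At
time 0 the coupling structure switches instantaneously from the pre- to
the post-partition with a fresh set of sources. "Subjects" are
replicate ensembles differing only by seed.

This is a *delayed shared source* model, not a coupled-oscillator
system with its own dynamics: it guarantees a nonzero imaginary
cross-spectrum with analytically predictable limits (dwPLI → 1 for a
noiseless constant lag; 0 for independent channels; pairs with equal
lags are invisible, which the config warns about). What it does not
emulate: 1/f background spectra, stimulation artifacts, evoked
potentials, inverse-modeling leakage (zero-lag mixing), nonstationary
amplitude dynamics, or between-subject anatomical variance. Passing
tests therefore demonstrate correctness of the estimators and
optimizers under the model's assumptions — not robustness to everything
real recordings contain.

### The canonical experiment

`example_config()` defines the package's reference recovery experiment,
scaled so the full chain runs in minutes on one CPU (the vignette and
acceptance script use exactly these sizes): 24 regions, 60 trials per
subject, 10 subjects, noise SD 0.3 against unit-variance sources,
coupling 0.9, lags spread over 0.4 cycles within each community. Alpha
carries two 12-region communities; at the pulse the community containing
the stimulation site splits in half. Beta carries three unperturbed
8-region communities, so band specificity is testable. The trial count
reflects a typical retained single-pulse count per stimulation site
after artifact rejection; the region count is a parcellation-scale
problem small enough for exhaustive validation.

The perturbed community spans half the network deliberately. A label
reorganization is adopted by the optimizer only when the modularity
gained across the 25 post-pulse layers exceeds the one-off interlayer
cost of changing labels at the pulse boundary ($2\omega$ per changed
node). A three-node split of a six-node community, for instance, is
*correctly* rejected at $\omega = 9$ — the constant partition really
does score higher — which is a useful reminder that $\omega$ sets the
minimum detectable reorganization size, not just label smoothness.

## Numerical choices and degenerate inputs

- dwPLI denominators of 0 → value 0 plus a degeneracy flag.
- Window extraction refuses to run past the epoch; data are never
  zero-filled.
- The frequency grid must lie on the zero-padded DFT grid; mismatches
  are configuration errors, not silent rounding.
- Layers with zero total weight abort multilayer construction
  (the per-layer null is undefined).
- Optimizer moves require a strictly positive gain beyond a relative
  tolerance of 1e-12, so accepted moves strictly increase $Q$ and
  runs terminate.
- z-Rand similarity falls back to the adjusted Rand index when the
  permutation-null variance is degenerate (tiny problems,
  single-community marginals).
- Scale-selection ties break toward smaller $\omega$, then smaller
  $\gamma$; a flat surface warns.
- All stochastic stages record their seeds; run `k` of an ensemble uses
  `base_seed + k` for exact replay.

## Worked example

A reduced cohort (12 regions, 24 trials, 2 subjects, alpha only) keeps
this vignette fast; the acceptance script runs the full canonical
experiment.

```{r pipeline, eval = FALSE}
cfg <- example_config(n_regions = 12, n_trials = 24, n_subjects = 2,
                      seed = 5, include_beta = FALSE)
report <- run_pipeline(cfg, params = example_params(), n_louvain = 20)
report
tidy(report, "recovery")
glance(report)
autoplot(report)
```

Module-level entry points compose the same way the pipeline does:

```{r modules, eval = FALSE}
ens  <- generate_trials(cfg)
cs   <- cross_spectra(ens, window_spec())
conn <- band_average(dwpli(cs), c(8, 12))
net  <- build_multilayer(conn, example_params())
cons <- consensus_partition(partition_ensemble(net, 20, base_seed = 0))
prepost_diff(cons, conn$manifest$tag)
```

## Known limitations

- The Louvain-style optimizer finds local maxima; strongly coupled
  layers can make genuinely better *dynamic* labelings unreachable by
  single-tuple moves (see the canonical-experiment discussion). The
  ensemble-plus-consensus machinery mitigates but does not remove this.
- The shuffled null permutes within layers; a cross-layer or
  degree-preserving null would test different hypotheses and is not
  implemented.
- No overlapping communities, no Leiden-style refinement, no
  negative-weight modularity variants; negative dwPLI entries are
  clipped before community detection.
- Community-level group statistics require community identities common
  to all subjects; `run_pipeline()` derives them from subject-averaged
  pre-pulse connectivity, which assumes subjects share a layout — true
  for the generator, an approximation for real cohorts.
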