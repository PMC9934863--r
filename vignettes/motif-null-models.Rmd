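---
title: "Motif null models and synthetic multipatch data: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motif null models and synthetic multipatch data: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coupledchains)
```

This vignette is the package's account of its models and the choices behind
them: what each stage assumes, which parameters matter and why their
defaults are what they are, what the synthetic-data generators do and do not
emulate, and where the numerics required a decision the underlying study
left open.

## 1. The scientific setting

Locus coeruleus (LC) noradrenergic neurons are recorded in simultaneous
multipatch cohorts of 3–8 cells ("recording sets"); every pair in a set is
tested for electrical coupling with 600 ms current steps, and each cell's
intrinsic properties and morphology are characterized. Cells fall into two
morpho-electric types: fusiform (FF; elongated soma, two primary dendrites
at opposite poles) and multipolar (MP; round soma, several dendrites at all
angles). Coupling is sparse (overall rate ~4%), strongly distance-dependent,
and largely confined to same-type pairs. The question the motif analysis
answers: given those pairwise rates, do coupled pairs cluster into chains
(A–B–C) more than independence predicts?

## 2. Motif taxonomy and the cluster index

Within one set's connection graph with `m` edges:

* **Doubles** — every unordered pair of distinct edges, `C(m, 2)` in total:
  *chain* when the edges share a cell, *non-chain* when vertex-disjoint.
* **Triples** — every unordered triple of edges, `C(m, 3)` in total:
  *chain* (3-edge path), *hub* (star), *circular* (triangle), *non-chain*
  (any disconnected union). Hub and circular shapes are tallied separately
  from non-chain because the study's model predictions report them
  separately; the non-chain triple category is the disconnected unions
  only.

The **cluster index** is chain/non-chain. Note a structural property that
matters for interpretation: configurations are counted *within* each set
and summed over sets, and disjoint edge pairs inside one long chain count as
non-chain (in a 4-cell path A–B–C–D, the pair {AB, CD} is non-chain). A
perfectly chain-like 3-edge set therefore still contributes one non-chain
double; the cohort-level cluster index is bounded well below infinity even
under maximal chaining.

Counting uses degree identities (chain doubles are `sum(C(deg, 2))`; hub
triples `sum(C(deg, 3))`; chain triples are 3-edge paths obtained from
`sum((deg_u - 1)(deg_v - 1))` over edges minus three per triangle), with the
complements filled in from `C(m, 2)` and `C(m, 3)`. The test suite checks
these against an independent brute-force enumerator that classifies edge
subsets by connected components.

## 3. The null models

`motif_model()` builds the four models:

* **M1 (random)**: one uniform probability per tested pair. Default
  `p_uniform = 0.0438`, the overall connectivity rate across recordings as
  used for the modeling (the raw worked-example ratio 65/1503 rounds to
  4.3%; the modeling value 0.0438 is retained as stated).
* **M2 (cell type)**: FF–FF 0.087, MP–MP 0.053, FF–MP 0.008.
* **M3 (type + distance)**: pairs farther than 80 µm never connect;
  same-type pairs within the cutoff use the short-range (16–40 µm) rates
  0.314 (FF–FF) and 0.107 (MP–MP); FF–MP pairs within the cutoff use 0.007.
  The FF–MP near-range rate is not a published number — it is configurable
  and must be overridden when fitting real data.

**Expected counts** follow the study's construction exactly: for every
configuration (edge subset of the right shape, over a set's tested pairs)
add the product of its pairwise probabilities; no non-edge factors enter.
The implementation enumerates the `C(P, 2)` and `C(P, 3)` pair-subset
configurations once per set size (3–8) and caches the classification.

**Monte Carlo** (`simulate_cohort()`) draws every tested pair independently
by its model probability on each of `n_runs` runs (default 1000), counts
motifs per set, and sums. Sets of equal size are batched into one matrix
operation, so a 1000-run simulation of a 100-set cohort takes about 1.5 s
on one core. `summarize_prediction()` reports means, SDs, percentile 95%
intervals (2.5/97.5, type-1 quantiles on the integer counts), upper-tail
count p-values, and the cluster-index comparison: the ratio p-value is the
fraction of runs whose simulated ratio is at least the observed one.
Zero-denominator runs are infinite ratios when the chain count is positive
and undefined (excluded, with the count reported) when both counts are
zero. Ratio p-values are raw `k/n`; the optional `(k+1)/(n+1)` correction
was considered and left out to match the stated resolution of 1/n_runs.

## 4. Model 4: the chain rule

The study's fourth model is described only as a concept — a cell's
connectivity is scaled up or down contingent on whether it already has an
electrical connection — so the generative mechanism here is the package's
own design. Literally multiplying by `alpha` for pairs touching a connected
cell *and* by `beta` for pairs creating degree ≥ 2 cancels exactly at the
reference values (4 × 0.25 = 1), because attaching to a degree-1 cell always
creates degree 2; the two rules are therefore applied exclusively:

* a pair of two unconnected cells has weight 1;
* a pair extending a chain end (exactly one endpoint connected, with degree
  exactly 1) has weight `alpha`;
* anything else — attaching to a cell of degree ≥ 2, closing a loop,
  merging two connected cells — has weight `beta`.

Edges are placed by weighted sequential sampling: the number of edges in a
set is binomial at `base_p` (so the overall rate matches the
independent-pair models *by construction*), then edges are chosen one at a
time with the weights above, updated as the graph grows. A rejection-sweep
variant (visit pairs in random order, accept with `base_p` times the
multiplier) was implemented first and discarded: pairs visited before any
edge exists never see the multiplier, which dilutes the chain enrichment by
an artifact of visit order rather than by the model concept.
`calibrate_chain_model()` verifies the rate match by simulation and remains
available for alternative mechanisms.

With `alpha > 1`, `beta < 1` the cohort cluster index exceeds the M1
prediction and rises with `alpha` (a tested invariant). Its magnitude is
bounded by the taxonomy, not the mechanism: with ~0.66 edges per set, sets
with three or more edges necessarily add non-chain doubles even when every
edge extends a chain, and at `alpha = 4` the probability that a two-edge,
six-cell set forms a chain is `8·alpha / (8·alpha + 6) ≈ 0.84`. The
observed cluster index of chain-rule cohorts at the study's scale (~100
sets, ~1500 tested pairs) therefore concentrates around 2 with substantial
replicate-to-replicate spread, and a single cohort's upper-tail ratio
p-value against M1 falls below 0.05 in roughly a third of replicates — a
power property of the statistic at this scale, reported as measured by the
test suite rather than adjusted away.

## 5. Synthetic cohorts

`cohort_spec()` fixes the study conditions: 100 sets by default (about
1500 tested pairs at the default set-size distribution, matching the scale
of the recorded data); 3–8 cells per set with weights centred on six cells
(the study reports an average of six; the exact distribution is not printed
and is configurable); per-set FF proportion from a two-component Beta
mixture (shapes (2, 14) and (14, 6), equal weights — modes near 0.07 and
0.72) reproducing the reported bimodality of FF proportions across sets;
soma positions uniform in a 100 µm-radius disc, which keeps most inter-soma
distances under 150 µm as in the recorded pairs (the true spatial point
process is unconstrained by the study); true coupling coefficients uniform
on [0.005, 0.13], the reported range.

## 6. Step recordings and feature extraction

Subthreshold responses follow the single-compartment charging curve
`V(t) = RMP + I·R·(1 − e^(−t/τ))` (units: pA × MΩ × 10⁻³ → mV). Spikes are
piecewise templates, not conductance models — determinism and exact
ground-truth recovery were preferred over biophysical realism. The template
rises linearly from threshold to peak over half the half-width (snapped to
the sampling grid so the peak voltage is sampled exactly), decays
exponentially toward an asymptote 10% below the trough with the decay
constant solved so the width at half-height equals the half-width parameter
exactly, and recovers exponentially (τ = 5 ms) toward the inter-spike
baseline. The threshold potential is 90% of the steady-state depolarization
at rheobase, so the first-spike delay at rheobase is `τ·ln 10`. Spike
counts grow by one per 10 pA above rheobase; inter-spike intervals form a
geometric sequence whose last/first ratio equals the adaptation parameter,
with spike count reduced when intervals would underrun the template
footprint plus a full recovery (this keeps the pre-spike baseline flat, so
threshold estimation sees a clean kink). Defaults: 20 kHz sampling, 600 ms
steps from −100 pA in +10 pA increments, 0.1 mV noise (0 for round-trip
tests). Rheobase parameters are drawn on the 10 pA grid, since a step
protocol can only resolve rheobase to its increment.

Feature extraction follows the measurement definitions: threshold is the
maximum of the third finite difference within 20 ms before the peak, on a
trace smoothed with a 5-sample centred moving average (the study does not
state its smoothing; the window is configurable, and the argmax of the
forward third difference is mapped back to the underlying sample with an
offset of `(smooth − 1)/2 + 2`, derived from the difference stencil).
Amplitude is peak minus threshold, half-width the time between the two
half-height crossings (linear interpolation), decay time the first return
to threshold voltage, AHP the threshold-to-trough drop with the trough
searched up to the next spike or the stimulus end. Input resistance and RMP
come from the least-squares line of steady-state potentials (mean of the
last 50 ms of the step; window configurable) of the first five
negative-current sweeps against current — slope and value at zero current
respectively. The "potential at the x-axis intersection" wording in the
source description is read as the fitted potential at I = 0; the literal
x-intercept would be a current, not a potential. τ is fitted per
hyperpolarizing sweep with `a·e^(−t/τ) + C` from onset to the minimum
within the first half of the step (nonlinear least squares via
`minpack.lm::nlsLM`, initialized from a log-linear regression of the
detrended trace) and averaged across sweeps. Spike detection defaults:
dV/dt ≥ 20 mV/ms, peak ≥ −10 mV, 2 ms refractory.

On noiseless synthetic recordings every parameter with a feature
counterpart (RMP, input resistance, τ, rheobase, amplitude, half-width,
AHP, adaptation) is recovered within 2% — most exactly; the spontaneous
rate has no counterpart because the emulated protocol holds cells below
threshold. The 2D embedding (`embed_features()`) is a standardized
principal-component projection with a deterministic sign convention; it
serves the visualization/cluster-separation contract (the original figures
use t-SNE, whose specific layout is an aesthetic choice outside this
package's scope).

## 7. Coupling estimation

Deflections are means over the last 15 ms of the step (the midpoint of the
10–20 ms measurement range; configurable) minus an equal-length pre-stimulus
baseline. Trials are averaged before the ratio is taken. A pair is coupled
when the mean of the two directional coefficients is ≥ 0.005 *and* the
partner deflection has the injected response's sign; the study states the
threshold but not whether it applies to the mean or either direction — the
mean matches its per-pair reporting, and one-sided pairs are classified on
the available direction with a flag. The rectification regression is
declared as `cc_ji` on `cc_ij` (so doubling `cc_ji` doubles the slope).
Injected deflections under 1 mV flag the estimate unreliable. The
chemical-connection detector averages spike-triggered sweeps and requires
the average to deviate by more than 3 baseline SDs for at least 1 ms within
1–15 ms after the spike; the sustained-duration requirement is the
package's choice (a single-sample criterion false-alarms on ~70-sample
windows), and the study gives no numeric criterion. Second-order coupling
is not modelled: graphs record direct classifications only.

## 8. Morphology

Analysis is 2D throughout (z collapsed), matching the camera-lucida slice
context. Soma ellipses use the direct least-squares conic fit with the
ellipse constraint; the soma bipolarity index is major/minor. The dendritic
bipolarity index is the fraction of primary-dendrite origins within ±45° of
either pole of the major axis — the study defines "around the major axis"
without a window, so the two 90° sectors covering half the circle are the
default (configurable), which makes the index 0.5 for uniformly distributed
stems. Origins are counted per stem by default (length-weighting is
available); whether the original index used stems, length, or nodes is
unknown. Sholl intersections solve the circle–segment quadratic exactly
(default 20 µm steps, circles centred on the soma centroid). The FF/MP
classifier is a single-hidden-layer network (`nnet`, 3 units, decay 5e-3)
with leave-one-out evaluation and per-fold seeding; on feature populations
separated as in the recorded data it reaches 100% accuracy, and a soma-only
variant is nearly as accurate.

Synthetic reconstructions emulate only what the indices measure: soma axis
ratio ranges (FF 2.2–3.5, MP 1.02–1.35), stem-origin concentration (FF
two poles with 12° jitter, MP 4–6 near-uniform stems), and branching
segment trees. They do not emulate tortuosity, branch-order statistics,
axon trajectories, tissue shrinkage, or 3D structure — so passing tests
certify the geometry operations, not anatomical realism.

## 9. Pipeline, seeds, and problem sizes

`run_pipeline()` chains generation → feature extraction → coupling →
rates → motif counting → model predictions, writing CSV/JSON when an
output directory is set. Every stage derives its seed from the master seed
by a counter scheme (`stage_seed()`), so stages re-run independently and
identical configurations produce byte-identical outputs. Trace-level
stages run on configurable subsamples (defaults: 6 cells, 8 + 8 pairs)
because a full cohort's 20 kHz traces are orders of magnitude larger than
the connectivity analysis needs; the motif analysis always uses the whole
cohort. The default demo (100 sets, 1000 Monte Carlo runs per model)
completes in well under five minutes on one core.

Test-suite problem sizes are chosen to keep the full suite in the
tens-of-minutes range while leaving Monte Carlo error far below the asserted
tolerances: 200 random graphs for the counting oracle, 1000-run simulations
for mean/interval checks, 200 replicate cohorts for interval calibration,
40 replicates for the chain-rule detection-power measurement, 100 random
cells for the feature round trip, and 100 random trees for the Sholl
oracle.

## 10. Known limitations

* Spike templates are kinematic; features tied to conductance dynamics
  (e.g. realistic upstroke/downstroke asymmetry distributions) are only
  qualitatively emulated.
* The chain-rule model is one minimal mechanism consistent with the stated
  concept; other mechanisms (e.g. latent connector-cell propensity) could
  produce similar motif statistics.
* Pairwise probabilities in M2/M3 are treated as fixed constants, not
  estimates with sampling error; prediction intervals therefore understate
  uncertainty when the rates come from small counts.
* The cluster index is undefined for cohorts without non-chain motifs;
  downstream summaries flag rather than impute such cases.
* Real recordings bring artifacts the synthetic module does not emulate:
  electrode drift, seal quality, spontaneous synaptic noise, truncated
  dendrites. Passing round-trip tests certifies the estimators on the
  stated model, not robustness to those artifacts.
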