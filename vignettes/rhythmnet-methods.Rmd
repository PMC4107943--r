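---
title: "Methods: correlogram-based functional connectivity in rhythmic spiking networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: correlogram-based functional connectivity in rhythmic spiking networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhythmnet)
```

## The problem

The pre-Bötzinger complex (preBötC) is the medullary microcircuit that
generates the inspiratory rhythm. Recorded in a brainstem slice on a
6 x 10 multi-electrode array (100 µm pitch, 25 kHz digitization), it
produces slow population bursts (fictive eupnea) on which individual
units and multi-unit clusters ride. The scientific question this package
serves is how the *functional network* — the set of statistically
coupled element pairs — reconfigures when the preparation is challenged
(hypoxia, which switches the rhythm to fictive gasping) or
pharmacologically supported (the Krebs-cycle intermediate isocitrate).

`rhythmnet` implements the full analysis chain: extracellular spike
detection and sorting, rate-normalized cross-correlogram connectivity
with a flank-noise significance rule, per-condition linkage matrices and
their differences (ΔCorrelation), and network summaries. Because no
recordings of this kind are publicly deposited, the package also ships a
ground-truthed synthetic recording generator so that every stage can be
validated against known structure.

## The connectivity estimator

Spike trains are binarized into half-open 1-ms bins (multiple spikes in
a bin collapse to one, logged). For elements $a, b$ with $N_a, N_b$
occupied bins over $n$ bins, the correlogram counts bin pairs at signed
lag $\tau$,

$$C(\tau) = \#\{(i, j): j - i = \tau,\; a_i = b_j = 1\},$$

and normalizes by the count expected under independence,

$$V(\tau) = \frac{C(\tau)}{N_a N_b / n},$$

so $V \approx 1$ for independent trains and is invariant under
proportional rate changes — the point of the normalization is that a
change in correlation cannot be an artefact of a change in firing rate.
$V$ is computed over a ±50 ms window; the peak is taken over the ±5 ms
analysis window; the **baseline** (mean) and **correlation noise SD**
are estimated from the flank lags (5 < |τ| ≤ 50 ms), a surrogate-free
estimate of chance-coincidence fluctuation. A pair is a functional link
when

$$V_\text{peak} - \text{baseline} > 5 \,\hat\sigma_\text{noise},$$

nominally a >99.9% one-sided Gaussian confidence
(`significance_confidence(5)` ≈ 99.99997%).

Two numerical guards matter in practice:

* **Poisson floor.** With sparse trains the flank counts per bin can be
  far below 1; the count distribution is then strongly skewed and the
  empirical flank SD understates its tail, so the Gaussian rule
  over-detects. The noise SD is therefore floored at
  $(q - \bar m)/5$ (in count units), where $\bar m$ is the flank mean
  and $q$ its Poisson quantile at the confidence the 5-SD rule implies.
  For dense trains the floor is inactive.
* **Exclusion, not zeroing.** Pairs where either element has fewer than
  `min_spikes` (default 50) spikes in the analysis window, or whose
  correlogram is flat (zero noise SD), are excluded from the linkage
  matrix and logged — they are never silently entered as zero and never
  auto-significant.

Peak-lag ties are broken toward smaller |lag|, then toward negative lag.
Significant peaks are classified as `zero_sharp` / `zero_broad`
(supra-threshold region includes lag 0; width ≤ 2 bins is sharp) or
`lag_short` (|lag| ≤ 2 ms) / `lag_long` (2.1–5 ms). The significance
test uses baseline-subtracted peaks; linkage-matrix entries store the
raw normalized peak. Whole 10-minute condition windows are analyzed
(burst epochs are not cut out), matching the workflow the analysis
reproduces; the burst-induced slow co-modulation this leaves in place is
flat across the ±50 ms window and is absorbed by the flank baseline.

Linkage matrices are symmetric with zero diagonal; ΔCorrelation is the
element-wise difference from the control matrix, with the *considered
set* defined as pairs significant in at least one of the two conditions
(so links that appear or vanish contribute).

## Preprocessing and sorting

* **Filtering**: 250–7000 Hz Butterworth, applied forward and backward
  (zero phase) so spike times are not shifted — a ±5 ms correlation
  analysis cannot tolerate group delay.
* **Burst trace**: peak-to-peak amplitude in 45-ms windows. Population
  bursts are runs above median + 3 scaled MADs (robust statistics, so
  the bursts themselves do not inflate the threshold — the stated
  mean + k·SD rule fails outright when bursts occupy ~10% of the
  trace), bridged across gaps < 200 ms, and must last ≥ 90 ms.
* **Detection**: negative-going crossings of −2.6 robust SDs (scaled
  MAD; −4.0 for multi-unit channels). Extracellular spikes are
  dominantly negative, which resolves the sign ambiguity the protocol
  leaves open. One event per crossing with one snippet (1 ms pre / 2 ms
  post) of dead time; events are timestamped at, and snippets aligned
  on, the deepest trough within the post-window of the crossing, so a
  spike arriving just after a shallow noise crossing is kept.
* **Sorting**: PCA of snippets (first 3 PCs for clustering, 2 for
  display), Gaussian-mixture EM over k = 1..6 selected by BIC
  (`mclust`), with a central low-amplitude cluster flagged as the noise
  class. Sorting runs on condition-concatenated data so element
  identity persists across conditions. A cluster is a single *unit*
  when its minimum Mahalanobis distance to other cluster centroids is
  ≥ 3 and its 2-ms refractory-violation fraction (greedy left-to-right
  enforcement, chosen for determinism) is < 0.5%; residual supra-4-SD
  activity forms the channel's multi-unit element.

## The synthetic-data generator

The generator replaces the study's non-deposited recordings; its
defaults *are* the simulated study conditions.

**Rhythm**: periodic population bursts, period 5 s with 0.3 s Gaussian
cycle jitter, burst duration 0.5 s. The preparation's cycle period is
not pinned down by the analysis chain itself; 5 s is a typical fictive
eupnea value at desk scale and is a free parameter.

**Elements**: ~87% inspiratory; inspiratory elements fire as
inhomogeneous Poisson processes with a boxcar envelope (intraburst rate
log-normal, median ≈ 3.6 Hz, chosen so the reciprocal median ISI lands
near the ~5 Hz control scale; tonic rate ≤ intraburst/3 so inspiratory
elements are burst-modulated by construction). Expiratory elements are
suppressed inside bursts. Multi-unit elements superpose 2–4 latent
neurons; each latent neuron respects a 2-ms refractory period.

**Couplings** are directed spike-copy links: each source spike, with
probability `strength` (times the condition's coupling multiplier,
capped at 1), produces a target spike at `lag_ms` plus Gaussian jitter
(0.3 ms). Copying is **rate-preserving**: each copy replaces one of the
target's own spikes, i.e. the driven element phase-locks to its driver
instead of adding spikes. This is the one place the implementation
deliberately departs from a plain additive-copy scheme: additive copies
inflate the target's spike count, which mechanically *lowers* the
rate-normalized correlogram value whenever a condition raises rates —
making it impossible, for instance, for normalized correlation to rise
under a 4.6-fold rate increase, which is precisely the empirical
pattern the isocitrate condition must reproduce. Synchronization
without rate change also keeps the generator's rate multipliers exact.

Couplings come in two classes on a core–follower layout: **strong**
links (disjoint: unique high-rate sources, unique targets from the
active remainder, so per-link ground truth is identifiable and no
common-source coincidences arise) and **weak ("latent")** links —
connections below the significance floor in control, standing in for
weak or silent synapses that a potentiating condition can recruit into
detectability. Rather than drawing copy probabilities uniformly, each
link's probability is calibrated to a target *detection margin* at the
600-s reference window (strong: 10–16x the significance threshold;
weak: 0.3–0.6x), computed from the pair's expected rates and burst
co-modulation. Uniform probabilities confound ground truth with firing
rate: the same probability yields an overwhelming peak from an active
source and an undetectable one from a sparse source.

**Condition profiles** carry the reported population statistics as
defaults: hypoxia raises a 34% subpopulation to 135 ± 6% of control and
lowers the rest to 64 ± 2% (global mean ≈ 88%), silences 0.4% of
elements, and halves coupling strength; isocitrate raises 84% of
elements to 463 ± 45% (the rest 58 ± 38%) and strongly potentiates
coupling (x12 — the emulated phenomenon is an *increase* in normalized
correlation despite the rate rise, which under this model requires
coupling efficacy to grow faster than rate); isocitrate + hypoxia
returns rates to control
with coupling still potentiated (x3). Up/down membership follows
activity rank (the most active elements form the up subset), reflecting
that the rhythmogenic core keeps driving in gasping; the subpopulation
proportions and multiplier values are unchanged by this choice.

**Raw signal**: each spike adds its element's template (biphasic or
triphasic, < 2 ms) on its electrode channel; additive stationary
Gaussian noise with a 0.2-ms correlation scale. Band-limited rather
than white noise, because extracellular background (distant multi-unit
activity, electrode/tissue filtering) is not white at 25 kHz and white
noise grossly overstates 2.6-SD threshold-crossing rates.

What the generator does *not* emulate: biophysical membrane dynamics,
electrode cross-talk or spike waveform spread across channels, drift
and electrode instability, true synaptic transmission (couplings only
produce correlated timing), and metabolic state. Tests passing on this
generator therefore demonstrate that the *analysis chain* recovers the
structure it assumes — not that real recordings satisfy those
assumptions.

## Statistics across conditions

Replicate-level comparisons use a paired t-test for two conditions
(identical replicates are reported as p = 1, which `t.test` cannot do),
repeated-measures ANOVA (replicate as block) with Tukey or Dunnett
contrasts (`multcomp`) for more, or Kruskal–Wallis with Dunn's post-hoc
z-tests (implemented here; Bonferroni-adjusted). Significance at
α = 0.05. In the recovery experiments
(`condition_recovery_experiment()`), the pooled considered-pair
ΔCorrelation is tested with a one-sided Wilcoxon signed-rank test —
per-link deltas are heavy-tailed across links of very different
magnitude, where a t-test has poor power.

## Desk-scale problem sizes

Validation experiments use 24-element slices (16 units, 8 multi-units),
8 strong + 7 latent couplings, 600-s condition windows, and 5 replicate
slices per simulated experiment (the study scale is 17–59 units per
slice and n = 5–7 slices; the window length and per-slice element count
are kept at, respectively, the study's value and roughly half of it).
Detection/sorting validation uses single channels at 25 kHz for 60–90 s
with SNR ≥ 5 templates.

## Known limitations

* The correlogram is symmetric evidence of correlated timing; no
  directionality or synapse identification is attempted.
* The flank-noise estimate assumes co-modulation is flat across ±50 ms;
  oscillatory coupling at 10–100 Hz would violate this.
* The automated isolation criterion stands in for human curation of
  sorting; borderline clusters are conservatively labelled multi-unit.
* Coupling chains are not propagated (copies are drawn from the
  pre-coupling source train), so second-order correlations are absent
  by design in the generator even though real circuits have them.
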