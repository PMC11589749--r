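---
title: "Models and methods behind icfmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind icfmap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icfmap)
```

## What the package computes

`icfmap` implements a two-stage analysis of paired-pulse intracortical
facilitation (ICF) TMS-EEG studies comparing a treatment-resistant
depression (TRD) group against healthy controls (HC):

1. **Neurophysiology.** Per subject and condition (single-pulse vs.
   paired-pulse), epoched EEG is cleaned by a deterministic chain, averaged
   into evoked responses, and projected into source space with a
   noise-normalized minimum-norm estimate (dSPM). Region time series over
   the 34 left-hemisphere Desikan–Killiany (DK) regions are contrasted
   (paired − single) and averaged over 50–120 ms, giving one ICF-dSPM index
   per subject and region. Group differences are summarized by pooled
   t-tests (the DLPFC region is the primary endpoint) and by a 34-region
   HC−TRD t-map.
2. **Virtual histology.** The regional profile of the group difference
   (the t-map) is correlated with the regional expression of cell-type
   marker gene sets derived from an AHBA-style donor expression dataset.
   For each of nine cell classes, the observed mean gene–map correlation is
   compared with an empirical null built from random gene sets of the same
   size, with Bonferroni correction across the nine classes.

Because no subject-level data are distributable, the package is built
around a synthetic-data module that generates both stages' inputs with
exhaustively recorded ground truth. All tests and the acceptance script run
against these simulations.

## The synthetic cohort

`synth_config()` defaults describe the emulated study: 60 TRD and 30 HC
subjects, 80 trials per condition, 64 channels at 3 kHz, epochs −2000 to
2000 ms, and a planted standardized reduction of the ICF index at the
stimulated region of d = 0.52 (the null configuration sets it to 0).
Demographics mirror the study's summary table: ages in the mid-forties,
40% female in both groups, MADRS 32.1 (SD 7.1) and illness duration
10.9 (SD 9.2) years in the TRD group. MADRS and duration are generated
independently of the planted effect, matching the absence of clinical
correlations in the emulated design.

The signal model per subject $s$, region $r$ and time $t$ is

$$x(t) \;=\; G\, a_{s,r}\, u(t) \;+\; \varepsilon(t),$$

where

* $u(t)$ is a **damped-sinusoid evoked waveform**, the sum of a 2.2 Hz
  component (decay 120 ms) and a small 10 Hz component (decay 40 ms)
  starting 20 ms after the pulse, normalized to unit peak. The mixture
  peaks ≈ 100 ms after the pulse, inside the 50–120 ms analysis window.
  All parameters are exposed in `synth_config(waveform = ...)`.
* $a_{s,r}$ is the source amplitude: a subject gain (SD 5%) times a
  regional propagation weight, plus — in the paired-pulse condition — a
  facilitation gain $F_s \sim N(0.5, 0.2^2)$ shared across regions. The
  TRD group's facilitation is reduced by
  $d \cdot 0.2 \cdot \rho_r$, where $\rho_r$ is the `propagation_profile`
  (1 at the stimulated rostral-middle-frontal region, decaying smoothly
  elsewhere by default). Because the same $F_s$ drives all regions, the
  regional *standardized* group difference is $d\,\rho_r$ by construction.
* $G$ is a **random leadfield** fixed per seed, with condition number
  bounded by 3. When sources do not outnumber channels the columns are
  drawn orthogonal with graded gains. This choice makes distinct regions
  project to distinguishable sensor topographies, so minimum-norm
  crosstalk stays a small perturbation and the planted regional effect
  profile is identifiable — with a fully unstructured random matrix the
  region estimates are dominated by arbitrary cross-region mixing, which
  no source method could disentangle and which has no analogue in real
  (spatially smooth) leadfields.
* $\varepsilon$ is spatially correlated Gaussian sensor noise: a random
  correlation matrix with unit diagonal, scaled by `noise_sd` (30 µV at
  full scale). The spatial correlation makes shrinkage covariance
  estimation non-trivial.

Planted artifacts are reported item by item in the ground truth: bad
channels (noise and signal scaled ×25, never a protected DLPFC electrode),
high-amplitude epochs (±1500 µV spikes on a good channel outside the pulse
window), and a pulse-window transient (3 mV decaying ramp in −2..15 ms)
emulating the TMS artifact.

### Desk-scale replicates and the noise budget

Monte-Carlo checks (effect recovery, type-I calibration) need hundreds of
cohorts, so they use `desk_config()`: the full 59/29 group sizes but 12
trials, 28 channels, 250 Hz, ±350 ms epochs and 12 µV noise. The relevant
design quantity is the ratio of trial-level measurement variance to the
between-subject variance of the ICF index; measurement noise attenuates
the recovered standardized effect by
$1/\sqrt{1 + \sigma^2_{\text{meas}}/\sigma^2_{\text{between}}}$. The desk
parameters keep that ratio below ≈ 0.1, so the planted d = 0.52 is
recovered essentially unattenuated (mean recovered d ≈ 0.52–0.55 over 200
replicates, against a pure sampling SD of ≈ 0.25 per cohort at n = 88).

## Preprocessing chain

`run_preprocessing()` applies, in order: baseline correction (−500 to
−150 ms), bad-channel detection, epoch rejection (> 1000 µV), pulse-window
excision (−5 to 30 ms) bridged by cubic interpolation, anti-aliased
decimation to 1 kHz with 0.5–100 Hz band-pass and 48–52 Hz notch
(Butterworth order 4, forward–backward for zero phase; the band-pass is a
high-pass/low-pass cascade because a direct order-4 band-pass with a
0.5 Hz edge is numerically fragile), spherical-spline interpolation of the
flagged channels, and average re-referencing. Each step appends a log
record with its parameters; filtering is flagged as the one
non-idempotent step.

Choices where the procedure was genuinely open:

* **Channel variability score.** The default flags channels whose
  *median across trials* of the within-trial robust z (median/MAD across
  channels of the per-trial channel SD) exceeds 3. A single pooled SD per
  channel, z-scored across channels, is available as
  `method = "pooled"`, but an asymptotically normal pooled score has an
  irreducible ≈ 0.1% per-channel false-positive rate, which at 16–64
  channels produces spurious flags in several percent of recordings; the
  per-trial median suppresses this to a negligible level while detecting
  genuinely deviant channels just as reliably. Variability is computed on
  residuals about the cross-trial *median*, so evoked-response strength
  and sparse high-amplitude trials do not masquerade as channel noise.
* **Rejection vs. excision.** The 1000 µV criterion is evaluated after
  baseline correction, on non-flagged channels, and *outside* the
  excision window: the pulse transient lives there and is handled by
  excision, not by discarding every trial.
* **Cubic bridge.** The excised segment is replaced by a cubic fitted to
  20 ms of data on each side — local enough to follow slow structure,
  long enough to be stable; an underlying cubic trend is reproduced
  exactly.
* **No independent component analysis.** The cleaning chain is fully
  deterministic; the generator does not plant ocular/decay components, and
  the package makes no claim about artifacts only ICA could remove.

## Source estimation (dSPM)

The noise covariance is estimated from the pooled pre-stimulus baselines
(−500 to −15 ms) of all trials with analytic (Ledoit–Wolf-style)
shrinkage toward the scaled identity; the shrinkage intensity is recorded.
The inverse uses identity source covariance scaled by $\alpha$, fixed
orientation and no depth weighting:

$$W = \alpha\,G^\top(\alpha\,G G^\top + \lambda^2 C)^{-1},\qquad
  z_i(t) = \frac{[W x(t)]_i}{\sqrt{[W C W^\top]_{ii}}},$$

with $\alpha$ chosen so the whitened predicted signal power equals the
channel count — the standard normalization that makes $\lambda^2$ the
conventional $1/\mathrm{SNR}^2$ heuristic (default $1/9$) and renders the
dSPM values invariant to global rescaling of either $C$ or $G$. Without
this scaling, $\lambda^2 C$ can dwarf $G G^\top$ at realistic noise
levels and the kernel degenerates into noise-covariance mixing. The
defining property — dSPM of pure baseline noise has per-source variance
≈ 1 — is verified in the test suite, as is agreement of the kernel with an
independently coded dense-matrix implementation to 1e−10.

Region series use the *signed mean* of member-source z values
(`method = "mean_abs"` is available); the per-subject index is the
50–120 ms window mean of the paired − single region series, endpoints
inclusive. Whether to project single trials or the evoked average is not
dictated by the procedure; the package projects the evoked average per
condition, and estimates one noise covariance per subject by averaging the
two conditions' baseline covariances.

## Group statistics

All group comparisons use the pooled-variance Student t (the printed
degrees of freedom in the emulated design, 88 and 86, equal
$n_1+n_2-2$, identifying the pooled form), with Cohen's d on the pooled
SD. The 34-region t-map is computed HC-first, so positive t means the
index is reduced in TRD; all regions are retained — the map is a
descriptive input to virtual histology, not an inferential endpoint, so no
multiple-comparison correction is applied to it. Clinical correlations
default to Pearson (Spearman available). Subject exclusions are applied
once, globally, before all analyses.

## Expression pipeline

The AHBA-style preprocessing follows the standard practical sequence:

1. **Background filter:** probes above background in ≥ 50% of samples
   survive ("at least 50%" read as an inclusive boundary).
2. **Sample assignment:** right-hemisphere samples are dropped (the real
   resource has right-hemisphere data for only two donors), and each
   remaining sample is assigned to the nearest region centroid within
   2 mm.
3. **Differential stability (DS):** a probe's DS is the mean over donor
   pairs of the correlation between its regional profiles; the max-DS
   probe represents each gene, and the top 50% of genes by DS are kept.
   The real pipeline's exact cutoff (which produced its 15,744 genes) is
   unreported, so the fraction is a configuration parameter and the
   pipeline reports the count it achieves.
4. **Matrix construction:** per donor, each gene is normalized across the
   donor's assigned samples by a scaled robust sigmoid (z-scoring
   available), averaged within region, and donor region-vectors are
   averaged into the final genes × 34 matrix.

The expression fixture plants items on both sides of every filter with
deterministic counts (so ground truth is exact), and gives one cell class
regional profiles with a specified correlation to a supplied 34-vector.

## Virtual histology

The observed statistic for a cell class is the mean over its genes of the
Pearson correlation (Spearman available) between the gene's 34-region
expression and the t-map. The null resamples same-size gene sets uniformly
without replacement from the full surviving-gene pool — by default *not*
excluding the target genes, matching a null drawn "from the pool" without
qualification; an exclusion option exists. Per-gene correlations are
computed once, so each draw reduces to averaging stored values, and the
desk default of $10^5$ draws (the emulated design's $10^6$ is one
configuration change away) runs in seconds. The two-sided p is the
doubled smaller add-one tail, capped at 1 — never exactly zero and valid
at finite draw counts. An exhaustive enumeration oracle
(`enumerate_null_exact()`) covers pools with up to $10^6$ combinations and
anchors the resampler in the tests. Spatial-autocorrelation-preserving
("spin") nulls are deliberately not offered: the emulated procedure uses a
random-gene null, and offering a different null would misrepresent what
the method controls for.

## What the simulations do and do not show

The generator reproduces the *structure* of the analysis problem — group
design, trial counts, planted effect sizes, artifact types, donor
structure, filter edge cases — but not the physics of real TMS-EEG:
there is no head model, no spatially smooth leadfield, no ocular or decay
components, no auditory co-activation, and the expression fixture has far
fewer genes than a real atlas. Passing tests therefore demonstrate that
the *procedures* are implemented correctly and calibrated (type-I error,
effect recovery, filter exactness), not that the pipeline would recover
biology from real recordings.

Two stochastic properties of the desk-scale study are worth knowing:

* With d = 0.52 at n = 59/29, the DLPFC t-test is significant in roughly
  half of replicate cohorts — the emulated study sits near 60% power, as
  a real study with that effect size would.
* The virtual-histology test is run against the *realized* t-map of one
  cohort. Its noise component hits all genes of a planted class
  coherently (the class shares one regional profile), so at planted
  correlation 0.6 the astrocyte class is flagged in only roughly half to
  three-quarters of seeds. Against the noiseless target profile the
  planted signal is detected essentially always, which the test suite
  verifies separately.

## Problem sizes used by the tests and the acceptance script

Replicate simulations use `desk_config()` (59/29 subjects, 12 trials, 28
channels, 250 Hz, ±350 ms, 12 µV noise; 200 cohorts for effect recovery
and null calibration), expression fixtures with 40–120 genes and 2–6
donors (500 null fixtures for type-I calibration of the resampling test),
and $10^5$ draws where the resampler is compared against exact
enumeration. These sizes were chosen so each Monte-Carlo estimate has
enough precision for its acceptance band (e.g. a binomial SE of ~1.5% at
200 replicates for a rejection-rate band of width 8%) while a full
verification run stays comfortably within an ordinary desktop session.
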