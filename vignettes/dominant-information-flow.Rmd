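---
title: "Measuring depth of anesthesia from dominant information flow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring depth of anesthesia from dominant information flow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Most EEG depth-of-anesthesia (DOA) monitors summarize one or two channels:
spectral edge frequency, band-limited spectral entropy, or bispectral
ratios computed from a prefrontal lead. Consciousness, however, is tied to
the integration and segregation of activity across cortical regions, and
anesthetic loss of consciousness is consistently accompanied by a
reduction in frontoparietal feedback connectivity. `doaflow` measures DOA
from the *directed information flow* in the whole channel set: it scans
every way of splitting the montage into a source group and a target group,
quantifies each split with Gaussian transfer entropy, and summarizes the
scan with three indices.

## The measure

For a target group $A$ and source group $B$, transfer entropy with
embedding dimension and delay fixed at 1 is

$$T_{B \to A} = H(A_{n+1}, A_n) - H(A_n) - H(A_{n+1}, A_n, B_n) + H(A_n, B_n),$$

where $A_{n+1}$ is the target block advanced by the lag $\tau$ and each
$H$ is the differential entropy of a multivariate Gaussian,
$H = \tfrac12 \ln\!\big((2\pi e)^k\,\lvert\Sigma\rvert\big)$, evaluated on
the sample covariance of the corresponding time-aligned blocks. All
entropies are in nats. Under the Gaussian model this transfer entropy is
equivalent to the Granger-causality log variance ratio for univariate
targets, which the test suite exploits as an independent oracle.

A *bipartition* is an ordered pair of disjoint non-empty channel subsets
(source, target). With $n$ channels there are $3^n - 2^{n+1} + 1$ such
ordered pairs when the union need not cover the montage
(`mode = "disjoint_pairs"`; 12 pairs for $n = 3$) and $2^n - 2$ ordered
two-block partitions (`mode = "covering"`; 126 for $n = 7$). Three indices
summarize the scan per analysis window:

* **T_max** — the largest table entry: the dominant information flow;
* **T_min** — the smallest entry: the flow across the minimum information
  bipartition (MIB), the split across which the montage is most nearly
  separable;
* **T_mean** — the arithmetic mean over all entries.

For T_min an alternative reading of the MIB criterion is available
(`rule = "maxmin"`): score each unordered split by its weaker direction
and take the split whose weaker direction is largest. Both readings are
implemented because the defining sentence of the MIB criterion is
genuinely ambiguous; the plain minimum is the default since the observed
behavior of the index (values far below T_max, strong modulation with
concentration) is consistent with it.

## Study conditions and defaults

| Parameter | Default | Why |
|---|---|---|
| channels | Fp1, Fp2, F3, F4, P3, P4, Cz | 7-lead frontoparietal 10–20 montage |
| sampling rate | 256 Hz | clinical EEG recorder rate |
| low-pass | Butterworth, order 9, 50 Hz | standard anti-noise preprocessing |
| window / step | 60 s / 30 s | index time-course resolution |
| lag $\tau$ | 2 samples | $2/256$ s $= 7.8$ ms |
| bipartition mode | `disjoint_pairs` | the 3-channel count of 12 identifies this enumeration |
| T_min rule | `min` | see above |

The filter is applied forward–backward (`signal::filtfilt`), so it is
zero-phase and does not shift window boundaries; this doubles the
effective order and squares the magnitude response (the one-way $-3$ dB
point becomes $-6$ dB). Filtering precedes segmentation. Windows are
half-open sample ranges; a trailing partial window is dropped. Covariances
are maximum-likelihood (divide by $N$) on per-window mean-removed data.

## Numerical choices

* Determinants are computed as Cholesky log-determinants after adding a
  ridge of $10^{-10}$ times the mean diagonal; a group with a constant
  channel is rejected rather than regularized into validity.
* Transfer-entropy estimates that come out negative by less than
  $10^{-9}$ nats — the round-off scale of 14-dimensional log-determinant
  combinations — are clipped to zero; larger negatives are a warning, not
  silently clipped.
* The per-window bipartition scan computes one pooled $2n \times 2n$
  lag-stacked covariance per window; every bipartition's four entropy
  terms are determinants of its sub-blocks, so the samples are traversed
  once per window regardless of the number of bipartitions.
* The effect-site ODE is solved exactly for piecewise-linear plasma
  curves; the three-compartment PK amounts are integrated with `lsoda`
  at relative tolerance $10^{-8}$, restarted at infusion-segment
  boundaries so piecewise-constant rates are exact.

## The VAR validation system

Validation uses a first-order vector autoregression
$x_t = F x_{t-1} + e_t$ with unit-variance independent Gaussian
innovations. Its stationary covariance solves the discrete Lyapunov
equation $\Sigma = F \Sigma F^\top + \Sigma_e$ and the lag-$\tau$
cross-covariance is $F^\tau \Sigma$, so every transfer entropy has an
analytic value (`analytic_te`) against which the sample estimator is
checked: decoupled sources give exactly zero; the system
$y_{t+1} = x_t + e_t$ gives $\tfrac12 \ln 2$; random stable systems match
the Granger variance-ratio form; estimates converge to the analytic value
as the sample grows.

## The synthetic anesthesia session

No clinical recordings are distributable, so `make_anesthesia_fixture()`
generates a surrogate session: a 7-channel VAR whose inter-channel
couplings are attenuated by a simulated effect-site concentration,

$$g(C_e) = \frac{1}{1 + (C_e/C_{50,\mathrm{mod}})^h},$$

with $C_e(t)$ produced by the package's own PK/effect-compartment chain
(three-compartment model, default published propofol estimates; 14 mg/min
— 12 mg/kg/h at a nominal 70 kg — for 8 minutes starting at 2 minutes of
a 20-minute session; $k_{e0} = 0.155\,\mathrm{min}^{-1}$,
$C_{50,\mathrm{mod}} = 1\ \mu$g/mL, $h = 2$).

Two fixture design choices matter. First, the baseline topology gives the
frontoparietal feedback edges (F3→P3, F4→P4) the largest weights but also
includes weaker reciprocal and midline couplings so that *every* channel
subset receives flow from its complement: if some cut carries no flow at
baseline, T_min sits on that zero-flow cut at the estimator's bias floor
and cannot respond to the drug. Second, by default *all* inter-channel
couplings attenuate with $C_e$, not only the feedback edges — anesthetic
suppression of effective cortical connectivity is broad, and a
feedback-only modulation cannot guarantee that the minimum-flow cut
crosses a modulated edge. The modulation map is a user parameter for
studying edge-specific designs. The concentration–coupling law itself is a
fixture choice; no quantitative link is claimed.

What passing tests on this fixture do show: the estimator pipeline
(windowing, pooled covariance, bipartition scan, index extraction)
recovers a monotone-decreasing coupling modulation as a T_min time course
that correlates strongly and negatively with the ground-truth $C_e$. What
they do not show: performance on real EEG, whose spectra are not VAR-like,
whose artifacts are not modeled, and whose connectivity changes are richer
than a scalar attenuation.

## Pharmacodynamic link and scoring

Index courses are linked to concentration with the sigmoid Emax /
effect-compartment model
$E = E_0 + (E_{\max} - E_0)\,C_e^\gamma / (C_{e50}^\gamma + C_e^\gamma)$.
Fitting is individual-level nonlinear least squares (Levenberg–Marquardt,
multistart over $k_{e0}$ and $\gamma$, positivity by log-transform);
population mixed-effects estimation and bootstrap validation are out of
scope, and published population parameter sets are consumed as fixed
defaults. Nested-model comparisons use the $\chi^2$ threshold helper
(3.84 at $\alpha = 0.05$, df 1). Indices are scored against $C_e$ with
Pearson and Spearman correlation and the prediction probability
$P_K = 1 - (1 - \lvert D\rvert)/2$, where $D$ is Somers' D conditioned on
concentration-untied pairs; its standard error is the delta-method
estimate for the ratio of pair-sum U-statistics, divided by 2 for the
$P_K$ scale.

## Problem sizes used in the tests

The suite exercises estimator consistency at $10^3$–$10^5$ samples,
Monte-Carlo covariance checks at $2\times10^5$ samples, a 20-minute
256 Hz fixture for the end-to-end index-recovery check, and 130-point
pharmacodynamic recovery studies over 20 noise seeds — sizes at which all
the asymptotic claims are already well resolved.

## Known limitations

* The Gaussian covariance estimator is the only transfer-entropy
  estimator provided; kernel, nearest-neighbor and binned estimators, and
  multivariate embeddings ($d > 1$), are out of scope.
* Artifact rejection, re-referencing and montage conversion are not
  performed.
* The EDF writer quantizes to 16 bits over each channel's range
  (round-trip error bounded by one digital step) and carries annotations
  in a YAML sidecar rather than EDF+ annotation blocks.
* SFS follows the published synch-fast-slow construction (log bispectral
  ratio); the proprietary clinical BIS index is not reproduced.
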