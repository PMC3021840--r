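---
title: "Models and methods in meegflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in meegflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

meegflow is a trial-based analysis toolbox for multichannel
electrophysiology (MEG/EEG).  This vignette explains the models the
package implements, the assumptions behind them, the parameters that
matter, and the design choices made where the design was genuinely open.
Everything the package claims about itself is checked by the test suite on
synthetic data generated through its own forward models; the last section
spells out what those tests do and do not show about real recordings.

## The data model

A recording is represented as a list of trials, each a channels x
timepoints matrix in SI units (volts for EEG, tesla for MEG), with one
time axis per trial.  Trials may differ in length: trial definitions are
windows `[begin, end)` around trigger events (0-based, half-open
internally; the BrainVision marker format's 1-based positions are
converted exactly once at the file boundary), and the per-trial time axis
carries an offset so that t = 0 marks the trigger.  Every derived object
carries a nested provenance tree — the step name and parameters of the
operation that produced it plus the provenance of each input — so the full
history of any result is recoverable by recursive descent, and
pipeline-produced results can be replayed from the provenance JSON alone.
Provenance stores parameters, never data payloads; intermediate data are
the user's to manage (the pipeline runner writes each step's output to
disk).  Provenance also records the package version string; tests do not
compare it.

On-disk serialization uses one RDS container per object with a JSON export
of the provenance tree.  Artifact reports and source maps additionally
export as plain-text CSV/TSV tables.

## Preprocessing

Filtering is delegated to `signal::butter`/`signal::fir1` for design;
application is this package's own: mirror padding (three filter orders, or
one period of the lowest cutoff, whichever is longer) absorbs edge
transients, and the default two-pass direction runs the filter forward and
backward for zero phase distortion at twice the effective order.  The mean
is removed before highpass/bandpass filtering — it lies in the stopband,
and removing it exactly kills the DC edge transient.  The default design
is Butterworth order 4, two-pass, a common electrophysiology practice; the
zero-phase symmetry property (filtering a time-reversed signal equals
time-reversing the filtered signal) holds to 1e-10 away from the edges.

The sliding median filter keeps the full odd kernel in the interior
(delegating to `stats::runmed`) and shrinks the window symmetrically at
the edges, so first and last samples pass through unchanged.  Baseline
windows are closed intervals in time with half-a-sample tolerance.

## Artifact handling

Detection follows the semi-automatic z-threshold scheme: the data are
transformed per channel to emphasize one artifact class, z-scored with
mean and standard deviation pooled over all trials (artifact-free trials
calibrate the null), accumulated over channels, thresholded, and nearby
suprathreshold runs merged and padded.  Two transform details matter and
were validated in the closed loop:

* **Jump transform.**  A median filter *preserves* a sharp step while
  suppressing noise and physiology, so the SQUID-jump statistic is the
  absolute first difference *of* the median-filtered signal (kernel 9
  samples, longer than a flux-jump edge, shorter than physiology).
  Subtracting the median-filtered signal from the data — a tempting
  alternative — cancels the step entirely and cannot detect it.  Inside
  this transform the median filter pads by edge replication; the shrinking
  window rule of the public `median_filter` would inflate the null at
  trial edges.
* **Channel accumulation.**  The per-channel z scores are summed and
  divided by `sqrt(n_channels)`, keeping the statistic unit-variance under
  the null whatever the channel count, so one threshold (default z = 10)
  is portable across montages.  With this statistic, injected 20-sigma
  jumps are recalled perfectly while pure noise trips the detector in
  under 5% of runs.

The muscle transform is a 110–140 Hz bandpass followed by the
analytic-signal amplitude envelope (requires a sampling rate above
220 Hz); both band and threshold defaults are this package's documented
choices.

Component-based removal uses PCA: components are eigenvectors of the
trial-pooled covariance, time courses are computed from the raw
(un-demeaned) data so that back-projecting all components reproduces the
data exactly and removing all of them yields zero.  Blink-like artifacts
with a fixed spatial topography concentrate in one component
(rank-1 by construction) and subtract cleanly.  A caution the tests make
explicit: projecting out one spatial direction necessarily removes the
brain signal's share of that direction — about `1/sqrt(n_channels)` of the
RMS when the brain signal is full-rank and isotropic.  The <= 5% residual
demonstrated in the closed loop holds for the realistic case of a low-rank
brain signal not aligned with the artifact topography; it cannot hold for
isotropic broadband data, whatever the algorithm.

## Spectral estimation

Slepian (DPSS) tapers are computed from the classical symmetric
tridiagonal eigenproblem and their in-band concentrations evaluated
exactly via the sinc-kernel Toeplitz quadratic form.  One mathematical
fact worth recording: with K = 2NW - 1 tapers (the usual recommendation,
and the default `floor(2 * smoothing * T) - 1`), the concentration of the
*last* taper is ~0.90–0.94 for every NW — not >= 0.99, which only holds
through taper 2NW - 2.  The tests assert exactly that.

All spectra are one-sided densities (unit²/Hz): each squared coefficient
is scaled by `2 / (fs * sum(taper^2))`, without doubling at DC and
Nyquist.  This makes the white-noise density exactly `sigma^2 / (fs/2)`
and Parseval's identity exact, both of which are asserted.  Trials of
unequal length are rejected by `mtmfft` rather than padded — padding
changes the Rayleigh frequency per trial and corrupts averages; use the
sliding-window estimator instead.  Sliding-window and Morlet-wavelet
estimates return NA (never extrapolations) where the window or wavelet
support (+/- 3 standard deviations) does not fit.  The wavelet envelope has
temporal standard deviation `m / (2 pi f)` (m cycles, default 7) and uses
the same density scaling with the Gaussian envelope as taper, so its peak
response matches a resolution-matched sliding hann estimate within a few
percent.

## Connectivity

Coherency, PLV and the phase slope index are computed from trial-resolved
spectral decompositions; PDC, DTF and spectral Granger causality from a
fitted MVAR model.  Conventions: coherence is reported as magnitude by
default (squared as an option); PSI is normalized by a leave-one-trial-out
jackknife standard deviation with the raw index also returned, positive
meaning the first channel leads; directed arrays are indexed
`[receiver, sender, frequency]`.  MVAR fitting is joint least squares over
all trials with strictly within-trial regressors, per-trial demeaning, and
an unbiased residual-covariance denominator; order selection is the
caller's duty (an AIC helper exists but is never auto-applied).  For more
than two channels, Granger causality is computed on bivariate refits,
following the bivariate formulation; PDC/DTF use the full model.  The
spectral Granger measure integrates (within about 10% at these problem
sizes) to the time-domain log variance ratio of restricted versus full
regressions, which the tests verify by explicit regression.

## Forward models

The MEG single-sphere field is the closed-form solution for a current
dipole in a spherically symmetric conductor; volume currents are handled
analytically, radial moments are silent, and the far field decays as the
inverse cube of distance (dipolar) — all asserted to machine precision,
along with rotational equivariance.  Sensors are point magnetometers;
gradiometers are composed by the caller as coil differences.

The EEG concentric-sphere potential is a Legendre series in the
source–electrode angle with per-shell radial transfer factors obtained, at
each harmonic order, from a small linear system expressing continuity of
potential and normal current at every interface and an insulating outer
boundary.  The expansion uses a per-shell normalized radial basis, which
keeps the system well conditioned to high order for realistic shell
geometries (shells at comparable radii); the series is truncated at
`n_max = 60` by default, giving <= 1e-8 relative error for sources within
90% of the innermost radius (asserted against n_max = 150).  Sources
within 0.2% of the innermost radius are rejected.  An independently
derived homogeneous-sphere closed form (the summed `(2n+1)/n` series)
serves as the collapse oracle: equal-conductivity multi-shell models must
reproduce it to 1e-8.  Electrodes are projected radially onto the outer
surface.  The conventional three-shell conductivity set
`c(0.33, 0.0042, 0.33)` S/m appears in examples without being asserted as
canonical.

## Inverse methods

Dipole fitting is a two-stage scheme: an exhaustive residual-variance scan
over the candidate grid (for several dipoles, greedy-sequential seeding —
fit, project out, rescan — since a joint combinatorial scan is
exponential), then Nelder–Mead refinement of all positions jointly with
two deterministic restarts and moments recovered linearly at the optimum.
Noiseless recovery is exact to sub-millimeter with residual variance below
1e-10.

The beamformers are vector (three-orientation) filters with trace power.
Regularization is a fraction of the mean sensor variance
(`lambda_reg * trace(C)/N`), scale-free across units; 5% is the power
mapping default.  For MEG sphere models the per-position gain matrix is
rank 2 (radial silence), so the 3x3 unit-gain identity `W L = I` holds
only for EEG; the MEG weights use a truncated pseudoinverse, which the
`singular` flag records.  The neural activity index divides the source
power by the noise power projected through the same weights (smallest
covariance eigenvalue times identity by default) and is the quantity to
inspect for localization: raw power grows toward deep positions.  DICS
applies the identical weight formula to a Hermitian cross-spectral matrix;
both beamformers compute power through the regularized matrix, which makes
a real-valued CSD reduce exactly to the time-domain result.  Source–
reference coherence projects each position onto its dominant orientation
(principal eigenvector of the 3x3 source CSD) before forming the 2x2
source-level CSD; for coherence mapping a weaker regularization
(`lambda_reg = 0.01`) is recommended, since wide spatial filters leak the
reference signal into the coherence floor (measured: floor 0.27 at 5%
regularization vs 0.06 at 1%).

The minimum-norm estimate is the regularized linear inverse
`M = R L' (L R L' + lambda^2 C)^-1` with identity source covariance by
default and optional depth weighting `R_ii = ||L_i||^(-2 gamma)`.
`lambda` is dimensionless — the noise covariance is internally rescaled to
the trace of the Gram matrix — for the same scale-freedom reason as the
beamformers.  Two facts shape how the package evaluates MNE localization:
the global peak of a minimum-norm map on a volumetric grid carries a
well-known radial bias (tens of millimeters here, for any fixed depth
exponent), and the appropriate reading of "where does MNE see a source"
is therefore its *local maxima* (`source_local_maxima`), computed on the
trial-averaged evoked response with the field-standard depth exponent 0.8.
Under those (standard) conditions a single simulated source produces a
local maximum within one grid step of the truth across seeds; dipole
fitting and the LCMV beamformer are held to the stricter global-peak
standard and meet it.

## Cluster-based permutation statistics

Per-sample statistics are the paired t (dependent designs) or Welch t
(independent designs).  The cluster-forming threshold is the two-sided
`cluster_alpha` quantile of the t reference distribution with n - 1
(dependent) or n1 + n2 - 2 (independent) degrees of freedom — a per-sample
Welch df would make the threshold sample-dependent, so the pooled df is
used for thresholding while the statistic itself remains Welch.
Suprathreshold samples are clustered by spatial adjacency (Euclidean
threshold on channel positions) crossed with temporal contiguity,
positive and negative clusters separately; the cluster statistic is the
mass (summed t), with the permutation distribution built from the maximum
absolute mass per relabeling (independent: full label reshuffles;
dependent: Bernoulli(0.5) within-pair swaps).  P-values use the
include-observed +1/+1 convention, so they are never zero and are bounded
below by `1/(n_permutations + 1)`; alpha is not split across tails.  The
permutation search runs in compiled code; an independent pure-R
connected-component implementation is cross-checked against it in the
tests, and with no spatial adjacency and a single time sample the
procedure provably reduces to max-statistic correction, which is also
asserted.  Calibration: across 200 null replications the family-wise
false-positive rate at alpha = 0.05 sits inside the binomial 99% interval,
for both designs.

## Synthetic data: what it does and does not emulate

The simulators generate: dipolar sources passed through the package's own
sphere forward models (with per-trial white sensor noise, optionally a
shared common-mode component), phase-jittered oscillations, stable MVAR
processes with known coupling (Gaussian innovations, burn-in discarded),
SQUID-jump steps, and blink-like transients (frontal Gaussian topography,
spatial scale 0.06 m, smooth temporal bump).  Every simulator is a pure
function of its arguments including a mandatory seed — identical seeds
give bit-identical data — and always returns the ground truth alongside.
Study conditions used by the validation suite, chosen once: 64 synthetic
magnetometers on an upper-hemisphere Fibonacci lattice (radius 0.12 m)
around a 0.1 m sphere; sources at 2–4 cm depth with 10 nA·m-scale moments;
Frobenius SNR 10 for localization; bivariate AR(2) with one-way coupling
0.5, 100 trials of 500 samples; 20 paired observations on an 8-channel x
25-sample map for the statistics; 10 trials x 1000 samples x 4 channels
for artifact detection.  The coherent source pair for DICS is *partially*
coherent (inter-trial phase jitter of 1 rad, coherence ~0.6): fully
coherent sources mutually cancel in any minimum-variance beamformer, so
partial coherence is both the realistic and the recoverable regime.

What passing these tests does not show: real recordings have correlated,
non-white, nonstationary noise (1/f background, line noise), imperfect
sphere geometry, sensor calibration errors, and artifacts that are neither
perfect steps nor fixed topographies.  The closed loop validates the
mathematics and the implementation, not robustness to model mismatch.

## Numerical choices

Positions are meters in a common head frame; the sphere center is
subtracted internally.  Grids are bounding box + spacing; positions
outside the innermost compartment are masked.  The exact sphere center has
a zero MEG lead field (a removable singularity of the closed form);
beamformer maps return NA there.  Matrix pseudoinverses use an SVD with
tolerance `max(dim) * max(singular value) * eps`.  Simplex convergence is
declared at an absolute residual-variance change below 1e-9 with two
deterministic restarts.  Dipole-fit positions are softly constrained
inside 99.5% of the innermost radius by a penalty.  Cross-spectra are
stored once per unordered channel pair (i < j) with the conjugate
returned on query.  The problem sizes above keep the full validation
suite within a few minutes on one CPU.
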