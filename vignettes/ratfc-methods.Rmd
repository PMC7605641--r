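---
title: "Preprocessing and functional connectivity analysis for awake-rat rsfMRI: methods and design notes"
author: "ratfc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ratfc methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`ratfc` implements a complete preprocessing and group-analysis chain for
resting-state BOLD fMRI acquired in awake, head-restrained rats: motion
scrubbing by framewise displacement (FD), rigid-body motion correction,
per-scan spatial ICA with a rat-adapted feature rule for labelling noise
components, Monte-Carlo CompCor nuisance selection, "soft" noise removal
that preserves variance shared with signal components, spatial smoothing
and temporal band-pass filtering, and the downstream group analyses (ROI
functional connectivity with mixed-model inference and max-statistic
permutation control, seed maps, structure–function comparison,
reproducibility, specificity categories, group ICA with Ward modules, and
SNR quality control). A synthetic phantom generator with complete ground
truth makes every stage testable without scanner data.

Inputs are NIfTI-1 volumes assumed to be in template space: manual
landmark co-registration and deformable normalization are acquisition-site
steps outside this package; a pluggable `align_hook` lets users insert an
external registration command, with identity as the default.

# The preprocessing model

A scan is a 4D array $Y$ (64×64×20 voxels at 0.5×0.5×1 mm, TR = 1 s in the
emulated acquisition; phantoms default to half that grid). The chain is:

1. **Scrubbing.** Each frame's rigid transform to the first frame gives
   six parameters $(x_i, y_i, z_i, \alpha_i, \beta_i, \gamma_i)$ and
   $FD_i = |\Delta x_i| + |\Delta y_i| + |\Delta z_i| +
   r(|\Delta\alpha_i| + |\Delta\beta_i| + |\Delta\gamma_i|)$ with
   $r = 5$ mm, the approximate cortex-to-head-centre distance in the rat.
   Frames with $FD > 0.2$ mm are discarded together with both temporal
   neighbours (spin-history effects contaminate both sides), along with
   the first 10 frames; a scan retaining less than 90% of its frames is
   excluded.
2. **Motion correction.** Every retained frame is resampled into the
   first frame's space through its rigid transform, estimated inside a
   dilated brain mask; the six parameter series become nuisance
   regressors.
3. **ICA labelling.** The scan is smoothed at FWHM 0.7 mm and decomposed
   into spatial ICs (50 for full-length real scans; configurable for
   phantoms). Each IC's map (z-scored, thresholded at $|z| > 2$), time
   course, and spectrum yield features, and the rat-adapted rule marks an
   IC as noise if it fires at least one "confident" feature or at least
   two of three "applicable" families (WM/CSF/boundary-dominated map;
   sudden time-course jumps; flat, very-low- or high-frequency-dominated
   spectrum).
4. **CompCor.** Principal components of the variance-normalized WM+CSF
   voxel time courses are selected against a Monte-Carlo null: 1000 iid
   normal datasets of the same size, $p$ = fraction of null datasets whose
   first-PC variance-explained exceeds the candidate's; components with
   $p < 0.05$ are kept.
5. **Soft cleaning.** On the *unsmoothed* data, motion and CompCor
   regressors are regressed out of both the IC time courses and every
   voxel ($ICA_m$, $Y_m$); the joint weights
   $\beta = \mathrm{pinv}(ICA_m)\,Y_m$ are computed over *all* components,
   and only the noise components' fitted part
   $ICA_m(\text{noise})\,\beta(\text{noise})$ is subtracted. Variance a
   noise IC shares with signal ICs is thereby retained; when noise and
   signal time courses are orthogonal this reduces exactly to hard
   regression of the noise ICs (a tested identity).
6. **Smoothing and filtering.** FWHM 1 mm Gaussian smoothing, then a
   4th-order Butterworth band-pass (0.01–0.1 Hz) applied forward-backward.

## Numerical choices

* **Registration** replaces the proprietary routines used in the original
  processing with a multi-resolution (power-of-two block means) BFGS
  minimization of the masked mean-squared intensity difference over the
  six rigid parameters, centre-of-mass initialization, rotations about
  the fixed image's intensity centroid, and a smooth penalty confining the
  search to ±10 mm / ±0.5 rad around the initialization (restrained heads
  move little; the penalty also excludes symmetry aliases of
  near-ellipsoidal objects). Two details matter numerically:
  the metric samples both images with cubic (Catmull–Rom) interpolation on
  a half-voxel-offset grid, because comparing an interpolated moving image
  against a never-interpolated fixed image makes grid-aligned transforms
  spuriously optimal (interpolation smooths; the bias is large enough to
  swallow rotations of ~0.01 rad); and parameter estimation runs on copies
  pre-smoothed at FWHM 2 mm (estimation only — the transforms are applied
  to the raw frames with trilinear interpolation, the package-wide
  resampling convention). Frames are warm-started from the previous
  frame's estimate. Expected accuracy on desk-scale phantoms is
  ~0.005–0.02 mm and ~0.001–0.003 rad per frame; through-plane rotations
  are least identifiable on 1 mm slices.
* **FD convention.** Transforms are estimated frame-to-first and FD takes
  consecutive differences of those parameters ("relative" displacement);
  the first frame's FD is 0. FD stored in sidecars is the pre-correction
  series, and scrubbing precedes motion correction, whose parameters are
  reused from the scrubbing-stage estimates on retained frames.
* **ICA** is symmetric fixed-point iteration with the logcosh contrast
  after PCA whitening, deterministic under a recorded seed, with maps
  sign-fixed to positive skewness. When `k` exceeds the number of
  genuinely non-Gaussian sources, the surplus components have no defined
  rotation and oscillate; the implementation runs up to three
  deterministic re-initializations, keeps the tightest fixed point, and
  accepts a residual oscillation below 0.05 (direction cosine), erroring
  beyond that. This affects only the noise-floor components, never the
  planted/structured ones.
* **Classification thresholds.** The published procedure was manual; the
  automated defaults are: spatial family fires when
  `wm_csf_overlap + edge_fraction > 0.5` and `gm_overlap < 0.5`; jumps
  fire when the maximal absolute first difference of the standardized
  time course exceeds 6; the spectral family fires when the 0.01–0.1 Hz
  periodogram fraction is below 0.5, the >0.2 Hz fraction above 0.5, or
  spectral flatness (geometric/arithmetic mean power) above 0.8. White
  noise has flatness ≈ 0.56, so flat spectra are caught by the low
  passband fraction rather than the flatness cut. All thresholds are
  arguments; fired features are recorded per IC for audit. Confident
  detectors (susceptibility masks, slice-banding via dominant high slice
  frequency of the signed supra-threshold profile) are off by default on
  phantoms.
* **Butterworth order.** "4th order" is read as the total band-pass order:
  an order-2 analog prototype, lowpass-to-bandpass transformed (doubling
  the pole count), bilinearly mapped with edge prewarping. Zero-phase
  forward-backward application preserves FC timing, so the effective
  amplitude response is the squared one-pass response; a single-pass
  option exists. Odd-symmetric padding plus steady-state initial
  conditions suppress end transients; per-voxel means are removed before
  and restored after filtering.
* **Filtering after scrubbing** treats retained frames as contiguous — an
  approximation shared with the original processing chain, documented
  here rather than hidden.

# Group analyses

Scans are truncated to 540-frame segments (two disjoint segments for
1200-frame scans) so every segment carries equal degrees of freedom.
ROI time courses are voxel means over an integer atlas; per-scan FC is the
Fisher z (atanh) of Pearson correlation with $r$ clipped at
$1 - 10^{-7}$. The group statistic per connection is the intercept t of a
random-intercept-per-subject linear mixed model (lme4); with one scan per
subject this reduces *exactly* to the classical one-sample t across
subjects, which is also the deterministic fallback (one-sample t on
subject means) used inside permutations, where refitting a mixed model
thousands of times is neither feasible nor, for balanced designs,
different. Zero-variance entries are capped at ±10^6 and flagged.

Familywise error is controlled by a max-statistic permutation test: ROI
labels are shuffled independently within each scan, the group t matrix is
recomputed, and its maximum forms the null; an entry is significant when
its permutation p-value $(1 + \#\{t^{max}_{perm} \ge t\})/(1 + n_{perm})$
is at most $\alpha$ (equivalently, when $t$ exceeds the corresponding
upper percentile of the null).

Seed maps correlate every brain voxel with the mean time course of a
3×3×2-voxel seed cube and feed the same group machinery. FC–distance uses
Pearson correlation of the off-diagonal upper triangle against Euclidean
centroid distances. The FC–SC Jaccard index uses a density-matched
Erdős–Rényi permutation null by default (the original report does not
specify its null); degree-preserving rewiring is available. Split-half and
leave-one-out reproducibility correlate off-diagonal entries of subgroup
mean-z matrices after regressing ROI distance out of both vectors.
Specificity of seed FC uses a Fisher-z threshold of 0.1 (the convention of
the methodology this categorization follows; configurable): specific /
unspecific / none / spurious by whether the specific and non-specific
reference connections clear it.

Group ICA reduces each scan temporally (PCA to ~1.5k dimensions),
concatenates, reduces to k = 30 (8 on phantoms) and unmixes with the same
fixed-point core; per-scan time courses come from spatial regression of
the group maps — the back-reconstruction variant used by the original
toolbox is unstated, and spatial regression is the documented choice here.
Between-component group t matrices are Ward-clustered
(`stats::hclust(method = "ward.D2")`) on the distance
$\max(t) - t$; the module count is an explicit argument, never hard-coded,
because the original cut was "an empirical threshold".

sSNR divides the 10th frame (1-based) by the standard deviation of two
5×5 out-of-brain corner squares per slice; tSNR divides each voxel's
temporal mean by its temporal standard deviation, with constant voxels
flagged infinite and excluded from within-brain means.

# The phantom: what it emulates, and what it does not

`phantom_spec()`/`make_phantom()` build an asymmetric ellipsoidal "brain"
with WM core, CSF ventricle, fixed texture bumps (asymmetry makes all six
rigid parameters identifiable — a perfectly symmetric phantom has
unidentifiable in-plane rotation), and three tissue compartments.
Defaults state the synthetic world once:

* grid 32×32×10 at 0.5×0.5×1 mm, TR 1 s, 300 frames — the acquisition
  geometry at half resolution (the full 64×64×20 grid is one argument
  away);
* 4 networks × 2 spherical GM blobs (radius 1.1 mm) with band-limited
  (0.01–0.1 Hz) unit-variance Gaussian time courses, amplitude 3 on a GM
  baseline of 100 (≈3% BOLD-scale fluctuations), organized into 2 modules
  with coupling weight 0.8;
* three artefacts at amplitude 5, each designed to fire two applicable
  feature families: a brain-boundary ring with a spiking time course
  (spike rate ≈ 1 per 60 frames, matching few-percent scrub fractions),
  a WM blob with 0.3 Hz content, a ventricle source with white-noise
  dynamics;
* iid parameter motion jitter of 0.01 mm / 0.001 rad (mean FD ≈ 0.05 mm,
  the awake-restrained operating point), with optional sustained
  displacement steps at chosen frames; frames are displaced with cubic
  interpolation so generator resampling artifacts stay below the planted
  motion signal;
* thermal noise sigma 2 (tSNR ≈ 50 in GM).

Subject groups share the network layout; each subject draws log-normal
amplitude effects (sd 0.2) so the mixed model has real between-subject
variance. All randomness derives from one spec seed through fixed
substreams; identical spec + seed is bit-reproducible.

What the phantom does **not** emulate: MR physics (susceptibility,
ghosting, slice-timing), physiological waveforms (absent from the
emulated acquisitions too), realistic anatomy, or spatially correlated
noise. A green phantom test therefore establishes algorithmic
correctness — formula fidelity, recovery of planted structure, calibrated
error rates — not performance on real rat data.

Tests that probe *separability* (ICA recovery, per-scan classification)
set module coupling to 0, because temporally coupled networks are not
separable by temporal structure and only partially by spatial
independence; the end-to-end group test keeps coupling 0.8 since its
question is modular FC recovery, not component separation. Registration
oracle tests evaluate the moved image analytically (smooth Gaussian-blob
fields) so that parameter recovery is not confounded by resampling
artifacts of the fixture itself.

# Scaled test and acceptance budgets

The full suite runs on one CPU in well under half an hour. To stay there,
the end-to-end 20-subject run uses a 24×24×8 grid with 200 frames, 12 ICs
per scan, a 200-sample CompCor null and 500 permutations — scaled-down
Monte-Carlo depths, with every threshold at its published default. The
CompCor null distribution depends only on the data dimensions, so it is
computed once and shared across scans. Scans that fail the 90% retention
rule on a desk-scale phantom are excluded exactly as real scans would be;
the group analyses run on the survivors.

# Known limitations

* Through-plane (x/y-axis) rotations on 1 mm slices are estimated at
  roughly 2–3× the error of in-plane parameters; FD inherits this.
* The automated IC classifier approximates a manual procedure; on real
  data its thresholds should be audited against the per-IC fired-feature
  records it emits, and the published per-scan noise-IC counts
  (≈25 ± 9 of 50) cannot be validated on phantoms.
* The mixed model inside permutations uses the subject-mean reduction;
  for strongly unbalanced designs the permutation null is therefore an
  approximation.
* Scrubbed series are filtered as if contiguous; with the few-percent
  scrub fractions of the restrained-awake paradigm the spectral leakage
  is negligible, but heavily scrubbed scans should be excluded (and are,
  by the 90% rule).
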