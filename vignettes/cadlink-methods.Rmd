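---
title: "Linking CAD peaks to LC-MS features: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking CAD peaks to LC-MS features: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cadlink)
```

## The problem and the model

A charged aerosol detector (CAD) responds to the mass of non-volatile
analyte reaching its nebulizer almost independently of chemical structure,
which makes its peak areas a usable semiquantitative measure for complex
natural extracts. It is, however, blind: a CAD peak says *something
abundant elutes here*, not *what*. Untargeted LC-MS/MS says *what might
elute here* thousands of times over, but its intensities reflect
ionization efficiency more than amount. `cadlink` treats the two signals
as complementary witnesses of the same elution process and asks, feature
by feature: does this XIC have the same chromatographic shape as the CAD
peak that envelops it? Features that do are candidates for the **major
metabolome**; everything else — poorly correlated features, features
outside any CAD envelope, features whose annotations are taxonomically or
spectrally implausible — is kept as the **minor metabolome**. Nothing is
deleted: demotion is a label, not a filter on the data.

The underlying assumption is chromatographic: if one compound dominates a
CAD peak, any MS feature of that compound (adduct, fragment, isotopologue)
shares its elution profile up to an intensity scale. Shape correlation is
therefore computed after intensity normalization, so a trace-level feature
with a perfect shape match scores the same as an intense one. The
assumption degrades when several compounds co-elute within one CAD
envelope; the downstream taxonomic and confidence filters exist precisely
to arbitrate those cases, and the residual ambiguity is reported (number
of candidate structures per peak), never hidden.

## Pretreatment

*Lag alignment.* With a post-column split, the MS signal arrives 0.090 min
after the PDA and 0.055 min after the CAD in the reference geometry these
defaults describe; PDA and CAD traces are delayed by those constants onto
the MS axis. Constant lags suffice because all detectors see the same
mobile phase; no time warping is attempted.

*Fourier denoising.* The CAD is acquired densely (tens of Hz) and set
sensitive, so the raw trace is noisy. Denoising retains the lowest
`ceiling(f·N)` discrete Fourier components (default `f = 0.01`) and zeroes
the rest — a one-parameter brick-wall low-pass. The hard cutoff has a known
cost: Gibbs ringing around tall, narrow peaks, at roughly the percent
level of the apex. We accept it for faithfulness to the single-parameter
component-retention approach and handle the consequences at detection
(below) rather than switching to a smooth window.

*Derivative sharpening.* Resolution enhancement subtracts a scaled second
derivative: `y − k₂·y″ + k₄·y⁗`. For a Gaussian of width σ this narrows
the full width at half maximum while conserving total area (the integral
of `y″` vanishes for a decaying signal); the price is negative undershoots
flanking each peak, which are deliberately not clipped. The coefficients
of the published sharpening implementations are width-scaled but not
printed, so the default here is `k₂ = (w/4)²` with a nominal peak width
`w = 0.1` min and `k₄ = 0`: the classic choice that gives visible
narrowing without ringing for peaks near the nominal width. Peaks much
narrower than `w` are over-sharpened — their apex is amplified and the
area integrated between the undershoot minima overshoots the true area by
up to ~15 % in our simulations. This is documented as a property of the
semiquantitative output, not corrected, because correcting it would
require knowing the per-peak width the sharpening is supposed to recover.
Derivatives are central finite differences on the uniform grid (one-sided
at the edges); Savitzky–Golay filtering was considered and rejected as a
second smoothing parameter the model does not need.

*Resampling.* Linear interpolation onto a uniform grid, default 2 Hz —
the MS1 scan rate, so CAD (~30× denser) and XIC grids become comparable.
Queries outside a trace's span take the nearest edge value; this matters
when a feature's XIC window is shorter than the CAD peak's bound interval.

*Order.* Align → denoise → sharpen on the native grid → resample. The
alternative (resample first) discards CAD resolution before the
derivative steps that benefit from it.

## CAD peak detection and integration

Detection runs on the pretreated trace: apexes are local maxima (leftmost
sample of a plateau wins, a deterministic tie-break), bounds extend to the
nearest local minimum on each side, and a peak is kept when its height
above the per-peak linear baseline reaches `min_snr` (default 5) times the
noise level and its width reaches `min_width` (default 0.05 min). The
noise level is the robust estimator `1.4826·MAD(diff(y))/√2`; in the
assembled pipeline it is estimated on the *raw* trace, because after
denoising the residual noise is tiny and an SNR gate against it would pass
every ripple of the filter. Filter ringing can still produce narrow
low-area satellite peaks next to tall apexes; they envelop no MS features,
so they vanish from the report and all per-peak statistics (which average
over peaks with at least one linked feature only). Integration is
trapezoidal between the bounds minus the linear baseline through the two
boundary intensities, clamped at zero; the per-peak baseline absorbs the
slow drift the low-pass filter leaves.

For shape comparison, in contrast, the pipeline uses the denoised but
*unsharpened* CAD trace: feature XICs are not derivative-enhanced, so
correlating them against a sharpened CAD shape would systematically
penalize exactly the features that match. Sharpening is a detection aid;
the similarity model compares undistorted shapes.

## Linking and classification

A feature belongs to the unique CAD peak whose bound interval contains its
apex retention time (apexes on a shared boundary go to the earlier peak).
Over that interval both traces are cropped, time-mapped to [0, 1],
min–max scaled (a constant segment becomes all zeros and can never score),
resampled to the common rate, and compared by Pearson correlation with
closest-point pairing. The similarity threshold is 0.8; candidates at or
above it are shape-majors. Min–max scaling provably does not change the
Pearson value — the property is tested — but it keeps the normalized
segments interpretable and makes the zero-information (constant) case
explicit.

## The filter cascade

Shape filtering alone leaves several candidate structures per peak. Two
further filters act in order, per CAD peak, on the best-ranked candidate
of each shape-major feature:

1. **Taxonomic prioritization.** If any candidate carries the
   species-level taxonomic distance score (0.9), exactly those candidates
   are retained — with ties all kept, since there is no principled way to
   choose among structures all previously reported in the studied
   species. Otherwise the same rule applies at genus level (0.8).
   Otherwise all pass through: below genus the score differences no longer
   encode a meaningful prior, and the confidence filter still acts. Score
   matching uses an absolute tolerance (1e-9), never float equality.
2. **Confidence.** Retained candidates need a final composite score
   strictly above 0.4. Scores above 1 are possible when every evidence
   component saturates; they are retained but flagged (`over_unity_score`)
   as worth manual inspection.

The cascade is idempotent, never loses features, and its per-stage linked
counts are non-increasing by construction; all three properties are
enforced by tests against a straight-line brute-force reimplementation.

## Reporting conventions

Per-stage means (features, distinct structures, distinct molecular
formulas, distinct chemical classes per peak) divide by the number of
peaks that still have at least one surviving linked feature, and are
rounded half-up to one decimal, matching the precision of printed run
tables. Distinctness keys are the stereochemistry-free structure id, the
formula string and the chemical-class string. Report area fractions are
relative to the total area of all integrated peaks, so a partially
annotated run sums below 1 and the unannotated remainder is visible.
Peaks whose candidates were all demoted stay in the report with an empty
candidate list — they are the natural targets for manual structure
elucidation. Alluvial bins on candidate-structure counts are 0 / 1 / 2 /
3–5 / >5. Treemap fractions weight majors by CAD area (the
semiquantitative view) and minors by annotation count (MS intensity is
deliberately ignored there).

## The synthetic-data generator

`fixture_spec()`/`simulate_extract()` emulate the statistical structure
the pipeline assumes: Gaussian (default) or exponentially modified
Gaussian peaks; CAD at 60 Hz versus MS at 2 Hz (the ~30× rate mismatch the
resampling step exists for); CAD/PDA traces generated on their own lagged
time axes; a slow sinusoidal baseline wave plus white detector noise;
major XICs that are intensity-scaled copies of the parent shape with 2 %
multiplicative-scale noise; decoy XICs shifted by at least two FWHM or
drawn with unrelated widths; and annotation tables with species/genus
scores on planted majors and weak scores on decoys. Defaults — 20 peaks
over 20 min, σ 0.03–0.08 min, apex heights 50–500 CAD units against 0.5
units of noise, 2 majors + 3 decoys per peak — were chosen once as a
realistic routine profiling run and are the conditions under which the
validation suite operates.

What the generator does *not* emulate, and what passing tests therefore do
not demonstrate: tailing/fronting beyond the EMG option, co-eluting
compounds sharing one CAD envelope with distinct shapes, gradient-induced
CAD response drift, adduct/fragment intensity correlations, missing XIC
scans, or annotation engines' correlated errors. Results on real data
depend on chromatographic peak capacity in a way no simulation default can
certify.

Test and validation problem sizes (20 peaks × 5 features for linking
recovery, 100 random table fixtures for the cascade oracle, 4–8 peaks for
end-to-end runs) were chosen as the smallest sizes at which the measured
properties are stable.

## Numerical choices and degenerate inputs

* Uniformity is asserted with a relative tolerance of 1e-6 on the grid
  step; denoising and sharpening refuse nonuniform input rather than
  silently resampling.
* `fourier_denoise` at fraction 1, or whenever the cutoff reaches the
  Nyquist index, is an exact identity.
* Zero-variance vectors in the similarity step return 0, never `NA`.
* Fewer than 3 pairable points is an error, not a degenerate correlation.
* Negative baseline-subtracted areas (possible on pathological baselines)
  clamp to 0 with a warning.
* All tie-breaks (plateau apexes, shared peak boundaries, closest-point
  ties) resolve to the earlier time point, making every output
  deterministic; the end-to-end byte-identity of two runs on the same
  input is part of the test suite.

## Known limitations

Quantitation is semiquantitative by design: no inverse-gradient
compensation of eluent-dependent CAD response, no power-function response
linearization, and the sharpening area bias for peaks far from the
nominal width (above). Ionization modes are processed independently
against their own CAD trace; merging per-mode peak lists into one report
is left to the caller because merge semantics (shared versus mode-specific
peaks) are study-dependent. The mzML writer is minimal fixture support —
chromatogram lists with 64-bit uncompressed arrays — not a general
converter.
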