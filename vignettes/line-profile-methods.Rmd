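---
title: "Quantifying expression-domain transitions with averaged line profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying expression-domain transitions with averaged line profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hcrprofile)
```

## The measurement problem

Multiplexed in-situ methods (HCR) produce quantitative, channel-separated
transcript signal in whole embryos. A recurring question in neural crest
development is geometric: does a query gene's expression domain overlap a
reference domain along the medial–lateral axis, or does it flank it?
Answering this from images requires reducing each embryo to a comparable
1-D measurement, registering embryos to a common coordinate, and
averaging — each step with choices that affect the result. This vignette
records those choices and why `hcrprofile` makes them.

## From stack to profile

Each embryo is a multi-channel, multi-z stack. We first take the
**maximum intensity projection** over z per channel; for stripe-shaped
domains imaged at low magnification, the maximum is robust to the small
number of informative slices and matches common practice for HCR
quantification. The projection assumes the signal of interest is the
brightest structure along z at each (row, column); densely stacked
off-target signal would violate this, and nothing in the pipeline
corrects for it.

A **line profile** samples the projection along a user-supplied segment
at unit (1 px) spacing using bilinear interpolation, optionally averaging
`linewidth` parallel samples taken perpendicular to the line
(default 1, i.e. a single-pixel line — the most literal reading of a
hand-drawn measurement line; widen it to suppress speckle). Bilinear
interpolation is exact on locally linear intensity fields and is the
standard choice for profile samplers. Profiles are always stored medial
to lateral, using the `medial_end` flag of the line specification, so
plots have a fixed orientation regardless of how endpoints were supplied.
Samples whose perpendicular offsets fall outside the image are clamped to
the border; with the default single-pixel line this never occurs for
in-bounds endpoints.

**Normalization** is per channel *and per profile*: subtract the
profile's channel minimum, divide by its range. The scope (per profile
rather than per image) matters: per-profile scaling makes replicate
curves comparable when staining efficiency varies between embryos, at
the cost of equating each profile's dynamic range. The (min, max) pair
actually used is stored in `norm_params`, so the alternative scaling
can be reconstructed. A constant channel has no defensible normalization
(0/0), so it is a hard error naming the channel — in practice it signals
a line placed outside the signal.

## Peak-centered alignment

Embryos differ in where the reference stripe falls along the measured
line, so replicate profiles are registered by a rigid 1-D shift. Per
image, the reference-channel values of that image's profiles are averaged
position-wise and fit with a **Gaussian-form peak plus baseline**

$$v(x) = b + A \exp\!\left(-\frac{(x-c)^2}{2\sigma^2}\right),$$

and the fitted centre $c$ is subtracted from every profile of that image.
A Gaussian-form peak (the exponential of a negative quadratic) is the
simplest smooth unimodal model with an explicit centre; a monotone
exponential has no peak to centre on, so it is not a candidate. The
functional form is an explicit argument (`peak_model = "gaussian"`) to
keep the choice visible.

Fitting is bounded Levenberg–Marquardt least squares
(`minpack.lm::nlsLM`) with deterministic initialization: baseline =
minimum, amplitude = range, centre = first argmax (so ties break toward
the smaller position), width = ¼ of the sampled range. The centre is
constrained inside the sampled range. On very wide grids with narrow
peaks the ¼-range width start can leave the optimizer with a numerically
singular Jacobian, so on failure the fit retries a fixed ladder of
smaller width starts (⅛, 1/16, 1/32 of the range, then 2 px) before
falling back to the argmax with `converged = FALSE`. All starts are
data-derived, so the procedure stays deterministic.

By default the fitted centre is **rounded to the nearest pixel** before
shifting. This keeps every profile on the integer pixel lattice, so the
common grid — the set intersection of all shifted position sets — is
non-degenerate, and reruns are byte-identical. The sub-pixel residue
(≤ 0.5 px per image) is the price; a `subpixel = TRUE` mode subtracts the
exact centre and re-interpolates onto the integer lattice instead, at the
cost of one extra interpolation of the data. Averaging then computes, per
channel and grid point, the mean and s.e.m. (sample sd / √n) over
profiles; every profile covers the common grid by construction, so n is
constant along the grid.

Alignment fits **one peak per image**, not per line: multiple lines drawn
on one embryo share that embryo's anatomy, so they should share one
shift; fitting each line separately would let noise shear apart
measurements of the same embryo.

## Domain metrics

On the averaged, centered profile, the **reference domain** is the
maximal contiguous interval containing 0 where the baseline-subtracted
reference mean is at least half its maximum (FWHM), with endpoints
interpolated linearly between grid points. FWHM is scale-free: it needs
no absolute intensity calibration and, for a Gaussian stripe of width σ,
equals $2\sqrt{2\ln 2}\,\sigma$, which ties the measured interval to the
generative parameters of the synthetic scenes.

The **overlap coefficient** is the share of baseline-subtracted query
signal mass (floored at zero) falling inside the reference FWHM. Being a
mass *ratio*, it is invariant to rescaling the query amplitude — an
important property given per-profile normalization. The baseline is the
minimum of the mean profile on the grid, consistent with the min-based
normalization upstream.

**Query modes** are local maxima of the query mean with prominence at
least `min_prominence` (default 0.1 normalized units), where prominence
is measured against the lower of the two flanking minima (each minimum
taken between the peak and the nearest higher point or grid edge). This
definition is deliberately permissive — on noisy averages a single band
can contribute adjacent near-equal maxima — because the classification
below only asks *on which side of the reference domain* modes lie, not
how many there are. Flat-plus-noise profiles stay well below the 0.1
prominence threshold.

The categorical **call** is:

* `overlapping` — overlap coefficient ≥ `t_hi` (default 0.5);
* `flanking` — overlap coefficient ≤ `t_lo` (default 0.2) *and* query
  modes lie on both sides of 0 outside the reference FWHM;
* `partial` — otherwise.

No numeric overlap criterion exists in the qualitative literature this
operationalizes; the thresholds are explicit configuration, are recorded
in every output (`thresholds_used`), and the defaults are chosen so the
two shipped presets classify with wide margin (the presets score ≈ 0.63
and ≈ 0.01). A useful anchor: a query *identical* to the reference scores
$2\Phi(\sqrt{2\ln 2}) - 1 \approx 0.761$ — the mass of a Gaussian inside
its own FWHM — so `t_hi = 0.5` asks for well over half of a
self-overlap, and `t_lo = 0.2` is far below it.

## The synthetic scene generator

Real stacks of this kind are not distributable at desk scale, so the
generator is a first-class module with analytic ground truth. A channel
is a mixture of Gaussian bands along the medial–lateral axis, constant
perpendicular to it:

$$I(d) = \text{background} + \sum_k A_k
  \exp\!\left(-\frac{(d-c_k)^2}{2w_k^2}\right),$$

with $d$ the signed distance along the axis (axis angle configurable;
0° runs along image columns). Per replicate, one normal shift
(`replicate_jitter_sd`, default 3 px) moves *all* band centres of *all*
channels rigidly — embryo-to-embryo placement variation that preserves
within-embryo geometry. Per z-slice, independent additive Gaussian noise
(`noise_sd`, default 0.02 on the unit intensity scale) is truncated at
zero. Identical seeds give bit-identical scenes.

Two presets pin the study conditions: `stage13` (reference stripe σ = 12
px with a unimodal query centred 1 px away, σ = 14) and `stage17`
(reference σ = 10 with query bands 38 px either side — well outside the
reference FWHM half-width of ≈ 11.8 px). Both use 5 replicates, 3
z-slices, 128 × 256 px, amplitudes 0.65–0.85 over a 0.05 background.
Intensities are stored as 32-bit float TIFFs on the unit scale; the
writer clips to [0, 1] (the detector-saturation analogue), while
in-memory arrays keep exact model values.

What the generator does **not** emulate: optics (PSF convolution), photon
shot noise, bleaching, curved or tapering stripes, segmentation error in
line placement, and intensity-dependent noise. Tests passing on these
scenes therefore validate the *measurement pipeline* — projection,
sampling, normalization, registration, averaging, and the metrics — not
robustness to every property of real confocal data.

## Numerical and testing choices

* Coordinates are 0-based (row, column); axis distances in pixels. An
  optional `pixel_size` (µm) is carried as metadata; all computations are
  in pixels.
* Peak-fit recovery is exercised on 0–99 px grids (noiseless recovery to
  1e-6; 200 noisy replicates at noise sd 0.05 recover the mean centre
  well within 0.5 px). Alignment and metrics checks run on 64 × 256 px,
  2-slice scenes with 5 replicates — small enough for seconds-scale test
  runs while keeping ≥ 5σ of stripe structure inside the image.
* The band-separation sweep that probes the overlapping → flanking
  transition uses separations 0–36 px in 4 px steps. Beyond ≈ 36 px
  (3σ outside the reference FWHM) the true in-domain query mass changes
  by < 0.001 between steps, below the noise floor of a 5-replicate
  average (≈ 0.002), so monotonicity of the measured coefficient is only
  meaningful inside that range; the chosen range spans coefficients from
  ≈ 0.73 down to ≈ 0.01.
* The two-group fold-change test defaults to **Student's** pooled
  t-test rather than Welch's. At the n = 3 biological replication
  typical of these qPCR assays, Welch's approximation is measurably
  conservative (simulated type-I error ≈ 0.035 at nominal 0.05 under
  equal variances), while Student's holds its nominal size
  (≈ 0.050); "unpaired, two-tailed t-test" in this literature
  conventionally means the pooled form. Welch remains one argument away
  (`var_equal = FALSE`), and the output's `method` column records which
  form produced each p-value. Groups with zero variance in both arms
  yield p = 1 (equal means) or p = 0 (unequal) with a `zero_variance`
  flag and warning, rather than NaN.
* Wilson score intervals (not Wald) for scored proportions: the scored
  percentages in these assays routinely approach 0% or 100%, where the
  Wald interval degenerates and Wilson does not.
* ΔΔCt uses group means of per-replicate ΔCt (the standard Livak
  formulation); adding a constant to all Ct values of a replicate cancels
  in the reference subtraction, which the tests verify.

## Known limitations

* Registration is a rigid 1-D translation; embryos that differ in stripe
  *width* (growth, stage spread) are averaged without rescaling, which
  broadens the mean profile.
* The FWHM definition presumes a unimodal reference peak near 0 (the
  alignment contract); a bimodal reference will produce an interval for
  whichever lobe contains 0 and should be treated as a misconfiguration.
* The overlap coefficient is defined on the mean profile, not per
  replicate, so it carries no dispersion estimate; per-replicate
  classification can be built from the per-profile outputs in
  `profiles.csv` if spread matters.
* Per-profile normalization discards absolute intensity differences
  between embryos and channels; the pipeline makes geometric claims, not
  expression-level claims.
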