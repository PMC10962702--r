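---
title: "Methods: allele-level DNA/RNA FISH image analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: allele-level DNA/RNA FISH image analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

Combined DNA and nascent-RNA FISH resolves, for every allele of a locus in
every imaged nucleus, two quantities at once: where the allele sits in the
nucleus and whether it is transcribing at that moment. `hifishr` implements
the image-analysis half of such an assay for multi-well plates of
maximum-projected confocal fields with three channels: DAPI (nuclei), a DNA
FISH probe (the locus) and an intronic RNA FISH probe (nascent transcripts).
Two acquisition protocols are supported. In the *simultaneous* protocol all
three channels come from one imaging round. In the *sequential* protocol RNA
is imaged first, DNA second, and the two rounds must be registered before
joint analysis; the DAPI channel, present in both rounds, provides the
registration reference.

## Registration

The plate is removed and re-mounted between sequential rounds, so the two
acquisitions of a field differ by a small, essentially pure translation. The
estimator searches integer displacements `(dx, dy)` within a window
(default 10% of the smaller image dimension; plate re-mounting errors are
small, and a bounded window avoids spurious distant peaks) and scores each
displacement by the *zero-mean* cross-correlation: both images are
mean-subtracted over the current overlap before the product sum. A raw
(unnormalized) cross-correlation of non-negative images is biased toward
bright regions and, at full overlap, trivially maximal near zero lag;
mean subtraction keeps the familiar "peak of the cross-correlation"
semantics while making the peak reflect pattern alignment rather than
brightness. The raw sliding-sum surface remains available through
`cross_correlate()` and is tested against a literal direct-sum oracle.

Ties at the peak are broken toward the smallest `|dx| + |dy|` (minimal
motion) and then row-major order, deterministically. Registration is
integer-pixel only: at 0.108 um per pixel the residual quantization is an
order of magnitude below the 1 um activity radius, and spot distances
tolerate it. The estimate is made per field, not per well, since stage
repositioning error is per-field. Applying a translation zero-fills pixels
that map outside the source frame, and all channels of the RNA acquisition
are shifted by the negated estimate so that content returns to the DNA
frame.

## Segmentation and nucleus QC

The built-in segmenter is intentionally classical: Gaussian smoothing
(sigma 3 px), Otsu thresholding, hole filling, connected-component labeling
and removal of objects under 50 px. It is adequate for the synthetic data
the package validates against; for real plates a learned segmenter's label
masks can be supplied as 16-bit TIFFs via `read_label_mask()` behind the
same contract. Touching nuclei are not split (the simulator guarantees
separation); this is a known limitation for dense real plates.

Per nucleus the package records area, equivalent circular diameter
`2 * sqrt(area / pi)`, perimeter and circularity
`4 * pi * area / perimeter^2`. The perimeter is measured by marching-squares
contouring of the lightly smoothed (sigma 1 px) binary mask at level 0.5
and summing the resulting polygon length. This estimator was chosen after
numerically comparing boundary-pixel counting, chain-code summation,
corner-corrected chain codes and Crofton-style intercept counts: only the
sub-pixel contour satisfies both calibration anchors at once — an
axis-aligned square measures circularity within 0.02 of the analytic
`pi / 4`, and rasterized disks measure 0.99-1.00 across radii 10-80 px.
Circularity of small rasterized disks may slightly exceed 1; values are not
clamped.

QC applies two gates, both read as marks of segmentation errors: equivalent
diameter below 10 um, or circularity below 0.95. "Smaller than 10 microns"
is interpreted as a diameter (a length unit; an area would carry um^2), and
a nucleus is filtered when *either* gate fails — filtering only when both
fail would keep tiny round debris. Border-touching nuclei are flagged but
kept by default; a `drop_border` switch removes them.

## Spot detection

FISH signals are diffraction-limited and near-constant in size, so
detection is single-scale: the scale-normalized Laplacian of Gaussian
`-sigma^2 * laplacian(G_sigma * img)` (default sigma 2 px, ~0.22 um) is
computed as one convolution with the equivalent kernel, and local maxima
above a threshold are kept. The threshold is an absolute response value by
default (100 at the default intensity scale) with an optional per-image
adaptive mode (`mean + 5 * sd` of the response), mirroring per-plate
parameter tuning practice. Maxima closer than `2 * sigma` merge into the
stronger one so a single transcription site is never double-counted;
plateau ties resolve row-major. Coordinates are integer pixels — no
sub-pixel refinement — converted to microns for all distance computations.
Spots not overlapping any nucleus are discarded, and spots in QC-failed
nuclei are discarded with their nuclei.

## Radial position

Radial position within the nucleus is defined from the Euclidean distance
transform of the binary nucleus mask: each nucleus pixel carries its
distance to the nearest background pixel; the transform is normalized per
nucleus by its maximum and subtracted from 1. The deepest point of a
nucleus therefore reads 0 and the rim reads 1. Note that the "center" in
this definition is the deepest point of the distance transform, not the
centroid; for non-convex nuclei these differ, and the distance-transform
definition is the one implemented. Pixels 8-adjacent to background are
clamped to exactly 1 (they are precisely the pixels with transform values
at most sqrt(2), so the clamp is a set identity, not a heuristic
threshold). Degenerate nuclei with maximum depth <= 1 px are assigned 0
everywhere; such nuclei never pass QC. Radial values are binned into five
shells of width 0.2, half-open with the last shell closed at 1.0, so the
shells partition [0, 1] exactly. Distribution comparisons always use the
un-binned values; shells are for reporting.

On a rasterized disk of radius R the normalized radial value at distance d
from the center equals `d / R` within discretization error, and spots
placed uniformly in a disk have mean radial value 2/3 (the analytic
`E[d/R]` for a uniform point in a disk) — both serve as oracles in the
test suite.

## Allele accounting and classification

Cells are diploid for the loci considered: the analysis unit is one DNA
spot (one allele), and each analyzable cell carries exactly two. Per-cell
spot counts per channel are binned into "0", "1", "2", ">=3"; only cells
with exactly 2 DNA spots and at most 2 RNA spots are analyzable (cells with
more RNA spots are excluded entirely, not truncated). For each DNA spot the
minimum 2D Euclidean distance to any RNA spot of the same cell is computed
in microns; cells without RNA yield NA. Classification: NA means
"NoTranscription"; a distance strictly below 1.0 um means "Active" (exactly
1.0 um is Inactive); the remainder are "Inactive". One RNA spot may
validate both DNA spots when within the threshold of both — the per-DNA-spot
minimum is taken verbatim, with no one-to-one matching imposed.

Radial distributions of allele groups are compared with a two-sided
two-sample Kolmogorov-Smirnov test. The statistic is computed with integer
numerators (`max |i * n2 - j * n1| / (n1 * n2)`), immune to floating-point
ECDF artifacts. For small samples without ties (`n1 * n2 <= 100` by
default; configurable) the p-value is exact, by counting monotone lattice
paths that stay strictly inside the band `|i/n1 - j/n2| < D` — the
classical distribution-free construction, equal to the full permutation
enumeration, which the test suite verifies exhaustively. Otherwise the
asymptotic Kolmogorov distribution is evaluated at the effective size
`n1 * n2 / (n1 + n2)`. Tied pooled samples fall back to the asymptotic
branch. No multiple-testing correction is applied across panels; p-values
are reported raw.

## The simulator

The simulator generates fields with known per-allele ground truth and is
itself first-class, tested code. What it emulates: non-overlapping round to
mildly elliptical nuclei (axis ratio 0.85-1, so true circularity stays
above the 0.95 QC gate) with a textured DAPI interior — a smooth random
field over a base level, floored at half the nuclear level so chromatin
texture modulates but never extinguishes the stain; the texture is what
gives cross-correlation registration its lock. Two DNA spots per nucleus
are placed by a configurable radial model (uniform within the nucleus, or a
Beta(alpha, beta) target radius for peripheral-bias regimes; Beta(5, 2)
gives mean 5/7 ~ 0.71). Each allele is independently active with
probability `p_active`; active alleles receive one RNA spot within 0.5 um.
Spots render as 2D Gaussians (sigma 2 px) on a constant background,
followed by shot noise and Gaussian read noise (the shot component uses the
Gaussian limit N(lambda, lambda) at the high counts simulated, exact
Poisson below 30 counts). Sequential fields emit two acquisitions sharing
the DAPI scene, the RNA pass translated by a configurable stage shift and
independently re-noised.

Placement choices that are study conditions, chosen once: DNA alleles are
placed at normalized radius <= 0.92, keeping the allele and its RNA offset
interior to the DAPI mask (a locus directly on the segmentation rim is
ambiguous in real data too); and the two homologous alleles are kept at
least 2.5 um apart (never below 4 PSF sigmas), so an RNA signal within
0.5 um of its own allele can never fall within the 1 um activity radius of
the homolog, making ground-truth activity unambiguous. A stray-spot rate
(default 0) injects false spots for negative-path testing of the ">=3"
bins. All randomness derives from one master seed with a fixed per-field
stride (7919), so plates are reproducible field-by-field under parallel
generation.

What the simulator does *not* emulate — and hence what passing tests do not
show about real data: 3D optics and true z-projection artifacts, spectral
bleed-through, photobleaching, cell-cycle and aneuploidy heterogeneity,
touching or overlapping nuclei, realistic chromatin texture, and
probe-specific background. Results on simulated plates validate the
pipeline's logic and calibration, not biological detection efficiencies.

## Problem sizes and numerical choices

Defaults mirror the target acquisition (0.108 um pixels, nuclei of 50-60 px
radius). Validation runs that need many cells use a coarser sampling chosen
once for tractability: 0.4 um pixels with 13.5-15.5 px nucleus radii (still
above the 10 um QC diameter) on 1024 px fields of ~110 nuclei; active-
fraction recovery uses 5 such fields (~500 analyzable cells) per plate,
with 20 plates per activity level (0.05, 0.3, 0.7) judged against exact
binomial 95% confidence intervals. The FFT cross-correlation is compared to
the direct sum at 1e-9 relative tolerance; the exact-KS switchover is
`n1 * n2 <= 100`; tie-breaks (correlation peak, spot plateaus) are
deterministic as described above, so two runs of the same configuration are
byte-identical.

## Known limitations

Integer-pixel registration (no sub-pixel phase correlation) and
translation-only motion; classical segmentation without touching-nucleus
splitting; single-scale spot detection without photometric quantification;
2D analysis of maximum projections throughout; connected-component labeling
follows the underlying image library's connectivity convention, which may
be 8-connected for masks supplied externally.
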