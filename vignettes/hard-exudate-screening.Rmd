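---
title: "Hard-exudate screening: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hard-exudate screening: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(funduscreen)
```

## The screening problem

Hard exudates are yellow, shiny lipid deposits left in the retina when
plasma leaks from capillaries damaged by diabetes. In a colour fundus
photograph they appear as small bright blobs, mostly in the macular area.
A screening decision — *does this retina show bright lesions at all?* — can
therefore be phrased as: find everything bright, discard the bright things
that are *normal* (the optic disk) or *cannot carry exudates* (the vessels),
and flag whatever remains.

`funduscreen` implements exactly that, as a deterministic pipeline of
classical image operations. The input is an 8-bit RGB photograph plus the
eye's laterality, a datum the operator always knows; laterality tells the
pipeline which side of the image the optic disk must be on.

## Pipeline and model assumptions

All processing runs on the green channel, where retinal contrast is
strongest: vessels are locally *dark* curvilinear structures, the optic
disk and exudates locally *bright*.

**Stage 1 — preprocessing.**

1. *Histogram stretching* maps the observed grey range onto the full
   0..255 span: `S' = round((S − k_min)/(k_max − k_min) · 255)`. We scale by
   `Z_k − 1 = 255`, not `Z_k = 256`, so the maximum lands exactly on 255;
   rounding is half-up everywhere an integer grey level is produced.
2. *Median denoising* (3×3, replicate borders) removes impulse noise; this
   step is what keeps isolated noise pixels from crossing the fixed lesion
   threshold later.
3. *Mean-adaptive gamma attenuation*: the coefficient
   `γ = −c·log₁₀(X̄)`, `c = 0.3`, `X̄ = mean/255 ∈ (0,1]`, multiplies every
   pixel. Bright images get a small `γ` (strong attenuation), dark images a
   larger one, so global brightness is unified across acquisitions. For a
   typical fundus frame (`X̄ ≈ 0.05–0.15`) `γ ≈ 0.25–0.4`, which sends the
   retinal background below the fixed lesion threshold while the optic disk
   and exudates — near the top of the stretched range — stay well above it.
   This is the design choice that makes a *fixed* threshold meaningful. A
   power-law transform with a mean-tied exponent was considered and
   rejected: with any exponent in a sane range it cannot push a mid-range
   background below grey level 13, so every image would classify as
   pathological. `γ` is clamped to `[0.02, 10]`; the lower clamp fires only
   in the singular limit `X̄ → 1`.

**Stage 2 — vascular pattern extraction** (on a separately enhanced copy of
the green channel):

median → global histogram equalization → multiplicative brightness
correction to mean 128 → matched filtering → entropy binarization →
short-component pruning.

The matched filter is the classic vessel detector: a negated Gaussian
cross-profile `−exp(−u²/2σ²)` (σ = 2 px) swept along a 9 px segment,
mean-subtracted to zero sum, rotated to twelve orientations at 15° steps;
the per-pixel response is the maximum over orientations. Zero-sum kernels
make the response invariant to constant offsets and identically zero on
flat images. The response is binarized at the maximum-entropy (Kapur)
threshold: quantize to 256 bins, exhaustively score every split by the sum
of background and foreground Shannon entropies, take the argmax (ties →
lowest split). "Length" pruning is implemented as 8-connected component
pixel count < 50, a robust proxy for geodesic length.

**Stage 3 — lesions and decision.** Vessel pixels are set to 0 in the
preprocessed image; pixels strictly above threshold 13 become lesion
candidates. The optic-disk anchor is the first candidate pixel found
scanning columns inward from the laterality-side edge (top-to-bottom within
a column), and an 80 × 80 px square centred on the anchor is blanked,
clipped at borders. Any surviving pixel (configurable `min_lesion_area`,
default 1) makes the decision *pathological*. A local variance map of the
binarized image (window 5, binary variance rescaled so 0.25 → 255) is
computed as a diagnostic — it highlights segmentation boundaries — but does
not enter the decision, which rests on the blue-point rule alone.

## Parameters

| parameter | default | units | why |
|---|---|---|---|
| `median_window` | 3 | px | smallest window that kills impulse noise |
| `gamma_constant` | 0.3 | – | published attenuation constant |
| `stretch_levels` | 256 | levels | full 8-bit range |
| `mf_sigma`, `mf_length` | 2, 9 | px | classic matched-filter vessel profile |
| `mf_orientations` | 12 | – | published mask count (15° steps) |
| `vessel_min_length` | 50 | px | pruning cut, order of a short vessel segment |
| `brightness_target` | 128 | grey | mid-range mean before filtering |
| `lesion_threshold` | 13 | grey | published fixed operating point |
| `variance_window` | 5 | px | diagnostic map resolution |
| `od_square_side` | 80 | px | published optic-disk removal square |
| `min_lesion_area` | 1 | px | strictest decision rule |

`od_scale` optionally rescales the square by `width/3000` (the native width
of a high-end fundus camera) since 80 px corresponds to different angular
sizes across devices; it is off by default.

Two conventions were genuinely open and are decided here: the anchor search
runs on the *binarized* image (not the variance map), and the removal
square is *centred* on the anchor. Centring tolerates the anchor being a
disk-rim pixel rather than the disk centre: a disk of radius ≤ ~19 px is
fully covered even when anchored at its outermost tangent point. The
laterality → scan-side map (right eye → right edge) is configurable because
mirroring optics can flip it.

## The phantom generator

No public image set matches the original clinical database, so validation
runs on synthetic phantoms with exact ground truth. A phantom emulates the
features each stage consumes: a circular field (radius 140 px in a 320 × 320
frame) on a black surround; a red-orange background whose *green* channel is
dim (22 at centre, 30% radial falloff) — in real fundus photographs the
red-dominant background is genuinely dark in green; a connected vessel tree
grown from the optic-disk centre by correlated random walks (root width
2–5 px tapering, darkness −14 grey); one optic disk (radius 16 px, +198
grey) at 0.78 field radii toward the laterality side; 0–4 anti-aliased
exudate discs (radius 8–20 px, +55 green contrast) in a central "macular"
zone of 0.55 field radii — clinically, hard exudates cluster in the macula
and never sit on the disk; and i.i.d. Gaussian noise (σ = 3) clipped to
0..255. The truth record carries the exudate, vessel, centerline and disk
masks plus the disk centre; the label is pathological iff exudates exist.

The photometric defaults follow the pipeline's signal arithmetic: after
stretching and a typical `γ ≈ 0.39`, the background centre sits ~4 grey
levels (≈ 6 noise standard deviations after median filtering) below the
lesion threshold, while the dimmest exudate stays ~15 levels above it. The
disk radius is chosen so the 80 px removal square covers the disk from any
rim anchor.

What phantoms do **not** emulate: lesion irregularity, haemorrhages and
cotton-wool spots, camera point-spread, vignetting and specular artifacts,
JPEG blocking. Passing phantom tests therefore demonstrates the pipeline's
internal consistency and its behaviour under the stated image model — not
clinical accuracy.

## Numerical choices and degenerate inputs

* Integer grey levels are produced by rounding half up; masks use strict
  `>` at thresholds.
* Every windowed operation (median, box means, convolution) replicates edge
  pixels at the borders.
* Connected components are 8-connected throughout.
* Constant images: histogram stretching returns zeros with a warning;
  equalization returns the input; vessel extraction returns an empty mask
  (no structure); the entropy threshold refuses a constant response; an
  all-black input screens healthy with an empty mask.
* An empty candidate mask yields no optic-disk anchor; removal is then a
  no-op and the image healthy.
* Kapur ties resolve to the lowest split, so on a bimodal histogram with an
  *empty* gap the threshold sits at the gap's lower edge; with overlapping
  modes the maximum is unique and central.

## Scope of the validation suite

The test suite exercises every operation against independent oracles
(brute-force median and variance, exhaustive entropy scan, flood-fill
labelling, per-pixel channel extraction) on inputs up to 32 × 32, and the
full pipeline on 320 × 320 phantoms: a frozen 40-phantom cohort (master
seed 2019, 20 pathological) must reach 100% sensitivity, and 20 exudate-free
phantoms must screen ≥ 95% healthy. These sizes keep the whole suite to a
few minutes while leaving every stage at its native parameterization.

## Known limitations

* **Equalization amplifies noise on structure-poor images.** Global
  histogram equalization maps whatever narrow histogram it receives onto
  the full grey range; on an image with no vascular structure the
  matched-filter response is amplified noise and the entropy threshold
  segments sizeable noise clusters into the "vessel" mask. This is a
  property of the stated method, not of the implementation. It is benign
  downstream — vessel masking only ever removes candidate pixels, so
  vessel-free phantoms still screen healthy — but the vessel mask itself
  should not be trusted on such images.
* The fixed threshold 13 presumes the gamma attenuation described above;
  images preprocessed differently need a recalibrated threshold.
* The first-white-pixel anchor assumes the optic disk is the outermost
  bright structure on its side; a bright peripheral lesion beyond the disk
  shifts the square onto itself (the disk then survives, which can only
  bias the decision toward pathological — a false *acceptance*, never a
  missed lesion).
* One decision per image; no lesion typing, grading, or macula
  localization.
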