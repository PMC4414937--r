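---
title: "Half-contour shape features for shadowed breast ultrasound: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Half-contour shape features: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Posterior acoustic shadowing (PAS) is the dark artifact cast below a
strongly attenuating breast mass in B-mode ultrasound. Solid tumors rich
in connective tissue absorb and scatter the beam, so the tissue behind
them is underinsonified and rendered dark. For computer-aided diagnosis
this is a serious problem: shape features of the segmented mass are the
workhorse of benign/malignant discrimination, and a shadow that merges
with the hypoechoic mass corrupts the segmented contour — mostly its
*lower* half, since the shadow is cast downward (deeper). The upper half
of the contour is comparatively intact.

`halfcontour` implements the resulting idea end to end: segment the mass,
trace its closed contour, split off the **upper half contour** between
the leftmost and rightmost contour pixels, and compute shape features on
either curve. On shadowed images, the half-contour variants of the most
discriminative features remain usable where the full-contour variants
degrade.

## Pipeline and model

### Column-adaptive binarization

For an image $I(x,y)$ with $N$ rows (depth $y$, increasing downward) and
columns indexed by the lateral position $x$, each column gets its own
threshold equal to its mean gray value,

$$TH_x = \frac{1}{N}\sum_{y=1}^{N} I(x,y),$$

and the binary image is

$$B(x,y)=\begin{cases}0,&I(x,y)<TH_x \ \text{and}\ \bar I(x,y)<TH_x\\ 1,&\text{otherwise,}\end{cases}$$

where $\bar I$ is the mean over a $(2n+1)\times(2n+1)$ window (default
$n=2$; edges handled by replication). Dark structures — the hypoechoic
mass and any posterior shadow — come out as 0. Both inequalities are
strict, so a constant image maps to an all-ones mask. Columns through a
lesion have their threshold pulled between the lesion and background
levels, which is what makes a single per-column number work as a local
threshold.

Both conditions are needed: the window-mean condition suppresses isolated
dark speckle pixels in bright tissue. The package exposes a second
reading (`use_smoothed = TRUE`) in which the *first* condition also tests
$\bar I$ rather than the raw pixel. The raw rule is the default for
`adaptive_binarize()`; the experiment pipeline defaults to the smoothed
reading because under multiplicative speckle a bright outlier inside the
lesion otherwise punches a hole in the mask, and once a shadow depresses
$TH_x$ toward the lesion level those holes become dense enough that the
morphological opening shatters the region. The cost of the smoothed
reading is a dilation of the segmented region by roughly $n$ pixels
(Dice against ground truth ≈ 0.93 instead of ≈ 0.99 on clean phantoms);
the benefit is robustness on shadowed images.

### Region extraction and contour tracing

The original work used a disk-expansion segmentation whose internals are
not public; this package substitutes a standard morphological pipeline
with the same observable behavior: opening of the dark field with a disc
(radius 3) to remove speckle specks and thin bridges, selection of one
8-connected dark component (the seed's component, or the largest; ties go
to the smaller top-left bounding box corner), and hole filling with
4-connected background. Foreground uses 8-connectivity and background
4-connectivity throughout — the standard complementary pair that avoids
digital-topology paradoxes, and the reason an 8-connected traced curve is
watertight to the 4-connected flood fill used for areas.

The closed boundary is traced with Moore-neighbor tracing, clockwise in
image coordinates, starting at the topmost-then-leftmost boundary pixel,
stopping when the start pixel is re-entered the way it was first left.

### The half contour

$P_l$ and $P_r$ are the leftmost and rightmost contour pixels (ties go to
the shallower pixel). The contour is split at $P_l$ and $P_r$; the arc
with the smaller mean row is the upper half, stored left-to-right, and
the chord $L_{lr}$ (Bresenham rasterization of the segment $P_l P_r$)
closes it into a region when area or centroid are needed. Two assists are
available for shadow-biased contours: column intervals to *exclude* when
locating the endpoints (the programmatic counterpart of an operator
excluding a shadow-contaminated flank) and an `endpoint_tol` band that
takes the shallowest pixel within a few columns of the extreme. Both
default to off; the plain rule is used unless the user opts in.

### The six features

With $P$ the number of boundary pixels and $A$ the number of enclosed
pixels (boundary included; for the half contour the chord pixels count
toward $P$, keeping the isoperimetric meaning of the ratio):

* **TC** (tumor circularity) $= P^2/A$. Minimized by a disk; grows with
  boundary irregularity.
* **NRL$_M$, NRL$_{STD}$**: mean and sample standard deviation of the
  normalized radial lengths $\hat d(i) = d(i)/\max_j d(j)$, where $d(i)$
  is the Euclidean distance from the $i$-th boundary pixel to the region
  centroid (centroid of *all* region pixels; in half mode, of the
  chord-closed half region).
* **AR** (area ratio) $= \frac{1}{\bar d N}\sum_i (\hat d(i)-\bar d)$
  with terms where $\hat d(i) \le \bar d$ set to zero — the one-sided
  mean excess over the mean radius, i.e. how much of the shape protrudes
  beyond the mean-radius circle.
* **RI** (roughness index): mean absolute difference of consecutive
  $\hat d$ values. On the closed contour the sum wraps around; on the
  open half arc it runs over the $N-1$ gaps and divides by $N-1$ (the
  wrapped difference across the chord would be meaningless).
* **SDD** (standard deviation of degree): for each boundary pixel $M_s$
  the vertex angle
  $\theta_s = \arccos\frac{\vec{M_sM_{s-k}}\cdot\vec{M_sM_{s+k}}}{|\vec{M_sM_{s-k}}||\vec{M_sM_{s+k}}|}$
  is formed with the pixels $k$ steps away along the contour, and SDD is
  the *population* standard deviation (1/N) of the series, in degrees.
  Straight stretches give 180°, spicule tips small angles; a smooth
  boundary has nearly constant $\theta_s$ and SDD near zero. Indices wrap
  on the closed contour; on the open arc only pixels with both neighbors
  available contribute. The cosine is clamped to $[-1,1]$ before the
  arccos, and degenerate (coincident-point) vertices are skipped with a
  warning.

The offset $k$ is not fixed by the original description; the package
defaults to $k=5$ pixels and the feature tests are exercised at
$k \in \{3, 5, 9\}$. Radial and circularity features are checked to be
translation-invariant exactly and scale-invariant within 10% when the
radius doubles (with $k$ scaled along, keeping the angular support of the
vertex angle fixed).

### Evaluation

Classification is evaluated per feature, malignant-high (spiculated ⇒
larger values for all six features; the direction is fixed rather than
auto-flipped to avoid silent sign errors). The ROC is a full threshold
sweep over the observed scores with the ≥-convention; the AUC is computed
as the midrank Mann–Whitney statistic (ties count one half), which equals
the area under the swept curve. The operating point maximizes Youden's
$J$ (ties to the lower threshold), and accuracy/sensitivity/specificity
are reported there, in percent. Because the threshold is chosen on the
same sample it is evaluated on (resubstitution), these numbers are
optimistic; the report says so. Group differences use the two-sided
Welch (unequal-variance) t-test via `stats::t.test`.

## The phantom generator

No clinical images ship with the method, so the package includes a seeded
synthetic phantom family that stands in for them. Each phantom is:

1. **Shape**: an ellipse (base radius $R$ px, lateral/axial aspect $q$)
   modulated in polar form by two sinusoidal harmonics with seeded random
   phases, $r(\phi)=r_e(\phi)\,(1+a\,u(\phi))$ with
   $u(\phi)=0.7\sin(L\phi+\psi_1)+0.3\sin(2L\phi+\psi_2)$. The amplitude
   $a\in[0,1)$ is the single "malignancy" knob: $a\approx 0$ is a smooth
   benign-like mass, large $a$ a spiculated malignant-like one. Because
   $|u|\le1$ and $a<1$ the region is star-shaped, hence connected.
2. **Echo**: a two-level mean field (hypoechoic lesion, default 50, on
   background 120, 0–255 float scale) multiplied by unit-mean
   multiplicative speckle $F = 1+s(E-1)$, $E\sim\mathrm{Exp}(1)$ — the
   intensity of a fully developed speckle envelope — with $s=0.3$ by
   default. A second, spatially smooth unit-mean texture field (window-
   averaged Gaussian noise) is available to emulate large-scale tissue
   inhomogeneity but is off by default, so that segmentation behavior is
   attributable to speckle and shadow alone.
3. **Shadow**: below the lesion's lowest row, per column, the image is
   multiplied by `attenuation_factor` (default 0.4) times an optional
   per-row decay; the shadow covers the central `lateral_coverage`
   fraction of the lesion's column span and runs to the bottom of the
   image, which is how a shadow behaves in a B-mode window.

### Study conditions and why they look the way they do

`generate_cohort()` freezes the synthetic study conditions:

* **Raster 384×192** (depth × width): a portrait B-mode window with the
  lesion in the near field, so the shadow has room to dominate the
  merged dark region the way clinical shadows dominate segmentations.
* **Lesion**: base radius 26–36 px, aspect 1.0–1.5, center depth drawn
  per case from 0.25–0.45 of the image depth — lesions sit at varying
  depths, so the shadow length varies case to case.
* **Spiculation amplitudes overlap**: benign 0.03–0.15, malignant
  0.12–0.30. Clinical series report substantial morphologic overlap
  between fibroadenomas and carcinomas; a cohort separable by eye would
  overstate every downstream result.
* **Shadow coverage is class-correlated**: benign 0.50–0.80, malignant
  0.65–0.95 of the lesion span, drawn per case. Malignant masses, with
  their desmoplastic stroma, typically cast wider and more complete
  shadows. This matters for the full contour: a wider shadow adds area
  and perimeter that *oppose* the spiculation signal in $P^2/A$, which
  is one of the mechanisms by which shadows ruin full-contour
  circularity in practice.
* **Attenuation 0.4**, no depth decay: a clearly visible but not black
  shadow; its segmented extent merges with the lesion, as in the
  clinical failure mode the method addresses.

These values were fixed while designing the generator — the aim being a
phantom family in which shadowing corrupts full-contour analysis the way
the clinical literature describes — and have not been revisited since;
the tests and the acceptance script consume them as-is.

### What the phantoms do and do not emulate

They emulate hypoechogenicity, fully developed speckle, boundary
spiculation, and a columnar posterior shadow that merges with the mass.
They do **not** emulate heterogeneous anatomy (fat lobules, Cooper's
ligaments, side shadows), beam-width and focal effects, log-compression
curves of specific scanners, or operator variability. Consequently,
passing the synthetic experiment shows the *pipeline* behaves as designed
under the stated conditions; it is not evidence about clinical
performance.

One consequence deserves emphasis. In this phantom family the shadow is
geometrically regular, so the full contour = upper lesion arc + a
near-deterministic shadow outline. Circularity is strongly corrupted
(the class-correlated shadow area/perimeter opposes the spiculation
signal), and the synthetic experiment reproduces the published direction
for TC: full-contour TC falls to chance-level AUC while half-contour TC
stays discriminative. The vertex-angle statistic is more stubborn: the
upper arc — which carries the angle-variance signal — is contained in
*both* curves, and a geometrically stable shadow contributes a stable
angle mixture, so full-contour SDD remains monotone in spiculation and
its AUC tracks the half-contour's instead of collapsing. Reproducing the
published full-SDD collapse appears to require erratic segmentation
driven by heterogeneous tissue; in our experiments every synthetic
corruption strong enough to degrade full-contour SDD (correlated
speckle, background texture) degraded the short half arc at least as
much, because the half contour has the noisier SDD estimate. This is a
documented limitation of the phantom family, not of the feature
implementation.

## Numerical choices

* Images are float matrices on a 0–255 scale; 8-bit files are promoted on
  read. Coordinates are 1-based (R convention), $x$ = column (lateral),
  $y$ = row (depth, downward).
* Strict `<` in both binarization conditions, exactly as defined
  (equality ⇒ 1).
* Window means at borders use edge replication, computed as separable
  shifted sums (each output an exact sum of $(2n+1)^2$ addends).
* Largest-component ties break toward the smaller top-left bounding box
  corner. A seed that misses the dark field falls back to the nearest
  component, except that among components within 4 px of the nearest the
  largest wins — a speck one pixel closer must not beat the lesion.
* The AUC uses midranks, so tied scores contribute exactly one half;
  the Youden tie-break takes the lower threshold.
* Degenerate inputs error early with messages naming the contract
  violated ("no candidate region", "degenerate region", "exclusion
  removes contour", zero-variance t-test groups, single-class ROC).

## Problem sizes

The bundled tests run the formula oracles on 20 random instances each,
the shape-discrimination ladder on 10 seeds × 4 amplitudes, segmentation
recovery on 10 noise-free + 10 speckled phantoms, and the cohort
experiment at 25+25 shadowed cases plus 5+5 unshadowed cases on the
384×192 raster — sizes chosen to mirror the 50-case clinical design while
keeping a complete run in the low minutes on a single core.
`scripts/acceptance.R` re-runs the cohort experiment and the Dice sweeps
from scratch at the same sizes.
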