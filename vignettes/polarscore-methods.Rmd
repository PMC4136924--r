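---
title: "Quantifying receptor clustering and polarity in migrating lymphocytes"
author: "polarscore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying receptor clustering and polarity in migrating lymphocytes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polarscore)
```

## The scientific problem

A migrating T cell is spatially organized: adhesion receptors such as
CD44 accumulate in the uropod (the trailing projection), and the
integrin LFA-1 segregates by conformational state along the
front--rear axis, with the low-affinity form restricted to the trailing
edge. Perturbations of this organization -- loss of polarity kinases,
myosin II inhibition -- show up in micrographs as receptor signal that
spreads around the membrane instead of capping. `polarscore` turns
such micrographs into per-cell numbers: a **clustering index** for how
tightly a stain is capped, a **trailing-edge localization call** for
where a marker sits relative to the cell's polarity axis, and
**migration statistics** from time-lapse tracks, with a two-branch
statistical comparison between experimental conditions.

## The clustering index

For one cell and one channel, let the cell's segmented region have
area $A$ pixels. The statistic is built from three mean pairwise
distances (MPD; the average Euclidean distance over all unordered
pairs of a point set):

* $D_\alpha$ -- MPD of the brightest decile of the cell's pixels,
  $n = \max(2, \mathrm{round}(0.1A))$ of them (half rounds up, so a
  25-pixel region selects 3).
* $S_l$ -- MPD of the same $n$ points packed, row-major, into a square
  block of side $\lceil\sqrt n\rceil$ at unit spacing. For $n = 100$
  this is a 10 x 10 pixel square, the reference configuration of
  maximal packing.
* $S_u$ -- MPD of $n$ points placed at equal arclength intervals along
  the cell's outer boundary contour: the reference configuration of a
  fully dispersed, membrane-uniform signal.

$$\mathrm{ci} = \frac{S_u - D_\alpha}{S_u - S_l}$$

so ci is ~1 when the brightest decile is packed as tightly as
geometrically possible and ~0 when it is spread evenly around the
perimeter. The affine form is the unique normalization consistent with
treating the packed square as the clustering ceiling and the perimeter
scatter as its floor; any other published variant can be swapped by
replacing `clustering_index()`.

Three properties of this construction deserve emphasis.

**It is not clipped.** Configurations more compact than the packed
square projected onto a particular cell geometry, or more dispersed
than the deterministic perimeter scatter, are possible; such values
are reported outside $[0, 1]$ and flagged `out_of_range`, never
silently truncated. Relatedly, exhaustive search over small lattices
shows the row-major $\lceil\sqrt n\rceil$ block is the exact MPD
minimizer for perfect-square $n$ (4, 9, ..., 100) but can be beaten by
a few percent by rounded clusters at other $n$ (worst observed ~4.5%
at $n = 7$). We keep the square-block construction because it
reproduces the 10 x 10 reference exactly and is a fixed, interpretable
yardstick; the test suite pins down both facts.

**It is deterministic.** The perimeter scatter uses equal-arclength
placement (steps of 1 and $\sqrt 2$ along the 8-connected Moore
contour, linear interpolation between pixel centers), not random
placement, so $S_u$ is a per-cell constant rather than a Monte Carlo
estimate.

**It is rigid-motion invariant.** Two details are load-bearing here
and were chosen after the naive alternatives measurably failed:

* *Top-decile ties.* Integer camera counts regularly tie at the cut
  intensity. Breaking ties lexicographically by (row, col) makes the
  selected set -- and hence ci -- change under a 90-degree rotation of
  the image. Ties are therefore broken by distance to the region
  centroid (nearest first), which transforms with the image;
  (row, col) order remains only as a final fallback for exactly
  symmetric double ties.
* *Scatter phase.* Starting the equal-arclength placement at the
  contour's traversal start (topmost-then-leftmost pixel) also breaks
  rotation invariance, because that pixel is defined by the image
  axes. The placement instead starts at the boundary vertex farthest
  from the boundary centroid, a geometric anchor that maps with the
  region under translation and right-angle rotation.

With both rules in place, ci is invariant to translation and
90/180/270-degree rotation to $10^{-6}$, and
$\mathrm{rear\_fraction}(a) + \mathrm{rear\_fraction}(-a) = 1$ holds
exactly (see below).

## Cell detection

Cells are segmented by a classical pipeline: Gaussian smoothing
(`smoothing_sigma`, default 1 px), a single global Otsu threshold,
hole filling, 8-connected component labeling, then filters on area
(defaults 200--10000 px), solidity (default 0.7) and border contact.
Touching cells are *rejected* by the solidity filter, not split by
watershed: the scoring is meant for singly detected cells, and an
ambiguous clump is better excluded than split wrongly.

Two numerical choices matter:

* **Threshold on log intensity.** Fluorescence foreground spans orders
  of magnitude -- a dim cytoplasm and a membrane cap tens of times
  brighter. On the raw scale Otsu's bimodal assumption fails and the
  threshold can land *above* the cytoplasm, detecting only membrane
  caps. Otsu is therefore computed on `log1p` intensity, which
  restores a background-versus-cell histogram; the threshold is still
  global and monotone in raw intensity.
* **Threshold level from the smoothed image, applied to the
  unsmoothed image.** Smoothing stabilizes the histogram, but a bright
  membrane rim drags the smoothed level set ~1.5 px outside the true
  cell edge, costing ~0.1 of IoU on typical cell sizes. Applying the
  level to the original image keeps boundaries sharp.

Solidity is area divided by the pixel count of the convex hull of the
pixel *corners* (pixels as unit squares), so a filled rectangle scores
exactly 1. Shape descriptors come from second central moments with the
1/12 unit-square correction, so a one-pixel-wide line has a finite
minor axis and a large, finite elongation.

## Trailing-edge localization

The paper-level readout "fraction of cells with the marker at the
trailing edge" is likely a by-eye call in the original work; here it
is operationalized so it can be computed, audited and swept:

1. The polarity axis is the unit vector from the region's geometric
   centroid to the intensity-weighted centroid of a *reference* uropod
   channel (CD44 by default). Cells whose offset is below 0.5 px have
   no defined axis and are excluded with a reason code. The axis can
   instead come from a matched track (rear = opposite of net motion)
   or be supplied directly.
2. The region is split by the line through the centroid perpendicular
   to the axis; `rear_fraction` is the marker channel's intensity
   share in the rear half-plane, with pixels exactly on the line
   counting half to each side -- this half-pixel rule is what makes
   the complement identity exact rather than approximate.
3. A cell is called localized when `rear_fraction >= 0.6`. The 0.6
   default asks for a clear majority of signal behind the midline
   while tolerating the diffuse cytoplasmic pool, which by itself
   contributes ~0.5; the threshold is an exposed parameter and the
   field-level summary reports evaluable and excluded counts
   separately so a sensitivity sweep is one loop.

A half-plane split was chosen over a rear "sector" because it needs no
second angular parameter and is reproducible across cell shapes.

## Migration tracks

Tracks are consumed from CSV (`track_id, frame, x, y`, with `x` = image
column and `y` = image row -- the single place the (x, y) convention
appears). Per track: path length, net displacement, mean speed (path
length over *elapsed* time, so frame gaps lengthen the denominator
rather than being ignored), directionality ratio (net/path: 1 = straight,
0 = closed loop), signed turning angles, and the origin-rebased
endpoint for rose plots. "Velocity" is reported as this scalar mean
speed per cell; instantaneous step speeds are also returned. Frame
interval and pixel size have no defaults -- they are acquisition facts
the user must supply.

## Statistical comparison

`compare_groups()` reproduces a common two-branch scheme: Shapiro-Wilk
on each group (gate $\alpha = 0.05$); if both pass, a two-sided
equal-variance Student's t-test (Welch behind a flag), otherwise a
two-sided Mann-Whitney U, exact (via the U distribution, which the
test suite verifies against complete enumeration of all
$\binom{n_a+n_b}{n_a}$ labelings) when the smaller group has at most 8
observations and there are no ties, and the tie-corrected normal
approximation otherwise. The branch decision and both normality
p-values are always part of the result -- the gate is auditable, never
silent. No multiple-testing correction is applied by default, matching
the single-contrast design; Benjamini-Hochberg can be applied
downstream when many channels are compared. Comparisons pool cells
across fields within a condition; per-experiment hierarchical modeling
is out of scope and the pooling caveat applies when fields are not
exchangeable.

## The synthetic-micrograph generator

Every stage is validated against `render_field()`/`simulate_field()`,
which draw cells as ellipses (semi-axes sampled from 10--16 and 8--12
px, i.e. lymphocyte-scale at ~0.5 um/px) with three intensity
components per channel, in camera counts: uniform background (5),
cytoplasmic interior (20), and a membrane annulus (width 3 px,
amplitude 100) whose angular density is von Mises,
$\propto \exp(\kappa\cos(\theta - \mu))$, normalized by $I_0(\kappa)$
so total membrane signal is approximately $\kappa$-independent.
$\kappa = 0$ is an unpolarized ring; $\kappa = 8$ a tight cap. Each
cell gets a random polarity direction; a channel's cap sits at a
configurable offset from it, so a marker can be placed at the rear
(offset 0) or front (offset $\pi$) of the reference stain.

The membrane term carries multiplicative gamma speckle (shape 3, mean
1, CV ~0.58) modeling receptor microclusters. This is not cosmetic: a
*smooth* angular profile has the same intensity ranking for every
$\kappa > 0$, so the brightest-decile set -- and with it ci --
saturates immediately and the statistic cannot grade polarization
strength. Granular membranes are both what real stains look like and
what makes a rank-based clustering statistic informative. Camera noise
is Poisson shot noise on the expected counts plus Gaussian read noise
(sd 2 counts, 2% of membrane amplitude), rounded to integers and
clamped at zero, so written TIFFs round-trip losslessly. Cells are
placed by rejection sampling with a minimum background gap (8 px) and
all randomness flows from one seed.

Tracks are persistent random walks: headings turn by wrapped-normal
increments with sd $\sqrt{-2\ln p}$, so the persistence parameter $p$
is the per-step heading correlation ($p = 0$ gives uniform turning);
step lengths are lognormal with mean `speed * dt`, so mean speed is
recovered without bias.

What the generator does *not* emulate -- and what passing tests
therefore do not certify on real data: point-spread-function blur,
uneven illumination, out-of-focus light, touching or non-elliptical
cells, photobleaching, and time-lapse image sequences (tracks are
generated as coordinates directly). On real micrographs the detection
defaults and the 0.6 polarity threshold are starting points to be
inspected, not guarantees.

## Validation at a glance

The test suite and `scripts/acceptance.R` recompute, at fixed seeds:
the analytic bounds (a planted packed square scores ci = 1, planted
perimeter scatter ci = 0, to $10^{-9}$); agreement of all three
distance primitives with naive double-loop oracles; the invariance
suite; recovery of segmentation ground truth (200/200 cells, IoU
$\ge$ 0.8) on 10 fields of 20 cells at 420 x 420 px; a strictly
increasing mean ci over $\kappa \in \{0, 1, 2, 4, 8\}$ with Spearman
$\rho > 0.8$ at 100 cells per level; a polarized ($\kappa = 4$) versus
depolarized ($\kappa = 1$) contrast at 200 cells per arm; rear- versus
front-cap classification; exact Mann-Whitney enumeration for all group
sizes with $n_a + n_b \le 12$; and byte-identical pipeline reruns.
These problem sizes keep the full validation run in well under a
minute per stage on a single core while leaving each estimate's
sampling error far from the margins being tested.

## A worked example

```{r example, eval = FALSE}
sim <- simulate_field(
  n_cells = 8, size = c(300, 300), seed = 1,
  channels = list(cd44 = membrane_channel(kappa = 6),
                  lfa1 = membrane_channel(kappa = 3)))
mask <- segment_field(sim$field, detection_params())
scores <- score_field(sim$field, mask)
head(scores)
calls <- classify_field(sim$field, mask, "cd44", "lfa1")
calls$summary
```

## Known limitations

* 2D only; z-stacks must be projected upstream.
* No watershed splitting: dense fields lose clumped cells to the
  solidity filter, which biases sampling toward isolated cells.
* The clustering index compares a cell only to its own geometry;
  comparisons across very different cell shapes lean on $S_u$'s
  normalization being adequate for both.
* PNG I/O is 8-bit (the underlying writer has no 16-bit mode); use
  TIFF for 16-bit data.
* Pooled-cell statistics treat cells as independent; they are not when
  fields or animals differ systematically.
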