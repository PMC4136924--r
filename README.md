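# polarscore

Receptor clustering and polarity scoring for single-cell fluorescence
micrographs of migrating lymphocytes.

Migrating T cells are strongly polarized: CD44 caps in the uropod
(trailing projection) and LFA-1 conformations segregate along the
front–rear axis, with the low-affinity form confined to the trailing
edge. When polarity machinery is perturbed (e.g. loss of the kinase
Mst1, or myosin II inhibition), receptor signal spreads around the
membrane instead of capping. `polarscore` is for cell biologists who
need to turn such images into per-cell numbers and defensible
statistics: it detects single cells, scores how tightly each stain is
clustered, classifies trailing-edge marker localization, summarizes
migration tracks, and compares conditions.

## The clustering index

For a segmented cell of area *A*, take the brightest decile of its
pixels, *n* = max(2, round(0.1 *A*)), and let *D<sub>α</sub>* be their
mean pairwise distance (MPD). Compare against two per-cell reference
configurations of the same *n* points:

- *S<sub>l</sub>* — MPD of the points packed row-major into a
  ⌈√*n*⌉-sided square block (for *n* = 100, a 10 × 10 pixel square):
  maximal clustering;
- *S<sub>u</sub>* — MPD of the points placed at equal arclength
  intervals along the cell's outer boundary contour: membrane-uniform
  signal, no clustering.

The clustering index is

&nbsp;&nbsp;&nbsp;&nbsp;ci = (S<sub>u</sub> − D<sub>α</sub>) / (S<sub>u</sub> − S<sub>l</sub>)

so ci ≈ 1 for a tight cap and ci ≈ 0 for a uniform membrane ring.
Values outside [0, 1] are possible, reported and flagged — never
clipped. Both reference configurations are deterministic, and tie
handling is rigid-motion equivariant, so ci is invariant to image
translation and right-angle rotation. Complementing ci, the
trailing-edge classifier reports the fraction of a marker channel's
signal in the rear half-plane defined by a uropod reference stain, and
the track module computes path length, net displacement, mean speed
and directionality ratio per cell. Conditions are compared with a
normality-gated two-branch test (Shapiro–Wilk, then Student's t or
Mann–Whitney U, exact for small tie-free samples).

A fully ground-truthed synthetic-micrograph generator (elliptical
cells, von Mises membrane caps with microcluster speckle,
Poisson–Gaussian camera noise, persistent-random-walk tracks) makes
every stage testable without external data; see the methods vignette
(`vignettes/polarscore-methods.Rmd`) for the model and all numerical
choices.

## Worked example

```r
library(polarscore)

sim <- simulate_field(
  n_cells = 8, size = c(300, 300), seed = 1,
  channels = list(cd44 = membrane_channel(kappa = 6),    # tight uropod cap
                  lfa1 = membrane_channel(kappa = 3)))   # looser cap
mask   <- segment_field(sim$field, detection_params())
scores <- score_field(sim$field, mask)
head(scores)
#>   cell_label channel  n d_alpha   s_l   s_u     ci flag
#> 1          1    cd44 44   5.275 3.546 15.00 0.8491   ok
#> 2          1    lfa1 44   5.949 3.546 15.00 0.7902   ok
#> 3          2    cd44 37   4.975 3.311 13.83 0.8419   ok
#> 4          2    lfa1 37   5.703 3.311 13.83 0.7726   ok
#> 5          3    cd44 38   4.828 3.328 13.83 0.8571   ok
#> 6          3    lfa1 38   5.399 3.328 13.83 0.8028   ok
```

Each row is one cell × channel: `n` selected pixels, their mean
pairwise distance `d_alpha`, the packed (`s_l`) and perimeter (`s_u`)
references in pixels, and the index. The κ = 6 channel scores higher
(mean ci 0.826) than the κ = 3 channel (0.770), as it should. The
trailing-edge classifier, using CD44 as the rear reference:

```r
calls <- classify_field(sim$field, mask, "cd44", "lfa1")
calls$summary
#> $fraction     [1] 1
#> $n_localized  [1] 8
#> $n_evaluable  [1] 8
#> $n_excluded   [1] 0
```

Here every cell is called localized because both caps were generated
on the same side; generating the marker with `cap_offset = pi` (front
cap) drives the fraction to 0.

`run_pipeline()` orchestrates everything from a YAML config
(simulate-or-load per condition, segmentation, scoring, polarity,
tracks, comparisons) into a results directory with CSV/JSON outputs
and full provenance. A thin command-line front end over the same
functions ships in `inst/cli/polarscore.R` with subcommands `segment`,
`score`, `polarity`, `tracks`, `compare` and `run`.

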