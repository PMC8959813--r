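---
title: "From TLS point clouds to crown architecture: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From TLS point clouds to crown architecture: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crownarch)
```

## The problem

Thinning changes the growing space of the trees left behind, and their
crowns respond: lower stand densities let crowns widen and reach deeper
down the stem. Terrestrial laser scanning (TLS) makes that response
measurable on standing trees — crown volume, surface area, diameters at
many heights — where field work traditionally recorded only crown-base
height and length. A quantity of particular interest is the stem
cross-sectional area at the height of the maximum crown diameter (SAHMC,
cm²): under pipe-model reasoning the conductive area at the crown base
should track the foliage above it, making SAHMC a candidate proxy for
growth potential.

`crownarch` implements the full chain from a plot-level point cloud to
treatment-level statistics: height normalization, individual-tree
segmentation, stem/crown point classification, taper-curve
reconstruction, the crown trait set, and a nested mixed-model analysis
of thinning effects. Because the original scan data are not required,
the package ships a synthetic-stand generator whose trees have
closed-form traits; every stage is validated against that analytic
ground truth.

## The synthetic stand generator

A tree is a stem plus a crown, both solids of revolution:

* **Stem**: power-law taper $d(h) = d_0\,((H-h)/H)^k$ with basal
  diameter $d_0$ derived from the DBH, total height $H$ (m) and
  exponent $k \ge 0$ ($k=0$ cylinder, $k=1$ cone; default $k=0.7$, a
  realistic mid-bole form for mature pine). Stem points are sampled on
  the surface with density proportional to local circumference
  (default 500 points/m²) plus radial Gaussian noise (default 5 mm).
* **Crown**: a convex radius profile $r(h)$ on $[h_b, H]$ — two
  half-spheroids joined at the height of maximum radius (`"spheroid"`,
  with `"ellipsoid"` the symmetric special case), or a cone widest at
  the crown base. Crown points fill the solid uniformly (default
  60 points/m³). Convexity means the 2D projection is a disk and the
  convex hull equals the solid, so projection area ($\pi r_c^2$), hull
  volume and slice diameters all have closed forms or 1-mm-grid
  integrals; `oracle_traits()` evaluates them.

Stands place trees on a jittered grid that enforces a minimum stem
spacing — plain rejection sampling jams well below 1,250 stems/ha under
a hard-core constraint — and drop them on a smooth sinusoidal terrain
(default amplitude 0.2 m, wavelength 40 m) carpeted with ground
returns. The seven stand conditions mirror a classical two-intensity ×
three-type thinning trial plus control: residual densities of
720/910/940 (moderate below/above/systematic), 290/450/470 (intensive)
and 1,250 stems/ha (untreated), with per-treatment DBH and height
distributions typical of such trials ~13 years after treatment
(means 18.7–26.4 cm and 19.1–21.2 m). Crown radii grow and crown bases
drop as density falls; crown-base means were derived analytically from
the taper so that treatment-mean SAHMC spans roughly 70–160 cm², the
scale reported for Scots pine under these treatments. Synthetic growth
columns are drawn as $a + b\,\mathrm{SAHMC} + \varepsilon$ with
positive $b$ (see `default_growth_model()`), so correlation screens
have a planted sign.

What the generator does **not** emulate: occlusion and the
range-dependent footprint of real multi-scan TLS, branch-level
structure, foliage clumping, crossing crowns, and registration error.
Passing tests therefore demonstrate correctness of the geometry and
statistics under clean sampling, not robustness to every field
artefact.

## Pipeline stages and their parameters

**Height normalization.** `build_dtm()` grids the cloud (0.5 m cells),
takes per-cell minimum heights, and rejects outlying minima with a
2.5×IQR rule applied across the cell minima — below-Q1 outliers are
spurious sub-ground returns, above-Q3 outliers are cells that saw only
canopy. The rejection is deliberately *across* cells: within a single
canopy cell the height distribution is dominated by crown returns and
any within-cell quantile rule discards the true ground hits. Rejected
and empty cells are nearest-neighbour filled, the surface is smoothed
once with a 3×3 mean, and `normalize_heights()` subtracts a bilinear
interpolation (nearest-neighbour at the raster edge).

**Segmentation.** `rasterize_chm()` builds a canopy height model from
per-cell maxima (0.20 m cells, one 3×3 median pass against
within-crown pits, cells below 2 m masked). `detect_treetops()` is a
variable window filter: a cell is a treetop iff it is the maximum in a
circular window of radius `max(0.5, 0.04 h)` m, with row-major
tie-breaking so plateaus yield one top. The window coefficient is
deliberately conservative for dense canopies and is a plain function
argument; broad flat-topped crowns sampled sparsely can split, which is
why the validation stands use conical crowns (pointed apices, as in
young dense pine) when exact counts are asserted.
`watershed_crowns()` floods the inverted CHM from the treetops (Meyer
priority-flood, 8-connected, deterministic FIFO tie-break, implemented
in C++ since no marker-controlled watershed exists in the R
dependency stack), and `assign_points()` transfers cell labels to
points through half-open cell intervals, an exhaustive and disjoint
partition.

**Stem/crown classification.** `classify_stem_points()` computes
per-point neighbourhood features from the k=20 nearest neighbours
(closed-form eigenvalues of the 3×3 covariance; the smallest
eigenvector is the local normal; verticality = 1 − |normal·up|), keeps
candidates with verticality ≥ 0.8, slices them into 0.5-m bins and
fits a circle per bin, accepting a bin when ≥ 60% of its candidates
lie within 3 cm of the circle and the centre drifts ≤ 25 cm from the
previous accepted slice, stopping after 3 consecutive rejections. Stem
points are all returns within 3 cm of an accepted circle — not only
the verticality candidates, since every return on the circle is a stem
return even if its neighbourhood features were diluted. All thresholds
live in `stem_classify_params()`. k-NN neighbourhoods (rather than a
fixed radius) keep the features stable across point densities.

**Taper and stem traits.** `fit_circle()` is Taubin's algebraic fit
with one Gauss–Newton refinement; `fit_taper_curve()` accepts slices
with residual ≤ 3 cm whose diameter does not grow more than 10% over
the previous accepted slice (crown-contamination guard) and
interpolates the knots with a natural cubic spline. Above the highest
knot — the bole hidden inside the crown — the curve follows a
power-law taper $d = c\,(H-h)^k$ fitted by residual-weighted log–log
regression to the uppermost eight knots; weighting by the inverse
squared circle residual keeps a crown-base-straddling knot from
steering the fit. This tip model is exact for cylinders, cones and
parabolic stems, where a straight taper to zero from the last knot is
not: the straight rule loses ~1.6% of a cylinder's volume outright and
underestimates concave stems at the crown base by enough to move SAHMC
several percent. Stem volume stacks 10-cm cylinders with midpoint
diameters (midpoint halves the bias of end evaluation for monotone
tapers); DBH is the curve at 1.3 m; the height at 50% cumulative
volume interpolates linearly within its crossing cylinder.

**Crown traits.** Projection area and maximum diameter come from the
2D hull (`grDevices::chull`, diameters over hull vertices); crown
volume and surface area from an exact 3D quickhull written in C++ for
this package (validated in the test suite against analytic solids —
cube, tetrahedron, densely sampled ellipsoids). "Height percentiles of
10%" are read as equal-point-count deciles of the crown height
distribution — percentile wording favours counts — with equal-height
bands selectable (`slice_crown(method = "height")`). A slice's
representative height is the mean height of its points. HMC is the
representative height of the widest slice; slices within 1 cm of the
maximum diameter count as tied and ties resolve to the lowest slice.
The tolerance matters: a crown widest exactly at a slice boundary
makes the neighbouring slice diameters differ by less than any point
sample resolves, and without it the chosen slice is a coin flip — a
quantization inherent in defining HMC from slices (HMC need not be the
physiological crown base; the trait follows the slice definition
regardless). Crown length is $H - \mathrm{HMC}$, live-crown ratio its
share of $H$, and SAHMC is $\tfrac{\pi}{4} d^2$ with $d$ the taper
diameter at HMC in cm.

## The statistical layer

For each trait $y$ the treatment analysis fits, by REML (lme4, bobyqa
optimizer),

$$ y_{ij} = \sum_{t=1}^{7} \beta_t\,\mathbb{1}[\text{treatment}=t]
   + a_{\text{site}} + c_{\text{plot(site)}} + \varepsilon, $$

cell means without intercept, with site and plot-within-site random
intercepts whose variances carry the between-site and between-plot
effects (`fit_nested_lmm()`, with `tidy()`/`glance()` accessors).
Tukey all-pairwise treatment contrasts use `multcomp::glht`'s
single-step multivariate-t on the model's fixed-effect covariance —
contrasts on the fitted LMM, not on raw group means. The reference
distribution uses the median Satterthwaite denominator df of the 21
contrasts (via `lmerTest::contest1D`): treatments vary at the plot
level, so those df are ~plot-count-sized, and the asymptotic normal
reference is visibly anticonservative in designs with ~27 plots.
`trait_screen()` reports Pearson **and** Spearman correlations of each
trait with SAHMC side by side (monotone-but-nonlinear relations make
the two diverge; both are informative) plus the slope of the nested
model with the trait as single fixed predictor (Satterthwaite
p-values; an OLS fallback covers degenerate zero-variance fits, and is
flagged).

A note on calibration: with three sites, a treatment *cell mean*
absorbs the average site effect and its Satterthwaite df is about 2,
where a ±2·SE normal band undercovers by construction (the t
distribution at 2 df puts ~18% outside ±2) — the package's validation
therefore checks coverage of the t-based interval of equal nominal
level, and checks the Tukey family-wise error rate under a simulated
null.
`simulate_trait_table()` draws balanced nested designs from exactly
the model above for such experiments.

## Problem sizes and determinism

The shipped validation suite runs single trees at 400–2,000 crown
points/m³, thirty dense noiseless trees for trait recovery, one stand
each at 290 and 1,250 stems/ha for segmentation, 200 replicates for
fixed-effect coverage, 500 for the null family-wise error rate and 20
for the planted-slope screen; `scripts/acceptance.R` repeats the same
computations at reduced replicate counts plus a two-site, fourteen-plot
end-to-end study. All generators are seeded; a stand is a pure function
of its `stand_spec()`, and the pipeline re-run with the same
configuration reproduces its trait table bit for bit.

## Known limitations

* Interlocking or heavily overlapping crowns are split by the 2D
  watershed boundary; no voxel/3D segmentation is attempted.
* Forked stems violate the single-circle-per-slice model and are left
  to the "no stem found" path.
* The classifier's thresholds were chosen for the generator's clean
  clouds; real TLS with occlusion will need the exposed parameters
  retuned, and agreement with any specific published classification
  implementation is not claimed.
* HMC, and hence SAHMC, inherits the slice quantization discussed
  above; comparisons across datasets should keep the slice count
  fixed.
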