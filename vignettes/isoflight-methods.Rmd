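---
title: "Inferring oceanic non-breeding areas from geolocators and feather isotopes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring oceanic non-breeding areas from geolocators and feather isotopes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Small pelagic seabirds such as Bulwer's petrel spend the non-breeding season
dispersed over oligotrophic open ocean, far from observers. Two complementary
data sources can reveal where: archival light-level geolocators (GLS), which
record light and saltwater immersion and yield two coarse positions per day,
and the stable isotope composition of feathers, which is fixed at the time
and place each feather grew. If the baseline isotopic gradients of oceanic
water masses (the marine "isoscape") propagate up the food web, then
$\delta^{15}\mathrm{N}$ and $\delta^{13}\mathrm{C}$ of a feather moulted in
the non-breeding quarters act as an intrinsic geographic marker: one feather
sample can stand in for a whole tracking deployment.

`isoflight` implements that inference chain end to end:

1. **Geolocation** — twilight times to daily positions, with the standard
   exclusion and speed filters.
2. **Space use** — kernel utilization distributions, core-use (isopleth)
   centroids, and k-medoids clustering of the per-bird centroids into
   oceanic non-breeding regions.
3. **Isotope statistics** — group comparisons, linear discriminant
   classification functions with a 70/30 train/test protocol, and standard
   ellipse areas for isotopic niches.
4. **Isoscapes** — ordinary kriging of feather values placed at the
   centroids, with a spherical semivariogram and a 4° buffer mask.
5. **Synthetic data** — a generator that produces tracks, twilights,
   immersion and feathers with the statistical structure the analysis
   assumes, so the chain is testable without field data.

## Geolocation model

Twilights are detected by the threshold method: a crossing of light level 20
(linearly interpolated between samples) marks dawn (upward) or dusk
(downward). For a dawn/dusk pair, longitude follows from the offset of the
pair's midpoint — local apparent noon — from 12:00 UTC, using the NOAA
low-precision equation of time; latitude is solved from day length and solar
declination by root finding on the monotone day-length relation. The same
solar formulas drive the simulator's forward model, so noise-free
round-trips close to machine precision; this is a deliberate property, and
it means the round-trip tests validate the inversion logic, not the NOAA
formulas themselves.

Three exclusion rules mirror standard GLS practice: transitions with a dark
period under 4 h are flagged (`short_dark`); dates within 20 days
(inclusive) of an equinox are flagged (`equinox`) because day length is
then ~12 h at every latitude; and logger days whose maximum light never
reaches the threshold are flagged as incubation shifts inside the burrow
(`flag_incubation_days()`). The sun elevation corresponding to light
threshold 20 is not knowable from the data alone; both simulator and
estimator default to −3.0°, and the value is configurable. All filters
*flag* rather than delete, so provenance is never lost.

The speed filter removes positions implying implausible travel: the
rejection threshold is the 95th percentile of the *per-bird maximum* travel
speeds across the processed cohort (the plural in the protocol points at a
cohort quantity), and each iteration flags the fix whose forward/backward
averaged great-circle speed is worst, until none exceeds the threshold. The
filter is idempotent by construction.

Departure from the colony is the first date outside a 200 km colony radius
(about one geolocation error unit) followed by three consecutive days of
increasing colony distance; arrival is symmetric. When an equinox gap makes
the positional arrival undecidable, the first all-dry night of the
immersion record (a bird inside its burrow never touches water) supplies
the arrival date instead, and the result says so (`arrival_method`).

## Space use and clustering

Per bird, the non-breeding positions feed an isotropic bivariate Gaussian
kernel density on a 0.25° geographic grid with the reference bandwidth
$h = \sqrt{\tfrac{1}{2}(\mathrm{var}(x)+\mathrm{var}(y))}\,n^{-1/6}$,
computed in degrees (the convention of the home-range tools this follows;
the metric distortion at these latitudes is modest and is accepted for
comparability). The "5% kernel" is read as the 5% isopleth — the smallest,
highest-density region holding 5% of the utilization mass — and its
density-weighted centroid summarizes the bird's core non-breeding area.
The plain polygon centroid would differ negligibly for unimodal cores; the
density-weighted choice is an interpretation and is recorded as such.

Centroids are clustered by partitioning around medoids on a haversine
distance matrix (R = 6371 km). The number of clusters is chosen by the
average silhouette width over k = 2..10 (the conventional range of the
silhouette-based selector; k = 1 is outside the criterion's domain). PAM
runs through `cluster::pam`; tests verify its cost equals the exhaustive
two-medoid optimum on every small instance, and the silhouette computed
here matches the reference implementation to 1e-10.

## Isotope statistics

Delta notation is $\delta X = (R_{sample}/R_{standard} - 1)$ expressed in
‰. The discriminant model is two-variable LDA stored in *classification
function* form: for class $g$, the linear score
$\Sigma^{-1}\mu_g \cdot x - \tfrac{1}{2}\mu_g^\top\Sigma^{-1}\mu_g + \ln\pi_g$
with pooled within-class covariance $\Sigma$ (divisor $n-g$) and equal
("uninformative") priors; a bird is assigned to the class with the larger
score. Equal priors add identical constants to both functions and cancel in
the comparison. Ties break to the first class, with a warning.
`reference_discriminant_functions()` carries the published S8/R6
coefficient tables so any new bird can be assigned without refitting.

The 70/30 protocol guards against pseudo-replication: the training pool
takes one randomly chosen record per bird; all remaining records (including
the repeats of multi-year birds) go to testing; then, per class, records
are moved at random from training to testing until the class's testing
share reaches 30%. The model is fitted once, after the final split.
Classification tables report per-class percent correct for training and
testing, with totals as sample-size-weighted means of class rates.

Group comparisons use one-way ANOVA with Tukey HSD letters for parametric
data and a tie-corrected Kruskal–Wallis test otherwise; "non-parametric" is
operationalized as any group failing a Shapiro–Wilk check at α = 0.05, and
the Kruskal–Wallis post-hoc is Dunn's test with Bonferroni correction
(the original report shows letters but does not name its post-hoc). Letters
come from the insert-and-absorb algorithm; groups sharing no letter differ
at α = 0.05.

Isotopic niche width is the standard ellipse area
$SEA = \pi\sqrt{\lambda_1\lambda_2}$ from the covariance eigenvalues, with
the small-sample correction $SEA_c = SEA\,(n-1)/(n-2)$. The optional
Bayesian posterior uses the conjugate normal–inverse-Wishart family with a
vague prior ($\nu_0 = 3$, scale 0.01 × sample covariance), sampled exactly
— no MCMC. This is deliberately not identical to JAGS-based samplers used
elsewhere; for the vague-prior regime the posteriors agree closely, and the
point estimates are identical by construction.

## Isoscapes

Feather values are attached to their bird's centroid and interpolated by
ordinary kriging with a spherical semivariogram
$\gamma(h) = c_0 + c\,(1.5 h/a - 0.5 (h/a)^3)$ for $h \le a$. The empirical
variogram uses planar degree distances (matching interpolation done
directly on geographic coordinates; a haversine-km mode is available), and
the fit is weighted least squares with pair-count weights. The default lag
cutoff spans the full extent of the data: with two point clouds ~35° apart
and no within-cloud spatial structure, the informative lags are the
between-cloud ones, and a cutoff at half the extent would discard exactly
the structure of interest. Flat empirical variograms leave the range
unidentified and trigger a documented fallback (nugget 0, sill = mean
γ, range = half the maximum lag) with a warning.

Kriging solves the semivariogram-form system with a Lagrange multiplier,
factorizing the data–data matrix once per surface; weights sum to 1 on
every cell (asserted to 1e-10), predictions are exact at data locations
when the nugget is zero, and exact duplicates are averaged with a warning.
The map is restricted to the union of 4° disks around the centroids, and a
Mollweide (equal-area) transform is provided for rendering only. Grid
resolution defaults to 1°.

## The synthetic generator

The generator is the package's null world, built to the study's design:

* four colonies at their true coordinates and breeding windows;
* two non-breeding boxes, Central Atlantic (40–15°W × 5°S–20°N) and South
  Atlantic (40°W–5°E × 35–15°S) — the study presents these regions only as
  a map, so the boxes are emulation geometry, not reported fact;
* per-bird itineraries with ~30 colony days, a great-circle migration leg
  capped at 700 km/day (configurable; well above sustained petrel travel),
  ≥ 150 days of reflecting random walk inside the box, and a return leg;
* twilights from the forward solar model plus Gaussian timing noise
  (default SD 2 min, chosen to land the resulting position error at the
  186 ± 114 km scale reported for GLS loggers);
* 10-minute immersion counts in 0..200, all-dry on colony nights;
* feather values drawn from bivariate normals at the published per-feather,
  per-area means and SDs. The within-class correlation between
  $\delta^{15}\mathrm{N}$ and $\delta^{13}\mathrm{C}$ is unreported and
  defaults to 0; it is exposed as a parameter because the published
  classification functions, read backwards through
  $\Sigma\,(a_C - a_S) = \mu_C - \mu_S$, imply the real pooled covariance
  had a correlation near −0.3. Cohort-scale experiments
  (`simulate_centroids()`) draw centroids directly as 2°-SD Gaussian
  clouds, the scale of geolocation error, with the study's 65/21 split.

What the generator does **not** emulate: behaviourally realistic movement
(no correlated random walk or state switching), raw lux-level light curves
(twilight times are emitted directly), weather- or shading-driven twilight
outliers, inter-annual baseline isotope variation, and moult-timing
variability among individuals. Passing tests therefore show the chain is
correct under its own assumptions — not that those assumptions hold for any
particular field dataset.

## Numerical and design choices

* Solar terms are evaluated at civil noon of each date; simulator and
  estimator share them, so round-trip error reflects inversion logic only.
* Latitude is declared indeterminate when declination is within 0.3° of
  zero or no root exists in ±89.5°; these days are flagged, and the ±20-day
  equinox exclusion subsumes them in practice.
* Equinox dates come from the declination zero-crossing of the same solar
  series; the exclusion window boundary is inclusive.
* PAM ties and LDA score ties resolve to the lowest index / first class,
  making runs deterministic; all generators are pure functions of
  (configuration, seed).
* The run configuration is a plain R list (`default_config()`), fully
  embedded in the run manifest; every protocol default (threshold 20,
  4 h dark minimum, 20-day equinox window, 95th-percentile speed filter,
  5% isopleth, 70/30 split, 4° buffer) sits in one place and can be
  overridden explicitly, never silently.
* `run_pipeline()` executes simulate → geolocate → cluster → assign →
  isoscape and records md5 digests of every output, so identical
  configurations reproduce identical files. The default demonstration
  cohort is 24 birds — large enough for every class to support the split
  protocol, small enough to run in seconds; cohort-scale properties are
  exercised at the study's 86 bird-years via `simulate_centroids()`.

## Known limitations

* KDE and buffer masks work in geographic degrees; longitudinal distances
  shrink with latitude, which mildly distorts bandwidths and disk shapes
  away from the equator.
* The Cape Verde colonies sit inside the Central Atlantic box, so a
  simulated residency walk can drift within the colony radius and produce
  an early "arrival"; with real birds the same ambiguity exists and is the
  reason the immersion rule matters.
* The latitude solver assumes a single twilight pair per day and does not
  attempt template-fit or state-space refinement; accuracy is bounded by
  the threshold method itself.
* Between-area isotope structure is what the kriged surfaces can show;
  within-area gradients are absent by construction in the generator, so
  simulated surfaces are flatter inside each mask than real ones.
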