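---
title: "Quantifying Golgi remodeling and PDZ cargo binding: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying Golgi remodeling and PDZ cargo binding: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(golgiquant)
```

## Scope

During spermatogenesis the Golgi apparatus of germ cells is remodeled
dramatically: it enlarges in pachytene spermatocytes, seeds the acrosome
in round spermatids, and its stacking machinery (GRASP-family tethers
with tandem PDZ domains) doubles as a cargo receptor for junctional
adhesion molecules. Interrogating that biology quantitatively requires a
heterogeneous toolbox — fluorescence image analysis, plate-reader and
calorimetry curve fitting, structural comparison of protein
conformations, and flow-cytometry gating. golgiquant implements each of
those pipelines as plain R functions, and pairs every one of them with a
seeded synthetic-data generator that carries exact ground truth, so the
whole chain can be exercised and validated without any external data.

This vignette records the models, the tunable parameters and their
defaults, the numerical choices, and the places where the design was
genuinely open.

## Per-cell Golgi density (`golgi_density`)

The workflow mirrors common practice for cultured-cell micrographs:

1. split channels (`split_channels`);
2. median-smooth each channel (`median_smooth`, default 3 x 3 kernel,
   replicated edges — no kernel size is canonical, 3 px is the smallest
   that removes single-pixel noise without eroding 2-px structures);
3. binarize the Golgi channel at an automatic threshold and the nucleus
   channel at its minimum intensity (`binarize_golgi`,
   `binarize_nucleus`);
4. fill interior holes (`fill_holes`) to obtain total areas;
5. per Golgi object, report `density = stacks area / hole-filled area`
   together with the hole-filled area relative to the nucleus area of
   the owning cell.

A compact Golgi ribbon has few interior gaps and scores near 1; a
fragmented Golgi whose pieces enclose background scores lower. The
pixel size cancels in the density ratio, so it is dimensionless and
comparable across magnifications.

Numerical choices worth stating explicitly:

* **Automatic threshold.** "Automatic" is implemented as Otsu's
  between-class-variance maximisation on a 256-bin histogram — the
  canonical parameter-free choice. When the histogram has an empty
  valley the objective is flat across it; `otsu_threshold()` returns the
  first maximiser. Any point of the plateau induces the same mask,
  which is what the tests assert when cross-checking against EBImage.
* **Nucleus threshold.** Strictly greater than the channel minimum
  after smoothing: every above-floor pixel belongs to the nucleus. This
  is deliberately permissive; the nucleus area only serves as a
  per-cell normalisation covariate.
* **Connectivity.** 8-connected foreground components, 4-connected hole
  detection — the standard complementary pair that avoids topological
  paradoxes (a diagonal crack neither splits an object nor drains a
  hole).
* **Speck removal.** Components below 0.05 um^2 (configurable) are
  discarded before densities are computed; they are segmentation noise
  at typical pixel sizes (0.05 um^2 is 5 px at 0.1 um/px).
* **Per-object statistics.** Density is computed per Golgi component,
  not per cell: one cell may legitimately carry several Golgi objects,
  and treating the object as the unit matches how such data are plotted
  (one point per Golgi).

An open design question was whether the nucleus-area normalisation
should divide the density itself. Since the density is a ratio of two
areas of the same object, dividing it by a third area changes its units
and meaning; we therefore emit **both** columns — the unnormalised
`density` and the `golgi_to_nucleus_ratio` — and leave the choice of
covariate adjustment to the analysis.

Group comparisons use the classical unpaired pooled-variance t-test
(`compare_groups`), with zero-variance degenerate inputs resolved by the
limit of the statistic rather than an error.

## Tissue-section Golgi areas (`golgi_area`)

Marker-positive regions are segmented with the same Otsu binarization,
labeled 8-connected, and measured as pixel counts times the squared
pixel size (`segment_regions`; regions below 0.2 um^2 are dropped).
Each region is classified against a 5 um^2 enlargement threshold with a
*strict* comparison — an area of exactly 5 um^2 is not enlarged
(`classify_area`). Tubule membership is taken from an annotation mask
(majority label over the region's pixels): seminiferous tubule staging
is a manual morphological call, and automating it is out of scope.
Stages are binned into the five groups II-III, IV, VI-VIII, IX, X-XII
(plus `unknown`).

Because tubules, not regions, are the experimental unit,
`summarize_by_stage()` first computes the percent of enlarged regions
per tubule and then averages across tubules (mean +/- s.e.m.); the
pooled region-level percentage is also reported for completeness, since
the two estimators differ when tubules contribute unequal region
counts. Two-condition comparisons run an unpaired t-test per stage on
the per-tubule percentages. `pseudocolor()` renders regions on a
continuous blue-to-yellow ramp by area with a distinct red class above
the threshold.

## Binding-assay computations (`assay_fits`)

**HTRF.** The acceptor/donor ratio R = A665/A615 is converted to the
background-corrected percent change `delta_f(R_sample, R_nsb) =
100 (R_s - R_nsb) / R_nsb`, and competition curves are normalised by the
no-competitor maximum (`normalize_competition`). Competition curves are
fitted with the variable-slope four-parameter logistic in log10 molar
concentration,

$$y = \mathrm{bottom} + \frac{\mathrm{top} - \mathrm{bottom}}
      {1 + 10^{(\log IC_{50} - x)\,h}},$$

by Levenberg-Marquardt least squares (minpack.lm). Starts come from the
response extremes and the interpolated half-maximum crossing, with the
Hill slope tried at both signs and seeded multistart jitter (default 8
starts) to escape local minima; the Hill slope and the bottom are left
unconstrained. `r_squared > 0.99` flags a fit as significant; flat
responses are returned with `r_squared = 0` and `significant = FALSE`
rather than erroring, so screening loops can proceed.

**DSF.** Melt curves are truncated at the global fluorescence maximum —
the post-peak decay reflects dye dissociation from aggregates and is
not part of the unfolding transition — and fitted with the Boltzmann
sigmoid `f_min + (f_max - f_min) / (1 + exp((Tm - T)/a))`, with Tm
bounded inside the data range. Thermal shifts are reported as
`delta_tm_c` against a reference (control) Tm. A curve that never rises
(no transition before its maximum) is an error, not a silent bad fit.

**ITC.** Integrated per-injection heats are modelled with the
differential one-site (Wiseman) isotherm: with total macromolecule
\(M_t\) (cell concentration), total injectant \(X_t\), stoichiometry
\(n\) and association constant \(K_A\), the bound fraction follows the
exact quadratic binding equation and the heat per mole of injectant is
\(\Delta H \, dB/dX_t\) in closed form (`wiseman_ndh`). The first
injection is discarded by default (the customary small priming
injection). Gibbs energy and entropy derive from
\(\Delta G = -RT\ln K_A\) and \(T\Delta S = \Delta H - \Delta G\) with
R = 8.314 J/(mol K), energies in kJ/mol; because they are derived, the
identity holds to machine precision on every fit. Fits with Wiseman
c-value \(K_A M_t n < 1\) are flagged low-confidence — below that the
isotherm is too shallow to pin the parameters independently.

## Hinge and normal-mode analysis (`hinge_analysis`)

The conformational comparison is CA-only — the convention of
hinge-analysis tools, and the only selection that is robust to differing
side-chain completeness between crystal structures. Models are parsed
from PDB files via bio3d (`read_structure`; waters dropped, alternate
locations resolved to the highest occupancy, one chain kept), and the
two domains default to residues 2-107 and 108-208, the PDZ-tandem
construct boundaries.

`hinge_metrics()` proceeds in three fixed steps: (1) superpose the
second model onto the first on the domain-1 CA pairs (Kabsch SVD
superposition with a determinant correction guaranteeing a proper
rotation); (2) report the domain-2 rmsd *in that frame*, without a
second fit — this is the displacement amplitude of the moving domain;
(3) report the effective hinge rotation as the angle of the best-fit
rigid rotation carrying domain 2 of one state onto the other,
`theta = acos((trace(R) - 1)/2)`, with the axis from the rotation's
fixed eigenvector (the antisymmetric part where defined, the +1
eigenvector at 180 degrees). Swapping the two states leaves both
metrics unchanged to numerical precision.

The elastic-network model is the anisotropic network flavor: unit
springs between CA pairs within a 10 A cutoff, the standard 3N x 3N
Hessian of super-element blocks \(-\hat d \hat d^T\), dense symmetric
eigendecomposition, rigid-body modes removed by eigenvalue gap (six for
generic geometries, fewer for degenerate ones such as a two-atom bond).
Overlaps between the lowest internal modes and the observed open-to-
closed displacement are normalised projections, so the squared overlaps
over any orthonormal subset sum to at most 1. Rotation-translation-block
variants used by some servers are intentionally not replicated; for
low-frequency inter-domain motions the plain ANM ranking is the
established baseline.

Reproducing the published open/closed comparison of the real PDZ-tandem
crystal structures requires the deposited PDB entries (ligand-free
3RLE; cargo-bound 5GMJ/5GMI). The package never downloads silently:
`fetch_pdb()` retrieves them on demand, and the acceptance test for
that comparison looks for the files under `inst/extdata/pdb/`. In an
offline environment that check reports the files as missing; all
geometric machinery behind it is validated on synthetic two-state
structures with known rotations instead. Note the deposited complexes
contain two molecules per asymmetric unit, so a chain choice is exposed
(`chain` argument) rather than guessed.

## Flow-cytometry gating (`flow_gating`)

DNA-content profiles of dissociated testis show four populations in
ascending stain intensity: elongated spermatids (condensed chromatin,
dimmest), round spermatids (1C), spermatogonia (2C) and primary
spermatocytes (4C). `fit_populations()` fits a 4-component
unequal-variance Gaussian mixture on log10 intensity — peak widths are
approximately proportional to the mean, so the log scale homogenises
them. EM (via mclust) is initialised deterministically: means at
empirical quantiles of the log-intensities, the initial 4C mean pinned
one log10(2) above the 2C mean (the DNA-content doubling, used for
initialisation only), then a few Lloyd re-centring passes that keep a
component's previous centre when it empties. We found model-based
hierarchical initialisation unreliable on such spiky, well-separated
1-D mixtures (it can split one peak and merge two others), whereas the
quantile/ploidy seeding is stable across the regimes the generator
produces. Components are labeled ES/RS/2C/4C by ascending mean; events
with maximum posterior below 0.5 (configurable) are left unassigned,
emulating debris exclusion; fits whose components collapse (vanishing
weight, or adjacent log-means closer than 0.1) carry a `degenerate`
flag instead of pretending four populations were resolved. Mixture
gating here is a reproducible substitute for manual gates, not a
reproduction of any particular manual gate boundary.

`compare_samples()` compares two conditions population by population
with unpaired t-tests on per-sample fractions and on absolute counts.

## The synthetic-data generators

The generators define the study conditions for every test; their
defaults are fixed once and not tuned against outcomes.

* **Cell images** (`gen_cell_image`): elliptical nuclei (8 x 6 um) with
  a smooth radial intensity falloff; Golgi fragments as quasi-circular
  exact pixel sets (the *n* pixels nearest the centre, so recorded
  areas equal pixel counts times px^2 exactly). A single fragment is a
  solid disc; *k* > 1 fragments form a slightly overlapping ring whose
  central gap becomes an interior hole of the union — this is what
  makes the density statistic respond to fragmentation. Overlapping
  ring pixels are partitioned by nearest fragment centre so the
  ground-truth masks stay pairwise disjoint. Intensity is confined to
  the planted masks with a soft interior profile (edge pixels just
  above half-maximum): the background is exactly zero at zero noise and
  pixel counts stay exact, while the thresholder still sees a soft
  edge. Noise is additive Gaussian clipped at zero; Poisson shot noise,
  optics (PSF), 3-D stacks and cell-boundary effects are deliberately
  not simulated — passing tests demonstrate correctness of the
  measurement chain, not robustness to real microscope physics.
* **Tissue images** (`gen_tissue_image`): annular tubules on a grid
  (diameter grown to fit the largest requested region, capped at
  100 um), planted quasi-circular regions realised to the nearest
  pixel, membership recorded. Regions too large for the tubule band are
  an error.
* **Assay curves** (`gen_curve`): the three fit models evaluated in
  closed form plus seeded noise, additive or multiplicative. At zero
  noise generation and fitting share the exact model, so noise-free
  recovery tests are exact by construction.
* **Two-state structures** (`gen_two_state`): two 10 A-radius uniform
  point clouds 24 A apart; the closed state rotates domain 2 about a
  chosen axis through the inter-domain midpoint, optionally followed by
  isotropic jitter. The default rotation angle is 33 degrees, the
  magnitude characteristic of PDZ-tandem closure.
* **Flow events** (`gen_flow_events`): a 4-component log-normal mixture
  with per-population arithmetic means (0.45, 1, 2, 4) — 1C:2C:4C in
  DNA proportion, ES dimmer than RS as condensed chromatin stains
  less — default fractions (0.3, 0.4, 0.2, 0.1) typical of juvenile
  testis profiles, and a common CV (default 0.05). No doublets, debris
  or scatter channels.

## Problem sizes and validation strategy

The test-suite sizes were chosen to make each statistical claim sharp
at desk scale: 100-replicate Monte-Carlo for IC50 recovery under 2%
multiplicative noise (median error a few percent, asserted < 15%),
50 noisy melts for the 0.3 degree Tm bound, 100 jittered structures for
the 1-degree hinge bound, 10^4 events for fraction recovery within
0.02, and 20+ cells per fragmentation level for the strict density
ordering 1 > 4 > 16 fragments. Every low-level primitive (median
filter, Otsu threshold, hole filling, component labeling/areas, Kabsch
rmsd, ENM eigenvalues) is additionally checked against an independent
brute-force oracle implemented in the test helpers, and against
EBImage / a quaternion method / a numeric Hessian where an independent
route exists.

## Known limitations

* The real-structure hinge comparison needs a one-time PDB download;
  offline, that single check is reported as unavailable.
* Tubule staging and tubule masks must be supplied; only the synthetic
  generator provides them automatically.
* The image pipelines are 2-D and intensity-threshold based; they do
  not attempt deconvolution, 3-D reconstruction, or cell segmentation
  beyond nearest-nucleus assignment.
* The minimum-intensity nucleus threshold presumes a flat dark
  background, as in background-subtracted micrographs (and the
  zero-noise generator). On images with substantial background noise it
  floods the background; subtract the background before running the
  density pipeline on such data. Components below 5 um^2 are discarded
  from the nucleus mask as a guard against residual speckle.
* Mixture gating reports model-based fractions; it does not reproduce
  manual gate boundaries drawn in cytometry software, and scatter-based
  debris/doublet exclusion is out of scope.
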