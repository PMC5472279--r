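# golgiquant

Quantitative pipelines for the cell biology of Golgi-mediated
spermatogenesis, for researchers who need the measurement chain — not
just the microscope or plate reader output. The package covers four
experimental modalities behind one consistent R interface:

* **Golgi morphology from fluorescence micrographs** — per-cell Golgi
  *density* in cultured cells (ratio of the binarized Golgi stacks area
  to the hole-filled total Golgi area, a dimensionless compactness
  score), and Golgi *area* distributions in tissue sections classified
  against a 5 µm² enlargement threshold and aggregated per seminiferous
  tubule stage.
* **PDZ-domain binding assays** — HTRF ratio algebra
  (ΔF = 100·(R_sample − R_NSB)/R_NSB) and variable-slope
  four-parameter-logistic competition fits
  (y = bottom + (top − bottom)/(1 + 10^((logIC₅₀ − x)·h)));
  differential scanning fluorimetry Boltzmann melts
  (f = f_min + (f_max − f_min)/(1 + exp((Tm − T)/a)));
  one-site Wiseman ITC isotherm fits with
  ΔG = −RT·ln K_A and TΔS = ΔH − ΔG.
* **Two-domain conformational analysis** — Kabsch superposition on
  domain 1, domain-2 rmsd in that frame, effective hinge rotation
  θ = acos((tr R − 1)/2), and anisotropic-network normal modes with
  overlaps against the observed transition.
* **DNA-content flow cytometry** — 4-component Gaussian-mixture gating
  on log10 stain intensity into elongated spermatids (ES), round
  spermatids (RS, 1C), spermatogonia (2C) and primary spermatocytes
  (4C), with per-population two-condition comparisons.

Every pipeline has a seeded synthetic-data generator with exact ground
truth (planted masks and areas, closed-form curves, constructed hinge
rotations, labeled event mixtures), so the full chain is testable
end-to-end with no external data.

## Worked example

Fragmentation lowers Golgi density; a competition curve fit recovers
its IC50; a constructed 33° hinge is recovered from coordinates alone:

```r
library(golgiquant)

solid <- gen_cell_image(n_cells = 3, fragments_per_cell = 1,
                        fragment_area_um2 = 12, pixel_size_um = 0.1,
                        seed = 42)
frag  <- gen_cell_image(n_cells = 3, fragments_per_cell = 8,
                        fragment_area_um2 = 1.5, pixel_size_um = 0.1,
                        seed = 42)
tab_s <- golgi_density(solid$image)
tab_f <- golgi_density(frag$image)
round(c(solid = mean(tab_s$density), fragmented = mean(tab_f$density)), 3)
#>      solid fragmented
#>      1.000      0.757
cmp <- compare_groups(tab_s$density, tab_f$density)
#> t = 280.78, p = 9.7e-10

d <- gen_curve(curve_ground_truth("4PL",
       list(top = 1, bottom = 0, logIC50 = log10(8.4e-6), hill = 1),
       noise_sd = 0.02, noise_type = "multiplicative", seed = 42),
     seq(-8.5, -2.5, length.out = 12))
fit_4pl(d$x, d$y, seed = 1)
#> 4PL fit: IC50 = 8.72e-06 M (logIC50 = -5.059), hill = 0.97,
#>   top = 1.03, bottom = -0.00143, R^2 = 0.9994 (significant)

ts <- gen_two_state(100, angle_deg = 33, axis = c(0.2, -0.4, 1),
                    jitter_sd = 0.1, seed = 42)
hinge_metrics(structure_from_coords(ts$open_coords),
              structure_from_coords(ts$closed_coords),
              domain_definition(c(1, 100), c(101, 200)))
#> hinge: rotation = 33.00 deg, domain-2 rmsd = 7.56 A
#>   (domain-1 fit rmsd 0.18 A, 100 + 100 CA pairs)

derive_thermo(K_A = 1 / 4.9e-6, delta_H = -40, T_kelvin = 298.15)
#> $delta_G
#> [1] -30.30672        # kJ/mol for a 4.9 uM dissociation constant
```

So: the solid Golgi scores density exactly 1 and the 8-fragment ring
0.76, a difference the pooled t-test resolves decisively at n = 3 per
group; the IC50 comes back within 4% of the generating 8.4 µM under 2%
multiplicative noise; and the hinge rotation is recovered to 0.01° at
0.1 Å coordinate jitter.

Applying the hinge analysis to real crystal structures only needs local
PDB files (e.g. fetched once with `fetch_pdb()`):

```r
h <- hinge_metrics(read_structure("3RLE.pdb"), read_structure("5GMJ.pdb"))
```

See `vignettes/golgi-quantification.Rmd` for the models, parameter
defaults, numerical choices and limitations.

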