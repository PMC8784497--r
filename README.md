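# pmmseg

Automated volumetry of the bilateral psoas major muscle (PMM) in abdominal
CT. The psoas volume (PMMV, cm³) is an opportunistic sarcopenia marker:
any abdominal CT depicts it, but manual segmentation is slow. `pmmseg`
implements and compares three automated segmentation routes plus the full
evaluation protocol, exercised end-to-end on a built-in synthetic CT
phantom cohort:

- **MAS** — multi-atlas segmentation: every annotated atlas is registered
  to the target by a dual-stage scheme (multi-resolution affine
  registration minimizing mean squared error, then a cubic B-spline
  free-form deformation maximizing mutual information); the five
  registrations with the lowest final energy (negative mutual
  information) propagate their masks, fused by strict-majority voting
  (a voxel is muscle iff found in > n/2 of the masks).
- **GAN** — a 2.5D adversarial slice segmenter: each axial slice, stacked
  with its neighbours above and below as three channels, is mapped to a
  mask by a U-Net generator trained against a patch discriminator with
  the loss `1.0 · L_GAN + 10.0 · L_L1`, where
  `L_GAN(G,D) = E_y[log D(x,y)] + E_x[log(1 − D(x, G(x)))]` and
  `L_L1(G) = E_{x,y}[‖y − G(x)‖₁]`, optimized with Adam (β₁ = 0.5).
- **COM** — their combination: the MAS mask dilated in-plane by 2 pixels,
  intersected voxel-wise (AND) with the GAN mask. The dilated atlas mask
  gates out the network's distant false positives; the network supplies
  the precise muscle borders.

Evaluation: PMMV = voxel count × voxel volume; Dice similarity
coefficient `2|A∩B|/(|A|+|B|)`; Spearman rank correlation; an exact
paired Wilcoxon signed-rank test; fivefold patient-level
cross-validation with bootstrap confidence intervals for median Dice.

Because the kind of clinical cohort this pipeline targets cannot be
redistributed, the package ships a seeded phantom generator
(`generate_cohort()`): body-like fat ellipses with a bone column and two
tapering muscle tubes, per-case smooth random deformations, per-case
volume variability and CT-like noise at 5 mm slice thickness. All tests
and the acceptance script run against these phantoms. See the methods
vignette (`vignettes/pmmseg-methods.Rmd`) for the model, parameter and
design details.

## Worked example

```r
library(pmmseg)

params <- phantom_params()                       # desk grid: 64 x 64 x 24 @ (2, 2, 5) mm
cohort <- generate_cohort(3, params, master_seed = 7)
case   <- cohort[[1]]
print(case$image)
#> image_volume 'case_001': 64 x 64 x 24 voxels @ (2, 2, 5) mm
cat("PMMV:", round(compute_volume(case$mask), 1), "cm^3\n")
#> PMMV: 34.8 cm^3

# multi-atlas segmentation of case 1 using cases 2-3 as atlas pool
atl <- lapply(cohort[2:3], function(cs) atlas(cs$image, cs$mask))
mas <- mas_segment(case$image, atl, k = 5, seed = 1)
cat("MAS DSC:", round(dsc(mas, case$mask), 3), "\n")
#> MAS DSC: 0.819
attr(mas, "energies")                            # per-atlas final energies (lower = better fit)
#> case_002 case_003
#>   -0.876   -0.774
```

The Dice of 0.82 against the ground-truth mask comes from registration
alone with a two-atlas pool; `run_experiment()` runs the full
cross-validated comparison. On the seed-1 desk cohort (10 phantoms,
fivefold CV) it prints:

```
truth: mean PMMV 27.5 +/- 6.4 cm^3 (n = 10)
GAN: median DSC 0.899 [0.874, 0.912], mean PMMV 28.6 cm^3 (+4.2%), rho 0.76, p 0.432
MAS: median DSC 0.872 [0.862, 0.884], mean PMMV 29.9 cm^3 (+8.6%), rho 0.64, p 0.193
COM: median DSC 0.915 [0.909, 0.918], mean PMMV 27.6 cm^3 (+0.3%), rho 0.84, p 0.846
```

The combined approach matches or beats both parts in median Dice, and
its cohort volume error (+0.3%) is far below the atlas pipeline's
(+8.6%) — the overlap-precision vs volume-robustness trade-off the
hybrid operator exists to resolve. (Last digits are machine-dependent;
runs are exactly reproducible per machine and seed.)

A thin command-line wrapper over the same functions ships in
`inst/cli/pmmseg` with subcommands `phantom`, `mas`, `gan-train`,
`gan-predict`, `fuse`, `evaluate` and `run-all`.

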