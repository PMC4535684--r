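# fishda

Quantification of **differential chromatin accessibility (DA)** between
homologous metaphase chromosomes from FISH images.

When a short single-copy FISH probe hybridizes to condensed metaphase
chromatin, its signal intensity reports how accessible the target locus is.
At some loci the two parental homologs differ reproducibly: the probe is
bright on one homolog and dim on the other in most cells. fishda implements
the image-analysis and statistics pipeline for detecting and quantifying
this effect, and for testing whether chromatin-modifying treatments (e.g. a
topoisomerase IIα inhibitor) abolish it.

## What it computes

Per cell, each probe signal is delineated with a **gradient vector flow
(GVF) active contour**: an edge map (gradient magnitude of the smoothed
probe image) is diffused into a force field

    u <- u + γ [ μ ∇²u − (u − f_x)(f_x² + f_y²) ]

whose snake equilibrium traces the spot boundary. Background-corrected
integrated intensities I_A, I_B inside the two contours give the
**normalized inter-homolog difference**

    d = |I_A − I_B| / (I_A + I_B)   ∈ [0, 1]

(0 = equal accessibility, 1 = signal absent on one homolog). A cell shows
DA when d ≥ 0.3; a locus is **called DA** when ≥ 2/3 of cells show DA with
a consistent weaker homolog (two-proportion z-test against the 0.5 null,
α = 0.05). Pre/post-treatment cohorts are compared with the same z statistic
signed so reductions are negative (z < −2 ⇒ significant reduction), the
group means Δμ, and a two-tailed Welch t-test on per-cell d.

A 3D module measures **hybridized probe depth and volume** per homolog from
reconstructed optical sections (depth = sections containing segmented
signal × axial step, e.g. 10 of 17 sections × 0.13 μm = 1.30 μm; volume =
voxel count × pixel² × step), with the same normalized-difference
comparison between homologs.

Because no public image data accompany this method, the package ships a
**synthetic scene generator** with exact analytic ground truth (Gaussian
spots, Poisson noise, seeded), which the tests and the acceptance script use
to exercise every stage end-to-end.

## Worked example

```r
library(fishda)

cfg <- run_config(
  locus_id = "demo_locus",
  scene_template = scene_spec(amplitude_bright = 200, amplitude_dim = 200,
                              background_level = 10, spot_sigma_xy = 2),
  pre_cohort  = cohort_spec(n_cells = 20, fraction_da_cells = 0.85, seed = 11L),
  post_cohort = cohort_spec(n_cells = 20, fraction_da_cells = 0.10, seed = 12L))
res <- run_pipeline(cfg)
cat(res$report, sep = "\n")
```

```
locus: demo_locus
cells measured: 40 (excluded by QC: 0)
pre:  16/20 cells DA (80.0%), direction A, z = 1.989, p = 0.0467, call = TRUE
post: 4/20 cells DA (20.0%), direction A, z = -1.989, p = 0.0467, call = FALSE
pre/post: z = -3.795 (significant reduction: TRUE), delta-mu 0.476 -> 0.216, t = 3.535 (p = 0.001101)
```

Reading it: in the untreated cohort 80% of cells exceeded the per-cell
threshold with homolog A consistently weaker, so the locus is called DA; in
the treated cohort only 20% did and no call is made. The pre/post
two-proportion z of −3.795 (< −2) declares the reduction significant, and
the mean normalized difference drops from 0.476 to 0.216 (Welch t = 3.535,
p = 0.0011). Per-cell rows carry the raw integrated intensities:

```
  cell_id intensity_A intensity_B normalized_difference weaker_homolog
 cell_001        2374        6999             0.4934386              A
 cell_002        1243        8150             0.7353348              A
 cell_003        2029        7403             0.5697625              A
```

## Analysis scripts

`analysis/01_simulate_cohorts.R` … `04_volumetrics_3dsim.R` run the full
study workflow at desk scale — simulate untreated/treated cohorts, segment
and quantify them, compute the locus statistics and figure, and measure 3D
probe depth/volume per homolog — writing tables under `results/`. Each is a
thin driver over the package functions and runs standalone.

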