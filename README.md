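# windowquant

Quantification of longitudinal, multichannel z-stack fluorescence imaging
from dorsal skinfold window chambers — the preclinical setup used to watch
diffusely growing, collectively migrating tumor-cell clusters (the
inflammatory breast cancer phenotype) interact with lymphatic and blood
vessels in vivo.

For imaging scientists and tumor biologists who need per-timepoint
population statistics of a cluster field rather than a single tumor volume,
the package turns raw 16-bit multi-page TIFF z-stacks into:

- **Tumor-cluster morphometry** — after exposure normalization, focus
  fusion of each 10-plane stack, thresholding at background mean + 2 sd,
  and morphological cleanup, every 8-connected component with area
  strictly > 50 px² is a cluster. Per cluster: area *A* (mm²), equivalent
  circular diameter *d* = 2√(*A*/π), distance of its centroid to the
  area-weighted center of mass, distance to the implantation site, and the
  **area moment** = distance × area (mm³), a summary of directional growth.
  Per timepoint: count, total area, and mean ± SEM of each quantity.
- **Linear vessel density** — summed vessel centerline length divided by
  ROI area (mm/mm² = mm⁻¹), either from hand-traced centerline CSVs or
  automatically by skeletonizing a vessel mask (endpoint-extended
  Zhang–Suen thinning traced into polylines).
- **Channel overlap** — tumor-on-lymphatic and lymphatic-on-tumor mask
  fractions, quantifying colocalization.

Because the original study distributes no images, the package includes a
first-class, seeded **synthetic scene generator**: ground-truth ellipse
clusters that drift away from the implantation site, grow, and fragment
(or stay put, as a control), tortuous vessels, a smooth in-focus plane map
with per-plane defocus blur, exposure variation, and optional coverslip
scratch artifacts — rendered to the same 16-bit multi-page TIFFs the
pipeline consumes, with truth tables for every quantity. All validation is
recovery against this truth.

## Worked example

```r
library(windowquant)

demo <- make_demo("demo_mig", scenario = "migrating", seed = 1)   # render scene
res  <- process_series(demo$manifest, output_dir = "results/migrating")
res$summary[, c("timepoint_hours", "n_clusters", "total_area_mm2",
                "mean_distance_origin_mm", "mean_moment_mm3")]
```

```
  timepoint_hours n_clusters total_area_mm2 mean_distance_origin_mm mean_moment_mm3
1               0         12         0.0664                   0.209         0.00117
2              24         13         0.0767                   0.237         0.00139
3              48         13         0.0890                   0.262         0.00179
4              72         15         0.1028                   0.282         0.00199
5              96         15         0.1209                   0.307         0.00254
```

Twelve clusters are implanted; over four simulated days they fragment to
fifteen, total area nearly doubles, and the mean distance to the
implantation site rises monotonically from 0.209 to 0.307 mm — the
dispersing phenotype. The measured counts match the ground truth exactly at
every timepoint (`12 13 13 15 15`), and the same pipeline on the stationary
control scenario returns a constant 12 clusters with distances flat at
0.209 mm. Lymphatic skeleton density for this scene is ≈ 5.9 mm⁻¹ across
timepoints.

The numbered drivers under `analysis/` reproduce this end to end:
`01_simulate_scenes.R` (render both phenotypes), `02_process_series.R`
(quantify them against truth), `03_figures.R` (longitudinal figures),
writing tables under `results/`.

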