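# pancmotion

Quantification of breathing-induced pancreas motion from dynamic (4D) MRI.

Respiratory motion displaces the pancreas by several millimeters — enough to
matter for gated particle therapy, where dose is delivered only in a
respiratory gate. This package implements the full analysis chain for
dynamic 2D multi-slice MR acquisitions:

* **Retrospective 4D reconstruction** — an image-based respiratory
  surrogate is extracted as the mutual information (MI) between each
  acquired slice and a self-consistent reference volume; a global harmonic
  fit of the pooled surrogate yields each slice's breathing-cycle fraction,
  which is binned into 6 phases (phase 1 = end inhalation) and assembled
  into one volume per phase.
* **Head/body/tail partition** — Lloyd k-means (k = 3) on the mask voxel
  coordinates in mm, with each phase initialized from the previous phase's
  centroids and phase 1 re-run from the last phase to cancel
  initialization effects.
* **Segmentation-reliability indexes** — Pearson correlation of
  COM-registered integral map profiles (the 1D marginals of the binary map
  along LL/AP/SI), and volume consistency `100 (Vmax − V) / Vmax`,
  summarized as median ± IQR across phases.
* **COM motion** — the phase-stability index
  `(|COM(ph−1) − COM(ph)| + |COM(ph+1) − COM(ph)|) / 2` selects the most
  stable (reference/gating) phase; motion is the per-phase COM displacement
  relative to it, per direction and in 3D.
* **Setup statistics** — Friedman rank tests (tie-corrected, with an exact
  permutation option) and Conover's Fisher-LSD-style post-hoc comparisons
  with homogeneous-group symbols, comparing prone vs supine positioning,
  immobilization devices (vacuum cushion, thermoplastic mask, compressor
  belt) and the pancreas vs its segments.

A digital breathing phantom (`generate_phantom()`) and an interleaved
multi-slice acquisition simulator (`simulate_dynamic_acquisition()`)
provide exact ground truth, so the whole pipeline is testable without any
patient data. Real data enter as per-phase NIfTI masks (`read_mask4d()`)
or a NIfTI dynamic stack with a CSV sidecar (`read_dyn_series()`).

## Worked example

```r
library(pancmotion)

bundle <- run_pipeline(pipeline_config(seed = 1), out_dir = "demo_out")

bundle$phase_accuracy           # fraction of slices sorted to the true or
#> [1] 1                        # an adjacent breathing phase

attr(bundle$records, "ref_phase")
#> [1] 3                        # most stable phase = early exhalation

bundle$reliability[, c("structure", "pearson_LL_median", "pearson_SI_median",
                       "volume_cc_median", "volume_consistency_median")]
#>   structure pearson_LL_median pearson_SI_median volume_cc_median volume_consistency_median
#> 1  pancreas             0.996             0.992            20.59                    1.0263
#> 2      head             0.998             0.986            10.11                    1.3629
#> 3      body             0.997             0.988             4.75                    0.5734
#> 4      tail             0.996             0.997             5.87                    0.0932

subset(bundle$motion_summary, structure == "pancreas",
       c(LL_median, LL_iqr, AP_median, AP_iqr, SI_median, SI_iqr))
#>   LL_median LL_iqr AP_median AP_iqr SI_median SI_iqr
#> 1       1.1    2.1      0.48   0.73       1.8    2.8
```

Reading the output: all 750 simulated slices were sorted to their true or a
cyclically adjacent phase; phase 3 (early exhalation, the flattest part of
the breathing waveform) is selected as the reference/gating phase; profile
correlations near 1 and volume consistency near 1% say the re-segmented
4D masks keep shape and volume across phases; the pancreas COM moves a
median ~1-2 mm in LL and SI and well under 1 mm in AP relative to phase 3,
matching the phantom's built-in amplitudes. `demo_out/` receives the phase
volumes and label maps (NIfTI), the reliability, motion and symbol tables
(CSV), the surrogate signal and a JSON run log.

Cohort-level statistics:

```r
records <- build_synthetic_cohort(prone_si_factor = 2, seed = 1)
suite <- build_comparison_suite(records, scope = "pooled")
render_symbol_table(suite)   # Table-style homogeneous-group symbols
```

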