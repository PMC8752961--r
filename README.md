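# twroi — tissue-weighted ROI means for multi-compartment diffusion MRI

Region-of-interest (ROI) analysis of diffusion-MRI microstructure metrics
usually summarises a fitted parameter map (e.g. NODDI's neurite density
index NDI or orientation dispersion index ODI) by its arithmetic mean over
the ROI voxels. Multi-compartment models, however, estimate these metrics
as properties of the *tissue* compartment of each voxel, alongside a
tissue volume fraction TF = 1 − FWF (free water fraction). Wherever an ROI
contains voxels with CSF partial volume — periventricular white matter,
atrophied brains with enlarged ventricles — the equal-weight mean
over-weights voxels that contain little tissue, and mis-states the mean
microstructure of the region's tissue.

`twroi` implements the corrected summary statistic and everything needed
to use and validate it:

- **Tissue-weighted mean.** For voxelwise metric values m_i and tissue
  fractions t_i over the N voxels of an ROI:

  m̄ₜ = Σᵢ tᵢ mᵢ / Σᵢ tᵢ  =  (t m̄) / t̄,

  an unbiased estimate of the mean metric over the ROI's tissue.
- **Closed-form bias of the conventional mean.** With the population
  covariance Cov(m, t) (denominator N, not N − 1):

  m̄ − m̄ₜ = −Cov(m, t) / t̄.

  The bias is positive under negative metric–TF correlation, vanishes
  when Cov(m, t) = 0, and grows as mean TF falls, i.e. as CSF
  contamination increases.
- **ROI extraction** from NIfTI parameter maps plus an integer label
  image (with a packaged 48-region JHU white-matter ROI table including
  periventricular flags), producing fixed-format per-subject CSV tables.
- **Group analysis workflow**: Welch t-tests on mean TF, one-sample and
  between-group bias tests, Pearson correlation of bias magnitude with
  1/TF, periventricular vs non-periventricular comparison, and Cohen's
  d_s effect sizes computed from both estimators — all with Bonferroni
  correction across ROIs.
- **Synthetic phantoms and cohorts** with exact ground truth: fine-grid
  phantoms whose block-downsampling reproduces the partial-volume
  mechanism analytically, and a seeded two-group cohort generator
  (default 21 vs 30 subjects, 48 ROIs, two metrics) writing NIfTI
  volumes and tables.
- A command-line interface (`inst/bin/twroi`) with `roistats`, `group`
  and `simulate` subcommands.

Audience: imaging scientists running ROI studies on NODDI-like metrics —
particularly group comparisons where the groups differ in atrophy or
ventricle size — and methodologists validating partial-volume corrections.

## Worked example

A two-voxel ROI where the first voxel is half CSF:

```r
library(twroi)
s <- roi_sample(metric_values = c(0.55, 0.60),
                tissue_fractions = c(0.5, 1.0),
                metric_name = "NDI", roi_label = "GCC")
summarise_roi(s)
#> <roi_summary> GCC / NDI (N = 2)
#>   conventional mean    0.575000
#>   tissue-weighted mean 0.583333
#>   bias                 -0.008333
#>   mean tissue fraction 0.7500
```

The conventional mean (0.575) over-weights the half-CSF voxel's lower
NDI; weighting by tissue content gives 0.5833, so the arithmetic mean
under-estimates the tissue's NDI by 0.0083 — exactly
−Cov(m, t)/t̄ = −0.00625/0.75.

A full synthetic cohort, and how much the choice of estimator moves
group effect sizes (control-minus-patient Cohen's d_s):

```r
cfg <- cohort_config(seed = 42)          # 21 vs 30 subjects, 48 ROIs
sim <- simulate_cohort(cfg)
es  <- effect_size_comparison(sim$cohort, contrast = c("control", "patient"))
head(es[order(-abs(es$difference)), 
        c("roi","metric","d_conventional","d_tissue_weighted","difference")], 5)
#>      roi metric d_conventional d_tissue_weighted difference
#>     EC-R    ODI           2.28              2.54     -0.264
#>     CP-R    ODI           2.08              2.33     -0.249
#>  FX-ST-R    ODI           2.21              2.46     -0.249
#>   RLIC-R    NDI           2.43              2.68     -0.247
#>      MCP    ODI           2.20              2.44     -0.246
```

Because the simulated patients carry more CSF partial volume and a more
negative metric–TF covariance, their conventional means are inflated and
the control-minus-patient effect size is under-estimated by up to ~0.26
standard deviations in the worst regions. The bias magnitude tracks the
inverse mean TF across regions:

```r
bias_tf_correlation(sim$cohort, contrast = c("control", "patient"))
#>  metric   group     r  p_value  n
#>     NDI control 0.911 2.79e-19 48
#>     NDI patient 0.976 2.63e-32 48
#>     ODI control 0.963 9.87e-28 48
#>     ODI patient 0.977 1.56e-32 48
```

From the shell, the same pipeline is:

```sh
twroi simulate --config config.yaml --seed 42 --outdir sim/
twroi roistats --metric NDI=sub-001_NDI.nii.gz --metric ODI=sub-001_ODI.nii.gz \
               --tf sub-001_tf.nii.gz --labels labels.nii.gz \
               --subject-id sub-001 --group control --out sub-001.csv
twroi group --table cohort.csv --contrast control,patient --outdir results/
```

(`twroi` is `system.file("bin", "twroi", package = "twroi")`; real FWF
maps are accepted with `--tf-kind freewater`.)

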