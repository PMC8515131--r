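# bpequant

Automated quantification of **fibroglandular tissue (FGT)** and
**background parenchymal enhancement (BPE)** from dynamic contrast-enhanced
(DCE) breast MRI, for imaging scientists studying BPE as a quantitative
marker of breast-cancer risk.

From one pre-contrast fat-suppressed T1-weighted volume and three
post-contrast volumes (60 / 180 / 300 s, k-space centre time) the package
measures, per breast:

- **FGT** = V<sub>fibroglandular</sub> / V<sub>breast</sub>
- **BPE_V**(p) = V<sub>enhanced</sub>(p) / V<sub>fibroglandular</sub> — the
  enhancing fraction of FGT at phase p
- **BPE_I**(p) = mean over enhanced voxels of
  I<sub>subtraction</sub> / I<sub>original</sub>

via a three-step segmentation scheme:

1. **whole breast** — per-slice dynamic-programming tracing of the skin
   line and chest wall on a gradient cost map, with a cross-slice
   continuity prior (`segment_whole_breast()`);
2. **FGT** — fuzzy c-means clustering of breast intensities with automatic
   cluster-number selection by the Xie-Beni index (`segment_fgt()`);
3. **enhanced FGT** — thresholding of the post-minus-pre subtraction image
   at k·σ, with σ estimated robustly from non-enhancing tissue
   (`segment_enhanced_fgt()`).

Controls are measured as the mean of both breasts; benign/cancer subjects
as the breast contralateral to the lesion.  The statistical layer provides
greedy 1:1 matched-cohort construction (age ≤ 5 y, menopausal status,
menstrual week), Mann-Whitney U comparisons and the nonparametric
(pair-counting) AUC, per metric, menopausal stratum and phase.

Because no patient data ship with the package, a digital phantom generator
(`make_phantom()`, `make_cohort()`) produces bilateral breast phantoms with
exact ground-truth masks and cohorts with the case–control structure of the
source study (396 subjects: 3 × 132, with 62 premenopausal per group in
menstrual-week strata 13/16/15/18), so the whole pipeline is testable end
to end.

## Worked example

Simulate one subject and push it through the full measurement chain:

```r
library(bpequant)

spec <- phantom_spec(seed = 42)        # 96^3 grid, FGT 16.4%, noise sigma 5
ph   <- make_phantom(spec)
q    <- quantify_series(ph$series)     # the three-step pipeline
select_measurement("control", q$left, q$right)
#> Quantitative metrics (combined breast)
#>   FGT:    16.5%
#>   BPE_V:  30.6%  48.2%  54.3%  (60/180/300 s)
#>   BPE_I: 0.264 0.323 0.359

true_metrics(ph$gt)                    # ground truth from the phantom masks
#> Quantitative metrics (combined breast)
#>   FGT:    16.4%
#>   BPE_V:  30.5%  48.1%  54.3%  (60/180/300 s)
#>   BPE_I: 0.265 0.323 0.359
```

The measured FGT fraction is within 0.1 percentage points of truth, the
enhancing fractions track the constructed per-phase values, and the
intensity ratios recover the constructed enhancement ratios.  A full
cohort-level run — simulation, segmentation, laterality selection, group
tables — is one call:

```r
run <- run_pipeline(run_config(seed = 1, out_dir = "out"))
run$comparisons   # cancer-vs-control / cancer-vs-benign rows with median %, U, p, AUC
```

A thin command-line wrapper is installed under `inst/cli/bpequant`
(`bpequant simulate|run|segment|quantify|analyze`).

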