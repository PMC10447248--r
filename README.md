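# batquant

Quantification of human brown adipose tissue (BAT) from co-registered
PET–MRI and PET–CT, plus the physiology metrics that accompany
cold-exposure studies of BAT activation (cold-induced thermogenesis,
supraclavicular thermal imaging, extracellular-flux respirometry).

## Who this is for

Imaging scientists and physiologists who quantify cold- or drug-modulated
BAT glucose uptake. The package turns the semi-automated analysis usually
spread across interactive imaging tools into a reproducible, tested
pipeline, and ships a synthetic phantom generator with voxel-level ground
truth so the whole chain can be validated end to end.

## The method

**PET–MRI branch.** From co-registered Dixon fat/water images and a PET
activity map (kBq/ml):

1. Fat-fraction map: FF(%) = 100 · SI_fat / (SI_fat + SI_water), with
   zero-signal voxels flagged invalid rather than set to 0.
2. 3×3×3 median spatial filter (reflect-padded, validity-aware).
3. Adipose mask: keep FF ≥ 50 %.
4. PET mask: SUV_lean ≥ 1.2 g/ml (BARCIST), with SUV_lean =
   activity / (dose / LBM) and LBM from the Janmahasatian formula
   (male 9270·W/(6680 + 216·BMI), female 9270·W/(8780 + 244·BMI)).
5. Intersection, optional exclusion masks (e.g. brain), depot tagging
   (cervical/supraclavicular/axillary grouped as "supraclavicular";
   paraspinal separate).
6. Binary erosion with a (3, 3, 1) in-plane structuring element to strip
   PET blooming; metrics are reported pre- and post-erosion.
7. Per-depot metrics: SUV_mean (g/ml), BAT volume (ml), total uptake
   (SUV_mean × volume) and mean fat fraction (%).

**PET–CT branch.** BAT voxels are those with SUV_bw > 1.5 g/ml
(body-mass normalized, strict) *and* CT radiodensity in [−190, −10] HU;
a scan with at least `min_voxels` such voxels (default 1) is
BAT-positive, and SUV_mean/volume are reported for positives.

**Physiology.** Energy expenditure per 15-min hood measurement discards
the first 5 min and averages the final 10; CIT = EE_cold − EE_warm.
Thermal imaging summarizes left/right supraclavicular and sternal ROI
means as a mean-of-means per condition. Seahorse OCR metrics (basal,
noradrenaline-stimulated, uncoupled, maximal) are computed after
subtracting non-mitochondrial respiration (post rotenone/antimycin A).

## Worked example

```r
library(batquant)

# a synthetic subject: Dixon fat/water + PET + CT + ground-truth labels
bundle <- generate_phantom(default_phantom_spec(seed = 3))
res <- run_mri_pipeline(bundle$fat, bundle$water, bundle$pet,
                        bundle$subject, bundle$depot_regions,
                        exclusions = bundle$brain_mask)
subset(res$metrics, !eroded)
#>             group eroded voxel_count suv_mean volume_ml total_uptake fat_fraction_pct
#> supraclavicular  FALSE         458 6.156587  7.156250     44.05807               70
#>      paraspinal  FALSE         347 6.156587  5.421875     33.38024               70
#>        combined  FALSE         805 6.156587 12.578125     77.43831               70
```

The phantom programs its BAT depots at SUV_lean 4.0 and fat fraction
70 %; on the default body-weight reporting scale the recovered SUV_mean
is 4.0 × weight/LBM = 6.16 g/ml for this 65-kg subject, the volume is
the depot voxel count times the 2.5-mm voxel volume, and the fat
fraction is recovered exactly. Against ground truth:

```r
evaluate_recovery(bundle$truth, res$segmentation)
#>             group dice volume_error_pct
#>   supraclavicular    1                0
#>        paraspinal    1                0
```

Physiology, from condition-level group means (kcal/day and °C):

```r
compute_cit(ee_warm = 1477, ee_cold = 1635)        # 158
cold_induced_change(warm = 35.4, cold = 34.4)      # -1.0
temperature_differential(scv = 34.4, sternal = 32.7)  # 1.7
```

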