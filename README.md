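# voiquant

Total-activity quantification in emission tomography by volume-of-interest
expansion, with a fully digital validation phantom.

## The problem

Quantitative SPECT/CT (and PET) reconstructions carry voxel values in
activity concentration (Bq/ml), and the total activity of a lesion or organ
is the input to internal dosimetry for radioisotope therapies (Y-90,
Lu-177, I-131, ...). Finite spatial resolution smears activity across the
object boundary (the partial volume effect), so a VOI drawn at the true
boundary underestimates the total — by 20% or more even for a 6 cm sphere
on a clinical SPECT system. The traditional fix, multiplicative recovery
coefficients, is strongly size-, system- and algorithm-dependent and needs
per-configuration calibration.

`voiquant` implements the alternative: **expand the VOI until it captures
the spill-out, then subtract the background sampled from a surrounding
shell**. For a spherical VOI at the object's true boundary (VOI1), an
expanded sphere defines the spill-out capture shell (VOI2), and a further
expansion defines a background-sampling shell (VOI3). The estimate is

```
A_corr = A + A_SP - V_SP * B_mean
```

where `A` is the activity in VOI1, `A_SP` and `V_SP` the activity and
volume of VOI2, and `B_mean` the mean concentration in VOI3. The background
is subtracted over VOI2 only — the object's interior contains no
background, so spill-in into VOI1 is deliberately left uncorrected. All
expansions are **diameter** increments: a "20 mm expansion" adds 10 mm of
radial margin. The accuracy metric is the true fraction
`TF = A_corr / true activity`; the zero-expansion TF is the traditional
recovery coefficient.

Because the physical validation used fillable hot spheres in a customized
IEC body phantom, the package ships a digital analogue: six spheres of
10–60 mm diameter, ≥ 30 mm surface separation, ~12 µCi/ml (444 000 Bq/ml),
background ratios 8:1 / 4:1 / 2:1 / none, voxelized at 3.2 mm, imaged by a
count-conserving Gaussian effective PSF (default FWHM 12 mm) with optional
Poisson counting noise, counts↔Bq/ml calibration, and an optional
edge-enhancement artifact. Everything is generated in code; ground truth
is known in closed form.

## Worked example

```r
library(voiquant)
spec  <- iec_phantom_spec(sphere_background_ratio = 8)   # 8:1 phantom
truth <- voxelize(spec)                                  # ground truth, Bq/ml
recon <- simulate_recon(truth, fwhm_mm = 12)             # effective PSF blur
tab   <- quantify_phantom(recon, spec, expansion_mm = 20,
                          background_ring_mm = 10)
tab[, c("sphere_id", "diameter_mm", "A_corr", "true_activity", "TF")]
#>   sphere_id diameter_mm   A_corr true_activity     TF
#> 1       S10          10   205915        232478 0.8857
#> 2       S20          20  1760104       1859823 0.9464
#> 3       S30          30  6076456       6276902 0.9681
#> 4       S40          40 14522988      14878583 0.9761
#> 5       S50          50 28535970      29059732 0.9820
#> 6       S60          60 49451658      50215217 0.9848
```

TF is close to 1 for the 20–60 mm spheres: the expanded VOI recovers the
total activity nearly independently of sphere size, where the bare
(zero-expansion) recovery coefficient is strongly size-dependent — 0.73
for the 40 mm sphere below. A single sphere in detail:

```r
s40 <- spec$spheres[[4]]
quantify_sphere(recon, voi_sphere(s40$center, 40, "S40"),
                expansion_mm = 20, background_ring_mm = 10,
                true_activity = true_activity(s40))
#> <quant_result> VOI 'S40' d=40 mm, expansion +20 mm, ring +10 mm
#>   A = 1.08747e+07 Bq, A_SP = 8.24509e+06 Bq, V_SP = 79.61 ml, B_mean = 57745 Bq/ml
#>   A_corr = 1.4523e+07 Bq, TF = 0.9761
recovery_coefficient(recon, voi_sphere(s40$center, 40), true_activity(s40))
#> [1] 0.7308986
```

The study drivers reproduce the validation programs:
`expansion_sweep()` (TF vs expansion size at zero background, with the
smallest sufficient expansion as a derived summary),
`background_study()` (TF and RC per background ratio, with a mean-TF
summary over the benign conditions), and `experiment_matrix()` (the
acquisition/reconstruction bookkeeping of the two-scanner experiment).
A thin command-line front-end is included:

```sh
Rscript inst/cli/voiquant.R phantom build --ratio 8:1 --spec spec.yaml --out truth.nii.gz
Rscript inst/cli/voiquant.R simulate --truth truth.nii.gz --fwhm 12 --out recon.nii.gz
Rscript inst/cli/voiquant.R quantify --recon recon.nii.gz --spec spec.yaml --out results.csv
Rscript inst/cli/voiquant.R study matrix
```

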