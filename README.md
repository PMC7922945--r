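# mvmseg

Automated left-ventricular myocardium segmentation and velocity
quantification for three-directional cine myocardial velocity mapping
(3Dir MVM) cardiac MR.

3Dir MVM acquires, for every frame of the cardiac cycle, a magnitude image
plus three phase images encoding tissue velocity along three orthogonal
directions. Turning these data into clinical measurements requires
delineating the myocardial ring — epicardial and endocardial borders — on
every one of the ~50 frames per slice, a task that takes an expert up to an
hour per slice by hand. `mvmseg` is for researchers building or evaluating
automated pipelines for such data. It provides:

* **Four segmentation networks** over a compact CPU convolutional engine:
  plain U-Nets on magnitude (`u_m`), phase (`u_p`) or stacked channels
  (`u_mp`), and a dual-encoder network (`amu_mp`) in which magnitude and
  phase streams are fused at every depth by a multi-channel attention block
  (concatenate → encoder-style convolution block → additive attention gate)
  before entering a single decoder. Training follows a fixed protocol:
  per-pixel cross-entropy, Adam (α = 0.001, β₁ = 0.9, β₂ = 0.999,
  ε = 1e-7), batch size 8, 5 epochs, flip/rotation augmentation, five-fold
  cross-validation by slice.
* **Ring repair**: predictions violating the closed-ring topology expected
  of a healthy short-axis myocardium are regressed into an ellipse by the
  numerically stable direct least-squares conic fit and a 3-pixel ellipse
  ring is overlaid to close gaps; the largest and second-largest closed
  contours then give the epicardium and endocardium.
* **Velocity quantification**: per-pixel decomposition into longitudinal,
  radial and circumferential components about the cavity centroid; global
  and six-sector velocity–time curves; the clinical peak markers
  PS/PD/PAS (longitudinal, radial) and C1/C2/C3 (circumferential), found
  as window-restricted local extrema,

  DSC(S_auto, S_gt) = 2 |S_auto ∩ S_gt| / (|S_auto| + |S_gt|),

  and agreement statistics between two marker sources: two-way mixed
  single-score ICC with the excellent/good/fair/poor bands, Bland–Altman
  bias and 95% limits of agreement, and exact-enumeration Wilcoxon
  signed-rank tests for model comparison.
* **A synthetic cine phantom** — a contracting, near-elliptical myocardium
  annulus with closed-form velocity profiles — giving analytically known
  masks, curves and peaks for end-to-end testing, plus corrupted-mask
  fixtures for the repair stage.

## A worked example

```r
library(mvmseg)

cfg <- phantom_config(noise_sd = 0.5, seed = 42)
ph  <- generate_phantom_dataset(cfg, n_slices = 3)
ph$slice[[1]]
#> <mvm_cine_slice sub01/slice001: 64x64 px, 50 frames, 4 channels, RR 1000 ms>

# break a ring and repair it
frame  <- ph$mask[[1]]$labels[, , 1]
broken <- corrupt_mask(frame, "wedge_gap", rng_seed = 1, gap_deg = 70)
c(broken = is_broken(broken), repaired_ok = !is_broken(repair_mask(broken)))
#>      broken repaired_ok
#>        TRUE        TRUE

# velocity curves and clinical peak markers from mask + phase channels
curves <- compute_curves(ph$slice[[1]], ph$mask[[1]])
peaks  <- extract_peaks(curves)
dplyr::filter(peaks, region == "global")
#> # A tibble: 9 × 6
#>   region direction       marker value_cm_s time_ms frame
#>   <chr>  <chr>           <chr>       <dbl>   <dbl> <int>
#> 1 global circumferential C1           1.87      80     5
#> 2 global circumferential C2          -2.34     300    16
#> 3 global circumferential C3           1.81     540    28
#> 4 global longitudinal    PS           8.88     140     8
#> 5 global longitudinal    PD         -11.7      560    29
#> 6 global longitudinal    PAS         -4.87     860    44
#> 7 global radial          PS          -3.57     140     8
#> 8 global radial          PD           3.54     560    29
#> 9 global radial          PAS          1.53     860    44

# agreement of the measured markers with the phantom's analytic truth
truth <- ph$truth_peaks[[1]]
m <- dplyr::inner_join(dplyr::filter(peaks, region == "global"), truth,
                       by = c("direction", "marker"),
                       suffix = c("_measured", "_truth"))
agreement_report(m$value_cm_s_truth, m$value_cm_s_measured)
#> # A tibble: 1 × 6
#>       n   icc icc_class    bias loa_low loa_high
#>   <int> <dbl> <chr>       <dbl>   <dbl>    <dbl>
#> 1     9 1.000 excellent 0.00102 -0.0195   0.0215
```

The nine global markers (systolic, early-diastolic and atrial-systolic
peaks of the longitudinal and radial curves; the two systolic peaks and the
early-diastolic peak of the circumferential curve) land at their prescribed
times and amplitudes, and the measured-vs-truth agreement is near-perfect:
ICC ≈ 1 ("excellent", i.e. > 0.75) with a bias of ~0.001 cm/s and limits of
agreement of ±0.02 cm/s.

Training and cross-validating the networks uses the same phantom data:

```r
spec <- net_spec("amu_mp", depth = 3, base_filters = 8)
cv   <- cross_validate(ph, spec, train_config(epochs = 5, seed = 1), k = 3)
glance(cv)          # mean per-frame Dice across held-out slices
tidy(cv, "slice")   # pooled per-slice Dice records
```

or, end to end from one configuration, `run_pipeline()` /
`inst/cli/mvmseg run --config cfg.yaml` (simulate → crossval → postprocess
→ velocity → evaluate, each stage writing its artifacts and a JSON run
manifest).

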