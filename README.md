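# roatrack

Spatiotemporal analysis of muscle fatigue from high-density surface EMG
(HD-sEMG): track the centroid of the region of activation (RoA) across an
electrode grid during a sustained isometric contraction, and quantify how the
muscle redistributes its activity with a suite of trajectory metrics adapted
from centre-of-pressure (CoP) posturography.

Intended users are biomedical signal-processing and neurophysiology
researchers working with gridded surface EMG of fatiguing contractions
(e.g. trunk-extensor endurance protocols), who need reproducible
segmentation, per-segment fatigue indices and endurance-time statistics.

## Method

From each monopolar channel a 500-ms RMS envelope is extracted
(20–450 Hz bandpass + 50 Hz notch first, all filters zero-phase). Every
envelope frame becomes an amplitude topography on the fused 26x5 grid
(8 mm pitch, 200 x 32 mm), and the **RoA** of a frame is the
amplitude-weighted centroid of the cells at or above 70% of the map maximum:

    RoA = sum(a_i * r_i) / sum(a_i)   over cells with a_i >= 0.7 * max(a)

with r_i the cell position in mm along the fiber-transverse (FT, x) and
fiber-parallel (FP, y) directions. The contraction is delimited from the
low-pass-filtered torque trace (quasi-zero windows around the ramp and
failure transients), and three 10-s segments T1 / T2 / T3 sample its
beginning, middle and end. On the RoA trajectory (u[n], v[n]) of each
segment (N frames, duration T, deviations x, y from the reference):

| metric | definition | CoP analogue |
|---|---|---|
| AID (mm) | mean sqrt(x² + y²) from the baseline position | MDIST |
| AIP (mm) | total path length sum sqrt(du² + dv²) | TOTEX |
| AIV (mm/s) | AIP / T | MVELO |
| AIS (mm) | sqrt(std_FT² + std_FP²) | RDIST |
| AEZ (mm²) | 2π F(.95; 2, N−2) sqrt(s_u² s_v² − s_uv²) | AREA-CE |
| ACZ (mm²) | π (mean RD + 1.645 sd RD)² | AREA-CC |
| AMZ (mm²/s) | 1/(2T) sum abs(x[n] y[n−1] − x[n−1] y[n]) | AREA-SW |

plus per-direction variants, grid-average envelope, the spectral-centroid
fatigue index AIF, torque level/CoV, and the T1-to-T3 displacement.
Per-variable statistics follow the repeated-measures battery (Shapiro–Wilk,
Friedman with Kendall's W, Bonferroni-corrected Wilcoxon post hocs) and
per-subject metric maxima are regressed against endurance time (the moment
torque stays below 50% MVT for 3 s).

A built-in simulator generates HD-sEMG + torque records with known ground
truth (drifting Gaussian activity kernel, declining spectral centroid,
rising torque variability, constructed failure time), so the whole chain is
validated as a parameter-recovery problem; see the methods vignette
(`vignettes/roa-fatigue-metrics.Rmd`).

## Worked example

```r
library(roatrack)

cfg <- sim_config(fs = 1024, duration_s = 60, failure_time_s = 50, seed = 42)
subject <- simulate_subject(cfg)              # EMG + torque + ground truth
res <- analyze_subject(subject$rec, subject$torque)

res$region$segments
#>   label   start_s    end_s
#> 1    T1  6.992676 16.99268
#> 2    T2 22.496582 32.49658
#> 3    T3 38.000488 48.00049

res$endurance$endurance_s
#> [1] 45.01

m <- res$metrics[, c("label","torque_cov","aif","aid","aid_ft","aip",
                     "aiv","aez","acz","amz","ais")]
m[-1] <- lapply(m[-1], round, 3)
print(m, row.names = FALSE)
#>  label torque_cov     aif    aid aid_ft    aip   aiv    aez    acz   amz   ais
#>     T1      0.027 129.077  3.005  0.992 33.957 3.396 30.149 29.877 1.611 1.848
#>     T2      0.042 123.465  6.295  1.338 64.833 6.483 44.474 37.214 4.832 2.314
#>     T3      0.050 118.833 11.854  0.557 21.352 2.135  4.100  5.851 0.490 0.707

res$displacement
#> [1] 9.36
```

Reading the output: torque variability (CoV) rises from 2.7% to 5.0% and the
spectral centroid (AIF) falls by ~10 Hz from T1 to T3 — both classical
fatigue signs. AID grows steadily (the activation centroid ends ~12 mm from
its initial position on average; the T1→T3 displacement of the mean position
is 9.4 mm), tracking the simulator's injected 20 mm fiber-parallel drift
across the record. The dispersion metrics (AEZ, ACZ, AMZ, AIS) reflect the
within-segment wandering of the centroid around its mean.

For a multi-subject cohort, `run_pipeline(subjects, out_dir)` writes
`metrics.csv`, `maxima.csv`, `trajectory.csv`, `stats.json` (the Friedman /
Wilcoxon battery per variable) and `regression.csv` (endurance-time R² per
metric). A thin command-line wrapper (`inst/cli/roatrack`) exposes
`simulate` and `analyze` subcommands over delimited-text files.

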