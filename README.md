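# effluentScreen

Peritoneal dialysis (PD) patients drain used dialysate several times a
day, and peritonitis — infection of the peritoneum — announces itself
there first: an effluent white blood cell (WBC) concentration above
100 WBCs/mm³ is the clinical flag. Because patients usually notice only
late, subjective symptoms, screening the effluent *in line*, during the
drain itself, can move detection days earlier.

`effluentScreen` implements the computational side of such an in-line
microscopy screen, for engineers and researchers building or evaluating
flow-imaging cell counters:

1. **Image batch analysis.** Frames arrive in bursts of 5, 100 ms
   apart. A pixel at position (x, y) in frame *i* is marked as a moving
   cell candidate when
   `|v_i(x,y) − mean_{j≠i} v_j(x,y)| > τ_cell` — deviation from the
   pooled mean of the other four frames. Anything static (background,
   fixed-pattern sensor noise, stuck debris) cancels exactly. The mask
   is blurred, re-binarised, size-filtered, and centroids falling in a
   coarser-scale bubble/artifact mask are discarded (`countCells()`).
2. **Counts → concentration calibration.** Per-drain counts are
   rank-filtered to their middle 50% (IQR filter), then converted with
   an ordinary least squares line `concentration = a·count + b` trained
   by k-fold cross validation (k = 10) with a
   heteroskedasticity-weighted R², and negative predictions clamped to
   zero (`iqrFilter()`, `kfoldTrain()`, `drainConcentration()`).
3. **Screening.** Session mean concentration is zoned: healthy
   [0, 50), caution [50, 100), risk [100, ∞) WBCs/mm³; binary screening
   is positive at ≥ 50. Confusion matrices and AUROC evaluate
   discrimination (`sessionReport()`, `evaluateScreening()`, `auroc()`).
4. **Parameter tuning.** A grid search scores every parameter
   combination by Wilcoxon signed-rank agreement (largest p = least
   significant difference) with reference counts, tie-broken by Pearson
   correlation and mean absolute error (`gridSearch()`).
5. **Synthetic scenes.** A simulator renders flowing-effluent bursts —
   dark Gaussian-profile WBCs carried 40 px per frame through a static
   noisy background, plus large bright bubbles — with exact ground
   truth, and count datasets mirroring the spiked-concentration
   training design (`makeFrameBatch()`, `makeCountDataset()`).

## Worked example

Calibrate on a synthetic training design, simulate a drain at
100 WBCs/mm³, count cells, and screen the session:

```r
library(effluentScreen)

ds    <- makeCountDataset(countDatasetConfig(seed = 42))
model <- kfoldTrain(iqrFilterDataset(ds), k = 10, seed = 42)
model
#> CalibrationModel (k = 10 folds, seed 42)
#>   concentration = 4.9449 * count + 1.6109   [WBCs/mm^3]
#>   weighted R^2 = 0.9854 (sd 0.00014); slope sd 0.0033, intercept sd 0.068

drain  <- makeDrainImages(sceneConfig(trueConcentration = 100, seed = 7),
                          nImages = 100L)
counts <- unlist(lapply(drain$batches,
                        function(b) cellCounts(countCells(b))))
report <- sessionReport(drainConcentration(counts, model)$mean)
cat(formatSessionReport(report))
#> PD session screening report
#>   drains analysed : 1
#>   mean WBC conc.  : 107.4 WBCs/mm^3
#>   min / max drain : 107.4 / 107.4 WBCs/mm^3
#>   zone            : RISK
#>   recommendation  : Contact your care team immediately for follow-up
#>                     diagnostic testing.
```

The recovered slope 4.94 sits within ~1% of the generating value 5
(the simulator yields 0.2 counts per WBC/mm³), and a drain spiked to
100 WBCs/mm³ is reported at 107 WBCs/mm³, in the at-risk zone.

A command-line wrapper mirroring the device's session loop lives in
`inst/scripts/effluent-screen.R` (subcommands `simulate`, `analyze`,
`calibrate`, `screen`, `tune`).

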