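# mcctrack

Single-cell live-imaging experiments can ask a question that bulk assays
cannot: *for each individual cell*, does the subcellular localization of a
protein predict whether — and when — that cell dies?  The motivating case
is telomerase reverse transcriptase (TERT), whose accumulation in
mitochondria after oxidative stress predetermines apoptosis while delaying
its execution.  `mcctrack` is an R package for analysts of such
experiments: it turns multi-channel time-lapse stacks (reporter,
mitochondrial stain, death dye) plus per-cell ROI masks into per-cell
colocalization time courses, dye-based death times, survival curves,
population summaries and the statistical inference on top — and it ships a
seeded synthetic time-lapse generator with known ground truth, so the
entire chain is testable without any raw microscopy data.

## The quantities at the core

**Thresholded Manders colocalization (M1).**  For a cell ROI with reporter
intensities $T_i$ and mitochondria intensities $M_i$,

$$\mathrm{MCC} = \frac{\sum_i T_{i,\mathrm{colocal}}}{\sum_i T_i},\qquad
T_{i,\mathrm{colocal}} = \begin{cases}T_i & M_i > 0\\ 0 &\text{else,}\end{cases}$$

with sums over reporter pixels above the reporter channel's Otsu
threshold, and "$M_i > 0$" meaning above the mitochondria channel's Otsu
threshold (256-bin per-ROI histograms).  MCC series are summarized as
5-frame block means; each cell's *initial MCC* (first defined smoothed
value) classifies it as high (> 0.60) or low.

**Death calling.**  A cell is dead at the first frame where the ROI-maximum
death-dye intensity exceeds `mean + k·SD` of pooled negative-control
intensities (k = 5 for tracking, k = 10 for endpoint imaging).  Survival
tables are normalized to no-stress controls
(`100·S_stress(t)/S_control(t)`).

**Inference.**  Mann–Whitney U (exact for small samples), Steel–Dwass
all-pairs rank comparison (Monte-Carlo or studentized-range null),
pairwise logrank, Tukey's comparison on arcsine-transformed proportions,
and Monte-Carlo power / sample-size analysis for multi-group proportion
comparisons — all implemented from first principles and calibrated in the
test suite.

## Worked example

Simulate a stressed 40-cell cohort, call deaths against a simulated
no-stress control, split by initial MCC and correlate with time-to-death:

```r
library(mcctrack)

cfg  <- sim_config(n_cells = 40L, field_shape = c(260L, 260L), seed = 7L)
sim  <- simulate_experiment(cfg, fate_model())        # WT-like fates
ctrl <- simulate_experiment(sim_config(n_cells = 20L,
                                       field_shape = c(260L, 260L),
                                       seed = 8L), control_fate_model())

thr   <- derive_threshold(extract_traces(ctrl$stacks$dye, ctrl$roi, 0.5), k = 5)
calls <- call_deaths(extract_traces(sim$stacks$dye, sim$roi, 0.5), thr, 1, 0.5)
mcc   <- mcc_timecourse(sim$stacks$reporter, sim$stacks$mito, sim$roi, 0.5)
ini   <- vapply(split(mcc, mcc$cell_id),
                function(d) initial_mcc(d$mcc[order(d$frame)]), numeric(1))

split_by_threshold(ini, calls, 0.60)
#> Initial-MCC split at 0.60
#>  class  n n_surviving pct_surviving mean_pct sem_pct
#>   high 16           0      0.000000 0.000000      NA
#>    low 24           2      8.333333 8.333333      NA

dead <- calls$status == "dead"
correlate_initial_mcc_vs_death_time(ini[dead], calls$death_time_h[dead])
#> Initial MCC vs time-to-death (n = 38 dead cells)
#>   Pearson r: 0.617 +/- 0.000 (mean +/- SEM over 1 replicate(s))
#>   OLS: time = 8.88 + 17.51 * MCC
```

Every high-accumulation cell died (the fate model's
`p_death_high = 1`), survivors sit in the low class, and among dying cells
a higher initial MCC predicts a later death — the structure the generator
encodes and the pipeline recovers.

Power of a three-group survival-percentage comparison at the reference
proportions 9.3% / 24.1% / 25.6% with 70 cells per condition:

```r
simulate_power(c(0.093, 0.241, 0.256), n_per_group = 70,
               n_reps = 2000, seed = 1)
#> Monte-Carlo power: 0.383 +/- 0.011 (MC SE, 2000 reps)
#>   steel_dwass, designated_all, alpha = 0.05, n = 70/70/70, props = 0.093/0.241/0.256
```

A power near one third means such a cohort would miss real survival
differences two times out of three; `min_n_for_power()` reports the
per-group size needed to reach 0.8.

The file-based pipeline wraps the same steps:
`run_simulate(pipeline_config(), "out/")` writes TIFF stacks, ROI labels,
ground truth and a manifest; `run_analyze("out/")` regenerates every
figure-analog (fate calls, survival, MCC, split, correlation) from the raw
stacks in one command.

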