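# chromodyn

Quantitative analysis of chromocenter dynamics, HP1α phase separation and
chromatin compaction in embryonic stem cells.

Pericentromeric heterochromatin from multiple chromosomes clusters into
DAPI-bright nuclear foci called **chromocenters**. In mouse embryonic stem
cells these behave like liquid condensates — they fuse, split, and exchange
molecules rapidly — and noncoding **major satellite repeat (MSR)
transcripts** keep them in that dynamic state: depleting MSR RNA slows FRAP
recovery, reduces fusion/fission activity, fragments chromocenters, and
compacts chromatin. chromodyn implements the measurements behind those
conclusions as a reusable, tested R pipeline for anyone quantifying nuclear
condensate dynamics from microscopy data:

* **FRAP** — background/control-ROI correction and normalization, one-phase
  association fitting *Y = Y₀ + (P − Y₀)(1 − e^(−Kx))*, half-time
  *t½ = ln2/K*, mobile fraction
  *Fm = (P − first post-bleach)/(pre-bleach − first post-bleach)*.
* **Chromocenter tracking** — detection, Hungarian-assignment linking with
  gap closing, coalescence/cleavage event calling, per-cell event engagement
  of ≥10-min tracks.
* **MSD** — time-averaged mean squared displacement and the anomalous
  diffusion fit *MSD(τ) = 4 D_app τ^α*, plus a directed-diffusion velocity.
* **Morphometry & colocalization** — nucleus/chromocenter segmentation,
  mid-section areas and major axes, per-focus channel intensities, pixelwise
  Pearson correlation, linescans, quartile-binned comparisons.
* **RNA-FISH localization** — focus detection and the within / periphery /
  between overlap classification (>50% overlap with one chromocenter;
  <50% with exactly one; <50% with at least two).
* **Droplet assays** — per-well droplet detection and the critical HP1α
  concentration (minimum tested concentration forming detectable droplets),
  with a monotonicity QC along the dilution series.
* **FLIM** — two-level heterochromatin/euchromatin masks and per-region
  monoexponential lifetime fits by Poisson maximum likelihood (shorter
  SiR-DNA lifetime = more compact chromatin).
* **Synthetic data** — `make_*()` generators with ground truth and named
  presets encoding each experimental condition, so the whole pipeline is
  testable end to end without raw microscopy data.

Everything takes data frames (or plain numeric arrays for images) and
returns tibbles; fitted objects have `tidy()`/`glance()` methods and
`autoplot()`/`plot_*()` figures.

## Worked example: does MSR depletion slow HP1α exchange?

Generate 45 FRAP traces per condition under the HP1α presets (2 baseline
frames at 1 s, then one frame every 5 s for 61 s), fit each, and compare:

```r
library(chromodyn)
library(purrr)

fits_ctrl <- map(1:45,  ~ fit_recovery(correct_trace(make_frap_trace("hp1a_ctrl", seed = .x))))
fits_msr  <- map(1:45,  ~ fit_recovery(correct_trace(make_frap_trace("hp1a_msr",  seed = 500 + .x))))

fits_ctrl[[1]]
#> <frap_fit> t1/2 = 7.81 s (K = 0.0887 /s), mobile = 87.0%, immobile = 13.0%

summarize_frap(c(fits_ctrl, fits_msr), rep(c("control", "msr_depleted"), each = 45))
#> $summary
#>      condition          quantity  n median   mean     sem
#> 1      control immobile_fraction 45  0.139  0.139 0.00520
#> 2      control   mobile_fraction 45  0.861  0.861 0.00520
#> 3      control          t_half_s 45  8.082  8.260 0.13060
#> 4 msr_depleted immobile_fraction 45  0.266  0.260 0.00615
#> 5 msr_depleted   mobile_fraction 45  0.734  0.740 0.00615
#> 6 msr_depleted          t_half_s 45 12.686 12.921 0.33715
#>
#> $tests
#>            quantity  p_value  group1       group2                   method
#> 1 immobile_fraction 1.28e-21 control msr_depleted Mann-Whitney (two-sided)
#> 2   mobile_fraction 1.28e-21 control msr_depleted Mann-Whitney (two-sided)
#> 3          t_half_s 9.79e-24 control msr_depleted Mann-Whitney (two-sided)
```

Fluorescence at bleached chromocenters recovers half-way in ~8 s in the
control condition versus ~13 s after MSR depletion, and the immobile
fraction rises from ~14% to ~26% — HP1α exchanges more slowly and a larger
share of it is stably bound when MSR transcripts are depleted. The same
pattern holds for every module: generate with a preset, run the analysis,
compare conditions with `mw_test()`-based summaries.

A time-lapse example, end to end:

```r
tl  <- make_timelapse("ctrl_dynamics", seed = 1)        # 20 min, 30-s frames
det <- detect_foci(tl, threshold = 90)
lt  <- link_tracks(det, max_disp_um = 1.2, max_gap_frames = 1)
event_engagement(lt, min_duration_s = 600)              # per-cell fraction
```

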