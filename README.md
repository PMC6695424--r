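# twitchindex

Quantitative analysis for the "in vitro exercise" experiment: cultured
myotubes driven to twitch by electric pulse stimulation (EPS; 1 Hz, 4 ms,
20 V/25 mm is the standard protocol). Human-only myotubes usually contract
poorly; fusing human myoblasts with mouse C2C12 myoblasts produces **hybrid
myotubes** that contract vigorously, and species-specific assays then read
out the human contribution separately. twitchindex is for cell biologists
running such experiments who need the three standard readouts as tested,
scriptable code:

1. **Contractility** — the *movement index* from time-lapse image stacks by
   differential image subtraction;
2. **Composition** — the human-nuclei ratio of hybrid cultures from
   two-channel masks, and the satellite-cell FACS gate
   (CD11b⁻CD31⁻CD34⁻CD45⁻CD56⁺);
3. **Response** — species-resolved qPCR fold changes (ΔΔCt against mouse
   GAPDH / human RPLP0) and classification of a 40-analyte secretion panel
   (LOD censoring, cross-reactivity exclusion via mouse-only media,
   Student's t-test).

Every input can also be **simulated** with known ground truth
(`simulate_*` functions), so the full pipeline is testable without any
microscope.

## The movement index

For a stack of frames $I_t$ at rate $\mathrm{fps}$ under $f$ Hz
stimulation:

* activity trace $a_t = \mathrm{mean}\,|I_t - I_{t-1}|$, smoothed; its
  first prominent peak is the first maximum-contraction frame $t_0$;
* contraction frames $c_k = t_0 + \mathrm{round}(k\,\mathrm{fps}/f)$ over a
  3–5 s window pair with relaxation frames
  $r_k = c_k + \mathrm{round}(\mathrm{fps}/2f)$;
* differential images $D_k = |I_{c_k} - I_{r_k}|$ are overlaid (pixelwise
  mean) and

$$\mathrm{MI} \;=\; \frac{1}{HW}\sum_{x,y}\ \overline{D}(x,y),$$

the average intensity of the overlaid differential image — larger MI, more
movement. Fields are summarized as mean ± SE (conventionally 3 fields per
condition).

## Worked example

```r
library(twitchindex)

sim <- simulate_myotube_field(video_sim_config(seed = 7, amplitude_px = 4,
                                               noise_sd = 0))
movement_index(sim$stack)
#> <movement_result> MI = 0.00246286 over 3 pairs
```

A noiseless 5 s stack (72 frames at 14.4 fps) of myotubes twitching with
4 px peak shortening gives MI ≈ 0.0025 intensity units; amplitude 0 gives
exactly 0 and the index grows monotonically with amplitude.

The full template experiment (three culture conditions, nuclei fields,
marker gating, qPCR, secretion panel):

```r
report <- run_all(default_run_config(seed = 1), output_dir = "run1")
report
#> twitchindex run (seed 1)
#>
#> Movement index (mean +/- SE per condition):
#>   HSMM     0.0113572 +/- 1.54e-05 (n = 3)
#>   C2C12    0.0146619 +/- 0.000145 (n = 3)
#>   hybrid   0.01451 +/- 0.000131 (n = 3)
#> Pairwise Student's t-tests:
#>   HSMM vs C2C12          t = -22.689  p = 2.235e-05 *
#>   HSMM vs hybrid         t = -23.868  p = 1.827e-05 *
#>   C2C12 vs hybrid        t =   0.777  p = 0.4804
#>
#> Human nuclei: 13.10% +/- 1.52% over 7 fields (planted 14.25%)
#>
#> Satellite gate: 60 / 200 cells selected (60 true; agreement 1.000)
#>
#> Relative expression (fold vs control):
#>   CXCL1  (human): fold 8.36 (planted 8), p = 0.002906 *
#>   IL6    (human): fold 7.00 (planted 6), p = 0.002702 *
#>   Cxcl1  (mouse): fold 19.82 (planted 15), p = 0.001557 *
#>   Il6    (mouse): fold 14.31 (planted 12), p = 8.468e-06 *
#>
#> Secretion panel: 24 upregulated, 1 detected-not-upregulated, 12 not detected,
#> 3 excluded (CX3CL1, CCL3, CCL12); truth agreement 1.000
```

Reading the output: the poorly contractile human-only condition (HSMM) sits
at the noise floor while the mouse-only and hybrid conditions are
significantly higher and indistinguishable from each other; the
human-nuclei estimate recovers the planted 14.25% within its SE; the
satellite gate matches the ground-truth labels; planted qPCR folds and all
40 planted analyte classes (including the three cross-reactive exclusions)
are recovered. `run1/` contains `report.json`, TSV tables, pseudo-colored
overlay PNGs, and a `summary.txt`.

A command-line front end is included at `inst/cli/twitchindex.R`
(`simulate`, `mi`, `nuclei`, `gate`, `ct`, `panel`, `run-all`), e.g.

```sh
Rscript inst/cli/twitchindex.R mi video.tif --fps 14.4 --freq 1.0 \
    --window 3 --out result.json --render overlay.png
```

## Vignette

`vignettes/twitchindex-methods.Rmd` documents the model and its
assumptions, every tunable parameter with units and defaults, what the
synthetic generators do and do not emulate, numerical conventions, and
known limitations.
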