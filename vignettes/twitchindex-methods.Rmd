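---
title: "Methods: movement index, hybrid-myotube composition, and species-resolved myokine statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: movement index, hybrid-myotube composition, and species-resolved myokine statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

twitchindex implements the quantitative readouts of an "in vitro exercise"
experiment: cultured myotubes are driven to twitch by electric pulse
stimulation (EPS; typically 1 Hz, 4 ms pulses, 20 V across a 25 mm gap), and
the package measures (i) how much they move, (ii) what a hybrid human/mouse
culture is made of, and (iii) which transcripts and secreted myokines respond
to contraction, separately per species. Because such experiments rarely
deposit raw videos or bead-assay plates, every input can be simulated with
known ground truth, and the package's tests are built on recovering that
truth.

# The movement index

## Model

A twitching field imaged at `fps` frames per second under `f` Hz stimulation
alternates between maximum-contraction states (one per cycle) and relaxed
states roughly half a period later. The differential image subtraction method
turns this into a scalar:

1. **Motion trace.** `a[1] = 0`; for `t >= 2`, `a[t]` is the mean absolute
   pixel difference between consecutive frames. This operationalizes "the
   first maximum contraction state", which is otherwise a visual judgment.
2. **Anchor.** The trace is smoothed by a centered moving average of width
   `round(fps / (4 f))` frames (forced odd, edges replicated) and the first
   local maximum whose height above the trace median reaches 25% of the
   max-minus-median range is the starting frame. Plateaus and ties resolve to
   the earliest frame. Both constants are arguments
   (`prominence_frac`, and the width follows `fps`/`f`).
3. **Pairing.** With 1-based indices, contraction frames are
   `start + round(k fps / f)` for `k = 0 .. floor(window_s f) - 1` and each
   pairs with the frame `round(fps / (2 f))` later. The analysis window
   `window_s` defaults to 3 s (3–5 s is conventional). Halves round up;
   pairs that overrun the stack are dropped; at least one must remain.
4. **Subtraction and overlay.** Each pair yields
   `|contraction - relaxation|` pixelwise; the per-pair images are averaged
   pixelwise into the overlay. The **movement index (MI)** is the spatial
   mean of the overlay, computed over the full frame without masking.

## Choices worth knowing about

* **Absolute, not signed, subtraction.** Intensity differences between the
  two states reflect displaced scattering objects; their sign depends on
  which edge of an object moved and would partially cancel in a spatial
  mean. `signed = TRUE` is available for diagnostics.
* **Mean overlay.** "Overlaying" subtracted images is not a defined
  operation; the pixelwise mean makes MI equal to the mean of per-pair
  indices and independent of window length in expectation. `overlay = "max"`
  gives the union-of-moving-parts rendering instead.
* **Non-contractile fallback.** A field with no qualifying activity peak
  (for example, human-only myotubes, which often barely contract) reports
  the MI of a pairing anchored at frame 1 with a `non_contractile` flag
  rather than erroring: low MIs of poorly contracting cultures are a result,
  not a failure.
* **Normalization.** Integer containers are scaled by their bit-depth
  maximum on read so MI is comparable across 8/16-bit sources. Consequently
  MI is invariant under a global additive offset, and scales linearly under
  intensity scaling — both are tested properties.
* **Indices are 1-based** (R convention); all pairing formulas are
  shift-invariant so only the reported anchor differs from a 0-based
  formulation.

Per-field MIs are summarized as mean ± SE over fields (three fields per
condition is the convention; SE is undefined, and reported `NA`, for a
single field).

# Hybrid-myotube composition

## Human-nuclei ratio

Input is a pair of binary masks per field — all nuclei (DAPI) and human
nuclei (human nuclear antigen, HNA) — not raw fluorescence: segmentation is
out of scope (counting is classically done by eye). Nuclei are the
8-connected components of the DAPI mask; a nucleus is human when at least
`overlap_threshold` (default 0.5) of its area is covered by the HNA mask.
Area-fraction overlap was chosen because colocalization is otherwise
undefined for masks; 0.5 is symmetric and configurable. An empty DAPI mask
yields a *missing* ratio, never 0. Ratios are summarized as mean ± SE over
fields, excluding (and reporting) empty fields. The component labeling is
implemented in the package because the installed image toolkit labels with
4-connectivity, which would split diagonally touching nuclei.

## Satellite-cell gate

Satellite cells sorted from a muscle biopsy are defined by the fixed boolean
rule CD11b⁻ CD31⁻ CD34⁻ CD45⁻ CD56⁺ — negative for blood (CD11b, CD45) and
endothelial (CD31, CD34) lineages, positive for CD56. CD34 is a *negative*
selection marker here (human muscle CD34⁺ cells are adipogenic). Thresholds
are user-supplied per marker; no automatic cutoff modeling, no
doublet/viability gating. PDGFRA (fibro-adipogenic progenitors) is recorded
but never gated.

# Species-resolved response statistics

## Relative expression (ΔΔCt)

In a hybrid culture, species-specific primers let human and mouse
transcripts be read separately; each is normalized to its own reference
(human RPLP0, mouse GAPDH). Per sample, `dCt = Ct_gene − Ct_ref`; relative
level `2^(−dCt)` is rescaled so the control-group mean is exactly 1, making
the EPS-group mean the fold change (ΔΔCt convention — the field standard
when no standard curve is modeled; raw ΔCt values are also returned).
Conditions are compared with an unpaired two-sided Student's t-test
(pooled variance, matching the named method; Welch is available via
`var_equal = FALSE`), and data are expressed as means ± SE.

## Secretion panel

A 40-analyte bead panel is reduced to one class per analyte, in strict
precedence order:

1. `excluded_cross_reactive` — the analyte's human assay reacts to the
   mouse homolog. Detection rule: mean signal in mouse-only conditioned
   media exceeds the blank mean by more than `k_sd` (default 3) blank SDs
   *and* is at least the limit of detection (LOD). The rule is this
   package's construction — published reports typically state only which
   analytes "emerged as cross-reactive" — so `k_sd` is configurable.
   Excluded analytes carry no up/down call.
2. `not_detected` — every well of both biological conditions below LOD; a
   single well at LOD in either condition makes the analyte detected.
3. `upregulated` — Student's t-test p < α (0.05) *and* EPS mean above
   control mean.
4. `detected_not_upregulated` — everything else, including significant
   decreases: there is deliberately no "downregulated" class, mirroring how
   such panels are reported.

No multiple-testing correction is applied by default (per-analyte p < 0.05
is the reporting convention this mirrors); Benjamini–Hochberg is available
via `p_adjust = "BH"`.

# The synthetic-data generators

Every generator takes a mandatory seed, uses an isolated RNG state, and
returns a `truth` sidecar; identical arguments give bit-identical output.

* **Videos.** Elongated ribbons with Gaussian cross-section and soft
  (logistic, 1.5 px) ends on a uniform background; each ribbon shortens
  longitudinally toward its centroid by `amplitude_px · s(t)`, where the
  twitch trace `s(t)` rises linearly over `twitch_rise_s` (default 0.1 s)
  and relaxes exponentially with constant `twitch_decay_s` (default 0.3 s) —
  the minimal two-parameter twitch with a well-defined peak (only the
  stimulation frequency is protocol-fixed; kinetics are not). Shortening
  (not whole-object translation) mimics contraction and guarantees edge
  differences; soft edges make sub-pixel motion visible. Additive Gaussian
  noise is applied post-warp and intensities clipped to [0, 1]. Default
  geometry 256 × 256 px, 5 myotubes, 5 s at 14.4 fps (desk scale, < 1 s per
  stack). The sampled trace is rescaled to peak at exactly 1; note that at
  14.4 fps the first-cycle sample nearest the continuous peak is frame 3
  (the decay side sample exceeds the rise side one).
* **Nuclei fields.** Non-overlapping ellipses (rejection-sampled with a
  2 px guard band, bounded retries, geometry error on failure); the human
  subset is a seeded binomial draw, recorded exactly. Default human
  fraction 0.1425, emulating the ~14% human-nuclei proportion of
  1:1-seeded hybrid cultures after differentiation. Non-overlap is
  guaranteed so that connected-component counting cannot undercount — real
  dense fields with touching nuclei are *not* emulated.
* **Marker tables.** Log-normal intensities; five populations (satellite,
  blood, endothelial, FAP, other) with shared bright/dim medians (defaults
  1000/10, `sdlog` 0.4 → ~11.5 SD separation on the log scale).
* **Ct tables.** EPS-condition Ct = control Ct − log2(planted fold) +
  N(0, `noise_sd_ct`); references identically distributed across
  conditions. Defaults: 0.2 cycles noise, 3 replicates.
* **Secretion panels.** The default class map has 24 upregulated analytes
  (IL-6, IL-8, IL-10, IL-16; CXCL1/2/5/6/10; CCL1, 2, 7, 8, 11, 13, 16, 17,
  19, 20, 21, 22, 25, 27; IFN-γ), MIF detected-not-upregulated, CX3CL1,
  CCL3 and CCL12 cross-reactive, and 12 below-LOD analytes (IL-1β, IL-2,
  IL-4, CXCL9, CXCL11, CXCL13, CCL15, CCL24, GM-CSF, TNF-α, plus CXCL12 and
  CXCL16 to complete the commercial 40-plex). CCL16 is classed as
  upregulated: published analyte lists for this profile name it both among
  secreted CC chemokines and in a not-detected enumeration, and the
  secreted list is taken as authoritative. Defaults: basal 50 pg/mL,
  fold 20 for upregulated analytes, LOD 5 pg/mL, 15% CV, 4 wells per
  condition.

What passing recovery tests show is that the *analysis* is correct under
the generators' assumptions — periodic twitch, stationary background,
non-overlapping nuclei, log-normal intensities, lognormal well noise. They
do not validate segmentation, drift/focus artifacts, bead-assay saturation,
or amplification-efficiency effects, all of which are out of scope.

# The pipeline template

`default_run_config()` encodes the template experiment: three video
conditions — HSMM (human-only, amplitude 0.5 px), C2C12 (mouse-only, 6 px),
hybrid (6 px) — with three fields each, reflecting the characteristic
pattern that human-only myotubes barely contract while hybrid myotubes reach
mouse-like contractility; seven nuclei fields of 67–140 nuclei at fraction
0.1425; a 200-cell marker table; planted qPCR folds (human IL6 6×, human
CXCL1 8×, mouse Il6 12×, mouse Cxcl1 15×); and the default panel. A single
master seed fans out to fixed per-stage child seeds so any stage can be
regenerated alone; `run_all()` is bit-reproducible for a fixed
(config, seed) and echoes every effective parameter in its report.

Problem sizes throughout (stack geometry, field counts, replicate numbers,
Monte-Carlo repetition counts in the tests: 20 seeds for ordering and
period recovery, 500 for CI coverage, 2000 for t calibration) are the
package's chosen desk-scale defaults: large enough for the properties under
test to be sharp, small enough to run interactively.

# Numerical notes and limitations

* Frame-index arithmetic uses half-up rounding (`floor(x + 0.5)`), never
  banker's rounding.
* TIFF round trips use a 32-bit container; values survive to ~1e-9 (not
  bit-exact for arbitrary doubles).
* Degenerate t-tests (zero variance in both groups) return p = 1 for equal
  means and p = 0 otherwise rather than erroring.
* `k_sd = Inf` disables cross-reactivity flagging even for constant blanks.
* The movement index is background-sensitive by construction (no masking):
  camera noise sets a floor that is shared across conditions; comparisons
  between conditions are therefore made on equal noise footing.
* No optical flow, force estimation, drift correction, PSF/optics
  simulation, calcium modeling, or in-silico PCR: the package analyzes the
  standard tabular/image inputs and nothing upstream of them.
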