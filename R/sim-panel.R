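#' Default analyte class map for the 40-plex secretion panel
#'
#' The default panel emulates the contraction-responsive secretion profile of
#' hybrid human/mouse myotube cultures measured on a 40-analyte human
#' chemokine bead panel:
#' \itemize{
#'   \item 24 `upregulated` analytes (4 interleukins, 5 CXC chemokines,
#'     14 CC chemokines, and IFN-gamma) secreted in response to
#'     contraction;
#'   \item 1 `detected_not_upregulated` analyte (MIF), present in the medium
#'     but insensitive to stimulation;
#'   \item 12 `not_detected` analytes below the assay's limit of detection in
#'     every well;
#'   \item 3 `cross_reactive` analytes (CX3CL1, CCL3, CCL12) whose human
#'     assays pick up the mouse homolog, detectable from mouse-only
#'     conditioned media and excluded from classification.
#' }
#' CCL16 is classed as `upregulated`; published analyte lists for this
#' profile are ambiguous about it (it also appears in a not-detected
#' enumeration), and the secreted-chemokine list is taken as authoritative
#' here.
#'
#' @return Named character vector of length 40 mapping analyte to class.
#' @export
default_analyte_classes <- function() {
  up <- c("IL-6", "IL-8", "IL-10", "IL-16",
          "CXCL1", "CXCL2", "CXCL5", "CXCL6", "CXCL10",
          "CCL1", "CCL2", "CCL7", "CCL8", "CCL11", "CCL13", "CCL16",
          "CCL17", "CCL19", "CCL20", "CCL21", "CCL22", "CCL25", "CCL27",
          "IFN-gamma")
  nd <- c("IL-1beta", "IL-2", "IL-4", "CXCL9", "CXCL11", "CXCL13",
          "CCL15", "CCL24", "GM-CSF", "TNF-alpha", "CXCL12", "CXCL16")
  cr <- c("CX3CL1", "CCL3", "CCL12")
  stats::setNames(
    c(rep("upregulated", length(up)), "detected_not_upregulated",
      rep("not_detected", length(nd)), rep("cross_reactive", length(cr))),
    c(up, "MIF", nd, cr)
  )
}

panel_classes <- c("upregulated", "detected_not_upregulated",
                   "not_detected", "cross_reactive")

#' Simulate a multiplex secretion panel
#'
#' Generates per-well analyte concentrations (pg/mL) for four conditions:
#' `EPS` and `control` wells of the stimulated culture, `mouse_only_media`
#' wells (conditioned media from a mouse-only culture, used to flag
#' cross-reactive human assays), and `blank` wells (fresh media). Planted
#' behavior per class:
#' \describe{
#'   \item{upregulated}{control wells around `basal_pg_ml`, EPS wells around
#'     `basal_pg_ml * fold_upregulated`.}
#'   \item{detected_not_upregulated}{both biological conditions around
#'     `basal_pg_ml`.}
#'   \item{not_detected}{every well strictly below the limit of detection.}
#'   \item{cross_reactive}{like upregulated in the biological wells, but with
#'     strong signal in `mouse_only_media` (the mouse homolog bleeding into
#'     the human assay).}
#' }
#' Concentrations are log-normal with coefficient of variation `noise_cv`;
#' blank and mouse-only wells of clean analytes carry only sub-LOD background.
#'
#' @param classes Named character vector mapping each analyte to one of
#'   `upregulated`, `detected_not_upregulated`, `not_detected`,
#'   `cross_reactive`; must partition the panel (see
#'   [default_analyte_classes()]).
#' @param basal_pg_ml Basal (control) concentration of detected analytes.
#' @param fold_upregulated Planted EPS/control fold change for upregulated
#'   analytes.
#' @param lod_pg_ml Limit of detection; scalar or named per analyte.
#' @param noise_cv Lognormal coefficient of variation of well concentrations.
#' @param n_wells Wells per condition.
#' @param seed Integer RNG seed.
#' @return A list with `panel` (class `secretion_panel`: data.frame with
#'   columns `analyte`, `well`, `condition`, `concentration`, plus
#'   attributes `lod` (named vector) and `panel_size`) and `truth` (the
#'   planted class map and seed).
#' @export
simulate_secretion_panel <- function(classes = default_analyte_classes(),
                                     basal_pg_ml = 50, fold_upregulated = 20,
                                     lod_pg_ml = 5, noise_cv = 0.15,
                                     n_wells = 4, seed) {
  if (missing(seed)) stop_classed("parameter_error", "`seed` is mandatory")
  analytes <- names(classes)
  if (is.null(analytes) || anyDuplicated(analytes) ||
      !all(classes %in% panel_classes)) {
    stop_classed("parameter_error",
                 "`classes` must map distinct analytes to one of: %s",
                 paste(panel_classes, collapse = ", "))
  }
  check_number(basal_pg_ml, "basal_pg_ml", min = 0, strict_min = TRUE)
  check_number(fold_upregulated, "fold_upregulated", min = 0, strict_min = TRUE)
  check_number(noise_cv, "noise_cv", min = 0)
  check_number(n_wells, "n_wells", min = 2)
  lod <- if (length(lod_pg_ml) == 1L) {
    stats::setNames(rep(lod_pg_ml, length(analytes)), analytes)
  } else {
    lod_pg_ml[analytes]
  }
  if (anyNA(lod) || any(lod <= 0)) {
    stop_classed("parameter_error", "lod_pg_ml must be positive for every analyte")
  }

  sdlog <- sqrt(log(1 + noise_cv^2))
  draw <- function(median_conc, k) {
    if (sdlog == 0) rep(median_conc, k) else
      stats::rlnorm(k, meanlog = log(median_conc), sdlog = sdlog)
  }

  with_seed(seed, {
    conds <- c("EPS", "control", "mouse_only_media", "blank")
    rows <- vector("list", length(analytes))
    for (j in seq_along(analytes)) {
      an <- analytes[j]; cl <- classes[[an]]
      background <- function(k) pmin(draw(lod[[an]] * 0.1, k), lod[[an]] * 0.8)
      conc <- switch(cl,
        upregulated = c(draw(basal_pg_ml * fold_upregulated, n_wells),
                        draw(basal_pg_ml, n_wells),
                        background(n_wells), background(n_wells)),
        detected_not_upregulated = c(draw(basal_pg_ml, n_wells),
                                     draw(basal_pg_ml, n_wells),
                                     background(n_wells), background(n_wells)),
        not_detected = c(background(n_wells), background(n_wells),
                         background(n_wells), background(n_wells)),
        cross_reactive = c(draw(basal_pg_ml * fold_upregulated, n_wells),
                           draw(basal_pg_ml, n_wells),
                           draw(basal_pg_ml * 2, n_wells),
                           background(n_wells))
      )
      rows[[j]] <- data.frame(
        analyte = an,
        well = paste0(rep(conds, each = n_wells), "_", seq_len(n_wells)),
        condition = rep(conds, each = n_wells),
        concentration = conc
      )
    }
    panel <- do.call(rbind, rows)
    rownames(panel) <- NULL
    attr(panel, "lod") <- lod
    attr(panel, "panel_size") <- length(analytes)
    class(panel) <- c("secretion_panel", "data.frame")

    truth <- structure(list(classes = classes, basal_pg_ml = basal_pg_ml,
                            fold_upregulated = fold_upregulated,
                            seed = as.integer(seed)),
                       class = "sim_truth")
    list(panel = panel, truth = truth)
  })
}
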