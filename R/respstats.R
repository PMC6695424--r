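#' Two-sample Student's t comparison with means +/- SE
#'
#' Two-sided two-sample t-test with pooled variance (Student's test; Welch's
#' unequal-variance correction available behind `var_equal = FALSE`),
#' returning the group means and standard errors alongside the statistic.
#' A degenerate comparison (zero variance in both groups) yields `t = 0,
#' p = 1` for equal means and `p = 0` otherwise.
#'
#' @param values_a,values_b Numeric vectors, each of length >= 2.
#' @param var_equal Pool the variances (default `TRUE`).
#' @return List: `t`, `p`, `df`, `mean_a`, `se_a`, `mean_b`, `se_b`, `n_a`,
#'   `n_b`.
#' @export
compare_groups <- function(values_a, values_b, var_equal = TRUE) {
  if (length(values_a) < 2L || length(values_b) < 2L) {
    stop_classed("parameter_error",
                 "both groups need at least 2 observations")
  }
  out <- list(mean_a = mean(values_a), se_a = standard_error(values_a),
              mean_b = mean(values_b), se_b = standard_error(values_b),
              n_a = length(values_a), n_b = length(values_b))
  if (stats::sd(values_a) == 0 && stats::sd(values_b) == 0) {
    if (out$mean_a == out$mean_b) {
      out$t <- 0; out$p <- 1
    } else {
      out$t <- sign(out$mean_a - out$mean_b) * Inf; out$p <- 0
    }
    out$df <- out$n_a + out$n_b - 2
    return(out)
  }
  ht <- stats::t.test(values_a, values_b, var.equal = var_equal,
                      alternative = "two.sided")
  out$t <- unname(ht$statistic)
  out$p <- ht$p.value
  out$df <- unname(ht$parameter)
  out
}

#' Relative expression from a Ct table (delta-delta-Ct)
#'
#' For each sample, the target gene's Ct is normalized to the species-matched
#' reference gene (`dCt = Ct_gene - Ct_ref`, mouse GAPDH / human RPLP0 by
#' default), converted to a relative level `2^(-dCt)`, and rescaled so the
#' control-group mean is exactly 1 (the delta-delta-Ct convention: the
#' EPS-group mean is then the fold change versus control). Conditions are
#' compared with [compare_groups()] on the relative levels.
#'
#' @param ct Ct table: `data.frame` with columns `sample`, `condition`
#'   (`"EPS"` / `"control"`), `species`, `gene`, `ct_value` (see
#'   [simulate_ct_table()]). Each (sample, species) block must contain its
#'   reference gene.
#' @param reference_genes Species -> reference gene map.
#' @param alpha Significance level for the per-gene call (default 0.05).
#' @return Object of class `expression_result`: `summary` (per gene/species:
#'   fold, group means +/- SE, `t`, `p`, `significant`, `delta_ct` means)
#'   and `samples` (per-sample relative levels and raw dCt).
#' @export
relative_expression <- function(ct,
                                reference_genes = default_reference_genes(),
                                alpha = 0.05) {
  needed <- c("sample", "condition", "species", "gene", "ct_value")
  if (!is.data.frame(ct) || !all(needed %in% names(ct))) {
    stop_classed("schema_error", "ct table needs columns: %s",
                 paste(needed, collapse = ", "))
  }
  ct$is_ref <- mapply(function(sp, g) {
    !is.na(reference_genes[sp]) && identical(unname(reference_genes[sp]), g)
  }, ct$species, ct$gene)

  # reference Ct per (sample, species)
  refs <- ct[ct$is_ref, ]
  key <- function(s, sp) paste(s, sp, sep = "\r")
  ref_ct <- stats::setNames(refs$ct_value, key(refs$sample, refs$species))

  targets <- ct[!ct$is_ref, ]
  k <- key(targets$sample, targets$species)
  if (anyNA(ref_ct[k])) {
    bad <- unique(k[is.na(ref_ct[k])])
    stop_classed("schema_error",
                 "missing reference gene for %d (sample, species) block(s)",
                 length(bad))
  }
  targets$delta_ct <- targets$ct_value - unname(ref_ct[k])
  targets$rel_raw <- 2^(-targets$delta_ct)

  groups <- split(targets, list(targets$gene, targets$species), drop = TRUE)
  summary_rows <- list()
  sample_rows <- list()
  for (g in groups) {
    ctrl <- g$rel_raw[g$condition == "control"]
    eps <- g$rel_raw[g$condition == "EPS"]
    if (length(ctrl) < 1L) {
      stop_classed("schema_error", "gene %s has no control samples", g$gene[1])
    }
    g$relative_level <- g$rel_raw / mean(ctrl)
    sample_rows[[length(sample_rows) + 1L]] <-
      g[, c("sample", "condition", "species", "gene", "ct_value",
            "delta_ct", "relative_level")]
    rc <- g$relative_level[g$condition == "control"]
    re <- g$relative_level[g$condition == "EPS"]
    cmp <- if (length(rc) >= 2L && length(re) >= 2L) {
      compare_groups(re, rc)
    } else {
      list(t = NA_real_, p = NA_real_, mean_a = mean(re), se_a = NA_real_,
           mean_b = mean(rc), se_b = NA_real_)
    }
    summary_rows[[length(summary_rows) + 1L]] <- data.frame(
      gene = g$gene[1], species = g$species[1],
      fold = mean(re) / mean(rc),
      mean_control = cmp$mean_b, se_control = cmp$se_b,
      mean_eps = cmp$mean_a, se_eps = cmp$se_a,
      delta_ct_control = mean(g$delta_ct[g$condition == "control"]),
      delta_ct_eps = mean(g$delta_ct[g$condition == "EPS"]),
      t = cmp$t, p = cmp$p,
      significant = !is.na(cmp$p) & cmp$p < alpha
    )
  }
  structure(list(
    summary = do.call(rbind, summary_rows),
    samples = do.call(rbind, sample_rows),
    reference_genes = reference_genes,
    alpha = alpha
  ), class = "expression_result")
}

#' @export
print.expression_result <- function(x, ...) {
  cat("<expression_result>\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

lod_of <- function(panel, lod = NULL) {
  lod <- lod %||% attr(panel, "lod")
  if (is.null(lod)) {
    stop_classed("schema_error",
                 "no limit of detection: supply `lod` or a panel with a lod attribute")
  }
  analytes <- unique(panel$analyte)
  if (length(lod) == 1L && is.null(names(lod))) {
    lod <- stats::setNames(rep(lod, length(analytes)), analytes)
  }
  if (!all(analytes %in% names(lod))) {
    stop_classed("schema_error", "lod missing for some analytes")
  }
  lod
}

#' Censor a secretion panel at the limit of detection
#'
#' Flags each well below its analyte's limit of detection (LOD) and calls an
#' analyte `not detected` when every well of both biological conditions
#' (`EPS` and `control`) is below LOD; a single well at or above LOD in
#' either condition makes the analyte detected.
#'
#' @param panel Secretion panel `data.frame` (columns `analyte`, `well`,
#'   `condition`, `concentration`; see [simulate_secretion_panel()]).
#' @param lod Per-analyte LOD (named vector or scalar); defaults to the
#'   panel's `lod` attribute.
#' @return List of class `censored_panel`: `wells` (the panel with a
#'   `below_lod` flag), `detection` (per analyte: `detected`), `lod`.
#' @export
censor_lod <- function(panel, lod = NULL) {
  stopifnot(is.data.frame(panel),
            all(c("analyte", "condition", "concentration") %in% names(panel)))
  lod <- lod_of(panel, lod)
  wells <- as.data.frame(panel)
  wells$below_lod <- wells$concentration < unname(lod[wells$analyte])
  bio <- wells[wells$condition %in% c("EPS", "control"), ]
  detected <- tapply(!bio$below_lod, bio$analyte, any)
  detection <- data.frame(analyte = names(detected),
                          detected = as.logical(detected))
  rownames(detection) <- NULL
  structure(list(wells = wells, detection = detection, lod = lod),
            class = "censored_panel")
}

#' Detect cross-reactive analytes from mouse-only conditioned media
#'
#' In a two-species culture, a human-analyte assay can pick up the secreted
#' mouse homolog. Conditioned media from a mouse-only culture, measured on
#' the same panel, expose such assays: an analyte is called cross-reactive
#' when its mean `mouse_only_media` signal exceeds the blank mean by more
#' than `k_sd` blank standard deviations and is at least the LOD.
#'
#' @param panel Secretion panel with `mouse_only_media` and `blank`
#'   conditions.
#' @param k_sd Blank-SD multiplier (default 3).
#' @param lod Per-analyte LOD (defaults to the panel attribute).
#' @return Character vector of cross-reactive analytes.
#' @export
detect_cross_reactive <- function(panel, k_sd = 3, lod = NULL) {
  stopifnot(is.data.frame(panel))
  if (!all(c("mouse_only_media", "blank") %in% panel$condition)) {
    stop_classed("schema_error",
                 "panel needs mouse_only_media and blank conditions")
  }
  lod <- lod_of(panel, lod)
  analytes <- unique(panel$analyte)
  flagged <- vapply(analytes, function(an) {
    mo <- panel$concentration[panel$analyte == an &
                                panel$condition == "mouse_only_media"]
    bl <- panel$concentration[panel$analyte == an & panel$condition == "blank"]
    threshold <- if (is.infinite(k_sd)) Inf else mean(bl) + k_sd * stats::sd(bl)
    mean(mo) > threshold && mean(mo) >= lod[[an]]
  }, logical(1))
  analytes[flagged]
}

#' Classify a secretion panel
#'
#' Assigns every analyte exactly one class, in order of precedence:
#' `excluded_cross_reactive` (in `cross_reactive`; no up/down call is made
#' for these), then `not_detected` (all biological wells below LOD), then
#' `upregulated` (Student's t-test p < alpha and EPS mean above control
#' mean), else `detected_not_upregulated`. There is no "downregulated"
#' class: a significant decrease still reports as detected-not-upregulated.
#' No multiple-testing correction is applied by default (per-analyte p <
#' alpha); `p_adjust = "BH"` switches the significance call to
#' Benjamini-Hochberg adjusted p-values across the tested analytes.
#'
#' @param panel Secretion panel `data.frame`.
#' @param cross_reactive Character vector of analytes to exclude; `NULL`
#'   (default) runs [detect_cross_reactive()] when the panel carries
#'   `mouse_only_media`/`blank` conditions, else none.
#' @param alpha Significance level (default 0.05).
#' @param k_sd Passed to [detect_cross_reactive()].
#' @param p_adjust `"none"` (default) or `"BH"`.
#' @param lod Per-analyte LOD (defaults to the panel attribute).
#' @return Object of class `panel_classification`: `table` (per analyte:
#'   class, group means +/- SE, `t`, `p`, `p_adj`), `excluded`, `alpha`,
#'   `counts` (class tally).
#' @export
classify_panel <- function(panel, cross_reactive = NULL, alpha = 0.05,
                           k_sd = 3, p_adjust = c("none", "BH"), lod = NULL) {
  p_adjust <- match.arg(p_adjust)
  check_number(alpha, "alpha", min = 0, max = 1, strict_min = TRUE)
  censored <- censor_lod(panel, lod)
  if (is.null(cross_reactive)) {
    cross_reactive <- if (all(c("mouse_only_media", "blank") %in%
                              panel$condition)) {
      detect_cross_reactive(panel, k_sd = k_sd, lod = censored$lod)
    } else {
      character(0)
    }
  }
  analytes <- unique(panel$analyte)
  rows <- lapply(analytes, function(an) {
    eps <- panel$concentration[panel$analyte == an & panel$condition == "EPS"]
    ctrl <- panel$concentration[panel$analyte == an &
                                  panel$condition == "control"]
    detected <- censored$detection$detected[censored$detection$analyte == an]
    cmp <- if (length(eps) >= 2L && length(ctrl) >= 2L) {
      compare_groups(eps, ctrl)
    } else {
      list(t = NA_real_, p = NA_real_, mean_a = mean(eps), se_a = NA_real_,
           mean_b = mean(ctrl), se_b = NA_real_)
    }
    data.frame(analyte = an, detected = detected,
               mean_eps = cmp$mean_a, se_eps = cmp$se_a,
               mean_control = cmp$mean_b, se_control = cmp$se_b,
               t = cmp$t, p = cmp$p)
  })
  tab <- do.call(rbind, rows)
  tab$excluded <- tab$analyte %in% cross_reactive
  testable <- !tab$excluded & tab$detected
  tab$p_adj <- NA_real_
  tab$p_adj[testable] <- stats::p.adjust(tab$p[testable],
                                         method = if (p_adjust == "BH") "BH"
                                                  else "none")
  p_used <- if (p_adjust == "BH") tab$p_adj else tab$p
  tab$class <- ifelse(
    tab$excluded, "excluded_cross_reactive",
    ifelse(!tab$detected, "not_detected",
           ifelse(!is.na(p_used) & p_used < alpha &
                    tab$mean_eps > tab$mean_control,
                  "upregulated", "detected_not_upregulated"))
  )
  # excluded analytes carry no up/down call
  tab$p_adj[tab$excluded] <- NA_real_
  counts <- table(factor(tab$class,
                         levels = c("upregulated", "detected_not_upregulated",
                                    "not_detected", "excluded_cross_reactive")))
  structure(list(table = tab, excluded = cross_reactive, alpha = alpha,
                 p_adjust = p_adjust, counts = counts),
            class = "panel_classification")
}

#' @export
print.panel_classification <- function(x, ...) {
  cat("<panel_classification>\n")
  print(x$counts)
  if (length(x$excluded)) {
    cat("excluded (cross-reactive):", paste(x$excluded, collapse = ", "), "\n")
  }
  invisible(x)
}
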