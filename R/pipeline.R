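#' Default end-to-end run configuration
#'
#' The template run emulates a complete hybrid-myotube contractility
#' experiment with three culture conditions — human myotubes alone (`HSMM`,
#' poorly contractile), mouse myotubes alone (`C2C12`, vigorously
#' contractile), and hybrid human/mouse myotubes (contractile at C2C12-like
#' levels) — three video fields per condition, seven nuclei fields at a
#' planted human fraction of 0.1425, a sorted-biopsy marker table, planted
#' qPCR fold changes for human and mouse IL-6/CXCL1, and the default
#' 40-analyte secretion panel with 4 wells per condition.
#'
#' @param seed Integer master seed; per-stage child seeds are derived from it
#'   by fixed offsets so stages are independently reproducible.
#' @return A list of class `run_config` with per-stage parameter blocks and
#'   shared analysis parameters.
#' @export
default_run_config <- function(seed = 1) {
  structure(list(
    seed = as.integer(seed),
    video = list(
      conditions = c(HSMM = 0.5, C2C12 = 6, hybrid = 6), # amplitude_px each
      n_fields = 3,
      width_px = 256, height_px = 256, fps = 14.4, stim_freq_hz = 1,
      duration_s = 5, n_myotubes = 5, noise_sd = 0.01, baseline = 0.1
    ),
    nuclei = list(
      n_fields = 7, human_fraction = 0.1425,
      n_nuclei_range = c(67, 140), width_px = 400, height_px = 400
    ),
    markers = list(
      n_cells = c(satellite = 60, blood = 50, endothelial = 40,
                  FAP = 25, other = 25),
      hi = 1000, lo = 10, sdlog = 0.4
    ),
    ct = list(
      fold_changes = c(IL6 = 6, CXCL1 = 8, Il6 = 12, Cxcl1 = 15),
      species = c(IL6 = "human", CXCL1 = "human",
                  Il6 = "mouse", Cxcl1 = "mouse"),
      noise_sd_ct = 0.2, n_reps = 3
    ),
    panel = list(
      classes = default_analyte_classes(),
      basal_pg_ml = 50, fold_upregulated = 20, lod_pg_ml = 5,
      noise_cv = 0.15, n_wells = 4
    ),
    analysis = list(
      window_s = 3, overlap_threshold = 0.5,
      gate_thresholds = c(CD11b = 100, CD31 = 100, CD34 = 100,
                          CD45 = 100, CD56 = 100),
      k_sd = 3, alpha = 0.05
    )
  ), class = "run_config")
}

validate_run_config <- function(config) {
  if (!is.list(config) || is.null(config$seed)) {
    stop_classed("config_error", "config must be a list with a `seed`")
  }
  a <- config$analysis
  if (is.null(a$alpha) || a$alpha <= 0 || a$alpha >= 1) {
    stop_classed("config_error", "analysis$alpha must lie in (0, 1)")
  }
  for (stage in c("video", "nuclei")) {
    blk <- config[[stage]]
    if (!is.null(blk) && !is.null(blk$paths) &&
        (!is.null(blk$conditions) || !is.null(blk$n_fields))) {
      stop_classed("config_error",
                   "stage `%s` specifies both input paths and simulation parameters",
                   stage)
    }
  }
  invisible(config)
}

# Fixed per-stage seed offsets; a single master seed fans out so each stage
# can be regenerated in isolation.
stage_seed <- function(seed, stage, i = 0, j = 0) {
  base <- c(video = 10000L, nuclei = 20000L, markers = 30000L,
            ct = 40000L, panel = 50000L)[[stage]]
  as.integer(seed) + base + 100L * as.integer(i) + as.integer(j)
}

#' Run the full synthetic-experiment pipeline
#'
#' Executes every enabled stage of a [default_run_config()]-style
#' configuration in order — video simulation + movement index per condition,
#' nuclei fields + human-nuclei ratio, marker table + satellite gate, Ct
#' table + relative expression, secretion panel + classification — and
#' assembles a report. Identical `(config, seed)` produce an identical
#' report. Set a stage's block to `NULL` to skip it.
#'
#' @param config A `run_config` list (see [default_run_config()]).
#' @param output_dir Optional directory; when given, writes `report.json`, a
#'   human-readable `summary.txt`, per-stage TSV tables, and a pseudo-colored
#'   overlay PNG per condition.
#' @return Object of class `run_report`: plain-data `report` (what
#'   `report.json` contains) and `details` (the rich per-stage result
#'   objects).
#' @export
run_all <- function(config = default_run_config(), output_dir = NULL) {
  validate_run_config(config)
  seed <- config$seed
  ana <- config$analysis
  details <- list()
  report <- list(provenance = list(
    package = "twitchindex",
    version = as.character(utils::packageVersion("twitchindex")),
    seed = seed
  ))

  if (!is.null(output_dir) &&
      !dir.exists(output_dir) && !dir.create(output_dir, recursive = TRUE)) {
    stop_classed("io_error", "cannot create output directory %s", output_dir)
  }

  if (!is.null(config$video)) {
    v <- config$video
    per_condition <- list()
    field_rows <- list()
    overlays <- list()
    for (ci in seq_along(v$conditions)) {
      cond <- names(v$conditions)[ci]
      results <- vector("list", v$n_fields)
      for (fi in seq_len(v$n_fields)) {
        sim <- simulate_myotube_field(video_sim_config(
          width_px = v$width_px, height_px = v$height_px, fps = v$fps,
          stim_freq_hz = v$stim_freq_hz, duration_s = v$duration_s,
          n_myotubes = v$n_myotubes, amplitude_px = v$conditions[[ci]],
          noise_sd = v$noise_sd, baseline = v$baseline,
          seed = stage_seed(seed, "video", ci, fi)
        ))
        results[[fi]] <- movement_index(
          sim$stack, stim_freq_hz = v$stim_freq_hz, window_s = ana$window_s,
          field_id = sprintf("%s_f%d", cond, fi)
        )
      }
      fs <- summarize_fields(results)
      per_condition[[cond]] <- fs
      overlays[[cond]] <- results[[1]]$overlay
      field_rows[[cond]] <- cbind(condition = cond, fs$fields)
    }
    mi_values <- lapply(per_condition, function(fs) fs$fields$movement_index)
    pairs <- utils::combn(names(v$conditions), 2, simplify = FALSE)
    tests <- do.call(rbind, lapply(pairs, function(p) {
      cmp <- compare_groups(mi_values[[p[1]]], mi_values[[p[2]]])
      data.frame(comparison = paste(p[1], "vs", p[2]),
                 t = cmp$t, p = cmp$p,
                 significant = cmp$p < ana$alpha)
    }))
    details$movement <- list(per_condition = per_condition, tests = tests,
                             overlays = overlays)
    report$movement <- list(
      conditions = data.frame(
        condition = names(per_condition),
        mean = vapply(per_condition, function(x) x$mean, numeric(1)),
        se = vapply(per_condition, function(x) x$se, numeric(1)),
        n_fields = vapply(per_condition, function(x) x$n_fields, numeric(1))
      ),
      fields = do.call(rbind, field_rows),
      tests = tests
    )
  }

  if (!is.null(config$nuclei)) {
    nu <- config$nuclei
    counts <- vector("list", nu$n_fields)
    planted <- integer(nu$n_fields)
    for (fi in seq_len(nu$n_fields)) {
      fseed <- stage_seed(seed, "nuclei", 0, fi)
      n_nuc <- with_seed(fseed + 99L,
                         sample(nu$n_nuclei_range[1]:nu$n_nuclei_range[2], 1))
      sim <- simulate_nuclei_field(
        n_nuclei = n_nuc, human_fraction = nu$human_fraction,
        width_px = nu$width_px, height_px = nu$height_px,
        seed = fseed, field_id = sprintf("field_%d", fi)
      )
      counts[[fi]] <- count_field(sim$field, ana$overlap_threshold)
      planted[fi] <- sim$truth$n_human
    }
    counts <- do.call(rbind, counts)
    rs <- ratio_summary(counts)
    details$nuclei <- list(summary = rs, planted_n_human = planted)
    report$nuclei <- list(
      fields = counts,
      mean_ratio = rs$mean, se_ratio = rs$se, n_fields = rs$n_fields,
      planted_fraction = nu$human_fraction
    )
  }

  if (!is.null(config$markers)) {
    mk <- config$markers
    tab <- simulate_marker_table(n_cells = mk$n_cells, hi = mk$hi, lo = mk$lo,
                                 sdlog = mk$sdlog,
                                 seed = stage_seed(seed, "markers"))
    gate <- gate_satellite_cells(tab, gate_config(ana$gate_thresholds))
    agree <- sum(gate$selected & tab$population == "satellite") +
      sum(!gate$selected & tab$population != "satellite")
    details$gating <- list(table = tab, gate = gate)
    report$gating <- list(
      n_cells = nrow(tab),
      n_selected = sum(gate$selected),
      n_true_satellite = sum(tab$population == "satellite"),
      truth_agreement = agree / max(1L, nrow(tab))
    )
  }

  if (!is.null(config$ct)) {
    cc <- config$ct
    sim <- simulate_ct_table(
      fold_changes = cc$fold_changes, species = cc$species,
      noise_sd_ct = cc$noise_sd_ct, n_reps = cc$n_reps,
      seed = stage_seed(seed, "ct")
    )
    expr <- relative_expression(sim$ct, alpha = ana$alpha)
    details$expression <- list(result = expr, truth = sim$truth)
    summ <- expr$summary
    summ$planted_fold <- unname(cc$fold_changes[summ$gene])
    report$expression <- summ
  }

  if (!is.null(config$panel)) {
    pn <- config$panel
    sim <- simulate_secretion_panel(
      classes = pn$classes, basal_pg_ml = pn$basal_pg_ml,
      fold_upregulated = pn$fold_upregulated, lod_pg_ml = pn$lod_pg_ml,
      noise_cv = pn$noise_cv, n_wells = pn$n_wells,
      seed = stage_seed(seed, "panel")
    )
    cls <- classify_panel(sim$panel, alpha = ana$alpha, k_sd = ana$k_sd)
    recovered <- mean(cls$table$class == recode_truth(sim$truth$classes[
      cls$table$analyte]))
    details$panel <- list(classification = cls, truth = sim$truth)
    report$panel <- list(
      counts = as.list(cls$counts),
      excluded = cls$excluded,
      truth_agreement = recovered,
      table = cls$table[, c("analyte", "class", "mean_eps", "se_eps",
                            "mean_control", "se_control", "t", "p")]
    )
  }

  out <- structure(list(report = report, details = details, config = config),
                   class = "run_report")
  if (!is.null(output_dir)) write_run_report(out, output_dir)
  out
}

# planted simulator classes -> classifier labels
recode_truth <- function(classes) {
  ifelse(classes == "cross_reactive", "excluded_cross_reactive", classes)
}

write_run_report <- function(x, output_dir) {
  stopifnot(inherits(x, "run_report"))
  jsonlite::write_json(x$report, file.path(output_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       dataframe = "rows")
  if (!is.null(x$report$movement)) {
    write_tsv(x$report$movement$fields,
              file.path(output_dir, "movement_fields.tsv"))
    write_tsv(x$report$movement$tests,
              file.path(output_dir, "movement_tests.tsv"))
    for (cond in names(x$details$movement$overlays)) {
      render_pseudocolor(x$details$movement$overlays[[cond]],
                         file.path(output_dir,
                                   sprintf("overlay_%s.png", cond)))
    }
  }
  if (!is.null(x$report$nuclei)) {
    write_tsv(x$report$nuclei$fields, file.path(output_dir, "nuclei_counts.tsv"))
  }
  if (!is.null(x$report$expression)) {
    write_tsv(x$report$expression, file.path(output_dir, "expression.tsv"))
  }
  if (!is.null(x$report$panel)) {
    write_tsv(x$report$panel$table, file.path(output_dir, "panel_classes.tsv"))
  }
  writeLines(format_run_summary(x), file.path(output_dir, "summary.txt"))
  invisible(output_dir)
}

format_run_summary <- function(x) {
  r <- x$report
  lines <- c(sprintf("twitchindex run (seed %d)", r$provenance$seed), "")
  if (!is.null(r$movement)) {
    lines <- c(lines, "Movement index (mean +/- SE per condition):")
    cm <- r$movement$conditions
    lines <- c(lines, sprintf("  %-8s %.6g +/- %.3g (n = %d)",
                              cm$condition, cm$mean, cm$se, cm$n_fields))
    lines <- c(lines, "Pairwise Student's t-tests:",
               sprintf("  %-22s t = %7.3f  p = %.4g%s",
                       r$movement$tests$comparison, r$movement$tests$t,
                       r$movement$tests$p,
                       ifelse(r$movement$tests$significant, " *", "")), "")
  }
  if (!is.null(r$nuclei)) {
    lines <- c(lines, sprintf(
      "Human nuclei: %.2f%% +/- %.2f%% over %d fields (planted %.2f%%)",
      100 * r$nuclei$mean_ratio, 100 * r$nuclei$se_ratio,
      r$nuclei$n_fields, 100 * r$nuclei$planted_fraction), "")
  }
  if (!is.null(r$gating)) {
    lines <- c(lines, sprintf(
      "Satellite gate: %d / %d cells selected (%d true; agreement %.3f)",
      r$gating$n_selected, r$gating$n_cells, r$gating$n_true_satellite,
      r$gating$truth_agreement), "")
  }
  if (!is.null(r$expression)) {
    e <- r$expression
    lines <- c(lines, "Relative expression (fold vs control):",
               sprintf("  %-6s (%s): fold %.2f (planted %.0f), p = %.4g%s",
                       e$gene, e$species, e$fold, e$planted_fold, e$p,
                       ifelse(e$significant, " *", "")), "")
  }
  if (!is.null(r$panel)) {
    cnt <- r$panel$counts
    lines <- c(lines, sprintf(
      "Secretion panel: %d upregulated, %d detected-not-upregulated, %d not detected, %d excluded (%s); truth agreement %.3f",
      cnt$upregulated, cnt$detected_not_upregulated, cnt$not_detected,
      cnt$excluded_cross_reactive,
      paste(r$panel$excluded, collapse = ", "),
      r$panel$truth_agreement))
  }
  lines
}

#' @export
print.run_report <- function(x, ...) {
  cat(paste(format_run_summary(x), collapse = "\n"), "\n")
  invisible(x)
}
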