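#' Label connected components of a binary mask
#'
#' 8-connectivity labeling (orthogonal and diagonal neighbors join), the
#' counting rule for nuclei in binary masks. Implemented as a vectorized
#' breadth-first flood fill; installed image toolkits label with
#' 4-connectivity only, which splits diagonally touching nuclei.
#'
#' @param mask Logical (or 0/1 numeric) matrix.
#' @return Integer matrix of the same shape; 0 is background, components are
#'   numbered from 1 in raster order of their first pixel.
#' @export
label_components <- function(mask) {
  if (!is.matrix(mask)) {
    stop_classed("parameter_error", "`mask` must be a matrix")
  }
  mask <- mask != 0
  h <- nrow(mask); w <- ncol(mask)
  labels <- matrix(0L, h, w)
  fg <- which(mask)
  if (length(fg) == 0L) return(labels)
  offsets <- expand.grid(dr = -1:1, dc = -1:1)
  offsets <- offsets[!(offsets$dr == 0 & offsets$dc == 0), ]
  current <- 0L
  for (start in fg) {
    if (labels[start] != 0L) next
    current <- current + 1L
    frontier <- start
    labels[start] <- current
    while (length(frontier) > 0L) {
      r <- ((frontier - 1L) %% h) + 1L
      c <- ((frontier - 1L) %/% h) + 1L
      nr <- rep(r, times = nrow(offsets)) + rep(offsets$dr, each = length(r))
      nc <- rep(c, times = nrow(offsets)) + rep(offsets$dc, each = length(r))
      ok <- nr >= 1L & nr <= h & nc >= 1L & nc <= w
      nidx <- (nc[ok] - 1L) * h + nr[ok]
      nidx <- unique(nidx[mask[nidx] & labels[nidx] == 0L])
      labels[nidx] <- current
      frontier <- nidx
    }
  }
  labels
}

#' Count total and human nuclei in a two-channel field
#'
#' Counts the 8-connected components of the all-nuclei (DAPI) mask, calls
#' each one HNA-positive (human) when at least `overlap_threshold` of its
#' area is covered by the HNA mask, and reports the human-nuclei ratio.
#'
#' @param field A `nuclei_field` (see [simulate_nuclei_field()]) or any list
#'   with logical `dapi_mask` / `hna_mask` matrices of equal shape and an
#'   optional `field_id`.
#' @param overlap_threshold Minimum area fraction of a DAPI component covered
#'   by the HNA channel to call it human (default 0.5).
#' @return A one-row `data.frame`: `field_id`, `n_total`, `n_hna_positive`,
#'   `ratio`. An empty DAPI mask yields `n_total = 0` and `ratio = NA`
#'   (missing, not zero).
#' @export
count_field <- function(field, overlap_threshold = 0.5) {
  dapi <- field$dapi_mask; hna <- field$hna_mask
  if (!is.matrix(dapi) || !is.matrix(hna) || !identical(dim(dapi), dim(hna))) {
    stop_classed("parameter_error", "masks must be matrices of the same shape")
  }
  check_number(overlap_threshold, "overlap_threshold", min = 0, max = 1,
               strict_min = TRUE)
  labels <- label_components(dapi)
  n_total <- max(labels)
  if (n_total == 0L) {
    return(data.frame(field_id = field$field_id %||% NA_character_,
                      n_total = 0L, n_hna_positive = 0L, ratio = NA_real_))
  }
  hna <- hna != 0
  lab_fg <- labels[labels > 0L]
  area <- tabulate(lab_fg, nbins = n_total)
  covered <- tabulate(lab_fg[hna[labels > 0L]], nbins = n_total)
  n_pos <- sum(covered / area >= overlap_threshold)
  data.frame(field_id = field$field_id %||% NA_character_,
             n_total = as.integer(n_total),
             n_hna_positive = as.integer(n_pos),
             ratio = n_pos / n_total)
}

#' Summarize human-nuclei ratios over fields
#'
#' Mean +/- standard error of per-field human-nuclei ratios. Fields with an
#' undefined ratio (no nuclei) are excluded from the summary and reported.
#'
#' @param counts A `data.frame` of per-field counts (rows from
#'   [count_field()]) or a list of such rows.
#' @return Object of class `ratio_summary`: `fields` (the usable per-field
#'   table), `mean`, `se`, `n_fields`, `excluded` (field ids with undefined
#'   ratio).
#' @export
ratio_summary <- function(counts) {
  if (is.list(counts) && !is.data.frame(counts)) {
    counts <- do.call(rbind, counts)
  }
  stopifnot(is.data.frame(counts),
            all(c("field_id", "n_total", "n_hna_positive", "ratio") %in%
                  names(counts)))
  usable <- !is.na(counts$ratio)
  if (!any(usable)) {
    stop_classed("parameter_error", "every field is empty: no ratio to summarize")
  }
  structure(list(
    fields = counts[usable, , drop = FALSE],
    mean = mean(counts$ratio[usable]),
    se = standard_error(counts$ratio[usable]),
    n_fields = sum(usable),
    excluded = counts$field_id[!usable]
  ), class = "ratio_summary")
}

#' @export
print.ratio_summary <- function(x, ...) {
  cat(sprintf("<ratio_summary> human nuclei: %.2f%% +/- %s%% over %d fields\n",
              100 * x$mean,
              if (is.na(x$se)) "NA" else sprintf("%.2f", 100 * x$se),
              x$n_fields))
  invisible(x)
}

#' Satellite-cell gate configuration
#'
#' Satellite cells are defined by the boolean marker rule
#' CD11b- CD31- CD34- CD45- CD56+: negative for the blood markers CD11b and
#' CD45 and the endothelial markers CD31 and CD34, positive for CD56. CD34
#' is a negative selection marker here (human muscle CD34+ cells are
#' adipogenic). PDGFRA (a fibro-adipogenic progenitor marker) is recorded
#' but not part of the gate.
#'
#' @param thresholds Named numeric vector of per-marker gate thresholds
#'   (fluorescence units, > 0) containing at least the five gate markers.
#' @return Object of class `gate_config`.
#' @export
gate_config <- function(thresholds) {
  gate_markers <- setdiff(satellite_panel_markers(), "PDGFRA")
  if (is.null(names(thresholds)) ||
      !all(gate_markers %in% names(thresholds))) {
    stop_classed("schema_error", "thresholds must name all of: %s",
                 paste(gate_markers, collapse = ", "))
  }
  if (any(thresholds <= 0) || anyNA(thresholds)) {
    stop_classed("parameter_error", "thresholds must be > 0")
  }
  structure(list(thresholds = thresholds[gate_markers],
                 gate_markers = gate_markers),
            class = "gate_config")
}

#' Apply the satellite-cell boolean gate
#'
#' Selects rows of a marker table satisfying CD11b < thr & CD31 < thr &
#' CD34 < thr & CD45 < thr & CD56 >= thr with per-marker thresholds.
#'
#' @param table Marker table with one row per cell (see
#'   [simulate_marker_table()]).
#' @param config A [gate_config()], or a named threshold vector passed to it.
#' @return List with `selected` (logical per row) and `cells` (the selected
#'   subtable).
#' @export
gate_satellite_cells <- function(table, config) {
  if (!inherits(config, "gate_config")) config <- gate_config(config)
  missing_cols <- setdiff(config$gate_markers, names(table))
  if (length(missing_cols) > 0L) {
    stop_classed("schema_error", "marker table lacks columns: %s",
                 paste(missing_cols, collapse = ", "))
  }
  thr <- config$thresholds
  selected <- table$CD11b < thr[["CD11b"]] &
    table$CD31 < thr[["CD31"]] &
    table$CD34 < thr[["CD34"]] &
    table$CD45 < thr[["CD45"]] &
    table$CD56 >= thr[["CD56"]]
  list(selected = selected, cells = table[selected, , drop = FALSE])
}
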