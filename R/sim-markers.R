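#' Markers measured in the satellite-cell sorting panel
#' @return Character vector of the six marker columns.
#' @export
satellite_panel_markers <- function() {
  c("CD11b", "CD31", "CD34", "CD45", "CD56", "PDGFRA")
}

#' Simulate a per-cell marker-intensity table
#'
#' Emulates the fluorescence intensities seen when sorting satellite cells
#' out of a digested muscle biopsy. Five populations are modeled: `satellite`
#' (CD56-bright, lineage-negative), `blood` (CD11b/CD45-bright), `endothelial`
#' (CD31/CD34-bright), `FAP` (fibro-adipogenic progenitors, PDGFRA-bright),
#' and `other` (dim in everything). Intensities are log-normal; the `hi` and
#' `lo` location parameters are shared across markers, so the separation
#' between positive and negative populations is `(log(hi) - log(lo)) / sdlog`
#' standard deviations on the log scale.
#'
#' @param n_cells Named integer vector of cells per population; names must be
#'   a subset of the five populations above.
#' @param hi,lo Median intensity of bright and dim markers (arbitrary
#'   fluorescence units).
#' @param sdlog Log-scale standard deviation of every marker.
#' @param seed Integer RNG seed.
#' @return A `data.frame` with one row per cell: `cell_id`, the six marker
#'   intensities, and the ground-truth `population` label.
#' @export
simulate_marker_table <- function(n_cells = c(satellite = 60, blood = 50,
                                              endothelial = 40, FAP = 25,
                                              other = 25),
                                  hi = 1000, lo = 10, sdlog = 0.4, seed) {
  if (missing(seed)) stop_classed("parameter_error", "`seed` is mandatory")
  pops <- c("satellite", "blood", "endothelial", "FAP", "other")
  if (is.null(names(n_cells)) || !all(names(n_cells) %in% pops)) {
    stop_classed("parameter_error",
                 "n_cells must be named with populations among: %s",
                 paste(pops, collapse = ", "))
  }
  if (any(n_cells < 0)) stop_classed("parameter_error", "n_cells must be >= 0")
  check_number(hi, "hi", min = 0, strict_min = TRUE)
  check_number(lo, "lo", min = 0, strict_min = TRUE)
  check_number(sdlog, "sdlog", min = 0, strict_min = TRUE)

  bright <- list(
    satellite = "CD56",
    blood = c("CD11b", "CD45"),
    endothelial = c("CD31", "CD34"),
    FAP = "PDGFRA",
    other = character(0)
  )
  markers <- satellite_panel_markers()

  with_seed(seed, {
    blocks <- lapply(names(n_cells), function(pop) {
      k <- n_cells[[pop]]
      if (k == 0) return(NULL)
      block <- as.data.frame(lapply(markers, function(m) {
        mu <- if (m %in% bright[[pop]]) log(hi) else log(lo)
        stats::rlnorm(k, meanlog = mu, sdlog = sdlog)
      }))
      names(block) <- markers
      block$population <- pop
      block
    })
    tab <- do.call(rbind, blocks)
    if (is.null(tab)) {
      tab <- as.data.frame(matrix(numeric(0), 0, length(markers),
                                  dimnames = list(NULL, markers)))
      tab$population <- character(0)
    }
    tab <- cbind(cell_id = seq_len(nrow(tab)), tab)
    rownames(tab) <- NULL
    tab
  })
}
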