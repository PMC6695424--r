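#' Default species -> reference gene map for relative expression
#'
#' In hybrid (two-species) cultures each species is normalized to its own
#' reference transcript: mouse GAPDH and human RPLP0.
#'
#' @return Named character vector `c(human = "RPLP0", mouse = "GAPDH")`.
#' @export
default_reference_genes <- function() {
  c(human = "RPLP0", mouse = "GAPDH")
}

#' Simulate a qPCR Ct table with planted fold changes
#'
#' Generates threshold-cycle (Ct) values for target genes measured with
#' species-specific primers in stimulated (`EPS`) and unstimulated
#' (`control`) samples, plus the per-species reference genes. A planted fold
#' change `f` for a gene lowers its EPS-condition Ct by `log2(f)` cycles
#' relative to control; reference genes are identically distributed across
#' conditions. Gaussian technical noise of `noise_sd_ct` cycles is added to
#' every measurement.
#'
#' @param fold_changes Named numeric vector: planted EPS/control fold change
#'   per target gene (must be > 0).
#' @param species Named character vector mapping each target gene to
#'   `"human"` or `"mouse"` (same names as `fold_changes`).
#' @param reference_genes Species -> reference gene map (see
#'   [default_reference_genes()]).
#' @param ct_ref_mean Mean Ct of reference genes.
#' @param ct_target_mean Mean control-condition Ct of target genes; scalar or
#'   named per gene.
#' @param noise_sd_ct SD of Ct noise, cycles.
#' @param n_reps Biological replicates per condition.
#' @param seed Integer RNG seed.
#' @return A list with `ct` (a `data.frame` with columns `sample`,
#'   `condition`, `species`, `gene`, `ct_value`) and `truth` (planted fold
#'   changes and the seed).
#' @export
simulate_ct_table <- function(fold_changes, species,
                              reference_genes = default_reference_genes(),
                              ct_ref_mean = 18, ct_target_mean = 25,
                              noise_sd_ct = 0.2, n_reps = 3, seed) {
  if (missing(seed)) stop_classed("parameter_error", "`seed` is mandatory")
  if (is.null(names(fold_changes)) || any(fold_changes <= 0) ||
      anyNA(fold_changes)) {
    stop_classed("parameter_error", "fold_changes must be named and > 0")
  }
  if (!setequal(names(species), names(fold_changes))) {
    stop_classed("parameter_error",
                 "`species` must name the same genes as `fold_changes`")
  }
  if (!all(species %in% names(reference_genes))) {
    stop_classed("parameter_error", "every species needs a reference gene")
  }
  check_number(noise_sd_ct, "noise_sd_ct", min = 0)
  check_number(n_reps, "n_reps", min = 1)

  genes <- names(fold_changes)
  target_mu <- if (length(ct_target_mean) == 1L) {
    stats::setNames(rep(ct_target_mean, length(genes)), genes)
  } else {
    ct_target_mean[genes]
  }

  with_seed(seed, {
    rows <- list()
    for (cond in c("control", "EPS")) {
      for (rep_i in seq_len(n_reps)) {
        sample_id <- sprintf("%s_%d", cond, rep_i)
        for (sp in unique(species)) {
          ref <- reference_genes[[sp]]
          rows[[length(rows) + 1L]] <- data.frame(
            sample = sample_id, condition = cond, species = sp, gene = ref,
            ct_value = ct_ref_mean + stats::rnorm(1, sd = noise_sd_ct)
          )
        }
        for (g in genes) {
          shift <- if (cond == "EPS") log2(fold_changes[[g]]) else 0
          rows[[length(rows) + 1L]] <- data.frame(
            sample = sample_id, condition = cond, species = species[[g]],
            gene = g,
            ct_value = target_mu[[g]] - shift + stats::rnorm(1, sd = noise_sd_ct)
          )
        }
      }
    }
    ct <- do.call(rbind, rows)
    rownames(ct) <- NULL
    if (any(ct$ct_value <= 0) || any(ct$ct_value >= 45)) {
      stop_classed("parameter_error",
                   "simulated Ct values fell outside (0, 45); adjust means/folds")
    }
    truth <- structure(list(fold_changes = fold_changes, species = species,
                            noise_sd_ct = noise_sd_ct, seed = as.integer(seed)),
                       class = "sim_truth")
    list(ct = ct, truth = truth)
  })
}
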