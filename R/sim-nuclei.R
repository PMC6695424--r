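#' Simulate a two-channel nuclei field
#'
#' Generates a pair of binary masks emulating a microscopy field of a hybrid
#' (human-mouse heterokaryon) myotube culture stained for all nuclei (DAPI
#' channel) and for human nuclei only (human nuclear antigen, HNA, channel).
#' Nuclei are non-overlapping filled ellipses; a seeded binomial draw
#' determines how many of them are human, and the exact subset is recorded in
#' the truth sidecar so counting can be validated against ground truth.
#'
#' The default `human_fraction` of 0.1425 reflects the typical human-nuclei
#' proportion observed in 1:1-seeded human/mouse hybrid cultures after a week
#' of differentiation, where the faster-growing mouse cells dominate.
#'
#' @param n_nuclei Number of nuclei to place.
#' @param human_fraction Probability that a nucleus is human (HNA-positive).
#' @param width_px,height_px Field size in pixels.
#' @param radius_px Length-2 range of nucleus semi-major axes, pixels.
#' @param seed Integer RNG seed.
#' @param field_id Label for the field.
#' @param max_tries Placement attempts per nucleus before giving up.
#' @return A list with `field` (class `nuclei_field`: logical `dapi_mask`,
#'   `hna_mask`, and `field_id`) and `truth` (a `sim_truth` list with the
#'   planted human indices, the binomial count, and the seed).
#' @export
simulate_nuclei_field <- function(n_nuclei, human_fraction = 0.1425,
                                  width_px = 400, height_px = 400,
                                  radius_px = c(4, 7), seed,
                                  field_id = "field_1", max_tries = 500L) {
  if (missing(seed)) stop_classed("parameter_error", "`seed` is mandatory")
  check_number(n_nuclei, "n_nuclei", min = 0)
  check_number(human_fraction, "human_fraction", min = 0, max = 1)
  stopifnot(length(radius_px) == 2L, all(radius_px > 0))

  with_seed(seed, {
    H <- as.integer(height_px); W <- as.integer(width_px)
    n <- as.integer(n_nuclei)
    a <- stats::runif(n, radius_px[1], radius_px[2])       # semi-major axis
    b <- a * stats::runif(n, 0.7, 1)                       # semi-minor axis
    ang <- stats::runif(n, 0, pi)
    cx <- numeric(n); cy <- numeric(n)
    gap <- 2 # guard band so 8-connected components never merge
    placed_x <- numeric(0); placed_y <- numeric(0); placed_r <- numeric(0)
    for (i in seq_len(n)) {
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        x <- stats::runif(1, a[i] + 1, W - a[i] - 1)
        y <- stats::runif(1, a[i] + 1, H - a[i] - 1)
        if (length(placed_x) == 0L ||
            all((placed_x - x)^2 + (placed_y - y)^2 >
                (placed_r + a[i] + gap)^2)) {
          ok <- TRUE; break
        }
      }
      if (!ok) {
        stop_classed("geometry_error",
                     "could not place %d non-overlapping nuclei in a %d x %d field",
                     n, W, H)
      }
      cx[i] <- x; cy[i] <- y
      placed_x <- c(placed_x, x); placed_y <- c(placed_y, y)
      placed_r <- c(placed_r, a[i])
    }

    rasterize <- function(indices) {
      m <- matrix(FALSE, H, W)
      for (i in indices) {
        x0 <- max(1L, floor(cx[i] - a[i])); x1 <- min(W, ceiling(cx[i] + a[i]))
        y0 <- max(1L, floor(cy[i] - a[i])); y1 <- min(H, ceiling(cy[i] + a[i]))
        xs <- x0:x1; ys <- y0:y1
        dx <- matrix(rep(xs - cx[i], each = length(ys)), length(ys))
        dy <- matrix(rep(ys - cy[i], times = length(xs)), length(ys))
        u <- dx * cos(ang[i]) + dy * sin(ang[i])
        v <- -dx * sin(ang[i]) + dy * cos(ang[i])
        inside <- (u / a[i])^2 + (v / b[i])^2 <= 1
        m[ys, xs] <- m[ys, xs] | inside
      }
      m
    }

    n_human <- if (n > 0) stats::rbinom(1, n, human_fraction) else 0L
    human_idx <- if (n_human > 0) sort(sample.int(n, n_human)) else integer(0)

    field <- structure(list(
      dapi_mask = rasterize(seq_len(n)),
      hna_mask = rasterize(human_idx),
      field_id = field_id
    ), class = "nuclei_field")

    truth <- structure(list(
      n_nuclei = n, human_indices = human_idx, n_human = as.integer(n_human),
      human_fraction = human_fraction, seed = as.integer(seed)
    ), class = "sim_truth")

    list(field = field, truth = truth)
  })
}
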