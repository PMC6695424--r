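# Independent brute-force oracles. These deliberately share no code with the
# package: scalar loops and textbook formulas only.

# Full naive recomputation of the movement index from raw frames: explicit
# loops for the activity trace, moving-average smoothing, first-peak search,
# frame pairing, subtraction, and overlay averaging.
oracle_movement_index <- function(frames, fps, stim_freq_hz, window_s,
                                  prominence_frac = 0.25) {
  H <- dim(frames)[1]; W <- dim(frames)[2]; T <- dim(frames)[3]
  rhu <- function(x) floor(x + 0.5)

  a <- numeric(T)
  for (t in 2:T) {
    s <- 0
    for (r in 1:H) for (c in 1:W) s <- s + abs(frames[r, c, t] - frames[r, c, t - 1])
    a[t] <- s / (H * W)
  }

  width <- max(1, rhu(fps / (4 * stim_freq_hz)))
  if (width %% 2 == 0) width <- width + 1
  half <- (width - 1) / 2
  sm <- numeric(T)
  for (t in 1:T) {
    s <- 0
    for (dlt in -half:half) {
      u <- min(max(t + dlt, 1), T) # edge replication
      s <- s + a[u]
    }
    sm[t] <- s / width
  }

  med <- stats::median(sm)
  rng <- max(sm) - med
  start <- NA
  if (rng > 0) {
    threshold <- med + prominence_frac * rng
    t <- 2
    while (t <= T && is.na(start)) {
      if (sm[t] > sm[t - 1]) {
        # scan over a possible plateau of equal values
        e <- t
        while (e < T && sm[e + 1] == sm[t]) e <- e + 1
        if ((e == T || sm[e + 1] < sm[t]) && sm[t] >= threshold) start <- t
        t <- e + 1
      } else {
        t <- t + 1
      }
    }
  }
  non_contractile <- is.na(start)
  if (non_contractile) start <- 1

  acc <- matrix(0, H, W)
  used <- 0
  for (k in 0:(floor(window_s * stim_freq_hz) - 1)) {
    ci <- start + rhu(k * fps / stim_freq_hz)
    ri <- ci + rhu(fps / (2 * stim_freq_hz))
    if (ci > T || ri > T) next
    for (r in 1:H) for (c in 1:W) {
      acc[r, c] <- acc[r, c] + abs(frames[r, c, ci] - frames[r, c, ri])
    }
    used <- used + 1
  }
  stopifnot(used >= 1)
  total <- 0
  for (r in 1:H) for (c in 1:W) total <- total + acc[r, c] / used
  list(movement_index = total / (H * W), start = start,
       non_contractile = non_contractile)
}

# Naive 8-connectivity component count: explicit depth-first fill, one pixel
# at a time.
oracle_component_count <- function(mask) {
  mask <- mask != 0
  h <- nrow(mask); w <- ncol(mask)
  seen <- matrix(FALSE, h, w)
  count <- 0L
  for (c0 in 1:w) for (r0 in 1:h) {
    if (!mask[r0, c0] || seen[r0, c0]) next
    count <- count + 1L
    stack <- list(c(r0, c0))
    seen[r0, c0] <- TRUE
    while (length(stack) > 0) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        r <- p[1] + dr; c <- p[2] + dc
        if (r >= 1 && r <= h && c >= 1 && c <= w &&
            mask[r, c] && !seen[r, c]) {
          seen[r, c] <- TRUE
          stack[[length(stack) + 1]] <- c(r, c)
        }
      }
    }
  }
  count
}

# Textbook pooled-variance two-sample t-test.
oracle_pooled_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  tval <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = tval, p = 2 * stats::pt(-abs(tval), na + nb - 2))
}

# Row-by-row satellite gate predicate.
oracle_gate <- function(table, thr) {
  out <- logical(nrow(table))
  for (i in seq_len(nrow(table))) {
    out[i] <- table$CD11b[i] < thr[["CD11b"]] &&
      table$CD31[i] < thr[["CD31"]] &&
      table$CD34[i] < thr[["CD34"]] &&
      table$CD45[i] < thr[["CD45"]] &&
      table$CD56[i] >= thr[["CD56"]]
  }
  out
}

# Random binary mask for labeling comparisons.
with_seed_matrix <- function(seed, h = 20, w = 20, p = 0.3) {
  set.seed(seed)
  matrix(stats::runif(h * w) < p, h, w)
}

# Small toy stack with two genuine stimulation cycles: a bright square whose
# intensity follows a rise/decay twitch at 10 fps, 1 Hz, on a 6x6 field.
make_toy_stack <- function(n_frames = 25, fps = 10) {
  s <- simulate_twitch_trace(fps = fps, stim_freq_hz = 1,
                             duration_s = n_frames / fps)
  frames <- array(0.2, dim = c(6, 6, n_frames))
  for (t in seq_len(n_frames)) {
    frames[2:4, 3:5, t] <- 0.2 + 0.5 * s[t]
  }
  frame_stack(frames, fps = fps)
}
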