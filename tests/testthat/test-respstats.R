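test_that("group comparison matches the textbook pooled t-test", {
  a <- c(1, 2, 3); b <- c(4, 5, 6)
  cmp <- compare_groups(a, b)
  orc <- oracle_pooled_t(a, b)
  expect_equal(cmp$t, orc$t, tolerance = 1e-12)
  expect_equal(cmp$p, orc$p, tolerance = 1e-12)
  # closed form: pooled SD 1, SE sqrt(2/3), t = -3 / sqrt(2/3)
  expect_equal(cmp$t, -3 / sqrt(2 / 3), tolerance = 1e-9)
  expect_equal(cmp$mean_a, 2)
  expect_equal(cmp$se_a, 1 / sqrt(3))
})

test_that("degenerate comparisons are handled explicitly", {
  same <- compare_groups(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  const_eq <- compare_groups(c(2, 2), c(2, 2))
  expect_identical(const_eq$p, 1)
  const_ne <- compare_groups(c(3, 3), c(2, 2))
  expect_identical(const_ne$p, 0)
  expect_error(compare_groups(1, c(1, 2)), class = "parameter_error")
})

test_that("relative expression follows the delta-delta-Ct convention", {
  # control dCt = 5 exactly, EPS dCt = 3 exactly -> fold 4
  ct <- rbind(
    data.frame(sample = paste0("c", 1:3), condition = "control",
               species = "human", gene = "RPLP0", ct_value = 18),
    data.frame(sample = paste0("c", 1:3), condition = "control",
               species = "human", gene = "GOI", ct_value = 23),
    data.frame(sample = paste0("e", 1:3), condition = "EPS",
               species = "human", gene = "RPLP0", ct_value = 18),
    data.frame(sample = paste0("e", 1:3), condition = "EPS",
               species = "human", gene = "GOI", ct_value = 21)
  )
  res <- relative_expression(ct)
  expect_equal(res$summary$fold, 4)
  expect_equal(res$summary$mean_control, 1) # control mean is 1 by construction
  samples <- res$samples
  expect_equal(samples$relative_level[samples$condition == "control"],
               rep(1, 3))
  # flat gene: everything 1
  flat <- ct
  flat$ct_value[flat$gene == "GOI"] <- 18
  rf <- relative_expression(flat)
  expect_equal(rf$summary$fold, 1)
  expect_equal(rf$samples$relative_level, rep(1, 6))
})

test_that("a missing reference gene is a schema error", {
  ct <- data.frame(sample = "s1", condition = "control", species = "human",
                   gene = "GOI", ct_value = 25)
  expect_error(relative_expression(ct), class = "schema_error")
})

test_that("relative expression normalizes every gene's control mean to 1", {
  sim <- simulate_ct_table(c(A = 3, B = 0.5, C = 1),
                           c(A = "human", B = "mouse", C = "human"),
                           noise_sd_ct = 0.3, n_reps = 4, seed = 6)
  res <- relative_expression(sim$ct)
  ctrl <- res$samples[res$samples$condition == "control", ]
  means <- tapply(ctrl$relative_level, ctrl$gene, mean)
  expect_equal(as.numeric(means), rep(1, 3), tolerance = 1e-12)
})

test_that("LOD censoring requires every biological well below the limit", {
  panel <- rbind(
    data.frame(analyte = "X", well = paste0("e", 1:3), condition = "EPS",
               concentration = c(1, 2, 8)),
    data.frame(analyte = "X", well = paste0("c", 1:3), condition = "control",
               concentration = c(1, 1, 2)),
    data.frame(analyte = "Y", well = paste0("e", 1:3), condition = "EPS",
               concentration = c(1, 2, 3)),
    data.frame(analyte = "Y", well = paste0("c", 1:3), condition = "control",
               concentration = c(1, 1, 2))
  )
  cen <- censor_lod(panel, lod = 5)
  det <- stats::setNames(cen$detection$detected, cen$detection$analyte)
  expect_true(det[["X"]])   # one EPS well at 8 >= 5
  expect_false(det[["Y"]])  # all wells below 5
  expect_identical(sum(cen$wells$below_lod), 11L)
})

test_that("cross-reactivity detection keys on mouse-only media", {
  sim <- simulate_secretion_panel(seed = 5)
  expect_setequal(detect_cross_reactive(sim$panel),
                  c("CX3CL1", "CCL3", "CCL12"))
  expect_identical(detect_cross_reactive(sim$panel, k_sd = Inf), character(0))
  # mouse-only identical to blank: nothing is flagged
  quiet <- sim$panel
  quiet$concentration[quiet$condition == "mouse_only_media"] <-
    quiet$concentration[quiet$condition == "blank"]
  expect_identical(detect_cross_reactive(quiet), character(0))
  no_mouse <- sim$panel[sim$panel$condition != "mouse_only_media", ]
  expect_error(detect_cross_reactive(no_mouse), class = "schema_error")
})

test_that("panel classification applies the precedence order", {
  sim <- simulate_secretion_panel(seed = 5)
  cls <- classify_panel(sim$panel)
  got <- stats::setNames(cls$table$class, cls$table$analyte)
  truth <- sim$truth$classes
  truth[truth == "cross_reactive"] <- "excluded_cross_reactive"
  expect_identical(got[names(truth)], truth)
  # a significantly *lower* EPS mean is not called upregulated
  down <- rbind(
    data.frame(analyte = "D", well = paste0("e", 1:4), condition = "EPS",
               concentration = c(10, 11, 10, 12)),
    data.frame(analyte = "D", well = paste0("c", 1:4), condition = "control",
               concentration = c(50, 52, 49, 51)),
    data.frame(analyte = "D", well = paste0("m", 1:4),
               condition = "mouse_only_media", concentration = 0.2),
    data.frame(analyte = "D", well = paste0("b", 1:4), condition = "blank",
               concentration = c(0.2, 0.25, 0.2, 0.22))
  )
  cd <- classify_panel(down, lod = 5)
  expect_identical(cd$table$class, "detected_not_upregulated")
  expect_lt(cd$table$p, 0.05)
})

test_that("all-below-LOD panels classify everything as not detected", {
  classes <- stats::setNames(rep("not_detected", 5),
                             paste0("A", 1:5))
  sim <- simulate_secretion_panel(classes, lod_pg_ml = 3, seed = 2)
  cls <- classify_panel(sim$panel)
  expect_true(all(cls$table$class == "not_detected"))
})

test_that("BH adjustment is available but off by default", {
  sim <- simulate_secretion_panel(seed = 5)
  raw <- classify_panel(sim$panel)
  bh <- classify_panel(sim$panel, p_adjust = "BH")
  expect_true(all(is.na(raw$table$p_adj) |
                    raw$table$p_adj == raw$table$p))
  testable <- !bh$table$excluded & bh$table$detected
  expect_true(all(bh$table$p_adj[testable] >= bh$table$p[testable]))
})
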