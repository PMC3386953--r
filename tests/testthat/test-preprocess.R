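# Background correction, cross-hybridizer removal, median-polish probe
# effects and presence detection.

test_that("background correction subtracts per-sample means with a floor", {
  ann <- probe_annotation(toy_annotation_df(n_background = 2L))
  vals <- matrix(c(150, 40, 80, 120, 60, 70,  # genomic P1..P6, sample s1
                   150, 40, 80, 120, 60, 70), ncol = 2,
                 dimnames = list(c("P1", "P2", "P3", "P4", "P5", "P6"),
                                 c("s1", "s2")))
  vals <- rbind(vals, BG1 = c(40, 60), BG2 = c(60, 40))  # mean 50 both samples
  m <- intensity_matrix(vals)
  corr <- background_correct(m, ann, floor_epsilon = 1)
  expect_true(corr$background_corrected)
  expect_identical(corr$values["P1", "s1"], 100)   # 150 - 50
  expect_identical(corr$values["P2", "s1"], 1)     # 40 - 50 floored
  expect_equal(unname(attr(corr, "background_means")), c(50, 50))
  expect_error(background_correct(corr, ann), "already",
               class = "exonsplice_data_error")
  # no background probes and no constant -> instructive error
  ann2 <- probe_annotation(toy_annotation_df(0L))
  m2 <- intensity_matrix(vals[1:6, ])
  expect_error(background_correct(m2, ann2), "background_constant",
               class = "exonsplice_data_error")
  expect_identical(
    background_correct(m2, ann2, background_constant = 50)$values["P1", "s1"],
    100)
})

test_that("corrected background probes sit at the epsilon floor on average", {
  sim <- simulate_experiment(small_sim_config())
  corr <- background_correct(sim$intensities, sim$annotation, floor_epsilon = 1)
  bg_rows <- corr$values[grep("^BG", rownames(corr$values)), ]
  # roughly half the background draws fall below their per-sample mean and
  # are floored; what remains is centered near zero
  expect_true(all(colMeans(bg_rows == 1) > 0.3))
  expect_true(all(colMeans(bg_rows) < sim$config$background_sd))
})

test_that("cross-hybridizer removal matches the planted truth", {
  ann <- probe_annotation(within(toy_annotation_df(), {
    cross_hyb_flag <- probe_id %in% c("P2", "P5", "P6")  # PS3 fully flagged
  }))
  m <- toy_intensity(matrix(1:12, 6, 2), probes = sprintf("P%d", 1:6),
                     samples = c("s1", "s2"))
  res <- drop_cross_hyb(m, ann)
  expect_identical(probe_ids(res$matrix), c("P1", "P3", "P4"))
  expect_setequal(res$report$dropped_probes, c("P2", "P5", "P6"))
  expect_identical(res$report$empty_probesets, "PS3")

  sim <- simulate_experiment(small_sim_config(frac_cross_hyb = 0.05))
  res <- drop_cross_hyb(sim$intensities, sim$annotation)
  expect_setequal(res$report$dropped_probes, sim$truth$cross_hyb)
})

test_that("median polish agrees with the stats::medpolish oracle", {
  set.seed(42)
  for (i in 1:5) {
    x <- matrix(stats::rnorm(8 * 6), 8, 6)
    ours <- exonsplice:::median_polish(x, max_iter = 200L, tol = 1e-10)
    # eps = 0 forces medpolish to the fixed point (its relative residual-sum
    # stopping rule can fire long before the effects stabilize)
    ref <- suppressWarnings(
      stats::medpolish(x, maxiter = 200L, eps = 0, trace.iter = FALSE))
    expect_equal(ours$row, unname(ref$row), tolerance = 1e-6)
    expect_equal(ours$col, unname(ref$col), tolerance = 1e-6)
    expect_equal(ours$overall, ref$overall, tolerance = 1e-6)
    expect_true(ours$converged)
  }
})

test_that("probe-effect estimation recovers planted affinities without noise", {
  sim <- simulate_experiment(small_sim_config(
    noise_sd = 0, background_sd = 0, frac_de = 0, frac_as = 0,
    frac_cross_hyb = 0, baseline_log2_sd = 0.5))
  corr <- background_correct(sim$intensities, sim$annotation)
  eff <- estimate_probe_effects(corr, sim$annotation)
  g <- eff[eff$probeset_id != "", ]
  planted <- stats::setNames(sim$truth$affinity$affinity,
                             sim$truth$affinity$probe_id)[g$probe_id]
  centered <- planted - stats::ave(planted, g$probeset_id)
  rmse <- sqrt(mean((g$affinity - centered)^2))
  expect_lt(rmse, 0.05)
  # invariant: per-probeset affinities sum to zero
  expect_equal(max(abs(tapply(g$affinity, g$probeset_id, sum))), 0,
               tolerance = 1e-9)
})

test_that("probe effects are zero for constant data and shift predictably", {
  ann <- probe_annotation(toy_annotation_df())
  vals <- matrix(64, 6, 4, dimnames = list(sprintf("P%d", 1:6),
                                           sprintf("s%d", 1:4)))
  m <- intensity_matrix(vals, background_corrected = TRUE)
  eff <- estimate_probe_effects(m, ann)
  expect_equal(eff$affinity, rep(0, 6))

  # adding c to one probe's log2 row moves its affinity by ~ c * (1 - 1/n)
  vals2 <- vals; vals2["P1", ] <- vals2["P1", ] * 2^1.5  # c = 1.5, n = 2 in PS1
  eff2 <- estimate_probe_effects(intensity_matrix(vals2, background_corrected = TRUE), ann)
  expect_equal(eff2$affinity[eff2$probe_id == "P1"], 1.5 * (1 - 1 / 2),
               tolerance = 1e-6)
})

test_that("probe-effect estimation is invariant to relabeling and offsets", {
  sim <- simulate_experiment(small_sim_config(n_transcripts = 30))
  corr <- background_correct(sim$intensities, sim$annotation)
  eff <- estimate_probe_effects(corr, sim$annotation)
  # permute samples
  perm <- sample(ncol(corr$values))
  m_perm <- intensity_matrix(corr$values[, perm], background_corrected = TRUE)
  eff_perm <- estimate_probe_effects(m_perm, sim$annotation)
  expect_equal(eff$affinity, eff_perm$affinity, tolerance = 1e-10)
  # add a constant on the log2 scale
  m_shift <- intensity_matrix(corr$values * 2^3, background_corrected = TRUE)
  eff_shift <- estimate_probe_effects(m_shift, sim$annotation)
  expect_equal(eff$affinity, eff_shift$affinity, tolerance = 1e-10)
})

test_that("applying probe effects is invertible and idempotent at zero", {
  sim <- simulate_experiment(small_sim_config(n_transcripts = 30))
  corr <- background_correct(sim$intensities, sim$annotation)
  eff <- estimate_probe_effects(corr, sim$annotation)
  fixed <- apply_probe_effects(corr, eff)
  # re-estimating on corrected data returns ~zero affinities
  eff2 <- estimate_probe_effects(fixed, sim$annotation)
  expect_lt(max(abs(eff2$affinity)), 0.05)
  # round trip
  neg <- eff; neg$affinity <- -neg$affinity
  back <- apply_probe_effects(fixed, neg)
  expect_equal(back$values, corr$values, tolerance = 1e-12)
  # zero effects = identity
  zero <- eff; zero$affinity <- 0
  expect_equal(apply_probe_effects(corr, zero)$values, corr$values)
  # missing probe errors
  expect_error(apply_probe_effects(corr, eff[-1, ]), "missing",
               class = "exonsplice_data_error")
})

test_that("presence detection separates expressed from background-level transcripts", {
  sim <- simulate_experiment(small_sim_config(baseline_log2_mean = 10,
                                              baseline_log2_sd = 0.3,
                                              frac_de = 0, frac_as = 0))
  calls <- detect_present(sim$intensities, sim$annotation, sim$design)
  expect_true(all(calls$present))  # everything far above background

  # a transcript switched off in naive (large planted negative shift makes it
  # background-level there) stays present in the affected condition only if
  # detection is condition-wise
  low <- simulate_experiment(small_sim_config(
    baseline_log2_mean = 1, baseline_log2_sd = 0.1, frac_de = 0, frac_as = 0))
  low_calls <- detect_present(low$intensities, low$annotation, low$design)
  expect_false(any(low_calls$present))  # signal ~2 vs background 50

  expect_error(detect_present(sim$intensities, sim$annotation, sim$design,
                              min_replicates = 5L),
               class = "exonsplice_config_error")
})

test_that("presence is monotone in intensity", {
  sim <- simulate_experiment(small_sim_config(n_transcripts = 30,
                                              baseline_log2_mean = 6,
                                              baseline_log2_sd = 1.5))
  calls <- detect_present(sim$intensities, sim$annotation, sim$design)
  # scale one transcript's probes up 8x: never flips present -> absent
  g <- exonsplice:::genomic_probes(sim$annotation)
  tx <- g$transcript_id[1L]
  rows <- g$probe_id[g$transcript_id == tx]
  vals <- sim$intensities$values
  vals[rows, ] <- vals[rows, ] * 8
  up <- detect_present(intensity_matrix(vals), sim$annotation, sim$design)
  expect_true(all(up$present[tx, ] >= calls$present[tx, ]))
  expect_equal(up$present[setdiff(rownames(up$present), tx), ],
               calls$present[setdiff(rownames(calls$present), tx), ])
})

test_that("condition-specific expression yields condition-specific presence", {
  # plant a strong negative fold change so the transcript drops to
  # background level in the affected condition
  sim <- simulate_experiment(small_sim_config(
    n_transcripts = 40, baseline_log2_mean = 7, baseline_log2_sd = 0.2,
    frac_de = 0.5, de_log2fc = 6, frac_as = 0))
  calls <- detect_present(sim$intensities, sim$annotation, sim$design)
  ev <- sim$truth$de_events
  down <- ev$transcript_id[ev$log2fc < 0]
  if (length(down)) {
    expect_false(any(calls$present[down, "TCR_CD28"]))
    expect_true(all(calls$present[down, "naive"]))
  }
})
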