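test_that("simulated input is a single-peaked bolus with physiological timing", {
  inp <- simulate_input()
  i_peak <- which.max(inp$parent_plasma)
  t_peak <- inp$time_s[i_peak] / 60
  expect_gt(t_peak, 0.5)
  expect_lt(t_peak, 2)
  # rising then monotone-decreasing tail
  expect_true(all(diff(inp$parent_plasma[1:i_peak]) >= 0))
  expect_true(all(diff(inp$parent_plasma[-(1:i_peak)]) <= 1e-9))
  expect_true(all(inp$parent_fraction <= 1 & inp$parent_fraction >= 0))
  expect_true(all(diff(inp$parent_fraction) <= 0))
  expect_error(simulate_input(params = list(l3 = -0.01)), "positive")
})

test_that("noise-free frame values match an independent convolution oracle", {
  K1 <- 0.15; k2 <- 0.02; bv <- 0.05
  tac <- fx_tac_1tc(K1, k2, bv)
  # oracle: FFT-based discrete convolution on the same grid, plus
  # trapezoidal frame averaging done directly
  dt <- 1
  tg <- fx_input$time_s
  kern <- exp(-(k2 / 60) * tg)
  conv <- stats::convolve(fx_input$parent_plasma, rev(kern), type = "open")[
    seq_along(tg)] * dt
  fine <- (1 - bv) * (K1 / 60) * conv + bv * fx_input$whole_blood
  oracle <- vapply(seq_len(nrow(fx_schedule)), function(i) {
    a <- fx_schedule$start_inj_s[i]; b <- fx_schedule$end_inj_s[i]
    if (b <= 0) return(0)
    idx <- which(tg >= max(a, 0) & tg <= b)
    v <- fine[idx]
    (sum(v) - (v[1] + v[length(v)]) / 2) * dt / (b - a)
  }, numeric(1))
  post <- fx_schedule$end_inj_s > 60  # skip partial/boundary frames where
                                      # the rectangle-rule oracle is crude
  expect_equal(tac$value_kBq_ml[post], oracle[post], tolerance = 0.01)
})

test_that("zero influx leaves only the vascular signal", {
  tac <- simulate_tac(list(K1 = 0, k2 = 0.02, bv = 0.05), fx_input,
                      fx_schedule)
  dt <- 1
  wb_frames <- vapply(seq_len(nrow(fx_schedule)), function(i) {
    a <- fx_schedule$start_inj_s[i]; b <- fx_schedule$end_inj_s[i]
    if (b <= 0) return(0)
    tg <- fx_input$time_s
    idx <- which(tg >= max(a, 0) & tg <= b)
    v <- fx_input$whole_blood[idx]
    (sum(v) - (v[1] + v[length(v)]) / 2) * dt / (b - a)
  }, numeric(1))
  post <- fx_schedule$end_inj_s > 60
  expect_equal(tac$value_kBq_ml[post], 0.05 * wb_frames[post],
               tolerance = 0.01)
})

test_that("noise is zero-mean: replicate means converge to the noise-free curve", {
  set.seed(202)
  noise_free <- fx_tac_1tc()$value_kBq_ml
  reps <- replicate(500, fx_tac_1tc(noise = 1)$value_kBq_ml)
  mc_sd <- apply(reps, 1, sd) / sqrt(ncol(reps))
  dev <- abs(rowMeans(reps) - noise_free)
  expect_true(all(dev < 5 * mc_sd + 1e-12))
})

test_that("cohorts are bit-reproducible and truth is mode-independent", {
  a <- simulate_cohort(n_subjects = 3, seed = 9)
  b <- simulate_cohort(n_subjects = 3, seed = 9)
  expect_identical(a$truth, b$truth)
  expect_identical(a$sessions$tacs, b$sessions$tacs)
  truth_only <- simulate_cohort(n_subjects = 3, seed = 9, tacs = FALSE)
  expect_identical(truth_only$truth, a$truth)
})

test_that("generated cohorts honour the requested variance components", {
  # empirical between-subject CV of true V_T, averaged over seeded
  # 15-subject cohorts (a single draw of 15 has wide sampling spread)
  cvs <- vapply(1:10, function(s) {
    tr <- simulate_cohort(n_subjects = 15, seed = s, tacs = FALSE)$truth
    subj_vt <- tapply(tr$vt_true[tr$region_id == "pallidum"],
                      tr$subject_id[tr$region_id == "pallidum"], mean)
    sd(subj_vt) / mean(subj_vt)
  }, numeric(1))
  expect_gt(mean(cvs), 0.35 * 0.8)
  expect_lt(mean(cvs), 0.35 * 1.2)
  # zero within-subject variance means identical sessions
  tr0 <- simulate_cohort(n_subjects = 4, seed = 2, ws_cv = 0,
                         tacs = FALSE)$truth
  wide <- tidyr::pivot_wider(tr0[, c("subject_id", "session", "region_id",
                                     "vt_true")],
                             names_from = "session", values_from = "vt_true")
  expect_equal(wide$test, wide$retest, tolerance = 1e-12)
})

test_that("the default profile keeps the pallidum/pons contrast", {
  prof <- default_region_profile()
  ratio <- prof$vt[prof$region_id == "pallidum"] /
    prof$vt[prof$region_id == "pons"]
  expect_equal(ratio, 3.6, tolerance = 0.01)
})

test_that("phantoms replicate region kinetics voxelwise", {
  masks <- phantom_masks(c(8, 8, 4), c("a", "b"))
  truth <- tibble::tibble(region_id = c("a", "b"), K1 = c(0.15, 0.08),
                          k2 = c(0.015, 0.027), bv = 0.05)
  ph <- simulate_phantom(masks, truth, fx_input, fx_schedule, noise_scale = 0)
  flat <- matrix(ph$data, nrow = 8 * 8 * 4)
  vox_a <- which(masks$a)
  # noise-free: every voxel of a region carries the identical TAC
  expect_equal(max(apply(flat[vox_a, ], 2, function(x) diff(range(x)))), 0)
  ref <- simulate_tac(truth[1, -1], fx_input, fx_schedule)$value_kBq_ml
  expect_equal(flat[vox_a[1], ], ref, tolerance = 1e-12)
  # masks cover the grid; with half-coverage masks, background is zero
  half <- list(a = masks$a)
  ph2 <- simulate_phantom(half, truth[1, ], fx_input, fx_schedule)
  expect_true(all(ph2$data[rep(!masks$a, nrow(fx_schedule))] == 0))
  # overlap rejected
  expect_error(simulate_phantom(list(a = masks$a, b = masks$a), truth,
                                fx_input, fx_schedule), "overlap")
  # noisy phantom: region mean of voxel TACs matches the ROI curve
  set.seed(33)
  ph3 <- simulate_phantom(masks, truth, fx_input, fx_schedule,
                          noise_scale = 1)
  flat3 <- matrix(ph3$data, nrow = 8 * 8 * 4)
  region_mean <- colMeans(flat3[vox_a, ])
  mc_sd <- apply(flat3[vox_a, ], 2, sd) / sqrt(length(vox_a))
  expect_true(all(abs(region_mean - ref) < 5 * mc_sd + 1e-9))
})
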