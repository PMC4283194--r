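test_that("frame weights follow length over trues rate", {
  tac <- fx_tac_1tc()
  # direct evaluation: L = 30 s, T = 1000 /s gives w = 0.03
  one <- tibble::tibble(value_kBq_ml = 1, trues_rate = 1000)
  sched1 <- frame_schedule(tibble::tibble(count = 1, duration_s = 30))
  expect_equal(compute_weights(one, sched1, normalise = FALSE), 0.03)
  # equal length and trues: uniform
  flat <- tibble::tibble(value_kBq_ml = rep(1, 3), trues_rate = rep(50, 3))
  sched3 <- frame_schedule(tibble::tibble(count = 3, duration_s = 60))
  expect_equal(compute_weights(flat, sched3), rep(1, 3))
  # long late frames with decaying trues weigh more late in the scan
  w <- compute_weights(tac, fx_schedule)
  expect_gt(mean(w[28:33]), mean(w[2:7]))
  expect_true(all(w >= 0))
  # missing trues: uniform fallback with a warning
  no_trues <- tac
  no_trues$trues_rate <- NA_real_
  expect_warning(w0 <- compute_weights(no_trues, fx_schedule), "uniform")
  expect_equal(w0, rep(1, nrow(tac)))
})

test_that("the one-tissue fit recovers noise-free parameters", {
  f <- fit_2kbv(fx_tac_1tc(), fx_input)
  expect_true(f$converged)
  expect_equal(f$K1, 0.15, tolerance = 0.005)
  expect_equal(f$k2, 0.02, tolerance = 0.005)
  expect_equal(f$bv, 0.05, tolerance = 0.01)
  expect_equal(f$vt, 7.5, tolerance = 0.01)
  # V_T is exactly the ratio of the stored rates
  expect_identical(f$vt, f$K1 / f$k2)
})

test_that("a purely vascular signal yields zero influx and the right bv", {
  tac <- simulate_tac(list(K1 = 0, k2 = 0.02, bv = 0.05), fx_input,
                      fx_schedule)
  f <- fit_2kbv(tac, fx_input)
  expect_lt(abs(f$K1), 1e-4)
  expect_equal(f$bv, 0.05, tolerance = 0.002)
})

test_that("rate estimates are invariant to a common activity rescaling", {
  tac <- fx_tac_1tc()
  tac10 <- tac
  tac10$value_kBq_ml <- tac$value_kBq_ml * 10
  inp10 <- fx_input
  inp10$parent_plasma <- fx_input$parent_plasma * 10
  inp10$whole_blood <- fx_input$whole_blood * 10
  f1 <- fit_2kbv(tac, fx_input, fx_schedule)
  f2 <- fit_2kbv(tac10, inp10, fx_schedule)
  expect_equal(f2$K1, f1$K1, tolerance = 1e-6)
  expect_equal(f2$k2, f1$k2, tolerance = 1e-6)
  expect_equal(f2$vt, f1$vt, tolerance = 1e-6)
})

test_that("the two-tissue fit recovers noise-free 2TC parameters", {
  tac <- simulate_tac(list(K1 = 0.1, k2 = 0.05, k3 = 0.03, k4 = 0.02,
                           bv = 0.05), fx_input, fx_schedule)
  f <- fit_4kbv(tac, fx_input)
  expect_true(f$converged)
  # V_T = (K1/k2)(1 + k3/k4) = 2 * 2.5 = 5
  expect_equal(f$vt, 5, tolerance = 0.02 * 5)
  expect_identical(f$vt, (f$K1 / f$k2) * (1 + f$k3 / f$k4))
})

test_that("the two-tissue model nests the one-tissue answer on 1TC data", {
  tac <- fx_tac_1tc()
  f2 <- fit_2kbv(tac, fx_input)
  f4 <- fit_4kbv(tac, fx_input)
  expect_equal(f4$vt, f2$vt, tolerance = 0.02 * f2$vt)
})

test_that("failure paths flag instead of erroring", {
  zero_if <- fx_input
  zero_if$parent_plasma <- 0
  f <- fit_2kbv(fx_tac_1tc(), zero_if, fx_schedule)
  expect_false(f$converged)
  expect_true(is.nan(f$vt))
  f4 <- fit_4kbv(fx_tac_1tc(), zero_if, fx_schedule)
  expect_false(f4$converged)
})

test_that("SRTM recovers its own forward model and handles self-reference", {
  ref_tac <- simulate_tac(list(K1 = 0.08, k2 = 0.08 / 3, bv = 0),
                          fx_input, fx_schedule, region_id = "pons")
  R1 <- 1; k2 <- 0.04; bp <- 1
  k2a <- k2 / (1 + bp)
  t_grid <- seq(0, max(fx_schedule$end_inj_s), 1)
  ref_fine <- petrel:::interp_tac_fine(fx_schedule$mid_inj_s,
                                       ref_tac$value_kBq_ml, t_grid)
  conv_frames <- petrel:::frame_average(
    petrel:::exp_conv(ref_fine, 1, k2a / 60), 1,
    fx_schedule$start_inj_s, fx_schedule$end_inj_s)
  target <- ref_tac
  target$value_kBq_ml <- R1 * ref_tac$value_kBq_ml +
    (k2 / 60 - R1 * k2a / 60) * conv_frames
  f <- fit_srtm(target, ref_tac, fx_schedule)
  expect_true(f$converged)
  expect_equal(f$R1, 1, tolerance = 0.02)
  expect_equal(f$bp, 1, tolerance = 0.02)
  expect_equal(f$k2, 0.04, tolerance = 0.02 * 0.04)
  self <- fit_srtm(ref_tac, ref_tac, fx_schedule)
  expect_equal(self$bp, 0, tolerance = 1e-8)
  expect_equal(self$R1, 1, tolerance = 1e-8)
  neg_ref <- ref_tac
  neg_ref$value_kBq_ml <- -abs(neg_ref$value_kBq_ml)
  expect_error(fit_srtm(target, neg_ref, fx_schedule), "positive")
})

test_that("tidy and glance expose fit results as tibbles", {
  f <- fit_2kbv(fx_tac_1tc(), fx_input)
  td <- tidy(f)
  expect_true(all(c("K1", "k2", "bv", "VT") %in% td$term))
  gl <- glance(f)
  expect_identical(gl$method, "2kbv")
  expect_true(gl$converged)
})
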