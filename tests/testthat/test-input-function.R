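# build raw blood data from a known whole-blood curve and known
# correction functions, so the derived input function has an analytic
# reference
make_blood <- function(pob = function(t) rep(1, length(t)),
                       pf = function(t) rep(1, length(t)),
                       calibration = 1, scale = 1) {
  wb <- function(t) scale * 30 * (t / 60) * exp(-t / 300) + scale * 2 * exp(-t / 4000)
  t_cont <- seq(0, 900, by = 2)
  t_disc <- c(180, 300, 600, 900, 1200, 1800, 3000, 4500, 5400)
  pf_vals <- pf(t_disc)
  pf_vals[length(pf_vals)] <- NA  # metabolite analysis impossible late
  blood_samples(
    continuous = tibble::tibble(time_s = t_cont,
                                whole_blood = wb(t_cont) / calibration),
    discrete = tibble::tibble(
      time_s = t_disc,
      whole_blood = wb(t_disc),
      plasma = wb(t_disc) * pob(t_disc),
      parent_fraction = pf_vals),
    calibration_factor = calibration
  )
}

test_that("identity corrections reproduce the whole-blood curve", {
  inp <- derive_input_function(make_blood(), pob_model = "constant",
                               pf_model = "constant")
  expect_equal(inp$parent_plasma, inp$whole_blood, tolerance = 1e-10)
  expect_true(all(inp$parent_plasma >= 0))
  expect_true(all(diff(inp$parent_fraction) <= 1e-12))
})

test_that("constant ratio and fraction give a pointwise product", {
  inp <- derive_input_function(
    make_blood(pob = function(t) rep(1.6, length(t)),
               pf = function(t) rep(0.5, length(t))),
    pob_model = "constant", pf_model = "constant")
  expect_equal(inp$parent_plasma, 0.8 * inp$whole_blood, tolerance = 1e-10)
})

test_that("the product identity parent = wb * pob * pf holds on the grid", {
  inp <- derive_input_function(
    make_blood(pob = function(t) 1.2 + 5e-5 * t,
               pf = function(t) 1 / (1 + (t / 1600)^1.7)))
  expect_equal(inp$parent_plasma,
               inp$whole_blood * inp$plasma_over_blood * inp$parent_fraction,
               tolerance = 1e-9)
  expect_true(all(inp$parent_fraction >= 0 & inp$parent_fraction <= 1))
  expect_true(all(diff(inp$parent_fraction) <= 1e-12))
})

test_that("fitted sigmoid recovers a declining parent fraction and extrapolates", {
  pf_true <- function(t) 1 / (1 + (t / 1500)^1.8)
  inp <- derive_input_function(make_blood(pf = pf_true))
  # the last discrete sample carries no parent fraction; the model must
  # extrapolate there
  expect_equal(inp$parent_fraction[inp$time_s == 5400],
               pf_true(5400), tolerance = 0.02)
  expect_equal(inp$parent_fraction[inp$time_s == 600],
               pf_true(600), tolerance = 0.02)
})

test_that("derivation is homogeneous of degree 1 in blood activity", {
  pob <- function(t) 1.3 + 4e-5 * t
  pf <- function(t) 1 / (1 + (t / 2000)^1.5)
  inp1 <- derive_input_function(make_blood(pob, pf, scale = 1))
  inp3 <- derive_input_function(make_blood(pob, pf, scale = 3))
  expect_equal(inp3$parent_plasma, 3 * inp1$parent_plasma, tolerance = 1e-6)
})

test_that("cross-calibration removes a continuous-detector scale offset", {
  inp1 <- derive_input_function(make_blood(calibration = 1))
  inp2 <- derive_input_function(make_blood(calibration = 4))
  expect_equal(inp2$parent_plasma, inp1$parent_plasma, tolerance = 1e-6)
})

test_that("insufficient or invalid samples are rejected", {
  b <- make_blood()
  few <- b
  few$discrete$plasma[-(1:2)] <- NA
  expect_error(derive_input_function(few), "at least 3 discrete samples")
  nopf <- b
  nopf$discrete$parent_fraction[-1] <- NA
  expect_error(derive_input_function(nopf), "parent-fraction")
  bad <- b$discrete
  bad$parent_fraction[2] <- 1.4
  expect_error(blood_samples(b$continuous, bad), "\\[0, 1\\]")
  late <- b$discrete
  late$time_s[1] <- 6000
  expect_error(blood_samples(b$continuous, late), "90")
  nat <- b$continuous
  nat$time_s[5] <- NA
  expect_error(blood_samples(nat, b$discrete), "ordered")
})
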