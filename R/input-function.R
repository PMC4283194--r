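#' Bundle raw arterial blood data for input-function derivation
#'
#' Arterial blood is measured two ways during a scan: a continuous
#' detector samples whole-blood activity at high rate over the early part
#' of the scan (here the first ~15 min), and discrete syringe samples
#' drawn at fixed times are spun down to give whole-blood activity,
#' plasma activity and (for most samples) the fraction of plasma activity
#' still attributable to unmetabolised parent tracer.
#'
#' @param continuous Data frame with columns `time_s`, `whole_blood`
#'   (kBq/ml, continuous-detector units) covering the early scan.
#' @param discrete Data frame with columns `time_s`, `whole_blood`,
#'   `plasma` (kBq/ml, well-counter units) and `parent_fraction`
#'   (in `[0, 1]`, `NA` where metabolite analysis was not possible,
#'   e.g. the final late sample).
#' @param calibration_factor Scalar mapping continuous-detector units to
#'   well-counter units (applied before cross-calibration).
#' @return A list of class `petrel_blood`.
#' @export
blood_samples <- function(continuous, discrete, calibration_factor = 1) {
  stopifnot(is.data.frame(continuous), is.data.frame(discrete))
  stopifnot(all(c("time_s", "whole_blood") %in% names(continuous)))
  stopifnot(all(c("time_s", "whole_blood", "plasma", "parent_fraction") %in%
                  names(discrete)))
  if (anyNA(discrete$time_s) || anyNA(continuous$time_s)) {
    stop("sample times contain NA and cannot be ordered", call. = FALSE)
  }
  if (any(discrete$time_s < 0) || any(discrete$time_s > 5400)) {
    stop("discrete sampling times must lie within [0, 90] min", call. = FALSE)
  }
  pf <- discrete$parent_fraction
  if (any(!is.na(pf) & (pf < 0 | pf > 1))) {
    stop("parent fractions must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(
      continuous = tibble::as_tibble(continuous)[order(continuous$time_s), ],
      discrete = tibble::as_tibble(discrete)[order(discrete$time_s), ],
      calibration_factor = calibration_factor
    ),
    class = "petrel_blood"
  )
}

# Model families for the two blood corrections. Both are deliberately
# low-dimensional, monotone shapes: the plasma-over-blood ratio drifts
# slowly as tracer partitions between cells and plasma, and the parent
# fraction declines from 1 as metabolites accumulate.
fit_plasma_over_blood <- function(time_s, ratio, model = c("linear", "constant")) {
  model <- match.arg(model)
  if (model == "constant" || length(unique(time_s)) < 2) {
    m <- mean(ratio)
    function(t) rep(max(m, 1e-3), length(t))
  } else {
    fit <- stats::lm(ratio ~ time_s, data = data.frame(time_s, ratio))
    function(t) {
      pmax(stats::predict(fit, newdata = data.frame(time_s = t)), 1e-3)
    }
  }
}

fit_parent_fraction <- function(time_s, pf, model = c("hill", "constant")) {
  model <- match.arg(model)
  if (model == "constant" || stats::sd(pf) < 1e-9) {
    m <- min(max(mean(pf), 0), 1)
    return(function(t) rep(m, length(t)))
  }
  # Hill-type sigmoid 1 / (1 + (t / t50)^h): equals 1 at t = 0,
  # monotone non-increasing, bounded in (0, 1] for t50, h > 0.
  start <- list(t50 = max(stats::median(time_s), 1), h = 1.5)
  fit <- minpack.lm::nlsLM(
    pf ~ 1 / (1 + (time_s / t50)^h),
    data = data.frame(time_s, pf),
    start = start,
    lower = c(t50 = 1, h = 0.2),
    upper = c(t50 = 1e5, h = 8),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  cf <- stats::coef(fit)
  function(t) 1 / (1 + (t / cf[["t50"]])^cf[["h"]])
}

#' Derive a metabolite-corrected plasma input function from blood data
#'
#' Builds the continuous parent-tracer plasma curve that compartmental
#' and spectral methods need: the continuous and discrete whole-blood
#' records are cross-calibrated and joined (continuous segment while it
#' lasts, interpolated discrete samples thereafter), the plasma-over-blood
#' ratio and the parent fraction are fitted by smooth monotone model
#' families from the discrete samples, and the parent plasma curve is the
#' pointwise product of the three.
#'
#' @param blood A [blood_samples()] object.
#' @param pob_model Model family for the plasma-over-blood ratio
#'   (`"linear"` in time with a positivity clamp, or `"constant"`).
#' @param pf_model Model family for the parent fraction (`"hill"`
#'   sigmoid or `"constant"`). The fitted curve extrapolates to late
#'   times where metabolite analysis was impossible.
#' @param t_end_s,dt_s Output grid: `[0, t_end_s]` in steps of `dt_s`
#'   seconds post-injection.
#' @return An input-function tibble with columns `time_s`,
#'   `whole_blood`, `plasma_over_blood`, `parent_fraction`,
#'   `parent_plasma`, satisfying
#'   `parent_plasma = whole_blood * plasma_over_blood * parent_fraction`.
#' @export
derive_input_function <- function(blood,
                                  pob_model = c("linear", "constant"),
                                  pf_model = c("hill", "constant"),
                                  t_end_s = 5400, dt_s = 1) {
  stopifnot(inherits(blood, "petrel_blood"))
  pob_model <- match.arg(pob_model)
  pf_model <- match.arg(pf_model)
  disc <- blood$discrete
  has_plasma <- !is.na(disc$plasma) & !is.na(disc$whole_blood)
  if (sum(has_plasma) < 3) {
    stop("need at least 3 discrete samples with plasma measurements",
         call. = FALSE)
  }
  has_pf <- !is.na(disc$parent_fraction)
  if (sum(has_pf) < 2) {
    stop("need at least 2 parent-fraction measurements", call. = FALSE)
  }

  grid <- seq(0, t_end_s, by = dt_s)
  cont <- blood$continuous
  cont_wb <- cont$whole_blood * blood$calibration_factor
  t_split <- max(cont$time_s)

  # multiplicative cross-calibration against discrete samples that fall
  # inside the continuous record
  overlap <- disc$time_s <= t_split & !is.na(disc$whole_blood)
  if (any(overlap)) {
    cont_at <- stats::approx(cont$time_s, cont_wb,
                             xout = disc$time_s[overlap], rule = 2)$y
    ok <- cont_at > 0
    if (any(ok)) {
      cc <- mean(disc$whole_blood[overlap][ok] / cont_at[ok])
      cont_wb <- cont_wb * cc
    }
  }

  wb_early <- stats::approx(cont$time_s, cont_wb, xout = grid, rule = 2)$y
  disc_wb <- disc[!is.na(disc$whole_blood), ]
  # anchor the late segment at the calibrated continuous value at the seam
  seam <- stats::approx(cont$time_s, cont_wb, xout = t_split, rule = 2)$y
  late_t <- c(t_split, disc_wb$time_s[disc_wb$time_s > t_split])
  late_v <- c(seam, disc_wb$whole_blood[disc_wb$time_s > t_split])
  wb_late <- stats::approx(late_t, late_v, xout = grid, rule = 2)$y
  whole_blood <- ifelse(grid <= t_split, wb_early, wb_late)
  whole_blood <- pmax(whole_blood, 0)

  ratio <- disc$plasma[has_plasma] / disc$whole_blood[has_plasma]
  pob_fun <- fit_plasma_over_blood(disc$time_s[has_plasma], ratio, pob_model)
  pf_fun <- fit_parent_fraction(disc$time_s[has_pf],
                                disc$parent_fraction[has_pf], pf_model)

  pf <- pf_fun(grid)
  if (any(pf < -1e-9 | pf > 1 + 1e-9)) {
    stop("fitted parent fraction leaves [0, 1]; model failure", call. = FALSE)
  }
  pob <- pob_fun(grid)
  out <- tibble::tibble(
    time_s = grid,
    whole_blood = whole_blood,
    plasma_over_blood = pob,
    parent_fraction = pmin(pmax(pf, 0), 1),
    parent_plasma = whole_blood * pob * pmin(pmax(pf, 0), 1)
  )
  class(out) <- c("petrel_input", class(out))
  out
}

# accept either a full input tibble or anything with time_s/parent_plasma
check_input_function <- function(input) {
  stopifnot(is.data.frame(input),
            all(c("time_s", "parent_plasma", "whole_blood") %in% names(input)))
  dt <- diff(input$time_s)
  if (length(dt) && (max(dt) - min(dt)) > 1e-9) {
    stop("input function must be tabulated on a uniform time grid",
         call. = FALSE)
  }
  invisible(input)
}
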