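#' Frame weights from frame length and true-coincidence rate
#'
#' Weighted fits use `w_i = L_i / T_i` per frame, where `L_i` is the
#' frame length in seconds and `T_i` the rate of true coincidences per
#' second. This is the reciprocal-variance weighting implied by counting
#' statistics when the variance of a frame mean scales with activity
#' over frame length.
#'
#' @param tac TAC tibble with columns `value_kBq_ml` and (ideally)
#'   `trues_rate`; the schedule is read from the `"schedule"` attribute
#'   unless given.
#' @param schedule Frame schedule providing `L_i`.
#' @param normalise Scale weights to mean 1 (default; weighting is only
#'   defined up to a global factor).
#' @return Numeric weight vector, one value per frame.
#' @export
compute_weights <- function(tac, schedule = attr(tac, "schedule"),
                            normalise = TRUE) {
  stopifnot(is.data.frame(tac), !is.null(schedule))
  L <- schedule$frame_duration_s
  trues <- tac$trues_rate
  if (is.null(trues) || anyNA(trues) || any(trues <= 0)) {
    warning("trues_rate missing or non-positive; falling back to uniform weights",
            call. = FALSE)
    w <- rep(1, nrow(tac))
  } else {
    w <- L / trues
  }
  if (normalise) w <- w / mean(w)
  w
}

# Exact active-set solution of the 2-variable box-constrained weighted
# least-squares problem min ||y - a m1 - b m2||_w with a >= 0,
# 0 <= b <= b_max. Candidate solutions: unconstrained stationary point
# plus every face/corner of the feasible box.
solve_amp_bv <- function(m1, m2, y, w, b_max = 0.2) {
  wm1 <- w * m1
  wm2 <- w * m2
  g11 <- sum(wm1 * m1); g12 <- sum(wm1 * m2); g22 <- sum(wm2 * m2)
  c1 <- sum(wm1 * y); c2 <- sum(wm2 * y)
  cand <- list()
  det <- g11 * g22 - g12^2
  if (det > 1e-300) {
    cand <- c(cand, list(c((g22 * c1 - g12 * c2) / det,
                           (g11 * c2 - g12 * c1) / det)))
  }
  a_at <- function(b) if (g11 > 0) max((c1 - b * g12) / g11, 0) else 0
  b_at <- function(a) if (g22 > 0) min(max((c2 - a * g12) / g22, 0), b_max) else 0
  cand <- c(cand,
            list(c(a_at(0), 0), c(a_at(b_max), b_max), c(0, b_at(0)),
                 c(0, 0), c(0, b_max)))
  best <- NULL
  best_rss <- Inf
  for (p in cand) {
    a <- p[1]; b <- p[2]
    if (!is.finite(a) || !is.finite(b) || a < 0 || b < -1e-12 ||
        b > b_max + 1e-12) next
    b <- min(max(b, 0), b_max)
    r <- y - a * m1 - b * m2
    rss <- sum(w * r^2)
    if (rss < best_rss - 1e-12 ||
        (abs(rss - best_rss) <= 1e-12 && !is.null(best) && b < best[2])) {
      best <- c(a, b)
      best_rss <- rss
    }
  }
  list(a = best[1], b = best[2], wrss = best_rss)
}

kfit_result <- function(method, K1, k2, k3, k4, bv, vt, bp = NA_real_,
                        wrss = NA_real_, converged = FALSE, n_starts = 0,
                        fitted = NULL, observed = NULL, schedule = NULL) {
  structure(
    list(method = method, K1 = K1, k2 = k2, k3 = k3, k4 = k4, bv = bv,
         vt = vt, bp = bp, wrss = wrss, converged = converged,
         n_starts = n_starts, fitted = fitted, observed = observed,
         schedule = schedule),
    class = "petrel_kfit"
  )
}

kfit_failure <- function(method, n_starts = 0) {
  kfit_result(method, NaN, NaN, NaN, NaN, NaN, NaN,
              converged = FALSE, n_starts = n_starts)
}

#' @export
print.petrel_kfit <- function(x, ...) {
  cat("<", x$method, " fit>  converged: ", x$converged, "\n", sep = "")
  cat(sprintf("  K1 = %.4g ml/cm3/min, k2 = %.4g /min, bv = %.3g\n",
              x$K1, x$k2, x$bv))
  if (!is.na(x$k3)) {
    cat(sprintf("  k3 = %.4g /min, k4 = %.4g /min\n", x$k3, x$k4))
  }
  if (!is.na(x$vt)) cat(sprintf("  V_T = %.4g\n", x$vt))
  if (!is.na(x$bp)) cat(sprintf("  BP_ND = %.4g\n", x$bp))
  invisible(x)
}

prepare_fit_data <- function(tac, input, schedule, weights) {
  stopifnot(is.data.frame(tac), "value_kBq_ml" %in% names(tac))
  if (is.null(schedule)) stop("a frame schedule is required", call. = FALSE)
  check_input_function(input)
  if (all(input$parent_plasma <= 0)) {
    stop("input function is identically zero", call. = FALSE)
  }
  if (sum(schedule$end_inj_s > 0) < 6) {
    stop("need at least 6 post-injection frames", call. = FALSE)
  }
  if (max(schedule$end_inj_s) > max(input$time_s) + 1e-9) {
    stop("input function does not cover the frame schedule", call. = FALSE)
  }
  if (is.null(weights)) {
    weights <- tryCatch(compute_weights(tac, schedule),
                        warning = function(w) rep(1, nrow(tac)))
  }
  dt <- input$time_s[2] - input$time_s[1]
  list(
    y = tac$value_kBq_ml,
    w = weights,
    dt = dt,
    cp = input$parent_plasma,
    wb_frames = frame_average(input$whole_blood, dt,
                              schedule$start_inj_s, schedule$end_inj_s),
    starts = schedule$start_inj_s,
    ends = schedule$end_inj_s
  )
}

#' Fit the one-tissue compartmental model with variable blood volume
#'
#' Weighted nonlinear least-squares fit of
#' `C(t) = (1 - bv) * K1 * int Cp(s) exp(-k2 (t - s)) ds + bv * C_blood(t)`
#' to a frame-averaged TAC. `K1` (influx) and `bv` enter the model
#' linearly once `k2` (efflux) is fixed, so the fit profiles a
#' box-constrained linear solve over a deterministic logarithmic `k2`
#' grid and refines the best bracket by golden-section search; ties are
#' broken by lowest weighted residual, then lowest `bv`. The total
#' volume of distribution is `V_T = K1 / k2` computed exactly from the
#' returned rates.
#'
#' @param tac TAC tibble (`value_kBq_ml` per frame).
#' @param input Metabolite-corrected input-function tibble (uniform
#'   grid covering the schedule).
#' @param schedule Frame schedule; defaults to the TAC's `"schedule"`
#'   attribute.
#' @param weights Frame weights (default [compute_weights()], uniform
#'   when `trues_rate` is unavailable).
#' @param options List: `k2_bounds` (1/min, default `c(0.001, 2)`),
#'   `bv_max` (default 0.2), `n_grid` (default 25).
#' @return A `petrel_kfit` object; on failure a flagged non-converged
#'   fit with `NaN` estimates (never an error mid-cohort).
#' @export
fit_2kbv <- function(tac, input, schedule = attr(tac, "schedule"),
                     weights = NULL, options = list()) {
  opt <- utils::modifyList(
    list(k2_bounds = c(0.001, 2), bv_max = 0.2, n_grid = 25), options)
  fd <- tryCatch(prepare_fit_data(tac, input, schedule, weights),
                 error = function(e) NULL)
  if (is.null(fd)) return(kfit_failure("2kbv", opt$n_grid))
  obj <- function(log_k2s) {
    k2s <- exp(log_k2s)
    m1 <- frame_average(exp_conv(fd$cp, fd$dt, k2s), fd$dt, fd$starts, fd$ends)
    sol <- solve_amp_bv(m1, fd$wb_frames, fd$y, fd$w, opt$bv_max)
    sol$wrss
  }
  res <- tryCatch({
    lo <- log(opt$k2_bounds[1] / 60)
    hi <- log(opt$k2_bounds[2] / 60)
    grid <- seq(lo, hi, length.out = opt$n_grid)
    vals <- vapply(grid, obj, numeric(1))
    i <- which.min(vals)
    bracket <- c(grid[max(i - 1L, 1L)], grid[min(i + 1L, length(grid))])
    ref <- stats::optimize(obj, interval = bracket, tol = 1e-10)
    log_k2 <- if (ref$objective <= vals[i]) ref$minimum else grid[i]
    k2s <- exp(log_k2)
    m1 <- frame_average(exp_conv(fd$cp, fd$dt, k2s), fd$dt, fd$starts, fd$ends)
    sol <- solve_amp_bv(m1, fd$wb_frames, fd$y, fd$w, opt$bv_max)
    a <- sol$a; bv <- sol$b
    K1s <- a / (1 - bv)
    fitted <- a * m1 + bv * fd$wb_frames
    kfit_result("2kbv",
                K1 = K1s * 60, k2 = k2s * 60, k3 = NA_real_, k4 = NA_real_,
                bv = bv, vt = (K1s * 60) / (k2s * 60), wrss = sol$wrss,
                converged = TRUE, n_starts = opt$n_grid,
                fitted = fitted, observed = fd$y, schedule = schedule)
  }, error = function(e) kfit_failure("2kbv", opt$n_grid))
  res
}

#' Fit the two-tissue compartmental model with variable blood volume
#'
#' Extends [fit_2kbv()] by two more rate constants: `k3` (transfer into
#' the specifically bound compartment) and `k4` (return). The tissue
#' impulse response is the standard bi-exponential in the macro-rates
#' `theta_1,2 = ((k2+k3+k4) -/+ sqrt((k2+k3+k4)^2 - 4 k2 k4)) / 2`,
#' scaled by `K1`; `K1` and `bv` are again profiled out linearly. The
#' three nonlinear rates are optimised from a deterministic 3-point
#' logarithmic multi-start per rate (the full grid is scored and the
#' best starts refined by bounded quasi-Newton steps); ties are broken
#' by lowest weighted residual, then lowest `bv`.
#' `V_T = (K1 / k2) * (1 + k3 / k4)`, exactly from the returned rates.
#' A `k4` pinned at its lower bound (near-singular `k3/k4`) is reported
#' with `converged = FALSE`.
#'
#' @inheritParams fit_2kbv
#' @param options List: `k2_bounds`, `k3_bounds`, `k4_bounds` (1/min),
#'   `bv_max`, `n_refine` (starts refined, default 3), `maxit`.
#' @return A `petrel_kfit` object (flagged `NaN` fit on failure).
#' @export
fit_4kbv <- function(tac, input, schedule = attr(tac, "schedule"),
                     weights = NULL, options = list()) {
  opt <- utils::modifyList(
    list(k2_bounds = c(0.001, 1), k3_bounds = c(0.001, 0.5),
         k4_bounds = c(0.001, 0.5), bv_max = 0.2, n_refine = 3,
         maxit = 60), options)
  fd <- tryCatch(prepare_fit_data(tac, input, schedule, weights),
                 error = function(e) NULL)
  if (is.null(fd)) return(kfit_failure("4kbv", 27))

  model_cols <- function(k2s, k3s, k4s) {
    s <- k2s + k3s + k4s
    d <- sqrt(max(s^2 - 4 * k2s * k4s, 0))
    th1 <- (s - d) / 2
    th2 <- (s + d) / 2
    if (th2 - th1 < 1e-12) th2 <- th1 * (1 + 1e-6) + 1e-12
    g <- ((k3s + k4s - th1) * exp_conv(fd$cp, fd$dt, th1) +
            (th2 - k3s - k4s) * exp_conv(fd$cp, fd$dt, th2)) / (th2 - th1)
    frame_average(g, fd$dt, fd$starts, fd$ends)
  }
  obj <- function(lp) {
    k <- exp(lp)
    m1 <- model_cols(k[1], k[2], k[3])
    solve_amp_bv(m1, fd$wb_frames, fd$y, fd$w, opt$bv_max)$wrss
  }

  res <- tryCatch({
    gpts <- function(b) log(exp(seq(log(b[1] / 60 * 3), log(b[2] / 60 / 3),
                                    length.out = 3)))
    starts <- as.matrix(expand.grid(gpts(opt$k2_bounds), gpts(opt$k3_bounds),
                                    gpts(opt$k4_bounds)))
    scores <- apply(starts, 1, obj)
    top <- order(scores)[seq_len(min(opt$n_refine, nrow(starts)))]
    lower <- log(c(opt$k2_bounds[1], opt$k3_bounds[1], opt$k4_bounds[1]) / 60)
    upper <- log(c(opt$k2_bounds[2], opt$k3_bounds[2], opt$k4_bounds[2]) / 60)
    best <- NULL
    for (i in top) {
      fit <- tryCatch(
        stats::optim(starts[i, ], obj, method = "L-BFGS-B",
                     lower = lower, upper = upper,
                     control = list(maxit = opt$maxit, factr = 1e4)),
        error = function(e) NULL)
      if (is.null(fit)) next
      if (is.null(best) || fit$value < best$value - 1e-12) best <- fit
    }
    if (is.null(best)) stop("all starts failed")
    k <- unname(exp(best$par))
    m1 <- model_cols(k[1], k[2], k[3])
    sol <- solve_amp_bv(m1, fd$wb_frames, fd$y, fd$w, opt$bv_max)
    a <- sol$a; bv <- sol$b
    K1 <- a / (1 - bv) * 60
    k2 <- k[1] * 60; k3 <- k[2] * 60; k4 <- k[3] * 60
    at_k4_floor <- k4 <= opt$k4_bounds[1] * 1.001
    fitted <- a * m1 + bv * fd$wb_frames
    kfit_result("4kbv", K1 = K1, k2 = k2, k3 = k3, k4 = k4, bv = bv,
                vt = (K1 / k2) * (1 + k3 / k4), wrss = sol$wrss,
                converged = best$convergence == 0 && !at_k4_floor,
                n_starts = nrow(starts), fitted = fitted, observed = fd$y,
                schedule = schedule)
  }, error = function(e) kfit_failure("4kbv", 27))
  res
}

#' Fit the simplified reference tissue model (basis-function method)
#'
#' Estimates the non-displaceable binding potential `BP_ND` from a
#' target and a (pseudo-)reference TAC without blood data, using the
#' operational equation
#' `C_T(t) = R1 * C_R(t) + (k2 - R1 * k2a) * C_R conv exp(-k2a t)`
#' with `k2a = k2 / (1 + BP_ND)`. The solution is computed over a
#' deterministic logarithmic grid of `k2a` basis rates, solving the two
#' linear coefficients per basis by weighted least squares, then
#' refining the best bracket continuously. With a pseudo-reference
#' region that itself carries specific binding (e.g. pons for a CB1
#' tracer), `BP_ND` is interpretable only relative to that region.
#'
#' @param tac Target-region TAC tibble.
#' @param reference_tac Reference-region TAC on the same schedule.
#' @param schedule Frame schedule.
#' @param weights Frame weights (defaults to the target's weights).
#' @param options List: `k2a_bounds` (1/min, default `c(0.006, 0.6)`),
#'   `n_basis` (default 100).
#' @return An object of class `petrel_srtm` with elements `R1`, `k2`
#'   (1/min), `k2a`, `bp`, `wrss`, `converged`.
#' @export
fit_srtm <- function(tac, reference_tac, schedule = attr(tac, "schedule"),
                     weights = NULL, options = list()) {
  opt <- utils::modifyList(list(k2a_bounds = c(0.006, 0.6), n_basis = 100),
                           options)
  stopifnot(is.data.frame(tac), is.data.frame(reference_tac))
  if (is.null(schedule)) stop("a frame schedule is required", call. = FALSE)
  ref <- reference_tac$value_kBq_ml
  if (all(ref <= 0)) stop("reference TAC must be positive", call. = FALSE)
  y <- tac$value_kBq_ml
  if (is.null(weights)) {
    weights <- tryCatch(compute_weights(tac, schedule),
                        warning = function(w) rep(1, length(y)))
  }
  dt <- 1
  t_grid <- seq(0, max(schedule$end_inj_s), by = dt)
  ref_fine <- interp_tac_fine(schedule$mid_inj_s, ref, t_grid)

  solve_lin <- function(k2a_s) {
    basis <- frame_average(exp_conv(ref_fine, dt, k2a_s), dt,
                           schedule$start_inj_s, schedule$end_inj_s)
    X <- cbind(ref, basis)
    fit <- stats::lm.wfit(X, y, weights)
    rss <- sum(weights * fit$residuals^2)
    list(coef = fit$coefficients, wrss = rss)
  }
  res <- tryCatch({
    lo <- log(opt$k2a_bounds[1] / 60)
    hi <- log(opt$k2a_bounds[2] / 60)
    grid <- seq(lo, hi, length.out = opt$n_basis)
    vals <- vapply(grid, function(g) solve_lin(exp(g))$wrss, numeric(1))
    i <- which.min(vals)
    bracket <- c(grid[max(i - 1L, 1L)], grid[min(i + 1L, length(grid))])
    refn <- stats::optimize(function(g) solve_lin(exp(g))$wrss,
                            interval = bracket, tol = 1e-10)
    log_k2a <- if (refn$objective <= vals[i]) refn$minimum else grid[i]
    k2a_s <- exp(log_k2a)
    sol <- solve_lin(k2a_s)
    R1 <- unname(sol$coef[1])
    phi <- unname(sol$coef[2])
    k2_s <- phi + R1 * k2a_s
    bp <- k2_s / k2a_s - 1
    structure(
      list(R1 = R1, k2 = k2_s * 60, k2a = k2a_s * 60, bp = bp,
           wrss = sol$wrss, converged = is.finite(bp) && bp > -1,
           n_basis = opt$n_basis),
      class = "petrel_srtm")
  }, error = function(e) {
    structure(list(R1 = NaN, k2 = NaN, k2a = NaN, bp = NaN, wrss = NaN,
                   converged = FALSE, n_basis = opt$n_basis),
              class = "petrel_srtm")
  })
  res
}

#' @export
print.petrel_srtm <- function(x, ...) {
  cat("<SRTM fit>  converged:", x$converged, "\n")
  cat(sprintf("  R1 = %.4g, k2 = %.4g /min, BP_ND = %.4g\n",
              x$R1, x$k2, x$bp))
  invisible(x)
}
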