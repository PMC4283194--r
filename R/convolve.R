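# Internal numerical kernels shared by the simulator and all fitters.
#
# All continuous-time kinetics are evaluated on a uniform fine grid
# (default 1 s) in seconds post-injection, then averaged over frames.
# Convolution with a decaying exponential is computed by the exact
# recursion for a piecewise-linear input, so the only discretisation
# error left is the piecewise-linear representation of the input itself.

# y(t) = int_0^t x(s) exp(-beta (t - s)) ds for x piecewise linear on a
# uniform grid with spacing dt. Exact for piecewise-linear x.
exp_conv <- function(x, dt, beta) {
  n <- length(x)
  if (n < 2L) return(numeric(n))
  a <- beta * dt
  if (a > 1e-4) {
    ea <- exp(-a)
    i0 <- (1 - ea * (1 + a)) / a^2
    i1 <- (a - 1 + ea) / a^2
  } else {
    # series expansion; avoids catastrophic cancellation for tiny beta*dt
    ea <- exp(-a)
    i0 <- 0.5 - a / 3 + a^2 / 8
    i1 <- 0.5 - a / 6 + a^2 / 24
  }
  z <- dt * (i0 * x[-n] + i1 * x[-1L])
  y <- stats::filter(z, ea, method = "recursive")
  c(0, as.numeric(y))
}

# Mean of a curve over [t0, t1], where the curve is tabulated on the grid
# t = 0, dt, 2*dt, ... and is identically zero for t < 0. Frames that
# start before t = 0 (pre-injection) average the zero segment in.
# Vectorised over frames via the cumulative trapezoidal integral.
frame_average <- function(values, dt, starts, ends) {
  n <- length(values)
  t_max <- (n - 1L) * dt
  if (any(ends > t_max + 1e-9)) {
    stop("frame schedule extends beyond the tabulated curve support",
         call. = FALSE)
  }
  cum <- c(0, cumsum((values[-1L] + values[-n]) / 2 * dt))
  cum_at <- function(t) {
    t <- pmax(t, 0)
    i <- pmin(floor(t / dt), n - 2L)
    frac <- t / dt - i
    lo <- cum[i + 1L]
    # linear-in-t correction within a grid cell (trapezoid of the cell)
    v0 <- values[i + 1L]
    v1 <- values[i + 2L]
    lo + dt * frac * (v0 + (v0 * (1 - frac) + v1 * frac)) / 2
  }
  (cum_at(ends) - cum_at(pmax(starts, 0))) / (ends - starts)
}

# Linear interpolation of a frame-level curve onto the fine grid,
# anchored at (0, 0) and held constant past the last midpoint. Used to
# put reference-region TACs on the model grid (SRTM).
interp_tac_fine <- function(mid, values, t_grid) {
  keep <- mid > 0                     # pre-injection frames sit on the anchor
  stats::approx(x = c(0, mid[keep]), y = c(0, values[keep]), xout = t_grid,
                rule = 2)$y
}
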