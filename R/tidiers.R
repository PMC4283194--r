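#' Tidy and glance methods for fitted objects
#'
#' Broom-style accessors: `tidy()` returns one row per estimated
#' parameter, `glance()` a one-row model summary.
#'
#' @param x A fitted object (`petrel_kfit`, `petrel_srtm`,
#'   `petrel_sa`, `petrel_rs` or `petrel_icc`).
#' @param ... Unused.
#' @return A tibble.
#' @name petrel-tidiers
NULL

#' @rdname petrel-tidiers
#' @export
tidy.petrel_kfit <- function(x, ...) {
  est <- c(K1 = x$K1, k2 = x$k2, k3 = x$k3, k4 = x$k4, bv = x$bv,
           VT = x$vt)
  unit <- c("ml/cm3/min", "1/min", "1/min", "1/min", "fraction",
            "ml/cm3")
  keep <- !is.na(est) | names(est) %in% c("K1", "k2")
  tibble::tibble(term = names(est)[keep], estimate = unname(est[keep]),
                 unit = unit[keep])
}

#' @rdname petrel-tidiers
#' @export
glance.petrel_kfit <- function(x, ...) {
  tibble::tibble(method = x$method, vt = x$vt, wrss = x$wrss,
                 converged = x$converged, n_starts = x$n_starts)
}

#' @rdname petrel-tidiers
#' @export
tidy.petrel_srtm <- function(x, ...) {
  tibble::tibble(term = c("R1", "k2", "k2a", "BP_ND"),
                 estimate = c(x$R1, x$k2, x$k2a, x$bp),
                 unit = c("ratio", "1/min", "1/min", "ratio"))
}

#' @rdname petrel-tidiers
#' @export
glance.petrel_srtm <- function(x, ...) {
  tibble::tibble(method = "srtm", bp = x$bp, wrss = x$wrss,
                 converged = x$converged)
}

#' @rdname petrel-tidiers
#' @export
tidy.petrel_sa <- function(x, ...) {
  sp <- x$spectrum[x$spectrum$alpha > 0, ]
  tibble::tibble(term = sprintf("beta=%.3g/s", sp$beta_acq),
                 estimate = sp$alpha, unit = "amplitude")
}

#' @rdname petrel-tidiers
#' @export
glance.petrel_sa <- function(x, ...) {
  tibble::tibble(method = "sa_roi", vt = x$vt,
                 n_components = sum(x$spectrum$alpha > 0),
                 alpha_bv = x$alpha_bv, wrss = x$wrss)
}

#' @rdname petrel-tidiers
#' @export
glance.petrel_rs <- function(x, ...) {
  tibble::tibble(method = "rs_sa", vt = x$vt,
                 plateau_found = x$plateau_found,
                 R_lo = x$R_grid[x$plateau_window[1]],
                 R_hi = x$R_grid[x$plateau_window[length(x$plateau_window)]])
}

#' @rdname petrel-tidiers
#' @export
tidy.petrel_icc <- function(x, ...) {
  tibble::tibble(term = c("ICC", "MSBS", "MSWS"),
                 estimate = c(x$icc, x$msbs, x$msws))
}

#' @rdname petrel-tidiers
#' @export
glance.petrel_icc <- function(x, ...) {
  tibble::tibble(icc = x$icc, n = x$n, k = x$k,
                 n_excluded = x$n_excluded, denominator = x$denominator)
}
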