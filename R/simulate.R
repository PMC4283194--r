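#' Default regional total-volume-of-distribution profile
#'
#' Median regional V_T values typical of a CB1-receptor tracer in healthy
#' adults, spanning high-binding basal ganglia through the low-binding
#' pons (the pseudo-reference region). Used as the centre of the
#' between-subject distribution by [simulate_cohort()].
#'
#' @return A tibble with columns `region_id` and `vt`.
#' @export
default_region_profile <- function() {
  tibble::tibble(
    region_id = c("hippocampus", "anterior_cingulate", "inferior_frontal",
                  "caudate", "pallidum", "accumbens", "thalamus", "pons"),
    vt = c(8.0, 10.3, 8.8, 7.4, 10.8, 8.4, 5.1, 3.0)
  )
}

#' Simulate a bolus-injection arterial input function
#'
#' Generates a tri-exponential, bolus-shaped parent-plasma curve (a
#' Feng-type model with a linear upslope: `(A1*t - A2 - A3)*exp(-l1*t) +
#' A2*exp(-l2*t) + A3*exp(-l3*t)`, `t` in minutes), together with a
#' companion whole-blood curve obtained through the inverse
#' plasma-over-blood ratio and a parent fraction declining from 1 (a
#' Hill sigmoid). Amplitude scales linearly with injected dose and
#' inversely with body weight.
#'
#' @param dose_MBq Injected dose (MBq).
#' @param weight_kg Body weight (kg).
#' @param params Named list overriding any of `A1`, `A2`, `A3` (kBq/ml),
#'   `l1`, `l2`, `l3` (1/min), `pob_intercept`, `pob_slope` (ratio per
#'   second), `pf_t50_s`, `pf_h` (parent-fraction Hill parameters).
#' @param jitter_cv Log-normal coefficient of variation applied to the
#'   amplitude and rate parameters (session-to-session physiological
#'   variation); 0 gives a deterministic curve.
#' @param t_end_s,dt_s Output grid in seconds post-injection.
#' @return An input-function tibble as in [derive_input_function()].
#' @export
simulate_input <- function(dose_MBq = 364, weight_kg = 75, params = list(),
                           jitter_cv = 0, t_end_s = 5400, dt_s = 1) {
  p <- utils::modifyList(list(
    A1 = 250, A2 = 1.5, A3 = 1.0,
    l1 = 1.5, l2 = 0.12, l3 = 0.0105,
    pob_intercept = 1.25, pob_slope = 8e-5,
    pf_t50_s = 1500, pf_h = 1.8
  ), params)
  if (any(unlist(p[c("l1", "l2", "l3")]) <= 0)) {
    stop("tail rates must be positive", call. = FALSE)
  }
  if (p$A1 < 0) stop("bolus amplitude must be non-negative", call. = FALSE)
  if (jitter_cv > 0) {
    sdlog <- sqrt(log(1 + jitter_cv^2))
    for (nm in c("A1", "A2", "A3", "l1", "l2", "l3")) {
      p[[nm]] <- p[[nm]] * stats::rlnorm(1, -sdlog^2 / 2, sdlog)
    }
  }
  scale <- (dose_MBq / 364) * (75 / weight_kg)
  t_min <- seq(0, t_end_s, by = dt_s) / 60
  cp <- scale * ((p$A1 * t_min - p$A2 - p$A3) * exp(-p$l1 * t_min) +
                   p$A2 * exp(-p$l2 * t_min) + p$A3 * exp(-p$l3 * t_min))
  cp <- pmax(cp, 0)
  t_s <- t_min * 60
  pob <- pmax(p$pob_intercept + p$pob_slope * t_s, 1e-3)
  pf <- 1 / (1 + (t_s / p$pf_t50_s)^p$pf_h)
  out <- tibble::tibble(
    time_s = t_s,
    whole_blood = cp / (pob * pf),
    plasma_over_blood = pob,
    parent_fraction = pf,
    parent_plasma = cp
  )
  class(out) <- c("petrel_input", class(out))
  out
}

# continuous tissue + blood model on the fine grid, all rates per second
model_curve_fine <- function(input, K1_s, k2_s, k3_s = NA, k4_s = NA,
                             bv = 0.05, dt_s = 1) {
  cp <- input$parent_plasma
  if (is.na(k3_s) || is.na(k4_s) || k3_s == 0) {
    ct <- K1_s * exp_conv(cp, dt_s, k2_s)
  } else {
    s <- k2_s + k3_s + k4_s
    d <- sqrt(s^2 - 4 * k2_s * k4_s)
    th1 <- (s - d) / 2
    th2 <- (s + d) / 2
    ct <- K1_s * ((k3_s + k4_s - th1) * exp_conv(cp, dt_s, th1) +
                    (th2 - k3_s - k4_s) * exp_conv(cp, dt_s, th2)) / (th2 - th1)
  }
  (1 - bv) * ct + bv * input$whole_blood
}

#' Simulate a regional time-activity curve
#'
#' Evaluates the continuous compartmental model
#' `C(t) = (1 - bv) * C_tissue(t) + bv * C_blood(t)` on a fine grid
#' (one-tissue kinetics when `k3`/`k4` are absent, two-tissue otherwise),
#' averages it over the frames of `schedule` (frames preceding the
#' injection contribute zero model signal), and adds zero-mean Gaussian
#' noise with variance proportional to `C / L_i` (activity over frame
#' length) scaled by `noise_scale` -- the variance structure that the
#' frame weights `w_i = L_i / T_i` assume. The true-coincidence rate
#' `trues_rate` is populated proportionally to the frame activity.
#'
#' @param truth Named list or one-row data frame with `K1`
#'   (ml cm^-3 min^-1), `k2` (min^-1), optional `k3`, `k4` (min^-1) and
#'   `bv` (fraction of the signal that is intravascular blood).
#' @param input Input-function tibble covering the schedule.
#' @param schedule A [frame_schedule()].
#' @param noise_scale Noise magnitude; 0 gives the exact frame-averaged
#'   model.
#' @param region_id Label stored with the curve.
#' @return A tibble with columns `region_id`, `frame`, `value_kBq_ml`,
#'   `trues_rate`; the schedule is attached as the `"schedule"` attribute.
#' @export
simulate_tac <- function(truth, input, schedule, noise_scale = 0,
                         region_id = "region") {
  truth <- as.list(truth)
  stopifnot(truth$K1 >= 0, is.null(truth$k2) || truth$k2 > 0)
  check_input_function(input)
  dt <- input$time_s[2] - input$time_s[1]
  fine <- model_curve_fine(
    input,
    K1_s = truth$K1 / 60, k2_s = truth$k2 / 60,
    k3_s = if (is.null(truth$k3) || is.na(truth$k3)) NA else truth$k3 / 60,
    k4_s = if (is.null(truth$k4) || is.na(truth$k4)) NA else truth$k4 / 60,
    bv = truth$bv %||% 0.05, dt_s = dt
  )
  mean_c <- frame_average(fine, dt, schedule$start_inj_s, schedule$end_inj_s)
  L <- schedule$frame_duration_s
  values <- mean_c
  if (noise_scale > 0) {
    sd_i <- noise_scale * sqrt(pmax(mean_c, 0) / L)
    values <- mean_c + stats::rnorm(length(mean_c), 0, sd_i)
  }
  trues <- 200 * (pmax(mean_c, 0) + 0.01 * max(mean_c, 1e-6))
  out <- tibble::tibble(
    region_id = region_id,
    frame = schedule$frame,
    value_kBq_ml = values,
    trues_rate = trues
  )
  attr(out, "schedule") <- schedule
  out
}

#' Simulate a two-session test-retest cohort with known ground truth
#'
#' Draws a cohort of `n_subjects`, each scanned twice. Between-subject
#' biological variation is modelled as a global log-normal receptor
#' density factor per subject (coefficient of variation `bs_cv`) shared
#' across regions and multiplying the regional V_T profile; each
#' subject x session x region value receives an independent
#' multiplicative log-normal session perturbation with coefficient of
#' variation `ws_cv`. Rates are decomposed as `k2 = K1 / V_T` with `K1`
#' drawn uniformly in a narrow physiological band, and the blood volume
#' fraction is fixed. Demographics are sampled within typical adult
#' ranges. The whole cohort is reproducible from `seed`.
#'
#' @param n_subjects Number of subjects (>= 2); each gets two sessions.
#' @param regions Regional V_T profile as from [default_region_profile()].
#' @param bs_cv,ws_cv Between-subject and within-subject (session)
#'   coefficients of variation of true V_T.
#' @param noise_scale TAC noise level passed to [simulate_tac()].
#' @param schedule Frame schedule (default [default_frame_schedule()]).
#' @param seed Integer seed; all randomness derives from it.
#' @param tacs If `FALSE`, only demographics and ground truth are
#'   generated (fast path for variance-component studies); the truth is
#'   identical to a `tacs = TRUE` run at the same seed.
#' @param k1_range Uniform sampling band for `K1` (ml cm^-3 min^-1).
#' @param bv Blood volume fraction applied to every simulated region.
#' @param if_jitter_cv Session-to-session physiological variation of the
#'   arterial input shape (passed to [simulate_input()]).
#' @return A list with elements `sessions` (a nested tibble: one row per
#'   subject x session with demographics and list-columns `input` and
#'   `tacs`), `truth` (subject x session x region tibble of true
#'   parameters including `vt_true`), and `schedule`.
#' @export
simulate_cohort <- function(n_subjects = 15, regions = default_region_profile(),
                            bs_cv = 0.35, ws_cv = 0.10, noise_scale = 1,
                            schedule = default_frame_schedule(), seed = 1,
                            tacs = TRUE, k1_range = c(0.05, 0.3), bv = 0.05,
                            if_jitter_cv = 0.05) {
  stopifnot(n_subjects >= 2, bs_cv >= 0, ws_cv >= 0)
  set.seed(seed)
  n_r <- nrow(regions)

  demo <- tibble::tibble(
    subject_id = sprintf("S%02d", seq_len(n_subjects)),
    age_y = sample(25:65, n_subjects, replace = TRUE),
    weight_kg = round(stats::runif(n_subjects, 55, 95), 1),
    interval_d = pmax(1, round(stats::rlnorm(n_subjects, log(24), 1)))
  )
  doses <- matrix(round(pmin(pmax(stats::rnorm(2 * n_subjects, 364, 15),
                                  316), 399)),
                  ncol = 2)

  sdlog_bs <- sqrt(log(1 + bs_cv^2))
  sdlog_ws <- sqrt(log(1 + ws_cv^2))
  g_subj <- stats::rlnorm(n_subjects, -sdlog_bs^2 / 2, sdlog_bs)
  K1 <- matrix(stats::runif(n_subjects * n_r, k1_range[1], k1_range[2]),
               nrow = n_subjects)

  truth <- tidyr::expand_grid(
    subject_id = demo$subject_id,
    session = c("test", "retest"),
    region_id = regions$region_id
  )
  i_subj <- match(truth$subject_id, demo$subject_id)
  i_reg <- match(truth$region_id, regions$region_id)
  sess_eff <- stats::rlnorm(nrow(truth), -sdlog_ws^2 / 2, sdlog_ws)
  truth$vt_true <- regions$vt[i_reg] * g_subj[i_subj] * sess_eff
  truth$K1 <- K1[cbind(i_subj, i_reg)]
  truth$k2 <- truth$K1 / truth$vt_true
  truth$bv <- bv

  sessions <- tidyr::expand_grid(subject_id = demo$subject_id,
                                 session = c("test", "retest"))
  sessions <- dplyr::left_join(sessions, demo, by = "subject_id")
  sessions$dose_MBq <- as.vector(t(doses))[
    (match(sessions$subject_id, demo$subject_id) - 1L) * 2L +
      ifelse(sessions$session == "test", 1L, 2L)]

  if (tacs) {
    sessions$input <- purrr::map2(sessions$dose_MBq, sessions$weight_kg,
                                  ~ simulate_input(.x, .y,
                                                   jitter_cv = if_jitter_cv))
    sessions$tacs <- purrr::pmap(
      list(sessions$subject_id, sessions$session, sessions$input),
      function(sid, sess, input) {
        rows <- truth[truth$subject_id == sid & truth$session == sess, ]
        purrr::list_rbind(purrr::map(seq_len(nrow(rows)), function(i) {
          simulate_tac(rows[i, c("K1", "k2", "bv")], input, schedule,
                       noise_scale = noise_scale,
                       region_id = rows$region_id[i])
        }))
      })
  }
  out <- list(sessions = sessions, truth = truth, schedule = schedule)
  attr(out, "params") <- list(bs_cv = bs_cv, ws_cv = ws_cv,
                              noise_scale = noise_scale, seed = seed)
  class(out) <- "petrel_cohort"
  out
}

#' Partition a small voxel grid into disjoint region masks
#'
#' @param dim Integer length-3 grid dimensions.
#' @param region_ids Region labels; voxels are split into contiguous
#'   equal blocks, one per region, covering the whole grid.
#' @return Named list of logical arrays.
#' @export
phantom_masks <- function(dim, region_ids) {
  n_vox <- prod(dim)
  n_r <- length(region_ids)
  idx <- split(seq_len(n_vox), cut(seq_len(n_vox), n_r, labels = FALSE))
  masks <- lapply(idx, function(i) {
    m <- array(FALSE, dim)
    m[i] <- TRUE
    m
  })
  names(masks) <- region_ids
  masks
}

#' Simulate a dynamic 4-D voxel phantom
#'
#' Every voxel inside a region mask receives that region's noise-free
#' frame-averaged model curve plus independent Gaussian voxel noise with
#' the same activity/frame-length variance structure as
#' [simulate_tac()]; voxels outside all masks stay zero.
#'
#' @param masks Named list of disjoint logical arrays (same dimensions).
#' @param truth Data frame with one row per region (`region_id`, `K1`,
#'   `k2`, optional `k3`, `k4`, `bv`).
#' @param input,schedule Input function and frame schedule.
#' @param noise_scale Voxel-level noise magnitude (0 = noise-free).
#' @return A list with `data` (4-D array x,y,z,frame) and `masks`.
#' @export
simulate_phantom <- function(masks, truth, input, schedule, noise_scale = 0) {
  dims <- dim(masks[[1]])
  stopifnot(length(dims) == 3)
  overlap <- Reduce(`+`, lapply(masks, function(m) m * 1L))
  if (any(overlap > 1L)) stop("region masks overlap", call. = FALSE)
  n_f <- nrow(schedule)
  vol <- array(0, c(dims, n_f))
  flat <- matrix(0, nrow = prod(dims), ncol = n_f)
  for (r in seq_len(nrow(truth))) {
    rid <- truth$region_id[r]
    base <- simulate_tac(truth[r, setdiff(names(truth), "region_id")],
                         input, schedule, noise_scale = 0,
                         region_id = rid)$value_kBq_ml
    vox <- which(masks[[rid]])
    flat[vox, ] <- matrix(base, nrow = length(vox), ncol = n_f, byrow = TRUE)
    if (noise_scale > 0) {
      sd_i <- noise_scale * sqrt(pmax(base, 0) / schedule$frame_duration_s)
      flat[vox, ] <- flat[vox, ] +
        matrix(stats::rnorm(length(vox) * n_f, 0, rep(sd_i, each = length(vox))),
               nrow = length(vox))
    }
  }
  vol[] <- flat
  list(data = vol, masks = masks)
}
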