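#' Modified standardised uptake value
#'
#' A tissue-only uptake index needing no arterial input: the mean
#' activity concentration over a late washout window, scaled by a size
#' term and the injected dose,
#' `mSUV = activity * ((weight_kg + 70) / 2) / dose_MBq`.
#' The size term shrinks the usual body-weight normalisation toward a
#' 70 kg standard subject, halving the influence of body habitus.
#' "Activity" is the duration-weighted mean concentration over all
#' frames overlapping the window; frames partially inside contribute in
#' proportion to their overlap. The window is specified in time rather
#' than frame indices, the default being roughly 30 to 59 minutes
#' post-injection (1790 to 3530 s), late enough for the signal to
#' reflect retention rather than delivery.
#'
#' @param tac TAC tibble with `value_kBq_ml` per frame.
#' @param weight_kg,dose_MBq Subject weight (kg) and injected dose
#'   (MBq); both must be positive.
#' @param window Length-2 numeric, window in seconds post-injection.
#' @param schedule Frame schedule (default: TAC attribute).
#' @return A tibble with `region_id`, `msuv`, `window_start_s`,
#'   `window_end_s`, `mean_activity_kBq_ml`.
#' @examples
#' sched <- default_frame_schedule()
#' inp <- simulate_input()
#' tac <- simulate_tac(list(K1 = 0.15, k2 = 0.02, bv = 0.05), inp, sched)
#' msuv(tac, weight_kg = 80, dose_MBq = 370)
#' @export
msuv <- function(tac, weight_kg, dose_MBq, window = c(1790, 3530),
                 schedule = attr(tac, "schedule")) {
  stopifnot(is.data.frame(tac), length(window) == 2, window[1] < window[2])
  if (is.null(schedule)) stop("a frame schedule is required", call. = FALSE)
  if (weight_kg <= 0) stop("weight must be positive", call. = FALSE)
  if (dose_MBq <= 0) stop("injected dose must be positive", call. = FALSE)
  overlap <- pmin(schedule$end_inj_s, window[2]) -
    pmax(schedule$start_inj_s, window[1])
  overlap <- pmax(overlap, 0)
  if (sum(overlap) <= 0) {
    stop("window does not overlap the frame schedule", call. = FALSE)
  }
  act <- sum(tac$value_kBq_ml * overlap) / sum(overlap)
  tibble::tibble(
    region_id = tac$region_id[1] %||% "region",
    msuv = act * ((weight_kg + 70) / 2) / dose_MBq,
    window_start_s = window[1],
    window_end_s = window[2],
    mean_activity_kBq_ml = act
  )
}

#' Global intensity of a summed-activity volume
#'
#' Mean voxel value within the implicit foreground mask defined as all
#' voxels exceeding one eighth of the whole-volume mean -- the
#' conventional quick global normaliser for brain images, robust to the
#' large zero background of a masked volume.
#'
#' @param volume Numeric array (any shape).
#' @return Scalar global intensity.
#' @examples
#' global_intensity(array(c(0, 1, 1, 6), c(2, 2, 1)))  # mean of {1,1,6}
#' @export
global_intensity <- function(volume) {
  v <- as.numeric(volume)
  if (length(v) == 0) stop("empty volume", call. = FALSE)
  thr <- mean(v) / 8
  sel <- v > thr
  if (!any(sel)) {
    stop("no voxel exceeds 1/8 of the volume mean; degenerate volume",
         call. = FALSE)
  }
  mean(v[sel])
}
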