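# CSV dialect used throughout: comma-separated, header row, UTF-8,
# '.' decimal; times in seconds, activities in kBq/ml.

#' Read and write cohort directories
#'
#' A cohort on disk is a directory of four flat CSV files:
#' \describe{
#'   \item{`cohort.csv`}{`subject_id, session, age_y, weight_kg,
#'     dose_MBq, interval_d` -- one row per subject x session.}
#'   \item{`schedule.csv`}{`frame_start_s, frame_duration_s,
#'     injection_offset_s` (offset repeated on every row).}
#'   \item{`tacs.csv`}{`subject_id, session, region_id, frame,
#'     value_kBq_ml, trues_rate`.}
#'   \item{`input.csv`}{`subject_id, session, time_s, parent_plasma,
#'     whole_blood`.}
#' }
#' `read_cohort()` returns the nested sessions tibble used across the
#' package (list-columns `input` and `tacs`); `write_cohort()` writes
#' one. Writing then reading reproduces all values to full precision.
#'
#' @param path Directory path.
#' @param sessions Nested sessions tibble (as produced by
#'   [simulate_cohort()] or `read_cohort()`).
#' @param schedule Frame schedule for `write_cohort()`.
#' @return `read_cohort()`: a list with `sessions` and `schedule`.
#' @export
read_cohort <- function(path) {
  need <- function(f) {
    p <- file.path(path, f)
    if (!file.exists(p)) stop("missing cohort file: ", f, call. = FALSE)
    readr::read_csv(p, show_col_types = FALSE, comment = "#")
  }
  demo <- need("cohort.csv")
  req <- c("subject_id", "session", "age_y", "weight_kg", "dose_MBq",
           "interval_d")
  missing_cols <- setdiff(req, names(demo))
  if (length(missing_cols)) {
    stop("cohort.csv lacks mandatory columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  sch_tbl <- need("schedule.csv")
  sched <- frame_schedule(
    tibble::tibble(count = 1, duration_s = sch_tbl$frame_duration_s),
    injection_offset_s = sch_tbl$injection_offset_s[1])
  tacs <- need("tacs.csv")
  inputs <- need("input.csv")

  n_f <- nrow(sched)
  sessions <- demo
  key <- paste(sessions$subject_id, sessions$session)
  by_key <- function(df) split(df, paste(df$subject_id, df$session))[key]
  tac_split <- by_key(tacs)
  inp_split <- by_key(inputs)
  for (i in seq_along(key)) {
    if (is.null(tac_split[[i]]) || is.null(inp_split[[i]])) {
      stop("cohort is missing data for subject ", sessions$subject_id[i],
           " session ", sessions$session[i], call. = FALSE)
    }
    counts <- table(tac_split[[i]]$region_id)
    if (any(counts != n_f)) {
      stop("tacs.csv frame count does not match the schedule for subject ",
           sessions$subject_id[i], call. = FALSE)
    }
  }
  sessions$tacs <- purrr::map(tac_split, function(d) {
    out <- tibble::as_tibble(d[order(d$region_id, d$frame),
                               c("region_id", "frame", "value_kBq_ml",
                                 "trues_rate")])
    attr(out, "schedule") <- sched
    out
  })
  sessions$input <- purrr::map(inp_split, function(d) {
    out <- tibble::as_tibble(d[order(d$time_s),
                               c("time_s", "parent_plasma", "whole_blood")])
    class(out) <- c("petrel_input", class(out))
    out
  })
  list(sessions = sessions, schedule = sched)
}

#' @rdname read_cohort
#' @export
write_cohort <- function(sessions, schedule, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  demo_cols <- c("subject_id", "session", "age_y", "weight_kg", "dose_MBq",
                 "interval_d")
  readr::write_csv(sessions[, demo_cols], file.path(path, "cohort.csv"))
  readr::write_csv(
    tibble::tibble(frame_start_s = schedule$frame_start_s,
                   frame_duration_s = schedule$frame_duration_s,
                   injection_offset_s = schedule_injection_offset(schedule)),
    file.path(path, "schedule.csv"))
  tacs <- purrr::pmap(
    list(sessions$subject_id, sessions$session, sessions$tacs),
    function(sid, sess, tac) {
      dplyr::mutate(tac, subject_id = sid, session = sess, .before = 1)
    }) |> purrr::list_rbind()
  readr::write_csv(tacs, file.path(path, "tacs.csv"))
  inputs <- purrr::pmap(
    list(sessions$subject_id, sessions$session, sessions$input),
    function(sid, sess, inp) {
      tibble::tibble(subject_id = sid, session = sess,
                     time_s = inp$time_s, parent_plasma = inp$parent_plasma,
                     whole_blood = inp$whole_blood)
    }) |> purrr::list_rbind()
  readr::write_csv(inputs, file.path(path, "input.csv"))
  invisible(path)
}

#' Write a per-region result table as CSV
#'
#' @param table Data frame (e.g. a reliability table or fits table).
#' @param path Output file.
#' @param provenance Optional character vector written as commented
#'   header lines (`# ...`) before the CSV body.
#' @return `path`, invisibly.
#' @export
write_region_table <- function(table, path, provenance = NULL) {
  if (!is.null(provenance)) {
    writeLines(paste0("# ", provenance), path)
    readr::write_csv(table, path, append = TRUE, col_names = TRUE)
  } else {
    readr::write_csv(table, path)
  }
  invisible(path)
}

#' Demographic and injectate details of the reference test-retest cohort
#'
#' Per-subject demographics of the fifteen-subject, two-session study
#' cohort that this package's reporting conventions follow: age, sex,
#' body-mass index, days between the two scans, and per-session
#' injected dose, radiochemical purity, co-injected stable mass and
#' specific activity. Medians of this table (364 MBq injected dose,
#' age 32 y, scan interval 24 d) serve as reference checks for cohort
#' ingestion.
#'
#' @return A tibble with one row per subject.
#' @export
demographics_table <- function() {
  path <- system.file("extdata", "demographics.csv", package = "petrel",
                      mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE)
}
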