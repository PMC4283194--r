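method_labels <- c("2kbv", "4kbv", "sa_roi", "sa_map", "rs_sa", "srtm", "msuv")

#' Fit every region of a cohort with one or more quantification methods
#'
#' Runs the TAC-based quantification methods over all subject x session
#' x region curves of a (simulated or read) cohort and returns one tidy
#' row per fit. A failed or degenerate fit yields a flagged row with
#' `NaN` estimates rather than an error, so downstream reliability
#' tables can report exclusions. The `value` column always carries the
#' method's primary outcome (V_T for compartmental and spectral
#' methods, BP_ND for the reference-tissue model, mSUV for the uptake
#' index).
#'
#' @param sessions Nested sessions tibble with list-columns `tacs` and
#'   `input` (see [simulate_cohort()], [read_cohort()]).
#' @param schedule Frame schedule shared by all TACs.
#' @param methods Subset of `"2kbv"`, `"4kbv"`, `"sa_roi"`, `"rs_sa"`,
#'   `"srtm"`, `"msuv"` (the voxelwise `"sa_map"` path is driven by
#'   [run_pipeline()], which has access to phantom data).
#' @param reference_region Pseudo-reference region label for SRTM
#'   (default `"pons"`; excluded from SRTM target rows).
#' @param msuv_window Late uptake window for [msuv()] in seconds
#'   post-injection.
#' @param options Named list of per-method option lists, e.g.
#'   `list("2kbv" = list(n_grid = 30))`.
#' @return A tibble with columns `subject_id`, `session`, `region_id`,
#'   `method`, `K1`, `k2`, `k3`, `k4`, `bv`, `vt`, `bp`, `value`,
#'   `converged`.
#' @export
fit_cohort <- function(sessions, schedule,
                       methods = c("2kbv", "sa_roi", "rs_sa", "srtm", "msuv"),
                       reference_region = "pons",
                       msuv_window = c(1790, 3530), options = list()) {
  methods <- match.arg(methods, setdiff(method_labels, "sa_map"),
                       several.ok = TRUE)
  rows <- purrr::pmap(
    list(sessions$subject_id, sessions$session, sessions$tacs,
         sessions$input, sessions$weight_kg, sessions$dose_MBq),
    function(sid, sess, tacs, input, wkg, dose) {
      regions <- split(tacs, tacs$region_id)
      ref_tac <- regions[[reference_region]]
      purrr::list_rbind(purrr::imap(regions, function(tac, rid) {
        attr(tac, "schedule") <- schedule
        purrr::list_rbind(purrr::map(methods, function(m) {
          fit_one(m, tac, input, schedule, ref_tac, rid, wkg, dose,
                  msuv_window, options[[m]])
        })) |>
          dplyr::mutate(subject_id = sid, session = sess, region_id = rid,
                        .before = 1)
      }))
    })
  purrr::list_rbind(rows)
}

empty_fit_row <- function(method) {
  tibble::tibble(method = method, K1 = NA_real_, k2 = NA_real_,
                 k3 = NA_real_, k4 = NA_real_, bv = NA_real_,
                 vt = NA_real_, bp = NA_real_, value = NaN,
                 converged = FALSE)
}

fit_one <- function(method, tac, input, schedule, ref_tac, rid, wkg, dose,
                    msuv_window, opts) {
  opts <- opts %||% list()
  row <- empty_fit_row(method)
  tryCatch({
    if (method == "2kbv") {
      f <- fit_2kbv(tac, input, schedule, options = opts)
      row[, c("K1", "k2", "bv", "vt", "value", "converged")] <-
        list(f$K1, f$k2, f$bv, f$vt, f$vt, f$converged)
    } else if (method == "4kbv") {
      f <- fit_4kbv(tac, input, schedule, options = opts)
      row[, c("K1", "k2", "k3", "k4", "bv", "vt", "value", "converged")] <-
        list(f$K1, f$k2, f$k3, f$k4, f$bv, f$vt, f$vt, f$converged)
    } else if (method == "sa_roi") {
      f <- sa_fit(tac, input, schedule)
      row[, c("bv", "vt", "value", "converged")] <-
        list(min(f$alpha_bv, 0.5), f$vt, f$vt, TRUE)
    } else if (method == "rs_sa") {
      f <- suppressWarnings(rs_sa_fit(tac, input, schedule))
      row[, c("vt", "value", "converged")] <-
        list(f$vt, f$vt, f$plateau_found)
    } else if (method == "srtm") {
      if (rid == ref_tac$region_id[1]) return(row[0, ])
      f <- fit_srtm(tac, ref_tac, schedule)
      row[, c("k2", "bp", "value", "converged")] <-
        list(f$k2, f$bp, f$bp, f$converged)
    } else if (method == "msuv") {
      f <- msuv(tac, weight_kg = wkg, dose_MBq = dose,
                window = msuv_window, schedule = schedule)
      row[, c("value", "converged")] <- list(f$msuv, TRUE)
    }
    row
  }, error = function(e) row)
}

#' Pipeline configuration
#'
#' @param seed Integer seed controlling every random draw of the run.
#' @param n_subjects,regions,bs_cv,ws_cv,noise_scale,if_jitter_cv Cohort
#'   generator settings (see [simulate_cohort()]).
#' @param methods Methods to run (default: all seven).
#' @param reference_region Pseudo-reference label for SRTM.
#' @param phantom_dim Grid for the voxelwise path (used when
#'   `"sa_map"` is requested).
#' @param icc_denominator Passed to reliability tables.
#' @param msuv_window Seconds post-injection.
#' @param options Per-method option lists (see [fit_cohort()]).
#' @return A `petrel_config` list.
#' @export
pipeline_config <- function(seed = 1, n_subjects = 15,
                            regions = default_region_profile(),
                            bs_cv = 0.35, ws_cv = 0.10, noise_scale = 1,
                            if_jitter_cv = 0.05,
                            methods = method_labels,
                            reference_region = "pons",
                            phantom_dim = c(8, 8, 4),
                            icc_denominator = "standard",
                            msuv_window = c(1790, 3530),
                            options = list()) {
  methods <- match.arg(methods, method_labels, several.ok = TRUE)
  structure(
    list(seed = seed, n_subjects = n_subjects, regions = regions,
         bs_cv = bs_cv, ws_cv = ws_cv, noise_scale = noise_scale,
         if_jitter_cv = if_jitter_cv,
         methods = methods, reference_region = reference_region,
         phantom_dim = phantom_dim, icc_denominator = icc_denominator,
         msuv_window = msuv_window, options = options),
    class = "petrel_config")
}

#' Run the full simulate / quantify / report pipeline
#'
#' Simulates a two-session cohort, quantifies every region with each
#' requested method (including, for `"sa_map"`, simulating a dynamic
#' voxel phantom per session and sampling the voxelwise spectral V_T
#' map), builds the per-method reliability tables and the cross-method
#' summary, and writes everything under `out_dir`:
#' `cohort/` (input CSVs), `fits.csv`, `ground_truth.csv`,
#' `reliability_<method>.csv`, `summary_methods.csv`, `run.log`.
#' Every CSV carries a provenance header (package version, seed,
#' configuration hash); a failed fit is logged and flagged, never
#' fatal. Runs are byte-identical for a fixed configuration.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with `fits`, `tables` (per method),
#'   `summary`, `truth`, `out_dir`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile("run")) {
  stopifnot(inherits(config, "petrel_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  log_con <- file(log_path, open = "wt")
  on.exit(close(log_con), add = TRUE)
  logf <- function(...) {
    writeLines(sprintf(...), log_con)
  }
  prov <- c(
    sprintf("petrel %s", as.character(utils::packageVersion("petrel"))),
    sprintf("seed %d", config$seed),
    sprintf("config_hash %s", rlang::hash(unclass(config))))
  logf("run_pipeline start: %s", paste(prov, collapse = "; "))

  sim <- simulate_cohort(
    n_subjects = config$n_subjects, regions = config$regions,
    bs_cv = config$bs_cv, ws_cv = config$ws_cv,
    noise_scale = config$noise_scale, seed = config$seed,
    if_jitter_cv = config$if_jitter_cv)
  write_cohort(sim$sessions, sim$schedule, file.path(out_dir, "cohort"))
  write_region_table(sim$truth, file.path(out_dir, "ground_truth.csv"),
                     provenance = prov)
  logf("cohort simulated: %d subjects x 2 sessions x %d regions",
       config$n_subjects, nrow(config$regions))

  tac_methods <- setdiff(config$methods, "sa_map")
  fits <- fit_cohort(sim$sessions, sim$schedule, methods = tac_methods,
                     reference_region = config$reference_region,
                     msuv_window = config$msuv_window,
                     options = config$options)

  if ("sa_map" %in% config$methods) {
    fits <- dplyr::bind_rows(fits, map_fits(sim, config))
  }
  for (i in seq_len(nrow(fits))) {
    if (!isTRUE(fits$converged[i])) {
      logf("non-converged fit: %s %s %s %s", fits$subject_id[i],
           fits$session[i], fits$region_id[i], fits$method[i])
    }
  }
  write_region_table(fits, file.path(out_dir, "fits.csv"), provenance = prov)

  tables <- lapply(split(fits, fits$method), function(d) {
    build_reliability_table(d, value_col = "value",
                            method_label = d$method[1],
                            icc_denominator = config$icc_denominator)
  })
  for (m in names(tables)) {
    write_region_table(tables[[m]],
                       file.path(out_dir, sprintf("reliability_%s.csv", m)),
                       provenance = prov)
  }
  summary <- purrr::list_rbind(purrr::map(tables, reliability_summary))
  write_region_table(summary, file.path(out_dir, "summary_methods.csv"),
                     provenance = prov)
  logf("run_pipeline done: %d fits, %d method tables",
       nrow(fits), length(tables))
  invisible(list(fits = fits, tables = tables, summary = summary,
                 truth = sim$truth, out_dir = out_dir))
}

# voxelwise spectral path: phantom per session from the ground truth,
# voxel noise at the cohort noise level, map sampled over the masks
map_fits <- function(sim, config) {
  masks <- phantom_masks(config$phantom_dim, config$regions$region_id)
  set.seed(config$seed + 1L)
  purrr::list_rbind(purrr::pmap(
    list(sim$sessions$subject_id, sim$sessions$session, sim$sessions$input),
    function(sid, sess, input) {
      truth <- sim$truth[sim$truth$subject_id == sid &
                           sim$truth$session == sess, ]
      ph <- simulate_phantom(masks, truth, input, sim$schedule,
                             noise_scale = config$noise_scale)
      map <- sa_voxelwise(ph, input, sim$schedule)
      sampled <- sample_map(map, masks)
      dplyr::mutate(empty_fit_row("sa_map")[rep(1, nrow(sampled)), ],
                    subject_id = sid, session = sess,
                    region_id = sampled$region_id,
                    vt = sampled$vt, value = sampled$vt,
                    converged = TRUE, .before = 1)
    }))
}

#' Read a pipeline configuration from a YAML file
#'
#' Accepts a flat YAML mapping of [pipeline_config()] arguments, plus an
#' optional `regions` block given as parallel `region_id` / `vt` lists.
#'
#' @param path YAML file path.
#' @return A `petrel_config`.
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("reading YAML configurations requires the 'yaml' package",
         call. = FALSE)
  }
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$regions)) {
    raw$regions <- tibble::tibble(region_id = unlist(raw$regions$region_id),
                                  vt = unlist(raw$regions$vt))
  }
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown configuration fields: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(pipeline_config, raw)
}
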