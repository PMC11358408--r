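#' Run configuration for the end-to-end pipeline
#'
#' Bundles and validates the analysis settings: the RWC evaluation
#' window, the RWC step `delta_s`, the CR reliability threshold, the
#' calibration source and the seed.
#'
#' @param window RWC window `c(lo, hi)`, percent; `lo < hi`.
#' @param delta_s RWC step, percentage points (> 0).
#' @param threshold CR reliability threshold (>= 0).
#' @param calibration `"fixed"` to use [default_calibrations()] (or the
#'   list supplied in `calibrations`), `"fit"` to fit per species from
#'   the table's `m_a`/`m_d`/`m_t` columns.
#' @param calibrations Named list of [lmd_rwc_calibration()] per species
#'   (used when `calibration = "fixed"`).
#' @param groups Named character vector mapping parameter names to
#'   groups; `NULL` to skip group summaries.
#' @param seed Integer seed recorded in the manifest.
#' @return An object of class `run_config`.
#' @export
run_config <- function(window = c(50, 100), delta_s = 10, threshold = 0.4,
                       calibration = c("fixed", "fit"),
                       calibrations = default_calibrations(),
                       groups = NULL, seed = 1) {
  calibration <- match.arg(calibration)
  stopifnot(length(window) == 2L, window[1L] < window[2L],
            delta_s > 0, threshold >= 0)
  structure(list(window = as.numeric(window), delta_s = delta_s,
                 threshold = threshold, calibration = calibration,
                 calibrations = calibrations, groups = groups,
                 seed = as.integer(seed)),
            class = "run_config")
}

mass_cols <- c("sample_id", "species", "time_h", "m_f", "m_a", "m_d", "m_t",
               "area_cm2")

# melt the wide sample table into the tidy series the reliability module
# consumes, attaching calibrated RWC per sample
build_series <- function(samples, config) {
  param_cols <- setdiff(names(samples), mass_cols)
  if (!length(param_cols))
    stop("pipeline stage 'series': no parameter columns in the sample table",
         call. = FALSE)
  per_species <- split(samples, samples$species)
  rows <- list()
  for (sp in names(per_species)) {
    d <- per_species[[sp]]
    cal <- if (config$calibration == "fixed") {
      if (is.null(config$calibrations[[sp]]))
        stop(sprintf("pipeline stage 'calibration': no fixed calibration for species %s", sp),
             call. = FALSE)
      config$calibrations[[sp]]
    } else {
      if (!all(c("m_d", "m_t") %in% names(d)) ||
          anyNA(d$m_d) || anyNA(d$m_t))
        stop(sprintf("pipeline stage 'calibration': species %s lacks m_d/m_t for fitting", sp),
             call. = FALSE)
      fit_lmd_rwc_calibration(compute_lmd(d$m_f, d$m_a),
                              compute_rwc_direct(d$m_a, d$m_d, d$m_t))
    }
    rwc <- suppressWarnings(apply_calibration(cal, compute_lmd(d$m_f, d$m_a)))
    for (p in param_cols) {
      rows[[length(rows) + 1L]] <- data.frame(
        species = sp, parameter = p,
        group = unname(if (is.null(config$groups)) NA_character_
                       else config$groups[[p]]),
        sample_id = d$sample_id, rwc = rwc, value = d[[p]],
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Run the full comparative-reliability pipeline
#'
#' Masses to calibrated RWC, parameter columns to tidy series,
#' reliability coefficients per parameter, CR ranking, per-group rank
#' sums (when groups are assigned) and coefficient-coefficient
#' correlations. Optionally writes all tables plus a run manifest.
#'
#' @param samples A wide per-sample table ([read_sample_table()] or
#'   [simulate_dataset()]'s `samples`).
#' @param config A [run_config()].
#' @param output_dir Directory for the output CSVs; `NULL` (default)
#'   writes nothing.
#' @return A list: `series`, `results` (reliability table), `ranked`
#'   (by CR), `group_summary` (or `NULL`), `correlations` (data.frame of
#'   pairwise r2: CR-CS, CR-CI, CS-CI per species), `manifest`.
#' @export
run_pipeline <- function(samples, config = run_config(), output_dir = NULL) {
  stopifnot(is.data.frame(samples), inherits(config, "run_config"))
  series <- build_series(samples, config)
  results <- reliability_table(series, delta_s = config$delta_s,
                               window = config$window,
                               threshold = config$threshold)
  ranked <- do.call(rbind, lapply(split(results, results$species),
                                  rank_parameters, by = "CR"))
  rownames(ranked) <- NULL

  group_summary <- if (!any(is.na(results$group)))
    group_rank_sums(results) else NULL

  pairs <- list(c("CR", "CS"), c("CR", "CI"), c("CS", "CI"))
  corr_rows <- list()
  for (sp in unique(results$species)) {
    res_sp <- results[results$species == sp, ]
    for (pr in pairs) {
      r2 <- tryCatch(
        suppressMessages(correlate_coefficients(res_sp, pr[1L], pr[2L])),
        error = function(e) NA_real_)
      corr_rows[[length(corr_rows) + 1L]] <- data.frame(
        species = sp, x = pr[1L], y = pr[2L], r2 = r2,
        stringsAsFactors = FALSE)
    }
  }
  correlations <- do.call(rbind, corr_rows)

  manifest <- data.frame(
    key = c("window_lo", "window_hi", "delta_s", "threshold", "calibration",
            "seed", "n_samples", "n_parameters", "package_version"),
    value = c(config$window[1L], config$window[2L], config$delta_s,
              config$threshold, config$calibration, config$seed,
              nrow(samples), length(unique(results$parameter)),
              as.character(utils::packageVersion("drydown"))),
    stringsAsFactors = FALSE)

  out <- list(series = series, results = results, ranked = ranked,
              group_summary = group_summary, correlations = correlations,
              manifest = manifest)

  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    ok <- FALSE
    on.exit(if (!ok) unlink(file.path(output_dir,
                                      c("ranked.csv", "results.csv",
                                        "group_summary.csv",
                                        "correlations.csv", "series.csv",
                                        "manifest.csv"))), add = TRUE)
    write_ranked_results(ranked, file.path(output_dir, "ranked.csv"))
    utils::write.csv(results, file.path(output_dir, "results.csv"),
                     row.names = FALSE)
    if (!is.null(group_summary))
      utils::write.csv(group_summary,
                       file.path(output_dir, "group_summary.csv"),
                       row.names = FALSE)
    utils::write.csv(correlations, file.path(output_dir, "correlations.csv"),
                     row.names = FALSE)
    utils::write.csv(series, file.path(output_dir, "series.csv"),
                     row.names = FALSE)
    utils::write.csv(manifest, file.path(output_dir, "manifest.csv"),
                     row.names = FALSE)
    ok <- TRUE
  }
  out
}
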