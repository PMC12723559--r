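#' Run the five-condition aging-microcircuit experiment
#'
#' For each condition and circuit seed: builds a randomized circuit under
#' the condition's aging profile, runs a brief-stimulus protocol (baseline
#' rate distribution, recurrent 10-50 ms rates, signal-detection overlap),
#' a stronger-stimulus protocol (spike-count decoding accuracy), and a
#' long baseline run that is forward-modeled to scalp EEG and decomposed
#' into spectral biomarkers (aperiodic offset/exponent, peak center
#' frequency, 1/f AUC, band AUCs, oscillation events). Group statistics
#' compare every metric against the reference condition.
#'
#' @param config A [circuit_config()].
#' @param conditions Condition labels to simulate.
#' @param n_circuits Randomized circuits per condition.
#' @param years Age offset for the aging profiles.
#' @param baseline_duration Duration of the spectral baseline run, ms.
#' @param n_trials Stimulus presentations per protocol.
#' @param trial_interval Spacing of presentations, ms.
#' @param pre_span Pre-stimulus baseline span of the brief run, ms.
#' @param stages Any of `"function"` (stimulus protocols and
#'   signal-detection/decoding metrics), `"spectral"` (EEG biomarkers),
#'   `"events"` (oscillation events; requires `"spectral"`).
#' @param decoding_classifier Classifier for [decoding_accuracy()].
#' @param n_boot Bootstrap resamples for [detection_error()].
#' @param n_perm Train/test splits for [decoding_accuracy()].
#' @param out_dir Optional directory: writes `circuits.csv`,
#'   `comparisons.csv` and `report.json`.
#' @param seed Base integer seed; circuit i of a condition uses
#'   `seed + 1000 * condition_index + i`.
#'
#' @return Object of class `experiment_report`: `circuits` (one row per
#'   condition x seed with all metrics), `comparisons` (group statistics
#'   vs the reference), `units`, and the run parameters.
#' @export
run_experiment <- function(config = circuit_config(),
                           conditions = AGING_CONDITIONS,
                           n_circuits = 20, years = 20,
                           baseline_duration = 28000,
                           n_trials = 20, trial_interval = 300,
                           pre_span = 3000,
                           stages = c("function", "spectral"),
                           decoding_classifier = "svm",
                           n_boot = 1000, n_perm = 100,
                           out_dir = NULL, seed = 1) {
  stopifnot(all(conditions %in% AGING_CONDITIONS))
  stages <- match.arg(stages, c("function", "spectral", "events"),
                      several.ok = TRUE)
  rows <- list()
  for (ci in seq_along(conditions)) {
    cond <- conditions[ci]
    profile <- make_profile(cond, years)
    for (k in seq_len(n_circuits)) {
      sd_k <- seed + 1000L * ci + k
      row <- data.frame(condition = cond, seed = sd_k,
                        baseline_rate = NA_real_, recurrent_rate = NA_real_,
                        recurrent_rate_strong = NA_real_,
                        detection_error = NA_real_,
                        decoding_accuracy = NA_real_,
                        offset = NA_real_, exponent = NA_real_,
                        peak_cf = NA_real_, aperiodic_auc = NA_real_,
                        theta_auc = NA_real_, alpha_auc = NA_real_,
                        beta_auc = NA_real_, n_events = NA_real_,
                        wave_height = NA_real_, error = NA_character_)
      res <- tryCatch({
        circ <- build_circuit(config, profile, seed = sd_k)
        if ("function" %in% stages) {
          brief <- simulate_circuit(circ, stimulus = brief_stimulus(),
                                    n_trials = n_trials,
                                    pre_span = pre_span,
                                    trial_interval = trial_interval,
                                    seed = sd_k)
          base_d <- baseline_rate_distribution(brief$spikes, span = pre_span)
          rec_d <- recurrent_rate_distribution(brief$spikes,
                                               trials = n_trials)
          det <- detection_error(base_d, rec_d, n_boot = n_boot,
                                 seed = sd_k)
          strong <- simulate_circuit(circ, stimulus = strong_stimulus(),
                                     n_trials = n_trials,
                                     pre_span = 1000,
                                     trial_interval = trial_interval,
                                     seed = sd_k + 1L)
          dec <- decoding_accuracy(strong$spikes,
                                   classifier = decoding_classifier,
                                   n_perm = n_perm, seed = sd_k)
          row$baseline_rate <- population_rate(brief$spikes, t_start = 0,
                                               t_end = pre_span)
          row$recurrent_rate <- mean(rec_d$rates)
          row$recurrent_rate_strong <- mean(
            recurrent_rate_distribution(strong$spikes, trials = n_trials,
                                        window = c(25, 75))$rates)
          row$detection_error <- det$overlap
          row$decoding_accuracy <- mean(dec)
        }
        if ("spectral" %in% stages) {
          base <- simulate_circuit(circ, duration = baseline_duration,
                                   seed = sd_k + 2L)
          eeg <- project_dipole(base$dipole)
          ps <- welch_psd(eeg)
          fit <- parameterize_spectrum(ps)
          row$offset <- fit$offset
          row$exponent <- fit$exponent
          row$peak_cf <- if (nrow(fit$peaks)) fit$peaks$cf[1] else NA_real_
          row$aperiodic_auc <- aperiodic_auc(fit)
          row$theta_auc <- band_auc(ps, EEG_BANDS$theta)
          row$alpha_auc <- band_auc(ps, EEG_BANDS$alpha)
          row$beta_auc <- band_auc(ps, EEG_BANDS$beta)
          if ("events" %in% stages) {
            ev <- detect_events(eeg)
            bandev <- ev[ev$band %in% names(EEG_BANDS), , drop = FALSE]
            row$n_events <- nrow(bandev)
            row$wave_height <- if (nrow(bandev))
              mean(bandev$wave_height) else NA_real_
          }
        }
        row
      }, error = function(e) {
        row$error <- conditionMessage(e)
        row
      })
      rows[[length(rows) + 1L]] <- res
    }
  }
  circuits <- do.call(rbind, rows)

  metric_units <- c(
    baseline_rate = "Hz (Pyr population, pre-stimulus span)",
    recurrent_rate = "Hz (Pyr, 10-50 ms post brief stimulus)",
    recurrent_rate_strong = "Hz (Pyr, 25-75 ms post stronger stimulus)",
    detection_error = "% overlap of baseline vs recurrent rate distributions",
    decoding_accuracy = "% correct, baseline vs response windows",
    offset = "log10 uV^2 (aperiodic offset, 3-30 Hz fit)",
    exponent = "1/f exponent (3-30 Hz fit)",
    peak_cf = "Hz (max-amplitude periodic peak)",
    aperiodic_auc = "area under aperiodic fit, 3-30 Hz",
    theta_auc = "uV^2 (4-8 Hz band area)",
    alpha_auc = "uV^2 (8-12 Hz band area)",
    beta_auc = "uV^2 (12-30 Hz band area)",
    n_events = "count (theta/alpha/beta oscillation events)",
    wave_height = "uV (mean band-filtered peak-to-trough)"
  )

  reference <- "middle_age"
  comparisons <- NULL
  if (reference %in% conditions && length(conditions) > 1 &&
      n_circuits >= 2) {
    for (m in names(metric_units)) {
      vals <- circuits[[m]]
      ok_groups <- vapply(conditions, function(cc)
        sum(is.finite(vals[circuits$condition == cc])) >= 2, logical(1))
      if (sum(is.finite(vals[circuits$condition == reference])) < 2) next
      sub <- circuits[circuits$condition %in% conditions[ok_groups], ]
      if (length(unique(sub$condition)) < 2) next
      cmp <- compare_conditions(sub, m, reference)
      cmp$metric <- m
      comparisons <- rbind(comparisons, cmp)
    }
  }

  report <- structure(list(
    circuits = circuits, comparisons = comparisons, units = metric_units,
    params = list(n_total = config$n_total, conditions = conditions,
                  n_circuits = n_circuits, years = years,
                  baseline_duration = baseline_duration,
                  n_trials = n_trials, trial_interval = trial_interval,
                  pre_span = pre_span, stages = stages, seed = seed)
  ), class = "experiment_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' Write an experiment report to CSV and JSON
#'
#' @param report An `experiment_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "experiment_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(report$circuits, file.path(dir, "circuits.csv"),
                   row.names = FALSE)
  if (!is.null(report$comparisons))
    utils::write.csv(report$comparisons, file.path(dir, "comparisons.csv"),
                     row.names = FALSE)
  jsonlite::write_json(
    list(params = report$params, units = as.list(report$units),
         comparisons = report$comparisons),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows")
  invisible(dir)
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("Experiment report:", nrow(x$circuits), "circuits (",
      paste(unique(x$circuits$condition), collapse = ", "), ")\n")
  n_err <- sum(!is.na(x$circuits$error))
  if (n_err) cat("  ", n_err, "circuit(s) failed\n")
  invisible(x)
}

#' Extract the labeled EEG feature dataset for the mechanism decoder
#'
#' One feature vector (offset, exponent, peak center frequency, 1/f AUC)
#' per successfully analyzed circuit, labeled by condition.
#'
#' @param report An `experiment_report` run with the `"spectral"` stage.
#' @param require_conditions Labels that must all be present (default the
#'   report's conditions).
#' @return List with `features` (matrix) and `labels`.
#' @export
feature_dataset <- function(report,
                            require_conditions = report$params$conditions) {
  stopifnot(inherits(report, "experiment_report"))
  cols <- c("offset", "exponent", "peak_cf", "aperiodic_auc")
  circ <- report$circuits
  ok <- is.finite(circ$offset) & is.finite(circ$exponent) &
    is.finite(circ$aperiodic_auc)
  if (!any(ok)) stop("report contains no spectral features")
  circ <- circ[ok, ]
  missing_cls <- setdiff(require_conditions, unique(circ$condition))
  if (length(missing_cls))
    stop("missing condition in feature dataset: ",
         paste(missing_cls, collapse = ", "))
  list(features = as.matrix(circ[, cols]), labels = circ$condition)
}
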