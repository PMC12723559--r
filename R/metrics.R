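#' Sliding-window baseline firing-rate distribution
#'
#' Mean pyramidal population rate in a sliding window over the pre-stimulus
#' baseline period (default 40 ms windows sliding in 1 ms steps over 3 s).
#'
#' @param spikes A `spike_data` object.
#' @param window Window length, ms.
#' @param step Window step, ms.
#' @param span Baseline span, ms. The span ends at the first stimulus time
#'   (or at `span` if the run has no stimulus).
#' @return Object of class `rate_distribution`: `rates` (Hz, one per
#'   window position), `window`, `step`.
#' @export
baseline_rate_distribution <- function(spikes, window = 40, step = 1,
                                       span = 3000) {
  stopifnot(inherits(spikes, "spike_data"))
  t_end <- if (length(spikes$stim_times)) min(spikes$stim_times) else span
  t_start <- t_end - span
  if (t_start < 0) stop("insufficient baseline span (need ", span, " ms)")
  pyr <- which(spikes$pop == "pyr")
  tt <- sort(spikes$time[spikes$neuron %in% pyr])
  starts <- seq(t_start, t_end - window, by = step)
  hi <- findInterval(starts + window, tt)
  lo <- findInterval(starts, tt)
  rates <- (hi - lo) / (length(pyr) * window / 1000)
  structure(list(rates = rates, window = window, step = step,
                 kind = "baseline"), class = "rate_distribution")
}

#' Per-trial firing rate during the recurrent activation period
#'
#' One pyramidal population rate per stimulus presentation over a fixed
#' post-stimulus window (default 10-50 ms).
#'
#' @param spikes A `spike_data` object with recorded stimulus times.
#' @param trials Number of stimulus presentations to use.
#' @param window Post-stimulus window `c(start, stop)`, ms.
#' @return Object of class `rate_distribution` with one rate per trial.
#' @export
recurrent_rate_distribution <- function(spikes, trials = 20,
                                        window = c(10, 50)) {
  stopifnot(inherits(spikes, "spike_data"))
  if (length(spikes$stim_times) == 0) stop("no stimulus times recorded")
  if (length(spikes$stim_times) < trials)
    stop("need ", trials, " stimulus presentations, have ",
         length(spikes$stim_times))
  st <- spikes$stim_times[seq_len(trials)]
  pyr <- which(spikes$pop == "pyr")
  tt <- sort(spikes$time[spikes$neuron %in% pyr])
  w_s <- (window[2] - window[1]) / 1000
  rates <- vapply(st, function(t0) {
    (findInterval(t0 + window[2], tt) - findInterval(t0 + window[1], tt)) /
      (length(pyr) * w_s)
  }, numeric(1))
  structure(list(rates = rates, window = diff(window), step = NA,
                 kind = "recurrent"), class = "rate_distribution")
}

as_rates <- function(x) {
  if (inherits(x, "rate_distribution")) x$rates else as.numeric(x)
}

# shared-bin histogram overlap, percent
overlap_percent <- function(x, y, breaks) {
  p1 <- graphics::hist(x, breaks = breaks, plot = FALSE)$counts
  p2 <- graphics::hist(y, breaks = breaks, plot = FALSE)$counts
  100 * sum(pmin(p1 / sum(p1), p2 / sum(p2)))
}

#' Signal-detection error as distribution overlap
#'
#' Percent overlap between the baseline and recurrent-period firing-rate
#' distributions on a shared equal-width binning (Freedman-Diaconis width
#' on the pooled sample, floored at 10 bins), with a bootstrap resampling
#' interval. Larger overlap means the stimulus response is harder to
#' distinguish from baseline.
#'
#' @param baseline,recurrent `rate_distribution` objects (or numeric
#'   vectors).
#' @param n_boot Bootstrap resamples.
#' @param seed Integer seed for the bootstrap.
#' @param breaks Optional explicit break points overriding the shared
#'   binning rule.
#' @return List: `overlap` (percent), `boot_mean`, `ci` (2.5/97.5
#'   percentiles), `breaks`.
#' @export
detection_error <- function(baseline, recurrent, n_boot = 1000, seed = 1,
                            breaks = NULL) {
  x <- as_rates(baseline)
  y <- as_rates(recurrent)
  if (length(x) == 0 || length(y) == 0) stop("empty rate distribution")
  if (is.null(breaks)) {
    pooled <- c(x, y)
    rng <- range(pooled)
    bw <- 2 * stats::IQR(pooled) / length(pooled)^(1 / 3)
    nbins <- if (bw > 0) max(10L, ceiling(diff(rng) / bw)) else 10L
    if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
    breaks <- seq(rng[1], rng[2], length.out = nbins + 1)
    # guard against values landing exactly on the open edge
    breaks[1] <- breaks[1] - 1e-9
    breaks[length(breaks)] <- breaks[length(breaks)] + 1e-9
  }
  ov <- overlap_percent(x, y, breaks)
  boot <- with_seed(seed, vapply(seq_len(n_boot), function(i) {
    overlap_percent(sample(x, replace = TRUE), sample(y, replace = TRUE),
                    breaks)
  }, numeric(1)))
  list(overlap = ov, boot_mean = mean(boot),
       ci = stats::quantile(boot, c(0.025, 0.975)), breaks = breaks)
}

#' Decoding accuracy of baseline versus recurrent response
#'
#' Builds per-window pyramidal spike-count vectors - one count per Pyr
#' neuron in the 50 ms pre-stimulus window (noise class) and in the
#' 25-75 ms post-stimulus window (signal class) of each trial - and trains
#' a classifier to separate the two classes on a random 70/30 train/test
#' split, repeated over `n_perm` splits.
#'
#' @param spikes A `spike_data` with stimulus times.
#' @param classifier `"svm"` (linear kernel, C = 1) or `"ann"`
#'   (single-hidden-layer perceptron, 20 ReLU units).
#' @param baseline_window Pre-stimulus count window, ms.
#' @param response_window Post-stimulus count window `c(start, stop)`, ms.
#' @param train_frac Training fraction of windows.
#' @param n_perm Number of random train/test splits.
#' @param seed Integer seed.
#' @param shuffle_labels Permute class labels independently on every
#'   split (chance control; accuracy then concentrates at 50%).
#' @return Numeric vector of test accuracies (percent), length `n_perm`.
#' @export
decoding_accuracy <- function(spikes, classifier = c("svm", "ann"),
                              baseline_window = 50,
                              response_window = c(25, 75),
                              train_frac = 0.7, n_perm = 100, seed = 1,
                              shuffle_labels = FALSE) {
  classifier <- match.arg(classifier)
  stopifnot(inherits(spikes, "spike_data"))
  if (length(spikes$stim_times) == 0) stop("no stimulus times recorded")
  pyr <- which(spikes$pop == "pyr")
  sel <- spikes$neuron %in% pyr
  st_all <- spikes$time[sel]
  sn_all <- match(spikes$neuron[sel], pyr)
  count_window <- function(t0, t1) {
    idx <- st_all >= t0 & st_all < t1
    tabulate(sn_all[idx], nbins = length(pyr))
  }
  X <- rbind(
    t(vapply(spikes$stim_times,
             function(s) count_window(s - baseline_window, s),
             numeric(length(pyr)))),
    t(vapply(spikes$stim_times,
             function(s) count_window(s + response_window[1],
                                      s + response_window[2]),
             numeric(length(pyr))))
  )
  n_tr <- length(spikes$stim_times)
  y <- rep(c(0L, 1L), each = n_tr)
  y0 <- y
  with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      y <- if (shuffle_labels) sample(y0) else y0
      tr <- c(sample(which(y == 0), round(train_frac * n_tr)),
              sample(which(y == 1), round(train_frac * n_tr)))
      te <- setdiff(seq_along(y), tr)
      if (classifier == "svm") {
        # constant features break scaling; drop them
        keep <- apply(X[tr, , drop = FALSE], 2, function(v) stats::var(v) > 0)
        if (!any(keep)) return(50)
        fit <- e1071::svm(X[tr, keep, drop = FALSE], factor(y[tr]),
                          kernel = "linear", cost = 1, scale = FALSE)
        pred <- stats::predict(fit, X[te, keep, drop = FALSE])
      } else {
        fit <- mlp_fit(X[tr, , drop = FALSE], y[tr] + 1L, n_classes = 2,
                       hidden = 20, epochs = 50, seed = sample.int(1e6, 1))
        pred <- mlp_predict_class(fit, X[te, , drop = FALSE]) - 1L
      }
      100 * mean(as.integer(as.character(pred)) == y[te])
    }, numeric(1))
  })
}

#' Cohen's d effect size with pooled standard deviation
#'
#' Standardized mean difference `(mean(y) - mean(x)) / s_pooled`, with the
#' pooled standard deviation
#' `sqrt(((Nx - 1) sd(x)^2 + (Ny - 1) sd(y)^2) / (Nx + Ny - 2))`.
#' Sign convention: comparison minus reference, so `x` is the reference
#' group and a negative d means `y` is lower.
#'
#' @param x Reference sample (length >= 2).
#' @param y Comparison sample (length >= 2).
#' @return Cohen's d.
#' @examples
#' cohens_d(c(1, 2, 3), c(2, 3, 4)) # 1
#' @export
cohens_d <- function(x, y) {
  nx <- length(x); ny <- length(y)
  if (nx < 2 || ny < 2) stop("both samples need at least 2 values")
  sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) /
    (nx + ny - 2)
  if (sp2 == 0) {
    if (mean(y) == mean(x)) return(0)
    stop("zero pooled variance: Cohen's d undefined")
  }
  (mean(y) - mean(x)) / sqrt(sp2)
}

#' Compare conditions on one metric against a reference condition
#'
#' Independent two-sample equal-variance t-test plus Cohen's d for each
#' condition against the reference, flagging `|d| > 0.5` with `p < 0.05`
#' as a meaningful effect.
#'
#' @param results Data frame with a `condition` column and metric columns
#'   (e.g. the per-circuit table from [run_experiment()]).
#' @param metric Metric column name.
#' @param reference Reference condition (default `middle_age`).
#' @return Data frame: condition, group means, `t`, `p`, `d`,
#'   `significant`.
#' @export
compare_conditions <- function(results, metric, reference = "middle_age") {
  stopifnot(is.data.frame(results), "condition" %in% names(results))
  if (!metric %in% names(results)) stop("unknown metric: ", metric)
  ref <- results[[metric]][results$condition == reference]
  ref <- ref[is.finite(ref)]
  if (length(ref) < 2) stop("need >= 2 reference values for ", metric)
  conds <- setdiff(unique(results$condition), reference)
  out <- lapply(conds, function(cc) {
    y <- results[[metric]][results$condition == cc]
    y <- y[is.finite(y)]
    if (length(y) < 2) stop("need >= 2 values for condition ", cc)
    if (stats::var(ref) == 0 && stats::var(y) == 0) {
      tt <- list(statistic = if (mean(y) == mean(ref)) 0 else Inf, p.value = NaN)
      d <- if (mean(y) == mean(ref)) 0 else NaN
    } else {
      ht <- stats::t.test(y, ref, var.equal = TRUE)
      tt <- list(statistic = unname(ht$statistic), p.value = ht$p.value)
      d <- cohens_d(ref, y)
    }
    data.frame(condition = cc, reference_mean = mean(ref),
               condition_mean = mean(y), t = tt$statistic, p = tt$p.value,
               d = d,
               significant = is.finite(d) && abs(d) > 0.5 &&
                 !is.na(tt$p.value) && tt$p.value < 0.05)
  })
  do.call(rbind, out)
}
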