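#' Welch power spectral density
#'
#' Hann-windowed, 50%-overlap averaged periodogram with per-segment
#' constant detrend, one-sided density scaling. With the default 2 s
#' windows the frequency resolution is 0.5 Hz.
#'
#' @param trace An `eeg_trace`/`dipole_trace` (list with `x` and `fs`), or
#'   a numeric vector (then `fs` must be given).
#' @param window Segment length, seconds.
#' @param fs Sampling rate, Hz (taken from `trace` if present).
#'
#' @return An object of class `power_spectrum`: `freq` (Hz), `power`
#'   (signal units squared per Hz).
#' @examples
#' t <- seq(0, 10, by = 1 / 500)
#' ps <- welch_psd(sin(2 * pi * 10 * t), window = 2, fs = 500)
#' @export
welch_psd <- function(trace, window = 2, fs = NULL) {
  if (is.list(trace)) {
    x <- trace$x
    fs <- trace$fs
  } else {
    x <- trace
    if (is.null(fs)) stop("'fs' required for a bare numeric trace")
  }
  nseg <- round(window * fs)
  if (length(x) < nseg)
    stop("trace shorter than one Welch window (", window, " s)")
  step <- nseg %/% 2
  starts <- seq(1, length(x) - nseg + 1, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, nseg - 1) / nseg) # periodic Hann
  scale <- 1 / (fs * sum(w^2))
  nfreq <- nseg %/% 2 + 1
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- x[s:(s + nseg - 1)]
    seg <- (seg - mean(seg)) * w
    X <- stats::fft(seg)[seq_len(nfreq)]
    p <- scale * (Re(X)^2 + Im(X)^2)
    # one-sided doubling except DC and Nyquist
    p[2:(nfreq - if (nseg %% 2 == 0) 1 else 0)] <-
      2 * p[2:(nfreq - if (nseg %% 2 == 0) 1 else 0)]
    acc <- acc + p
  }
  structure(list(freq = (seq_len(nfreq) - 1) * fs / nseg,
                 power = acc / length(starts), fs = fs),
            class = "power_spectrum")
}

# aperiodic model in log10 power: offset - exponent * log10(f)
aperiodic_log10 <- function(freq, offset, exponent) offset - exponent * log10(freq)

gaussian_log10 <- function(freq, cf, height, sd) height * exp(-(freq - cf)^2 / (2 * sd^2))

# robust aperiodic fit: OLS, then refit on the points least affected by
# peaks (lowest-residual half), twice
robust_aperiodic <- function(freq, logp) {
  lx <- log10(freq)
  fit <- stats::lm.fit(cbind(1, -lx), logp)
  for (i in 1:2) {
    resid <- logp - cbind(1, -lx) %*% fit$coefficients
    keep <- resid <= stats::median(resid)
    fit <- stats::lm.fit(cbind(1, -lx[keep]), logp[keep])
  }
  c(offset = fit$coefficients[1], exponent = fit$coefficients[2])
}

fit_gaussians <- function(freq, flat, guesses, bw_limits) {
  npk <- nrow(guesses)
  sd_lo <- bw_limits[1] / 2
  sd_hi <- bw_limits[2] / 2
  par0 <- as.numeric(t(guesses)) # cf, height, sd per peak
  lower <- rep(c(min(freq), 0, sd_lo), npk)
  upper <- rep(c(max(freq), Inf, sd_hi), npk)
  obj <- function(par) {
    model <- numeric(length(freq))
    for (k in seq_len(npk)) {
      p <- par[(3 * k - 2):(3 * k)]
      model <- model + gaussian_log10(freq, p[1], p[2], p[3])
    }
    sum((flat - model)^2)
  }
  res <- stats::optim(par0, obj, method = "L-BFGS-B", lower = lower,
                      upper = upper)
  matrix(res$par, ncol = 3, byrow = TRUE,
         dimnames = list(NULL, c("cf", "height", "sd")))
}

#' Decompose a power spectrum into aperiodic and periodic components
#'
#' Iterative fit in log10-power space: (1) robust aperiodic (offset +
#' exponent) fit that down-weights peak regions, (2) detection of up to
#' `max_peaks` Gaussian peaks on the flattened spectrum, largest first,
#' accepted while the candidate exceeds `relative_threshold` times the SD
#' of the flattened spectrum and `min_height`, (3) joint Gaussian refit
#' with bandwidth clamped to `bw_limits`, (4) aperiodic refit on the
#' peak-subtracted spectrum.
#'
#' @param ps A [welch_psd()] `power_spectrum`.
#' @param freq_range Fit range, Hz (default 3-30).
#' @param max_peaks Maximum number of peaks.
#' @param bw_limits Peak bandwidth limits `[min, max]`, Hz (bandwidth =
#'   2 Gaussian SD).
#' @param relative_threshold Peak detection threshold in SD units of the
#'   flattened spectrum.
#' @param min_height Minimum peak height, log10 power units.
#'
#' @return An object of class `spectral_fit`: `offset` (log10 power),
#'   `exponent`, and `peaks`, a data frame (`cf` Hz, `amplitude` log10
#'   power above the aperiodic fit, `bandwidth` Hz) sorted by amplitude.
#' @examples
#' t <- seq(0, 30, by = 1 / 500)
#' ps <- welch_psd(stats::rnorm(length(t)), window = 2, fs = 500)
#' fit <- parameterize_spectrum(ps)
#' @export
parameterize_spectrum <- function(ps, freq_range = c(3, 30), max_peaks = 3,
                                  bw_limits = c(2, 6),
                                  relative_threshold = 2, min_height = 0) {
  stopifnot(inherits(ps, "power_spectrum"))
  sel <- ps$freq >= freq_range[1] & ps$freq <= freq_range[2]
  if (!any(sel)) stop("spectrum does not cover the fit range")
  freq <- ps$freq[sel]
  pw <- ps$power[sel]
  if (any(pw <= 0)) stop("non-positive power in the fit range")
  logp <- log10(pw)

  ap <- robust_aperiodic(freq, logp)
  flat <- logp - aperiodic_log10(freq, ap[1], ap[2])

  # iterative peak detection on the flattened spectrum
  guesses <- NULL
  resid <- flat
  for (k in seq_len(max_peaks)) {
    i <- which.max(resid)
    h <- resid[i]
    if (h < relative_threshold * stats::sd(resid) || h <= min_height) break
    cf <- freq[i]
    # half-height width estimate
    half <- h / 2
    li <- i; while (li > 1 && resid[li] > half) li <- li - 1
    ri <- i; while (ri < length(resid) && resid[ri] > half) ri <- ri + 1
    fwhm <- max(freq[ri] - freq[li], diff(freq)[1])
    sd0 <- min(max(fwhm / 2.355, bw_limits[1] / 2), bw_limits[2] / 2)
    guesses <- rbind(guesses, c(cf, h, sd0))
    resid <- resid - gaussian_log10(freq, cf, h, sd0)
  }

  peaks <- data.frame(cf = numeric(0), amplitude = numeric(0),
                      bandwidth = numeric(0))
  peak_model <- numeric(length(freq))
  if (!is.null(guesses)) {
    fitted <- fit_gaussians(freq, flat, as.data.frame(guesses), bw_limits)
    for (k in seq_len(nrow(fitted)))
      peak_model <- peak_model + gaussian_log10(freq, fitted[k, 1],
                                                fitted[k, 2], fitted[k, 3])
    peaks <- data.frame(cf = fitted[, 1], amplitude = fitted[, 2],
                        bandwidth = 2 * fitted[, 3])
  }

  # final aperiodic fit on the peak-subtracted spectrum
  lx <- log10(freq)
  fit <- stats::lm.fit(cbind(1, -lx), logp - peak_model)
  offset <- unname(fit$coefficients[1])
  exponent <- unname(fit$coefficients[2])

  # refit peaks against the final aperiodic component
  if (nrow(peaks) > 0) {
    flat2 <- logp - aperiodic_log10(freq, offset, exponent)
    fitted <- fit_gaussians(freq, flat2,
                            data.frame(cf = peaks$cf,
                                       height = peaks$amplitude,
                                       sd = peaks$bandwidth / 2), bw_limits)
    peaks <- data.frame(cf = fitted[, 1], amplitude = fitted[, 2],
                        bandwidth = 2 * fitted[, 3])
    # drop degenerate peaks fitted to zero height
    peaks <- peaks[peaks$amplitude > max(min_height, 1e-3), , drop = FALSE]
    peaks <- peaks[order(-peaks$amplitude), , drop = FALSE]
    rownames(peaks) <- NULL
  }

  structure(list(offset = offset, exponent = exponent, peaks = peaks,
                 freq_range = freq_range), class = "spectral_fit")
}

#' @export
print.spectral_fit <- function(x, ...) {
  cat(sprintf("Spectral fit (%g-%g Hz): offset %.3f, exponent %.3f, %d peak(s)\n",
              x$freq_range[1], x$freq_range[2], x$offset, x$exponent,
              nrow(x$peaks)))
  if (nrow(x$peaks)) print(round(x$peaks, 3))
  invisible(x)
}

#' Area under the power spectrum over a frequency band
#'
#' Trapezoidal integral of spectral power over `[low, high]`, with linear
#' interpolation at the band edges so adjacent bands add exactly.
#'
#' @param ps A `power_spectrum`.
#' @param band Numeric `c(low, high)`, Hz.
#' @return Band area (power units times Hz).
#' @examples
#' # theta-band area
#' @export
band_auc <- function(ps, band) {
  stopifnot(inherits(ps, "power_spectrum"), length(band) == 2)
  if (band[2] <= band[1]) stop("band must be increasing")
  if (band[1] < min(ps$freq) || band[2] > max(ps$freq))
    stop("band outside the spectrum")
  inside <- ps$freq > band[1] & ps$freq < band[2]
  f <- c(band[1], ps$freq[inside], band[2])
  p <- c(stats::approx(ps$freq, ps$power, band[1])$y,
         ps$power[inside],
         stats::approx(ps$freq, ps$power, band[2])$y)
  sum(diff(f) * (utils::head(p, -1) + utils::tail(p, -1)) / 2)
}

#' Area under the fitted aperiodic component (1/f AUC)
#'
#' Closed-form integral of `10^offset * f^(-exponent)` over the fit range;
#' the `exponent = 1` case uses the logarithmic antiderivative.
#'
#' @param fit A [parameterize_spectrum()] `spectral_fit`, or a list with
#'   `offset` and `exponent`.
#' @param freq_range Integration range, Hz.
#' @return Area under the aperiodic curve.
#' @export
aperiodic_auc <- function(fit, freq_range = c(3, 30)) {
  b <- fit$offset
  a <- fit$exponent
  f1 <- freq_range[1]; f2 <- freq_range[2]
  if (abs(a - 1) < 1e-12) return(10^b * log(f2 / f1))
  10^b * (f2^(1 - a) - f1^(1 - a)) / (1 - a)
}

# Morlet wavelet power spectrogram via FFT convolution.
# width = number of cycles; returns nf x nt power matrix.
morlet_power <- function(x, fs, freqs, width = 7) {
  n <- length(x)
  nfft <- stats::nextn(n, 2)
  X <- stats::fft(c(x, numeric(nfft - n)))
  om <- (seq_len(nfft) - 1) / nfft * fs
  om[om > fs / 2] <- om[om > fs / 2] - fs # signed frequency axis
  out <- matrix(0, length(freqs), n)
  for (i in seq_along(freqs)) {
    f0 <- freqs[i]
    sigma_f <- f0 / width
    H <- exp(-(om - f0)^2 / (2 * sigma_f^2)) # analytic Morlet in freq domain
    y <- stats::fft(X * H, inverse = TRUE) / nfft
    out[i, ] <- Mod(y[seq_len(n)])^2
  }
  out
}

# connected components of a logical matrix (4-neighborhood) via row runs
# and union-find; returns a data.frame of component bounding boxes
label_components <- function(mask, value) {
  nr <- nrow(mask)
  runs <- list() # per row: matrix with start, end, id
  parent <- integer(0)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  union <- function(a, b) {
    ra <- find(a); rb <- find(b)
    if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb)
  }
  next_id <- 0L
  for (r in seq_len(nr)) {
    v <- mask[r, ]
    rl <- rle(v)
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1L
    sel <- rl$values
    if (!any(sel)) { runs[[r]] <- NULL; next }
    st <- starts[sel]; en <- ends[sel]
    ids <- next_id + seq_along(st)
    next_id <- next_id + length(st)
    parent <- c(parent, ids)
    runs[[r]] <- cbind(start = st, end = en, id = ids)
    if (r > 1 && !is.null(runs[[r - 1]])) {
      prev <- runs[[r - 1]]
      i <- 1L; j <- 1L
      while (i <= nrow(prev) && j <= length(st)) {
        if (prev[i, "end"] < st[j]) i <- i + 1L
        else if (en[j] < prev[i, "start"]) j <- j + 1L
        else {
          union(prev[i, "id"], ids[j])
          if (prev[i, "end"] < en[j]) i <- i + 1L else j <- j + 1L
        }
      }
    }
  }
  if (next_id == 0L) return(NULL)
  # collect bounding boxes and peak values
  comp <- new.env()
  for (r in seq_len(nr)) {
    rr <- runs[[r]]
    if (is.null(rr)) next
    for (k in seq_len(nrow(rr))) {
      root <- as.character(find(rr[k, "id"]))
      seg <- value[r, rr[k, "start"]:rr[k, "end"]]
      pk <- max(seg)
      pt <- rr[k, "start"] + which.max(seg) - 1L
      if (is.null(comp[[root]])) {
        comp[[root]] <- list(r0 = r, r1 = r, c0 = rr[k, "start"],
                             c1 = rr[k, "end"], peak = pk, pr = r, pc = pt)
      } else {
        b <- comp[[root]]
        b$r0 <- min(b$r0, r); b$r1 <- max(b$r1, r)
        b$c0 <- min(b$c0, rr[k, "start"]); b$c1 <- max(b$c1, rr[k, "end"])
        if (pk > b$peak) { b$peak <- pk; b$pr <- r; b$pc <- pt }
        comp[[root]] <- b
      }
    }
  }
  boxes <- do.call(rbind, lapply(ls(comp), function(nm) {
    b <- comp[[nm]]
    data.frame(r0 = b$r0, r1 = b$r1, c0 = b$c0, c1 = b$c1,
               peak = b$peak, pr = b$pr, pc = b$pc)
  }))
  boxes
}

# merge bounding boxes whose fractional overlap (intersection over the
# smaller box) is >= thr; repeats until stable
merge_boxes <- function(boxes, thr) {
  repeat {
    n <- nrow(boxes)
    if (n <= 1) return(boxes)
    merged <- FALSE
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        rint <- min(boxes$r1[i], boxes$r1[j]) - max(boxes$r0[i], boxes$r0[j]) + 1
        cint <- min(boxes$c1[i], boxes$c1[j]) - max(boxes$c0[i], boxes$c0[j]) + 1
        if (rint <= 0 || cint <= 0) next
        a_i <- (boxes$r1[i] - boxes$r0[i] + 1) * (boxes$c1[i] - boxes$c0[i] + 1)
        a_j <- (boxes$r1[j] - boxes$r0[j] + 1) * (boxes$c1[j] - boxes$c0[j] + 1)
        if (rint * cint >= thr * min(a_i, a_j)) {
          boxes$r0[i] <- min(boxes$r0[i], boxes$r0[j])
          boxes$r1[i] <- max(boxes$r1[i], boxes$r1[j])
          boxes$c0[i] <- min(boxes$c0[i], boxes$c0[j])
          boxes$c1[i] <- max(boxes$c1[i], boxes$c1[j])
          if (boxes$peak[j] > boxes$peak[i]) {
            boxes$peak[i] <- boxes$peak[j]
            boxes$pr[i] <- boxes$pr[j]; boxes$pc[i] <- boxes$pc[j]
          }
          boxes <- boxes[-j, , drop = FALSE]
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
    if (!merged) return(boxes)
  }
}

EEG_BANDS <- list(theta = c(4, 8), alpha = c(8, 12), beta = c(12, 30))

#' Detect oscillation events in a trace via a Morlet spectrogram
#'
#' Computes a Morlet wavelet power spectrogram on a regular frequency grid,
#' normalizes each frequency row by its median power, and extracts
#' suprathreshold connected regions as candidate events. Bounding boxes
#' whose fractional overlap exceeds `box_overlap` are merged. Each event is
#' assigned a band (theta 4-8, alpha 8-12, beta 12-30 Hz) by its peak
#' frequency, and its wave height is the peak-to-trough amplitude of the
#' band-filtered signal inside the event window (4th-order zero-phase
#' Butterworth at the band edges).
#'
#' @param trace An `eeg_trace` (or list with `x`, `fs`).
#' @param median_threshold Event threshold in units of the per-frequency
#'   median power.
#' @param fmin,fmax,fstep Frequency grid, Hz.
#' @param box_overlap Fractional-overlap threshold for merging boxes.
#' @param wavelet_width Morlet width (cycles).
#' @param min_cycles Minimum event duration in cycles of its peak
#'   frequency.
#' @param peak_power_min Minimum median-normalized peak power of an event.
#'   Suprathreshold chance excursions in broadband noise rarely exceed
#'   15-20 times the per-frequency median, whereas genuine oscillation
#'   bursts carry far higher normalized power; together with `min_cycles`
#'   this keeps the false-positive rate on pure noise below about one
#'   event per analysis window.
#'
#' @return Data frame of class `oscillation_events`: `band`, `t_start`,
#'   `t_stop` (s), `f_low`, `f_high`, `peak_freq` (Hz), `peak_power`
#'   (median-normalized), `wave_height` (trace units).
#' @export
detect_events <- function(trace, median_threshold = 4.0, fmin = 1,
                          fmax = 100, fstep = 0.5, box_overlap = 0.5,
                          wavelet_width = 7, min_cycles = 6,
                          peak_power_min = 20) {
  x <- trace$x
  fs <- trace$fs
  if (length(x) == 0) stop("empty trace")
  x <- x - mean(x) # a constant trace has no oscillatory power
  fmax <- min(fmax, fs / 2 - fstep)
  freqs <- seq(fmin, fmax, by = fstep)
  pw <- morlet_power(x, fs, freqs, wavelet_width)
  med <- apply(pw, 1, stats::median)
  events <- data.frame(band = character(0), t_start = numeric(0),
                       t_stop = numeric(0), f_low = numeric(0),
                       f_high = numeric(0), peak_freq = numeric(0),
                       peak_power = numeric(0), wave_height = numeric(0))
  if (all(med <= 0)) {
    return(structure(events, class = c("oscillation_events", "data.frame")))
  }
  nm <- pw / pmax(med, .Machine$double.xmin)
  boxes <- label_components(nm >= median_threshold, nm)
  if (is.null(boxes) || nrow(boxes) == 0) {
    return(structure(events, class = c("oscillation_events", "data.frame")))
  }
  boxes <- merge_boxes(boxes, box_overlap)
  # screens: minimum duration in cycles and minimum normalized peak power
  dur <- (boxes$c1 - boxes$c0) / fs
  boxes <- boxes[dur * freqs[boxes$pr] >= min_cycles &
                   boxes$peak >= peak_power_min, , drop = FALSE]
  if (nrow(boxes) == 0) {
    return(structure(events, class = c("oscillation_events", "data.frame")))
  }

  out <- lapply(seq_len(nrow(boxes)), function(i) {
    b <- boxes[i, ]
    pf <- freqs[b$pr]
    band <- "other"
    for (nm_b in names(EEG_BANDS)) {
      bb <- EEG_BANDS[[nm_b]]
      if (pf >= bb[1] && pf < bb[2]) { band <- nm_b; break }
    }
    wh <- NA_real_
    if (band != "other") {
      bb <- EEG_BANDS[[band]]
      bf <- signal::butter(4, bb / (fs / 2), type = "pass")
      xf <- signal::filtfilt(bf, x)
      seg <- xf[b$c0:b$c1]
      wh <- max(seg) - min(seg)
    }
    data.frame(band = band, t_start = (b$c0 - 1) / fs, t_stop = (b$c1 - 1) / fs,
               f_low = freqs[b$r0], f_high = freqs[b$r1], peak_freq = pf,
               peak_power = b$peak, wave_height = wh)
  })
  events <- do.call(rbind, out)
  events <- events[order(events$t_start), ]
  rownames(events) <- NULL
  structure(events, class = c("oscillation_events", "data.frame"))
}

#' Extract the EEG feature vector used by the mechanism decoder
#'
#' Composes [welch_psd()], [parameterize_spectrum()] and
#' [aperiodic_auc()]: aperiodic offset and exponent, center frequency of
#' the maximum-amplitude periodic peak (`NA` when no peak is detected), and
#' the 1/f AUC over the fit range.
#'
#' @param trace An `eeg_trace`.
#' @param freq_range Spectral fit range, Hz.
#' @param window Welch window, s.
#' @return Named numeric vector `offset`, `exponent`, `peak_cf`,
#'   `aperiodic_auc`.
#' @export
extract_features <- function(trace, freq_range = c(3, 30), window = 2) {
  ps <- welch_psd(trace, window = window)
  fit <- parameterize_spectrum(ps, freq_range = freq_range)
  cf <- if (nrow(fit$peaks)) fit$peaks$cf[1] else NA_real_
  c(offset = fit$offset, exponent = fit$exponent, peak_cf = cf,
    aperiodic_auc = aperiodic_auc(fit, freq_range))
}
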