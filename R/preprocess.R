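#' Construct a stimulus-locked epoch set
#'
#' Container for one participant-condition's epochs: an array of
#' `epochs x channels x samples` in microvolts, spanning -500..1000 ms
#' around stimulus onset.
#'
#' @param data numeric array `epochs x channels x samples`.
#' @param channel_names character vector, unique, length = dim 2.
#' @param sampling_rate_hz sampling rate in Hz; the sample dimension
#'   must equal exactly 1.5 s times the rate.
#' @param condition task-condition label.
#' @param t_start_ms epoch start relative to stimulus onset (ms).
#' @param baseline_window_ms two-element window for baseline correction.
#' @return object of class `epoch_set`.
#' @export
epoch_set <- function(data, channel_names, sampling_rate_hz,
                      condition = NA_character_, t_start_ms = -500,
                      baseline_window_ms = c(-200, 0)) {
  if (length(dim(data)) != 3) stop("data must be epochs x channels x samples")
  if (anyDuplicated(channel_names)) stop("channel names must be unique")
  if (dim(data)[2] != length(channel_names))
    stop("channel dimension does not match channel_names")
  expected <- round(1.5 * sampling_rate_hz)
  if (dim(data)[3] != expected)
    stop("epoch length must be exactly 1.5 s x sampling rate (",
         expected, " samples), got ", dim(data)[3])
  structure(list(data = data, channel_names = channel_names,
                 sampling_rate_hz = sampling_rate_hz,
                 t_start_ms = t_start_ms,
                 baseline_window_ms = baseline_window_ms,
                 condition = condition),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<epoch_set> %s: %d epochs x %d channels x %d samples @ %g Hz\n",
    x$condition, d[1], d[2], d[3], x$sampling_rate_hz))
  invisible(x)
}

#' Sample times of an epoch set (ms relative to stimulus onset)
#' @param x an `epoch_set`.
#' @return numeric vector of times in ms.
#' @export
epoch_times <- function(x) {
  n <- dim(x$data)[3]
  x$t_start_ms + (seq_len(n) - 1) * 1000 / x$sampling_rate_hz
}

#' The five scalp regions and their representative electrodes
#'
#' frontal (Fz, F1, F2), fronto-central (FCz, FC1, FC2), central
#' (Cz, C1, C2), centro-parietal (CP1, CP2) and parietal (Pz, P3, P4) --
#' 14 electrodes in five regions.
#'
#' @return named list region -> character vector of electrode labels.
#' @export
region_map <- function() {
  list(frontal = c("Fz", "F1", "F2"),
       fronto_central = c("FCz", "FC1", "FC2"),
       central = c("Cz", "C1", "C2"),
       centro_parietal = c("CP1", "CP2"),
       parietal = c("Pz", "P3", "P4"))
}

#' The four IAT task-condition labels, in canonical order
#' @return character vector.
#' @export
iat_conditions <- function() {
  c("affective_compatible", "affective_incompatible",
    "instrumental_compatible", "instrumental_incompatible")
}

# Linear-phase FIR applied zero-phase by delay compensation with
# reflection padding. h must have odd length.
fir_apply <- function(x, h) {
  d <- (length(h) - 1) / 2
  n <- length(x)
  if (n < 3 * length(h))
    stop("signal shorter than 3x filter length (", 3 * length(h),
         " samples needed)")
  xp <- c(2 * x[1] - x[(d + 1):2], x, 2 * x[n] - x[(n - 1):(n - d)])
  y <- stats::filter(xp, h, method = "convolution", sides = 2)
  as.numeric(y[(d + 1):(d + n)])
}

# Hamming-windowed-sinc band-pass: difference of two ideal low-passes,
# so the half-amplitude (-6 dB) points sit exactly at the band edges
# (the frequency-sampled design of signal::fir1 places them elsewhere).
fir_design_bandpass <- function(rate, band = c(3, 40), transition = 1.5) {
  ntaps <- ceiling(3.3 * rate / transition)
  if (ntaps %% 2 == 0) ntaps <- ntaps + 1
  M <- ntaps - 1
  k <- 0:M - M / 2
  sinc <- function(fc) {
    h <- 2 * fc / rate * sin(pi * 2 * fc / rate * k) /
      (pi * 2 * fc / rate * k)
    h[k == 0] <- 2 * fc / rate
    h
  }
  w <- 0.54 - 0.46 * cos(2 * pi * (0:M) / M)
  h <- (sinc(band[2]) - sinc(band[1])) * w
  # unit gain at the geometric band center
  f0 <- sqrt(prod(band))
  h / abs(sum(h * exp(-2i * pi * f0 * (0:M) / rate)))
}

#' Zero-phase FIR band-pass filter
#'
#' Hamming-window FIR band-pass with half-amplitude (-6 dB) edges at
#' `band` (default 3--40 Hz), applied once with group-delay
#' compensation so the output is zero-phase at single-pass attenuation.
#' The default transition width of 1.5 Hz (narrow enough that the low
#' edge is undistorted by its negative-frequency image) gives stop-band
#' attenuation beyond 40 dB by 1.5 Hz below and 13 Hz above the band
#' edges.
#'
#' @param x numeric vector or `channels x samples` matrix (continuous
#'   recording, microvolts).
#' @param rate sampling rate, Hz; must exceed 80 Hz so the 40 Hz edge
#'   is below Nyquist.
#' @param band two-element band edges in Hz.
#' @param transition transition width in Hz (controls filter length,
#'   3.3 * rate / transition taps for the Hamming window).
#' @return filtered signal, same shape as `x`.
#' @export
bandpass_filter <- function(x, rate, band = c(3, 40), transition = 1.5) {
  if (rate <= 80) stop("sampling rate must exceed 80 Hz")
  h <- fir_design_bandpass(rate, band, transition)
  if (is.matrix(x)) t(apply(x, 1, fir_apply, h = h)) else fir_apply(x, h)
}

#' Downsample a continuous recording
#'
#' Integer decimation from `from_rate` to `to_rate` (default 500 Hz).
#' An anti-alias low-pass (cut-off 80% of the target Nyquist) is applied
#' before decimation unless `antialias = FALSE` (appropriate when the
#' signal is already band-limited below the target Nyquist, as
#' synthetically generated epochs are).
#'
#' @param x numeric vector or `channels x samples` matrix.
#' @param from_rate,to_rate rates in Hz; `from_rate` must be an integer
#'   multiple of `to_rate`.
#' @param antialias apply a protective low-pass before decimation?
#' @return downsampled signal.
#' @export
downsample <- function(x, from_rate, to_rate = 500, antialias = TRUE) {
  if (to_rate > from_rate) stop("to_rate must not exceed from_rate")
  if (from_rate %% to_rate != 0)
    stop("from_rate must be an integer multiple of to_rate")
  fac <- from_rate / to_rate
  if (fac == 1) return(x)
  if (antialias) {
    nyq <- to_rate / 2
    ntaps <- ceiling(3.3 * from_rate / (0.2 * nyq))
    if (ntaps %% 2 == 0) ntaps <- ntaps + 1
    h <- signal::fir1(ntaps - 1, 0.8 * nyq / (from_rate / 2), type = "low")
    h <- h / sum(h) # exact unit DC gain
    x <- if (is.matrix(x)) t(apply(x, 1, fir_apply, h = h)) else
      fir_apply(x, h)
  }
  idx <- seq(1, if (is.matrix(x)) ncol(x) else length(x), by = fac)
  if (is.matrix(x)) x[, idx, drop = FALSE] else x[idx]
}

#' Extract stimulus-locked epochs from a continuous recording
#'
#' Cuts -500..1000 ms windows around each stimulus-onset sample. Events
#' without at least 500 ms of pre-stimulus and 1000 ms of post-stimulus
#' context are skipped with a warning. Only events flagged in `keep`
#' (e.g. correct formal trials, from the trial-log join) are epoched.
#'
#' @param continuous `channels x samples` matrix.
#' @param events integer vector of stimulus-onset sample indices.
#' @param rate sampling rate, Hz.
#' @param channel_names channel labels (rownames of `continuous` used
#'   when missing).
#' @param keep logical vector parallel to `events`; default all.
#' @param condition condition label for the resulting epoch set.
#' @return an [epoch_set()].
#' @export
extract_epochs <- function(continuous, events, rate,
                           channel_names = rownames(continuous),
                           keep = rep(TRUE, length(events)),
                           condition = NA_character_) {
  pre <- round(0.5 * rate); post <- round(1.0 * rate)
  nsamp <- ncol(continuous)
  events <- events[keep]
  ok <- events - pre >= 1 & events + post - 1 <= nsamp
  if (any(!ok))
    warning(sum(!ok), " event(s) without full epoch context skipped")
  events <- events[ok]
  arr <- array(0, dim = c(length(events), nrow(continuous), pre + post))
  for (i in seq_along(events)) {
    sl <- (events[i] - pre):(events[i] + post - 1)
    arr[i, , ] <- continuous[, sl]
  }
  epoch_set(arr, channel_names, rate, condition = condition)
}

#' Baseline-correct epochs
#'
#' Subtracts, per epoch and channel, the mean over the baseline window
#' (default -200..0 ms before stimulus onset).
#'
#' @param epochs an [epoch_set()].
#' @return the epoch set with corrected data.
#' @export
baseline_correct <- function(epochs) {
  t <- epoch_times(epochs)
  w <- epochs$baseline_window_ms
  sel <- t >= w[1] & t < w[2]
  if (!any(sel)) stop("baseline window contains no samples")
  d <- epochs$data
  bl <- apply(d[, , sel, drop = FALSE], c(1, 2), mean)
  epochs$data <- d - array(bl, dim = dim(d))
  epochs
}

#' Reject epochs on an amplitude criterion
#'
#' Drops an epoch if any channel sample strictly exceeds `limit_uv`
#' microvolts in absolute value (an epoch peaking at exactly the limit
#' is kept).
#'
#' @param epochs a baseline-corrected [epoch_set()].
#' @param limit_uv rejection threshold, microvolts.
#' @return list with `kept` (epoch set) and `n_rejected`. When every
#'   epoch is rejected, `kept` carries attribute `excluded = TRUE`: the
#'   participant-condition must be excluded downstream.
#' @export
reject_epochs <- function(epochs, limit_uv = 100) {
  peak <- apply(abs(epochs$data), 1, max)
  keep <- peak <= limit_uv
  out <- epochs
  out$data <- epochs$data[keep, , , drop = FALSE]
  if (!any(keep)) attr(out, "excluded") <- TRUE
  list(kept = out, n_rejected = sum(!keep))
}

#' Preprocess an epoch-form recording
#'
#' Applies the fixed pipeline order to already-epoched data:
#' downsample -> (optional per-epoch band-pass) -> baseline correction
#' -> amplitude rejection. Synthetic epochs are generated band-limited
#' and referenced, so the band-pass and re-referencing steps are
#' pass-throughs by default; for real recordings, band-pass filter the
#' continuous signal with [bandpass_filter()] before epoching.
#'
#' @param epochs an [epoch_set()].
#' @param target_rate_hz target sampling rate (applied only when the
#'   input rate is an integer multiple of it).
#' @param reject_uv amplitude-rejection threshold in microvolts.
#' @return list with `kept` epoch set and `n_rejected`.
#' @export
preprocess_epochs <- function(epochs, target_rate_hz = 500,
                              reject_uv = 100) {
  if (epochs$sampling_rate_hz > target_rate_hz &&
      epochs$sampling_rate_hz %% target_rate_hz == 0) {
    fac <- epochs$sampling_rate_hz / target_rate_hz
    idx <- seq(1, dim(epochs$data)[3], by = fac)
    epochs$data <- epochs$data[, , idx, drop = FALSE]
    epochs$sampling_rate_hz <- target_rate_hz
  }
  epochs <- baseline_correct(epochs)
  reject_epochs(epochs, limit_uv = reject_uv)
}
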