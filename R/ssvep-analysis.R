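#' Multichannel EEG recording container
#'
#' @param data Channels x samples numeric matrix, microvolts.
#' @param fs Sampling rate in Hz.
#' @param labels Unique channel labels (length = rows of `data`).
#' @param events Tibble with at least `sample` (onset sample index) and
#'   `condition` columns; samples must lie within the recording.
#'
#' @return An object of class `vd_eeg`.
#' @export
eeg_recording <- function(data, fs, labels, events = tibble::tibble()) {
  if (!is.matrix(data)) abort("`data` must be a channels x samples matrix.")
  if (length(labels) != nrow(data)) abort("One label per channel required.")
  if (anyDuplicated(labels)) abort("Channel labels must be unique.")
  if (nrow(events) > 0) {
    if (!all(c("sample", "condition") %in% names(events))) {
      abort("`events` needs `sample` and `condition` columns.")
    }
    if (any(events$sample < 1 | events$sample > ncol(data))) {
      abort("Event samples must lie within the recording.")
    }
  }
  structure(list(data = data, fs = fs, labels = labels,
                 events = tibble::as_tibble(events)),
            class = "vd_eeg")
}

#' @exportS3Method base::print
print.vd_eeg <- function(x, ...) {
  cat(sprintf("<vd_eeg> %d channels x %d samples @ %g Hz (%.1f s), %d events\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs,
              nrow(x$events)))
  invisible(x)
}

# Zero-phase frequency-domain band-pass with raised-cosine transitions.
fft_bandpass <- function(x, fs, band, transition = c(0.05, 5)) {
  n <- length(x)
  f <- abs(fft_freqs(n)) * fs
  lo <- band[1]; hi <- band[2]
  tl <- transition[1]; th <- transition[2]
  g <- rep(1, n)
  below <- f < lo
  rampl <- f >= (lo - tl) & f < lo
  g[below] <- 0
  g[rampl] <- 0.5 * (1 - cos(pi * (f[rampl] - (lo - tl)) / tl))
  above <- f > (hi + th)
  ramph <- f > hi & f <= (hi + th)
  g[above] <- 0
  g[ramph] <- 0.5 * (1 + cos(pi * (f[ramph] - hi) / th))
  Re(fft(fft(x) * g, inverse = TRUE)) / n
}

# Fourier-domain resampling of a band-limited series to a new rate.
fft_resample <- function(x, fs_in, fs_out) {
  if (fs_in == fs_out) return(x)
  n <- length(x)
  m <- round(n * fs_out / fs_in)
  X <- fft(x)
  Y <- complex(m)
  half <- min(floor((n - 1) / 2), floor((m - 1) / 2))
  Y[1] <- X[1]
  if (half > 0) {
    Y[2:(half + 1)] <- X[2:(half + 1)]
    Y[(m - half + 1):m] <- X[(n - half + 1):n]
  }
  Re(fft(Y, inverse = TRUE)) / n
}

#' Preprocess an EEG recording
#'
#' Re-references every channel to the mean of the two mastoid channels,
#' applies a zero-phase band-pass (frequency-domain filter with
#' raised-cosine transition bands; stop-band gain is exactly zero), and
#' resamples to `fs_out`. Event sample indices are rescaled to the new
#' rate. Reference channels are retained in the output (they become the
#' negated common reference).
#'
#' @param rec A [eeg_recording()].
#' @param band Pass band in Hz, default `c(0.1, 40)`.
#' @param fs_out Output sampling rate, default 256 Hz.
#' @param reference Mastoid channel labels, default `c("M1", "M2")`.
#'
#' @return A preprocessed [eeg_recording()].
#' @export
preprocess <- function(rec, band = c(0.1, 40), fs_out = 256,
                       reference = c("M1", "M2")) {
  stopifnot(inherits(rec, "vd_eeg"))
  missing_ref <- setdiff(reference, rec$labels)
  if (length(missing_ref)) {
    abort(sprintf("Reference channel(s) %s not found. Available: %s",
                  paste(missing_ref, collapse = ", "),
                  paste(rec$labels, collapse = ", ")))
  }
  ref <- colMeans(rec$data[match(reference, rec$labels), , drop = FALSE])
  d <- sweep(rec$data, 2, ref, `-`)
  for (ch in seq_len(nrow(d))) {
    d[ch, ] <- fft_bandpass(d[ch, ], rec$fs, band)
  }
  if (fs_out != rec$fs) {
    m <- round(ncol(d) * fs_out / rec$fs)
    out <- matrix(0, nrow(d), m)
    for (ch in seq_len(nrow(d))) out[ch, ] <- fft_resample(d[ch, ], rec$fs, fs_out)
    d <- out
  }
  ev <- rec$events
  if (nrow(ev) > 0 && fs_out != rec$fs) {
    ev$sample <- pmax(1L, round((ev$sample - 1) * fs_out / rec$fs) + 1L)
  }
  eeg_recording(d, fs_out, rec$labels, ev)
}

#' Epoch a recording and reject artifact sub-epochs
#'
#' For each event (trial): subtract the mean of the 1 s pre-onset baseline
#' per channel, cut the `epoch_s`-second stimulation window into
#' `sub_epoch_s`-second sub-epochs, drop the first sub-epoch (transients),
#' and reject any sub-epoch whose absolute amplitude exceeds
#' `amp_thresh_uV` on any analyzed channel. Trials extending past the end
#' of the recording are skipped with a message.
#'
#' @param rec A preprocessed [eeg_recording()] with events.
#' @param epoch_s Stimulation epoch length (s).
#' @param baseline_s Baseline length before onset (s).
#' @param sub_epoch_s Sub-epoch length (s).
#' @param drop_first Drop the first sub-epoch of every trial.
#' @param amp_thresh_uV Absolute rejection threshold in microvolts.
#' @param channels Labels examined by the rejection rule (default: all).
#'
#' @return A tibble with one row per sub-epoch: `condition`, `trial`,
#'   `sub_epoch`, `kept` (logical) and list-column `data`
#'   (channels x samples matrix).
#' @export
epoch_and_reject <- function(rec, epoch_s = 20, baseline_s = 1,
                             sub_epoch_s = 2, drop_first = TRUE,
                             amp_thresh_uV = 500, channels = NULL) {
  stopifnot(inherits(rec, "vd_eeg"))
  if (nrow(rec$events) == 0) abort("Recording has no events to epoch.")
  fs <- rec$fs
  nb <- round(baseline_s * fs)
  ne <- round(epoch_s * fs)
  ns <- round(sub_epoch_s * fs)
  chan_idx <- if (is.null(channels)) seq_len(nrow(rec$data)) else {
    miss <- setdiff(channels, rec$labels)
    if (length(miss)) abort(paste0("Unknown channel(s): ", paste(miss, collapse = ", ")))
    match(channels, rec$labels)
  }
  ev <- rec$events
  if (!"trial" %in% names(ev)) ev$trial <- seq_len(nrow(ev))
  rows <- list()
  for (i in seq_len(nrow(ev))) {
    onset <- ev$sample[i]
    if (onset - nb < 1 || onset + ne - 1 > ncol(rec$data)) {
      message(sprintf("Trial %d (%s) extends past the recording; skipped.",
                      i, ev$condition[i]))
      next
    }
    base <- rowMeans(rec$data[, (onset - nb):(onset - 1), drop = FALSE])
    seg <- rec$data[, onset:(onset + ne - 1), drop = FALSE] - base
    n_sub <- ne %/% ns
    first <- if (drop_first) 2L else 1L
    for (s in seq(first, n_sub)) {
      sub <- seg[, ((s - 1) * ns + 1):(s * ns), drop = FALSE]
      bad <- any(abs(sub[chan_idx, , drop = FALSE]) > amp_thresh_uV)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        condition = ev$condition[i], trial = ev$trial[i], sub_epoch = s,
        kept = !bad, data = list(sub))
    }
  }
  if (!length(rows)) abort("No trial fit inside the recording.")
  out <- dplyr::bind_rows(rows)
  attr(out, "labels") <- rec$labels
  attr(out, "fs") <- fs
  out
}

#' Welch power spectral density over sub-epochs
#'
#' Averages per-segment periodograms over the supplied sub-epochs
#' (Welch's method with non-overlapping segments; each sub-epoch is one
#' segment). With 2 s segments at 256 Hz the frequency resolution is
#' exactly 0.5 Hz, so the 5 Hz fundamental and 10 Hz harmonic fall on
#' bins. The default rectangular taper makes an on-bin sinusoid
#' leakage-free; the one-sided density is normalized so that
#' `sum(psd) * df` equals the mean signal power (a tone of amplitude `a`
#' integrates to `a^2 / 2`).
#'
#' @param sub_epochs Output of [epoch_and_reject()] (kept rows are used),
#'   or a plain list of channels x samples matrices.
#' @param fs Sampling rate (taken from the epochs attribute if present).
#' @param window Taper: `"rectangular"` (default) or `"hann"`.
#' @param labels Channel labels (from the epochs attribute if present).
#'
#' @return A list of class `vd_psd`: `freq` (Hz), `psd` (channels x
#'   frequencies, uV^2/Hz), `labels`, `n_segments`, `df`.
#' @export
welch_psd <- function(sub_epochs, fs = NULL,
                      window = c("rectangular", "hann"), labels = NULL) {
  window <- match.arg(window)
  if (is.data.frame(sub_epochs)) {
    if (is.null(fs)) fs <- attr(sub_epochs, "fs")
    if (is.null(labels)) labels <- attr(sub_epochs, "labels")
    segs <- sub_epochs$data[sub_epochs$kept]
  } else {
    segs <- sub_epochs
  }
  if (!length(segs)) abort("No sub-epochs supplied (all rejected?).")
  if (is.null(fs)) abort("Sampling rate `fs` required.")
  n <- ncol(segs[[1]])
  nch <- nrow(segs[[1]])
  w <- if (window == "hann") 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / (n - 1))) else rep(1, n)
  U <- mean(w^2)
  nf <- n %/% 2 + 1
  acc <- matrix(0, nch, nf)
  for (seg in segs) {
    xw <- sweep(seg, 2, w, `*`)
    for (ch in seq_len(nch)) {
      X <- fft(xw[ch, ])[1:nf]
      p <- (Mod(X)^2) / (fs * n * U)
      p[2:(nf - 1)] <- 2 * p[2:(nf - 1)]   # one-sided
      acc[ch, ] <- acc[ch, ] + p
    }
  }
  psd <- acc / length(segs)
  structure(list(freq = (0:(nf - 1)) * fs / n, psd = psd,
                 labels = labels, n_segments = length(segs), df = fs / n),
            class = "vd_psd")
}

#' Extract SSVEP power at the fundamental and harmonic
#'
#' Averages the power spectral density over the posterior channels of
#' interest at the exact fundamental (5 Hz) and harmonic (10 Hz) bins.
#'
#' @param psd A [welch_psd()] result.
#' @param channels_of_interest Channel labels averaged over (default the
#'   nine posterior channels).
#' @param f0 Fundamental frequency in Hz.
#' @param harmonic Harmonic frequency in Hz.
#'
#' @return One-row tibble: `power_fundamental`, `power_harmonic`
#'   (uV^2/Hz), `n_channels`.
#' @export
extract_ssvep <- function(psd, channels_of_interest = posterior_channels(),
                          f0 = 5, harmonic = 10) {
  stopifnot(inherits(psd, "vd_psd"))
  if (is.null(psd$labels)) abort("PSD carries no channel labels.")
  miss <- setdiff(channels_of_interest, psd$labels)
  if (length(miss)) {
    abort(paste0("Channel(s) not present: ", paste(miss, collapse = ", ")))
  }
  bin_of <- function(f) {
    i <- which(abs(psd$freq - f) < psd$df / 1e6)
    if (length(i) != 1L) {
      abort(sprintf("%g Hz does not fall on the frequency grid (df = %g Hz).",
                    f, psd$df))
    }
    i
  }
  rows <- match(channels_of_interest, psd$labels)
  tibble::tibble(
    power_fundamental = mean(psd$psd[rows, bin_of(f0)]),
    power_harmonic = mean(psd$psd[rows, bin_of(harmonic)]),
    n_channels = length(rows))
}

#' Full SSVEP pipeline for a recording
#'
#' Preprocess, epoch with artifact rejection, Welch PSD per condition and
#' SSVEP extraction at the fundamental and harmonic, with per-condition
#' epoch bookkeeping.
#'
#' @param rec A raw [eeg_recording()] with events.
#' @inheritParams preprocess
#' @inheritParams epoch_and_reject
#' @inheritParams extract_ssvep
#'
#' @return Tibble with one row per condition: `condition`,
#'   `power_fundamental`, `power_harmonic`, `n_epochs_kept`,
#'   `n_epochs_rejected`.
#' @export
analyze_ssvep <- function(rec, band = c(0.1, 40), fs_out = 256,
                          reference = c("M1", "M2"), epoch_s = 20,
                          amp_thresh_uV = 500,
                          channels_of_interest = posterior_channels(),
                          f0 = 5, harmonic = 10) {
  pp <- preprocess(rec, band = band, fs_out = fs_out, reference = reference)
  ep <- epoch_and_reject(pp, epoch_s = epoch_s, amp_thresh_uV = amp_thresh_uV)
  labels <- attr(ep, "labels"); fs <- attr(ep, "fs")
  purrr::map_dfr(unique(ep$condition), function(cond) {
    sub <- ep[ep$condition == cond, ]
    kept <- sub[sub$kept, ]
    res <- if (nrow(kept)) {
      psd <- welch_psd(kept$data, fs = fs, labels = labels)
      extract_ssvep(psd, channels_of_interest, f0 = f0, harmonic = harmonic)
    } else {
      tibble::tibble(power_fundamental = NA_real_, power_harmonic = NA_real_,
                     n_channels = 0L)
    }
    tibble::tibble(condition = cond,
                   power_fundamental = res$power_fundamental,
                   power_harmonic = res$power_harmonic,
                   n_epochs_kept = sum(sub$kept),
                   n_epochs_rejected = sum(!sub$kept))
  })
}
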