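#' Ground truth for synthetic ratings and EEG
#'
#' Bundles the generative parameters used to simulate discomfort ratings
#' (a linear mixed model: fixed effects on standardized image statistics,
#' an observer random intercept, residual noise, mapped onto a 1-7 Likert
#' scale) and steady-state EEG (per-condition 5 Hz amplitudes plus a
#' harmonic and 1/f background noise).
#'
#' @param rating_coefficients Named numeric vector of fixed-effect
#'   coefficients; names must match predictor columns, which are z-scored
#'   before the linear predictor is formed.
#' @param rating_intercept Intercept on the 1-7 rating scale.
#' @param observer_sd SD of the observer random intercept (rating units).
#' @param residual_sd Residual SD (rating units).
#' @param ssvep_amplitude_map Named numeric vector mapping condition id to
#'   the 5 Hz amplitude in microvolts on posterior channels.
#' @param harmonic_ratio Amplitude of the 10 Hz harmonic relative to the
#'   fundamental.
#' @param noise_sd_uv RMS amplitude (microvolts) of the 1/f EEG background
#'   noise per channel.
#' @param seed Integer seed governing all randomness downstream.
#'
#' @return An object of class `vd_ground_truth`.
#' @export
synthetic_ground_truth <- function(rating_coefficients = c(total_response = 0.5),
                                   rating_intercept = 4,
                                   observer_sd = 0.3,
                                   residual_sd = 0.8,
                                   ssvep_amplitude_map = c(default = 2),
                                   harmonic_ratio = 0.3,
                                   noise_sd_uv = 1,
                                   seed = 1) {
  stopifnot(observer_sd >= 0, residual_sd >= 0, harmonic_ratio >= 0,
            noise_sd_uv >= 0)
  if (is.null(names(rating_coefficients))) {
    abort("`rating_coefficients` must be named after predictor columns.")
  }
  structure(
    list(rating_coefficients = rating_coefficients,
         rating_intercept = rating_intercept,
         observer_sd = observer_sd, residual_sd = residual_sd,
         ssvep_amplitude_map = ssvep_amplitude_map,
         harmonic_ratio = harmonic_ratio, noise_sd_uv = noise_sd_uv,
         seed = as.integer(seed)),
    class = "vd_ground_truth"
  )
}

#' Simulate discomfort ratings from known ground truth
#'
#' Draws per-observer, per-image ratings from the generative linear mixed
#' model in `truth`: predictors are z-scored, the linear predictor is
#' `intercept + X beta`, an observer random intercept `N(0, observer_sd^2)`
#' and residual noise `N(0, residual_sd^2)` are added, and (by default) the
#' result is rounded and clipped onto the 1-7 Likert scale. With
#' `likert = FALSE` the continuous latent rating is returned instead,
#' which preserves exact linear-model recovery in noise-free settings.
#'
#' @param stats_table Data frame with one row per image, an `id` column
#'   (or rownames) and the predictor columns named in
#'   `truth$rating_coefficients`.
#' @param truth A [synthetic_ground_truth()].
#' @param n_observers Number of observers (>= 2; the reference study
#'   analyzed 11).
#' @param likert Round and clip onto the 1-7 scale (default `TRUE`).
#'
#' @return A trial-table tibble with columns `observer`, `image_id`,
#'   `rating`, the (standardized) predictor columns, and any `category` /
#'   `spatial_frequency` columns carried over from `stats_table`.
#' @export
generate_synthetic_ratings <- function(stats_table, truth, n_observers = 11,
                                       likert = TRUE) {
  stopifnot(inherits(truth, "vd_ground_truth"))
  if (n_observers < 2) abort("`n_observers` must be at least 2.")
  preds <- names(truth$rating_coefficients)
  missing <- setdiff(preds, names(stats_table))
  if (length(missing)) {
    abort(paste0("Missing predictor columns: ", paste(missing, collapse = ", ")))
  }
  ids <- if ("id" %in% names(stats_table)) stats_table$id else
    sprintf("img_%03d", seq_len(nrow(stats_table)))

  X <- sapply(preds, function(p) {
    x <- stats_table[[p]]
    s <- sd(x)
    if (is.na(s) || s == 0) rep(0, length(x)) else (x - mean(x)) / s
  })
  X <- matrix(X, nrow = nrow(stats_table),
              dimnames = list(NULL, preds))
  eta <- truth$rating_intercept + drop(X %*% truth$rating_coefficients)

  carry <- intersect(c("category", "spatial_frequency"), names(stats_table))
  withr::with_seed(truth$seed, {
    b_obs <- rnorm(n_observers, 0, truth$observer_sd)
    out <- purrr::map_dfr(seq_len(n_observers), function(o) {
      eps <- rnorm(length(eta), 0, truth$residual_sd)
      r <- eta + b_obs[o] + eps
      if (likert) r <- pmin(pmax(round(r), 1), 7)
      tb <- tibble::tibble(observer = sprintf("obs_%02d", o),
                           image_id = ids, rating = r)
      tb <- dplyr::bind_cols(tb, tibble::as_tibble(X))
      if (length(carry)) tb <- dplyr::bind_cols(tb, stats_table[carry])
      tb
    })
    out
  })
}

# Master channel list: required analysis channels first (mastoid references,
# then the nine posterior channels of interest), then a 10-20 complement.
eeg_channel_names <- function(n_channels) {
  master <- c("M1", "M2", "Iz", "Oz", "O1", "O2", "POz", "PO3", "PO4",
              "PO7", "PO8", "Pz", "P3", "P4", "P7", "P8", "Cz", "C3",
              "C4", "T7", "T8", "Fz", "F3", "F4", "F7", "F8", "Fp1", "Fp2")
  if (n_channels < 11) {
    abort("`n_channels` must be >= 11 (two mastoids + nine posterior channels).")
  }
  if (n_channels <= length(master)) return(master[seq_len(n_channels)])
  c(master, sprintf("EX%02d", seq_len(n_channels - length(master))))
}

#' Posterior channels of interest for SSVEP extraction
#'
#' @return Character vector of the nine posterior channel labels over which
#'   SSVEP power is averaged.
#' @export
posterior_channels <- function() {
  c("Iz", "Oz", "O1", "O2", "POz", "PO3", "PO4", "PO7", "PO8")
}

#' Simulate a steady-state EEG recording
#'
#' Builds a multichannel recording containing, for each condition and
#' trial, a 1 s pre-onset baseline followed by a 20 s stimulation period in
#' which posterior channels carry a 5 Hz sinusoid (amplitude from
#' `truth$ssvep_amplitude_map`, in microvolts) plus a 10 Hz harmonic, on
#' top of seeded 1/f background noise on every channel. Optional artifact
#' epochs inject a +/-`artifact_uv` low-frequency transient into chosen 2 s
#' sub-epochs so that downstream amplitude rejection can be exercised.
#'
#' @param conditions Character vector of condition ids. Amplitudes are
#'   looked up by name in `truth$ssvep_amplitude_map`, falling back to its
#'   first element.
#' @param truth A [synthetic_ground_truth()].
#' @param n_channels Number of channels (>= 11); labels from a 10-20 subset
#'   with `M1`/`M2` mastoids and the nine posterior channels first.
#' @param fs_hz Sampling rate in Hz (>= 256).
#' @param epoch_s Stimulation epoch length in seconds (20 in the protocol).
#' @param n_trials Trials per condition.
#' @param artifact_epochs Optional data frame with columns `condition`,
#'   `trial`, `sub_epoch` (1-10) marking 2 s sub-epochs to contaminate.
#' @param artifact_uv Peak amplitude of the injected artifact.
#'
#' @return A [eeg_recording()] whose `events` table has one row per trial.
#' @export
generate_synthetic_eeg <- function(conditions, truth, n_channels = 13,
                                   fs_hz = 256, epoch_s = 20, n_trials = 1,
                                   artifact_epochs = NULL, artifact_uv = 600) {
  stopifnot(inherits(truth, "vd_ground_truth"))
  if (fs_hz < 256) abort("`fs_hz` must be at least 256.")
  labels <- eeg_channel_names(n_channels)
  post <- which(labels %in% posterior_channels())
  base_s <- 1.5                           # pre-onset span; baseline uses last 1 s
  gap <- round(0.5 * fs_hz)
  trial_len <- round((base_s + epoch_s) * fs_hz) + gap
  n_trial_rows <- length(conditions) * n_trials
  # pad the recording to a 5-smooth length so whole-record FFTs stay fast
  total <- next_smooth(trial_len * n_trial_rows + round(fs_hz))

  amp_of <- function(cond) {
    m <- truth$ssvep_amplitude_map
    if (cond %in% names(m)) unname(m[[cond]]) else unname(m[[1]])
  }

  withr::with_seed(truth$seed, {
    data <- matrix(0, length(labels), total)
    if (truth$noise_sd_uv > 0) {
      for (ch in seq_along(labels)) {
        data[ch, ] <- one_over_f_series(total, fs_hz) * truth$noise_sd_uv
      }
    }
    events <- vector("list", n_trial_rows)
    i <- 0L
    for (cond in conditions) {
      for (tr in seq_len(n_trials)) {
        i <- i + 1L
        onset <- (i - 1L) * trial_len + round(base_s * fs_hz) + 1L
        events[[i]] <- tibble::tibble(sample = onset, condition = cond,
                                      trial = tr)
        t <- (seq_len(round(epoch_s * fs_hz)) - 1) / fs_hz
        a <- amp_of(cond)
        sig <- a * sin(2 * pi * 5 * t) +
          a * truth$harmonic_ratio * sin(2 * pi * 10 * t)
        idx <- onset:(onset + length(t) - 1L)
        data[post, idx] <- sweep(data[post, idx, drop = FALSE], 2, sig, `+`)
        if (!is.null(artifact_epochs)) {
          hits <- artifact_epochs[artifact_epochs$condition == cond &
                                    artifact_epochs$trial == tr, , drop = FALSE]
          for (se in hits$sub_epoch) {
            s0 <- onset + round((se - 1) * 2 * fs_hz)
            tt <- (seq_len(round(0.5 * fs_hz)) - 1) / fs_hz
            pulse <- sin(2 * pi * 2 * tt) *
              sin(pi * tt / max(tt))^2     # in-band (2 Hz) windowed transient
            pulse <- artifact_uv * pulse / max(abs(pulse))
            j <- s0 + round(0.5 * fs_hz) + seq_along(pulse) - 1L
            scalp <- which(!labels %in% c("M1", "M2"))
            data[scalp, j] <- sweep(data[scalp, j, drop = FALSE], 2, pulse, `+`)
          }
        }
      }
    }
    eeg_recording(data, fs_hz, labels, dplyr::bind_rows(events))
  })
}

# Smallest integer >= n whose prime factors are all in {2, 3, 5}.
next_smooth <- function(n) {
  repeat {
    m <- n
    for (p in c(2, 3, 5)) while (m %% p == 0) m <- m / p
    if (m == 1) return(n)
    n <- n + 1
  }
}

# Seeded 1/f-amplitude noise series, unit RMS.
one_over_f_series <- function(n, fs) {
  x <- rnorm(n)
  ph <- fft(x)
  f <- abs(fft_freqs(n)) * fs
  a <- numeric(n)
  a[f > 0] <- 1 / f[f > 0]
  z <- Re(fft(ph / ifelse(Mod(ph) == 0, 1, Mod(ph)) * a, inverse = TRUE)) / n
  s <- sd(z)
  if (s == 0) z else z / s
}
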