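#' Sinusoidal grating stimulus
#'
#' Renders a sinusoidal luminance grating around mid-gray. Orientation 0
#' is a vertical grating, i.e. luminance modulated along the horizontal
#' axis. Michelson contrast equals `contrast` exactly (amplitude
#' `0.5 * contrast` about a 0.5 mean).
#'
#' @param frequency Spatial frequency in cycles per degree; must be below
#'   the Nyquist limit `ppd / 2`.
#' @param ppd Pixels per degree calibration.
#' @param size Image side in pixels (square image).
#' @param contrast Michelson contrast in `[0, 1]`.
#' @param orientation Grating orientation in degrees (0 = vertical bars).
#' @param phase Phase offset in degrees.
#'
#' @return A [vd_image()] with category `"grating"`.
#' @export
#' @examples
#' g <- make_grating(3, ppd = 30, size = 64)
#' range(g$pixels)
make_grating <- function(frequency, ppd, size = 512, contrast = 1,
                         orientation = 0, phase = 0) {
  stopifnot(length(frequency) == 1L, frequency > 0, size >= 2)
  if (contrast < 0 || contrast > 1) abort("`contrast` must be in [0, 1].")
  if (frequency >= ppd / 2) {
    abort(sprintf(
      "Calibration error: frequency %.4g c/deg is at or above the Nyquist limit %.4g c/deg (ppd = %.4g).",
      frequency, ppd / 2, ppd))
  }
  th <- orientation * pi / 180
  # column index = horizontal position; orientation 0 modulates along columns
  xs <- (seq_len(size) - 1) / ppd
  x <- matrix(xs, size, size, byrow = TRUE)
  y <- matrix(xs, size, size, byrow = FALSE)
  u <- cos(th) * x + sin(th) * y
  pix <- 0.5 + 0.5 * contrast * sin(2 * pi * frequency * u + phase * pi / 180)
  vd_image(pix, ppd, "grating",
           meta = list(frequency = frequency, contrast = contrast,
                       orientation = orientation, phase = phase))
}

#' Raised radial cosine filter gain
#'
#' Gain of the band-pass "bump" filter as a function of spatial frequency.
#' The filter is a raised cosine in log2 spatial frequency
#' `v = log2(f / f0)`: gain 1 for `|v| <= (1 - beta) / (2 T)`, a cosine
#' roll-off to 0 at `|v| = (1 + beta) / (2 T)`, and 0 beyond. Defaults
#' `T = 0.9`, `beta = 0.5`.
#'
#' @param f Spatial frequency (same units as `f0`); vectorized.
#' @param f0 Center (peak) frequency.
#' @param T_period Period parameter of the raised cosine (dimensionless).
#' @param beta Roll-off parameter in `(0, 1]`.
#'
#' @return Gain in `[0, 1]`, 0 at `f = 0`.
#' @export
#' @examples
#' raised_cosine_gain(3, f0 = 3)   # 1 at the pass-band center
raised_cosine_gain <- function(f, f0, T_period = 0.9, beta = 0.5) {
  stopifnot(f0 > 0, T_period > 0, beta > 0, beta <= 1)
  g <- numeric(length(f))
  pos <- f > 0
  v <- abs(log2(f[pos] / f0))
  flat <- (1 - beta) / (2 * T_period)
  edge <- (1 + beta) / (2 * T_period)
  gp <- numeric(sum(pos))
  gp[v <= flat] <- 1
  roll <- v > flat & v < edge
  gp[roll] <- 0.5 * (1 + cos(pi * T_period / beta * (v[roll] - flat)))
  g[pos] <- gp
  g
}

#' Band-pass "bump" noise stimulus
#'
#' White Gaussian noise filtered in the frequency domain by the raised
#' radial cosine [raised_cosine_gain()] centered (in log frequency) at
#' `f0`, then rescaled into `[0, 1]` around mid-gray. Deterministic for a
#' given `seed`.
#'
#' @param f0 Center frequency in cycles per degree.
#' @inheritParams make_grating
#' @param seed Integer seed for the underlying white-noise field.
#' @param T_period,beta Raised-cosine parameters (defaults 0.9 and 0.5).
#'
#' @return A [vd_image()] with category `"bump"`.
#' @export
make_bump_noise <- function(f0, ppd, size = 512, seed = 1,
                            T_period = 0.9, beta = 0.5) {
  stopifnot(f0 > 0, size >= 4)
  if (f0 >= ppd / 2) {
    abort(sprintf("Center frequency %.4g c/deg is at or above Nyquist (%.4g c/deg).",
                  f0, ppd / 2))
  }
  upper <- f0 * 2^((1 + beta) / (2 * T_period))
  if (upper > ppd / 2) {
    warn(sprintf(
      "Bump roll-off extends to %.3g c/deg, beyond Nyquist (%.3g c/deg); the filter is truncated.",
      upper, ppd / 2))
  }
  noise <- withr::with_seed(seed, matrix(rnorm(size * size), size, size))
  gain <- raised_cosine_gain(freq_grid_cpd(size, size, ppd), f0,
                             T_period = T_period, beta = beta)
  z <- Re(fft(fft(noise) * gain, inverse = TRUE)) / (size * size)
  vd_image(rescale_midgray(z), ppd, "bump",
           meta = list(f0 = f0, T_period = T_period, beta = beta, seed = seed))
}

#' Random-phase noise with a power-law amplitude spectrum
#'
#' Synthesizes a noise image whose Fourier amplitude spectrum is exactly
#' proportional to `f^k` (DC excluded), with phases taken from a seeded
#' white-noise field. `k = 0` gives white noise; `k` near -1 emulates the
#' amplitude-spectrum statistics typical of natural scenes. Used as the
#' natural-image surrogate and to validate the spectral-slope estimator.
#'
#' @param k Spectral exponent in `[-3, 1]`.
#' @inheritParams make_bump_noise
#'
#' @return A [vd_image()] with category `"onef_noise"`.
#' @export
make_onef_noise <- function(k, size = 512, seed = 1, ppd = default_ppd()) {
  stopifnot(size >= 4)
  if (k < -3 || k > 1) abort("`k` must lie in [-3, 1].")
  noise <- withr::with_seed(seed, matrix(rnorm(size * size), size, size))
  ph <- fft(noise)
  mod <- Mod(ph)
  mod[mod == 0] <- 1
  ph <- ph / mod                          # unit-modulus random phase, Hermitian
  f <- freq_grid_cpd(size, size, ppd = 1) # cycles/pixel; proportionality only
  amp <- matrix(0, size, size)
  amp[f > 0] <- f[f > 0]^k
  z <- Re(fft(ph * amp, inverse = TRUE)) / (size * size)
  vd_image(rescale_midgray(z), ppd, "onef_noise",
           meta = list(k = k, seed = seed))
}

#' High-contrast stripe texture (op-art surrogate)
#'
#' A full-contrast square-wave stripe pattern with an optional sinusoidal
#' curvature of the stripe boundaries. This is a synthetic surrogate for
#' high-contrast op-art imagery; it reproduces the class's statistics
#' (periodic, high RMS contrast, strongly anisotropic edges), not any
#' particular artwork.
#'
#' @inheritParams make_grating
#' @param wobble_amplitude_deg Amplitude of the sinusoidal displacement of
#'   stripe boundaries, in degrees of visual angle (0 = straight stripes).
#' @param wobble_frequency Spatial frequency of the displacement along the
#'   stripe axis, cycles per degree.
#'
#' @return A [vd_image()] with category `"stripe_texture"`.
#' @export
make_stripe_texture <- function(frequency, ppd, size = 512, contrast = 1,
                                orientation = 0,
                                wobble_amplitude_deg = 0,
                                wobble_frequency = 0.5) {
  if (frequency >= ppd / 2) {
    abort(sprintf("Calibration error: frequency %.4g c/deg is at or above Nyquist (%.4g c/deg).",
                  frequency, ppd / 2))
  }
  th <- orientation * pi / 180
  xs <- (seq_len(size) - 1) / ppd
  x <- matrix(xs, size, size, byrow = TRUE)
  y <- matrix(xs, size, size, byrow = FALSE)
  u <- cos(th) * x + sin(th) * y
  v <- -sin(th) * x + cos(th) * y
  u <- u + wobble_amplitude_deg * sin(2 * pi * wobble_frequency * v)
  pix <- 0.5 + 0.5 * contrast * sign(sin(2 * pi * frequency * u))
  vd_image(pix, ppd, "stripe_texture",
           meta = list(frequency = frequency, contrast = contrast,
                       wobble_amplitude_deg = wobble_amplitude_deg))
}

#' Gaussian-edged aperture
#'
#' Attenuates contrast (deviation from mid-gray) outside a flat circular
#' region: pixels within `flat_radius_px` of the image center are
#' unchanged; beyond it the deviation from 0.5 is multiplied by a Gaussian
#' of the radial distance past the flat region, so the far field tends to
#' uniform mid-gray. Defaults follow the 150-px flat radius and 10-px
#' sigma used for a ~7.3 deg viewable aperture at 44 ppd.
#'
#' @param img A [vd_image()].
#' @param flat_radius_px Radius of the untouched flat region, pixels.
#' @param sigma_px Standard deviation of the Gaussian edge, pixels.
#'
#' @return A windowed [vd_image()].
#' @export
apply_gaussian_window <- function(img, flat_radius_px = 150, sigma_px = 10) {
  stopifnot(inherits(img, "vd_image"), flat_radius_px >= 0, sigma_px > 0)
  nr <- nrow(img$pixels); nc <- ncol(img$pixels)
  if (2 * flat_radius_px > min(nr, nc)) {
    abort("Flat radius larger than the image; the window must fit inside.")
  }
  cy <- (nr + 1) / 2; cx <- (nc + 1) / 2
  r <- sqrt(outer((seq_len(nr) - cy)^2, (seq_len(nc) - cx)^2, `+`))
  w <- ifelse(r <= flat_radius_px, 1,
              exp(-((r - flat_radius_px)^2) / (2 * sigma_px^2)))
  out <- 0.5 + (img$pixels - 0.5) * w
  vd_image(out, img$ppd, img$category,
           meta = c(img$meta, list(window_flat_px = flat_radius_px,
                                   window_sigma_px = sigma_px)))
}

#' Temporal contrast envelope for flickering presentation
#'
#' Raised-sinusoid contrast multipliers for a stimulus that grows in
#' contrast and fades back to mid-gray at `rate_hz`. The envelope starts at
#' 0 (uniform mid-gray), stays within `[0, 1]`, and leaves the space-mean
#' luminance of a mid-gray-balanced stimulus constant over time.
#'
#' @param rate_hz Modulation rate in Hz (5 Hz in the reference protocol).
#' @param duration_s Duration in seconds.
#' @param frame_rate_hz Display frame rate in Hz; must exceed `2 * rate_hz`.
#'
#' @return Numeric vector of per-frame contrast multipliers.
#' @export
#' @examples
#' env <- temporal_contrast_envelope(5, 20, 60)
#' length(env)  # 1200 frames, 100 cycles
temporal_contrast_envelope <- function(rate_hz = 5, duration_s = 20,
                                       frame_rate_hz = 60) {
  stopifnot(rate_hz > 0, duration_s > 0)
  if (frame_rate_hz <= 2 * rate_hz) {
    abort("`frame_rate_hz` must exceed twice the modulation rate.")
  }
  t <- seq_len(round(duration_s * frame_rate_hz)) - 1
  0.5 * (1 - cos(2 * pi * rate_hz * t / frame_rate_hz))
}

#' Standard stimulus batteries
#'
#' Generates the model battery (bumps and gratings at center frequencies
#' 0.1875, 0.375, 0.75, 1.5, 3, 6 and 12 c/deg) or the shorter EEG battery
#' (0.75, 1.5, 3, 6 and 9 c/deg), plus the requested number of 1/f noise
#' natural-image surrogates.
#'
#' @param battery `"model"` or `"eeg"`.
#' @param ppd,size Calibration and image side in pixels.
#' @param n_natural Number of 1/f natural-image surrogates to include.
#' @param natural_k Spectral exponents recycled across the surrogates.
#' @param seed Master seed; per-image seeds are derived from it.
#'
#' @return A tibble with columns `id`, `category`, `frequency`, `seed` and a
#'   list-column `image` of [vd_image()] objects.
#' @export
stimulus_battery <- function(battery = c("model", "eeg"), ppd = default_ppd(),
                             size = 512, n_natural = 0, natural_k = -1,
                             seed = 1) {
  battery <- match.arg(battery)
  freqs <- switch(battery,
                  model = c(0.1875, 0.375, 0.75, 1.5, 3, 6, 12),
                  eeg   = c(0.75, 1.5, 3, 6, 9))
  rows <- list()
  i <- 0L
  for (f in freqs) {
    i <- i + 1L
    rows[[length(rows) + 1L]] <- tibble::tibble(
      id = sprintf("bump_%03.4g", f), category = "bump", frequency = f,
      seed = seed * 100L + i,
      image = list(make_bump_noise(f, ppd = ppd, size = size,
                                   seed = seed * 100L + i)))
  }
  for (f in freqs) {
    rows[[length(rows) + 1L]] <- tibble::tibble(
      id = sprintf("grating_%03.4g", f), category = "grating", frequency = f,
      seed = NA_integer_,
      image = list(make_grating(f, ppd = ppd, size = size)))
  }
  if (n_natural > 0) {
    ks <- rep_len(natural_k, n_natural)
    for (j in seq_len(n_natural)) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        id = sprintf("natural_%02d", j), category = "onef_noise",
        frequency = NA_real_, seed = seed * 1000L + j,
        image = list(make_onef_noise(ks[j], size = size,
                                     seed = seed * 1000L + j, ppd = ppd)))
    }
  }
  dplyr::bind_rows(rows)
}
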