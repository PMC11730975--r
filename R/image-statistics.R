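#' Rotationally averaged Fourier amplitude spectrum
#'
#' Mean Fourier amplitude in integer radial-frequency annuli (cycles per
#' image), with the frequency axis returned in cycles per degree through
#' the image's calibration. DC is excluded; annuli extend to just below
#' Nyquist.
#'
#' @param img A [vd_image()].
#' @return Tibble with columns `freq_cpd`, `freq_cpi` (cycles/image) and
#'   `amplitude`.
#' @export
radial_amplitude_spectrum <- function(img) {
  px <- img$pixels
  n1 <- nrow(px); n2 <- ncol(px)
  amp <- Mod(fft(px - mean(px)))
  # radius in cycles/image of the square-equivalent grid
  fx <- fft_freqs(n2) * n2
  fy <- fft_freqs(n1) * n1
  r <- sqrt(outer(fy^2, fx^2, `+`))
  rb <- round(r)
  kmax <- floor(min(n1, n2) / 2) - 1L
  keep <- rb >= 1 & rb <= kmax
  m <- tapply(amp[keep], rb[keep], mean)
  k <- as.numeric(names(m))
  tibble::tibble(freq_cpd = k / (min(n1, n2) / img$ppd),
                 freq_cpi = k, amplitude = as.numeric(m))
}

#' Fourier spectral slope of an image
#'
#' Fits a first-order polynomial to log amplitude against log spatial
#' frequency over the rotationally averaged amplitude spectrum (DC and
#' Nyquist excluded). The slope `k` of the `A ~ f^k` relationship is about
#' -1 for natural scenes. Periodic one-dimensional stimuli (gratings,
#' stripe patterns) have no meaningful slope: they are detected through
#' the power-weighted orientation coherence of the windowed spectrum (the
#' resultant length of doubled spectral angles, 1 for a perfect grating,
#' near 0 for isotropic noise) and flagged invalid above
#' `coherence_limit`.
#'
#' @param img A [vd_image()].
#' @param coherence_limit Orientation-coherence value above which the
#'   image is treated as periodic and the slope flagged invalid.
#' @return A list: `k` (slope, `NA` when invalid), `valid` (logical),
#'   `coherence` (the periodicity statistic), `fit` (the `lm` object or
#'   `NULL`).
#' @export
#' @examples
#' spectral_slope(make_onef_noise(-1, size = 128, seed = 1))$k
spectral_slope <- function(img, coherence_limit = 0.5) {
  px <- img$pixels
  if (max(px) - min(px) < 1e-12) {
    return(list(k = NA_real_, valid = FALSE, coherence = NA_real_, fit = NULL))
  }
  coh <- orientation_coherence(px)
  rad <- radial_amplitude_spectrum(img)
  rad <- rad[rad$amplitude > 0, ]
  fit <- lm(log(amplitude) ~ log(freq_cpi), data = rad)
  k <- unname(coef(fit)[2])
  if (coh > coherence_limit) {
    return(list(k = NA_real_, valid = FALSE, coherence = coh, fit = fit))
  }
  list(k = k, valid = TRUE, coherence = coh, fit = fit)
}

# Power-weighted orientation coherence of the Hann-windowed spectrum:
# |sum p exp(2i theta)| / sum p over non-DC coefficients (axial resultant).
orientation_coherence <- function(px) {
  n1 <- nrow(px); n2 <- ncol(px)
  w1 <- 0.5 * (1 - cos(2 * pi * (0:(n1 - 1)) / (n1 - 1)))
  w2 <- 0.5 * (1 - cos(2 * pi * (0:(n2 - 1)) / (n2 - 1)))
  a2 <- Mod(fft((px - mean(px)) * outer(w1, w2)))^2
  FX <- matrix(fft_freqs(n2), n1, n2, byrow = TRUE)
  FY <- matrix(fft_freqs(n1), n1, n2, byrow = FALSE)
  keep <- !(FX == 0 & FY == 0)
  s <- sum(a2[keep])
  if (s == 0) return(0)
  Mod(sum(a2[keep] * exp(2i * atan2(FY, FX)[keep]))) / s
}

#' Box-counting fractal dimension
#'
#' Posterizes the image (rescaled to 0-255; values >= 128 are foreground),
#' zero-pads to the smallest power of two not smaller than the longest
#' side, counts occupied boxes at every power-of-two box size, and
#' estimates the dimension from the local slopes
#' `(log n(r_{i+1}) - log n(r_i)) / (log r_{i+1} - log r_i)`. The estimate
#' is minus the mean local slope over the longest plateau of at least
#' `min_run` consecutive slopes agreeing within `plateau_tol`; when no such
#' plateau exists a global log-log fit is used and flagged.
#'
#' @param img A [vd_image()] (or a plain 0/1 matrix).
#' @param threshold Posterization cut-off on the 0-255 scale (128 = half
#'   the maximum).
#' @param plateau_tol Maximum spread of local slopes within a plateau.
#' @param min_run Minimum plateau length.
#' @return A list: `D`, `valid`, `method` (`"plateau"` or `"global_fit"`),
#'   `curve` (tibble of `box_size_r`, `count_n`, `local_slope`) and
#'   `padded_size`.
#' @export
fractal_dimension <- function(img, threshold = 128, plateau_tol = 0.1,
                              min_run = 3) {
  px <- if (inherits(img, "vd_image")) img$pixels else img
  fg <- round(px * 255) >= threshold
  if (!any(fg)) {
    return(list(D = NA_real_, valid = FALSE, method = "empty",
                curve = tibble::tibble(), padded_size = NA_integer_))
  }
  x <- ceiling(log2(max(dim(fg))))
  N <- 2^x
  pad <- matrix(FALSE, N, N)
  pad[seq_len(nrow(fg)), seq_len(ncol(fg))] <- fg

  sizes <- 2^(0:x)
  counts <- integer(length(sizes))
  occ <- pad
  counts[1] <- sum(occ)
  for (i in seq_along(sizes)[-1]) {
    m <- nrow(occ)
    occ <- occ[seq(1, m, by = 2), , drop = FALSE] |
      occ[seq(2, m, by = 2), , drop = FALSE]
    occ <- occ[, seq(1, m, by = 2), drop = FALSE] |
      occ[, seq(2, m, by = 2), drop = FALSE]
    counts[i] <- sum(occ)
  }

  ls <- diff(log(counts)) / diff(log(sizes))
  # slopes where the count still resolves structure (start count > 1)
  usable <- which(counts[-length(counts)] > 1)
  slopes <- ls[usable]

  run <- longest_plateau(slopes, plateau_tol, min_run)
  if (!is.null(run)) {
    D <- -mean(slopes[run])
    method <- "plateau"
  } else {
    fit <- lm(log(counts) ~ log(sizes),
              data = list(counts = counts[counts > 0], sizes = sizes[counts > 0]))
    D <- -unname(coef(fit)[2])
    method <- "global_fit"
  }
  curve <- tibble::tibble(box_size_r = sizes, count_n = counts,
                          local_slope = c(ls, NA_real_))
  list(D = D, valid = TRUE, method = method, curve = curve, padded_size = N)
}

# Longest run of >= min_run consecutive values whose spread is <= tol.
longest_plateau <- function(x, tol, min_run) {
  n <- length(x)
  if (n < min_run) return(NULL)
  best <- NULL
  for (i in seq_len(n - min_run + 1)) {
    for (j in seq(i + min_run - 1, n)) {
      w <- x[i:j]
      if (max(w) - min(w) <= tol) {
        if (is.null(best) || length(i:j) > length(best)) best <- i:j
      } else break
    }
  }
  best
}

#' Mannos-Sakrison contrast sensitivity function
#'
#' `A(f) = 2.6 (0.0192 + 0.114 f) exp(-(0.114 f)^1.1)` with `f` in cycles
#' per degree; gain is set to zero above `cutoff_cpd`.
#'
#' @param f Spatial frequency in cycles per degree (vectorized).
#' @param cutoff_cpd Hard cut-off frequency (default 60 c/deg).
#' @return Sensitivity values.
#' @export
csf_mannos_sakrison <- function(f, cutoff_cpd = 60) {
  a <- 2.6 * (0.0192 + 0.114 * f) * exp(-(0.114 * f)^1.1)
  a[f > cutoff_cpd] <- 0
  a
}

#' CSF-filtered ("effective") contrast
#'
#' Weights the image's contrast spectrum by the Mannos-Sakrison contrast
#' sensitivity function (zero above 60 c/deg and at DC) and returns the
#' RMS contrast of the filtered contrast image. This is the "effective"
#' contrast as seen through a standard human contrast sensitivity profile.
#'
#' @param img A [vd_image()] (calibration `ppd` required).
#' @param cutoff_cpd Frequency cut-off in cycles per degree.
#' @return Nonnegative scalar.
#' @export
csf_filter_contrast <- function(img, cutoff_cpd = 60) {
  if (is.null(img$ppd) || !is.finite(img$ppd)) abort("`ppd` calibration missing.")
  mu <- mean(img$pixels)
  if (mu == 0 || max(img$pixels) - min(img$pixels) < 1e-15) return(0)
  con <- (img$pixels - mu) / mu
  gain <- csf_mannos_sakrison(
    freq_grid_cpd(nrow(con), ncol(con), img$ppd), cutoff_cpd)
  gain[1, 1] <- 0
  z <- Re(fft(fft(con) * gain, inverse = TRUE)) / length(con)
  sqrt(mean((z - mean(z))^2))
}

#' RMS contrast
#'
#' Standard deviation of pixel luminance divided by the mean luminance
#' (population SD; a full-contrast sinusoid about mid-gray gives
#' `1/sqrt(2)`).
#'
#' @param img A [vd_image()].
#' @return Nonnegative scalar.
#' @export
rms_contrast <- function(img) {
  mu <- mean(img$pixels)
  if (mu == 0) return(0)
  sqrt(mean((img$pixels - mu)^2)) / mu
}

#' Compute the full set of per-image statistics
#'
#' Runs the spectral slope, box-counting fractal dimension, RMS and
#' CSF-filtered contrast, and first/second-order edge-orientation entropy
#' on one image, collecting validity flags instead of aborting: a periodic
#' image yields an invalid slope but valid contrast and entropy fields.
#'
#' @param img A [vd_image()].
#' @param id Image identifier for the output row.
#' @param edge_config An [edge_extraction_config()].
#' @return One-row tibble: `id`, `category`, `slope_k`, `slope_valid`,
#'   `fractal_D`, `fractal_valid`, `rms_contrast`, `csf_contrast`,
#'   `entropy_first`, `entropy_second`, `flags` (semicolon-joined string,
#'   empty when fully valid).
#' @export
compute_image_stats <- function(img, id = "img", edge_config = edge_extraction_config()) {
  sl <- spectral_slope(img)
  fd <- fractal_dimension(img)
  flags <- character(0)
  if (!sl$valid) flags <- c(flags, "slope_invalid")
  if (!fd$valid) flags <- c(flags, "fractal_invalid")
  if (identical(fd$method, "global_fit")) flags <- c(flags, "fractal_global_fit")
  ent <- tryCatch({
    ed <- extract_edges(img, edge_config)
    edge_orientation_entropy(ed, edge_config)
  }, error = function(e) {
    flags <<- c(flags, "entropy_failed")
    list(entropy_first = NA_real_, entropy_second = NA_real_)
  })
  tibble::tibble(
    id = id, category = img$category,
    slope_k = sl$k, slope_valid = sl$valid,
    fractal_D = fd$D, fractal_valid = fd$valid,
    rms_contrast = rms_contrast(img),
    csf_contrast = csf_filter_contrast(img),
    entropy_first = ent$entropy_first,
    entropy_second = ent$entropy_second,
    flags = paste(flags, collapse = ";"))
}

#' Batch image statistics
#'
#' @param images List of [vd_image()] objects.
#' @param ids Image ids (default names or index).
#' @param edge_config An [edge_extraction_config()].
#' @return Tibble with one row per image (see [compute_image_stats()]).
#' @export
compute_image_stats_batch <- function(images, ids = NULL,
                                      edge_config = edge_extraction_config()) {
  if (is.null(ids)) {
    ids <- names(images)
    if (is.null(ids)) ids <- sprintf("img_%03d", seq_along(images))
  }
  purrr::map2_dfr(images, ids, compute_image_stats, edge_config = edge_config)
}
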