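#' Default tuning distributions for the model population
#'
#' Parametric approximations to physiologically reported distributions of
#' V1 tuning properties: a log-normal peak spatial frequency (truncated to
#' `freq_range`), a cardinal-biased orientation mixture (excess mass near
#' 0 and 90 degrees), a phase distribution bimodal at 0/180 degrees, a
#' truncated-normal spatial-frequency bandwidth in octaves, and a uniform
#' 16-17 degree orientation bandwidth. All parameters can be overridden.
#'
#' @return Named list of distribution parameters.
#' @export
default_distribution_params <- function() {
  list(
    freq_meanlog = log(2.2), freq_sdlog = 0.65, freq_range = c(0.5, 16),
    ori_weights = c(cardinal0 = 0.35, cardinal90 = 0.35, uniform = 0.30),
    ori_sd = 15,
    phase_sd = 25,
    sfbw_mean = 1.45, sfbw_sd = 0.3, sfbw_range = c(0.8, 2.6),
    oribw_range = c(16, 17)
  )
}

#' Sample a population of model V1 cells
#'
#' Draws `n` cells (default 500) with peak spatial frequency, orientation,
#' phase, spatial-frequency bandwidth and orientation bandwidth from the
#' distributions in `distribution_params`. Resampling with the same seed
#' reproduces the population exactly.
#'
#' @param n Number of cells.
#' @param seed Integer sampling seed.
#' @param distribution_params List as from [default_distribution_params()];
#'   partial overrides are merged over the defaults.
#'
#' @return A tibble of class `vd_population` with one row per cell:
#'   `cell`, `peak_frequency` (c/deg), `orientation` (deg in `[0, 180)`),
#'   `phase` (deg in `[0, 360)`), `sf_bandwidth` (octaves),
#'   `ori_bandwidth` (deg, half-width at half height).
#' @export
#' @examples
#' pop <- sample_population(50, seed = 1)
#' range(pop$ori_bandwidth)
sample_population <- function(n = 500, seed = 1,
                              distribution_params = list()) {
  stopifnot(n >= 1)
  p <- utils::modifyList(default_distribution_params(), distribution_params)
  if (p$freq_range[1] <= 0 || diff(p$freq_range) <= 0) {
    abort("`freq_range` must be an increasing positive pair.")
  }
  if (any(p$ori_weights < 0) || sum(p$ori_weights) <= 0) {
    abort("`ori_weights` must be nonnegative with positive sum.")
  }
  w <- p$ori_weights / sum(p$ori_weights)

  withr::with_seed(seed, {
    # truncated log-normal by inverse-CDF
    lo <- plnorm(p$freq_range[1], p$freq_meanlog, p$freq_sdlog)
    hi <- plnorm(p$freq_range[2], p$freq_meanlog, p$freq_sdlog)
    pf <- qlnorm(runif(n, lo, hi), p$freq_meanlog, p$freq_sdlog)

    comp <- sample(c(0, 90, NA), n, replace = TRUE, prob = w)
    ori <- ifelse(is.na(comp), runif(n, 0, 180),
                  rnorm(n, mean = ifelse(is.na(comp), 0, comp), sd = p$ori_sd))
    ori <- ori %% 180

    ph <- rnorm(n, mean = sample(c(0, 180), n, replace = TRUE),
                sd = p$phase_sd) %% 360

    sfbw <- pmin(pmax(rnorm(n, p$sfbw_mean, p$sfbw_sd),
                      p$sfbw_range[1]), p$sfbw_range[2])
    oribw <- runif(n, p$oribw_range[1], p$oribw_range[2])

    out <- tibble::tibble(
      cell = seq_len(n), peak_frequency = pf, orientation = ori,
      phase = ph, sf_bandwidth = sfbw, ori_bandwidth = oribw)
    attr(out, "sampling_seed") <- as.integer(seed)
    attr(out, "distribution_params") <- p
    class(out) <- c("vd_population", class(out))
    out
  })
}

#' Orientation mixture density of the default population
#'
#' Density over `[0, 180)` degrees of the cardinal-biased orientation
#' mixture used by [sample_population()], with normal components wrapped
#' onto the half-circle. Used by distributional tests as the reference.
#'
#' @param x Orientations in degrees.
#' @param distribution_params Parameter overrides as in
#'   [sample_population()].
#' @return Density values.
#' @export
orientation_mixture_density <- function(x, distribution_params = list()) {
  p <- utils::modifyList(default_distribution_params(), distribution_params)
  w <- p$ori_weights / sum(p$ori_weights)
  wrapped <- function(x, mu, sd) {
    d <- 0
    for (k in -3:3) d <- d + dnorm(x + 180 * k, mu, sd)
    d
  }
  w[["cardinal0"]] * wrapped(x, 0, p$ori_sd) +
    w[["cardinal90"]] * wrapped(x, 90, p$ori_sd) +
    w[["uniform"]] / 180
}

#' Frequency-domain log-Gabor filter for one model cell
#'
#' Builds the complex-analytic log-Gabor transfer function: a Gaussian in
#' log spatial frequency centered at the cell's peak frequency (width set
#' by its bandwidth in octaves, half-gain at +/- half the bandwidth) times
#' a Gaussian in orientation (width set by the orientation half-width at
#' half height), with exactly zero gain at DC. The angular term is centered
#' on one half-plane only, so the spatial-domain response is complex and
#' carries quadrature phase. Filters are L2-normalized so cells differ by
#' tuning, not gain.
#'
#' @param cell One-row data frame (a row of a `vd_population`) with
#'   `peak_frequency`, `orientation`, `sf_bandwidth`, `ori_bandwidth`.
#' @param image_shape Integer vector `c(rows, cols)`.
#' @param ppd Pixels per degree of the images the filter will be applied to.
#'
#' @return A real gain matrix in FFT layout (class `matrix`).
#' @export
build_filter <- function(cell, image_shape, ppd) {
  stopifnot(length(image_shape) == 2, ppd > 0)
  f0 <- cell$peak_frequency
  if (f0 <= 0) abort("Peak frequency must be positive.")
  if (f0 >= ppd / 2) {
    abort(sprintf("Peak frequency %.3g c/deg is at or above Nyquist (%.3g c/deg).",
                  f0, ppd / 2))
  }
  n1 <- image_shape[1]; n2 <- image_shape[2]
  fx <- fft_freqs(n2) * ppd               # horizontal frequency, cycles/deg
  fy <- fft_freqs(n1) * ppd
  FX <- matrix(fx, n1, n2, byrow = TRUE)
  FY <- matrix(fy, n1, n2, byrow = FALSE)
  f <- sqrt(FX^2 + FY^2)

  # radial term: Gaussian in log frequency; half gain at +/- bw/2 octaves
  sig_ln <- (cell$sf_bandwidth / 2) / sqrt(2 * log(2)) * log(2)
  radial <- matrix(0, n1, n2)
  nz <- f > 0
  radial[nz] <- exp(-(log(f[nz] / f0))^2 / (2 * sig_ln^2))

  # angular term: full-circle angular distance to the preferred direction,
  # one lobe only (analytic filter). Orientation 0 = vertical grating,
  # whose energy lies along the horizontal-frequency axis.
  th0 <- cell$orientation * pi / 180
  ang <- atan2(FY, FX)
  d <- atan2(sin(ang - th0), cos(ang - th0))
  sig_th <- (cell$ori_bandwidth * pi / 180) / sqrt(2 * log(2))
  angular <- exp(-d^2 / (2 * sig_th^2))

  g <- radial * angular
  nrm <- sqrt(sum(g^2))
  if (nrm > 0) g <- g / nrm
  g
}

#' Respond to an image with a population of model cells
#'
#' Converts the image to contrast units `(pixels - mean) / mean`, filters
#' it with each cell's log-Gabor (phase applied through the quadrature
#' construction), half-wave rectifies the phase-specific output and
#' averages over pixels. Returns the per-cell response vector together
#' with the total population output (their sum) and the non-excess sample
#' kurtosis of the per-cell responses (the sparseness index).
#'
#' @param img A [vd_image()].
#' @param pop A `vd_population` from [sample_population()].
#' @param output Per-pixel nonlinearity: `"halfwave"` (default) rectifies
#'   the phase-specific response; `"energy"` uses the quadrature energy
#'   (squared modulus) instead.
#' @param kurtosis Kurtosis convention: `"nonexcess"` (default, `m4/m2^2`)
#'   or `"excess"`.
#' @param filters Optional precomputed list of gain matrices from
#'   [build_filter()] (one per cell, for repeated use on same-shape images).
#'
#' @return A list of class `vd_response`: `per_cell`, `total`, `kurtosis`,
#'   `output`, `n_cells`.
#' @export
respond <- function(img, pop, output = c("halfwave", "energy"),
                    kurtosis = c("nonexcess", "excess"), filters = NULL) {
  stopifnot(inherits(img, "vd_image"), inherits(pop, "vd_population"))
  output <- match.arg(output)
  kurtosis <- match.arg(kurtosis)
  shape <- dim(img$pixels)
  mu <- mean(img$pixels)
  con <- if (mu > 0) (img$pixels - mu) / mu else img$pixels * 0
  C <- fft(con)
  np <- prod(shape)
  per_cell <- numeric(nrow(pop))
  for (i in seq_len(nrow(pop))) {
    g <- if (is.null(filters)) build_filter(pop[i, ], shape, img$ppd) else
      filters[[i]]
    z <- fft(C * g, inverse = TRUE) / np
    if (output == "halfwave") {
      s <- Re(z * exp(-1i * pop$phase[i] * pi / 180))
      per_cell[i] <- mean(pmax(s, 0))
    } else {
      per_cell[i] <- mean(Mod(z)^2)
    }
  }
  k <- response_kurtosis(per_cell, convention = kurtosis)
  structure(list(per_cell = per_cell, total = sum(per_cell), kurtosis = k,
                 output = output, n_cells = nrow(pop)),
            class = "vd_response")
}

#' Sample kurtosis of a response vector
#'
#' @param x Numeric vector.
#' @param convention `"nonexcess"` (`m4 / m2^2`, >= 1 for any
#'   non-degenerate sample) or `"excess"` (`m4 / m2^2 - 3`).
#' @return Kurtosis value (`NA` for a constant vector).
#' @export
response_kurtosis <- function(x, convention = c("nonexcess", "excess")) {
  convention <- match.arg(convention)
  m2 <- mean((x - mean(x))^2)
  if (m2 == 0) return(NA_real_)
  k <- mean((x - mean(x))^4) / m2^2
  if (convention == "excess") k - 3 else k
}

#' @exportS3Method base::print
print.vd_response <- function(x, ...) {
  cat(sprintf("<vd_response> %d cells (%s): total = %.4g, kurtosis = %.4g\n",
              x$n_cells, x$output, x$total, x$kurtosis))
  invisible(x)
}

#' Model responses for a battery of images
#'
#' Applies [respond()] to each image, precomputing the filter bank when
#' all images share one shape.
#'
#' @param images List of [vd_image()] objects (or the `image` list-column
#'   of [stimulus_battery()]).
#' @param pop A `vd_population`.
#' @param ids Optional image ids (default names or index).
#' @inheritParams respond
#'
#' @return Tibble with columns `id`, `total_response`, `kurtosis`.
#' @export
respond_battery <- function(images, pop, ids = NULL,
                            output = c("halfwave", "energy")) {
  output <- match.arg(output)
  if (is.null(ids)) {
    ids <- names(images)
    if (is.null(ids)) ids <- sprintf("img_%03d", seq_along(images))
  }
  shapes <- vapply(images, function(im) paste(dim(im$pixels), collapse = "x"),
                   character(1))
  ppds <- vapply(images, function(im) im$ppd, numeric(1))
  filters <- NULL
  if (length(unique(shapes)) == 1L && length(unique(ppds)) == 1L) {
    shape <- dim(images[[1]]$pixels)
    filters <- lapply(seq_len(nrow(pop)),
                      function(i) build_filter(pop[i, ], shape, ppds[1]))
  }
  purrr::map2_dfr(images, ids, function(im, id) {
    r <- respond(im, pop, output = output, filters = filters)
    tibble::tibble(id = id, total_response = r$total, kurtosis = r$kurtosis)
  })
}
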