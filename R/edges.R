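#' Edge extraction configuration
#'
#' Defaults follow the reference procedure: a bank of 24 odd-symmetric
#' Gabor filters with envelope sigma 1.669 px spanning orientations 0 to
#' pi, images downscaled so the longest side is at most 340 px, responses
#' within 15 px of the border discarded, and only the 10,000 strongest
#' edge responses retained.
#'
#' @param n_orientations Number of filter orientations over `[0, pi)`.
#' @param gabor_sigma Gaussian envelope SD in pixels.
#' @param gabor_wavelength Carrier wavelength in pixels (default
#'   `pi * gabor_sigma`).
#' @param max_side_px Maximum image side after downscaling.
#' @param border_discard_px Border width whose responses are discarded.
#' @param top_edges Number of strongest responses retained.
#' @param n_distance_bins,n_alpha_bins Pair-histogram bin counts for the
#'   second-order entropy (500 distance bins; 48 bins of pairwise angle
#'   over the full 0-360 degree range, polarity included).
#'
#' @return A list of class `vd_edge_config`.
#' @export
edge_extraction_config <- function(n_orientations = 24, gabor_sigma = 1.669,
                                   gabor_wavelength = pi * gabor_sigma,
                                   max_side_px = 340, border_discard_px = 15,
                                   top_edges = 10000,
                                   n_distance_bins = 500, n_alpha_bins = 48) {
  stopifnot(n_orientations >= 2, gabor_sigma > 0, top_edges >= 1,
            n_distance_bins >= 1, n_alpha_bins >= 1)
  structure(list(n_orientations = n_orientations, gabor_sigma = gabor_sigma,
                 gabor_wavelength = gabor_wavelength,
                 max_side_px = max_side_px,
                 border_discard_px = border_discard_px,
                 top_edges = top_edges, n_distance_bins = n_distance_bins,
                 n_alpha_bins = n_alpha_bins),
            class = "vd_edge_config")
}

# Odd-symmetric Gabor kernel at orientation theta (radians), zero-mean,
# unit L2 norm.
gabor_kernel_odd <- function(theta, sigma, wavelength) {
  half <- max(5L, ceiling(3 * sigma))
  xs <- -half:half
  X <- matrix(xs, length(xs), length(xs), byrow = TRUE)
  Y <- matrix(xs, length(xs), length(xs), byrow = FALSE)
  xr <- X * cos(theta) + Y * sin(theta)
  yr <- -X * sin(theta) + Y * cos(theta)
  g <- exp(-(xr^2 + yr^2) / (2 * sigma^2)) * sin(2 * pi * xr / wavelength)
  g <- g - mean(g)
  g / sqrt(sum(g^2))
}

#' Extract oriented edges from an image
#'
#' Downscales the image so its longest side is at most `max_side_px`
#' (aspect preserved), convolves it with the bank of odd-symmetric Gabor
#' filters, and keeps, per pixel, the orientation of the strongest
#' absolute response and its magnitude. The response sign assigns a
#' contrast polarity, extending the edge direction onto the full 0-360
#' degree circle. Border responses are discarded and only the strongest
#' `top_edges` responses are retained.
#'
#' @param img A [vd_image()].
#' @param cfg An [edge_extraction_config()].
#' @param intensity_floor Responses at or below this magnitude are treated
#'   as numerically zero (no edge), guarding the FFT-based convolution's
#'   rounding noise on locally uniform regions.
#' @return Tibble with columns `x`, `y` (pixel coordinates in the resized
#'   image), `ori_bin` (1..24, orientation modulo 180 degrees),
#'   `theta_deg` (polarity-extended direction in `[0, 360)`) and
#'   `intensity`. Attributes `image_dim` (resized dimensions) and `cfg`
#'   are attached for downstream binning.
#' @export
extract_edges <- function(img, cfg = edge_extraction_config(),
                          intensity_floor = 1e-8) {
  stopifnot(inherits(img, "vd_image"), inherits(cfg, "vd_edge_config"))
  px <- img$pixels
  side <- max(dim(px))
  if (side > cfg$max_side_px) {
    sc <- cfg$max_side_px / side
    px <- EBImage::resize(EBImage::Image(px),
                          w = max(2L, round(nrow(px) * sc)),
                          h = max(2L, round(ncol(px) * sc)))
    px <- EBImage::imageData(px)
  }
  nr <- nrow(px); nc <- ncol(px)
  b <- cfg$border_discard_px
  if (nr <= 2 * b + 1 || nc <= 2 * b + 1) {
    abort("Image too small: nothing remains after discarding the border region.")
  }
  thetas <- (seq_len(cfg$n_orientations) - 1) * pi / cfg$n_orientations
  best <- matrix(-Inf, nr, nc)
  best_ori <- matrix(1L, nr, nc)
  best_sign <- matrix(1, nr, nc)
  for (k in seq_along(thetas)) {
    ker <- gabor_kernel_odd(thetas[k], cfg$gabor_sigma, cfg$gabor_wavelength)
    r <- EBImage::imageData(EBImage::filter2(EBImage::Image(px), ker,
                                             boundary = "replicate"))
    a <- abs(r)
    upd <- a > best
    best[upd] <- a[upd]
    best_ori[upd] <- k
    best_sign[upd] <- sign(r[upd])
  }
  interior <- matrix(FALSE, nr, nc)
  interior[(b + 1):(nr - b), (b + 1):(nc - b)] <- TRUE
  idx <- which(interior & best > intensity_floor)
  if (!length(idx)) {
    out <- tibble::tibble(x = integer(0), y = integer(0), ori_bin = integer(0),
                          theta_deg = numeric(0), intensity = numeric(0))
  } else {
    ord <- idx[order(best[idx], decreasing = TRUE)]
    keep <- head(ord, cfg$top_edges)
    rowi <- ((keep - 1L) %% nr) + 1L
    coli <- ((keep - 1L) %/% nr) + 1L
    ori <- best_ori[keep]
    theta <- (ori - 1L) * 180 / cfg$n_orientations
    theta <- ifelse(best_sign[keep] < 0, theta + 180, theta)
    out <- tibble::tibble(x = coli, y = rowi, ori_bin = as.integer(ori),
                          theta_deg = theta, intensity = best[keep])
  }
  attr(out, "image_dim") <- c(nr, nc)
  attr(out, "cfg") <- cfg
  out
}

#' First- and second-order edge-orientation entropy
#'
#' First-order entropy is the Shannon entropy (bits) of the
#' intensity-weighted histogram of edge orientations (24 bins over 180
#' degrees). For the second-order entropy every unordered pair of edges
#' is binned by Euclidean distance `d` (500 bins up to the image diagonal)
#' and pairwise angle `alpha` (48 bins over 0-360 degrees of
#' polarity-extended direction difference); each pair contributes the
#' product of the two edge intensities to the orientation histograms of
#' both its members within that `(d, alpha)` cell. Per-cell histograms
#' are normalized to probabilities (an even spread gives 1/24 per
#' orientation section), their Shannon entropies computed, and the result
#' averaged over all occupied `(d, alpha)` cells.
#'
#' @param edges Output of [extract_edges()].
#' @param cfg The [edge_extraction_config()] (defaults to the one attached
#'   to `edges`).
#' @return A list: `entropy_first`, `entropy_second` (bits),
#'   `pair_histogram` (3-D array `d x alpha x orientation`) and
#'   `cell_entropy` (matrix of per-cell entropies, `NA` where empty).
#' @export
edge_orientation_entropy <- function(edges, cfg = attr(edges, "cfg")) {
  if (is.null(cfg)) cfg <- edge_extraction_config()
  n <- nrow(edges)
  if (n < 1) abort("No edges supplied.")
  w <- tapply(edges$intensity, factor(edges$ori_bin,
                                      levels = seq_len(cfg$n_orientations)), sum)
  w[is.na(w)] <- 0
  entropy_first <- shannon_bits(as.numeric(w))

  if (n < 2) {
    return(list(entropy_first = entropy_first, entropy_second = 0,
                pair_histogram = NULL, cell_entropy = NULL))
  }
  dims <- attr(edges, "image_dim")
  d_max <- if (!is.null(dims)) sqrt(sum(dims^2)) else
    sqrt(diff(range(edges$x))^2 + diff(range(edges$y))^2) + 1e-9
  hist3 <- edge_pair_hist_cpp(
    as.numeric(edges$x), as.numeric(edges$y),
    as.numeric(edges$theta_deg), as.integer(edges$ori_bin) - 1L,
    as.numeric(edges$intensity),
    cfg$n_distance_bins, cfg$n_alpha_bins, cfg$n_orientations, d_max)
  dim(hist3) <- c(cfg$n_distance_bins, cfg$n_alpha_bins, cfg$n_orientations)

  mass <- apply(hist3, c(1, 2), sum)
  cell_entropy <- matrix(NA_real_, cfg$n_distance_bins, cfg$n_alpha_bins)
  occ <- which(mass > 0, arr.ind = TRUE)
  for (r in seq_len(nrow(occ))) {
    p <- hist3[occ[r, 1], occ[r, 2], ]
    cell_entropy[occ[r, 1], occ[r, 2]] <- shannon_bits(p)
  }
  entropy_second <- mean(cell_entropy[!is.na(cell_entropy)])
  list(entropy_first = entropy_first, entropy_second = entropy_second,
       pair_histogram = hist3, cell_entropy = cell_entropy)
}

# Shannon entropy in bits of an unnormalized weight vector.
shannon_bits <- function(w) {
  s <- sum(w)
  if (s <= 0) return(0)
  p <- w[w > 0] / s
  -sum(p * log2(p))
}
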