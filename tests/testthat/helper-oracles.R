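# Independent oracles and fixture builders used across the suite.
# These deliberately re-derive quantities from first principles rather than
# calling the package's vectorized/compiled implementations.

# Sierpinski-triangle raster of side n (power of two): pixel (i, j) is in the
# set iff bitwAnd(i, j) == 0; the ideal set has dimension log(3)/log(2).
sierpinski_raster <- function(n = 512) {
  m <- matrix(0, n, n)
  for (i in 0:(n - 1)) {
    j <- which(bitwAnd(i, 0:(n - 1)) == 0)
    m[i + 1, j] <- 1
  }
  m
}

# Grating whose spatial period divides the image side exactly, so the pixel
# mean is exactly 0.5 (needed for exact-linearity checks).
integer_cycle_grating <- function(frequency, ppd, size, contrast = 1) {
  stopifnot((size * frequency / ppd) %% 1 == 0)
  make_grating(frequency, ppd = ppd, size = size, contrast = contrast)
}

# Brute-force second-order edge-pair entropy: plain double loop following
# the definitions (distance bins over (0, d_max], 48 bins of the stored-order
# direction difference, intensity products credited to both members'
# orientation bins, per-cell Shannon entropy in bits averaged over occupied
# cells).
brute_force_pair_entropy <- function(edges, cfg, d_max) {
  nd <- cfg$n_distance_bins; na <- cfg$n_alpha_bins; no <- cfg$n_orientations
  H <- array(0, dim = c(nd, na, no))
  n <- nrow(edges)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- sqrt((edges$x[i] - edges$x[j])^2 + (edges$y[i] - edges$y[j])^2)
      db <- ceiling(d / (d_max / nd))
      db <- min(max(db, 1), nd)
      alpha <- (edges$theta_deg[i] - edges$theta_deg[j]) %% 360
      ab <- min(floor(alpha / (360 / na)) + 1, na)
      w <- edges$intensity[i] * edges$intensity[j]
      H[db, ab, edges$ori_bin[i]] <- H[db, ab, edges$ori_bin[i]] + w
      H[db, ab, edges$ori_bin[j]] <- H[db, ab, edges$ori_bin[j]] + w
    }
  }
  ents <- c()
  for (a in seq_len(nd)) {
    for (b in seq_len(na)) {
      m <- sum(H[a, b, ])
      if (m > 0) {
        p <- H[a, b, ][H[a, b, ] > 0] / m
        ents <- c(ents, -sum(p * log2(p)))
      }
    }
  }
  mean(ents)
}

# Hand-made edge tables for entropy contracts (positions in a 100x100 frame).
synthetic_edges <- function(x, y, ori_bin, theta_deg, intensity,
                            dims = c(100, 100),
                            cfg = edge_extraction_config()) {
  out <- tibble::tibble(x = x, y = y, ori_bin = as.integer(ori_bin),
                        theta_deg = theta_deg, intensity = intensity)
  attr(out, "image_dim") <- dims
  attr(out, "cfg") <- cfg
  out
}

# Numeric CDF of the population orientation mixture on [0, 180), by
# trapezoidal integration of the density (brute-force reference).
orientation_mixture_cdf <- function(q, distribution_params = list()) {
  grid <- seq(0, 180, length.out = 20001)
  dens <- orientation_mixture_density(grid, distribution_params)
  cdf <- cumsum((dens[-1] + dens[-length(dens)]) / 2 * diff(grid))
  cdf <- c(0, cdf / cdf[length(cdf)])
  approx(grid, cdf, xout = q, rule = 2)$y
}

# Trial table with a quadratic (octave-scale) spatial-frequency tuning of
# the latent rating, observer intercepts and Gaussian noise.
quadratic_tuning_table <- function(vertex_cpd = 3, curvature = 0.5,
                                   frequencies = c(0.75, 1.5, 3, 6, 9),
                                   n_observers = 11, n_rep = 4,
                                   observer_sd = 0.3, residual_sd = 0.3,
                                   direction = 1, seed = 1) {
  withr::with_seed(seed, {
    b_obs <- rnorm(n_observers, 0, observer_sd)
    rows <- list()
    for (o in seq_len(n_observers)) {
      for (f in rep(frequencies, n_rep)) {
        mu <- 4 + direction * curvature * (log2(f) - log2(vertex_cpd))^2
        rows[[length(rows) + 1L]] <- tibble::tibble(
          observer = sprintf("obs%02d", o), category = "bump",
          spatial_frequency = f,
          rating = mu + b_obs[o] + rnorm(1, 0, residual_sd))
      }
    }
    dplyr::bind_rows(rows)
  })
}
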