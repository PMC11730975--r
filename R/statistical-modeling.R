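#' Principal component analysis of the image-statistics table
#'
#' Eigen-decomposition of the correlation matrix of the (standardized)
#' image statistics, with the Kaiser rule (eigenvalue > 1) deciding which
#' components are retained. Rows with an invalid spectral slope (periodic
#' stimuli) are excluded, mirroring the analysis protocol; loadings are
#' signed so that the variable with the largest absolute loading on each
#' component is positive.
#'
#' @param stats_table Data frame with one row per image.
#' @param vars Variable columns entering the PCA.
#' @param standardize Z-score each variable (correlation-matrix PCA,
#'   default `TRUE`).
#' @param retain Optional explicit component indices to retain, overriding
#'   the Kaiser rule (overrides are recorded in the result).
#'
#' @return Object of class `vd_pca`: `loadings`, `eigenvalues`,
#'   `variance_explained`, `retained`, `kaiser_retained`, `scores`
#'   (tibble with `id` if present), `n`, `vars`.
#' @export
pca_image_stats <- function(stats_table,
                            vars = c("slope_k", "fractal_D", "rms_contrast",
                                     "csf_contrast", "total_response",
                                     "entropy_first", "entropy_second"),
                            standardize = TRUE, retain = NULL) {
  vars <- intersect(vars, names(stats_table))
  if (length(vars) < 3) abort("At least 3 variables are required for the PCA.")
  tb <- stats_table
  if ("slope_valid" %in% names(tb)) tb <- tb[tb$slope_valid %in% TRUE, ]
  keep <- stats::complete.cases(tb[vars])
  tb <- tb[keep, ]
  if (nrow(tb) < length(vars) + 1) {
    abort("Need at least one more complete row than variables.")
  }
  X <- as.matrix(tb[vars])
  sds <- apply(X, 2, sd)
  if (any(sds == 0)) {
    abort(paste0("Constant column(s): ", paste(vars[sds == 0], collapse = ", ")))
  }
  pc <- prcomp(X, center = TRUE, scale. = standardize)
  L <- pc$rotation
  S <- pc$x
  for (j in seq_len(ncol(L))) {
    i <- which.max(abs(L[, j]))
    if (L[i, j] < 0) { L[, j] <- -L[, j]; S[, j] <- -S[, j] }
  }
  ev <- pc$sdev^2
  kaiser <- which(ev > 1)
  retained <- if (is.null(retain)) kaiser else sort(unique(as.integer(retain)))
  scores <- tibble::as_tibble(S)
  if ("id" %in% names(tb)) scores <- dplyr::bind_cols(tb["id"], scores)
  structure(list(loadings = L, eigenvalues = ev,
                 variance_explained = ev / sum(ev),
                 retained = retained, kaiser_retained = kaiser,
                 retain_override = !is.null(retain),
                 scores = scores, n = nrow(tb), vars = vars),
            class = "vd_pca")
}

#' @exportS3Method base::print
print.vd_pca <- function(x, ...) {
  cat(sprintf("<vd_pca> %d rows, %d variables\n", x$n, length(x$vars)))
  cat("eigenvalues:", paste(sprintf("%.3f", x$eigenvalues), collapse = ", "), "\n")
  cat("variance explained:",
      paste(sprintf("%.1f%%", 100 * x$variance_explained), collapse = ", "), "\n")
  cat("retained:", paste0("PC", x$retained, collapse = ", "),
      if (x$retain_override) "(manual override)" else "(Kaiser rule)", "\n")
  invisible(x)
}

#' Fit a linear mixed model for ratings or SSVEP power
#'
#' Fits `response ~ predictors + (1 | random)` (optionally with a random
#' slope) through lmerTest, and packages coefficients with standard
#' errors, Wald 95% confidence intervals and Satterthwaite p values,
#' variance components, and marginal/conditional R2 (fixed-effect variance
#' over total variance). When the response is a category factor, releveled
#' contrasts are taken against the `"natural"` baseline if present.
#'
#' @param table Trial-table data frame.
#' @param predictors Character vector of fixed-effect column names (may
#'   include factors such as `category`).
#' @param response Response column (default `"rating"`).
#' @param random Grouping column for the random intercept (default
#'   `"observer"`).
#' @param random_slope Optional predictor given a by-group random slope.
#' @param level Confidence level for the intervals.
#'
#' @return Object of class `vd_fit`: `model` (the `lmerMod`), `coefficients`
#'   (tibble), `varcomp`, `r2_marginal`, `r2_conditional`, `singular`,
#'   `formula`.
#' @export
fit_rating_model <- function(table, predictors, response = "rating",
                             random = "observer", random_slope = NULL,
                             level = 0.95) {
  miss <- setdiff(c(predictors[!grepl(":", predictors)], response, random),
                  names(table))
  if (length(miss)) abort(paste0("Missing column(s): ", paste(miss, collapse = ", ")))
  if (length(unique(table[[random]])) < 2) {
    abort("At least two grouping levels are required for the random effect.")
  }
  bad <- !is.finite(table[[response]])
  for (p in predictors[!grepl(":", predictors)]) {
    if (is.numeric(table[[p]])) bad <- bad | !is.finite(table[[p]])
  }
  table <- table[!bad, , drop = FALSE]
  if ("category" %in% predictors && "natural" %in% unique(table$category)) {
    table$category <- stats::relevel(factor(table$category), ref = "natural")
  }
  re <- if (is.null(random_slope)) sprintf("(1 | %s)", random) else
    sprintf("(1 + %s | %s)", random_slope, random)
  fml <- stats::as.formula(paste(response, "~",
                                 paste(predictors, collapse = " + "), "+", re))
  fit <- lmerTest::lmer(fml, data = table, REML = TRUE)
  vd_fit_from_lmer(fit, fml, level)
}

vd_fit_from_lmer <- function(fit, fml, level = 0.95) {
  sm <- summary(fit)
  co <- as.data.frame(sm$coefficients)
  z <- stats::qnorm(1 - (1 - level) / 2)
  coefs <- tibble::tibble(
    term = rownames(co), estimate = co$Estimate, std_error = co$`Std. Error`,
    conf_low = co$Estimate - z * co$`Std. Error`,
    conf_high = co$Estimate + z * co$`Std. Error`,
    df = if ("df" %in% names(co)) co$df else NA_real_,
    p_value = if ("Pr(>|t|)" %in% names(co)) co$`Pr(>|t|)` else NA_real_)
  vc <- as.data.frame(lme4::VarCorr(fit))
  var_re <- sum(vc$vcov[vc$grp != "Residual"])
  var_res <- vc$vcov[vc$grp == "Residual"]
  X <- lme4::getME(fit, "X")
  var_fix <- var(as.numeric(X %*% lme4::fixef(fit)))
  tot <- var_fix + var_re + var_res
  singular <- lme4::isSingular(fit)
  if (singular) {
    warn("Random-effects fit is singular; variance components are on the boundary.")
  }
  structure(list(model = fit, coefficients = coefs,
                 varcomp = tibble::as_tibble(vc),
                 r2_marginal = var_fix / tot,
                 r2_conditional = (var_fix + var_re) / tot,
                 singular = singular, formula = deparse(fml), level = level),
            class = "vd_fit")
}

#' @exportS3Method base::print
print.vd_fit <- function(x, ...) {
  cat("<vd_fit>", x$formula, "\n")
  print(x$coefficients)
  cat(sprintf("marginal R2 = %.3f, conditional R2 = %.3f%s\n",
              x$r2_marginal, x$r2_conditional,
              if (x$singular) " [singular fit]" else ""))
  invisible(x)
}

#' Spatial-frequency tuning of ratings or SSVEP power
#'
#' Restricted to the frequency-varying stimulus classes (bumps and
#' stripes/gratings), fits a mixed model with linear and quadratic
#' spatial-frequency terms on the octave (log2) scale, the image type, and
#' a linear frequency-by-type interaction, with an observer random
#' intercept (random slope optional). The quadratic term captures tuning
#' around a non-zero peak or trough frequency; [vertex_frequency()]
#' recovers that frequency in c/deg from the fitted coefficients.
#'
#' @param table Trial table with `spatial_frequency` (c/deg) and
#'   `category` columns.
#' @param response Response column.
#' @param categories Frequency-varying categories to keep.
#' @param include_quadratic,include_interaction Model terms.
#' @param random,random_slope,level As in [fit_rating_model()].
#'
#' @return A `vd_fit` (with attribute `sf_scale = "log2"`).
#' @export
fit_sf_tuning <- function(table, response = "rating",
                          categories = c("bump", "grating", "stripe",
                                         "stripe_texture"),
                          include_quadratic = TRUE,
                          include_interaction = TRUE,
                          random = "observer", random_slope = NULL,
                          level = 0.95) {
  if (!"spatial_frequency" %in% names(table)) {
    abort("`spatial_frequency` column required.")
  }
  tb <- table[table$category %in% categories &
                is.finite(table$spatial_frequency), , drop = FALSE]
  nfreq <- length(unique(tb$spatial_frequency))
  if (include_quadratic && nfreq < 3) {
    abort("A quadratic frequency term needs at least 3 distinct frequencies.")
  }
  tb$log2_sf <- log2(tb$spatial_frequency)
  terms <- "log2_sf"
  if (include_quadratic) terms <- c(terms, "I(log2_sf^2)")
  if (length(unique(tb$category)) > 1) {
    tb$category <- factor(tb$category)
    terms <- c(terms, "category")
    if (include_interaction) terms <- c(terms, "log2_sf:category")
  }
  re <- if (is.null(random_slope)) sprintf("(1 | %s)", random) else
    sprintf("(1 + %s | %s)", random_slope, random)
  fml <- stats::as.formula(paste(response, "~",
                                 paste(terms, collapse = " + "), "+", re))
  fit <- lmerTest::lmer(fml, data = tb, REML = TRUE)
  out <- vd_fit_from_lmer(fit, fml, level)
  attr(out, "sf_scale") <- "log2"
  out
}

#' Vertex (peak or trough) frequency of a quadratic tuning fit
#'
#' @param fit A [fit_sf_tuning()] result.
#' @return Frequency in cycles per degree at the fitted quadratic's
#'   vertex (`NA` if the quadratic coefficient is zero).
#' @export
vertex_frequency <- function(fit) {
  co <- fit$coefficients
  b <- co$estimate[co$term == "log2_sf"]
  a <- co$estimate[co$term == "I(log2_sf^2)"]
  if (!length(a) || a == 0) return(NA_real_)
  2^(-b / (2 * a))
}
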