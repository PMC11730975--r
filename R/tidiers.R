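#' Tidy a mixed-model fit
#'
#' @param x A `vd_fit`.
#' @param ... Unused.
#' @return Tibble of fixed-effect terms with estimates, standard errors,
#'   confidence bounds, degrees of freedom and p values.
#' @export
#' @exportS3Method generics::tidy
tidy.vd_fit <- function(x, ...) x$coefficients

#' One-row summary of a mixed-model fit
#'
#' @param x A `vd_fit`.
#' @param ... Unused.
#' @export
#' @exportS3Method generics::glance
glance.vd_fit <- function(x, ...) {
  tibble::tibble(
    r2_marginal = x$r2_marginal, r2_conditional = x$r2_conditional,
    sigma = stats::sigma(x$model), n_obs = stats::nobs(x$model),
    singular = x$singular, logLik = as.numeric(stats::logLik(x$model)))
}

#' Tidy PCA loadings
#'
#' @param x A `vd_pca`.
#' @param ... Unused.
#' @return Long tibble: `variable`, `component`, `loading`.
#' @export
#' @exportS3Method generics::tidy
tidy.vd_pca <- function(x, ...) {
  L <- x$loadings
  tibble::tibble(
    variable = rep(rownames(L), ncol(L)),
    component = rep(colnames(L), each = nrow(L)),
    loading = as.numeric(L))
}

#' Per-component PCA summary
#'
#' @param x A `vd_pca`.
#' @param ... Unused.
#' @return Tibble with eigenvalues, variance fractions and retention.
#' @export
#' @exportS3Method generics::glance
glance.vd_pca <- function(x, ...) {
  k <- seq_along(x$eigenvalues)
  tibble::tibble(
    component = paste0("PC", k), eigenvalue = x$eigenvalues,
    variance_explained = x$variance_explained,
    retained = k %in% x$retained)
}

#' PCA scores joined back to image ids
#'
#' @param x A `vd_pca`.
#' @param data Optional data frame with an `id` column to join onto.
#' @param ... Unused.
#' @export
#' @exportS3Method generics::augment
augment.vd_pca <- function(x, data = NULL, ...) {
  if (is.null(data)) return(x$scores)
  dplyr::left_join(data, x$scores, by = "id")
}
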