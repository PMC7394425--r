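# broom-style tidiers for the package's fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.error_pca <- function(x, ...) {
  tibble::tibble(
    axis = x$axis,
    landmark = rep(x$landmarks, ncol(x$loadings)),
    component = rep(seq_len(ncol(x$loadings)), each = length(x$landmarks)),
    loading = as.vector(x$loadings)
  )
}

#' @export
glance.error_pca <- function(x, ...) {
  tibble::tibble(
    axis = x$axis,
    n_subjects = nrow(x$data),
    n_landmarks = ncol(x$data),
    pc1_variance_explained = x$variance_explained[1]
  )
}

#' @export
tidy.lt_lmm <- function(x, ...) x$anova

#' @export
glance.lt_lmm <- function(x, ...) {
  tibble::tibble(
    dependent = x$dependent,
    nobs = stats::nobs(x$model),
    n_subjects = lme4::ngrps(x$model)[["subject_id"]],
    random_structure = x$random_structure,
    singular = x$singular,
    shapiro_p = x$normality$p_value
  )
}

#' @export
tidy.lt_glm <- function(x, ...) x$anova

#' @export
glance.lt_glm <- function(x, ...) {
  tibble::tibble(
    scope = x$scope,
    nobs = stats::nobs(x$model),
    deviance = x$model$deviance,
    n_clipped = x$n_clipped
  )
}

#' @export
tidy.width_slope_fit <- function(x, ...) x$summary

#' @export
glance.width_slope_fit <- function(x, ...) {
  s <- summary(x$model)
  tibble::tibble(
    adj_r_squared = s$adj.r.squared,
    r_squared = s$r.squared,
    nobs = nrow(x$data)
  )
}

#' @export
tidy.knuckle_trends <- function(x, ...) {
  lin <- dplyr::mutate(x$linear$anova, fit = "linear_vx")
  if (is.null(x$quadratic)) {
    return(lin)
  }
  quad <- x$quadratic$coefficients |>
    dplyr::mutate(fit = "quadratic_consistency", num_df = NA_real_, den_df = NA_real_)
  dplyr::bind_rows(lin, quad)
}
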