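# Principal-component decomposition of per-subject mean error components,
# and removal of the dominant shared component (the candidate overlap bias).

#' PCA of per-subject mean error components
#'
#' Builds the subjects x 10-landmarks matrix of per-subject mean
#' medio-lateral (or proximo-distal) errors, column-centres it, and extracts
#' principal components from the covariance structure (unstandardized, so
#' loadings stay on the cm scale and are comparable across landmarks). The
#' sign of PC1 is oriented so that the mean of its loadings agrees in sign
#' with the grand-mean error, i.e. PC1 points "with" the dominant error
#' direction; this prevents arbitrary sign flips across runs.
#'
#' @param errors An error table from [error_table()].
#' @param axis `"medio_lateral"` (vx) or `"proximo_distal"` (vy).
#' @return An object of class `error_pca`: list with `axis`, `data` (the
#'   subjects x landmarks matrix), `center` (column means), `loadings`
#'   (10 x k, orthonormal columns), `scores` (subjects x k),
#'   `variance_explained`, `subjects`, `landmarks`.
#' @export
pca_errors <- function(errors, axis = c("medio_lateral", "proximo_distal")) {
  check_errors_table(errors)
  axis <- match.arg(axis)
  comp <- if (axis == "medio_lateral") "vx_cm" else "vy_cm"

  X <- errors |>
    dplyr::group_by(subject_id, landmark) |>
    dplyr::summarise(value = mean(.data[[comp]]), .groups = "drop") |>
    tidyr::pivot_wider(names_from = landmark, values_from = value)
  missing <- setdiff(hand_landmark_labels(), names(X))
  if (length(missing) > 0) {
    abort(paste("Missing landmark(s) for the PCA:", paste(missing, collapse = ", ")))
  }
  subjects <- X$subject_id
  M <- as.matrix(X[, hand_landmark_labels()])
  if (anyNA(M)) abort("Every subject must have a mean error for all 10 landmarks.")
  if (nrow(M) < 3) abort("PCA needs at least 3 subjects.")

  pc <- prcomp(M, center = TRUE, scale. = FALSE)
  loadings <- pc$rotation
  scores <- pc$x
  # orient PC1 with the dominant error direction
  s <- sign(mean(loadings[, 1])) * sign(mean(colMeans(M)))
  if (is.finite(s) && s < 0) {
    loadings[, 1] <- -loadings[, 1]
    scores[, 1] <- -scores[, 1]
  }

  structure(
    list(
      axis = axis,
      data = M,
      center = colMeans(M),
      loadings = loadings,
      scores = scores,
      variance_explained = pc$sdev^2 / sum(pc$sdev^2),
      subjects = subjects,
      landmarks = hand_landmark_labels()
    ),
    class = "error_pca"
  )
}

#' @exportS3Method
print.error_pca <- function(x, ...) {
  cat(sprintf(
    "<error_pca> axis %s: %d subjects x %d landmarks; PC1 explains %.1f%% of variance\n",
    x$axis, nrow(x$data), ncol(x$data), 100 * x$variance_explained[1]
  ))
  invisible(x)
}

#' Remove PC1 and recompute the hand width estimation ratio
#'
#' Subtracts the first principal component — interpreted as the shared bias
#' source — from each subject's per-landmark mean error component, rebuilds
#' the perceived landmark positions (the untouched axis keeps its original
#' mean errors), and recomputes the per-subject hand width ER.
#'
#' By default (`keep_mean = FALSE`) the full projection of the data onto the
#' PC1 axis is removed, mean included: if the shared bias is a nonzero-mean
#' common shift (as an overlap bias toward the shoulder is), its average
#' contribution to the perceived hand width is removed along with its
#' between-subject variation. With `keep_mean = TRUE` only the centred PC1
#' variation is removed and the grand-mean errors are preserved exactly.
#'
#' @param errors An error table from [error_table()].
#' @param decomposition An `error_pca` from [pca_errors()] (any axis; the
#'   width ER is recomputed with that axis reconstructed and the other axis
#'   original).
#' @param landmarks Actual landmark coordinates (all subjects).
#' @param keep_mean Keep the column means of the reconstructed matrix
#'   (orthodox centred reconstruction) instead of removing the full PC1-axis
#'   projection.
#' @return A tibble with `subject_id`, `width_er` (original) and
#'   `width_er_pc1_removed`.
#' @export
remove_pc1_and_recompute <- function(errors, decomposition, landmarks,
                                     keep_mean = FALSE) {
  if (!inherits(decomposition, "error_pca")) {
    abort("`decomposition` must come from `pca_errors()`.")
  }
  X <- decomposition$data
  l1 <- decomposition$loadings[, 1]
  if (keep_mean) {
    Xc <- sweep(X, 2, decomposition$center)
    R <- sweep(Xc - (Xc %*% l1) %*% t(l1), 2, decomposition$center, `+`)
  } else {
    R <- X - (X %*% l1) %*% t(l1)
  }

  recon <- tibble::as_tibble(R) |>
    dplyr::mutate(subject_id = decomposition$subjects) |>
    tidyr::pivot_longer(-subject_id, names_to = "landmark", values_to = "recon")

  mean_err <- errors |>
    dplyr::group_by(subject_id, landmark) |>
    dplyr::summarise(vx_cm = mean(vx_cm), vy_cm = mean(vy_cm), .groups = "drop") |>
    dplyr::inner_join(recon, by = c("subject_id", "landmark"))
  if (decomposition$axis == "medio_lateral") {
    mean_err$vx_cm <- mean_err$recon
  } else {
    mean_err$vy_cm <- mean_err$recon
  }

  width_from_means <- function(me) {
    canonical_landmarks(landmarks) |>
      dplyr::select(subject_id, landmark, actual_x = x_cm, actual_y = y_cm) |>
      dplyr::inner_join(me, by = c("subject_id", "landmark")) |>
      dplyr::filter(landmark %in% c("index_knuckle", "little_knuckle")) |>
      dplyr::mutate(px = actual_x + vx_cm, py = actual_y + vy_cm) |>
      dplyr::group_by(subject_id) |>
      dplyr::summarise(
        width_er = dist2(px[1], py[1], px[2], py[2]) /
          dist2(actual_x[1], actual_y[1], actual_x[2], actual_y[2]),
        .groups = "drop"
      )
  }

  original <- estimation_ratios(errors, landmarks)[, c("subject_id", "width_er")]
  removed <- width_from_means(mean_err) |>
    dplyr::rename(width_er_pc1_removed = width_er)
  dplyr::inner_join(original, removed, by = "subject_id")
}
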