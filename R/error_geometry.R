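# Systematic error vectors: components, magnitude, direction, with the
# medio-lateral / proximo-distal sign conventions of the aligned frame.

#' Normalize a trial index to the 0--100 scale
#'
#' Returns `100 * trial_index / total_trials`, putting sessions with
#' different lengths (e.g. 400 vs 160 trials) on a common scale.
#'
#' @param trial_index Trial number(s), 1-based.
#' @param total_trials Total number of trials in the session.
#' @return Numeric in (0, 100].
#' @export
#' @examples
#' normalize_trial(200, 400) # 50
normalize_trial <- function(trial_index, total_trials) {
  if (any(trial_index < 1 | trial_index > total_trials)) {
    abort("`trial_index` must lie in [1, total_trials].")
  }
  100 * trial_index / total_trials
}

#' Systematic error vector of a localization judgment
#'
#' The systematic error is the vector from the actual landmark location to
#' the perceived location, in the aligned frame. Sign conventions: negative
#' vx is a lateral error (toward the shoulder line), positive vx medial
#' (toward the body midline); negative vy is proximal (toward the body),
#' positive vy distal. For right hands the x component is negated before
#' storage so that "lateral" is negative vx for both hands. The direction
#' `alpha` is `atan2(vy, vx)` mapped to \[0, 360) (0 = medial, 90 = distal);
#' it is undefined (`NA`) for exact hits (zero magnitude).
#'
#' @param actual_x,actual_y,perceived_x,perceived_y Coordinates in cm
#'   (vectorized).
#' @param handedness `"left"` or `"right"` (scalar or vector).
#' @return A tibble with columns `vx_cm`, `vy_cm`, `magnitude_cm`,
#'   `alpha_deg`.
#' @export
#' @examples
#' systematic_error(0, 0, -2, -3) # lateral-proximal error, third quadrant
systematic_error <- function(actual_x, actual_y, perceived_x, perceived_y,
                             handedness = "left") {
  vx <- perceived_x - actual_x
  vy <- perceived_y - actual_y
  vx <- ifelse(handedness == "right", -vx, vx)
  magnitude <- sqrt(vx^2 + vy^2)
  alpha <- ifelse(magnitude > 0, wrap_deg(rad2deg(atan2(vy, vx))), NA_real_)
  tibble::tibble(
    vx_cm = vx, vy_cm = vy, magnitude_cm = magnitude, alpha_deg = alpha
  )
}

#' Error table: one systematic error vector per kept trial
#'
#' Joins the (aligned, filtered) trials to the actual landmark coordinates
#' and computes each kept trial's error vector, direction and normalized
#' trial number. Excluded trials are dropped.
#'
#' @param dataset An `lt_dataset`, aligned (see [align_dataset()]) and,
#'   typically, filtered (see [mahalanobis_filter()]).
#' @return A tibble with columns `subject_id`, `trial_index`,
#'   `normalized_trial`, `landmark`, `finger`, `type`, `vx_cm`, `vy_cm`,
#'   `magnitude_cm`, `alpha_deg`.
#' @export
error_table <- function(dataset) {
  if (!inherits(dataset, "lt_dataset")) abort("`dataset` must be an `lt_dataset`.")
  trials <- dataset$trials
  if (!"excluded" %in% names(trials)) trials$excluded <- FALSE

  totals <- trials |>
    dplyr::group_by(subject_id) |>
    dplyr::summarise(n_total = max(trial_index), .groups = "drop")

  actual <- dataset$landmarks |>
    dplyr::select(subject_id, landmark, actual_x = x_cm, actual_y = y_cm, handedness)

  err <- trials |>
    dplyr::filter(!excluded) |>
    dplyr::left_join(totals, by = "subject_id") |>
    dplyr::left_join(actual, by = c("subject_id", "landmark"))
  if (anyNA(err$actual_x)) {
    abort("Some trials reference a subject/landmark absent from the landmarks table.")
  }

  err |>
    dplyr::mutate(
      normalized_trial = normalize_trial(trial_index, n_total),
      systematic_error(actual_x, actual_y, perceived_x_cm, perceived_y_cm, handedness)
    ) |>
    add_landmark_factors() |>
    dplyr::select(
      subject_id, trial_index, normalized_trial, landmark, finger, type,
      vx_cm, vy_cm, magnitude_cm, alpha_deg
    )
}
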