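# Perceived hand structure: estimation ratios and the regression of the
# knuckle lateral-error gradient on the hand width ER.

# Landmarks in the canonical (left-equivalent) error frame: error components
# are stored with the right-hand x sign flipped, so right-hand actual
# coordinates are mirrored before perceived positions are rebuilt. Distances
# are unaffected (reflection isometry).
canonical_landmarks <- function(landmarks) {
  landmarks |>
    dplyr::mutate(x_cm = ifelse(handedness == "right", -x_cm, x_cm))
}

#' Trial-averaged perceived landmark positions
#'
#' Rebuilds each subject's perceived landmark positions as the actual
#' position plus the mean error vector over kept trials (in the canonical
#' left-equivalent frame).
#'
#' @param errors An error table from [error_table()].
#' @param landmarks Actual landmark coordinates (all subjects).
#' @return A tibble: `subject_id`, `landmark`, actual and perceived
#'   coordinates in cm.
#' @export
perceived_hand <- function(errors, landmarks) {
  check_errors_table(errors)
  mean_err <- errors |>
    dplyr::group_by(subject_id, landmark) |>
    dplyr::summarise(vx_cm = mean(vx_cm), vy_cm = mean(vy_cm), .groups = "drop")
  canonical_landmarks(landmarks) |>
    dplyr::select(subject_id, landmark, actual_x = x_cm, actual_y = y_cm) |>
    dplyr::inner_join(mean_err, by = c("subject_id", "landmark")) |>
    dplyr::mutate(
      perceived_x_cm = actual_x + vx_cm,
      perceived_y_cm = actual_y + vy_cm
    ) |>
    dplyr::select(subject_id, landmark, actual_x, actual_y, perceived_x_cm, perceived_y_cm)
}

dist2 <- function(x1, y1, x2, y2) sqrt((x1 - x2)^2 + (y1 - y2)^2)

#' Hand-structure estimation ratios
#'
#' The estimation ratio (ER) of a hand dimension is perceived / actual: an
#' ER below 1 means the dimension is underestimated, above 1 overestimated.
#' The hand width uses the Euclidean distance between the index and little
#' knuckles (perceived positions averaged across kept trials); each finger
#' length uses the fingertip--knuckle distance of that finger. Subjects
#' missing a landmark are dropped from the affected metric with a warning.
#'
#' @param errors An error table from [error_table()].
#' @param landmarks Actual landmark coordinates (all subjects).
#' @return A tibble with one row per subject: `width_er`,
#'   `length_er_<finger>` for the five fingers, and `mean_length_er`.
#' @export
#' @examples
#' ds <- generate_dataset(preset_scenarios(n_subjects = 3, n_trials_per_landmark = 4)$sim1_baseline)
#' er <- estimation_ratios(error_table(align_dataset(ds)), ds$landmarks)
estimation_ratios <- function(errors, landmarks) {
  ph <- perceived_hand(errors, landmarks)
  wide <- ph |>
    tidyr::pivot_wider(
      names_from = landmark,
      values_from = c(actual_x, actual_y, perceived_x_cm, perceived_y_cm)
    )

  pair_er <- function(w, a, b) {
    dist2(
      w[[paste0("perceived_x_cm_", a)]], w[[paste0("perceived_y_cm_", a)]],
      w[[paste0("perceived_x_cm_", b)]], w[[paste0("perceived_y_cm_", b)]]
    ) /
      dist2(
        w[[paste0("actual_x_", a)]], w[[paste0("actual_y_", a)]],
        w[[paste0("actual_x_", b)]], w[[paste0("actual_y_", b)]]
      )
  }

  out <- tibble::tibble(subject_id = wide$subject_id)
  out$width_er <- tryCatch(
    pair_er(wide, "index_knuckle", "little_knuckle"),
    error = function(e) rep(NA_real_, nrow(wide))
  )
  for (f in FINGERS) {
    col <- paste0("length_er_", f)
    out[[col]] <- tryCatch(
      pair_er(wide, paste0(f, "_tip"), paste0(f, "_knuckle")),
      error = function(e) rep(NA_real_, nrow(wide))
    )
  }
  out$mean_length_er <- rowMeans(out[paste0("length_er_", FINGERS)])
  if (anyNA(out)) {
    warn("Some subjects are missing landmarks; affected estimation ratios are NA.")
  }
  out
}

#' Regress the hand width ER on the knuckle lateral-error gradient
#'
#' Each subject's slope of the mean medio-lateral error across the four
#' finger knuckles (index to little coded 1 to 4, thumb excluded) is used as
#' a predictor of that subject's hand width estimation ratio in an ordinary
#' least-squares regression. A more negative slope (lateral error growing
#' toward the little knuckle) stretches the perceived index--little segment
#' and predicts a larger width ER.
#'
#' @param errors An error table from [error_table()].
#' @param width_ers A tibble with `subject_id` and `width_er` (e.g. from
#'   [estimation_ratios()]).
#' @param slopes Optional tibble `subject_id`, `slope` (e.g. the per-subject
#'   random slopes from [knuckle_trend_fits()]). When `NULL`, per-subject
#'   OLS slopes of the mean knuckle vx on the 1--4 coding are used.
#' @return An object of class `width_slope_fit` wrapping the `lm`, with the
#'   coefficient, adjusted R^2, t and p in `$summary`.
#' @export
knuckle_slope_predicts_width <- function(errors, width_ers, slopes = NULL) {
  check_errors_table(errors)
  if (is.null(slopes)) {
    slopes <- errors |>
      add_landmark_factors() |>
      dplyr::filter(type == "knuckle", finger != "thumb") |>
      dplyr::mutate(knuckle_pos = as.integer(finger) - 1L) |>
      dplyr::group_by(subject_id, knuckle_pos) |>
      dplyr::summarise(vx_cm = mean(vx_cm), .groups = "drop") |>
      dplyr::group_by(subject_id) |>
      dplyr::summarise(slope = coef(lm(vx_cm ~ knuckle_pos))[["knuckle_pos"]], .groups = "drop")
  }
  d <- dplyr::inner_join(slopes, width_ers[, c("subject_id", "width_er")], by = "subject_id")
  d <- d[stats::complete.cases(d), ]
  if (nrow(d) < 3) abort("At least 3 subjects with slope and width ER are required.")
  fit <- lm(width_er ~ slope, data = d)
  s <- summary(fit)
  structure(
    list(
      model = fit,
      data = d,
      summary = tibble::tibble(
        term = "slope",
        estimate = coef(fit)[["slope"]],
        adj_r_squared = s$adj.r.squared,
        statistic = s$coefficients["slope", "t value"],
        df = fit$df.residual,
        p_value = s$coefficients["slope", "Pr(>|t|)"]
      )
    ),
    class = "width_slope_fit"
  )
}

#' @exportS3Method
print.width_slope_fit <- function(x, ...) {
  cat("<width_slope_fit> hand width ER ~ knuckle lateral-error slope\n")
  print(x$summary)
  invisible(x)
}
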