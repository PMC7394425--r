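# Spatial preprocessing: unit conversion, knuckle-line alignment,
# Mahalanobis/chi-square outlier exclusion.

#' Convert pixel coordinates to cm
#'
#' Divides coordinates by the conversion index (pixels per cm).
#'
#' @param x A numeric vector/matrix, or a data frame.
#' @param conversion_index Pixels per cm (> 0).
#' @param cols For data frames, the coordinate columns to convert.
#' @return `x` with the coordinates divided by `conversion_index`.
#' @export
#' @examples
#' to_cm(c(100, 50), 10)
to_cm <- function(x, conversion_index, cols = NULL) {
  stop_if_not_scalar_pos(conversion_index, "conversion_index")
  if (is.data.frame(x)) {
    if (is.null(cols)) abort("`cols` must name the coordinate columns of a data frame.")
    x[cols] <- lapply(x[cols], function(v) v / conversion_index)
    return(x)
  }
  x / conversion_index
}

#' Compute the alignment transform for one subject's hand
#'
#' Builds the rigid transform that re-centres the coordinates on the midpoint
#' of the actual index--little knuckle segment and rotates the hand so that
#' this segment lies on the horizontal axis. For a left hand the index
#' knuckle ends up at positive x (medial side); a right hand is handled
#' mirror-symmetrically, so fingertips lie at positive y for both. The
#' transform is a proper rotation (determinant +1) and preserves all pairwise
#' distances.
#'
#' @param landmarks One subject's actual landmarks (tibble with `landmark`,
#'   `x_cm`, `y_cm` and a `handedness` column).
#' @return An object of class `alignment_transform`: list with `origin`
#'   (length-2 shift), `angle` (radians) and `rotation` (2x2 matrix).
#' @export
compute_alignment <- function(landmarks) {
  idx <- landmarks[landmarks$landmark == "index_knuckle", ]
  lit <- landmarks[landmarks$landmark == "little_knuckle", ]
  if (nrow(idx) != 1L || nrow(lit) != 1L) {
    abort("`landmarks` must contain exactly one index_knuckle and one little_knuckle row.")
  }
  p_idx <- c(idx$x_cm, idx$y_cm)
  p_lit <- c(lit$x_cm, lit$y_cm)
  if (sqrt(sum((p_idx - p_lit)^2)) < 1e-12) {
    abort("Degenerate geometry: index and little knuckles coincide.")
  }
  handed <- if ("handedness" %in% names(landmarks)) landmarks$handedness[1] else "left"
  # align little->index (left) or index->little (right) with the +x axis
  d <- if (identical(handed, "right")) p_lit - p_idx else p_idx - p_lit
  angle <- -atan2(d[2], d[1])
  rot <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2, 2)
  structure(
    list(origin = (p_idx + p_lit) / 2, angle = angle, rotation = rot),
    class = "alignment_transform"
  )
}

#' @exportS3Method
print.alignment_transform <- function(x, ...) {
  cat(sprintf(
    "<alignment_transform> shift (%.3f, %.3f) cm, rotation %.3f deg\n",
    -x$origin[1], -x$origin[2], rad2deg(x$angle)
  ))
  invisible(x)
}

apply_transform_xy <- function(transform, x, y) {
  dx <- x - transform$origin[1]
  dy <- y - transform$origin[2]
  list(
    x = transform$rotation[1, 1] * dx + transform$rotation[1, 2] * dy,
    y = transform$rotation[2, 1] * dx + transform$rotation[2, 2] * dy
  )
}

#' Apply an alignment transform to a dataset
#'
#' Applies the same shift and rotation to the actual and the perceived
#' coordinates, so error vectors are rotated but magnitude-invariant.
#' `apply_alignment()` applies one given transform (single-subject data);
#' [align_dataset()] computes and applies each subject's own transform.
#'
#' @param dataset An `lt_dataset`.
#' @param transform An `alignment_transform` from [compute_alignment()].
#' @return The dataset with transformed coordinates.
#' @export
apply_alignment <- function(dataset, transform) {
  if (!inherits(transform, "alignment_transform")) {
    abort("`transform` must come from `compute_alignment()`.")
  }
  lm_xy <- apply_transform_xy(transform, dataset$landmarks$x_cm, dataset$landmarks$y_cm)
  dataset$landmarks$x_cm <- lm_xy$x
  dataset$landmarks$y_cm <- lm_xy$y
  tr_xy <- apply_transform_xy(transform, dataset$trials$perceived_x_cm, dataset$trials$perceived_y_cm)
  dataset$trials$perceived_x_cm <- tr_xy$x
  dataset$trials$perceived_y_cm <- tr_xy$y
  dataset
}

#' @rdname apply_alignment
#' @export
align_dataset <- function(dataset) {
  if (!inherits(dataset, "lt_dataset")) abort("`dataset` must be an `lt_dataset`.")
  subjects <- unique(dataset$landmarks$subject_id)
  lm_parts <- list()
  tr_parts <- list()
  for (s in subjects) {
    sub <- list(
      landmarks = dataset$landmarks[dataset$landmarks$subject_id == s, ],
      trials = dataset$trials[dataset$trials$subject_id == s, ]
    )
    tr <- compute_alignment(sub$landmarks)
    sub <- apply_alignment(structure(sub, class = "lt_dataset"), tr)
    lm_parts[[s]] <- sub$landmarks
    tr_parts[[s]] <- sub$trials
  }
  dataset$landmarks <- dplyr::bind_rows(lm_parts)
  dataset$trials <- dplyr::bind_rows(tr_parts)
  dataset
}

#' Mahalanobis / chi-square outlier filter
#'
#' For each subject x landmark cell, computes every trial's squared
#' Mahalanobis distance from that cell's sample mean using the unbiased
#' sample covariance (single pass: one estimate, one exclusion sweep), and
#' flags trials whose distance exceeds the 95th percentile of a chi-square
#' distribution with 2 degrees of freedom.
#'
#' Cells with fewer than `min_trials` trials pass through unfiltered with a
#' warning; a singular covariance (e.g. identical or collinear points) is an
#' error naming the offending cell.
#'
#' @param x An `lt_dataset` or a trials tibble (`subject_id`, `landmark`,
#'   `perceived_x_cm`, `perceived_y_cm`).
#' @param level Chi-square quantile used as the exclusion threshold.
#' @param min_trials Minimum trials per cell for the filter to run.
#' @return Input with logical `excluded` and numeric `mahalanobis_sq` columns
#'   added to the trials.
#' @export
mahalanobis_filter <- function(x, level = 0.95, min_trials = 3L) {
  trials <- if (inherits(x, "lt_dataset")) x$trials else tibble::as_tibble(x)
  threshold <- qchisq(level, df = 2)

  cell_dist <- function(px, py, grp) {
    if (length(px) < min_trials) {
      warn(sprintf(
        "Cell %s/%s has %d trial(s) (< %d): passed through unfiltered.",
        grp$subject_id, grp$landmark, length(px), min_trials
      ))
      return(rep(NA_real_, length(px)))
    }
    m <- cbind(px, py)
    S <- cov(m) # unbiased (n - 1) estimator
    if (!is.finite(det(S)) || abs(det(S)) < 1e-12) {
      abort(sprintf(
        "Degenerate covariance for subject %s, landmark %s (identical or collinear points).",
        grp$subject_id, grp$landmark
      ))
    }
    mahalanobis(m, colMeans(m), S)
  }

  trials <- trials |>
    dplyr::group_by(subject_id, landmark) |>
    dplyr::mutate(
      mahalanobis_sq = cell_dist(perceived_x_cm, perceived_y_cm, dplyr::cur_group()),
      excluded = !is.na(mahalanobis_sq) & mahalanobis_sq > threshold
    ) |>
    dplyr::ungroup() |>
    dplyr::arrange(subject_id, trial_index)

  if (inherits(x, "lt_dataset")) {
    x$trials <- trials
    x
  } else {
    trials
  }
}
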