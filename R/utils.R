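# Shared vocabulary and small numeric helpers.

FINGERS <- c("thumb", "index", "middle", "ring", "little")
LANDMARK_TYPES <- c("fingertip", "knuckle")

#' Canonical hand-landmark labels
#'
#' The ten landmarks probed in the hand Localization Task: the five fingertips
#' and the five knuckles (metacarpophalangeal joints), in canonical order
#' (thumb to little, fingertips first).
#'
#' @return Character vector of the 10 landmark labels.
#' @export
#' @examples
#' hand_landmark_labels()
hand_landmark_labels <- function() {
  c(paste0(FINGERS, "_tip"), paste0(FINGERS, "_knuckle"))
}

#' Landmark metadata table
#'
#' Maps each landmark label to its finger (thumb--little) and type
#' (fingertip/knuckle), the two factors used throughout the analyses.
#'
#' @return A tibble with columns `landmark`, `finger`, `type`.
#' @export
landmark_info <- function() {
  tibble::tibble(
    landmark = hand_landmark_labels(),
    finger = factor(rep(FINGERS, 2), levels = FINGERS),
    type = factor(rep(LANDMARK_TYPES, each = 5), levels = LANDMARK_TYPES)
  )
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# wrap angles (degrees) to [0, 360)
wrap_deg <- function(x) {
  out <- x %% 360
  out[out == 360] <- 0
  out
}

stop_if_not_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    abort(sprintf("`%s` must be a single positive finite number.", name))
  }
  invisible(x)
}

check_errors_table <- function(errors) {
  needed <- c("subject_id", "landmark", "vx_cm", "vy_cm")
  missing <- setdiff(needed, names(errors))
  if (length(missing) > 0) {
    abort(paste0(
      "`errors` is missing column(s): ", paste(missing, collapse = ", "),
      ". Did you run `error_table()`?"
    ))
  }
  invisible(errors)
}

# attach finger/type factors if absent
add_landmark_factors <- function(df) {
  if (all(c("finger", "type") %in% names(df))) {
    df$finger <- factor(df$finger, levels = FINGERS)
    df$type <- factor(df$type, levels = LANDMARK_TYPES)
    return(df)
  }
  df |>
    dplyr::select(-dplyr::any_of(c("finger", "type"))) |>
    dplyr::left_join(landmark_info(), by = "landmark")
}
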