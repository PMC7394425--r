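#' Build a plausible hand-landmark layout
#'
#' Generates actual landmark coordinates (in cm) for one hand, laid out in the
#' analysis frame: the index--little knuckle segment is horizontal and centred
#' on the origin, fingertips point distally (positive y). For a left hand the
#' index knuckle lies at positive x (medial side, toward the body midline) and
#' the little knuckle at negative x; a right hand is the mirror image about
#' the vertical axis.
#'
#' The layout is constructed so that the index--little knuckle distance equals
#' `hand_width` exactly and the mean fingertip--knuckle distance over the five
#' fingers equals `mean_finger_length` exactly. Relative finger lengths and
#' the knuckle arc follow typical adult hand proportions. Defaults are the
#' sample averages of the study this package models (7.526 cm mean finger
#' length, 6.039 cm hand width).
#'
#' @param mean_finger_length Mean fingertip-to-knuckle distance in cm (> 0).
#' @param hand_width Index-to-little knuckle distance in cm (> 0).
#' @param handedness `"left"` or `"right"`.
#' @param subject_id Identifier stored in the output table.
#' @return A tibble with columns `subject_id`, `handedness`, `landmark`,
#'   `x_cm`, `y_cm` (10 rows, one per landmark).
#' @export
#' @examples
#' hand <- make_hand_template()
#' hand
make_hand_template <- function(mean_finger_length = 7.526,
                               hand_width = 6.039,
                               handedness = c("left", "right"),
                               subject_id = "template") {
  handedness <- match.arg(handedness)
  stop_if_not_scalar_pos(mean_finger_length, "mean_finger_length")
  stop_if_not_scalar_pos(hand_width, "hand_width")

  w <- hand_width
  L <- mean_finger_length

  # relative finger lengths (thumb..little), rescaled so their mean is exactly 1
  rel <- c(0.72, 0.98, 1.08, 1.02, 0.80)
  rel <- rel / mean(rel)
  len <- rel * L

  # knuckles: index..little spaced along a shallow arc spanning `w`;
  # index and little share y = 0 so their distance is exactly `w`
  kx <- c(w / 2, w / 6, -w / 6, -w / 2)
  ky <- c(0, 0.06, 0.04, 0) * w
  # thumb knuckle offset medially (+x for a left hand) and proximally
  thumb_kn <- c(0.85 * w, -0.55 * w)

  # fingertips: distal from each knuckle with a slight outward splay
  # (angles measured from the +y axis, positive toward +x / medial side)
  splay <- deg2rad(c(6, 0, -6, -14))
  tips_x <- kx + len[2:5] * sin(splay)
  tips_y <- ky + len[2:5] * cos(splay)
  # thumb points medially and distally
  thumb_dir <- deg2rad(50) # from +x axis
  thumb_tip <- thumb_kn + len[1] * c(cos(thumb_dir), sin(thumb_dir))

  coords <- tibble::tibble(
    landmark = hand_landmark_labels(),
    x_cm = c(thumb_tip[1], tips_x, thumb_kn[1], kx),
    y_cm = c(thumb_tip[2], tips_y, thumb_kn[2], ky)
  )
  if (handedness == "right") coords$x_cm <- -coords$x_cm

  tibble::tibble(
    subject_id = subject_id,
    handedness = handedness,
    coords
  )
}
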