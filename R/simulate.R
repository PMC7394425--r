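# Synthetic Localization Task data: per-landmark mean error vectors with
# controlled angle consistency, multi-level Gaussian noise, and proximal drift.

#' Simulation parameters for the synthetic Localization Task generator
#'
#' Bundles the per-landmark error parameters (mean magnitude, most frequent
#' direction, angle consistency) with the noise scales, drift, counts and seed
#' that [generate_dataset()] needs.
#'
#' @param landmark_params A data frame with one row per landmark and columns
#'   `landmark`, `magnitude` (mean error-vector magnitude, cm),
#'   `theta_deg` (most frequent error direction, degrees, wrapped to
#'   \[0, 360)), `consistency` (target angle consistency r in \[0, 1\]).
#'   All 10 canonical landmarks must be present.
#' @param subject_sd Inter-individual noise: SD (cm) of the bivariate Gaussian
#'   offset added to every landmark's mean error vector, drawn once per
#'   subject.
#' @param landmark_sd Inter-landmark noise: SD (cm) of the offset drawn once
#'   per subject and landmark.
#' @param trial_sd Inter-trial noise: SD (cm) of the Gaussian perturbation of
#'   the trial error magnitude (reflected at 0, so magnitudes stay
#'   non-negative without an atom of exact hits).
#' @param drift_slope Proximo-distal drift in cm per 100 normalized trials
#'   (signed; negative = proximal drift toward the body).
#' @param n_subjects,n_trials_per_landmark Counts (>= 1).
#' @param hand_template Actual landmark coordinates shared by all simulated
#'   subjects, as returned by [make_hand_template()].
#' @param seed Integer root seed; per-subject substreams are derived from it.
#' @return An object of class `sim_params`.
#' @seealso [preset_scenarios()] for ready-made parameter sets.
#' @export
sim_params <- function(landmark_params,
                       subject_sd = 0.3,
                       landmark_sd = 0.2,
                       trial_sd = 0.8,
                       drift_slope = 0,
                       n_subjects = 20,
                       n_trials_per_landmark = 16,
                       hand_template = make_hand_template(),
                       seed = 1L) {
  landmark_params <- tibble::as_tibble(landmark_params)
  needed <- c("landmark", "magnitude", "theta_deg", "consistency")
  if (!all(needed %in% names(landmark_params))) {
    abort(paste("`landmark_params` needs columns:", paste(needed, collapse = ", ")))
  }
  if (!setequal(landmark_params$landmark, hand_landmark_labels()) ||
      nrow(landmark_params) != 10L) {
    abort("`landmark_params` must contain exactly the 10 canonical landmarks.")
  }
  if (any(landmark_params$consistency < 0 | landmark_params$consistency > 1)) {
    abort("`consistency` must lie in [0, 1].")
  }
  if (any(landmark_params$magnitude < 0)) abort("`magnitude` must be >= 0.")
  for (nm in c("subject_sd", "landmark_sd", "trial_sd")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || v < 0) {
      abort(sprintf("`%s` must be a single number >= 0.", nm))
    }
  }
  if (n_subjects < 1 || n_trials_per_landmark < 1) {
    abort("`n_subjects` and `n_trials_per_landmark` must be >= 1.")
  }
  landmark_params$theta_deg <- wrap_deg(landmark_params$theta_deg)
  # fixed canonical row order so the RNG stream is reproducible
  landmark_params <- landmark_params[
    match(hand_landmark_labels(), landmark_params$landmark),
  ]

  structure(
    list(
      landmark_params = landmark_params,
      subject_sd = subject_sd,
      landmark_sd = landmark_sd,
      trial_sd = trial_sd,
      drift_slope = drift_slope,
      n_subjects = as.integer(n_subjects),
      n_trials_per_landmark = as.integer(n_trials_per_landmark),
      hand_template = hand_template,
      seed = as.integer(seed)
    ),
    class = "sim_params"
  )
}

#' @exportS3Method
print.sim_params <- function(x, ...) {
  cat(sprintf(
    "<sim_params> %d subjects x %d trials/landmark (seed %d)\n",
    x$n_subjects, x$n_trials_per_landmark, x$seed
  ))
  cat(sprintf(
    "  noise sd (subject/landmark/trial): %.2f / %.2f / %.2f cm; drift %.2f cm per 100 trials\n",
    x$subject_sd, x$landmark_sd, x$trial_sd, x$drift_slope
  ))
  print(x$landmark_params, n = 10)
  invisible(x)
}

# --- von Mises machinery ----------------------------------------------------

# Concentration kappa whose population mean resultant length I1(k)/I0(k)
# equals r. Exponentially-scaled Bessel ratios keep this stable at large kappa.
vm_kappa <- function(r) {
  if (r < 0 || r > 1) abort("`r` must lie in [0, 1].")
  if (r == 0) return(0)
  if (r >= 1) return(Inf)
  ratio <- function(k) besselI(k, 1, expon.scaled = TRUE) /
    besselI(k, 0, expon.scaled = TRUE)
  if (r > 0.9999) return(1 / (2 * (1 - r))) # asymptotic: A(k) ~ 1 - 1/(2k)
  upper <- 10
  while (ratio(upper) < r) upper <- upper * 10
  uniroot(function(k) ratio(k) - r, c(1e-10, upper), tol = 1e-12)$root
}

# Best & Fisher (1979) rejection sampler; radians in, radians out.
rvonmises_rad <- function(n, mu, kappa) {
  if (kappa == 0) return(runif(n, 0, 2 * pi))
  if (!is.finite(kappa)) return(rep(mu %% (2 * pi), n))
  if (kappa > 5e5) {
    # wrapped-normal limit; negligible wrapping mass at this concentration
    return((rnorm(n, mu, 1 / sqrt(kappa))) %% (2 * pi))
  }
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    c_ <- kappa * (r - f)
    if (c_ * (2 - c_) - u[2] > 0 || log(c_ / u[2]) + 1 - c_ >= 0) {
      out[i] <- (mu + sign(u[3] - 0.5) * acos(f)) %% (2 * pi)
      i <- i + 1L
    }
  }
  out
}

#' Sample error directions with a target angle consistency
#'
#' Draws `n` directions from a von Mises distribution centred on `theta` whose
#' concentration is chosen (by inverting the Bessel-function ratio
#' I1(k)/I0(k) = r) so that the population mean resultant length — hence the
#' expected ITPC of a large sample — equals `r`. `r = 1` returns `n` copies of
#' `theta`; `r = 0` returns uniform directions.
#'
#' @param theta Circular mean direction, degrees.
#' @param r Target angle consistency in \[0, 1\].
#' @param n Number of draws (>= 1).
#' @return Numeric vector of `n` angles in degrees, wrapped to \[0, 360).
#' @export
#' @examples
#' set.seed(1)
#' a <- sample_error_angles(240, 0.9, 1000)
#' itpc(a)$itpc # close to 0.9
sample_error_angles <- function(theta, r, n) {
  if (!is.numeric(r) || length(r) != 1L || r < 0 || r > 1) {
    abort("`r` must be a single number in [0, 1].")
  }
  if (n < 1) abort("`n` must be >= 1.")
  if (r == 1) return(rep(wrap_deg(theta), n))
  wrap_deg(rad2deg(rvonmises_rad(n, deg2rad(theta), vm_kappa(r))))
}

# --- dataset generation -----------------------------------------------------

#' Generate a synthetic Localization Task dataset
#'
#' For each subject, a bivariate Gaussian subject-level offset (scale
#' `subject_sd`) is added to every landmark's mean error vector, then a
#' landmark-level offset (scale `landmark_sd`). Each trial samples a direction
#' via [sample_error_angles()] around the resulting per-subject, per-landmark
#' direction, a magnitude perturbed at scale `trial_sd` (reflected at 0), and
#' a proximo-distal drift of `drift_slope` x (normalized trial / 100). The
#' perceived position is the actual landmark position plus this error. Trials
#' are emitted in randomized landmark order; the output is bit-for-bit
#' reproducible for a given seed.
#'
#' @param params A [sim_params()] object.
#' @return An object of class `lt_dataset`: a list with tibbles `landmarks`
#'   (actual coordinates per subject) and `trials` (perceived coordinates per
#'   trial), `conversion_index = 1` (coordinates already in cm),
#'   `provenance = "synthetic"`, and the `params` used.
#' @export
#' @examples
#' ps <- preset_scenarios(n_subjects = 2, n_trials_per_landmark = 4)
#' ds <- generate_dataset(ps$sim1_baseline)
#' ds$trials
generate_dataset <- function(params) {
  if (!inherits(params, "sim_params")) abort("`params` must be a `sim_params` object.")
  lp <- params$landmark_params
  labels <- lp$landmark
  n_trials <- params$n_trials_per_landmark
  total <- 10L * n_trials

  set.seed(params$seed)
  subject_seeds <- sample.int(.Machine$integer.max - 1L, params$n_subjects)
  subject_ids <- sprintf("S%03d", seq_len(params$n_subjects))

  hand <- params$hand_template
  actual <- setNames(
    lapply(labels, function(l) {
      r <- hand[hand$landmark == l, ]
      c(r$x_cm, r$y_cm)
    }),
    labels
  )
  mean_vec <- lapply(seq_len(10L), function(i) {
    lp$magnitude[i] * c(cos(deg2rad(lp$theta_deg[i])), sin(deg2rad(lp$theta_deg[i])))
  })

  one_subject <- function(s) {
    set.seed(subject_seeds[s])
    d_subj <- rnorm(2, 0, params$subject_sd)
    # per-landmark mean error vector after subject- and landmark-level noise
    v_sl <- lapply(seq_len(10L), function(i) {
      mean_vec[[i]] + d_subj + rnorm(2, 0, params$landmark_sd)
    })
    # randomized presentation order
    order_lm <- sample(rep.int(seq_len(10L), n_trials))
    trial_of_landmark <- split(seq_len(total), order_lm)

    px <- numeric(total)
    py <- numeric(total)
    for (i in seq_len(10L)) {
      v <- v_sl[[i]]
      M <- sqrt(sum(v^2))
      th <- if (M > 0) wrap_deg(rad2deg(atan2(v[2], v[1]))) else lp$theta_deg[i]
      alpha <- deg2rad(sample_error_angles(th, lp$consistency[i], n_trials))
      mag <- abs(M + rnorm(n_trials, 0, params$trial_sd))
      idx <- trial_of_landmark[[as.character(i)]]
      nt <- 100 * idx / total
      a <- actual[[labels[i]]]
      px[idx] <- a[1] + mag * cos(alpha)
      py[idx] <- a[2] + mag * sin(alpha) + params$drift_slope * nt / 100
    }
    tibble::tibble(
      subject_id = subject_ids[s],
      trial_index = seq_len(total),
      landmark = labels[order_lm],
      perceived_x_cm = px,
      perceived_y_cm = py
    )
  }

  trials <- purrr::map_dfr(seq_len(params$n_subjects), one_subject)
  landmarks <- purrr::map_dfr(subject_ids, function(id) {
    dplyr::mutate(hand, subject_id = id)
  })

  structure(
    list(
      landmarks = landmarks,
      trials = trials,
      conversion_index = 1,
      provenance = "synthetic",
      params = params
    ),
    class = "lt_dataset"
  )
}

#' @exportS3Method
print.lt_dataset <- function(x, ...) {
  cat(sprintf(
    "<lt_dataset> %s: %d subject(s), %d trial(s)\n",
    x$provenance,
    dplyr::n_distinct(x$landmarks$subject_id),
    nrow(x$trials)
  ))
  invisible(x)
}

# --- presets ----------------------------------------------------------------

# helper: per-landmark parameter rows from mean (vx, vy) components and r
lp_from_components <- function(vx, vy, r) {
  tibble::tibble(
    landmark = hand_landmark_labels(),
    magnitude = sqrt(vx^2 + vy^2),
    theta_deg = wrap_deg(rad2deg(atan2(vy, vx))),
    consistency = r
  )
}

#' Preset simulation scenarios
#'
#' Named [sim_params()] presets spanning the qualitative regimes of interest:
#' a baseline calibrated to the published group-level error pattern
#' (fingertip errors large, proximal and lateral with high angle consistency;
#' knuckle errors small with an index-to-little lateral gradient; proximal
#' drift over trials) and variants that alter magnitude, consistency or
#' direction per landmark class. Two diagnostic presets are included: `null`
#' (no systematic error, for calibration checks) and `no_gradient` (knuckle
#' lateral errors equal across fingers, so the hand width is unbiased).
#' Numeric values are approximations chosen from the published group
#' statistics, not a transcription of any specific study's parameters.
#'
#' @param n_subjects,n_trials_per_landmark,seed Shared counts and seed for all
#'   presets.
#' @return Named list of `sim_params` objects (>= 7 scenario presets plus the
#'   two diagnostics).
#' @export
preset_scenarios <- function(n_subjects = 20, n_trials_per_landmark = 16, seed = 1L) {
  # mean components (cm), order: tips thumb..little, knuckles thumb..little
  tip_vx <- c(-1.3, -1.0, -1.1, -1.8, -1.6)
  tip_vy <- c(-3.3, -3.3, -3.3, -3.3, -3.3)
  kn_vx <- c(-0.60, 0.25, -0.25, -0.70, -1.10) # index medial, little most lateral
  kn_vy <- rep(-0.6, 5)
  r_tip <- 0.98
  r_kn <- 0.90

  base <- function(lp, ...) {
    sim_params(
      lp,
      subject_sd = 0.5, landmark_sd = 0.2, trial_sd = 1,
      n_subjects = n_subjects, n_trials_per_landmark = n_trials_per_landmark,
      seed = seed, ...
    )
  }

  list(
    # 1: paper-like baseline
    sim1_baseline = base(
      lp_from_components(c(tip_vx, kn_vx), c(tip_vy, kn_vy), c(rep(r_tip, 5), rep(r_kn, 5))),
      drift_slope = -0.3
    ),
    # 2: same mean structure, lower consistency and larger raw magnitudes
    sim2_low_consistency = base(
      lp_from_components(
        c(tip_vx, kn_vx) * 1.25, c(tip_vy, kn_vy) * 1.25,
        c(rep(0.80, 5), rep(0.72, 5))
      ),
      drift_slope = -0.3
    ),
    # 3: greater knuckle errors (reduced finger-length underestimation)
    sim3_large_knuckle_errors = base(
      lp_from_components(
        c(tip_vx, kn_vx * 1.5), c(tip_vy, kn_vy - 1.6),
        c(rep(r_tip, 5), rep(r_kn, 5))
      ),
      drift_slope = -0.3
    ),
    # 4: reduced fingertip angle consistency
    sim4_low_tip_consistency = base(
      lp_from_components(c(tip_vx, kn_vx), c(tip_vy, kn_vy), c(rep(0.60, 5), rep(r_kn, 5))),
      drift_slope = -0.3
    ),
    # 5: whole error field rotated by 30 degrees (same magnitudes)
    sim5_rotated_direction = {
      th <- deg2rad(30)
      vx <- c(tip_vx, kn_vx) * cos(th) - c(tip_vy, kn_vy) * sin(th)
      vy <- c(tip_vx, kn_vx) * sin(th) + c(tip_vy, kn_vy) * cos(th)
      base(
        lp_from_components(vx, vy, c(rep(r_tip, 5), rep(r_kn, 5))),
        drift_slope = -0.3
      )
    },
    # 6: doubled knuckle lateral gradient (stronger width overestimation)
    sim6_steep_knuckle_gradient = base(
      lp_from_components(
        c(tip_vx, c(-0.60, 0.70, -0.30, -1.30, -2.30)), c(tip_vy, kn_vy),
        c(rep(r_tip, 5), rep(r_kn, 5))
      ),
      drift_slope = -0.3
    ),
    # 7: knuckle errors point outward from the hand midline (width inflation
    # through direction rather than a lateral-magnitude gradient)
    sim7_outward_knuckles = base(
      lp_from_components(
        c(tip_vx, c(-0.60, 1.20, 0.00, -0.80, -1.60)), c(tip_vy, kn_vy),
        c(rep(r_tip, 5), rep(r_kn, 5))
      ),
      drift_slope = -0.3
    ),
    # diagnostics
    null = sim_params(
      lp_from_components(rep(0, 10), rep(0, 10), 0.5),
      subject_sd = 0.5, landmark_sd = 0, trial_sd = 1, drift_slope = 0,
      n_subjects = n_subjects, n_trials_per_landmark = n_trials_per_landmark,
      seed = seed
    ),
    no_gradient = base(
      lp_from_components(c(tip_vx, rep(-0.6, 5)), c(tip_vy, kn_vy), c(rep(r_tip, 5), rep(r_kn, 5))),
      drift_slope = 0
    )
  )
}

# --- I/O --------------------------------------------------------------------

#' Write / read a Localization Task dataset as CSV tables
#'
#' `write_dataset()` writes `landmarks.csv` (subject_id, landmark, x_cm, y_cm,
#' handedness) and `trials.csv` (subject_id, trial_index, landmark,
#' perceived_x_cm, perceived_y_cm) to `dir`, plus a `params.json` sidecar when
#' the dataset is synthetic. `read_dataset()` reads them back; pixel-space
#' coordinates are converted to cm with `conversion_index` (pixels per cm).
#'
#' @param dataset An `lt_dataset`.
#' @param dir Directory path.
#' @param units `"cm"` (default) or `"px"`.
#' @param conversion_index Pixels per cm, used when `units = "px"`.
#' @return `write_dataset()` returns `dir` invisibly; `read_dataset()` returns
#'   an `lt_dataset`.
#' @export
write_dataset <- function(dataset, dir) {
  if (!inherits(dataset, "lt_dataset")) abort("`dataset` must be an `lt_dataset`.")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(
    dataset$landmarks[, c("subject_id", "landmark", "x_cm", "y_cm", "handedness")],
    file.path(dir, "landmarks.csv")
  )
  readr::write_csv(
    dataset$trials[, c("subject_id", "trial_index", "landmark", "perceived_x_cm", "perceived_y_cm")],
    file.path(dir, "trials.csv")
  )
  if (identical(dataset$provenance, "synthetic") && !is.null(dataset$params)) {
    p <- dataset$params
    jsonlite::write_json(
      list(
        landmark_params = p$landmark_params,
        subject_sd = p$subject_sd, landmark_sd = p$landmark_sd,
        trial_sd = p$trial_sd, drift_slope = p$drift_slope,
        n_subjects = p$n_subjects, n_trials_per_landmark = p$n_trials_per_landmark,
        seed = p$seed
      ),
      file.path(dir, "params.json"),
      auto_unbox = TRUE, digits = NA
    )
  }
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir, units = c("cm", "px"), conversion_index = 1) {
  units <- match.arg(units)
  landmarks <- readr::read_csv(file.path(dir, "landmarks.csv"), show_col_types = FALSE)
  trials <- readr::read_csv(file.path(dir, "trials.csv"), show_col_types = FALSE)
  if (units == "px") {
    landmarks <- to_cm(landmarks, conversion_index, cols = c("x_cm", "y_cm"))
    trials <- to_cm(trials, conversion_index, cols = c("perceived_x_cm", "perceived_y_cm"))
  }
  structure(
    list(
      landmarks = tibble::as_tibble(landmarks),
      trials = tibble::as_tibble(trials),
      conversion_index = if (units == "px") conversion_index else 1,
      provenance = "imported",
      params = NULL
    ),
    class = "lt_dataset"
  )
}
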