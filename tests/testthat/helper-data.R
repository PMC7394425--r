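# Shared builders and independent oracles for the test suite.

# Brute-force ITPC oracle: explicit loop over complex exponentials,
# independent of the package implementation.
brute_itpc <- function(angles_deg) {
  angles_deg <- angles_deg[!is.na(angles_deg)]
  acc <- 0 + 0i
  for (a in angles_deg) acc <- acc + exp(1i * a * pi / 180)
  Mod(acc / length(angles_deg))
}

# Uniform per-landmark parameter table.
flat_params <- function(magnitude = 0, theta = 0, r = 0.5) {
  tibble::tibble(
    landmark = hand_landmark_labels(),
    magnitude = magnitude, theta_deg = theta, consistency = r
  )
}

# A dataset with no systematic error and no noise: perceived == actual.
zero_dataset <- function(n_subjects = 3, n_trials = 4, seed = 11) {
  generate_dataset(sim_params(
    flat_params(0, 0, 0.5),
    subject_sd = 0, landmark_sd = 0, trial_sd = 0, drift_slope = 0,
    n_subjects = n_subjects, n_trials_per_landmark = n_trials, seed = seed
  ))
}

# Generator -> aligned, filtered error table in one step.
errors_from <- function(params) {
  ds <- generate_dataset(params)
  ds <- mahalanobis_filter(align_dataset(ds))
  list(errors = error_table(ds), dataset = ds)
}

# Hand-constructed error table: one "trial" per subject x landmark holding
# the per-subject mean error components (enough for PCA/structure stages).
errors_from_means <- function(vx_matrix, vy_matrix = NULL, subjects = NULL) {
  labels <- hand_landmark_labels()
  n <- nrow(vx_matrix)
  subjects <- subjects %||% sprintf("S%03d", seq_len(n))
  if (is.null(vy_matrix)) vy_matrix <- matrix(0, n, 10)
  purrr::map_dfr(seq_len(n), function(i) {
    tibble::tibble(
      subject_id = subjects[i],
      trial_index = seq_len(10L),
      normalized_trial = 100 * seq_len(10L) / 10,
      landmark = labels,
      vx_cm = vx_matrix[i, ],
      vy_cm = vy_matrix[i, ]
    )
  }) |>
    dplyr::mutate(
      magnitude_cm = sqrt(vx_cm^2 + vy_cm^2),
      alpha_deg = ifelse(magnitude_cm > 0,
        (atan2(vy_cm, vx_cm) * 180 / pi) %% 360, NA_real_
      )
    ) |>
    dplyr::left_join(landmark_info(), by = "landmark")
}

# Landmarks table for n copies of the default template.
template_landmarks <- function(subjects) {
  purrr::map_dfr(subjects, function(s) {
    h <- make_hand_template(subject_id = s)
    h
  })
}

`%||%` <- rlang::`%||%`
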