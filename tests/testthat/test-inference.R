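test_that("the LMM recovers injected type means and reports the full factorial", {
  lp <- tibble::tibble(
    landmark = hand_landmark_labels(),
    magnitude = rep(c(3.3, 0.6), each = 5),
    theta_deg = 270,
    consistency = 0.99
  )
  ps <- sim_params(lp,
    subject_sd = 0.3, landmark_sd = 0.1, trial_sd = 0.5,
    n_subjects = 12, n_trials_per_landmark = 16, seed = 111
  )
  err <- errors_from(ps)$errors
  fit <- fit_component_lmm(err, "vy", emm_at = 0)

  expect_setequal(
    fit$anova$term,
    c("finger", "type", "normalized_trial", "finger:type",
      "finger:normalized_trial", "type:normalized_trial",
      "finger:type:normalized_trial")
  )
  p_type <- fit$anova$p_value[fit$anova$term == "type"]
  expect_lt(p_type, 0.001)

  emm <- fit$emmeans$type
  d <- emm$emmean[emm$type == "fingertip"] - emm$emmean[emm$type == "knuckle"]
  expect_lt(abs(d - (-2.7)), 0.25)
  expect_equal(fit$n_comparisons, choose(10, 2))
})

test_that("a drift-only generator produces a trial effect but no type interaction", {
  ps <- sim_params(flat_params(0, 0, 0.5),
    subject_sd = 0.2, landmark_sd = 0, trial_sd = 1, drift_slope = -1.5,
    n_subjects = 12, n_trials_per_landmark = 16, seed = 112
  )
  err <- errors_from(ps)$errors
  fit <- fit_component_lmm(err, "vy")
  a <- fit$anova
  expect_lt(a$p_value[a$term == "normalized_trial"], 0.05)
  expect_gt(a$p_value[a$term == "type:normalized_trial"], 0.05)
  # marginal slope close to the injected -1.5 cm per 100 normalized trials
  expect_lt(abs(fit$trend$normalized_trial.trend - (-0.015)), 0.005)
})

test_that("omnibus statistics are invariant to factor level relabeling", {
  ps <- sim_params(flat_params(1, 240, 0.9),
    subject_sd = 0.3, landmark_sd = 0.2, trial_sd = 0.8,
    n_subjects = 6, n_trials_per_landmark = 8, seed = 113
  )
  err <- errors_from(ps)$errors
  f1 <- fit_component_lmm(err, "vx", random = "intercepts")
  err2 <- dplyr::mutate(err,
    finger = factor(finger, levels = rev(levels(finger))),
    type = factor(type, levels = rev(levels(type)))
  )
  f2 <- fit_component_lmm(err2, "vx", random = "intercepts")
  expect_equal(
    sort(f1$anova$statistic), sort(f2$anova$statistic),
    tolerance = 1e-6
  )
})

test_that("the consistency GLM detects a fingertip-knuckle difference", {
  lp <- tibble::tibble(
    landmark = hand_landmark_labels(),
    magnitude = 2, theta_deg = 240,
    consistency = rep(c(0.99, 0.90), each = 5)
  )
  ps <- sim_params(lp,
    subject_sd = 0.2, landmark_sd = 0.1, trial_sd = 0,
    n_subjects = 12, n_trials_per_landmark = 24, seed = 114
  )
  err <- errors_from(ps)$errors
  cw <- within_subject_consistency(err)
  fit <- fit_consistency_glm(cw, "within")
  a <- fit$anova
  expect_lt(a$p_value[a$term == "type"], 0.01)
  emm <- fit$emmeans$type
  expect_gt(emm$response[emm$type == "fingertip"],
            emm$response[emm$type == "knuckle"])
})

test_that("a null consistency table yields no significant GLM terms", {
  set.seed(115)
  info <- landmark_info()
  d <- purrr::map_dfr(sprintf("S%02d", 1:15), function(s) {
    tibble::tibble(
      scope = "within_subject_landmark", subject_id = s,
      landmark = info$landmark, finger = info$finger, type = info$type,
      cluster_index = NA_integer_, n_vectors = 40L,
      itpc = pmin(0.999, pmax(1e-4, rnorm(10, 0.8, 0.1))),
      theta_deg = 240
    )
  })
  fit <- fit_consistency_glm(d, "within")
  expect_true(all(fit$anova$p_value > 0.05))
})

test_that("a cluster-independent between-subject consistency shows no trial effect", {
  set.seed(116)
  info <- landmark_info()
  d <- purrr::map_dfr(1:10, function(cl) {
    tibble::tibble(
      scope = "between_landmark_cluster", subject_id = NA_character_,
      landmark = info$landmark, finger = info$finger, type = info$type,
      cluster_index = cl, n_vectors = 40L,
      itpc = pmin(0.999, pmax(
        1e-4,
        rnorm(10, ifelse(info$type == "fingertip", 0.85, 0.5), 0.08)
      )),
      theta_deg = 240
    )
  })
  fit <- fit_consistency_glm(d, "between")
  a <- fit$anova
  expect_gt(a$p_value[a$term == "cluster_index"], 0.05)
  expect_lt(a$p_value[a$term == "type"], 0.01)
})

test_that("knuckle trend fits recover a linear gradient and expose subject slopes", {
  set.seed(117)
  n_subj <- 40
  rows <- purrr::map_dfr(sprintf("S%03d", seq_len(n_subj)), function(s) {
    intercept <- rnorm(1, 0, 0.3)
    purrr::map_dfr(1:4, function(pos) {
      lm_name <- paste0(c("index", "middle", "ring", "little")[pos], "_knuckle")
      tibble::tibble(
        subject_id = s, trial_index = seq_len(10) + (pos - 1) * 10,
        normalized_trial = 100 * (seq_len(10) + (pos - 1) * 10) / 40,
        landmark = lm_name,
        vx_cm = -0.3 * pos + intercept + rnorm(10, 0, 0.5),
        vy_cm = 0
      )
    })
  }) |>
    dplyr::mutate(
      magnitude_cm = sqrt(vx_cm^2 + vy_cm^2),
      alpha_deg = (atan2(vy_cm, vx_cm) * 180 / pi) %% 360
    )
  # add thumb knuckle rows so the filter has the full vocabulary to drop
  trends <- knuckle_trend_fits(rows)
  expect_lt(abs(trends$linear$fixed_slope - (-0.3)), 0.05)
  expect_equal(nrow(trends$linear$slopes), n_subj)
})

test_that("the quadratic consistency fit flags a U shape and not a flat profile", {
  set.seed(118)
  info <- landmark_info()
  make_records <- function(f) {
    purrr::map_dfr(1:8, function(cl) {
      tibble::tibble(
        scope = "between_landmark_cluster", subject_id = NA_character_,
        landmark = info$landmark, finger = info$finger, type = info$type,
        cluster_index = cl, n_vectors = 40L,
        itpc = pmax(1e-4, pmin(0.999, f(as.integer(info$finger)) + rnorm(10, 0, 0.03))),
        theta_deg = 240
      )
    })
  }
  ushape <- make_records(function(pos) 0.3 + 0.05 * (pos - 3)^2)
  flat <- make_records(function(pos) 0.5)

  err_stub <- errors_from_means(matrix(rnorm(40), 4, 10))
  tu <- knuckle_trend_fits(err_stub, ushape)
  qu <- tu$quadratic$coefficients
  expect_gt(qu$estimate[qu$term == "I(knuckle_pos^2)"], 0)
  expect_lt(qu$p_value[qu$term == "I(knuckle_pos^2)"], 0.05)

  tf <- knuckle_trend_fits(err_stub, flat)
  qf <- tf$quadratic$coefficients
  expect_gt(qf$p_value[qf$term == "I(knuckle_pos^2)"], 0.05)
})

test_that("broom-style tidiers return well-formed tibbles", {
  ps <- sim_params(flat_params(1, 240, 0.9),
    n_subjects = 5, n_trials_per_landmark = 6, seed = 119
  )
  res <- errors_from(ps)
  fit <- fit_component_lmm(res$errors, "vy", random = "intercepts")
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("term", "statistic", "p_value") %in% names(td)))
  gl <- glance(fit)
  expect_equal(gl$nobs, nrow(res$errors))

  pc <- pca_errors(res$errors, "proximo_distal")
  expect_equal(nrow(tidy(pc)), 10 * ncol(pc$loadings))
  expect_equal(glance(pc)$n_subjects, 5)
})
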