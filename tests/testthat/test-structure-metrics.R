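test_that("estimation ratios are exact on constructed and zero-error data", {
  # zero-error dataset: every ER exactly 1
  ds <- zero_dataset()
  err <- error_table(align_dataset(ds))
  er <- estimation_ratios(err, ds$landmarks)
  expect_equal(er$width_er, rep(1, nrow(er)))
  expect_equal(unlist(er[, grep("length_er_", names(er))]),
    rep(1, 5 * nrow(er)),
    ignore_attr = TRUE
  )

  # direct ratio: actual width 6.039 stretched to 9 cm
  actual <- make_hand_template(7.526, 6.039, subject_id = "S001")
  stretch <- (9 - 6.039) / 2
  vx <- matrix(0, 1, 10)
  vx[1, match(c("index_knuckle", "little_knuckle"), hand_landmark_labels())] <-
    c(stretch, -stretch)
  err2 <- errors_from_means(vx)
  er2 <- estimation_ratios(err2, actual)
  expect_equal(er2$width_er, 9 / 6.039, tolerance = 1e-12)
})

test_that("an index-to-little lateral gradient stretches the perceived width", {
  # knuckle lateral (negative x) errors growing toward the little finger
  grad <- c(0, -0.3, -0.6, -0.9) # index..little
  vx <- matrix(0, 5, 10)
  kn_cols <- match(paste0(c("index", "middle", "ring", "little"), "_knuckle"),
                   hand_landmark_labels())
  for (i in 1:5) vx[i, kn_cols] <- grad
  err <- errors_from_means(vx)
  er <- estimation_ratios(err, template_landmarks(sprintf("S%03d", 1:5)))
  expect_true(all(er$width_er > 1))
})

test_that("estimation ratios are invariant to a global rescaling", {
  ps <- sim_params(flat_params(1.5, 230, 0.9), n_subjects = 3,
                   n_trials_per_landmark = 8, seed = 81)
  res <- errors_from(ps)
  er1 <- estimation_ratios(res$errors, res$dataset$landmarks)
  scaled_err <- dplyr::mutate(res$errors,
    vx_cm = 3 * vx_cm, vy_cm = 3 * vy_cm, magnitude_cm = 3 * magnitude_cm
  )
  scaled_lm <- dplyr::mutate(res$dataset$landmarks,
    x_cm = 3 * x_cm, y_cm = 3 * y_cm
  )
  er2 <- estimation_ratios(scaled_err, scaled_lm)
  expect_equal(er2$width_er, er1$width_er, tolerance = 1e-9)
  expect_equal(er2$mean_length_er, er1$mean_length_er, tolerance = 1e-9)
})

test_that("PCA recovers a rank-1 structure exactly", {
  set.seed(91)
  w <- rnorm(10)
  w <- w / sqrt(sum(w^2))
  s <- rnorm(12, 0, 2)
  mu <- rnorm(10, -1, 0.5)
  X <- outer(s, w) + matrix(mu, 12, 10, byrow = TRUE)
  err <- errors_from_means(X)
  pc <- pca_errors(err, "medio_lateral")
  expect_equal(pc$variance_explained[1], 1, tolerance = 1e-9)
  expect_equal(abs(as.vector(pc$loadings[, 1])), abs(w), tolerance = 1e-6)
})

test_that("PCA reconstruction and orthonormality invariants hold", {
  set.seed(92)
  X <- matrix(rnorm(15 * 10), 15, 10)
  err <- errors_from_means(X)
  pc <- pca_errors(err, "medio_lateral")
  # orthonormal loadings
  expect_equal(t(pc$loadings) %*% pc$loadings, diag(ncol(pc$loadings)),
    tolerance = 1e-9, ignore_attr = TRUE
  )
  # full reconstruction reproduces the centred matrix
  Xc <- sweep(pc$data, 2, pc$center)
  expect_equal(pc$scores %*% t(pc$loadings), Xc,
    tolerance = 1e-9, ignore_attr = TRUE
  )
  # variance shares non-increasing and summing to 1
  expect_true(all(diff(pc$variance_explained) <= 1e-12))
  expect_equal(sum(pc$variance_explained), 1, tolerance = 1e-9)

  expect_error(pca_errors(errors_from_means(X[1:2, ])), "3 subjects")
})

test_that("PC1 loadings recover injected common weights under noise", {
  set.seed(93)
  w <- seq(0.2, 1.4, length.out = 10) # increasing index-to-little style weights
  w <- w / sqrt(sum(w^2))
  n <- 40
  s <- rnorm(n, -1.5, 1)
  signal <- outer(s, w)
  noise <- matrix(rnorm(n * 10, 0, sd(signal) / 4), n, 10) # SNR 4:1
  err <- errors_from_means(signal + noise)
  pc <- pca_errors(err, "medio_lateral")
  expect_gt(abs(cor(as.vector(pc$loadings[, 1]), w)), 0.9)
})

test_that("removing PC1 undoes a width overestimation injected via a common gradient", {
  set.seed(94)
  n <- 40
  landmarks <- template_landmarks(sprintf("S%03d", seq_len(n)))
  # common lateral component weighted index -> little (both landmark types)
  w_raw <- c(0.6, 0.0, 0.35, 0.75, 1.1, 0.6, 0.0, 0.35, 0.75, 1.1)
  g <- rnorm(n, 1.4, 0.35) # common-source strength per subject
  vx <- -outer(g, w_raw) + matrix(rnorm(n * 10, 0, 0.08), n, 10)
  err <- errors_from_means(vx)

  pc <- pca_errors(err, "medio_lateral")
  out <- remove_pc1_and_recompute(err, pc, landmarks)
  expect_gt(mean(out$width_er), 1.1)
  expect_gte(mean(out$width_er_pc1_removed), 0.97)
  expect_lte(mean(out$width_er_pc1_removed), 1.03)
  expect_gt(abs(cor(as.vector(pc$loadings[, 1]), w_raw)), 0.9)
})

test_that("mean-preserving removal keeps column means and the reconstruction identity", {
  set.seed(95)
  n <- 10
  landmarks <- template_landmarks(sprintf("S%03d", seq_len(n)))
  w <- rnorm(10); w <- w / sqrt(sum(w^2))
  mu <- rnorm(10, -0.5, 0.3)
  X <- outer(rnorm(n), w) + matrix(mu, n, 10, byrow = TRUE)
  err <- errors_from_means(X)
  pc <- pca_errors(err, "medio_lateral")

  # column means preserved by the keep_mean variant
  l1 <- pc$loadings[, 1]
  Xc <- sweep(pc$data, 2, pc$center)
  R <- sweep(Xc - (Xc %*% l1) %*% t(l1), 2, pc$center, `+`)
  expect_equal(colMeans(R), pc$center, tolerance = 1e-9)

  # with only PC1 inter-subject structure, keep_mean removal leaves exactly
  # the column-mean errors
  out <- remove_pc1_and_recompute(err, pc, landmarks, keep_mean = TRUE)
  err_mu <- errors_from_means(matrix(colMeans(X), 1, 10, byrow = TRUE))
  er_mu <- estimation_ratios(err_mu, template_landmarks("S001"))
  expect_equal(out$width_er_pc1_removed, rep(er_mu$width_er, n), tolerance = 1e-6)

  # zero-error data: removal is a no-op at width ER 1
  zero_err <- errors_from_means(matrix(0, 4, 10) + 1e-9 * matrix(rnorm(40), 4, 10))
  pc0 <- pca_errors(zero_err, "medio_lateral")
  out0 <- remove_pc1_and_recompute(
    zero_err, pc0, template_landmarks(sprintf("S%03d", 1:4))
  )
  expect_equal(out0$width_er, rep(1, 4), tolerance = 1e-6)
  expect_equal(out0$width_er_pc1_removed, rep(1, 4), tolerance = 1e-6)
})

test_that("width ER grows monotonically with the injected lateral gradient", {
  set.seed(96)
  gradients <- seq(0.1, 1, length.out = 6)
  kn_cols <- match(paste0(c("index", "middle", "ring", "little"), "_knuckle"),
                   hand_landmark_labels())
  mean_er <- vapply(gradients, function(g) {
    n <- 8
    vx <- matrix(rnorm(n * 10, 0, 0.05), n, 10)
    vx[, kn_cols] <- vx[, kn_cols] +
      matrix(-g * (0:3), n, 4, byrow = TRUE)
    er <- estimation_ratios(
      errors_from_means(vx),
      template_landmarks(sprintf("S%03d", seq_len(n)))
    )
    mean(er$width_er)
  }, numeric(1))
  expect_gt(cor(gradients, mean_er, method = "spearman"), 0.95)
})

test_that("the knuckle slope predicts the width ER as constructed", {
  set.seed(97)
  n <- 40
  landmarks <- template_landmarks(sprintf("S%03d", seq_len(n)))
  kn_cols <- match(paste0(c("index", "middle", "ring", "little"), "_knuckle"),
                   hand_landmark_labels())
  slopes <- -runif(n, 0.1, 1)
  vx <- matrix(0, n, 10)
  for (i in seq_len(n)) vx[i, kn_cols] <- slopes[i] * (1:4)
  err <- errors_from_means(vx)
  er <- estimation_ratios(err, landmarks)

  fit <- knuckle_slope_predicts_width(err, er)
  # noiseless construction: slope fully determines the width ER (almost
  # linearly; tiny curvature from the Euclidean distance)
  expect_gt(fit$summary$adj_r_squared, 0.99)
  expect_lt(fit$summary$estimate, 0)
  expect_lt(fit$summary$p_value, 1e-6)

  # permutation null: shuffled slopes explain nothing on average
  r2 <- replicate(100, {
    perm <- dplyr::mutate(er, width_er = sample(width_er))
    summary(lm(perm$width_er ~ slopes))$adj.r.squared
  })
  expect_lt(mean(r2), 0.05)
})
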