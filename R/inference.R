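# Model-fitting stages: mixed models on error components, Gamma log-link
# GLMs on angle consistency, and the knuckle trend fits. The backends are
# lme4/lmerTest (Satterthwaite F), car::Anova (Wald chi-square) and emmeans
# (estimated marginal means, Bonferroni post-hocs); this module owns the
# factor coding, design, fallback ladder and reporting.

prepare_model_frame <- function(errors, dependent) {
  check_errors_table(errors)
  col <- switch(dependent, vx = "vx_cm", vy = "vy_cm",
    abort("`dependent` must be \"vx\" or \"vy\".")
  )
  errors |>
    add_landmark_factors() |>
    dplyr::transmute(
      subject_id = factor(subject_id),
      finger, type, normalized_trial,
      response = .data[[col]]
    )
}

fit_lmer_ladder <- function(formula_fixed, random_terms, data) {
  for (i in seq_along(random_terms)) {
    f <- as.formula(paste(formula_fixed, "+", random_terms[[i]]))
    fit <- tryCatch(
      withCallingHandlers(
        lmerTest::lmer(f, data = data),
        warning = function(w) {
          # optimizer chatter; convergence status is re-checked below and the
          # structure actually used is reported in the fit object
          if (grepl("conver|unidentifiable|rescale|Hessian",
                    conditionMessage(w), ignore.case = TRUE)) {
            invokeRestart("muffleWarning")
          }
        }
      ),
      error = function(e) NULL
    )
    if (!is.null(fit)) {
      conv <- fit@optinfo$conv$lme4
      failed <- !is.null(conv$messages) &&
        any(grepl("failed to converge", conv$messages, ignore.case = TRUE))
      if (!failed) {
        return(list(model = fit, random = random_terms[[i]], step = i))
      }
    }
  }
  abort("No random-effects structure in the fallback ladder converged.")
}

#' Linear mixed model on an error component
#'
#' Fits the full factorial fixed structure finger x type x normalized trial
#' on the trial-level medio-lateral (`vx`) or proximo-distal (`vy`) errors,
#' with by-subject random effects. The maximal requested structure is random
#' intercepts plus by-subject slopes for type and normalized trial; on
#' convergence failure the model falls back along a documented ladder
#' (drop the type slope, then all slopes), and the structure actually used
#' is recorded in the result. Omnibus tests are type III F tests with
#' Satterthwaite degrees of freedom; estimated marginal means use balanced
#' factor margins with the continuous covariate fixed at `emm_at` (its mean
#' by default), and pairwise post-hocs are Bonferroni-corrected. A residual
#' normality check (Shapiro-Wilk on up to 5000 residuals) is reported.
#'
#' @param errors An error table from [error_table()].
#' @param dependent `"vy"` (proximo-distal) or `"vx"` (medio-lateral).
#' @param random `"maximal"` to start the ladder at the full by-subject
#'   structure, `"intercepts"` for random intercepts only.
#' @param emm_at Value of normalized trial at which marginal means are
#'   evaluated (`NULL` = observed mean).
#' @return An object of class `lt_lmm`: list with `model`, `anova` (tibble),
#'   `emmeans` (list of tibbles for type, finger, finger x type),
#'   `contrasts` (Bonferroni pairwise), `random_structure`, `singular`,
#'   `normality`, `dependent`, `n_comparisons`.
#' @export
fit_component_lmm <- function(errors, dependent = c("vy", "vx"),
                              random = c("maximal", "intercepts"),
                              emm_at = NULL) {
  dependent <- match.arg(dependent)
  random <- match.arg(random)
  d <- prepare_model_frame(errors, dependent)
  if (nlevels(d$subject_id) < 2) abort("At least 2 subjects are required.")

  ladder <- list(
    "(1 + type + normalized_trial | subject_id)",
    "(1 + normalized_trial | subject_id)",
    "(1 | subject_id)"
  )
  if (random == "intercepts") ladder <- ladder[3]
  res <- fit_lmer_ladder("response ~ finger * type * normalized_trial", ladder, d)
  model <- res$model

  an <- as.data.frame(anova(model, type = 3))
  anova_tbl <- tibble::tibble(
    term = rownames(an),
    statistic = an[["F value"]],
    num_df = an[["NumDF"]],
    den_df = an[["DenDF"]],
    p_value = an[["Pr(>F)"]]
  )

  at_list <- list(normalized_trial = emm_at %||% mean(d$normalized_trial))
  # messages about averaging over interacting factors are expected here:
  # the marginal means over balanced margins are exactly what is reported
  emm_type <- suppressMessages(emmeans::emmeans(model, ~type, at = at_list,
    lmer.df = "satterthwaite", lmerTest.limit = 1e6))
  emm_finger <- suppressMessages(emmeans::emmeans(model, ~finger, at = at_list,
    lmer.df = "satterthwaite", lmerTest.limit = 1e6))
  emm_cell <- suppressMessages(emmeans::emmeans(model, ~ finger * type, at = at_list,
    lmer.df = "satterthwaite", lmerTest.limit = 1e6))
  contrasts <- tibble::as_tibble(as.data.frame(
    emmeans::contrast(emm_cell, "pairwise", adjust = "bonferroni")
  ))
  # marginal slope of normalized trial, averaged over the factor margins
  trend <- tibble::as_tibble(as.data.frame(
    emmeans::emtrends(model, ~1, var = "normalized_trial",
      lmer.df = "satterthwaite", lmerTest.limit = 1e6)
  ))

  r <- resid(model)
  if (length(r) > 5000) r <- sample(r, 5000)
  sh <- shapiro.test(r)

  structure(
    list(
      model = model,
      anova = anova_tbl,
      emmeans = list(
        type = tibble::as_tibble(as.data.frame(emm_type)),
        finger = tibble::as_tibble(as.data.frame(emm_finger)),
        cell = tibble::as_tibble(as.data.frame(emm_cell))
      ),
      contrasts = contrasts,
      trend = trend,
      n_comparisons = nrow(contrasts),
      random_structure = res$random,
      singular = lme4::isSingular(model),
      normality = tibble::tibble(statistic = sh$statistic, p_value = sh$p.value),
      dependent = dependent
    ),
    class = "lt_lmm"
  )
}

#' @exportS3Method
print.lt_lmm <- function(x, ...) {
  cat(sprintf(
    "<lt_lmm> %s ~ finger * type * normalized_trial, random %s%s\n",
    x$dependent, x$random_structure, if (x$singular) " (singular fit)" else ""
  ))
  print(x$anova)
  invisible(x)
}

#' Gamma log-link GLM on angle consistency
#'
#' Models ITPC values with a Gamma distribution and log link. For the
#' within-subject scope the predictors are finger x type; for the
#' between-subject scope the normalized-trial cluster (as a continuous
#' covariate) enters the full factorial. Omnibus tests are type III Wald
#' chi-square tests (sum-to-zero factor coding); post-hoc pairwise contrasts
#' are Bonferroni-corrected. ITPC values of exactly 0 are clipped to
#' `epsilon` (count reported by message), since the Gamma family requires
#' strictly positive responses.
#'
#' @param records Consistency records from [within_subject_consistency()] or
#'   [between_subject_consistency()].
#' @param scope `"within"` (uses the per-subject x landmark records) or
#'   `"between"` (uses the landmark x cluster records).
#' @param epsilon Positive clip value for zero ITPCs.
#' @return An object of class `lt_glm`: list with `model`, `anova`
#'   (Wald chi-square tibble), `emmeans`, `contrasts`, `n_clipped`, `scope`.
#' @export
fit_consistency_glm <- function(records, scope = c("within", "between"),
                                epsilon = 1e-6) {
  scope <- match.arg(scope)
  wanted <- switch(scope,
    within = "within_subject_landmark",
    between = "between_landmark_cluster"
  )
  d <- records |>
    dplyr::filter(scope == !!wanted) |>
    add_landmark_factors()
  if (nrow(d) == 0) abort(sprintf("No records with scope \"%s\".", wanted))
  if (all(d$itpc == 0)) abort("All ITPC values are zero; the Gamma GLM is undefined.")

  n_clipped <- sum(d$itpc <= 0)
  if (n_clipped > 0) {
    message(sprintf("%d ITPC value(s) of 0 clipped to %g.", n_clipped, epsilon))
    d$itpc[d$itpc <= 0] <- epsilon
  }

  form <- if (scope == "within") {
    itpc ~ finger * type
  } else {
    itpc ~ finger * type * cluster_index
  }
  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old), add = TRUE)
  model <- stats::glm(form, family = stats::Gamma(link = "log"), data = d)
  aw <- car::Anova(model, type = 3, test.statistic = "Wald")
  aw <- aw[rownames(aw) != "(Intercept)", , drop = FALSE]
  anova_tbl <- tibble::tibble(
    term = rownames(aw),
    statistic = aw[["Chisq"]],
    df = aw[["Df"]],
    p_value = aw[["Pr(>Chisq)"]]
  )

  emm_type <- suppressMessages(emmeans::emmeans(model, ~type, type = "response"))
  emm_finger <- suppressMessages(emmeans::emmeans(model, ~finger, type = "response"))
  contrasts <- tibble::as_tibble(as.data.frame(
    emmeans::contrast(
      suppressMessages(emmeans::emmeans(model, ~ finger * type)),
      "pairwise", adjust = "bonferroni"
    )
  ))

  structure(
    list(
      model = model,
      anova = anova_tbl,
      emmeans = list(
        type = tibble::as_tibble(as.data.frame(emm_type)),
        finger = tibble::as_tibble(as.data.frame(emm_finger))
      ),
      contrasts = contrasts,
      n_comparisons = nrow(contrasts),
      n_clipped = n_clipped,
      scope = scope
    ),
    class = "lt_glm"
  )
}

#' @exportS3Method
print.lt_glm <- function(x, ...) {
  cat(sprintf("<lt_glm> %s-subject angle consistency, Gamma log-link\n", x$scope))
  print(x$anova)
  invisible(x)
}

#' Knuckle trend fits
#'
#' Two trend analyses across the knuckles: (i) a linear mixed model of the
#' trial-level medio-lateral error on the knuckle position coded index to
#' little as 1--4 (thumb excluded), with by-subject random slopes — the
#' per-subject slopes quantify each subject's lateral-error gradient and
#' feed [knuckle_slope_predicts_width()]; (ii) an ordinary quadratic
#' regression of the between-subject angle consistency on the knuckle
#' position coded thumb to little as 1--5, capturing the decrease of
#' consistency from the hand boundaries to its centre.
#'
#' @param errors An error table from [error_table()].
#' @param consistency Optional between-subject consistency records (for the
#'   quadratic fit); `NULL` skips that fit.
#' @return An object of class `knuckle_trends`: list with `linear` (model,
#'   `fixed_slope`, `slopes` tibble of per-subject slopes, `random_structure`)
#'   and `quadratic` (lm and coefficient tibble, or `NULL`).
#' @export
knuckle_trend_fits <- function(errors, consistency = NULL) {
  d <- errors |>
    add_landmark_factors() |>
    dplyr::filter(type == "knuckle", finger != "thumb") |>
    dplyr::mutate(
      subject_id = factor(subject_id),
      knuckle_pos = as.integer(finger) - 1L # index 1 .. little 4
    )
  if (nrow(d) == 0 || dplyr::n_distinct(d$knuckle_pos) < 4) {
    abort("All four finger knuckles (index..little) are required.")
  }
  res <- fit_lmer_ladder(
    "vx_cm ~ knuckle_pos",
    list("(1 + knuckle_pos | subject_id)", "(1 | subject_id)"),
    d
  )
  model <- res$model
  cf <- coef(model)$subject_id
  slopes <- tibble::tibble(
    subject_id = rownames(cf),
    slope = if ("knuckle_pos" %in% names(cf)) cf[["knuckle_pos"]] else lme4::fixef(model)[["knuckle_pos"]]
  )
  an <- as.data.frame(anova(model, type = 3))
  linear <- list(
    model = model,
    fixed_slope = lme4::fixef(model)[["knuckle_pos"]],
    anova = tibble::tibble(
      term = rownames(an), statistic = an[["F value"]],
      num_df = an[["NumDF"]], den_df = an[["DenDF"]], p_value = an[["Pr(>F)"]]
    ),
    slopes = slopes,
    random_structure = res$random
  )

  quadratic <- NULL
  if (!is.null(consistency)) {
    q <- consistency |>
      dplyr::filter(scope == "between_landmark_cluster") |>
      add_landmark_factors() |>
      dplyr::filter(type == "knuckle") |>
      dplyr::mutate(knuckle_pos = as.integer(finger)) # thumb 1 .. little 5
    if (nrow(q) >= 3) {
      qfit <- lm(itpc ~ knuckle_pos + I(knuckle_pos^2), data = q)
      sq <- summary(qfit)$coefficients
      quadratic <- list(
        model = qfit,
        coefficients = tibble::tibble(
          term = rownames(sq),
          estimate = sq[, "Estimate"],
          statistic = sq[, "t value"],
          p_value = sq[, "Pr(>|t|)"]
        )
      )
    }
  }

  structure(list(linear = linear, quadratic = quadratic), class = "knuckle_trends")
}

#' @exportS3Method
print.knuckle_trends <- function(x, ...) {
  cat(sprintf(
    "<knuckle_trends> linear vx slope across knuckles (1-4): %.3f cm/step\n",
    x$linear$fixed_slope
  ))
  if (!is.null(x$quadratic)) {
    cat("quadratic consistency fit (knuckles 1-5):\n")
    print(x$quadratic$coefficients)
  }
  invisible(x)
}
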