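# Angle consistency: inter-trial phase clustering (ITPC) of error directions
# at the grouping scopes used in the analysis.

#' Inter-trial phase clustering (ITPC) of a set of directions
#'
#' Each direction is represented as a unit complex vector `exp(i * alpha)`;
#' the ITPC is the modulus of their arithmetic mean and the most frequent
#' direction `theta` its argument. ITPC lies in \[0, 1\]: 1 means all
#' directions coincide, 0 complete cancellation (in which case `theta` is
#' undefined and returned as `NA`). `NA` angles (undefined directions from
#' zero-magnitude errors) are dropped.
#'
#' @param angles_deg Directions in degrees.
#' @return A list with elements `itpc`, `theta_deg` (in \[0, 360) or `NA`)
#'   and `n_vectors`.
#' @export
#' @examples
#' itpc(c(0, 90)) # itpc = sqrt(2)/2, theta = 45
itpc <- function(angles_deg) {
  angles_deg <- angles_deg[!is.na(angles_deg)]
  if (length(angles_deg) == 0L) abort("`angles_deg` must contain at least one defined angle.")
  z <- mean(exp(1i * deg2rad(angles_deg)))
  r <- Mod(z)
  theta <- if (r < 1e-12) NA_real_ else wrap_deg(rad2deg(Arg(z)))
  list(itpc = r, theta_deg = theta, n_vectors = length(angles_deg))
}

itpc_row <- function(angles_deg) {
  res <- itpc(angles_deg)
  tibble::tibble(
    n_vectors = res$n_vectors, itpc = res$itpc, theta_deg = res$theta_deg
  )
}

#' Within-subject angle consistency
#'
#' Computes the ITPC of each subject's error directions pooled over all
#' landmarks (`scope = "within_subject_overall"`) and separately per subject
#' and landmark (`scope = "within_subject_landmark"`). Subjects without any
#' defined direction are skipped with a warning.
#'
#' @param errors An error table from [error_table()].
#' @return A tibble of consistency records: `scope`, `subject_id`,
#'   `landmark`, `finger`, `type`, `cluster_index`, `n_vectors`, `itpc`,
#'   `theta_deg`.
#' @export
within_subject_consistency <- function(errors) {
  check_errors_table(errors)
  e <- dplyr::filter(errors, !is.na(alpha_deg))
  dropped <- setdiff(unique(errors$subject_id), unique(e$subject_id))
  if (length(dropped) > 0) {
    warn(paste("Subjects without defined error directions skipped:", paste(dropped, collapse = ", ")))
  }
  overall <- e |>
    dplyr::group_by(subject_id) |>
    dplyr::reframe(itpc_row(alpha_deg)) |>
    dplyr::mutate(scope = "within_subject_overall", landmark = NA_character_)
  per_lm <- e |>
    dplyr::group_by(subject_id, landmark) |>
    dplyr::reframe(itpc_row(alpha_deg)) |>
    dplyr::mutate(scope = "within_subject_landmark")
  dplyr::bind_rows(overall, per_lm) |>
    add_landmark_factors() |>
    dplyr::mutate(cluster_index = NA_integer_) |>
    dplyr::select(scope, subject_id, landmark, finger, type, cluster_index, n_vectors, itpc, theta_deg)
}

#' Between-subject angle consistency
#'
#' The overall record pools the unit vectors of all subjects and trials and
#' takes the modulus of the grand mean (`pooling = "trials"`, the default);
#' `pooling = "subject_means"` instead averages each subject's mean complex
#' vector before taking the modulus. Per landmark x trial-cluster records are
#' computed over the vectors whose normalized trial falls in that cluster;
#' cluster `c` of `n_clusters` covers normalized trials in
#' `(100 (c-1) / n_clusters, 100 c / n_clusters]`. Empty clusters are
#' omitted.
#'
#' @param errors An error table from [error_table()].
#' @param n_clusters Number of equal-width normalized-trial clusters.
#' @param pooling `"trials"` or `"subject_means"` (see Details).
#' @return A tibble of consistency records (same columns as
#'   [within_subject_consistency()]).
#' @export
between_subject_consistency <- function(errors, n_clusters = 100,
                                        pooling = c("trials", "subject_means")) {
  check_errors_table(errors)
  pooling <- match.arg(pooling)
  if (n_clusters < 1) abort("`n_clusters` must be >= 1.")
  if (dplyr::n_distinct(errors$subject_id) < 2) {
    abort("Between-subject consistency needs at least 2 subjects.")
  }
  e <- dplyr::filter(errors, !is.na(alpha_deg))

  pooled_row <- function(df) {
    if (pooling == "trials") {
      itpc_row(df$alpha_deg)
    } else {
      z <- df |>
        dplyr::group_by(subject_id) |>
        dplyr::summarise(z = mean(exp(1i * deg2rad(alpha_deg))), .groups = "drop")
      zz <- mean(z$z)
      r <- Mod(zz)
      tibble::tibble(
        n_vectors = nrow(z), itpc = r,
        theta_deg = if (r < 1e-12) NA_real_ else wrap_deg(rad2deg(Arg(zz)))
      )
    }
  }

  overall <- pooled_row(e) |>
    dplyr::mutate(scope = "between_overall", landmark = NA_character_, cluster_index = NA_integer_)

  per_cell <- e |>
    dplyr::mutate(cluster_index = pmin(n_clusters, as.integer(ceiling(normalized_trial * n_clusters / 100)))) |>
    dplyr::group_by(landmark, cluster_index) |>
    dplyr::reframe(pooled_row(dplyr::pick(dplyr::everything()))) |>
    dplyr::mutate(scope = "between_landmark_cluster")

  n_empty <- 10L * n_clusters - nrow(per_cell)
  if (n_empty > 0) {
    message(sprintf("%d empty landmark x cluster cell(s) omitted.", n_empty))
  }

  dplyr::bind_rows(overall, per_cell) |>
    add_landmark_factors() |>
    dplyr::mutate(subject_id = NA_character_) |>
    dplyr::select(scope, subject_id, landmark, finger, type, cluster_index, n_vectors, itpc, theta_deg)
}

#' Median and interquartile range of consistency records
#'
#' Convenience summary in the form used to report angle consistency:
#' median +/- interquartile range, optionally split by grouping columns
#' (e.g. `type`).
#'
#' @param records Consistency records.
#' @param ... Grouping columns (tidy-select), e.g. `type`.
#' @return A tibble with `median_itpc`, `iqr_itpc`, `n`.
#' @export
summarise_consistency <- function(records, ...) {
  records |>
    dplyr::group_by(...) |>
    dplyr::summarise(
      median_itpc = median(itpc),
      iqr_itpc = IQR(itpc),
      n = dplyr::n(),
      .groups = "drop"
    )
}
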