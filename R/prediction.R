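#' Cross-predict a patient's tumour evolution from another patient's
#' mean-value sets
#'
#' The patient-pair methodology: the mean-value parameter sets assigned to
#' a *source* patient for a given tumour profile are used to predict the
#' volumetric evolution of a *target* patient's tumour for the same
#' profile.  For each CKR value with a mean-value set, the target's own
#' geometry, dose maps and treatment schedule are simulated under the
#' source's parameters and scored against the target's clinical volumes;
#' the directional error is the arithmetic mean of these per-CKR MAEs.
#'
#' @param target A `cv_patient` with clinical volumes.
#' @param source_mean_sets List of `cv_mean_set` objects (one per CKR
#'   value) of the source patient, from [mean_value_set()].
#' @param profile The shared [tumour_profile()].
#' @param seed Spatial tie-break seed.
#' @return Directional MAE (percent), with attribute `per_ckr` (named
#'   vector of the per-CKR MAEs).
#' @export
cross_predict <- function(target, source_mean_sets, profile, seed = 1L) {
  stopifnot(inherits(target, "cv_patient"))
  if (length(source_mean_sets) == 0)
    stop("source has no mean-value sets for this profile")
  if (is.null(target$clinical))
    stop("target has no clinical volume series")
  per_ckr <- vapply(source_mean_sets, function(ms) {
    stopifnot(inherits(ms, "cv_mean_set"))
    sim <- patient_course(target, profile, ms$params, seed = seed)
    mae_solution(sim$volumes, target$clinical)
  }, numeric(1))
  names(per_ckr) <- vapply(source_mean_sets,
                           function(ms) as.character(ms$ckr), character(1))
  structure(mean(per_ckr), per_ckr = per_ckr)
}

#' Bilateral patient-pair error
#'
#' Combines the two directional cross-prediction errors of a patient pair
#' into a single pair error: the mean of the two when both are available.
#' When only one of the two patients retrieved solutions for the profile,
#' the single available run's MAE is assigned to the pair (single-run
#' rule) and the score is flagged one-sided.
#'
#' @param mae_ab MAE of predicting A from B's sets (percent), or `NA`.
#' @param mae_ba MAE of predicting B from A's sets (percent), or `NA`.
#' @param pair Optional identifier, e.g. `"68-71"`.
#' @param profile Optional profile label carried into the score.
#' @return A `cv_pair_score`: list with `pair`, `mae_pair`, `mae_a_from_b`,
#'   `mae_b_from_a`, `sidedness` (`"both"` or `"single"`).
#' @export
#' @examples
#' pair_mae(5.3, 9.5, pair = "68-71")$mae_pair  # 7.4
#' pair_mae(9.7, NA, pair = "88-68")$mae_pair   # single-run rule
pair_mae <- function(mae_ab, mae_ba, pair = NA_character_, profile = NULL) {
  ab_ok <- length(mae_ab) == 1 && is.finite(mae_ab)
  ba_ok <- length(mae_ba) == 1 && is.finite(mae_ba)
  if (!ab_ok && !ba_ok)
    stop("pair error undefined: both directional MAEs are absent")
  if (ab_ok && mae_ab < 0 || ba_ok && mae_ba < 0)
    stop("MAE values must be non-negative")
  total <- if (ab_ok && ba_ok) (mae_ab + mae_ba) / 2
           else if (ab_ok) as.numeric(mae_ab) else as.numeric(mae_ba)
  structure(list(pair = pair, profile = profile,
                 mae_pair = total,
                 mae_a_from_b = if (ab_ok) as.numeric(mae_ab) else NA_real_,
                 mae_b_from_a = if (ba_ok) as.numeric(mae_ba) else NA_real_,
                 sidedness = if (ab_ok && ba_ok) "both" else "single"),
            class = "cv_pair_score")
}

#' @export
print.cv_pair_score <- function(x, ...) {
  cat(sprintf("Pair %s: MAE %.2f%% (A<-B %.2f, B<-A %.2f, %s)\n",
              x$pair, x$mae_pair, x$mae_a_from_b, x$mae_b_from_a,
              x$sidedness))
  invisible(x)
}

#' Rank patient pairs by bilateral error
#'
#' Sorts pair scores in ascending order of the pair MAE (ties broken
#' lexicographically by pair name) and annotates which pairs fall at or
#' below the threshold regarded as very good mutual predictability.
#'
#' @param scores List of `cv_pair_score` objects ([pair_mae()]).
#' @param good_threshold Annotation threshold in percentage points
#'   (default 10).
#' @return Data frame with columns `pair`, `profile`, `mae_pair`,
#'   `mae_a_from_b`, `mae_b_from_a`, `sidedness`, `good`, in ascending
#'   `mae_pair` order.
#' @export
rank_pairs <- function(scores, good_threshold = 10) {
  if (length(scores) == 0)
    return(data.frame(pair = character(0), profile = character(0),
                      mae_pair = numeric(0), mae_a_from_b = numeric(0),
                      mae_b_from_a = numeric(0), sidedness = character(0),
                      good = logical(0)))
  df <- do.call(rbind, lapply(scores, function(s) data.frame(
    pair = s$pair, profile = NA_character_,
    mae_pair = s$mae_pair, mae_a_from_b = s$mae_a_from_b,
    mae_b_from_a = s$mae_b_from_a, sidedness = s$sidedness,
    stringsAsFactors = FALSE)))
  df$profile <- vapply(scores, function(s) {
    if (is.null(s$profile)) NA_character_
    else if (inherits(s$profile, "cv_profile"))
      sprintf("GF%g-HF%g-DF%g", s$profile$gf, s$profile$hf, s$profile$df)
    else as.character(s$profile)
  }, character(1))
  df <- df[order(df$mae_pair, df$pair), , drop = FALSE]
  df$good <- df$mae_pair <= good_threshold
  rownames(df) <- NULL
  df
}
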