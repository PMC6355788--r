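# Draw one candidate parameter set uniformly within the plausible ranges.
# beta is drawn through an alpha/beta ratio around the typical 10 Gy and
# clamped to its own range, so that alpha and beta stay physiologically
# coupled.
.draw_params <- function(profile, ckr) {
  rg <- param_ranges()
  r <- function(f) {
    k <- match(f, rg$parameter)
    runif(1, rg$min[k], rg$max[k])
  }
  alpha <- r("alpha")
  beta <- min(max(alpha / runif(1, 5, 20), 0.001), 0.06)
  gf <- profile$gf / 100; hf <- profile$hf / 100; df <- profile$df / 100
  # stem cells live in the proliferating + dormant pools only
  sf_max <- min(0.07, 0.95 * (gf * (1 - df) + hf) / (1 - df))
  sf_min <- min(0.0013, sf_max / 2)
  parameter_set(
    t_cycle = r("t_cycle"), t_g0 = r("t_g0"),
    t_necrosis = exp(runif(1, log(34), log(3456))),
    t_apoptosis = r("t_apoptosis"),
    n_limp = sample(1:18, 1),
    lq = lq_params(alpha, beta, t_half = r("t_half"), oer = r("oer")),
    ckr = ckr, r_a = r("r_a"), r_ndiff = r("r_ndiff"),
    r_adiff = r("r_adiff"), p_g0g1 = r("p_g0g1"),
    p_sleep = r("p_sleep"), p_sym = r("p_sym"),
    stem_frac = runif(1, sf_min, sf_max))
}

# Bisection of a single scalar field so that doubling_time(params) hits
# `td` days.  `increasing` states whether Td grows with the field.
# Returns params or NULL if the bracket cannot contain the target.
.calibrate_field <- function(params, field, lo, hi, td, increasing,
                             rel_tol = 0.01, max_iter = 60) {
  set_f <- function(p, v) { p[[field]] <- v; p }
  td_of <- function(v) doubling_time(set_f(params, v))
  t_lo <- td_of(lo); t_hi <- td_of(hi)
  if (!increasing) { tmp <- t_lo; t_lo <- t_hi; t_hi <- tmp }
  # after normalisation: Td at the "low-Td end" is t_lo
  if (td < t_lo || td > t_hi) return(NULL)
  a <- if (increasing) lo else hi
  b <- if (increasing) hi else lo
  for (it in seq_len(max_iter)) {
    mid <- (a + b) / 2
    tm <- td_of(mid)
    if (is.finite(tm) && abs(tm - td) / td <= rel_tol)
      return(set_f(params, mid))
    if (tm < td) a <- mid else b <- mid
  }
  mid <- (a + b) / 2
  if (abs(td_of(mid) - td) / td <= 0.1) return(set_f(params, mid))
  NULL
}

#' Calibrate a parameter set to a target doubling time
#'
#' Adjusts the spontaneous apoptosis rate `r_a` (and, if its range is
#' insufficient, the symmetric-division fraction `p_sym`) by bisection so
#' that the set's free-growth [doubling_time()] matches `td`.
#'
#' @param params A [parameter_set()].
#' @param td Target volume doubling time (days).
#' @param rel_tol Relative tolerance on the achieved doubling time.
#' @return The calibrated [parameter_set()], or an error if the target is
#'   unreachable within the plausible ranges.
#' @export
#' @examples
#' p <- calibrate_td(parameter_set(p_sleep = 0.1), td = 80)
#' doubling_time(p)
calibrate_td <- function(params, td, rel_tol = 0.01) {
  rg <- param_ranges()
  rng <- function(f) rg[match(f, rg$parameter), c("min", "max")]
  ra <- rng("r_a"); ps <- rng("p_sym")
  out <- .calibrate_field(params, "r_a", ra$min, ra$max, td,
                          increasing = TRUE, rel_tol = rel_tol)
  if (is.null(out)) {
    base <- params
    base$r_a <- ra$min
    if (doubling_time(base) <= td) base$r_a <- ra$max
    out <- .calibrate_field(base, "p_sym", ps$min, ps$max, td,
                            increasing = FALSE, rel_tol = rel_tol)
  }
  if (is.null(out))
    stop(sprintf("doubling time %g days unreachable for this parameter set",
                 td))
  out
}

#' Sample parameter sets compatible with a tumour profile
#'
#' Implements the one-to-many mapping from the clinically meaningful
#' tumour features \{GF, HF, DF, Td, CKR\} to full parameter sets: fields
#' are drawn within the plausible ranges of [param_ranges()], the initial
#' tumour composition realises \{GF, HF, DF\} exactly by construction at
#' [init_tumour()] time, and each draw is calibrated so its free-growth
#' doubling time ([doubling_time()]) matches the target `td`.  Calibration
#' bisects the spontaneous apoptosis rate `r_a` first and the symmetric-
#' division fraction `p_sym` second (both monotone levers on the growth
#' rate); draws for which the target is unreachable inside the ranges are
#' rejected and redrawn.
#'
#' @param profile A [tumour_profile()].
#' @param td Target volume doubling time (days).
#' @param ckr Cisplatin kill rate assigned to every set.
#' @param n Number of sets to return (the study workflow uses 100).
#' @param seed Integer seed; same seed, same sets.
#' @param max_attempts Attempted draws per accepted set before giving up.
#' @return List of [parameter_set()] objects (possibly shorter than `n`,
#'   empty if the (profile, td) combination is infeasible), with attributes
#'   `td_target` and `diagnostic` (reason when short).
#' @export
#' @examples
#' sets <- sample_parameter_sets(tumour_profile(60, 30, 5), td = 80,
#'                               ckr = 0.2, n = 5, seed = 1)
#' sapply(sets, doubling_time)
sample_parameter_sets <- function(profile, td, ckr, n = 100, seed = 1L,
                                  max_attempts = 40L) {
  stopifnot(inherits(profile, "cv_profile"), td > 0, n >= 1)
  rg <- param_ranges()
  rng <- function(f) rg[match(f, rg$parameter), c("min", "max")]
  with_seed(seed, {
    out <- vector("list", n)
    n_ok <- 0L; n_try <- 0L
    for (i in seq_len(n)) {
      got <- NULL
      for (a in seq_len(max_attempts)) {
        n_try <- n_try + 1L
        cand <- .draw_params(profile, ckr)
        ra <- rng("r_a"); ps <- rng("p_sym")
        got <- .calibrate_field(cand, "r_a", ra$min, ra$max, td,
                                increasing = TRUE)
        if (is.null(got)) {
          # r_a exhausted: move p_sym instead (Td decreases with p_sym),
          # pinning r_a at whichever end the target overshot
          base <- cand
          base$r_a <- ra$min
          if (doubling_time(base) <= td) base$r_a <- ra$max
          got <- .calibrate_field(base, "p_sym", ps$min, ps$max, td,
                                  increasing = FALSE)
        }
        if (!is.null(got)) break
      }
      if (is.null(got)) break
      n_ok <- n_ok + 1L
      out[[n_ok]] <- got
    }
    out <- out[seq_len(n_ok)]
    diag <- if (n_ok < n)
      sprintf(paste0("only %d/%d sets found after %d draws: target Td = %g",
                     " days appears unreachable for this profile within the",
                     " plausible parameter ranges"), n_ok, n, n_try, td)
    else sprintf("%d sets from %d draws", n_ok, n_try)
    structure(out, td_target = td, ckr = ckr, diagnostic = diag)
  })
}

#' Mean absolute VRP error of one simulated course
#'
#' The mean over the available follow-up timepoints (`midterm`, `BT0`,
#' `BT1`, `BT2`) of the absolute difference between the clinical and
#' simulated volume reduction percentages.
#'
#' @param sim,clin [volume_series()] objects sharing at least one
#'   follow-up timepoint.
#' @return MAE in percentage points.
#' @export
#' @examples
#' clin <- volume_series(c(pretherapy = 100, midterm = 60, BT0 = 40))
#' sim <- volume_series(c(pretherapy = 100, midterm = 58, BT0 = 44))
#' mae_solution(sim, clin)
mae_solution <- function(sim, clin) {
  tps <- intersect(.FOLLOWUP_TPS, intersect(names(sim), names(clin)))
  if (length(tps) == 0)
    stop("no common follow-up timepoints: MAE undefined")
  mean(abs(vrp(clin, tps) - vrp(sim, tps)))
}

#' Fit a patient's longitudinal volumes by profile-based search
#'
#' For each cisplatin kill rate in `ckr_grid` and each doubling time in
#' `td_grid`, samples `n` parameter sets compatible with the profile
#' ([sample_parameter_sets()]), simulates the patient's full treatment
#' course with each, and retains as *solutions* the sets whose simulated
#' volumes satisfy the chosen volumetric criterion at every available
#' timepoint.  Solutions are grouped into one family per CKR value.
#'
#' @param patient A `cv_patient` (see [synth_patient()]) with clinical
#'   volumes attached.
#' @param profile A [tumour_profile()].
#' @param ckr_grid Cisplatin kill-rate grid (default: the study grid
#'   0--0.5).
#' @param td_grid Doubling-time grid in days (default: the study grid, 20
#'   to 500 by 20, then 500-day steps to 3750).
#' @param criterion Volumetric compliance criterion for
#'   [check_criteria()].
#' @param n Sets sampled per (ckr, td) cell.
#' @param seed Integer seed.
#' @param keep_series Keep each solution's simulated [volume_series()].
#' @return Named list (one entry per CKR value) of `cv_family` objects:
#'   `ckr`, `criterion`, `members` (each with `params`, `td_target`,
#'   `mae`, `series`).  Families may be empty.
#' @export
fit_patient <- function(patient, profile,
                        ckr_grid = c(0, 0.05, 0.1, 0.2, 0.3, 0.4, 0.5),
                        td_grid = c(seq(20, 500, by = 20),
                                    seq(1000, 3750, by = 500)),
                        criterion = "VRP10", n = 100, seed = 1L,
                        keep_series = TRUE) {
  stopifnot(inherits(patient, "cv_patient"))
  if (is.null(patient$clinical))
    stop("patient has no clinical volume series to fit")
  fams <- list()
  for (ci in seq_along(ckr_grid)) {
    ckr <- ckr_grid[ci]
    members <- list()
    for (ti in seq_along(td_grid)) {
      td <- td_grid[ti]
      sets <- sample_parameter_sets(profile, td, ckr, n = n,
                                    seed = seed + 1000L * ci + ti)
      stopper <- .criterion_stopper(patient$clinical, criterion)
      for (s in sets) {
        sim <- patient_course(patient, profile, s, seed = seed,
                              early_stop = stopper)
        if (!is.null(sim$aborted_at)) next  # failed at first bad timepoint
        ok <- check_criteria(sim$volumes, patient$clinical, criterion)
        if (ok) {
          members[[length(members) + 1L]] <- list(
            params = s, td_target = td,
            mae = mae_solution(sim$volumes, patient$clinical),
            series = if (keep_series) sim$volumes else NULL)
        }
      }
    }
    fams[[as.character(ckr)]] <- structure(
      list(patient_id = patient$id, profile = profile, ckr = ckr,
           criterion = criterion, members = members),
      class = "cv_family")
  }
  fams
}

#' @export
print.cv_family <- function(x, ...) {
  cat(sprintf(
    "Solution family: patient %s, CKR %g, criterion %s, %d member(s)\n",
    x$patient_id, x$ckr, x$criterion, length(x$members)))
  if (length(x$members))
    cat(sprintf("  member MAE: %s%%\n",
                paste(sprintf("%.2f", vapply(x$members, `[[`, numeric(1),
                                             "mae")), collapse = ", ")))
  invisible(x)
}

# Early-rejection rule for the fitting search: abort a candidate's
# simulation at the first follow-up timepoint where the chosen volumetric
# criterion is already violated (identical thresholds and slack as
# check_criteria, so the retained set is unchanged -- only wasted
# simulation hours are saved).
.criterion_stopper <- function(clin, criterion) {
  v0 <- clin[["pretherapy"]]
  function(tp, vol) {
    if (!(tp %in% .FOLLOWUP_TPS) || !(tp %in% names(clin))) return(FALSE)
    if (criterion == "DV40")
      return(abs(vol - clin[[tp]]) > 0.4 * clin[[tp]] + 1e-9)
    dev <- abs((v0 - vol) / v0 * 100 - (clin[["pretherapy"]] - clin[[tp]]) /
                 clin[["pretherapy"]] * 100)
    thr <- switch(criterion, VRP5 = 5, VRP10 = 10,
                  MIXED = if (tp %in% c("midterm", "BT0")) 5 else 10)
    dev > thr + 1e-9
  }
}

#' Simulate one patient's course under a given parameter set
#'
#' Convenience wrapper: initialises the patient's mask with the profile
#' and parameter set and runs [simulate_course()] with the patient's
#' schedule.
#'
#' @param patient A `cv_patient`.
#' @param profile A [tumour_profile()].
#' @param params A [parameter_set()].
#' @param seed Spatial tie-break seed.
#' @param ... Passed on to [simulate_course()] (e.g. `trajectory`,
#'   `early_stop`).
#' @return A `cv_simulation` (see [simulate_course()]).
#' @export
patient_course <- function(patient, profile, params, seed = 1L, ...) {
  lat <- init_tumour(patient$mask, profile, params,
                     gc_edge = patient$gc_edge, density = patient$density)
  simulate_course(lat, params, patient$schedule, seed = seed, ...)
}

#' Mean-value parameter set of a solution family
#'
#' Collapses a solution family into a single representative parameter set
#' by assigning to each parameter the arithmetic mean of the corresponding
#' values across the family members (`n_limp` is rounded to the nearest
#' integer).  The mean set is then re-simulated on the patient and scored:
#' its MAE against the clinical volumes quantifies how well a single set
#' represents the patient/profile/CKR combination, and `pass` records
#' whether the mean set is itself a solution under the family's criterion.
#'
#' @param family A `cv_family` from [fit_patient()] (must be nonempty).
#' @param patient The fitted `cv_patient`.
#' @param seed Spatial tie-break seed for the re-simulation.
#' @return A `cv_mean_set`: list with `params`, `ckr`, `mae`, `pass`,
#'   `series`, `n_members`.
#' @export
mean_value_set <- function(family, patient, seed = 1L) {
  stopifnot(inherits(family, "cv_family"))
  if (length(family$members) == 0)
    stop("empty solution family: no mean-value set")
  plist <- lapply(family$members, `[[`, "params")
  fields <- c("t_cycle", "t_g0", "t_necrosis", "t_apoptosis", "n_limp",
              "alpha", "beta", "t_half", "oer", "ckr", "r_a", "r_ndiff",
              "r_adiff", "p_g0g1", "p_sleep", "p_sym", "stem_sens",
              "stem_frac")
  mean_fields <- lapply(fields, function(f)
    mean(vapply(plist, function(p) as.numeric(p[[f]]), numeric(1))))
  names(mean_fields) <- fields
  mp <- plist[[1]]
  for (f in fields) mp[[f]] <- mean_fields[[f]]
  mp$n_limp <- as.integer(round(mp$n_limp))
  validate_params(mp)
  sim <- patient_course(patient, family$profile, mp, seed = seed)
  structure(list(params = mp, ckr = family$ckr,
                 mae = mae_solution(sim$volumes, patient$clinical),
                 pass = as.logical(check_criteria(sim$volumes,
                                                  patient$clinical,
                                                  family$criterion)),
                 series = sim$volumes,
                 n_members = length(family$members),
                 profile = family$profile,
                 patient_id = patient$id),
            class = "cv_mean_set")
}

#' @export
print.cv_mean_set <- function(x, ...) {
  cat(sprintf(
    "Mean-value set: patient %s, CKR %g, %d members, MAE %.2f%%%s\n",
    x$patient_id, x$ckr, x$n_members, x$mae,
    if (x$pass) " (itself a solution)" else ""))
  invisible(x)
}

#' Patient/profile MAE over CKR values
#'
#' The single number characterising how well a tumour profile represents a
#' patient: the arithmetic mean of the per-CKR mean-value-set MAEs, taken
#' over the `M` CKR values that retrieved solutions.
#'
#' @param maes Numeric vector of per-CKR MAEs (one per CKR value with a
#'   nonempty family), or a list of `cv_mean_set` objects.
#' @return MAE in percentage points.
#' @export
#' @examples
#' mae_patient_profile(c(2.39, 1.58, 2.13, 1.84, 1.91, 2.15, 2.07))
mae_patient_profile <- function(maes) {
  if (is.list(maes))
    maes <- vapply(maes, function(m) m$mae, numeric(1))
  maes <- maes[!is.na(maes)]
  if (length(maes) == 0)
    stop("no CKR value retrieved solutions: patient/profile MAE undefined")
  mean(maes)
}
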