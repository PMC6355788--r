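#' Treatment schedule for a full chemoradiotherapy course
#'
#' Collects the timed therapy events of the modelled protocol on a common
#' clock of whole hours from pretherapy day 0, 00:00: external-beam
#' fractions (dose in Gy, uniform over the tumour), weekly cisplatin
#' administrations, and pulsed-dose-rate brachytherapy fractions (each a
#' [pulse_train()] plus a per-voxel total-dose map; the per-pulse dose map
#' is the total map divided by the number of pulses).  Imaging timepoints
#' are named hours at which the tumour volume is read out (at 00:00 of the
#' imaging day).
#'
#' @param ebrt Data frame with columns `hour` and `dose` (Gy).
#' @param cisplatin Integer vector of administration hours.
#' @param bt List of BT fractions, each a list with elements `hour` (first
#'   pulse start), `dose_map` (3-D array of total fraction dose per voxel,
#'   Gy) and `train` (a [pulse_train()]).
#' @param timepoints Named numeric vector of imaging hours; must include
#'   `pretherapy`.  Canonical names: `pretherapy`, `midterm`, `BT0`, `BT1`,
#'   `BT2` (subsets allowed).
#' @param t_end Final simulated hour (defaults to the last timepoint).
#'
#' @return An object of class `cv_schedule`.
#' @export
treatment_schedule <- function(ebrt = NULL, cisplatin = integer(0),
                               bt = list(), timepoints, t_end = NULL) {
  if (is.null(ebrt)) ebrt <- data.frame(hour = numeric(0), dose = numeric(0))
  stopifnot(is.data.frame(ebrt), all(c("hour", "dose") %in% names(ebrt)),
            all(ebrt$dose >= 0))
  if (!("pretherapy" %in% names(timepoints)))
    stop("timepoints must include `pretherapy`")
  for (f in bt) {
    stopifnot(is.list(f), !is.null(f$hour), inherits(f$train, "pulse_train"))
    if (!is.array(f$dose_map) || length(dim(f$dose_map)) != 3)
      stop("each BT fraction needs a 3-D total-dose map")
  }
  if (length(bt) && nrow(ebrt) &&
      min(vapply(bt, `[[`, numeric(1), "hour")) < max(ebrt$hour))
    warning("BT fractions start before the EBRT course ends")
  if (is.null(t_end)) t_end <- max(timepoints)
  structure(list(ebrt = ebrt[order(ebrt$hour), , drop = FALSE],
                 cisplatin = sort(cisplatin), bt = bt,
                 timepoints = timepoints[order(timepoints)],
                 t_end = t_end),
            class = "cv_schedule")
}

#' @export
print.cv_schedule <- function(x, ...) {
  cat(sprintf(
    "Treatment schedule: %d EBRT fractions (%g Gy total), %d cisplatin administrations, %d BT fractions; %d timepoints over %g days\n",
    nrow(x$ebrt), sum(x$ebrt$dose), length(x$cisplatin), length(x$bt),
    length(x$timepoints), x$t_end / 24))
  invisible(x)
}

#' Simulate a full treatment course on a tumour lattice
#'
#' Advances the tumour in 1 h steps from hour 0 to `schedule$t_end`.  Each
#' hour applies, in this fixed order: (1) the therapy events scheduled for
#' that hour (EBRT fraction, cisplatin administration, or one BT pulse,
#' with per-voxel pulse doses from the fraction dose map divided by the
#' number of pulses and the quadratic LQ term weighted by the
#' incomplete-repair increment of that pulse); (2) the cytokinetic scan of
#' every tumour GC at its current local crowding; (3) the spatial
#' rebalancing scan.  Volumes (census-based readout of [tumour_volume()])
#' are recorded at the schedule's named timepoints and, optionally, every
#' hour.
#'
#' @param lattice A [cv_lattice][init_tumour()] (left unmodified).
#' @param params A [parameter_set()] with `n_limp` matching the lattice.
#' @param schedule A [treatment_schedule()].
#' @param seed Integer seed for the spatial-scan tie-break hash.
#' @param spatial Run the spatial rebalancing scan (disable only for
#'   controlled numerical experiments).
#' @param trajectory Record the volume at every hour.
#' @param early_stop Optional `function(timepoint, volume)` called as each
#'   named timepoint is recorded; returning `TRUE` aborts the run
#'   (remaining timepoints stay `NA` and the result carries
#'   `aborted_at`).  Used by the fitting search to drop candidates at
#'   their first failing timepoint.
#'
#' @return A list of class `cv_simulation`: `volumes` (a [volume_series()]),
#'   `trajectory` (hourly volumes if requested), `final` (final lattice),
#'   `births`/`cleared` totals.
#' @export
simulate_course <- function(lattice, params, schedule, seed = 1L,
                            spatial = TRUE, trajectory = FALSE,
                            early_stop = NULL) {
  stopifnot(inherits(lattice, "cv_lattice"), inherits(params, "cv_params"),
            inherits(schedule, "cv_schedule"))
  if (lattice$n_limp != params$n_limp)
    stop("lattice was initialised for a different LIMP ladder depth")
  for (f in schedule$bt)
    if (!identical(dim(f$dose_map), as.integer(lattice$dim)) &&
        !identical(dim(f$dose_map), lattice$dim))
      stop(sprintf("schedule/grid mismatch: BT dose map is %s but the lattice grid is %s",
                   paste(dim(f$dose_map), collapse = "x"),
                   paste(lattice$dim, collapse = "x")))
  lat <- .dup_lattice(lattice)  # compiled kernels mutate these arrays

  t_end <- schedule$t_end
  # hour -> events lookup tables
  ebrt_dose <- numeric(t_end + 1)
  if (nrow(schedule$ebrt))
    ebrt_dose[schedule$ebrt$hour + 1] <- schedule$ebrt$dose
  cis_hours <- logical(t_end + 1)
  cis_hours[schedule$cisplatin + 1] <- TRUE
  # BT pulses: list indexed by hour
  pulse_at <- vector("list", t_end + 1)
  for (f in schedule$bt) {
    tr <- f$train
    dg <- delta_g(seq_len(tr$n_pulses), params_lq(params), tr)
    for (i in seq_len(tr$n_pulses)) {
      h <- f$hour + (i - 1) * (tr$pulse_duration + tr$interpulse_gap)
      h <- as.integer(round(h))
      if (h > t_end) next
      pulse_at[[h + 1]] <- c(pulse_at[[h + 1]],
                             list(list(map = f$dose_map / tr$n_pulses,
                                       dg = dg[i])))
    }
  }

  tp <- schedule$timepoints
  vols <- setNames(rep(NA_real_, length(tp)), names(tp))
  traj <- if (trajectory) numeric(t_end + 1) else NULL
  tot_births <- 0; tot_cleared <- 0
  aborted_at <- NULL

  for (h in 0:t_end) {
    act <- which(lat$active)
    # record volumes at 00:00, before this hour's events
    hit_tp <- which(tp == h)
    if (length(hit_tp)) {
      vols[hit_tp] <- tumour_volume(lat)[["volume_cm3"]]
      if (!is.null(early_stop)) {
        for (k in hit_tp) {
          if (isTRUE(early_stop(names(tp)[k], vols[[k]]))) {
            aborted_at <- names(tp)[k]
            break
          }
        }
        if (!is.null(aborted_at)) break
      }
    }
    if (trajectory) traj[h + 1] <- tumour_volume(lat)[["volume_cm3"]]
    if (length(act) == 0) next

    # (1) therapy events
    if (ebrt_dose[h + 1] > 0)
      irradiate_cpp(lat$states, act, rep(ebrt_dose[h + 1], length(act)),
                    params$n_limp, params$alpha, params$beta, 1.0,
                    params$oer, params$stem_sens, params$kill_diff)
    if (cis_hours[h + 1])
      cisplatin_cpp(lat$states, act, params$n_limp, params$ckr,
                    params$stem_sens)
    for (pu in pulse_at[[h + 1]]) {
      dvec <- pu$map[lat$coords[act, , drop = FALSE]]
      irradiate_cpp(lat$states, act, dvec, params$n_limp, params$alpha,
                    params$beta, pu$dg, params$oer, params$stem_sens,
                    params$kill_diff)
    }

    # (2) cytokinetic scan at the neighbourhood-aware local crowding: a GC
    # adjacent to densely packed tissue shares its saturated nutrient
    # supply, so the effective occupancy is the max over the GC and its
    # active neighbours
    tot <- col_totals_cpp(lat$states, act)
    if (!all(is.finite(tot)))
      stop(sprintf("non-finite census at hour %d", h))
    tot_all <- numeric(ncol(lat$states))
    tot_all[act] <- tot
    eff <- neighbour_max_occ_cpp(lat$index, lat$coords, lat$active, act,
                                 tot_all, as.integer(lat$dim)) / lat$capacity
    crowd <- pmin(eff / params$crowd_saturation, 1)
    res <- cyto_step_cpp(lat$states, params, act, crowd)
    tot_births <- tot_births + sum(res$births)
    tot_cleared <- tot_cleared + sum(res$cleared)

    # (3) spatial scan
    if (spatial) lat <- .spatial_step_(lat, seed = seed, hour = h)
  }

  if (anyNA(vols) && is.null(aborted_at))
    warning("timepoint(s) beyond t_end were never recorded")
  structure(list(volumes = volume_series(vols),
                 trajectory = traj, final = lat,
                 births = tot_births, cleared = tot_cleared,
                 aborted_at = aborted_at),
            class = "cv_simulation")
}

#' @export
print.cv_simulation <- function(x, ...) {
  cat("Simulated course\n")
  print(x$volumes)
  invisible(x)
}

#' Longitudinal tumour-volume series
#'
#' Named volumes (cm^3) at imaging timepoints.  `pretherapy` must be
#' present; canonical follow-up names are `midterm`, `BT0`, `BT1`, `BT2`.
#'
#' @param volumes Named numeric vector of volumes (cm^3), all >= 0.
#' @return An object of class `cv_volume_series`.
#' @export
#' @examples
#' volume_series(c(pretherapy = 38.2, midterm = 21.0, BT0 = 12.4,
#'                 BT1 = 11.1, BT2 = 9.0))
volume_series <- function(volumes) {
  stopifnot(is.numeric(volumes), !is.null(names(volumes)),
            all(volumes >= 0, na.rm = TRUE))
  if (!("pretherapy" %in% names(volumes)))
    stop("a volume series must contain a `pretherapy` volume")
  structure(volumes, class = "cv_volume_series")
}

#' @export
print.cv_volume_series <- function(x, ...) {
  df <- data.frame(timepoint = names(x), volume_cm3 = round(as.numeric(x), 4))
  ok <- names(x) != "pretherapy"
  df$VRP <- NA_real_
  df$VRP[ok] <- round(vrp(x, names(x)[ok]), 2)
  print(df, row.names = FALSE)
  invisible(x)
}

# follow-up timepoints entering volumetric compliance and MAE scores
.FOLLOWUP_TPS <- c("midterm", "BT0", "BT1", "BT2")

#' Volume reduction percentage
#'
#' `VRP = (V_pretherapy - V_final) / V_pretherapy * 100` for the requested
#' timepoint(s).  Negative values indicate growth.
#'
#' @param series A [volume_series()] (or named numeric vector with a
#'   `pretherapy` element).
#' @param final_tp Timepoint name(s) to evaluate; defaults to every
#'   post-baseline timepoint present.
#' @return Named numeric vector of VRPs (%).
#' @export
#' @examples
#' vrp(volume_series(c(pretherapy = 100, BT2 = 103.37)), "BT2")
vrp <- function(series, final_tp = setdiff(names(series), "pretherapy")) {
  v0 <- series[["pretherapy"]]
  if (!is.finite(v0) || v0 <= 0) stop("pretherapy volume must be positive")
  missing_tp <- setdiff(final_tp, names(series))
  if (length(missing_tp))
    stop("timepoint(s) not in series: ", paste(missing_tp, collapse = ", "))
  setNames((v0 - as.numeric(series[final_tp])) / v0 * 100, final_tp)
}

#' Volumetric compliance between a simulated and a clinical tumour
#'
#' Tests whether a simulated volume series agrees with the clinical one at
#' every common follow-up timepoint (`midterm`, `BT0`, `BT1`, `BT2`), under
#' one of four criteria devised to absorb tumour-delineation uncertainty:
#' \describe{
#'   \item{VRP5}{`|VRP_sim - VRP_clin| <= 5` percentage points everywhere.}
#'   \item{VRP10}{as above with a 10-point threshold.}
#'   \item{MIXED}{5 points at `midterm`/`BT0`, 10 points at `BT1`/`BT2`.}
#'   \item{DV40}{`|GTV_sim - GTV_clin| <= 0.4 * GTV_clin` everywhere
#'     (may be stricter or more lenient than VRP10 depending on the
#'     volume).}
#' }
#' All bounds are inclusive.
#'
#' @param sim,clin [volume_series()] objects.
#' @param criterion One of `"VRP5"`, `"VRP10"`, `"MIXED"`, `"DV40"`.
#' @return Logical (accepted?) with attribute `ledger`: a data frame with
#'   one row per evaluated timepoint (deviation, threshold, pass).
#' @export
check_criteria <- function(sim, clin,
                           criterion = c("VRP5", "VRP10", "MIXED", "DV40")) {
  criterion <- match.arg(criterion)
  tps <- intersect(.FOLLOWUP_TPS, intersect(names(sim), names(clin)))
  if (length(tps) == 0) stop("no common follow-up timepoints to compare")
  if (criterion == "DV40") {
    dev <- abs(as.numeric(sim[tps]) - as.numeric(clin[tps]))
    thr <- 0.4 * as.numeric(clin[tps])
  } else {
    dev <- abs(vrp(sim, tps) - vrp(clin, tps))
    thr <- switch(criterion,
                  VRP5 = rep(5, length(tps)),
                  VRP10 = rep(10, length(tps)),
                  MIXED = ifelse(tps %in% c("midterm", "BT0"), 5, 10))
  }
  # inclusive bounds with a numerical guard so that a deviation of exactly
  # the threshold passes despite floating-point VRP arithmetic
  ledger <- data.frame(timepoint = tps, deviation = dev, threshold = thr,
                       pass = dev <= thr + 1e-9, row.names = NULL)
  structure(all(ledger$pass), ledger = ledger, criterion = criterion)
}
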