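# Seed hygiene: run `code` under a temporary RNG state so that generators
# are reproducible without clobbering the caller's RNG stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Synthetic patient fixture
#'
#' Generates a deterministic synthetic patient emulating the modelled
#' treatment protocol and data layout: an ellipsoidal gross-tumour-volume
#' mask of the requested volume; 25 external-beam fractions of 2 Gy on
#' weekdays; weekly cisplatin; two brachytherapy fractions of 20 pulses at
#' a 1 h start-to-start interval and 0.25 h pulse duration, each with a
#' centrally peaked per-voxel total-dose map (inverse-square falloff from
#' an internal source, scaled to a prescribed tumour-mean fraction dose);
#' and the five imaging timepoints `pretherapy` (day 0), `midterm` (during
#' EBRT), `BT0` (before BT), `BT1` and `BT2` (starts of the BT fractions).
#' Clinical volumes are not filled in: pair with [synth_clinical()] to
#' plant a known parameter set, or attach measured volumes.
#'
#' @param volume_cm3 Requested pretherapy tumour volume (cm^3).
#' @param seed Integer seed; identical seeds give identical patients.
#' @param id Patient identifier string.
#' @param gc_edge GC edge length (mm).
#' @param density Cell density (cells/cm^3).
#' @param mean_bt_dose Tumour-mean total dose of each BT fraction (Gy).
#' @param ebrt_fraction_dose Dose per EBRT fraction (Gy).
#' @param n_ebrt_fractions Number of EBRT fractions (5 per week).
#' @param pulse_duration BT pulse duration (h); the start-to-start pulse
#'   interval is fixed at 1 h, so the irradiation-free gap is
#'   `1 - pulse_duration`.
#' @param aspect Ellipsoid axis ratios (length 3), jittered slightly by the
#'   seed.
#'
#' @return An object of class `cv_patient`: list with `id`, `mask`,
#'   `gc_edge`, `density`, `schedule` (a [treatment_schedule()]),
#'   `clinical` (NULL slot for a [volume_series()]).
#' @export
#' @examples
#' p <- synth_patient(volume_cm3 = 2, seed = 7)
#' p$schedule
synth_patient <- function(volume_cm3 = 30, seed = 1L, id = "synth",
                          gc_edge = 1, density = 1e9, mean_bt_dose = 15,
                          ebrt_fraction_dose = 2, n_ebrt_fractions = 25,
                          pulse_duration = 0.25,
                          aspect = c(1, 1.15, 0.9)) {
  with_seed(seed, {
    gc_vol <- (gc_edge / 10)^3
    n_target <- volume_cm3 / gc_vol
    jit <- runif(3, 0.95, 1.05)
    ax <- aspect * jit
    # semi-axes (voxels) of an ellipsoid with ~n_target voxels
    r0 <- (3 * n_target / (4 * pi * prod(ax)))^(1 / 3)
    semi <- ax * r0
    margin <- 6L
    dims <- as.integer(2 * ceiling(semi) + 2 * margin + 1)
    ctr <- (dims + 1) / 2
    g <- expand.grid(i = seq_len(dims[1]), j = seq_len(dims[2]),
                     k = seq_len(dims[3]))
    inside <- ((g$i - ctr[1]) / semi[1])^2 + ((g$j - ctr[2]) / semi[2])^2 +
      ((g$k - ctr[3]) / semi[3])^2 <= 1
    mask <- array(0, dims)
    mask[cbind(g$i, g$j, g$k)[inside, , drop = FALSE]] <- 1

    # EBRT: 5 fractions/week at 10:00, no weekend irradiation
    frac_day <- vapply(seq_len(n_ebrt_fractions) - 1L,
                       function(f) 7L * (f %/% 5L) + f %% 5L, integer(1))
    ebrt <- data.frame(hour = frac_day * 24 + 10,
                       dose = ebrt_fraction_dose)
    # weekly cisplatin at 09:00 on the first day of each EBRT week
    cis <- unique(7L * (frac_day %/% 7L)) * 24 + 9
    ebrt_end_day <- max(frac_day)

    # BT fractions: day gaps after EBRT, pulses start 10:00
    bt1_day <- ebrt_end_day + 4L
    bt2_day <- bt1_day + 7L
    train <- pulse_train(n_pulses = 20, pulse_dose = mean_bt_dose / 20,
                         pulse_duration = pulse_duration,
                         interpulse_gap = 1 - pulse_duration)
    mkmap <- function() {
      src <- ctr + runif(3, -0.15, 0.15) * semi
      d2 <- ((g$i - src[1]) * gc_edge)^2 + ((g$j - src[2]) * gc_edge)^2 +
        ((g$k - src[3]) * gc_edge)^2
      raw <- 1 / (sqrt(d2) + 2)^2
      m <- array(raw, dims)
      m * (mean_bt_dose / mean(m[mask == 1]))
    }
    bt <- list(
      list(hour = bt1_day * 24 + 10, dose_map = mkmap(), train = train),
      list(hour = bt2_day * 24 + 10, dose_map = mkmap(), train = train))

    tps <- c(pretherapy = 0,
             midterm = 21 * 24,
             BT0 = (bt1_day - 1L) * 24,
             BT1 = bt1_day * 24,
             BT2 = bt2_day * 24)
    sched <- treatment_schedule(ebrt = ebrt, cisplatin = cis, bt = bt,
                                timepoints = tps,
                                t_end = (bt2_day + 1L) * 24)
    structure(list(id = id, mask = mask, gc_edge = gc_edge,
                   density = density, schedule = sched, clinical = NULL),
              class = "cv_patient")
  })
}

#' @export
print.cv_patient <- function(x, ...) {
  cat(sprintf("Patient %s: %.3g cm^3 mask (%d voxels of %g mm)\n", x$id,
              sum(x$mask) * (x$gc_edge / 10)^3, sum(x$mask), x$gc_edge))
  print(x$schedule)
  if (!is.null(x$clinical)) print(x$clinical)
  invisible(x)
}

#' Plant a known parameter set as a patient's clinical truth
#'
#' Simulates the patient's treatment course with the given profile and
#' parameter set and stores the resulting volume series as the patient's
#' clinical (ground-truth) data.  Used to build round-trip
#' parameter-recovery fixtures and synthetic cohorts.
#'
#' @param patient A [synth_patient()].
#' @param profile A [tumour_profile()].
#' @param params A [parameter_set()].
#' @param seed Spatial tie-break seed for the truth simulation.
#' @return The patient with `clinical`, `true_params` and `profile` filled
#'   in.
#' @export
synth_clinical <- function(patient, profile, params, seed = 1L) {
  stopifnot(inherits(patient, "cv_patient"))
  lat <- init_tumour(patient$mask, profile, params,
                     gc_edge = patient$gc_edge, density = patient$density)
  sim <- simulate_course(lat, params, patient$schedule, seed = seed)
  patient$clinical <- sim$volumes
  patient$true_params <- params
  patient$profile <- profile
  patient
}

#' Synthetic cohort with two planted regression archetypes
#'
#' Builds a cohort whose tumours follow one of two characteristic
#' regression profiles observed clinically: steep regressors
#' (radiosensitive, fast dead-cell clearance — near-exponential volume
#' decay from the start) and shouldered regressors (radioresistant, slow
#' clearance — little early shrinkage).  Archetype membership drives the
#' planted parameter sets; geometry and exact parameter values are
#' jittered per patient by the seed.
#'
#' @param n_per_archetype Patients per archetype.
#' @param seed Integer seed.
#' @param profile The [tumour_profile()] shared by the cohort.
#' @param ckr Cisplatin kill rate of every planted set.
#' @param volume_cm3 Mean pretherapy volume (jittered +/-25%).
#' @param ... Passed to [synth_patient()] (e.g. `gc_edge`).
#' @return List of [synth_patient()] objects with clinical truths planted;
#'   each carries an `archetype` field.
#' @export
synth_cohort <- function(n_per_archetype = 3, seed = 1L,
                         profile = tumour_profile(60, 30, 5), ckr = 0.2,
                         volume_cm3 = 1, ...) {
  n <- 2L * n_per_archetype
  arch <- rep(c("steep", "shouldered"), each = n_per_archetype)
  with_seed(seed, {
    sub_seeds <- sample.int(2^30, n + 1)
    vols <- volume_cm3 * runif(n, 0.75, 1.25)
    alpha_s <- runif(n_per_archetype, 0.38, 0.5)
    tn_s <- runif(n_per_archetype, 40, 80)
    alpha_r <- runif(n_per_archetype, 0.04, 0.08)
    tn_r <- runif(n_per_archetype, 600, 1200)
    alphas <- c(alpha_s, alpha_r)
    tns <- c(tn_s, tn_r)
    thalf <- runif(n, 1.2, 1.8)
    psym <- runif(n, 0.35, 0.5)
    lapply(seq_len(n), function(i) {
      pars <- parameter_set(
        t_cycle = runif(1, 22, 30), t_g0 = runif(1, 120, 200),
        t_necrosis = tns[i], t_apoptosis = runif(1, 4, 10), n_limp = 6,
        lq = lq_params(alpha = alphas[i], beta = alphas[i] / 10,
                       t_half = thalf[i], oer = 2),
        ckr = ckr, r_a = runif(1, 1e-3, 3e-3), r_ndiff = 0.005,
        r_adiff = 0.095, p_g0g1 = 0.03, p_sleep = runif(1, 0.1, 0.3),
        p_sym = psym[i])
      pat <- synth_patient(volume_cm3 = vols[i], seed = sub_seeds[i],
                           id = sprintf("%s%02d", substr(arch[i], 1, 2), i),
                           ...)
      pat <- synth_clinical(pat, profile, pars, seed = sub_seeds[n + 1])
      pat$archetype <- arch[i]
      pat
    })
  })
}
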