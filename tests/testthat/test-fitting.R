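test_that("sampled parameter sets respect ranges, realise the profile and
          recover the target doubling time", {
  prof <- high_prolif()
  sets <- sample_parameter_sets(prof, td = 80, ckr = 0.2, n = 100, seed = 1)
  expect_length(sets, 100)
  expect_true(all(vapply(sets, params_in_range, logical(1))))
  tds <- vapply(sets, doubling_time, numeric(1))
  expect_true(all(abs(tds - 80) / 80 < 0.1))
  expect_true(all(vapply(sets, function(s) s$ckr, numeric(1)) == 0.2))
  # sets differ from one another
  alphas <- vapply(sets, function(s) s$alpha, numeric(1))
  expect_gt(length(unique(alphas)), 90)
  # the sampled composition realises the profile exactly at init
  p <- sets[[7]]
  lat <- init_tumour(array(1, c(2, 2, 2)), prof, p)
  s <- summary_census(gc_state(p$n_limp, lat$states[, 1]))
  expect_equal(s[["cycling"]] / s[["living"]], 0.6, tolerance = 5e-3)
  expect_equal(s[["dormant"]] / s[["total"]], 0.3, tolerance = 5e-3)
  expect_equal(s[["necrotic"]] / s[["total"]], 0.05, tolerance = 5e-3)
})

test_that("free-growth simulation confirms the sampler's doubling-time
          calibration", {
  prof <- high_prolif()
  sets <- sample_parameter_sets(prof, td = 60, ckr = 0, n = 3, seed = 11)
  sch <- treatment_schedule(timepoints = c(pretherapy = 0, end = 24 * 80),
                            t_end = 24 * 80)
  for (s in sets) {
    lat <- init_tumour(sphere_mask(5, pad = 9), prof, s)
    sim <- simulate_course(lat, s, sch, seed = 1, trajectory = TRUE)
    # slope after the cell-lineage composition transient (LIMP ladders up
    # to 18 generations x a long cell cycle take ~6 weeks to equilibrate)
    w <- (60 * 24):(80 * 24)
    slope <- stats::coef(stats::lm(log(sim$trajectory[w]) ~ w))[2]
    expect_lt(abs(log(2) / slope / 24 - 60) / 60, 0.1)
  }
})

test_that("unreachable doubling times yield an empty result with a
          diagnostic, and seeds reproduce draws", {
  prof <- high_prolif()
  out <- sample_parameter_sets(prof, td = 1, ckr = 0.2, n = 4, seed = 1,
                               max_attempts = 8)
  expect_length(out, 0)
  expect_match(attr(out, "diagnostic"), "unreachable")
  a <- sample_parameter_sets(prof, td = 120, ckr = 0.1, n = 6, seed = 42)
  b <- sample_parameter_sets(prof, td = 120, ckr = 0.1, n = 6, seed = 42)
  expect_identical(a[], b[])
})

test_that("the VRP mean absolute error is a metric-like score", {
  clin <- volume_series(c(pretherapy = 100, midterm = 60, BT0 = 50,
                          BT1 = 40, BT2 = 30))
  expect_equal(mae_solution(clin, clin), 0)
  # deviations {2,4,6,8} average to 5
  sim <- volume_series(c(pretherapy = 100, midterm = 62, BT0 = 54,
                         BT1 = 46, BT2 = 38))
  expect_equal(mae_solution(sim, clin), 5)
  # a single common timepoint gives that deviation
  one <- volume_series(c(pretherapy = 100, BT0 = 53))
  expect_equal(mae_solution(one, clin), 3)
  expect_gt(mae_solution(sim, clin), 0)
  no_common <- volume_series(c(pretherapy = 100, BT2 = 10))
  expect_error(mae_solution(one, no_common), "no common")
})

test_that("self-fit: a sampled set passes VRP5 against its own simulation
          and is recovered by the search", {
  prof <- high_prolif()
  truth <- typical_params(td = 80, n_limp = 5)
  pat <- synth_patient(volume_cm3 = 0.3, seed = 31, id = "selffit")
  pat <- synth_clinical(pat, prof, truth, seed = 1)
  sim <- patient_course(pat, prof, truth, seed = 1)
  expect_true(check_criteria(sim$volumes, pat$clinical, "VRP5"))
  expect_lt(mae_solution(sim$volumes, pat$clinical), 1e-9)
  fams <- fit_patient(pat, prof, ckr_grid = 0.2, td_grid = 80,
                      criterion = "VRP10", n = 12, seed = 5)
  expect_s3_class(fams[["0.2"]], "cv_family")
})

test_that("a profile incompatible with the observed course returns empty
          families", {
  # a tumour that quintuples under full-dose EBRT is unreachable for slow
  # growers within the plausible parameter ranges
  prof <- high_prolif()
  pat <- synth_patient(volume_cm3 = 0.3, seed = 32, id = "regrow")
  pat$clinical <- volume_series(c(pretherapy = 0.3, midterm = 1.5,
                                  BT0 = 2.0, BT1 = 2.1, BT2 = 2.5))
  fams <- fit_patient(pat, prof, ckr_grid = 0, td_grid = 1000,
                      criterion = "VRP5", n = 6, seed = 9)
  expect_length(fams[["0"]]$members, 0)
})

test_that("mean-value sets are field-wise means inside the member hull", {
  prof <- high_prolif()
  pat <- synth_patient(volume_cm3 = 0.3, seed = 33, id = "mv")
  truth <- typical_params(td = 80, n_limp = 5)
  pat <- synth_clinical(pat, prof, truth, seed = 1)
  # construct a family by hand from sampled sets (all self-consistent sims)
  sets <- sample_parameter_sets(prof, td = 80, ckr = 0.2, n = 5, seed = 2)
  members <- lapply(sets, function(s) {
    sim <- patient_course(pat, prof, s, seed = 1)
    list(params = s, td_target = 80,
         mae = mae_solution(sim$volumes, pat$clinical), series = sim$volumes)
  })
  fam <- structure(list(patient_id = pat$id, profile = prof, ckr = 0.2,
                        criterion = "VRP10", members = members),
                   class = "cv_family")
  ms <- mean_value_set(fam, pat)
  for (f in c("alpha", "beta", "t_cycle", "r_a", "p_sym", "t_necrosis")) {
    vals <- vapply(sets, function(s) s[[f]], numeric(1))
    expect_equal(ms$params[[f]], mean(vals), tolerance = 1e-12)
    expect_gte(ms$params[[f]], min(vals))
    expect_lte(ms$params[[f]], max(vals))
  }
  # a family of identical sets collapses to that set
  fam1 <- fam
  fam1$members <- rep(members[1], 3)
  ms1 <- mean_value_set(fam1, pat)
  expect_equal(ms1$params$alpha, sets[[1]]$alpha)
  # two members give the field-wise midpoint
  fam2 <- fam
  fam2$members <- members[1:2]
  ms2 <- mean_value_set(fam2, pat)
  expect_equal(ms2$params$alpha,
               (sets[[1]]$alpha + sets[[2]]$alpha) / 2, tolerance = 1e-12)
  expect_error(mean_value_set(structure(list(members = list()),
                                        class = "cv_family"), pat),
               "empty")
})

test_that("the patient/profile error is the mean over CKR values with
          solutions", {
  expect_equal(round(mae_patient_profile(
    c(2.39, 1.58, 2.13, 1.84, 1.91, 2.15, 2.07)), 2), 2.01)
  expect_equal(round(mae_patient_profile(
    c(4.85, 7.15, 7.19, 5.80, 3.03, 3.60)), 2), 5.27)
  expect_equal(mae_patient_profile(7.3), 7.3)
  expect_error(mae_patient_profile(numeric(0)), "undefined")
})
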