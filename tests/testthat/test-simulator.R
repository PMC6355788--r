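test_that("volume reduction percentage handles regression, growth and
          degenerate input", {
  s <- volume_series(c(pretherapy = 100, midterm = 100, BT2 = 0))
  expect_equal(unname(vrp(s, "midterm")), 0)
  expect_equal(unname(vrp(s, "BT2")), 100)
  # growth gives a negative VRP
  g <- volume_series(c(pretherapy = 100, midterm = 103.37))
  expect_equal(unname(vrp(g, "midterm")), -3.37, tolerance = 1e-12)
  expect_error(vrp(volume_series(c(pretherapy = 0, BT0 = 1))), "positive")
  expect_error(vrp(s, "BT1"), "not in series")
  expect_error(volume_series(c(midterm = 3)), "pretherapy")
})

test_that("volumetric compliance criteria behave at their boundaries", {
  clin <- volume_series(c(pretherapy = 100, midterm = 60, BT0 = 50,
                          BT1 = 40, BT2 = 30))
  expect_true(check_criteria(clin, clin, "VRP5"))
  expect_true(check_criteria(clin, clin, "VRP10"))
  expect_true(check_criteria(clin, clin, "MIXED"))
  expect_true(check_criteria(clin, clin, "DV40"))
  # a VRP deviation of exactly 5 points everywhere is accepted (inclusive)
  sim5 <- volume_series(c(pretherapy = 100, midterm = 55, BT0 = 45,
                          BT1 = 35, BT2 = 25))
  expect_true(check_criteria(sim5, clin, "VRP5"))
  sim6 <- volume_series(c(pretherapy = 100, midterm = 54, BT0 = 45,
                          BT1 = 35, BT2 = 25))
  expect_false(check_criteria(sim6, clin, "VRP5"))
  expect_true(check_criteria(sim6, clin, "VRP10"))
  # MIXED: 5 points early, 10 points late
  simM <- volume_series(c(pretherapy = 100, midterm = 55, BT0 = 45,
                          BT1 = 31, BT2 = 21))
  expect_true(check_criteria(simM, clin, "MIXED"))
  simM2 <- volume_series(c(pretherapy = 100, midterm = 54, BT0 = 45,
                           BT1 = 31, BT2 = 21))
  expect_false(check_criteria(simM2, clin, "MIXED"))
  # DV40 boundary: simulated volume at exactly 1.4x clinical passes
  sim14 <- volume_series(setNames(1.4 * as.numeric(clin), names(clin)))
  expect_true(check_criteria(sim14, clin, "DV40"))
  sim15 <- volume_series(setNames(1.41 * as.numeric(clin), names(clin)))
  expect_false(check_criteria(sim15, clin, "DV40"))
})

test_that("DV40 and VRP10 flip relative strictness with tumour volume", {
  # near-complete response: tiny absolute volumes, small VRP deviations --
  # VRP10 accepts, DV40 rejects
  clin_small <- volume_series(c(pretherapy = 100, midterm = 1))
  sim_small <- volume_series(c(pretherapy = 100, midterm = 2))
  expect_true(check_criteria(sim_small, clin_small, "VRP10"))
  expect_false(check_criteria(sim_small, clin_small, "DV40"))
  # modest response on a large tumour: VRP deviation 20 points, but within
  # 40% of the clinical volume -- DV40 accepts, VRP10 rejects
  clin_big <- volume_series(c(pretherapy = 100, midterm = 80))
  sim_big <- volume_series(c(pretherapy = 100, midterm = 100))
  expect_false(check_criteria(sim_big, clin_big, "VRP10"))
  expect_true(check_criteria(sim_big, clin_big, "DV40"))
})

test_that("a fixed seed reproduces a course bit for bit", {
  p <- typical_params(td = 100, n_limp = 4)
  pat <- synth_patient(volume_cm3 = 0.3, seed = 21)
  lat <- init_tumour(pat$mask, high_prolif(), p)
  a <- simulate_course(lat, p, pat$schedule, seed = 3)
  b <- simulate_course(lat, p, pat$schedule, seed = 3)
  expect_identical(as.numeric(a$volumes), as.numeric(b$volumes))
  expect_identical(a$final$states, b$final$states)
})

test_that("higher radiosensitivity never increases post-treatment volume", {
  pat <- synth_patient(volume_cm3 = 0.3, seed = 22)
  vols <- lapply(c(0.15, 0.3, 0.5), function(a) {
    p <- parameter_set(n_limp = 4, lq = lq_params(a, a / 10, 1.5, 2),
                       ckr = 0.2, t_necrosis = 200, p_sleep = 0.2)
    lat <- init_tumour(pat$mask, high_prolif(), p)
    simulate_course(lat, p, pat$schedule, seed = 1)$volumes
  })
  for (tp in c("midterm", "BT0", "BT1", "BT2")) {
    v <- vapply(vols, `[[`, numeric(1), tp)
    expect_true(all(diff(v) <= 1e-12))
  }
})

test_that("near-total kill with instant clearance collapses the tumour to
          its dead remnant", {
  p <- parameter_set(n_limp = 2, lq = lq_params(20, 0, 1.5, 1),
                     t_necrosis = 1, t_apoptosis = 1, r_a = 0, p_sleep = 0)
  mask <- sphere_mask(3)
  lat <- init_tumour(mask, tumour_profile(60, 30, 5), p)
  sch <- treatment_schedule(ebrt = data.frame(hour = 10, dose = 2),
                            timepoints = c(pretherapy = 0, BT0 = 24 * 5),
                            t_end = 24 * 5)
  sim <- simulate_course(lat, p, sch, seed = 1)
  expect_lt(sim$volumes[["BT0"]] / sim$volumes[["pretherapy"]], 1e-4)
})

test_that("a 20-pulse BT fraction at the lattice level telescopes per GC at
          its own dose", {
  # frozen kinetics, no spatial scan, non-uniform dose map
  p <- parameter_set(n_limp = 2, t_cycle = 1e9, r_a = 0, r_ndiff = 0,
                     r_adiff = 0, p_g0g1 = 0, p_sleep = 0, t_g0 = 1e12,
                     t_necrosis = 1e12, t_apoptosis = 1e12,
                     lq = lq_params(0.3, 0.03, 1.5, 2))
  mask <- array(0, c(4, 4, 4)); mask[2:3, 2, 2] <- 1
  dose_map <- array(0, c(4, 4, 4)); dose_map[2, 2, 2] <- 12; dose_map[3, 2, 2] <- 20
  tr <- pulse_train(20, pulse_duration = 0.25)
  sch <- treatment_schedule(
    bt = list(list(hour = 10, dose_map = dose_map, train = tr)),
    timepoints = c(pretherapy = 0, BT1 = 0, BT2 = 48), t_end = 48)
  lat <- init_tumour(mask, tumour_profile(60, 30, 0), p)
  sim <- simulate_course(lat, p, sch, seed = 1, spatial = FALSE)
  g20 <- g_factor(20, repair_rate(1.5), 0.25, 0.75)
  for (j in 1:2) {
    d <- dose_map[j + 1, 2, 2] / 20
    # normoxic compartments: whole-train survival at the per-GC dose
    sf <- exp(-(0.3 * 20 * d + 0.03 * 20 * g20 * d^2))
    idx <- which(lat$states[, j] > 0 &
                   !grepl("G0|necrotic", rownames(lat$states)))
    expect_equal(sim$final$states[idx, j], lat$states[idx, j] * sf,
                 tolerance = 1e-6)
  }
})

test_that("schedule construction validates and warns about protocol
          violations", {
  expect_error(treatment_schedule(timepoints = c(midterm = 24)), "pretherapy")
  tr <- pulse_train(20)
  dm <- array(1, c(3, 3, 3))
  expect_warning(
    treatment_schedule(ebrt = data.frame(hour = c(10, 200), dose = 2),
                       bt = list(list(hour = 100, dose_map = dm, train = tr)),
                       timepoints = c(pretherapy = 0, BT1 = 96), t_end = 240),
    "before the EBRT course ends")
})
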