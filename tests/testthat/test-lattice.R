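test_that("profile constructor enforces the accounting identities", {
  expect_s3_class(tumour_profile(60, 30, 5), "cv_profile")
  expect_error(tumour_profile(10, 60, 50), "exceed 100")
  expect_error(tumour_profile(-1, 30, 5))
  # dormant pool cannot exceed the non-proliferating living pool
  p <- parameter_set(n_limp = 2)
  mask <- array(1, c(2, 2, 2))
  expect_error(init_tumour(mask, tumour_profile(90, 30, 5), p),
               "infeasible profile")
})

test_that("initialization realises the tumour profile exactly", {
  p <- parameter_set(n_limp = 6)
  mask <- sphere_mask(4)
  lat <- init_tumour(mask, high_prolif(), p)
  s <- summary_census(gc_state(6, lat$states[, 1]))
  expect_equal(s[["necrotic"]] / s[["total"]], 0.05, tolerance = 5e-3)
  expect_equal(s[["dormant"]] / s[["total"]], 0.30, tolerance = 5e-3)
  expect_equal(s[["cycling"]] / s[["living"]], 0.60, tolerance = 5e-3)
  expect_equal(s[["stem"]] / s[["living"]], p$stem_frac, tolerance = 5e-3)
  # zero dead fraction leaves an empty dead pool
  lat0 <- init_tumour(mask, tumour_profile(60, 30, 0), p)
  expect_equal(sum(lat0$states[c("apoptotic", "necrotic"), 1]), 0)
})

test_that("cell count equals volume times density", {
  p <- parameter_set(n_limp = 3)
  # a 10 x 10 x 10 block of 1 mm GCs is exactly 1 cm^3
  mask <- array(0, c(14, 14, 14)); mask[3:12, 3:12, 3:12] <- 1
  lat <- init_tumour(mask, high_prolif(), p, gc_edge = 1, density = 1e9)
  v <- tumour_volume(lat)
  expect_equal(v[["cells"]], 1e9)
  expect_equal(v[["volume_cm3"]], 1)
  expect_equal(v[["volume_gc_cm3"]], 1)
  # empty lattice reads zero
  lat$active[] <- FALSE
  expect_equal(tumour_volume(lat)[["volume_cm3"]], 0)
})

test_that("masks are validated", {
  p <- parameter_set(n_limp = 2)
  expect_error(init_tumour(array(0, c(4, 4, 4)), high_prolif(), p), "empty")
  bad <- array(0, c(4, 4, 4)); bad[2, 2, 2] <- 2
  expect_error(init_tumour(bad, high_prolif(), p), "not binary")
  expect_error(init_tumour(array(1, c(4, 4)), high_prolif(), p), "3-D")
})

test_that("an under-populated GC dissolves into its neighbour", {
  lat <- two_gc_lattice(0.01, 0.5)
  before <- sum(col_totals <- tumour_volume(lat)[["cells"]])
  out <- spatial_step(lat)
  expect_equal(sum(out$active), 1)
  expect_equal(tumour_volume(out)[["cells"]], before, tolerance = 1e-12)
  # the survivor holds everything
  j <- which(out$active)
  expect_equal(sum(out$states[, j]), before, tolerance = 1e-12)
})

test_that("a full lattice is a fixed point of the spatial scan", {
  p <- parameter_set(n_limp = 3)
  lat <- init_tumour(sphere_mask(3), high_prolif(), p)
  out <- spatial_step(lat)
  expect_equal(out$active, lat$active)
  expect_equal(out$states, lat$states)
})

test_that("an over-full GC spills into neighbours and annexes at the
          boundary", {
  p <- parameter_set(n_limp = 2)
  mask <- array(0, c(5, 5, 5)); mask[3, 3, 3] <- 1
  lat <- init_tumour(mask, high_prolif(), p)
  lat$states[, 1] <- lat$states[, 1] * 2.5   # 250% occupancy
  out <- spatial_step(lat)
  expect_gt(sum(out$active), 1)
  occ <- cervosim:::col_totals_cpp(out$states, which(out$active)) / out$capacity
  expect_lt(max(occ), 1 + 1e-9)
  expect_equal(tumour_volume(out)[["cells"]],
               tumour_volume(lat)[["cells"]], tolerance = 1e-12)
})

test_that("the spatial scan conserves cells over random lattices", {
  p <- parameter_set(n_limp = 2)
  for (s in 1:100) {
    set.seed(s)
    mask <- array(0, c(7, 7, 7))
    mask[2:6, 2:6, 2:6] <- rbinom(125, 1, 0.6)
    if (sum(mask) == 0) next
    lat <- init_tumour(mask, high_prolif(), p)
    n_act <- sum(lat$active)
    scale <- runif(n_act, 0, 1.8)
    for (j in seq_len(n_act)) lat$states[, j] <- lat$states[, j] * scale[j]
    before <- tumour_volume(lat)[["cells"]]
    out <- spatial_step(lat, seed = s)
    expect_equal(tumour_volume(out)[["cells"]], before, tolerance = 1e-9)
  }
})

test_that("the scan outcome is independent of column storage order", {
  p <- parameter_set(n_limp = 2)
  set.seed(3)
  mask <- array(0, c(7, 7, 7)); mask[2:6, 2:6, 2:6] <- rbinom(125, 1, 0.7)
  lat <- init_tumour(mask, high_prolif(), p)
  n_act <- sum(lat$active)
  scale <- runif(n_act, 0, 1.6)
  for (j in seq_len(n_act)) lat$states[, j] <- lat$states[, j] * scale[j]
  # rebuild the same physical lattice with permuted column order
  perm <- sample(n_act)
  lat2 <- lat
  lat2$states[, seq_len(n_act)] <- lat$states[, perm]
  lat2$coords[seq_len(n_act), ] <- lat$coords[perm, ]
  lat2$index[lat2$coords[seq_len(n_act), ]] <- seq_len(n_act)
  occ_field <- function(l) {
    a <- array(0, l$dim)
    act <- which(l$active)
    a[l$coords[act, , drop = FALSE]] <- cervosim:::col_totals_cpp(l$states, act)
    a
  }
  o1 <- occ_field(spatial_step(lat, seed = 9))
  o2 <- occ_field(spatial_step(lat2, seed = 9))
  expect_equal(o1, o2, tolerance = 1e-9)
})

test_that("free growth on the lattice reproduces the calibrated doubling
          time", {
  p <- parameter_set(n_limp = 4, p_sleep = 0.2, r_a = 0.002)
  td <- doubling_time(p)
  lat <- init_tumour(sphere_mask(6, pad = 16), high_prolif(), p)
  sch <- treatment_schedule(timepoints = c(pretherapy = 0, end = 24 * 60),
                            t_end = 24 * 60)
  sim <- simulate_course(lat, p, sch, seed = 1, trajectory = TRUE)
  # fit the asymptotic slope after the composition transient has decayed
  w <- (40 * 24):(60 * 24)
  slope <- stats::coef(stats::lm(log(sim$trajectory[w]) ~ w))[2]
  td_meas <- log(2) / slope / 24
  expect_lt(abs(td_meas - td) / td, 0.1)
})

test_that("synthetic patients are deterministic and protocol-shaped", {
  a <- synth_patient(volume_cm3 = 2, seed = 7)
  b <- synth_patient(volume_cm3 = 2, seed = 7)
  expect_identical(a, b)
  c <- synth_patient(volume_cm3 = 2, seed = 8)
  expect_false(identical(a$mask, c$mask))
  # requested volume within one GC shell
  vol <- sum(a$mask) * (a$gc_edge / 10)^3
  shell <- 4 * pi * (3 * 2 / (4 * pi))^(2 / 3) * (a$gc_edge / 10)
  expect_lt(abs(vol - 2), shell)
  # protocol: 25 weekday fractions, weekly cisplatin, 2 x 20-pulse BT
  expect_equal(nrow(a$schedule$ebrt), 25)
  expect_true(all((a$schedule$ebrt$hour %/% 24) %% 7 < 5))
  expect_equal(length(a$schedule$cisplatin), 5)
  expect_equal(length(a$schedule$bt), 2)
  expect_equal(a$schedule$bt[[1]]$train$n_pulses, 20)
  expect_equal(a$schedule$bt[[1]]$train$pulse_duration +
                 a$schedule$bt[[1]]$train$interpulse_gap, 1)
  expect_setequal(names(a$schedule$timepoints),
                  c("pretherapy", "midterm", "BT0", "BT1", "BT2"))
  # per-pulse dose map is the fraction map divided by the pulse count
  f <- a$schedule$bt[[1]]
  expect_equal(mean(f$dose_map[a$mask == 1]) / f$train$n_pulses,
               f$train$pulse_dose, tolerance = 1e-9)
})
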