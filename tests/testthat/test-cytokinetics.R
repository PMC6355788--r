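test_that("empty and inert states are fixed points of the cytokinetic hour", {
  p <- parameter_set(n_limp = 3)
  empty <- gc_state(3)
  out <- cytokinetic_step(empty, p, local_crowding = 0.5)
  expect_equal(as.numeric(out), as.numeric(empty))
  # all rates/probabilities zero and no cohort at a phase boundary:
  # (long phases so the per-hour advance is < 1 and we place cells only in
  # G0/diff pools, which then have no active transition)
  p0 <- parameter_set(n_limp = 3, r_a = 0, r_ndiff = 0, r_adiff = 0,
                      p_g0g1 = 0, p_sleep = 0, t_g0 = 1e12,
                      t_necrosis = 1e12, t_apoptosis = 1e12)
  st <- gc_state(3, c(stem_G0 = 500, diff = 300, necrotic = 100))
  out0 <- cytokinetic_step(st, p0, local_crowding = 1)
  expect_equal(as.numeric(out0), as.numeric(st))
})

test_that("mitosis splits stem daughters by symmetric fraction", {
  # M phase of 1 h empties every hour; Psym = 0.5, no dormancy
  p <- parameter_set(n_limp = 4, t_cycle = 20, p_sym = 0.5, p_sleep = 0,
                     r_a = 0, r_ndiff = 0, r_adiff = 0, p_g0g1 = 0)
  st <- gc_state(4, c(stem_M = 1000))
  out <- cytokinetic_step(st, p, local_crowding = 0)
  expect_equal(unname(out["stem_G1"]), 1500)
  expect_equal(unname(out["limp0_G1"]), 500)
  expect_equal(unname(out["stem_M"]), 0)
  expect_equal(attr(out, "births"), 1000)
})

test_that("expected-value engine matches the per-cell stochastic oracle", {
  p <- parameter_set(n_limp = 3, t_cycle = 24, p_sym = 0.5, p_sleep = 0.3,
                     r_a = 0.002, t_necrosis = 60, t_apoptosis = 6)
  st <- gc_state(3, c(stem_G1 = 2e4, stem_S = 1e4, limp0_G1 = 5e4,
                      stem_G0 = 1e4, diff = 1e4))
  det <- st
  for (h in 1:240) det <- cytokinetic_step(det, p, local_crowding = 0.5)
  det_tot <- summary_census(det)[["living"]]
  set.seed(42)
  reps <- 12
  sto_tot <- vapply(seq_len(reps), function(r) {
    s <- st
    for (h in 1:240) s <- cytokinetic_step(s, p, local_crowding = 0.5,
                                           stochastic = TRUE)
    summary_census(s)[["living"]]
  }, numeric(1))
  se <- sd(sto_tot) / sqrt(reps)
  expect_lt(abs(mean(sto_tot) - det_tot), 3 * se + 1e-6 * det_tot)
})

test_that("each cytokinetic hour conserves cells up to births and clearance", {
  p <- parameter_set(n_limp = 5)
  set.seed(7)
  st <- gc_state(5, setNames(runif(n_compartments <- 33, 0, 1e5),
                             names(gc_state(5))))
  for (h in 1:50) {
    before <- sum(st)
    st <- cytokinetic_step(st, p, local_crowding = 0.7)
    expect_equal(sum(st), before + attr(st, "births") - attr(st, "cleared"),
                 tolerance = 1e-12)
    expect_true(all(st >= 0))
  }
})

test_that("growth is exponential without death and accelerates with more
          symmetric stem divisions", {
  tds <- vapply(c(0.25, 0.45, 0.65), function(psym) {
    p <- parameter_set(n_limp = 4, p_sym = psym, p_sleep = 0, r_a = 0,
                       p_g0g1 = 0)
    doubling_time(p)
  }, numeric(1))
  expect_true(all(is.finite(tds)))
  expect_true(all(diff(tds) < 0))
  # exponentiality: operator growth factor applies each hour
  p <- parameter_set(n_limp = 4, p_sym = 0.45, p_sleep = 0, r_a = 0,
                     p_g0g1 = 0)
  st <- gc_state(4, c(stem_G1 = 1e6))
  tot <- numeric(72)
  for (h in 1:72) {
    st <- cytokinetic_step(st, p, local_crowding = 1)
    tot[h] <- summary_census(st)[["living"]]
  }
  ratios <- tot[-1] / tot[-72]
  late <- ratios[48:71]
  expect_lt(diff(range(late)) / mean(late), 5e-3)
})

test_that("EBRT kill follows acute LQ with hypoxia protection and fills the
          necrotic pool", {
  # half-kill construction: alpha = ln2/2, beta = 0, d = 2
  p <- parameter_set(n_limp = 4, lq = lq_params(log(2) / 2, 0, 1.5, 2))
  st <- gc_state(4, c(stem_G1 = 1000))
  out <- apply_ebrt(st, 2, p)
  expect_equal(unname(out["stem_G1"]), 500, tolerance = 1e-12)
  expect_equal(unname(out["necrotic"]), 500, tolerance = 1e-12)
  expect_equal(as.numeric(apply_ebrt(st, 0, p)), as.numeric(st))
  # hypoxic (dormant) cohort loses fewer cells than a normoxic one
  p2 <- parameter_set(n_limp = 4, lq = lq_params(0.3, 0.03, 1.5, oer = 2))
  hyp <- apply_ebrt(gc_state(4, c(stem_G0 = 1000)), 2, p2)
  nor <- apply_ebrt(gc_state(4, c(stem_G1 = 1000)), 2, p2)
  expect_gt(unname(hyp["stem_G0"]), unname(nor["stem_G1"]))
  expect_equal(unname(hyp["stem_G0"]),
               1000 * acute_survival(2, params_lq(p2), hypoxic = TRUE),
               tolerance = 1e-12)
})

test_that("a 20-pulse BT train on frozen kinetics equals the whole-train
          survival", {
  # freeze the cycle and every death/transition channel
  p <- parameter_set(n_limp = 2, t_cycle = 1e9, r_a = 0, r_ndiff = 0,
                     r_adiff = 0, p_g0g1 = 0, p_sleep = 0, t_g0 = 1e12,
                     t_necrosis = 1e12, t_apoptosis = 1e12,
                     lq = lq_params(0.3, 0.03, 1.5, 2))
  tr <- pulse_train(20, pulse_dose = 0.6, pulse_duration = 0.25)
  st <- gc_state(2, c(stem_G1 = 1e6))
  for (i in 1:20) {
    st <- apply_bt_pulse(st, i, 0.6, p, tr)
    st <- cytokinetic_step(st, p, local_crowding = 1)
  }
  g20 <- g_factor(20, repair_rate(1.5), 0.25, 0.75)
  expected <- 1e6 * exp(-(0.3 * 20 * 0.6 + 0.03 * 20 * g20 * 0.36))
  expect_equal(unname(st["stem_G1"]), expected, tolerance = 1e-6)
  # with proliferation enabled the survivor count can only be larger
  p_live <- parameter_set(n_limp = 2, t_cycle = 16, r_a = 0, p_sleep = 0,
                          lq = lq_params(0.3, 0.03, 1.5, 2))
  st2 <- gc_state(2, c(stem_G1 = 2.5e5, stem_S = 2.5e5, stem_G2 = 2.5e5,
                       stem_M = 2.5e5))
  for (i in 1:20) {
    st2 <- apply_bt_pulse(st2, i, 0.6, p_live, tr)
    st2 <- cytokinetic_step(st2, p_live, local_crowding = 0)
  }
  expect_gt(summary_census(st2)[["living"]], expected)
})

test_that("cisplatin removes the prescribed fraction of stem and LIMP cells
          through apoptosis", {
  p <- parameter_set(n_limp = 4, ckr = 0.3)
  st <- gc_state(4, c(stem_G1 = 1000, limp0_G1 = 2000, diff = 500))
  out <- apply_cisplatin(st, p)
  expect_equal(unname(out["apoptotic"]), 900, tolerance = 1e-12)
  expect_equal(unname(out["diff"]), 500)
  # boundary cases
  p0 <- parameter_set(n_limp = 4, ckr = 0)
  expect_equal(as.numeric(apply_cisplatin(st, p0)), as.numeric(st))
  p1 <- parameter_set(n_limp = 4, ckr = 1)
  out1 <- apply_cisplatin(st, p1)
  expect_equal(unname(out1["apoptotic"]), 3000)
  expect_equal(summary_census(out1)[["stem"]], 0)
})

test_that("therapy and cytokinetics do not commute (order is load-bearing)", {
  p <- parameter_set(n_limp = 3, t_cycle = 20, p_sleep = 0,
                     lq = lq_params(0.5, 0.05, 1.5, 2))
  st <- gc_state(3, c(stem_M = 1e4, stem_G1 = 1e4))
  a <- cytokinetic_step(apply_ebrt(st, 2, p), p, local_crowding = 1)
  b <- apply_ebrt(cytokinetic_step(st, p, local_crowding = 1), 2, p)
  expect_false(isTRUE(all.equal(as.numeric(a), as.numeric(b))))
})
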