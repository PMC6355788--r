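#' Census of biological cells in one geometrical cell
#'
#' A geometrical cell (GC) is the elementary voxel of the discretization
#' mesh; its state is the census of biological cells it contains, split
#' into stem cells (by cycle phase G1/S/G2/M and dormant G0), LIMP
#' (limited-mitotic-potential progenitor) cells by phase and generation,
#' terminally differentiated cells, and apoptotic/necrotic cells awaiting
#' clearance.  Counts are expected values (non-negative reals).
#'
#' @param n_limp Depth of the LIMP generation ladder (from the matching
#'   [parameter_set()]).
#' @param counts Optional named numeric vector of initial counts; names
#'   must match `state_compartments(n_limp)` entries, e.g. `"stem_M"`,
#'   `"limp0_G1"`, `"diff"`, `"necrotic"`.
#'
#' @return An object of class `gc_state`: a named numeric vector with
#'   attribute `n_limp`.
#' @export
#' @examples
#' gc_state(4, c(stem_G1 = 900, stem_M = 100))
gc_state <- function(n_limp, counts = NULL) {
  nl <- as.integer(n_limp)
  v <- setNames(numeric(n_compartments(nl)), state_compartments(nl))
  if (!is.null(counts)) {
    if (is.null(names(counts)) || !all(names(counts) %in% names(v)))
      stop("`counts` must be named with valid compartment names")
    if (any(counts < 0)) stop("cell counts must be non-negative")
    v[names(counts)] <- counts
  }
  structure(v, n_limp = nl, class = "gc_state")
}

#' @export
print.gc_state <- function(x, ...) {
  s <- summary_census(x)
  cat(sprintf(
    "GC census: %.5g cells (stem %.4g, LIMP %.4g, diff %.4g, apoptotic %.4g, necrotic %.4g)\n",
    s[["total"]], s[["stem"]], s[["limp"]], s[["diff"]],
    s[["apoptotic"]], s[["necrotic"]]))
  invisible(x)
}

#' Summarise a GC census by cell class
#'
#' @param state A [gc_state()].
#' @return Named vector with stem, limp, diff, apoptotic, necrotic,
#'   cycling, dormant, living and total counts.
#' @export
summary_census <- function(state) {
  idx <- state_idx(attr(state, "n_limp"))
  v <- unclass(state)
  c(stem = sum(v[idx$stem]), limp = sum(v[idx$limp]),
    diff = unname(v[idx$diff]), apoptotic = unname(v[idx$apoptotic]),
    necrotic = unname(v[idx$necrotic]),
    cycling = sum(v[idx$cycling]), dormant = sum(v[idx$g0]),
    living = sum(v[idx$living]), total = sum(v))
}

.state_as_matrix <- function(state) {
  matrix(as.numeric(state), ncol = 1,
         dimnames = list(names(state), NULL))
}

.matrix_as_state <- function(m, nl) {
  structure(setNames(as.numeric(m[, 1]), state_compartments(nl)),
            n_limp = nl, class = "gc_state")
}

#' One cytokinetic hour for a single geometrical cell
#'
#' Applies the hourly cell-state transition calculator to one GC census, in
#' this fixed order: spontaneous apoptosis of stem/LIMP cells and death of
#' differentiated cells; dormancy exit (permitted only below the crowding
#' threshold); phase advancement and mitosis (symmetric or asymmetric for
#' stem cells, generation bookkeeping and terminal differentiation for
#' LIMP cells, a crowding-scaled fraction `p_sleep` of daughters entering
#' G0); necrotic death of dormant cells that outstay `t_g0`; clearance of
#' the apoptotic and necrotic pools.  The default engine propagates
#' expected values (continuous counts); `stochastic = TRUE` draws every
#' transition from binomial/multinomial distributions instead, which is
#' used to cross-check the expected-value engine.
#'
#' @param state A [gc_state()].
#' @param params A [parameter_set()] with matching `n_limp`.
#' @param local_crowding Occupancy proxy in `[0, 1]` gating dormancy entry
#'   and exit.
#' @param stochastic Draw integer transitions instead of propagating
#'   expected values (uses the current RNG state; seed with [set.seed()]).
#' @return The updated [gc_state()], with attributes `births` and
#'   `cleared` (this hour's mitotic births and removed dead cells).
#' @export
#' @examples
#' p <- parameter_set(n_limp = 4)
#' st <- gc_state(4, c(stem_G1 = 1e5))
#' cytokinetic_step(st, p, local_crowding = 0)
cytokinetic_step <- function(state, params, local_crowding,
                             stochastic = FALSE) {
  stopifnot(inherits(state, "gc_state"), inherits(params, "cv_params"),
            attr(state, "n_limp") == params$n_limp,
            local_crowding >= 0, local_crowding <= 1)
  if (stochastic)
    return(.cyto_step_stochastic(state, params, local_crowding))
  S <- .state_as_matrix(state)
  res <- cyto_step_cpp(S, params, 1L, local_crowding)
  out <- .matrix_as_state(S, params$n_limp)
  if (any(out < 0)) {
    if (any(out < -1e-9)) stop("internal error: negative census")
    out[out < 0] <- 0
  }
  attr(out, "births") <- res$births
  attr(out, "cleared") <- res$cleared
  out
}

# Per-cell stochastic counterpart of the expected-value hour: every
# transition that the compiled kernel applies as a fraction is drawn from
# the corresponding binomial/multinomial distribution on integer counts.
.cyto_step_stochastic <- function(state, params, crowding) {
  p <- params
  nl <- p$n_limp
  v <- round(as.numeric(state))
  cmp <- state_compartments(nl)
  names(v) <- cmp
  dcol <- 5L + 5L * nl + 1L; acol <- dcol + 1L; ncl <- dcol + 2L
  p_ph <- pmin(1, 1 / (p$phase_frac * p$t_cycle))
  ps_eff <- p$p_sleep * crowding
  exit_ok <- crowding < p$crowd_exit_threshold
  births <- 0; cleared <- 0
  rb <- function(n, prob) if (n <= 0) 0 else rbinom(1, n, min(1, prob))

  # spontaneous apoptosis of stem/LIMP
  for (c in seq_len(5L + 5L * nl)) {
    loss <- rb(v[c], p$r_a); v[c] <- v[c] - loss; v[acol] <- v[acol] + loss
  }
  # differentiated cell death
  dtot <- rb(v[dcol], p$r_adiff + p$r_ndiff)
  la <- rb(dtot, p$r_adiff / (p$r_adiff + p$r_ndiff + 1e-300))
  v[dcol] <- v[dcol] - dtot
  v[acol] <- v[acol] + la; v[ncl] <- v[ncl] + (dtot - la)
  # dormancy exit
  if (exit_ok) for (g in 0:nl) {
    b <- if (g == 0) 1L else 5L * g + 1L
    e <- rb(v[b + 4L], p$p_g0g1)
    v[b + 4L] <- v[b + 4L] - e; v[b] <- v[b] + e
  }
  # phase advancement + mitosis from a snapshot
  snap <- v
  adv <- function(b) vapply(1:4, function(k) rb(snap[b + k - 1L], p_ph[k]),
                            numeric(1))
  fl <- adv(1L)
  v[1L] <- v[1L] - fl[1]; v[2L] <- v[2L] + fl[1] - fl[2]
  v[3L] <- v[3L] + fl[2] - fl[3]; v[4L] <- v[4L] + fl[3] - fl[4]
  m <- fl[4]; births <- births + m
  sym <- rb(m, p$p_sym)
  stem_d <- 2 * sym + (m - sym); limp_d <- m - sym
  sd_g0 <- rb(stem_d, ps_eff); ld_g0 <- rb(limp_d, ps_eff)
  v[5L] <- v[5L] + sd_g0; v[1L] <- v[1L] + stem_d - sd_g0
  v[10L] <- v[10L] + ld_g0; v[6L] <- v[6L] + limp_d - ld_g0
  for (g in seq_len(nl)) {
    b <- 5L * g + 1L
    fl <- adv(b)
    v[b] <- v[b] - fl[1]; v[b + 1L] <- v[b + 1L] + fl[1] - fl[2]
    v[b + 2L] <- v[b + 2L] + fl[2] - fl[3]; v[b + 3L] <- v[b + 3L] + fl[3] - fl[4]
    m <- fl[4]; births <- births + m
    daughters <- 2 * m
    if (g < nl) {
      dg0 <- rb(daughters, ps_eff)
      v[b + 9L] <- v[b + 9L] + dg0
      v[b + 5L] <- v[b + 5L] + daughters - dg0
    } else v[dcol] <- v[dcol] + daughters
  }
  # dormancy timeout
  for (g in 0:nl) {
    b <- if (g == 0) 1L else 5L * g + 1L
    dd <- rb(v[b + 4L], 1 / p$t_g0)
    v[b + 4L] <- v[b + 4L] - dd; v[ncl] <- v[ncl] + dd
  }
  # clearance
  ca <- rb(v[acol], if (p$t_apoptosis <= 1) 1 else 1 / p$t_apoptosis)
  cn <- rb(v[ncl], if (p$t_necrosis <= 1) 1 else 1 / p$t_necrosis)
  v[acol] <- v[acol] - ca; v[ncl] <- v[ncl] - cn
  cleared <- ca + cn
  out <- structure(setNames(as.numeric(v), cmp), n_limp = nl,
                   class = "gc_state")
  attr(out, "births") <- births
  attr(out, "cleared") <- cleared
  out
}

#' Apply an acute external-beam fraction to one GC census
#'
#' Every living compartment is scaled by the acute LQ survival at the given
#' dose: dormant (G0) compartments are treated as hypoxic (effective dose
#' `d / oer`), stem compartments use `alpha * stem_sens` and
#' `beta * stem_sens`, and differentiated cells are killed too unless
#' `params$kill_diff` is `FALSE`.  Irradiation-killed cells move to the
#' necrotic pool.
#'
#' @param state A [gc_state()].
#' @param dose Fraction dose (Gy), >= 0.
#' @param params A [parameter_set()].
#' @return Updated [gc_state()].
#' @export
apply_ebrt <- function(state, dose, params) {
  stopifnot(inherits(state, "gc_state"), dose >= 0,
            attr(state, "n_limp") == params$n_limp)
  S <- .state_as_matrix(state)
  irradiate_cpp(S, 1L, dose, params$n_limp, params$alpha, params$beta,
                1.0, params$oer, params$stem_sens, params$kill_diff)
  .matrix_as_state(S, params$n_limp)
}

#' Apply one brachytherapy pulse to one GC census
#'
#' As [apply_ebrt()], but the quadratic LQ term is weighted by the
#' incomplete-repair increment `i G_i - (i-1) G_(i-1)` of [delta_g()], so
#' that the pulse-by-pulse product over a full train reproduces the
#' protracted-LQ survival of the whole fraction while the kill acts on the
#' evolving cell census.
#'
#' @param state A [gc_state()].
#' @param i Pulse index within the fraction (1-based).
#' @param d Pulse dose for this GC (Gy).
#' @param params A [parameter_set()].
#' @param train A [pulse_train()].
#' @return Updated [gc_state()].
#' @export
apply_bt_pulse <- function(state, i, d, params, train) {
  stopifnot(inherits(state, "gc_state"), inherits(train, "pulse_train"),
            i >= 1, i <= train$n_pulses, d >= 0)
  dg <- delta_g(i, params_lq(params), train)
  S <- .state_as_matrix(state)
  irradiate_cpp(S, 1L, d, params$n_limp, params$alpha, params$beta,
                dg, params$oer, params$stem_sens, params$kill_diff)
  .matrix_as_state(S, params$n_limp)
}

#' Apply one cisplatin administration to one GC census
#'
#' A fraction `ckr` of LIMP cells and `min(1, ckr * stem_sens)` of stem
#' cells (cycling and dormant) is lethally hit and moves to the apoptotic
#' pool; differentiated cells are unaffected.
#'
#' @param state A [gc_state()].
#' @param params A [parameter_set()].
#' @return Updated [gc_state()].
#' @export
apply_cisplatin <- function(state, params) {
  stopifnot(inherits(state, "gc_state"),
            attr(state, "n_limp") == params$n_limp)
  S <- .state_as_matrix(state)
  cisplatin_cpp(S, 1L, params$n_limp, params$ckr, params$stem_sens)
  .matrix_as_state(S, params$n_limp)
}
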