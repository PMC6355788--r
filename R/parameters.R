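#' Literature-derived plausible ranges of the tumour-dynamics parameters
#'
#' The biologically plausible value ranges for cervical carcinoma used to
#' constrain parameter sampling and to validate candidate parameter sets.
#' Durations are in hours, rates in fraction per hour, fractions are
#' dimensionless proportions.
#'
#' The range for `r_ndiff` (necrosis rate of differentiated cells) is a
#' package choice: the literature review behind the catalogue reports no
#' range for it, so it is bounded by a conservative 0--0.02 h^-1, of the
#' same order as the apoptosis rate of differentiated cells.
#'
#' @return A data frame with columns `parameter`, `min`, `max`, `typical`.
#' @export
#' @examples
#' param_ranges()
param_ranges <- function() {
  data.frame(
    parameter = c("t_cycle", "t_g0", "t_necrosis", "t_apoptosis", "n_limp",
                  "alpha", "beta", "oer", "t_half", "ckr", "r_a", "r_ndiff",
                  "r_adiff", "p_g0g1", "p_sleep", "p_sym", "stem_frac"),
    min = c(16, 96, 34, 0, 1,
            0.01, 0.001, 1.5, 0.26, 0, 4e-4, 0,
            0.09, 0.01, 0, 0.2, 0.0013),
    max = c(70, 240, 3456, 25, 18,
            0.7, 0.06, 3.0, 5.7, 0.86, 8e-3, 0.02,
            0.104, 0.06, 1, 0.66, 0.07),
    typical = c(25, NA, NA, NA, NA,
                0.3, 0.03, 2, 1.5, NA, NA, NA,
                NA, NA, NA, NA, 0.01),
    stringsAsFactors = FALSE)
}

#' Tumour-dynamics parameter set
#'
#' The full set of kinetic and radiobiological parameters governing one
#' virtual tumour: cell-cycle and residence durations, the LQ survival
#' parameters (wrapped in [lq_params()]), cisplatin chemosensitivity, death
#' rates, and the stem-cell division programme.
#'
#' @param t_cycle Cell-cycle duration Tc (h).
#' @param t_g0 Mean dormancy (G0) duration before necrotic death (h).
#' @param t_necrosis Mean clearance time of necrotic cells (h).
#' @param t_apoptosis Mean clearance time of apoptotic cells (h); 0 means
#'   apoptotic products are removed within the hour.
#' @param n_limp Number of mitoses a LIMP (limited mitotic potential)
#'   cell performs before terminal differentiation.
#' @param lq An [lq_params()] object (alpha, beta, t_half, oer).
#' @param ckr Cisplatin cell-kill rate: fraction of stem and LIMP cells
#'   lethally hit at each drug administration.
#' @param r_a Spontaneous apoptosis rate of stem and LIMP cells (h^-1).
#' @param r_ndiff Necrosis rate of differentiated cells (h^-1).
#' @param r_adiff Spontaneous apoptosis rate of differentiated cells (h^-1).
#' @param p_g0g1 Fraction of dormant cells re-entering the cycle per hour
#'   (when local crowding permits).
#' @param p_sleep Fraction of stem/LIMP daughters entering G0 after mitosis
#'   (scaled by local crowding).
#' @param p_sym Fraction of stem-cell mitoses that are symmetric.
#' @param stem_sens Relative radio/chemo-sensitivity multiplier of stem
#'   cells versus LIMP cells (1 = equal sensitivity).
#' @param stem_frac Fraction of living cells that are stem cells at tumour
#'   initialization.
#' @param phase_frac Split of `t_cycle` across G1, S, G2, M (must sum
#'   to 1).
#' @param kill_diff Are terminally differentiated cells radio-killable?
#' @param crowd_exit_threshold Local crowding below which dormant cells may
#'   re-enter the cycle.
#' @param crowd_saturation Occupancy (fraction of GC capacity) at which
#'   local crowding saturates at 1: `crowding = min(1, occupancy /
#'   crowd_saturation)`.  A voxel above ~30% of maximal packing is already
#'   treated as nutrient-limited bulk, so only sparsely populated (newly
#'   colonised or heavily depleted) voxels see relaxed dormancy pressure.
#'
#' @return An object of class `cv_params` (a validated named list).
#' @export
#' @examples
#' p <- parameter_set()
#' doubling_time(p)
parameter_set <- function(t_cycle = 25, t_g0 = 168, t_necrosis = 200,
                          t_apoptosis = 6, n_limp = 8,
                          lq = lq_params(), ckr = 0.2,
                          r_a = 0.002, r_ndiff = 0.005, r_adiff = 0.1,
                          p_g0g1 = 0.03, p_sleep = 0.2, p_sym = 0.45,
                          stem_sens = 1, stem_frac = 0.01,
                          phase_frac = c(G1 = 0.40, S = 0.35,
                                         G2 = 0.20, M = 0.05),
                          kill_diff = TRUE, crowd_exit_threshold = 0.9,
                          crowd_saturation = 0.3) {
  stopifnot(inherits(lq, "lq_params"))
  p <- list(t_cycle = t_cycle, t_g0 = t_g0, t_necrosis = t_necrosis,
            t_apoptosis = t_apoptosis, n_limp = as.integer(n_limp),
            alpha = lq$alpha, beta = lq$beta, t_half = lq$t_half,
            oer = lq$oer, ckr = ckr, r_a = r_a, r_ndiff = r_ndiff,
            r_adiff = r_adiff, p_g0g1 = p_g0g1, p_sleep = p_sleep,
            p_sym = p_sym, stem_sens = stem_sens, stem_frac = stem_frac,
            phase_frac = phase_frac, kill_diff = isTRUE(kill_diff),
            crowd_exit_threshold = crowd_exit_threshold,
            crowd_saturation = crowd_saturation)
  validate_params(p)
  structure(p, class = "cv_params")
}

validate_params <- function(p) {
  with(p, {
    stopifnot(t_cycle > 0, t_g0 > 0, t_necrosis > 0, t_apoptosis >= 0,
              n_limp >= 1, alpha >= 0, beta >= 0, t_half > 0, oer >= 1,
              ckr >= 0, ckr <= 1, r_a >= 0, r_ndiff >= 0, r_adiff >= 0,
              p_g0g1 >= 0, p_g0g1 <= 1, p_sleep >= 0, p_sleep <= 1,
              p_sym >= 0, p_sym <= 1, stem_sens > 0,
              stem_frac > 0, stem_frac < 1,
              crowd_saturation > 0, crowd_saturation <= 1,
              length(phase_frac) == 4, all(phase_frac > 0),
              abs(sum(phase_frac) - 1) < 1e-9)
  })
  invisible(p)
}

#' @export
print.cv_params <- function(x, ...) {
  cat("Tumour-dynamics parameter set\n")
  cat(sprintf("  cycle Tc = %.3g h (G1/S/G2/M = %s), G0 %.3g h, NLIMP = %d\n",
              x$t_cycle, paste(signif(x$phase_frac, 2), collapse = "/"),
              x$t_g0, x$n_limp))
  cat(sprintf("  LQ: alpha %.3g /Gy, beta %.3g /Gy^2, T1/2 %.3g h, OER %.3g\n",
              x$alpha, x$beta, x$t_half, x$oer))
  cat(sprintf("  CKR %.3g, RA %.3g/h, RNDiff %.3g/h, RADiff %.3g/h\n",
              x$ckr, x$r_a, x$r_ndiff, x$r_adiff))
  cat(sprintf("  PG0toG1 %.3g/h, Psleep %.3g, Psym %.3g, stem frac %.3g, stem sens %.3g\n",
              x$p_g0g1, x$p_sleep, x$p_sym, x$stem_frac, x$stem_sens))
  cat(sprintf("  clearance: necrosis %.3g h, apoptosis %.3g h\n",
              x$t_necrosis, x$t_apoptosis))
  invisible(x)
}

#' Extract the LQ parameters of a parameter set
#'
#' @param params A [parameter_set()].
#' @return An [lq_params()] object.
#' @export
params_lq <- function(params) {
  lq_params(params$alpha, params$beta, params$t_half, params$oer)
}

#' Are a parameter set's values within the plausible ranges?
#'
#' Checks every field of a [parameter_set()] against [param_ranges()].
#'
#' @param params A [parameter_set()].
#' @return Logical; attribute `"violations"` names out-of-range fields.
#' @export
params_in_range <- function(params) {
  rg <- param_ranges()
  bad <- character(0)
  for (k in seq_len(nrow(rg))) {
    f <- rg$parameter[k]
    val <- params[[f]]
    if (val < rg$min[k] - 1e-12 || val > rg$max[k] + 1e-12) bad <- c(bad, f)
  }
  structure(length(bad) == 0L, violations = bad)
}

# Number of state compartments for a given LIMP ladder depth.
n_compartments <- function(n_limp) 5L + 5L * as.integer(n_limp) + 3L

# Row names of the state layout, in storage order.
state_compartments <- function(n_limp) {
  ph <- c("G1", "S", "G2", "M", "G0")
  c(paste0("stem_", ph),
    as.vector(t(outer(paste0("limp", seq_len(n_limp) - 1, "_"), ph, paste0))),
    "diff", "apoptotic", "necrotic")
}

# Index helpers into a state vector/matrix rows.
state_idx <- function(n_limp) {
  nl <- as.integer(n_limp)
  cyc <- c(1:4, as.vector(vapply(seq_len(nl) - 1L,
                                 function(g) 5L + 5L * g + 1:4, integer(4))))
  g0 <- c(5L, 5L + 5L * (seq_len(nl) - 1L) + 5L)
  dcol <- 5L + 5L * nl + 1L
  list(cycling = cyc, g0 = g0, diff = dcol,
       apoptotic = dcol + 1L, necrotic = dcol + 2L,
       stem = 1:5, limp = if (nl > 0) 6L:(5L + 5L * nl) else integer(0),
       living = c(1:(5L + 5L * nl), dcol),
       dead = c(dcol + 1L, dcol + 2L))
}

#' Hourly linear operator of the cytokinetic model
#'
#' The expected-value cytokinetic hour is linear in the cell counts for a
#' fixed local crowding, so its action is fully described by a square
#' matrix `A` with `state_new = A %*% state`.  The matrix is obtained by
#' pushing unit vectors through the same compiled kernel used by the
#' simulator, which keeps analysis and simulation consistent by
#' construction.
#'
#' @param params A [parameter_set()].
#' @param crowding The fixed local crowding in `[0, 1]` at which to
#'   linearise; the default 1 corresponds to the fully packed tumour bulk.
#' @return The transition matrix (compartments x compartments).
#' @export
cyto_operator <- function(params, crowding = 1) {
  k <- n_compartments(params$n_limp)
  S <- diag(k)
  cyto_step_cpp(S, params, seq_len(k), rep(crowding, k))
  dimnames(S) <- list(state_compartments(params$n_limp),
                      state_compartments(params$n_limp))
  S
}

#' Asymptotic volume doubling time of a parameter set
#'
#' The free-growth doubling time implied by a parameter set, computed from
#' the dominant eigenvalue of the living-compartment block of the hourly
#' transition operator (see [cyto_operator()]).  The operator is evaluated
#' at full crowding, the regime of the packed tumour bulk that dominates a
#' compact growing tumour.
#'
#' @param params A [parameter_set()].
#' @param crowding Crowding at which growth is assessed (default 1).
#' @return Doubling time in days (`Inf` if the population does not grow).
#' @export
#' @examples
#' doubling_time(parameter_set())
doubling_time <- function(params, crowding = 1) {
  A <- cyto_operator(params, crowding)
  idx <- state_idx(params$n_limp)
  Al <- A[idx$living, idx$living, drop = FALSE]
  lam <- max(Re(eigen(Al, only.values = TRUE)$values))
  if (lam <= 1) return(Inf)
  log(2) / log(lam) / 24
}
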