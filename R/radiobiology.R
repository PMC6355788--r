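#' Linear-quadratic survival parameters
#'
#' Bundles the four radiobiological constants used throughout the simulator:
#' the linear (`alpha`) and quadratic (`beta`) radiosensitivity coefficients
#' of the linear-quadratic (LQ) cell-survival model, the sublethal-damage
#' repair half-time `t_half`, and the oxygen enhancement ratio `oer` applied
#' to hypoxic (dormant) cells.
#'
#' @param alpha Linear radiosensitivity (Gy^-1), >= 0.
#' @param beta Quadratic radiosensitivity (Gy^-2), >= 0.
#' @param t_half Sublethal-damage repair half-time (h), > 0.
#' @param oer Oxygen enhancement ratio (dimensionless), >= 1.  Applied as a
#'   dose-modifying factor: hypoxic cells see an effective dose `d / oer`.
#'   For the LQ model this is algebraically identical to dividing `alpha` by
#'   `oer` and `beta` by `oer^2`, so no separate convention switch is
#'   provided.
#'
#' @return An object of class `lq_params`.
#' @seealso [repair_rate()], [acute_survival()], [pulse_survival()]
#' @export
#' @examples
#' lq_params(alpha = 0.3, beta = 0.03, t_half = 1.5, oer = 2)
lq_params <- function(alpha = 0.3, beta = 0.03, t_half = 1.5, oer = 2) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha >= 0,
            is.numeric(beta), length(beta) == 1L, beta >= 0,
            is.numeric(oer), length(oer) == 1L, oer >= 1)
  if (!is.numeric(t_half) || length(t_half) != 1L || t_half <= 0)
    stop("`t_half` must be a single positive repair half-time in hours")
  structure(list(alpha = alpha, beta = beta, t_half = t_half, oer = oer),
            class = "lq_params")
}

#' @export
print.lq_params <- function(x, ...) {
  cat(sprintf(
    "LQ parameters: alpha = %g /Gy, beta = %g /Gy^2 (a/b = %g Gy), T1/2 = %g h (mu = %.4g /h), OER = %g\n",
    x$alpha, x$beta, if (x$beta > 0) x$alpha / x$beta else Inf,
    x$t_half, repair_rate(x$t_half), x$oer))
  invisible(x)
}

#' Pulse train of a pulsed-dose-rate brachytherapy fraction
#'
#' Describes the temporal pattern of one PDR-BT fraction: `n_pulses` pulses
#' of dose `pulse_dose` each, delivered over `pulse_duration` hours, with an
#' irradiation-free gap `interpulse_gap` between the end of one pulse and
#' the start of the next.  The clinical protocol modelled here uses 20
#' pulses at a 1 h start-to-start interval with pulse durations of
#' 0.2--0.3 h, so the default gap is `1 - pulse_duration`.
#'
#' @param n_pulses Number of pulses N (>= 1).
#' @param pulse_dose Dose per pulse d (Gy), >= 0.  For spatially resolved
#'   fractions the per-voxel pulse dose comes from the dose map and this
#'   field holds the prescribed (mean) pulse dose.
#' @param pulse_duration Pulse duration t (h), > 0.
#' @param interpulse_gap Irradiation-free time x (h) between pulses, >= 0.
#'   Defaults to a 1 h start-to-start spacing, i.e. `1 - pulse_duration`.
#'
#' @return An object of class `pulse_train`.
#' @export
#' @examples
#' pulse_train(n_pulses = 20, pulse_dose = 0.75, pulse_duration = 0.25)
pulse_train <- function(n_pulses = 20, pulse_dose = 0.5,
                        pulse_duration = 0.25,
                        interpulse_gap = 1 - pulse_duration) {
  stopifnot(is.numeric(n_pulses), length(n_pulses) == 1L, n_pulses >= 1,
            n_pulses == round(n_pulses),
            is.numeric(pulse_dose), pulse_dose >= 0,
            is.numeric(pulse_duration), pulse_duration > 0,
            is.numeric(interpulse_gap), interpulse_gap >= 0)
  structure(list(n_pulses = as.integer(n_pulses), pulse_dose = pulse_dose,
                 pulse_duration = pulse_duration,
                 interpulse_gap = interpulse_gap),
            class = "pulse_train")
}

#' Sublethal-damage repair rate constant
#'
#' First-order (monoexponential) repair with half-time `t_half` has rate
#' constant mu = ln(2) / `t_half`.
#'
#' @param t_half Repair half-time (h), > 0.
#' @return Repair rate mu (h^-1).
#' @export
#' @examples
#' repair_rate(1.5)
repair_rate <- function(t_half) {
  if (!is.numeric(t_half) || any(t_half <= 0))
    stop("repair half-time must be positive")
  log(2) / t_half
}

# Series switch for the first-pulse protraction factor: below this mu*t the
# closed form 2[exp(-mt)+mt-1]/(mt)^2 loses ~8 significant digits to
# cancellation, so a Taylor expansion is used instead.
.G_SERIES_SWITCH <- 1e-4

#' Protraction factor of a single pulse
#'
#' The Lea-Catcheside dose-protraction factor for one continuous exposure of
#' duration `t` with repair rate `mu`:
#' G1 = 2 \[exp(-mu t) + mu t - 1\] / (mu t)^2.
#' For mu t below `1e-4` the Taylor expansion
#' 1 - mu t / 3 + (mu t)^2 / 12 is used to avoid catastrophic cancellation.
#' G1 -> 1 for acute exposures (mu t -> 0) and G1 -> 0 for very long
#' exposures.
#'
#' @param mu Repair rate (h^-1), >= 0.  Vectorised over `mu` and `t`.
#' @param t Exposure (pulse) duration (h), > 0.
#' @return G1 in (0, 1].
#' @export
#' @examples
#' g_first(repair_rate(1.5), 0.3)
g_first <- function(mu, t) {
  stopifnot(all(mu >= 0), all(t > 0))
  mt <- mu * t
  out <- ifelse(mt < .G_SERIES_SWITCH,
                1 - mt / 3 + mt^2 / 12,
                2 * (exp(-mt) + mt - 1) / mt^2)
  as.numeric(out)
}

#' Lea-Catcheside factor after pulse i of a pulsed exposure
#'
#' Incomplete-repair generalisation of the protraction factor for a train of
#' equal pulses of duration `t` separated by irradiation-free gaps `x`, with
#' monoexponential sublethal-damage repair at rate `mu`.  For `i = 1` the
#' single-pulse form of [g_first()] applies (the pulsed formula reduces to it
#' exactly; the gap is irrelevant before a second pulse exists).  For
#' `i >= 2`:
#'
#' G_i = (2 / (mu t)) \[1 - (i Y - S Y^2) / (i mu t)\]
#'
#' with Y = 1 - exp(-mu t), K = exp(-mu x) and
#' S = \[i K - K - i K^2 exp(-mu t) + K^(i+1) exp(-mu i t)\] /
#'     (1 - K exp(-mu t))^2.
#'
#' @section Normalisation:
#' `G_i` is expressed in the *per-pulse* convention used by the
#' whole-fraction survival `SF_N = exp[-(alpha N d + beta N G_N d^2)]`: the
#' quadratic term carries `N G_N d^2`, not `G (N d)^2`.  Consequently
#' `G_i` equals `i` times the canonical Lea-Catcheside factor
#' `(2/D^2) int int dD dD' exp[-mu(t-t')]` of the train truncated at pulse
#' `i`, and may exceed 1 when inter-pulse repair is substantially
#' incomplete (long `t_half` relative to the 1 h pulse spacing).  With this
#' convention the per-pulse quadratic increments `i G_i - (i-1) G_(i-1)`
#' are strictly positive and tend to `G_1` as `x -> Inf` (independent
#' pulses), and the telescoped product of [pulse_survival()] reproduces the
#' standard protracted-LQ survival of the whole train.
#'
#' @param i Pulse index (>= 1).  Vectorised over `i`.
#' @param mu Repair rate (h^-1), >= 0.
#' @param t Pulse duration (h), > 0.
#' @param x Irradiation-free gap between pulses (h), >= 0.
#' @return G_i in (0, 1].
#' @seealso [lea_catcheside_numeric()] for a brute-force quadrature
#'   evaluation of the same quantity.
#' @export
#' @examples
#' g_factor(1:20, mu = repair_rate(1.5), t = 0.25, x = 0.75)
g_factor <- function(i, mu, t, x) {
  if (any(i < 1) || any(i != round(i)))
    stop("pulse index `i` must be a positive integer")
  stopifnot(all(mu >= 0), all(t > 0), all(x >= 0))
  n <- max(length(i), length(mu), length(t), length(x))
  i <- rep_len(as.integer(i), n); mu <- rep_len(mu, n)
  t <- rep_len(t, n); x <- rep_len(x, n)
  out <- numeric(n)
  for (k in seq_len(n)) {
    out[k] <- if (i[k] == 1L) g_first(mu[k], t[k])
              else .g_pulsed(i[k], mu[k], t[k], x[k])
  }
  out
}

# Closed-form pulsed protraction factor, i >= 2, in the per-pulse
# normalisation (see g_factor docs): equals i times the canonical
# (2/D^2) double-integral factor of the train truncated at pulse i.
.g_pulsed <- function(i, mu, t, x) {
  mt <- mu * t
  if (mt < .G_SERIES_SWITCH) {
    # Stable route for near-acute pulses: build i*G_i from the exact
    # pairwise decomposition  (i G_i) (mu t)^2 / 2 = i [e^-mt + mt - 1] +
    # sum over ordered pulse pairs of the cross terms.  Each cross term for
    # pulses separated by m gaps is Y^2 K^m e^{-mu t (m-1)}; summing and
    # dividing by the same (mt)^2 keeps all terms positive.
    Y <- -expm1(-mt)                       # 1 - e^{-mu t}, accurate for small mt
    K <- exp(-mu * x)
    r <- K * exp(-mt)
    m <- seq_len(i - 1L)
    cross <- sum((i - m) * r^(m - 1)) * Y^2 * K
    # series form of i*[exp(-mt)+mt-1] avoids cancellation at tiny mu*t
    same <- i * mt^2 / 2 * (1 - mt / 3 + mt^2 / 12)
    return(2 * (same + cross) / (i * mt^2))
  }
  Y <- -expm1(-mt)
  K <- exp(-mu * x)
  emt <- exp(-mt)
  S <- (i * K - K - i * K^2 * emt + K^(i + 1) * exp(-mu * i * t)) /
    (1 - K * emt)^2
  (2 / mt) * (1 - (i * Y - S * Y^2) / (i * mt))
}

#' Per-pulse survival fraction under incomplete repair
#'
#' Survival fraction of the cells alive just before pulse `i` of a PDR-BT
#' fraction, evaluated after that pulse:
#' SF_i(d) = exp(-alpha d) exp\[-beta d^2 (i G_i - (i-1) G_\{i-1\})\].
#' The per-pulse quadratic increments telescope, so the product of SF_i over
#' a full train of N equal pulses equals the whole-fraction survival
#' exp\[-(alpha N d + beta N G_N d^2)\] exactly.  Applying the survival pulse
#' by pulse lets the kill act on the current (proliferating, repopulating)
#' cell census rather than the pre-fraction one.
#'
#' @param i Pulse index in `1:train$n_pulses`.
#' @param d Dose of this pulse (Gy), >= 0.  Vectorised over `d` (e.g. one
#'   dose per voxel).
#' @param lq An [lq_params()] object.
#' @param train A [pulse_train()] object supplying the pulse duration and
#'   inter-pulse gap.
#' @return Survival fraction(s) in (0, 1].
#' @export
#' @examples
#' lq <- lq_params(0.3, 0.03, t_half = 1.5)
#' tr <- pulse_train(20, pulse_duration = 0.25)
#' pulse_survival(3, d = 0.6, lq, tr)
pulse_survival <- function(i, d, lq, train) {
  stopifnot(inherits(lq, "lq_params"), inherits(train, "pulse_train"),
            length(i) == 1L, i >= 1, i <= train$n_pulses, all(d >= 0))
  dg <- delta_g(i, lq, train)
  exp(-lq$alpha * d) * exp(-lq$beta * d^2 * dg)
}

#' Per-pulse quadratic-term increments i G_i - (i-1) G_(i-1)
#'
#' The multiplier of `beta d^2` in the pulse-by-pulse survival of
#' [pulse_survival()].  Strictly positive for all valid inputs; the
#' increments sum to N G_N over a full train.
#'
#' @inheritParams pulse_survival
#' @return Numeric vector of increments, one per requested index.
#' @export
delta_g <- function(i, lq, train) {
  mu <- repair_rate(lq$t_half)
  t <- train$pulse_duration
  x <- train$interpulse_gap
  g_i <- g_factor(i, mu, t, x)
  g_prev <- ifelse(i > 1, g_factor(pmax(i - 1, 1), mu, t, x), 0)
  i * g_i - (i - 1) * g_prev
}

#' Acute-exposure LQ survival
#'
#' Survival after an acute (G = 1) exposure of dose `d`:
#' SF = exp\[-(alpha d_eff + beta d_eff^2)\], with `d_eff = d / oer` for
#' hypoxic cells and `d_eff = d` otherwise.  Used for external-beam
#' fractions, which are delivered in minutes and carry no incomplete-repair
#' correction.
#'
#' @param d Dose (Gy), >= 0.  Vectorised.
#' @param lq An [lq_params()] object.
#' @param hypoxic Logical; apply the oxygen enhancement ratio as a
#'   dose-modifying factor.
#' @return Survival fraction(s) in (0, 1].
#' @export
#' @examples
#' acute_survival(2, lq_params(0.3, 0.03))
acute_survival <- function(d, lq, hypoxic = FALSE) {
  stopifnot(inherits(lq, "lq_params"), all(d >= 0))
  d_eff <- if (hypoxic) d / lq$oer else d
  exp(-(lq$alpha * d_eff + lq$beta * d_eff^2))
}

#' Brute-force Lea-Catcheside factor by numerical quadrature
#'
#' Independent numerical evaluation of the Lea-Catcheside factor from its
#' double-integral definition
#' G = (2 / D^2) \int \int_\{t' < t\} R(t) R(t') exp\[-mu (t - t')\] dt' dt
#' for the piecewise-constant dose rate R of a pulse train truncated at
#' pulse `up_to`.  The domain is decomposed into per-pulse triangles and
#' pulse-pair rectangles, each integrated by adaptive 2-D quadrature
#' ([pracma::integral2()]).  This routine is deliberately independent of the
#' closed-form recursion in [g_factor()] and serves as its oracle.
#'
#' @param train A [pulse_train()] object (equal pulses).
#' @param up_to Truncate the train after this pulse (defaults to the full
#'   train).
#' @param mu Repair rate (h^-1), >= 0.
#' @param tol Requested quadrature tolerance.
#' @param convention `"per_pulse"` (default) rescales the canonical factor
#'   by `up_to` so that the value is directly comparable with
#'   [g_factor()] (see its Normalisation section); `"total"` returns the
#'   canonical `(2/D^2)` double integral itself.
#' @return The protraction factor (dimensionless, > 0; the canonical form
#'   lies in (0, 1]).
#' @export
#' @examples
#' tr <- pulse_train(4, pulse_duration = 0.3, interpulse_gap = 0.7)
#' lea_catcheside_numeric(tr, mu = repair_rate(1.5))
lea_catcheside_numeric <- function(train, up_to = train$n_pulses, mu,
                                   tol = 1e-10,
                                   convention = c("per_pulse", "total")) {
  convention <- match.arg(convention)
  stopifnot(inherits(train, "pulse_train"), up_to >= 1,
            up_to <= train$n_pulses, mu >= 0)
  n <- as.integer(up_to)
  t <- train$pulse_duration
  x <- train$interpulse_gap
  if (train$pulse_dose == 0)
    stop("zero total dose: the Lea-Catcheside factor is undefined")
  if (mu == 0) return(if (convention == "per_pulse") as.numeric(n) else 1)
  starts <- (seq_len(n) - 1) * (t + x)
  kern <- function(u, v) exp(-mu * (u - v))
  total <- 0
  for (k in seq_len(n)) {
    # same-pulse triangle v < u within pulse k
    total <- total + pracma::integral2(
      kern, xmin = starts[k], xmax = starts[k] + t,
      ymin = starts[k], ymax = function(u) u,
      reltol = tol)$Q
    if (k > 1) for (j in seq_len(k - 1)) {
      total <- total + pracma::integral2(
        kern, xmin = starts[k], xmax = starts[k] + t,
        ymin = starts[j], ymax = starts[j] + t,
        reltol = tol)$Q
    }
  }
  # unit dose rate: total dose D = n * t
  canonical <- 2 * total / (n * t)^2
  if (convention == "per_pulse") n * canonical else canonical
}
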