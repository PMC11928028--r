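# Two-channel Hodgkin-Huxley-type membrane model for blue-light-stressed
# E. coli. The model carries three currents -- the fast, light-gated Q channel
# (the mechanosensitive-channel product MscK x MscL x MscS), the voltage-gated
# Kch potassium channel, and a leak -- plus an accumulating ROS stress
# variable S driven by the applied irradiance:
#
#   C_m dV/dt = -[ g_Q m h (V - E_Q) + g_K n^p (V - E_K) + g_L (V - E_L) ]
#   dx/dt     = (x_inf(V, S, I) - x) / tau_x      for x in {m, h, n}
#   dS/dt     = alpha_ROS I(t) - delta_ROS S
#
# Gating structure (see the methods vignette for the full rationale):
#  * m (Q activation) is gated by the instantaneous irradiance I, fast.
#  * h (Q inactivation) has a voltage window: Q inactivates only at the
#    intermediate voltages reached while Kch partially repolarizes the cell.
#    Sustained ROS (S above S_plat) removes the window, so Q reopens and
#    carries the persistent second plateau (habituation).
#  * n (Kch activation) = A(V) * B(S): hyperpolarization-activated times a
#    ROS band-pass; sustained ROS shuts Kch down (refractoriness).

#' Hodgkin-Huxley parameter set for the two-channel E. coli model
#'
#' Returns the canonical default parameter set, with any field overridable.
#' Time is in minutes and voltage in mV throughout. Defaults are pinned so
#' the wildtype trace under the working irradiance of 15.99 uW/mm^2 shows a
#' first hyperpolarization peak at ~2-3 min, a quiescent phase at ~10-25 min
#' and a persistent second plateau from ~35 min, and so the knockout variants
#' (\code{\link{make_variant}}) reproduce their observed phenotypes.
#'
#' @param ... named overrides of any default field, e.g. \code{g_K = 0}.
#' @return an object of class \code{hh_params} (a validated named list).
#'
#' @section Fields:
#' \describe{
#'   \item{C_m}{membrane capacitance (uF/cm^2).}
#'   \item{g_Q, g_K, g_L}{maximal conductances (mS/cm^2).}
#'   \item{E_Q, E_K, E_L}{reversal potentials (mV); E_K sits below the
#'     resting potential E_L (potassium efflux hyperpolarizes).}
#'   \item{tau_act_Q, tau_act_K}{activation time constants (min); Q activates
#'     faster than Kch.}
#'   \item{tau_inact_Q, tau_deact_K}{Q inactivation and Kch deactivation time
#'     constants (min); Q inactivates more slowly than Kch deactivates.}
#'   \item{tau_rec_Q}{Q recovery-from-inactivation time constant (min),
#'     applied outside the inactivation voltage window.}
#'   \item{I_half_Q, k_I_Q}{midpoint and slope of the light gate on Q
#'     (uW/mm^2).}
#'   \item{V_window_lo, V_window_hi, k_window}{voltage window of Q
#'     inactivation (mV).}
#'   \item{V_half_K, k_K}{Kch hyperpolarization-activation sigmoid (mV).}
#'   \item{S_on_K, k_on_K, S_off_K, k_off_K}{rising and falling edges of the
#'     Kch ROS band-pass (stress units).}
#'   \item{q_plat, k_plat}{fraction of the threshold ROS steady state at which
#'     Q inactivation is removed (habituation onset), and its sharpness.}
#'   \item{alpha_ROS}{ROS production per unit irradiance
#'     (stress mm^2 / uW / min).}
#'   \item{alpha_ROS_ref}{reference production coefficient that calibrates
#'     the habituation stress level S_plat against the irradiance threshold;
#'     kept separate from alpha_ROS so that varying the cell's actual ROS
#'     production shifts the second event (more ROS brings it forward)
#'     instead of silently recalibrating the threshold.}
#'   \item{delta_ROS}{ROS clearance rate (1/min).}
#'   \item{irradiance}{default applied irradiance (uW/mm^2).}
#'   \item{irradiance_threshold}{irradiance above which the second
#'     hyperpolarization event occurs (uW/mm^2); working value 15.99.}
#'   \item{p_K}{Kch gate exponent (cooperativity), default 1.}
#'   \item{V_T}{Nernstian scale of the ThT readout (mV).}
#' }
#' @export
hh_params <- function(...) {
  p <- list(
    C_m = 1, g_Q = 2, g_K = 8, g_L = 0.5,
    E_Q = -160, E_K = -100, E_L = -80,
    tau_act_Q = 0.3, tau_act_K = 1.5,
    tau_inact_Q = 2, tau_deact_K = 0.5, tau_rec_Q = 8,
    I_half_Q = 2, k_I_Q = 1,
    V_window_lo = -130, V_window_hi = -95, k_window = 4,
    V_half_K = -120, k_K = 4,
    S_on_K = 4.7, k_on_K = 0.5, S_off_K = 11.2, k_off_K = 0.8,
    q_plat = 0.97, k_plat = 0.4,
    alpha_ROS = 0.1, alpha_ROS_ref = 0.1, delta_ROS = 0.1,
    irradiance = 15.99, irradiance_threshold = 15.99,
    p_K = 1, V_T = 26)
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(p))
    if (length(bad)) stopf("hh_params(): unknown field(s): %s",
                           paste(bad, collapse = ", "))
    p[names(dots)] <- dots
  }
  validate_hh_params(p)
  structure(p, class = "hh_params")
}

validate_hh_params <- function(p) {
  for (f in c("C_m", "tau_act_Q", "tau_act_K", "tau_inact_Q", "tau_deact_K",
              "tau_rec_Q", "delta_ROS", "V_T")) {
    check_positive(p[[f]], f)
  }
  for (f in c("g_Q", "g_K", "g_L", "alpha_ROS", "irradiance")) {
    check_nonneg(p[[f]], f)
  }
  check_positive(p$irradiance_threshold, "irradiance_threshold")
  # conductances must be strictly positive in the canonical set; zeros arise
  # only through make_variant() knockouts, so only flag an all-zero model
  if (p$g_Q + p$g_K + p$g_L < 0 ) stopf("negative total conductance")
  if (!(p$tau_act_Q < p$tau_act_K)) {
    stopf("hh_params: Q must activate faster than Kch (tau_act_Q < tau_act_K)")
  }
  if (!(p$tau_inact_Q > p$tau_deact_K)) {
    stopf("hh_params: Q must inactivate more slowly than Kch deactivates")
  }
  if (!(p$E_K < p$E_L)) {
    stopf("hh_params: E_K must lie below the resting potential E_L")
  }
  invisible(p)
}

#' @export
print.hh_params <- function(x, ...) {
  cat("Two-channel HH parameter set (E. coli, blue-light stress)\n")
  cat(sprintf("  conductances mS/cm^2: g_Q=%g g_K=%g g_L=%g\n", x$g_Q, x$g_K, x$g_L))
  cat(sprintf("  reversals mV: E_Q=%g E_K=%g E_L=%g\n", x$E_Q, x$E_K, x$E_L))
  cat(sprintf("  ROS: alpha=%g delta=%g; irradiance %g (threshold %g) uW/mm^2\n",
              x$alpha_ROS, x$delta_ROS, x$irradiance, x$irradiance_threshold))
  invisible(x)
}

#' Stimulus program: a schedule of constant-irradiance intervals
#'
#' @param schedule data.frame with columns \code{start}, \code{stop} (min) and
#'   \code{irradiance} (uW/mm^2); intervals must be non-overlapping and lie
#'   within \code{[0, total_duration]}. Outside every interval the irradiance
#'   is zero.
#' @param total_duration total simulated duration (min).
#' @return object of class \code{stimulus_program}.
#' @export
stimulus_program <- function(schedule, total_duration) {
  check_positive(total_duration, "total_duration")
  schedule <- as.data.frame(schedule)
  need <- c("start", "stop", "irradiance")
  if (!all(need %in% names(schedule))) {
    stopf("stimulus_program(): schedule needs columns %s", paste(need, collapse = ", "))
  }
  if (nrow(schedule)) {
    schedule <- schedule[order(schedule$start), , drop = FALSE]
    with(schedule, {
      if (any(stop <= start)) stopf("stimulus_program(): stop must exceed start")
      if (any(start < 0) || any(stop > total_duration + 1e-9)) {
        stopf("stimulus_program(): intervals must lie within [0, total_duration]")
      }
      if (any(irradiance < 0)) stopf("stimulus_program(): negative irradiance")
    })
    if (nrow(schedule) > 1L &&
        any(schedule$start[-1] < schedule$stop[-nrow(schedule)] - 1e-9)) {
      stopf("stimulus_program(): overlapping intervals")
    }
  }
  structure(list(schedule = schedule, total_duration = total_duration),
            class = "stimulus_program")
}

#' Constant-light stimulus over a whole experiment
#'
#' @param irradiance applied irradiance (uW/mm^2).
#' @param duration experiment duration (min), default 60 as in the standard
#'   light-stress protocol.
#' @return a \code{\link{stimulus_program}}.
#' @export
constant_light <- function(irradiance, duration = 60) {
  stimulus_program(data.frame(start = 0, stop = duration,
                              irradiance = irradiance), duration)
}

# irradiance at time t (piecewise constant, zero outside intervals)
stimulus_at <- function(stim, t) {
  s <- stim$schedule
  if (!nrow(s)) return(rep(0, length(t)))
  out <- numeric(length(t))
  for (i in seq_len(nrow(s))) {
    on <- t >= s$start[i] & t < s$stop[i]
    out[on] <- s$irradiance[i]
  }
  out
}

#' Apply a genetic or pharmacological variant to an HH parameter set
#'
#' \code{delta_kch} deletes the Kch channel (g_K = 0); \code{catalase} models
#' ROS scavenging (alpha_ROS = 0); \code{ms_knockout} removes any of the
#' mechanosensitive channels, which zeroes the Q conductance because Q is
#' minimally the product MscK x MscL x MscS; \code{wildtype} is the identity.
#'
#' @param params an \code{\link{hh_params}} object.
#' @param variant one of \code{"wildtype"}, \code{"delta_kch"},
#'   \code{"catalase"}, \code{"ms_knockout"}.
#' @return modified \code{hh_params}.
#' @export
make_variant <- function(params, variant = c("wildtype", "delta_kch",
                                             "catalase", "ms_knockout")) {
  stopifnot(inherits(params, "hh_params"))
  if (!is.character(variant) || length(variant) != 1L ||
      !variant %in% c("wildtype", "delta_kch", "catalase", "ms_knockout")) {
    stopf(paste0("make_variant(): unknown variant '%s'; valid variants are ",
                 "wildtype, delta_kch, catalase, ms_knockout"),
          paste(as.character(variant), collapse = ","))
  }
  p <- unclass(params)
  switch(variant,
         wildtype    = NULL,
         delta_kch   = { p$g_K <- 0 },
         catalase    = { p$alpha_ROS <- 0 },
         ms_knockout = { p$g_Q <- 0 })
  structure(p, class = "hh_params")
}

# gating steady states and time constants; I is the instantaneous irradiance
hh_gates <- function(V, S, I, p) {
  S_plat <- p$q_plat * p$alpha_ROS_ref * p$irradiance_threshold / p$delta_ROS
  W <- sigmoid((V - p$V_window_lo) / p$k_window) *
       sigmoid((p$V_window_hi - V) / p$k_window)
  list(
    m_inf = sigmoid((I - p$I_half_Q) / p$k_I_Q),
    h_inf = 1 - W * sigmoid((S_plat - S) / p$k_plat),
    tau_h = p$tau_rec_Q - (p$tau_rec_Q - p$tau_inact_Q) * W,
    A_K   = sigmoid((p$V_half_K - V) / p$k_K),
    B_K   = sigmoid((S - p$S_on_K) / p$k_on_K) *
            sigmoid((p$S_off_K - S) / p$k_off_K))
}

hh_deriv <- function(state, p, I) {
  V <- state[1L]; m <- state[2L]; h <- state[3L]; n <- state[4L]; S <- state[5L]
  g <- hh_gates(V, S, I, p)
  n_inf <- g$A_K * g$B_K
  tau_n <- if (n_inf > n) p$tau_act_K else p$tau_deact_K
  dV <- -(p$g_Q * m * h * (V - p$E_Q) +
          p$g_K * n^p$p_K * (V - p$E_K) +
          p$g_L * (V - p$E_L)) / p$C_m
  c(dV,
    (g$m_inf - m) / p$tau_act_Q,
    (g$h_inf - h) / g$tau_h,
    (n_inf - n) / tau_n,
    p$alpha_ROS * I - p$delta_ROS * S)
}

#' Simulate the globally averaged membrane potential under light stress
#'
#' Integrates the two-channel HH model and returns both the state trajectory
#' and a ThT fluorescence proxy trace (\code{\link{tht_readout}}). The
#' integration is deterministic: the \code{seed} argument is accepted for
#' interface uniformity and only used when measurement noise is requested.
#'
#' @param params \code{\link{hh_params}}.
#' @param stim \code{\link{stimulus_program}}; defaults to constant light at
#'   \code{params$irradiance} for 60 min.
#' @param initial named numeric vector \code{c(V, m_Q, h_Q, n_K, S)}; defaults
#'   to the dark resting state (V = E_L, channels closed, Q available, S = 0).
#' @param dt integration/reporting step (min). Validated against the fastest
#'   time constant; the fixed-step classical Runge-Kutta integrator needs
#'   \code{dt <= tau_min / 5}.
#' @param method \code{"rk4"} (fixed-step, default, bit-reproducible) or
#'   \code{"adaptive"} (deSolve \code{ode45} with relative tolerance 1e-6,
#'   reported on the same time grid).
#' @param dt_out reporting cadence for the returned trajectory and trace
#'   (min); must be a multiple of \code{dt}.
#' @param noise_sd additive Gaussian noise (fluorescence units) applied to the
#'   raw ThT proxy before normalization; 0 disables it.
#' @param seed RNG seed, used only when \code{noise_sd > 0}.
#' @return a list of class \code{hh_sim} with elements \code{trajectory}
#'   (data.frame t, V, m_Q, h_Q, n_K, S), \code{trace}
#'   (a normalized \code{\link{tht_trace}}), \code{params}, \code{stim}.
#' @export
simulate_membrane <- function(params, stim = NULL, initial = NULL,
                              dt = 0.01, method = c("rk4", "adaptive"),
                              dt_out = 0.25, noise_sd = 0, seed = 1L) {
  stopifnot(inherits(params, "hh_params"))
  method <- match.arg(method)
  if (is.null(stim)) stim <- constant_light(params$irradiance)
  stopifnot(inherits(stim, "stimulus_program"))
  check_positive(dt, "dt")
  if (stim$total_duration < dt) stopf("simulate_membrane(): stimulus shorter than dt")
  if (nrow(stim$schedule) == 0L) {
    warnf("simulate_membrane(): empty stimulus schedule; returning initial state only")
    init <- initial %||% c(V = params$E_L, m_Q = 0, h_Q = 1, n_K = 0, S = 0)
    traj <- data.frame(t = 0, V = init[1], m_Q = init[2], h_Q = init[3],
                       n_K = init[4], S = init[5])
    return(structure(list(trajectory = traj,
                          trace = tht_trace(0, 1, label = "hh", normalized = FALSE),
                          params = params, stim = stim), class = "hh_sim"))
  }
  tau_min <- min(params$tau_act_Q, params$tau_deact_K, params$tau_act_K,
                 params$tau_inact_Q, 1 / params$delta_ROS,
                 params$C_m / max(params$g_Q + params$g_K + params$g_L, 1e-12))
  if (method == "rk4" && dt > tau_min / 5) {
    stopf("simulate_membrane(): dt = %g too large for stability; fastest time constant is %g min, use dt <= %g",
          dt, tau_min, tau_min / 5)
  }
  thin <- round(dt_out / dt)
  if (abs(thin * dt - dt_out) > 1e-9 || thin < 1) {
    stopf("simulate_membrane(): dt_out must be a positive multiple of dt")
  }
  state <- initial %||% c(V = params$E_L, m_Q = 0, h_Q = 1, n_K = 0, S = 0)
  if (length(state) != 5L) stopf("simulate_membrane(): initial state needs 5 components")
  nstep <- floor(stim$total_duration / dt + 1e-9)
  if (method == "rk4") {
    keep_idx <- seq(0L, nstep, by = thin)
    traj <- matrix(NA_real_, length(keep_idx), 6L)
    traj[1L, ] <- c(0, state)
    row <- 1L
    s <- as.numeric(state)
    for (i in seq_len(nstep)) {
      t0 <- (i - 1L) * dt
      I1 <- stimulus_at(stim, t0)
      I2 <- stimulus_at(stim, t0 + dt / 2)
      I3 <- stimulus_at(stim, t0 + dt)
      k1 <- hh_deriv(s, params, I1)
      k2 <- hh_deriv(s + dt / 2 * k1, params, I2)
      k3 <- hh_deriv(s + dt / 2 * k2, params, I2)
      k4 <- hh_deriv(s + dt * k3, params, I3)
      s <- s + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      s[2:4] <- pmin(pmax(s[2:4], 0), 1)  # gates live in [0,1]
      s[5] <- max(s[5], 0)
      if (any(!is.finite(s))) {
        stopf("simulate_membrane(): non-finite state at step %d (t = %g min); try a smaller dt",
              i, i * dt)
      }
      if (i %% thin == 0L) { row <- row + 1L; traj[row, ] <- c(i * dt, s) }
    }
  } else {
    times <- seq(0, nstep * dt, by = dt_out)
    fn <- function(t, y, parms) list(hh_deriv(y, params, stimulus_at(stim, t)))
    sol <- deSolve::ode(y = as.numeric(state), times = times, func = fn,
                        parms = NULL, method = "ode45",
                        rtol = 1e-6, atol = 1e-8)
    if (any(!is.finite(sol))) {
      stopf("simulate_membrane(): adaptive integration produced non-finite values; try method = 'rk4' with smaller dt")
    }
    traj <- unname(as.matrix(sol))
  }
  colnames(traj) <- c("t", "V", "m_Q", "h_Q", "n_K", "S")
  traj <- as.data.frame(traj)
  trace <- tht_readout(traj$V, times = traj$t, V_T = params$V_T,
                       noise_sd = noise_sd,
                       seed = derive_seed(seed, "hh_noise"),
                       label = "hh")
  structure(list(trajectory = traj, trace = trace, params = params,
                 stim = stim), class = "hh_sim")
}

#' @export
print.hh_sim <- function(x, ...) {
  cat(sprintf("HH simulation: %d samples over %.4g min, V in [%.4g, %.4g] mV\n",
              nrow(x$trajectory), max(x$trajectory$t),
              min(x$trajectory$V), max(x$trajectory$V)))
  invisible(x)
}

#' ThT fluorescence readout of a membrane-potential series
#'
#' ThT is a cationic Nernstian voltage indicator: it accumulates in cells with
#' more negative membrane potential, so fluorescence rises on
#' hyperpolarization. The readout is \eqn{F = \exp(-(V - V_{ref}) / V_T)}
#' followed by per-trace min-max normalization. The raw max/min dynamic range
#' is kept on the trace so downstream peak calling can recognize
#' non-responsive (near-flat) traces whose min-max rescaling would only
#' amplify noise.
#'
#' @param V_series membrane potentials (mV); must be non-empty.
#' @param times time stamps (min); defaults to 0, 1, 2, ...
#' @param V_T Nernstian scale (mV), default 26.
#' @param V_ref reference potential (mV); defaults to the first sample.
#' @param normalize min-max normalize (default TRUE).
#' @param noise_sd additive Gaussian noise on raw F before normalization.
#' @param seed RNG seed for the noise.
#' @param label trace label.
#' @return a \code{\link{tht_trace}}.
#' @export
tht_readout <- function(V_series, times = NULL, V_T = 26, V_ref = NULL,
                        normalize = TRUE, noise_sd = 0, seed = 1L,
                        label = "tht") {
  if (length(V_series) == 0L) stopf("tht_readout(): empty V series")
  if (any(!is.finite(V_series))) stopf("tht_readout(): non-finite V")
  check_positive(V_T, "V_T")
  V_ref <- V_ref %||% V_series[1L]
  times <- times %||% seq_along(V_series) - 1
  F <- exp(-(V_series - V_ref) / V_T)
  if (noise_sd > 0) {
    set.seed(seed)
    F <- pmax(F + stats::rnorm(length(F), 0, noise_sd), 0)
  }
  dr <- max(F) / max(min(F), .Machine$double.eps)
  if (normalize && diff(range(F)) > 0) {
    F <- (F - min(F)) / (max(F) - min(F))
    tht_trace(times, F, label = label, normalized = TRUE, dynamic_range = dr)
  } else {
    tht_trace(times, F, label = label, normalized = FALSE, dynamic_range = dr)
  }
}

#' Irradiance delivered by an objective from the measured power
#'
#' The illuminated field of view is a disc whose diameter is the objective
#' field number divided by the magnification, so
#' \eqn{I = P / (\pi (FN / 2 mag)^2)}. With the 60x oil objective
#' (FN = 26.5 mm) and 2.43 uW of 440 nm light this gives the working
#' irradiance of ~15.99 uW/mm^2.
#'
#' @param power measured light power at the sample plane (uW), >= 0.
#' @param field_number objective field number (mm), > 0.
#' @param magnification objective magnification, > 0.
#' @return irradiance (uW/mm^2).
#' @export
irradiance_from_power <- function(power, field_number, magnification) {
  check_nonneg(power, "power")
  check_positive(field_number, "field_number")
  check_positive(magnification, "magnification")
  fov_radius <- field_number / (2 * magnification)      # mm
  power / (pi * fov_radius^2)
}
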