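# Phenomenological membrane kinetics. The solver is written against a small
# "cell model" interface (rate function + gate update + voltage mapping) so
# a full ionic model can be slotted in later; the default is the two-variable
# Mitchell-Schaeffer model, whose activation/repolarization structure is all
# the downstream quantities of interest depend on.

#' Mitchell-Schaeffer parameter set
#'
#' Two-variable phenomenological membrane model in normalized units:
#' `du/dt = h u^2 (1 - u) / tau_in - u / tau_out + I_stim`,
#' with the recovery gate `h` opening towards 1 with time constant
#' `tau_open` while `u < u_gate` and closing towards 0 with `tau_close`
#' otherwise. `tau_close` sets the action-potential duration
#' (APD ~ tau_close * log(tau_close-independent excitation level)), `tau_in`
#' the upstroke speed and, with the tissue diffusivity, the conduction
#' velocity.
#'
#' @param tau_in,tau_out,tau_open,tau_close time constants, ms.
#' @param u_gate dimensionless gate threshold.
#' @return list of class `ms_params`.
#' @export
ms_params <- function(tau_in = 0.3, tau_out = 6, tau_open = 120,
                      tau_close = 80, u_gate = 0.13) {
  stopifnot(tau_in > 0, tau_out > 0, tau_open > 0, tau_close > 0,
            u_gate > 0, u_gate < 1)
  structure(list(tau_in = tau_in, tau_out = tau_out, tau_open = tau_open,
                 tau_close = tau_close, u_gate = u_gate),
            class = "ms_params")
}

#' Cell model with healthy and border-zone variants
#'
#' Bundles per-tissue-class membrane parameter sets with the mapping from the
#' normalized state `u` to physical voltage, `V = v_rest + v_amp * u` (mV).
#' The border-zone defaults prolong APD (`tau_close` x 1.2) and reduce
#' excitability (`tau_in` x 1.5) relative to healthy tissue, the remodeling
#' the repolarization-gradient analysis probes.
#'
#' @param healthy,bz [ms_params()] for the two excitable tissue classes.
#' @param v_rest resting potential, mV.
#' @param v_amp action-potential amplitude, mV (> 0).
#' @return list of class `cell_model`.
#' @export
cell_model <- function(healthy = ms_params(),
                       bz = ms_params(tau_in = 0.45, tau_close = 96),
                       v_rest = -85, v_amp = 120) {
  stopifnot(inherits(healthy, "ms_params"), inherits(bz, "ms_params"),
            v_amp > 0)
  structure(list(name = "mitchell_schaeffer", healthy = healthy, bz = bz,
                 v_rest = v_rest, v_amp = v_amp),
            class = "cell_model")
}

# vectorized reaction rate du/dt; parameters may be per-node vectors
ms_rate <- function(u, h, tau_in, tau_out) {
  h * u * u * (1 - u) / tau_in - u / tau_out
}

# exact exponential gate update over one step dt (the h ODE is linear in h
# for fixed side of the gate threshold)
ms_gate_update <- function(u, h, dt, tau_open, tau_close, u_gate) {
  below <- u < u_gate
  tau <- ifelse(below, tau_open, tau_close)
  target <- as.numeric(below)
  target + (h - target) * exp(-dt / tau)
}

#' Single-cell (0-D) action potential
#'
#' Integrates the membrane model for one stimulated beat with forward-Euler
#' reaction and exact gate updates (the same scheme as the tissue solver's
#' reaction substep), returning the voltage trace in mV.
#'
#' @param params an [ms_params()].
#' @param dt time step, ms.
#' @param duration total time, ms.
#' @param stim_start,stim_duration,stim_amplitude stimulus (normalized
#'   units/ms).
#' @param v_rest,v_amp voltage mapping, mV.
#' @return data.frame with columns `time` (ms), `v` (mV), `u`, `h`.
#' @export
run_cell_0d <- function(params, dt = 0.01, duration = 400,
                        stim_start = 1, stim_duration = 1,
                        stim_amplitude = 1, v_rest = -85, v_amp = 120) {
  stopifnot(inherits(params, "ms_params"), dt > 0, duration > dt)
  n <- floor(duration / dt)
  u <- 0; h <- 1
  out_u <- numeric(n + 1); out_h <- numeric(n + 1)
  out_u[1] <- u; out_h[1] <- h
  for (s in seq_len(n)) {
    t <- (s - 1) * dt
    stim <- if (t >= stim_start && t < stim_start + stim_duration)
      stim_amplitude else 0
    u_new <- u + dt * (ms_rate(u, h, params$tau_in, params$tau_out) + stim)
    h <- ms_gate_update(u, h, dt, params$tau_open, params$tau_close,
                        params$u_gate)
    u <- u_new
    out_u[s + 1] <- u; out_h[s + 1] <- h
  }
  data.frame(time = (0:n) * dt, v = v_rest + v_amp * out_u,
             u = out_u, h = out_h)
}

#' Action-potential duration at a voltage threshold
#'
#' APD measured on a 0-D trace as the time from the upstroke crossing of
#' `threshold` to the repolarization crossing (linear interpolation between
#' samples).
#'
#' @param trace data.frame from [run_cell_0d()].
#' @param threshold voltage threshold, mV (default -70, the repolarization
#'   criterion used throughout).
#' @return APD in ms, or `NA` if the trace never crosses.
#' @export
apd_at_threshold <- function(trace, threshold = -70) {
  v <- trace$v; t <- trace$time
  up <- which(v[-1] > threshold & v[-length(v)] <= threshold)
  if (!length(up)) return(NA_real_)
  i <- up[1]
  t_up <- t[i] + (threshold - v[i]) / (v[i + 1] - v[i]) * (t[i + 1] - t[i])
  dn <- which(v[-1] < threshold & v[-length(v)] >= threshold)
  dn <- dn[dn > i]
  if (!length(dn)) return(NA_real_)
  j <- dn[1]
  t_dn <- t[j] + (threshold - v[j]) / (v[j + 1] - v[j]) * (t[j + 1] - t[j])
  t_dn - t_up
}
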