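#' Leaky integrate-and-fire neuron parameters
#'
#' Defaults are the striatal medium-spiny-neuron parameter set used
#' throughout the package: membrane capacitance 200 pF, leak conductance
#' 12.5 nS (membrane time constant 16 ms), leak reversal -80 mV, spike
#' threshold -45 mV, reset -80 mV, 2 ms absolute refractory period, and
#' synaptic reversal potentials of 0 mV (excitatory) and -64 mV
#' (inhibitory). Note that `E_inh` lies above rest, so inhibition near rest
#' is shunting/depolarising; it is hyperpolarising for a neuron held above
#' -64 mV.
#'
#' @param C_m Membrane capacitance, pF.
#' @param g_L Leak conductance, nS.
#' @param E_L Leak reversal potential, mV.
#' @param V_th Spike threshold, mV.
#' @param V_reset Post-spike reset potential, mV.
#' @param t_ref Absolute refractory period, ms.
#' @param E_exc,E_inh Excitatory / inhibitory synaptic reversal potentials, mV.
#' @return A list of class `neuron_parameters`.
#' @export
neuron_parameters <- function(C_m = 200, g_L = 12.5, E_L = -80, V_th = -45,
                              V_reset = -80, t_ref = 2, E_exc = 0,
                              E_inh = -64) {
  stopifnot(C_m > 0, g_L > 0, t_ref > 0, V_reset <= V_th)
  structure(list(C_m = C_m, g_L = g_L, E_L = E_L, V_th = V_th,
                 V_reset = V_reset, t_ref = t_ref, E_exc = E_exc,
                 E_inh = E_inh),
            class = "neuron_parameters")
}

#' Alpha-function synapse parameters
#'
#' Conductance transients are alpha functions
#' `g(t) = g_peak * (t / tau) * exp(1 - t / tau)`, peaking at `g_peak`
#' exactly `tau` after the presynaptic spike. Default time constants are 5 ms
#' (excitatory) and 10 ms (inhibitory). Peak conductances default to `NA` and
#' are normally filled in by [calibrate_psp()] so that unitary PSPs have the
#' reference amplitudes (0.8 mV IPSP at a -44 mV holding potential, 1.6 mV
#' EPSP at -70 mV). The synaptic delay applies to recurrent connections and
#' must be at least one integration step.
#'
#' @param tau_exc,tau_inh Conductance time constants, ms.
#' @param g_peak_exc,g_peak_inh Peak conductances, nS (`NA` = calibrate).
#' @param delay Recurrent synaptic delay, ms.
#' @return A list of class `synapse_parameters`.
#' @export
synapse_parameters <- function(tau_exc = 5, tau_inh = 10,
                               g_peak_exc = NA_real_, g_peak_inh = NA_real_,
                               delay = 1) {
  stopifnot(tau_exc > 0, tau_inh > 0, delay > 0)
  structure(list(tau_exc = tau_exc, tau_inh = tau_inh,
                 g_peak_exc = g_peak_exc, g_peak_inh = g_peak_inh,
                 delay = delay),
            class = "synapse_parameters")
}

#' Alpha-function conductance time course
#'
#' @param t_since_spike Time since the presynaptic spike, ms (`>= 0`).
#' @param tau Time-to-peak, ms.
#' @param g_peak Peak conductance, nS.
#' @return Conductance in nS: `g_peak * (t/tau) * exp(1 - t/tau)`.
#' @examples
#' alpha_conductance(10, tau = 10, g_peak = 2) # == 2 (peak at t = tau)
#' @export
alpha_conductance <- function(t_since_spike, tau, g_peak) {
  stopifnot(all(t_since_spike >= 0), tau > 0)
  g_peak * (t_since_spike / tau) * exp(1 - t_since_spike / tau)
}

#' Membrane response to a single synaptic event at a holding potential
#'
#' Integrates the (non-spiking) membrane equation at fixed step `dt` with a
#' constant holding current that places the free membrane potential at
#' `holding_mV`, delivers one alpha-conductance event at `t = 0`, and returns
#' the voltage trajectory. Uses the same exact-conductance /
#' exponential-Euler-voltage scheme as the network simulator.
#'
#' @param g_peak Peak conductance of the event, nS.
#' @param tau Synaptic time constant, ms.
#' @param E_syn Synaptic reversal potential, mV.
#' @param holding_mV Holding potential, mV.
#' @param neuron A [neuron_parameters()].
#' @param dt Integration step, ms.
#' @param t_max Duration, ms (default `12 * tau`, ample for the PSP peak).
#' @return A tibble with columns `time_ms`, `v_mV`.
#' @export
psp_response <- function(g_peak, tau, E_syn, holding_mV,
                         neuron = neuron_parameters(), dt = 0.1,
                         t_max = 12 * tau) {
  nstep <- ceiling(t_max / dt)
  # constant current holding the free membrane at holding_mV
  I_hold <- neuron$g_L * (holding_mV - neuron$E_L)
  decay <- exp(-dt / tau)
  # alpha kernel as two-stage exact propagator: y2 is the conductance,
  # a spike adds e * g_peak / tau to y1
  y1 <- exp(1) * g_peak / tau
  y2 <- 0
  v <- holding_mV
  out_v <- numeric(nstep + 1)
  out_v[1] <- v
  for (s in seq_len(nstep)) {
    y2 <- (y2 + dt * y1) * decay
    y1 <- y1 * decay
    g_tot <- neuron$g_L + y2
    v_inf <- (neuron$g_L * neuron$E_L + y2 * E_syn + I_hold) / g_tot
    v <- v_inf + (v - v_inf) * exp(-dt * g_tot / neuron$C_m)
    out_v[s + 1] <- v
  }
  tibble::tibble(time_ms = dt * (0:nstep), v_mV = out_v)
}

#' Peak deflection of a unitary PSP
#'
#' @inheritParams psp_response
#' @return Peak absolute deviation from the holding potential, mV (signed
#'   deviation available via `psp_response()`).
#' @export
psp_amplitude <- function(g_peak, tau, E_syn, holding_mV,
                          neuron = neuron_parameters(), dt = 0.1) {
  tr <- psp_response(g_peak, tau, E_syn, holding_mV, neuron, dt)
  max(abs(tr$v_mV - holding_mV))
}

#' Calibrate a peak synaptic conductance to a target PSP amplitude
#'
#' Finds by root-finding the alpha-synapse peak conductance for which a
#' single presynaptic spike onto a neuron held at `holding_mV` (by constant
#' current, spiking disabled) deflects the membrane by `target_mV` at the PSP
#' peak. The reference calibration gives weak striatal synapses: a 0.8 mV
#' unitary IPSP at a holding potential of -44.0 mV and a 1.6 mV unitary EPSP
#' at -70.0 mV.
#'
#' @param synapse_type `"exc"` or `"inh"` (selects the reversal potential).
#' @param tau Synaptic time constant, ms.
#' @param holding_mV Holding potential, mV.
#' @param target_mV Target PSP amplitude, mV (> 0, absolute deflection).
#' @param neuron A [neuron_parameters()].
#' @param dt Integration step, ms.
#' @param tol Amplitude tolerance, mV.
#' @return Calibrated peak conductance, nS.
#' @examples
#' g_inh <- calibrate_psp("inh", tau = 10, holding_mV = -44, target_mV = 0.8)
#' psp_amplitude(g_inh, 10, neuron_parameters()$E_inh, -44) # ~0.8
#' @export
calibrate_psp <- function(synapse_type = c("exc", "inh"), tau, holding_mV,
                          target_mV, neuron = neuron_parameters(), dt = 0.1,
                          tol = 0.001) {
  synapse_type <- match.arg(synapse_type)
  stopifnot(target_mV > 0)
  E_syn <- if (synapse_type == "exc") neuron$E_exc else neuron$E_inh
  if (abs(E_syn - holding_mV) < 1e-9) {
    stop("holding potential equals the synaptic reversal potential: no driving force, target unreachable")
  }
  f <- function(g) psp_amplitude(g, tau, E_syn, holding_mV, neuron, dt) - target_mV
  hi <- 1
  while (f(hi) < 0 && hi < 1e6) hi <- hi * 4
  if (f(hi) < 0) {
    stop(sprintf("PSP target %.3f mV unreachable: amplitude at g_peak = %g nS is only %.3f mV",
                 target_mV, hi, f(hi) + target_mV))
  }
  root <- stats::uniroot(f, c(0, hi), tol = 1e-10)
  g <- root$root
  achieved <- f(g) + target_mV
  if (abs(achieved - target_mV) > tol) {
    stop(sprintf("calibration did not reach tolerance: achieved %.5f mV for target %.5f mV",
                 achieved, target_mV))
  }
  g
}

#' Reference calibrated synapse set
#'
#' Convenience wrapper: returns [synapse_parameters()] with both peak
#' conductances calibrated to the reference unitary amplitudes (1.6 mV EPSP
#' at -70 mV; 0.8 mV IPSP at -44 mV).
#'
#' @param neuron A [neuron_parameters()].
#' @param delay Recurrent synaptic delay, ms.
#' @param dt Integration step used in calibration, ms.
#' @return A `synapse_parameters` object with `g_peak_exc`, `g_peak_inh` set.
#' @export
calibrated_synapses <- function(neuron = neuron_parameters(), delay = 1,
                                dt = 0.1) {
  synapse_parameters(
    tau_exc = 5, tau_inh = 10,
    g_peak_exc = calibrate_psp("exc", 5, -70, 1.6, neuron, dt),
    g_peak_inh = calibrate_psp("inh", 10, -44, 0.8, neuron, dt),
    delay = delay
  )
}
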