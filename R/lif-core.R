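#' Per-layer LIF state
#'
#' Holds one layer's membrane potentials `V`, excitatory conductances `g_E`,
#' spike indicators `delta` and surrogate outputs `S`. Each field is either a
#' numeric vector (one sample) or a samples-by-neurons matrix (a batch); all
#' four must have the same shape.
#'
#' @param V membrane potential per neuron.
#' @param g_E excitatory conductance per neuron (non-negative at init).
#' @param delta spike indicator per neuron, 0 or 1.
#' @param S surrogate output per neuron.
#' @return An object of class `layer_state`.
#' @export
layer_state <- function(V, g_E = V * 0, delta = V * 0, S = V * 0) {
  check_same_shape(V, g_E, "V", "g_E")
  check_same_shape(V, delta, "V", "delta")
  check_same_shape(V, S, "V", "S")
  if (!all(delta %in% c(0, 1))) {
    stop("delta must contain only 0 or 1", call. = FALSE)
  }
  structure(list(V = V, g_E = g_E, delta = delta, S = S),
            class = "layer_state")
}

#' Resting state for a layer
#'
#' All neurons start at the reset potential with zero conductance, no spike
#' and zero surrogate output. State is re-initialized like this for every
#' sample, so simulations never leak activity across inputs.
#'
#' @param n_neurons layer width.
#' @param params a [neuron_params()] object.
#' @param batch_size number of independent samples (rows).
#' @return A `layer_state` whose fields are `batch_size x n_neurons` matrices.
#' @export
initial_state <- function(n_neurons, params, batch_size = 1L) {
  z <- matrix(0, nrow = batch_size, ncol = n_neurons)
  layer_state(V = z + params$V_reset, g_E = z, delta = z, S = z)
}

#' One discrete LIF update step
#'
#' Advances a layer by one step `dt` under the weighted input `drive`
#' (the sum of presynaptic surrogate outputs times the forward weights).
#' The update order is fixed and canonical:
#'
#' 1. membrane: `V' = V - (dt/tau_m) * ((V - V_L) + (g_E/g_L) * (V - V_E))`,
#'    using the conductance from *before* this step;
#' 2. conductance: `g_E' = g_E + (dt/tau_E) * (-g_E + drive)`;
#' 3. threshold: neurons with `V' > V_th` (strict) spike — `delta = 1` and
#'    `V'` is set to `V_reset`; all others have `delta = 0`;
#' 4. surrogate output: `S = drive + tau_s * delta`.
#'
#' There is no refractory period and no inhibitory conductance. The input
#' state is not modified.
#'
#' @param state a [layer_state()].
#' @param drive per-neuron weighted input, same shape as the state fields.
#' @param params a [neuron_params()] object.
#' @return The new `layer_state`.
#' @examples
#' p <- neuron_params()
#' st <- initial_state(3, p)
#' lif_step(st, drive = matrix(c(0, 10, 20), 1), p)
#' @export
lif_step <- function(state, drive, params) {
  stopifnot(inherits(state, "layer_state"), inherits(params, "neuron_params"))
  check_same_shape(state$V, drive, "state", "drive")
  check_finite(drive, "drive")

  V <- state$V
  g_E <- state$g_E
  V_new <- V - (params$dt / params$tau_m) *
    ((V - params$V_L) + (g_E / params$g_L) * (V - params$V_E))
  g_new <- g_E + (params$dt / params$tau_E) * (-g_E + drive)
  spiked <- V_new > params$V_th
  V_new[spiked] <- params$V_reset
  delta <- V * 0
  delta[spiked] <- 1
  layer_state(V = V_new, g_E = g_new, delta = delta,
              S = surrogate_output(drive, delta, params$tau_s))
}

#' Residual-style surrogate layer output
#'
#' The real-valued signal a layer passes on: its weighted input plus a spike
#' bonus, `S = drive + tau_s * delta`. Carrying the input through alongside
#' the (sparse, binary) spikes is what lets learning signals reach deep
#' layers within a short simulation.
#'
#' @param drive per-neuron weighted input.
#' @param delta spike indicator (0/1), same shape as `drive`.
#' @param tau_s spike amplitude.
#' @return Elementwise `drive + tau_s * delta`.
#' @export
surrogate_output <- function(drive, delta, tau_s) {
  check_same_shape(drive, delta, "drive", "delta")
  if (!all(delta %in% c(0, 1))) {
    stop("delta must contain only 0 or 1", call. = FALSE)
  }
  drive + tau_s * delta
}

#' Fixed point of the conductance recursion
#'
#' Under constant drive the conductance update
#' `g_E' = g_E + (dt/tau_E) * (-g_E + drive)` is a linear recursion whose
#' fixed point is the drive itself; the gap shrinks geometrically by
#' `(1 - dt/tau_E)` per step. Exposed as an analytic reference for the
#' dynamics.
#'
#' @param drive per-neuron constant input.
#' @return `drive`, unchanged (the fixed point).
#' @export
conductance_fixed_point <- function(drive) {
  check_finite(drive, "drive")
  drive
}

#' Membrane fixed point under constant conductance
#'
#' With the threshold out of reach and conductance settled at `g_E*`, the
#' membrane relaxes to the conductance-weighted average of the leak and
#' reversal potentials, `V* = (g_L V_L + g_E* V_E) / (g_L + g_E*)`.
#'
#' @param g_E_star settled conductance (equals the constant drive).
#' @param params a [neuron_params()] object.
#' @return The equilibrium membrane potential.
#' @export
membrane_fixed_point <- function(g_E_star, params) {
  stopifnot(inherits(params, "neuron_params"))
  (params$g_L * params$V_L + g_E_star * params$V_E) /
    (params$g_L + g_E_star)
}
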