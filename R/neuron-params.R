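#' Conductance-based LIF neuron and simulation constants
#'
#' Bundles every constant of the discrete-time leaky integrate-and-fire
#' (LIF) neuron with a conductance-based excitatory synapse, plus the
#' simulation grid. The defaults are the values used throughout the
#' package's experiments: an excitatory reversal potential of 0.2, a firing
#' threshold of 9e-4 just above the reset/leak potential at 0, membrane and
#' conductance time constants of 0.5 and 0.2, a leak conductance of 20, a
#' surrogate spike amplitude of 0.01, and a 0.1-long simulation resolved in
#' steps of 0.01 (ten steps).
#'
#' All potentials are in arbitrary units on a common scale; `tau_m`, `tau_E`,
#' `dt` and `T` share one time unit; `tau_s` (the spike's contribution to the
#' surrogate output) and the conductances are dimensionless on the scale of
#' the weights.
#'
#' @param V_L leak (resting) potential.
#' @param V_E excitatory reversal potential; must satisfy `V_L <= V_E`.
#' @param V_th firing threshold; a neuron spikes when its updated potential
#'   strictly exceeds it.
#' @param V_reset post-spike reset potential; must satisfy `V_reset <= V_th`.
#' @param tau_m membrane time constant (= C_m / g_L).
#' @param tau_E excitatory conductance decay time constant.
#' @param g_L leak conductance.
#' @param tau_s surrogate spike amplitude: the real-valued layer output is
#'   the weighted input plus `tau_s` times the spike indicator.
#' @param dt simulation step; `dt/tau_m` and `dt/tau_E` must be at most 1 for
#'   the explicit update to be stable.
#' @param T total simulated time; `T/dt` must be a positive integer.
#'
#' @return An object of class `neuron_params` (a named list).
#' @examples
#' p <- neuron_params()
#' n_steps(p)  # 10
#' @export
neuron_params <- function(V_L = 0, V_E = 0.2, V_th = 0.0009, V_reset = 0,
                          tau_m = 0.5, tau_E = 0.2, g_L = 20, tau_s = 0.01,
                          dt = 0.01, T = 0.1) {
  p <- list(V_L = V_L, V_E = V_E, V_th = V_th, V_reset = V_reset,
            tau_m = tau_m, tau_E = tau_E, g_L = g_L, tau_s = tau_s,
            dt = dt, T = T)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop(sprintf("neuron parameter '%s' must be a finite scalar", nm),
           call. = FALSE)
    }
    p[[nm]] <- as.double(v)
  }
  if (p$dt <= 0) stop("dt must be positive", call. = FALSE)
  if (p$T < p$dt) stop("T must be at least dt", call. = FALSE)
  steps <- p$T / p$dt
  if (abs(steps - round(steps)) > 1e-9 || round(steps) < 1) {
    stop("T/dt must be a positive integer number of steps", call. = FALSE)
  }
  if (p$tau_m <= 0 || p$tau_E <= 0 || p$g_L <= 0) {
    stop("tau_m, tau_E and g_L must be positive", call. = FALSE)
  }
  if (p$dt / p$tau_m > 1 || p$dt / p$tau_E > 1) {
    stop("dt/tau_m and dt/tau_E must not exceed 1 (discrete-update stability)",
         call. = FALSE)
  }
  if (p$V_reset > p$V_th) stop("V_reset must not exceed V_th", call. = FALSE)
  if (p$V_L > p$V_E) stop("V_L must not exceed V_E", call. = FALSE)
  structure(p, class = "neuron_params")
}

#' Number of simulation steps implied by neuron parameters
#'
#' @param params a [neuron_params()] object.
#' @return `T/dt` as an integer.
#' @export
n_steps <- function(params) {
  stopifnot(inherits(params, "neuron_params"))
  as.integer(round(params$T / params$dt))
}

#' @export
print.neuron_params <- function(x, ...) {
  cat("LIF neuron parameters\n")
  cat(sprintf("  potentials: V_L=%g V_E=%g V_th=%g V_reset=%g\n",
              x$V_L, x$V_E, x$V_th, x$V_reset))
  cat(sprintf("  dynamics:   tau_m=%g tau_E=%g g_L=%g tau_s=%g\n",
              x$tau_m, x$tau_E, x$g_L, x$tau_s))
  cat(sprintf("  simulation: dt=%g T=%g (%d steps)\n",
              x$dt, x$T, n_steps(x)))
  invisible(x)
}

neuron_param_keys <- c("V_L", "V_E", "V_th", "V_reset", "tau_m", "tau_E",
                       "g_L", "tau_s", "dt", "T")

#' Serialize neuron parameters to a flat key-value section
#'
#' @param params a [neuron_params()] object.
#' @return Named character vector, one entry per parameter, keys exactly
#'   `V_L, V_E, V_th, V_reset, tau_m, tau_E, g_L, tau_s, dt, T`.
#' @seealso [neuron_params_from_config()]
#' @export
neuron_params_to_config <- function(params) {
  stopifnot(inherits(params, "neuron_params"))
  vapply(neuron_param_keys, function(k) format(params[[k]], digits = 17),
         character(1))
}

#' Build neuron parameters from a flat key-value section
#'
#' Unknown keys are rejected; missing keys fall back to the defaults of
#' [neuron_params()].
#'
#' @param kv named list or named character vector of parameter values.
#' @return A [neuron_params()] object.
#' @export
neuron_params_from_config <- function(kv) {
  kv <- as.list(kv)
  unknown <- setdiff(names(kv), neuron_param_keys)
  if (length(unknown) > 0) {
    stop(sprintf("unknown neuron parameter key(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  args <- lapply(kv, function(v) as.double(v))
  do.call(neuron_params, args)
}
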