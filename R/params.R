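#' Izhikevich neuron parameters
#'
#' Bundle of the Izhikevich model constants for one population.  The membrane
#' obeys `dv/dt = 0.04 v^2 + 5 v + 140 - u + I_psc + I_dc` and
#' `du/dt = a (b v - u)`; when `v` exceeds the 30 mV threshold the neuron
#' spikes and is reset (`v <- c`, `u <- u + d`).  Following the original
#' Izhikevich convention, `a`, `b`, `c`, `d` and `u` carry no explicit units;
#' `v` is in mV, currents in nA, time in ms.
#'
#' @param a recovery time-scale (> 0).
#' @param b recovery coupling to `v`.
#' @param c post-spike reset potential, mV (must lie below the 30 mV
#'   threshold).
#' @param d post-spike recovery increment.
#' @param v_init,u_init initial state.
#' @param i_dc constant bias current, nA.
#' @return An object of class `izh_params`.
#' @examples
#' izh_params(a = 0.02, b = 0.2, c = -65, d = 6, v_init = -65, u_init = -13)
#' @export
izh_params <- function(a, b, c, d, v_init = c, u_init = b * v_init,
                       i_dc = 0) {
  stopifnot(is.numeric(a), length(a) == 1L, is.finite(a))
  if (a <= 0) stop("izh_params: 'a' must be > 0")
  if (c >= 30) stop("izh_params: reset potential 'c' must lie below the 30 mV threshold")
  structure(list(a = a, b = b, c = c, d = d,
                 v_init = v_init, u_init = u_init, i_dc = i_dc),
            class = "izh_params")
}

#' @export
print.izh_params <- function(x, ...) {
  cat(sprintf("Izhikevich parameters: a=%g b=%g c=%g d=%g v0=%g u0=%g I_dc=%g nA\n",
              x$a, x$b, x$c, x$d, x$v_init, x$u_init, x$i_dc))
  invisible(x)
}

# defaults file shipped with the package, parsed once per session
the <- new.env(parent = emptyenv())

default_yaml_path <- function() {
  system.file("extdata", "lgn-defaults.yaml", package = "lgnss", mustWork = TRUE)
}

lgn_defaults <- function() {
  if (is.null(the$defaults))
    the$defaults <- yaml::read_yaml(default_yaml_path())
  the$defaults
}

#' Tonic-firing parameter presets for the LGN populations
#'
#' Returns the per-population Izhikevich presets used throughout the model:
#' TCR and TRN cells fire in regular-spiking (RS) mode, IN cells in
#' fast-spiking (FS) mode.  The values are read from the packaged defaults
#' file (`inst/extdata/lgn-defaults.yaml`), which can serve as a template for
#' user overrides.
#'
#' @param i_dc optional constant bias current, nA, applied to every preset
#'   (the networked model uses 0; the unconnected firing demonstration uses a
#'   positive value).
#' @return Named list of [izh_params()] for `TCR`, `IN` and `TRN`.
#' @examples
#' izh_presets()$TCR
#' @export
izh_presets <- function(i_dc = 0) {
  pops <- lgn_defaults()$populations
  out <- lapply(pops[c("TCR", "IN", "TRN")], function(p)
    izh_params(a = p$a, b = p$b, c = p$c, d = p$d,
               v_init = p$v_init, u_init = p$u_init, i_dc = i_dc))
  out
}

#' Exponential synapse kinetics
#'
#' Decay time constants of the current-based synapses: an arrival of weight
#' `w` adds `w` nA to the population-specific accumulator, which then decays
#' as `w * exp(-t / tau)`.
#'
#' @param tau_e,tau_i excitatory / inhibitory decay constants, ms (> 0).
#' @return Object of class `syn_kinetics`.
#' @export
syn_kinetics <- function(tau_e = lgn_defaults()$kinetics$tau_e,
                         tau_i = lgn_defaults()$kinetics$tau_i) {
  if (tau_e <= 0 || tau_i <= 0)
    stop("syn_kinetics: time constants must be > 0")
  structure(list(tau_e = tau_e, tau_i = tau_i), class = "syn_kinetics")
}
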