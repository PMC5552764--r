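#' Neuron state
#'
#' Evolving state of one Izhikevich neuron with its two synaptic current
#' accumulators.  `g_e` and `g_i` are magnitudes (both >= 0); the sign of the
#' inhibitory current is applied at summation, `I_psc = g_e - g_i`.
#'
#' @param v membrane potential, mV.
#' @param u recovery variable.
#' @param g_e,g_i excitatory / inhibitory synaptic current accumulators, nA.
#' @return Object of class `neuron_state`.
#' @export
neuron_state <- function(v, u, g_e = 0, g_i = 0) {
  if (!all(is.finite(c(v, u, g_e, g_i))))
    stop("neuron_state: state must be finite")
  if (g_e < 0 || g_i < 0)
    stop("neuron_state: synaptic accumulators are magnitudes and must be >= 0")
  structure(list(v = v, u = u, g_e = g_e, g_i = g_i), class = "neuron_state")
}

#' Advance one neuron by one RK2 step
#'
#' Explicit-midpoint (second-order Runge-Kutta) step of the Izhikevich
#' equations with the total current `I = g_e - g_i + I_dc` held constant over
#' the step.  The spike test is applied after the full step: if the advanced
#' `v` exceeds 30 mV the neuron spikes, `v` is reset to `c`, `u` incremented
#' by `d`, and the reported membrane value (`v_rec`) is clamped at 30 mV for
#' recording.
#'
#' This is the reference single-neuron implementation; the network engine
#' applies the identical update in compiled code.
#'
#' @param state a [neuron_state()].
#' @param params an [izh_params()].
#' @param dt time-step, ms (> 0).
#' @return List with `state` (advanced [neuron_state()]), `spiked` (logical)
#'   and `v_rec` (recorded membrane value, clamped at 30 on spike steps).
#' @examples
#' p <- izh_presets(i_dc = 5)$TCR
#' s <- neuron_state(v = p$v_init, u = p$u_init)
#' step_neuron(s, p, dt = 0.1)
#' @export
step_neuron <- function(state, params, dt) {
  stopifnot(inherits(state, "neuron_state"), inherits(params, "izh_params"))
  if (dt <= 0) stop("step_neuron: dt must be > 0")
  I <- state$g_e - state$g_i + params$i_dc
  v <- state$v; u <- state$u
  k1v <- 0.04 * v * v + 5 * v + 140 - u + I
  k1u <- params$a * (params$b * v - u)
  vm <- v + 0.5 * dt * k1v
  um <- u + 0.5 * dt * k1u
  vn <- v + dt * (0.04 * vm * vm + 5 * vm + 140 - um + I)
  un <- u + dt * params$a * (params$b * vm - um)
  if (!is.finite(vn) || !is.finite(un))
    stop("step_neuron: integration blow-up")
  spiked <- vn > 30
  if (spiked) {
    v_rec <- 30
    state$v <- params$c
    state$u <- un + params$d
  } else {
    v_rec <- vn
    state$v <- vn
    state$u <- un
  }
  list(state = state, spiked = spiked, v_rec = v_rec)
}

#' Decay synaptic accumulators and inject arrivals
#'
#' Exact between-event solution of the exponential current synapse: over one
#' step each accumulator decays by `exp(-dt/tau)`, then the summed weight of
#' spikes arriving this step is added.  Superposition over multiple afferents
#' holds because the kinetics are linear.
#'
#' @param state a [neuron_state()].
#' @param kinetics a [syn_kinetics()].
#' @param dt time-step, ms.
#' @param arrivals_e,arrivals_i summed arriving weights, nA (>= 0).
#' @return The updated [neuron_state()].
#' @export
decay_and_inject <- function(state, kinetics, dt, arrivals_e = 0,
                             arrivals_i = 0) {
  stopifnot(inherits(state, "neuron_state"), inherits(kinetics, "syn_kinetics"))
  if (arrivals_e < 0 || arrivals_i < 0)
    stop("decay_and_inject: arrival totals must be >= 0")
  state$g_e <- state$g_e * exp(-dt / kinetics$tau_e) + arrivals_e
  state$g_i <- state$g_i * exp(-dt / kinetics$tau_i) + arrivals_i
  state
}

#' Firing demonstration of the unconnected populations
#'
#' Runs the three LGN populations with all connectivity removed and a common
#' constant bias current, demonstrating the tonic regular-spiking (TCR, TRN)
#' and fast-spiking (IN) regimes.  Within a population every neuron receives
#' the same drive from identical initial conditions, so all spike trains in a
#' population coincide.
#'
#' @param i_dc constant bias current, nA.
#' @param duration simulated time, ms.
#' @param n_per_pop neurons instantiated per population.
#' @param dt time-step, ms.
#' @param params_by_population named list of [izh_params()]; defaults to the
#'   packaged presets with `i_dc` applied.
#' @return Named list (per population) of lists of per-neuron spike-time
#'   vectors (ms), with attribute `rates_hz` giving the mean firing rate per
#'   population.
#' @examples
#' demo <- tonic_demo(i_dc = 5, duration = 500, n_per_pop = 2)
#' attr(demo, "rates_hz")
#' @export
tonic_demo <- function(i_dc = 5, duration = 1000, n_per_pop = 5, dt = 0.1,
                       params_by_population = izh_presets(i_dc = i_dc)) {
  n_steps <- as.integer(round(duration / dt))
  roles <- names(params_by_population)
  par <- do.call(rbind, lapply(params_by_population, function(p)
    matrix(rep(c(p$a, p$b, p$c, p$d, p$v_init, p$u_init, p$i_dc),
               each = n_per_pop), nrow = n_per_pop)))
  group <- rep(seq_along(roles) - 1L, each = n_per_pop)
  res <- sim_core(par, group, length(roles),
                  integer(0), integer(0), numeric(0), integer(0),
                  integer(0), integer(0), 0L,
                  integer(0), integer(0),
                  2, 6, dt, n_steps, FALSE)
  out <- lapply(seq_along(roles), function(g) {
    lapply(seq_len(n_per_pop), function(j) {
      idx <- (g - 1L) * n_per_pop + j
      res$spike_step[res$spike_neuron == idx] * dt
    })
  })
  names(out) <- roles
  rates <- vapply(out, function(pop)
    mean(vapply(pop, length, 1L)) / (duration / 1000), 1.0)
  attr(out, "rates_hz") <- rates
  out
}
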