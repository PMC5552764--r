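#' Run one simulation trial
#'
#' Clock-driven simulation of a realized network at fixed step `dt`:
#' stimulus events enter through the realized retinal edges (configured
#' weights, 10 ms delays), spikes propagate with per-edge integer step delays, the
#' synaptic accumulators decay-and-inject and every neuron advances one RK2
#' step per tick.  Membrane potentials are recorded every step (clamped at
#' 30 mV on spike steps).
#'
#' @param network an `lgn_network` from [build_lgn()] or
#'   [build_multi_node()].
#' @param stimulus a [spike_events()] set on the retinal channels (or `NULL`
#'   for no stimulus).
#' @param duration simulated time, ms.
#' @param dt time-step, ms (all delays must be >= `dt`).
#' @param seed integer seed governing the connectivity realization.
#' @param record `"mean"` stores per-population mean membrane series only
#'   (memory-light); `"full"` additionally stores the neurons x steps
#'   matrices.
#' @param i_dc_override optional named vector of bias currents per
#'   population role, nA.
#' @param edges optional pre-realized edge table (from [realize_network()]);
#'   when supplied, `seed` is not used for wiring.
#' @return Object of class `lgn_trial`: `v_mean` (populations x steps),
#'   `v_full` (list or `NULL`), `spikes` (data frame `neuron`, `time_ms`),
#'   `pops`, `dt`, `duration`, `seed`, `n_delivered`.
#' @examples
#' net <- build_lgn(lgn_config())
#' tr <- run_trial(net, periodic_train(20, 500), duration = 500, seed = 1)
#' dim(tr$v_mean)
#' @export
run_trial <- function(network, stimulus, duration = 6000, dt = 0.1, seed = 1,
                      record = c("mean", "full"), i_dc_override = NULL,
                      edges = NULL) {
  stopifnot(inherits(network, "lgn_network"))
  record <- match.arg(record)
  n_steps <- as.integer(round(duration / dt))
  if (any(network$projections$d_conn < dt))
    stop("run_trial: projection delay shorter than dt")
  if (is.null(edges)) edges <- realize_network(network, seed, dt)

  par <- matrix(0, network$n_neurons, 7)
  group <- integer(network$n_neurons)
  for (i in seq_len(nrow(network$pops))) {
    p <- network$pops[i, ]
    prm <- network$params[[p$name]]
    idc <- prm$i_dc
    if (!is.null(i_dc_override) && p$role %in% names(i_dc_override))
      idc <- i_dc_override[[p$role]]
    rows <- p$offset + seq_len(p$size)
    par[rows, ] <- matrix(rep(c(prm$a, prm$b, prm$c, prm$d, prm$v_init,
                                prm$u_init, idc), each = p$size), p$size)
    group[rows] <- i - 1L
  }

  if (is.null(stimulus)) {
    s_chan <- integer(0); s_step <- integer(0)
  } else {
    stopifnot(inherits(stimulus, "spike_events"))
    if (attr(stimulus, "n_channels") != network$n_sources)
      stop(sprintf("run_trial: stimulus has %d channels, network expects %d",
                   attr(stimulus, "n_channels"), network$n_sources))
    s_step <- as.integer(round(stimulus$time_ms / dt))
    keep <- s_step < n_steps
    s_chan <- stimulus$channel[keep] - 1L
    s_step <- s_step[keep]
    ord <- order(s_step, method = "radix")
    s_chan <- s_chan[ord]; s_step <- s_step[ord]
  }

  res <- sim_core(par, group, nrow(network$pops),
                  as.integer(edges$pre - 1L), as.integer(edges$post - 1L),
                  as.numeric(edges$weight), as.integer(edges$delay_steps),
                  as.integer(edges$sign == "inhibitory"),
                  as.integer(edges$from_source),
                  network$n_sources,
                  s_chan, s_step,
                  network$kinetics$tau_e, network$kinetics$tau_i,
                  dt, n_steps, record == "full")
  rownames(res$v_mean) <- network$pops$name

  v_full <- NULL
  if (record == "full") {
    v_full <- lapply(seq_len(nrow(network$pops)), function(i) {
      p <- network$pops[i, ]
      res$v_full[p$offset + seq_len(p$size), , drop = FALSE]
    })
    names(v_full) <- network$pops$name
  }
  structure(list(v_mean = res$v_mean, v_full = v_full,
                 spikes = data.frame(neuron = res$spike_neuron,
                                     time_ms = res$spike_step * dt),
                 pops = network$pops, dt = dt, duration = duration,
                 seed = seed, n_delivered = res$n_delivered),
            class = "lgn_trial")
}

#' Multi-trial simulation with averaging
#'
#' Simulates `n_trials` trials; trial `k` uses seed `base_seed + k - 1`,
#' which by default governs both the connectivity realization and any
#' stochastic stimulus (mirroring repeated stimulation trials in SSVEP
#' recordings).  Per trial each population's neuron-mean membrane series is
#' taken; the trial means are then averaged.
#'
#' @param network an `lgn_network`.
#' @param stimulus_spec either a [spike_events()] set (used verbatim in
#'   every trial) or a list `list(type = "periodic", freq = )` /
#'   `list(type = "poisson", rate = )` built per trial on the retinal
#'   channels.
#' @param n_trials number of trials (>= 1).
#' @param base_seed integer seed of trial 1.
#' @param duration,dt simulation extent and step, ms.
#' @param redraw_wiring if `FALSE`, the wiring of trial 1 is reused in all
#'   trials (only stimulus noise varies).
#' @return Object of class `lgn_avg`: `v_mean` (populations x steps, the
#'   across-trial average of neuron-mean series), `trial_means` (list of the
#'   per-trial matrices), `pops`, `n_trials`, `dt`, `duration`, `base_seed`.
#' @export
run_trials <- function(network, stimulus_spec, n_trials = 10, base_seed = 1,
                       duration = 6000, dt = 0.1, redraw_wiring = TRUE) {
  stopifnot(inherits(network, "lgn_network"), n_trials >= 1)
  make_stim <- function(trial_seed) {
    if (inherits(stimulus_spec, "spike_events")) return(stimulus_spec)
    if (is.null(stimulus_spec)) return(NULL)
    switch(stimulus_spec$type,
      periodic = periodic_train(stimulus_spec$freq, duration,
                                network$n_sources,
                                jitter_sd = stimulus_spec$jitter_sd %||% 0,
                                seed = trial_seed + 1000003L),
      poisson = poisson_trains(stimulus_spec$rate, duration,
                               network$n_sources,
                               seed = trial_seed + 1000003L),
      stop("run_trials: unknown stimulus type '", stimulus_spec$type, "'"))
  }
  edges1 <- if (!redraw_wiring) realize_network(network, base_seed, dt)
  trial_means <- vector("list", n_trials)
  for (k in seq_len(n_trials)) {
    trial_seed <- base_seed + k - 1L
    tr <- run_trial(network, make_stim(trial_seed), duration, dt,
                    seed = trial_seed,
                    edges = if (!redraw_wiring) edges1)
    trial_means[[k]] <- tr$v_mean
  }
  avg <- Reduce(`+`, trial_means) / n_trials
  structure(list(v_mean = avg, trial_means = trial_means,
                 pops = network$pops, n_trials = n_trials, dt = dt,
                 duration = duration, base_seed = base_seed),
            class = "lgn_avg")
}

#' Model output series
#'
#' The designated "model output": the trial-averaged neuron-mean TCR
#' membrane potential series, an LFP-like signal.  For multi-node networks
#' the per-node TCR series are averaged elementwise.
#'
#' @param avg an `lgn_avg` from [run_trials()] (an `lgn_trial` is also
#'   accepted).
#' @return Numeric vector of length `duration/dt` (mV) with attributes `dt`
#'   and `fs` (sampling rate, Hz).
#' @export
model_output <- function(avg) {
  stopifnot(inherits(avg, c("lgn_avg", "lgn_trial")))
  tcr <- which(avg$pops$role == "TCR")
  if (!length(tcr)) stop("model_output: network has no TCR population")
  out <- colMeans(avg$v_mean[tcr, , drop = FALSE])
  attr(out, "dt") <- avg$dt
  attr(out, "fs") <- 1000 / avg$dt
  out
}

#' Write the output series as CSV
#'
#' Flat two-column CSV (`time_ms`, `value`).
#'
#' @param series numeric series with a `dt` attribute (e.g. from
#'   [model_output()]), or any numeric vector with `dt` supplied.
#' @param path file path.
#' @param dt sample spacing, ms.
#' @return `path`, invisibly.
#' @export
write_series_csv <- function(series, path, dt = attr(series, "dt")) {
  if (is.null(dt)) stop("write_series_csv: dt unknown")
  df <- data.frame(time_ms = (seq_along(series) - 1) * dt,
                   value = as.numeric(series))
  write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}
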