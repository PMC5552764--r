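#' DVS pixel parameters
#'
#' Constants of the dynamic-vision-sensor pixel model.  The photocurrent is
#' log-converted, `V_log = K log(I_ph)`; a differentiator tracks
#' `V_diff = V_ref + A * (V_log - V_log_at_last_reset)`.  An upward crossing
#' of `V_t_plus` emits an ON event and self-resets `V_diff` to `V_ref`; a
#' downward crossing of `V_t_minus` emits an OFF event and resets likewise.
#'
#' @param K log-conversion constant, V per ln-unit of illumination.
#' @param A differentiator gain.
#' @param V_ref reset reference voltage, V.
#' @param V_t_plus,V_t_minus ON / OFF comparison thresholds, V; must satisfy
#'   `V_t_minus < V_ref < V_t_plus`.
#' @return Object of class `dvs_params`.
#' @export
dvs_params <- function(K = NULL, A = NULL, V_ref = NULL, V_t_plus = NULL,
                       V_t_minus = NULL) {
  d <- lgn_defaults()$dvs
  p <- list(K = K %||% d$K, A = A %||% d$A, V_ref = V_ref %||% d$V_ref,
            V_t_plus = V_t_plus %||% d$V_t_plus,
            V_t_minus = V_t_minus %||% d$V_t_minus)
  if (!(p$V_t_minus < p$V_ref && p$V_ref < p$V_t_plus))
    stop("dvs_params: thresholds must satisfy V_t_minus < V_ref < V_t_plus")
  structure(p, class = "dvs_params")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Flashing-LED illumination signal
#'
#' Square-wave illumination emulating an LED driven by a periodic signal,
#' sampled at `fs` kHz, with the OFF->ON transition times recorded.  A dark
#' floor keeps the signal strictly positive so the logarithmic pixel front
#' end is defined.
#'
#' @param freq flashing frequency, Hz.
#' @param duration ms.
#' @param level_on,level_off illumination levels (arbitrary positive units;
#'   `level_on > level_off > 0`); their ratio is the edge contrast.
#' @param duty ON fraction of each cycle.
#' @param fs sampling rate, kHz (default 10, matching the simulation step).
#' @return Object of class `illumination` with `time_ms`, `values`,
#'   `transitions` (OFF->ON edge times, ms), `fs`.
#' @examples
#' led <- led_square_wave(10, 1000)
#' length(led$transitions)   # 10 OFF->ON edges
#' @export
led_square_wave <- function(freq, duration, level_on = 2, level_off = 1,
                            duty = 0.5, fs = 10) {
  if (!(level_on > level_off) || level_off <= 0)
    stop("led_square_wave: need level_on > level_off > 0")
  if (duty <= 0 || duty >= 1) stop("led_square_wave: duty must be in (0, 1)")
  t <- (seq_len(round(duration * fs)) - 1) / fs
  period <- 1000 / freq
  phase <- (t %% period) / period
  vals <- ifelse(phase < duty, level_on, level_off)
  n_tr <- ceiling(duration / period - 1e-12)    # cycle starts < duration
  transitions <- (seq_len(n_tr) - 1) * period
  structure(list(time_ms = t, values = vals, transitions = transitions,
                 fs = fs), class = "illumination")
}

#' Emulate a DVS pixel array
#'
#' Runs the pixel model over the sampled illumination for every pixel of the
#' grid (full-field stimulation: all pixels see the same signal).  Between
#' consecutive samples the accumulated differentiator excursion may cross a
#' threshold several times (e.g. on a square-wave edge); each crossing emits
#' one event at that sample, so an OFF->ON edge of contrast `C` yields
#' `floor(A K ln C / (V_t_plus - V_ref))` ON events.  Optional seeded
#' per-pixel threshold jitter emulates pixel mismatch (default none).
#'
#' @param signal an [led_square_wave()] or compatible `illumination` object.
#' @param params a [dvs_params()].
#' @param grid `c(rows, cols)` pixel grid.
#' @param jitter_sd relative threshold mismatch s.d. (fraction; default 0).
#' @param noise_seed seed for the mismatch draw.
#' @return A [spike_events()] set with `polarity` (+1 ON, -1 OFF); channels
#'   are pixel indices, column-major.
#' @examples
#' ev <- dvs_simulate(led_square_wave(10, 500), dvs_params(), grid = c(2, 2))
#' table(ev$polarity)
#' @export
dvs_simulate <- function(signal, params = dvs_params(), grid = c(12, 12),
                         jitter_sd = 0, noise_seed = NULL) {
  if (any(signal$values <= 0))
    stop("dvs_simulate: illumination must be strictly positive")
  if (any(grid < 1)) stop("dvs_simulate: grid must be at least 1x1")
  n_pix <- prod(grid)
  th_on <- rep(params$V_t_plus - params$V_ref, n_pix)
  th_off <- rep(params$V_ref - params$V_t_minus, n_pix)
  if (jitter_sd > 0) {
    if (is.null(noise_seed)) stop("dvs_simulate: jitter requires noise_seed")
    with_local_seed(noise_seed, {
      th_on <- th_on * pmax(0.1, 1 + rnorm(n_pix, sd = jitter_sd))
      th_off <- th_off * pmax(0.1, 1 + rnorm(n_pix, sd = jitter_sd))
    })
  }
  v_log <- params$K * log(signal$values)
  dv <- params$A * diff(v_log)          # differentiator increment per sample
  vd <- numeric(n_pix)                  # V_diff - V_ref per pixel
  ch <- integer(0); tm <- numeric(0); pol <- integer(0)
  for (s in seq_along(dv)) {
    if (dv[s] == 0) next    # residuals never straddle a threshold
    vd <- vd + dv[s]
    n_on <- pmax(0L, as.integer(floor(vd / th_on)))
    n_off <- pmax(0L, as.integer(floor(-vd / th_off)))
    if (any(n_on > 0L)) {
      idx <- which(n_on > 0L)
      ch <- c(ch, rep(idx, n_on[idx]))
      tm <- c(tm, rep(signal$time_ms[s + 1], sum(n_on)))
      pol <- c(pol, rep(1L, sum(n_on)))
      vd[idx] <- vd[idx] - n_on[idx] * th_on[idx]
    }
    if (any(n_off > 0L)) {
      idx <- which(n_off > 0L)
      ch <- c(ch, rep(idx, n_off[idx]))
      tm <- c(tm, rep(signal$time_ms[s + 1], sum(n_off)))
      pol <- c(pol, rep(-1L, sum(n_off)))
      vd[idx] <- vd[idx] + n_off[idx] * th_off[idx]
    }
  }
  dur <- signal$time_ms[length(signal$time_ms)] + 1 / signal$fs
  spike_events(ch, tm, n_pix, dur, polarity = pol)
}

#' First-positive-spike filter
#'
#' Mimics the retina post-processing: OFF events are discarded (ON-center
#' assumption) and, for each pixel and each LED OFF->ON transition, only the
#' earliest ON event at or after that transition (and before the next) is
#' retained.
#'
#' @param events a [spike_events()] set with polarity.
#' @param transitions increasing OFF->ON transition times, ms.
#' @return A [spike_events()] set of at most one event per pixel per
#'   transition (polarity column retained, all +1).
#' @export
first_spike_filter <- function(events, transitions) {
  stopifnot(inherits(events, "spike_events"))
  if (is.unsorted(transitions))
    stop("first_spike_filter: transitions must be sorted increasing")
  if (is.null(events$polarity))
    stop("first_spike_filter: events must carry polarity")
  on <- events[events$polarity > 0, , drop = FALSE]
  if (!nrow(on))
    return(spike_events(integer(0), numeric(0), attr(events, "n_channels"),
                        attr(events, "duration"), polarity = integer(0)))
  win <- findInterval(on$time_ms, transitions)
  keep <- win >= 1
  on <- on[keep, , drop = FALSE]; win <- win[keep]
  # earliest event per (pixel, window); events are time-sorted already
  first <- !duplicated(paste(on$channel, win))
  out <- on[first, , drop = FALSE]
  spike_events(out$channel, out$time_ms, attr(events, "n_channels"),
               attr(events, "duration"), polarity = out$polarity)
}

#' Emulated-retina stimulus for the network
#'
#' Convenience wrapper reproducing the recording protocol: a flashing LED at
#' `freq` Hz drives the DVS pixel array, OFF events are dropped and the
#' first-spike filter applied, yielding a 144-channel stimulus stream.
#'
#' @param freq LED flashing frequency, Hz.
#' @param duration ms.
#' @param grid pixel grid (`c(12, 12)` crop by default).
#' @param contrast ON/OFF illumination ratio.
#' @param params a [dvs_params()].
#' @param jitter_sd,noise_seed per-pixel threshold mismatch (see
#'   [dvs_simulate()]).
#' @return A [spike_events()] set (ON events only, first per transition).
#' @export
retina_stimulus <- function(freq, duration, grid = c(12, 12), contrast = 2,
                            params = dvs_params(), jitter_sd = 0,
                            noise_seed = NULL) {
  led <- led_square_wave(freq, duration, level_on = contrast, level_off = 1)
  ev <- dvs_simulate(led, params, grid, jitter_sd, noise_seed)
  first_spike_filter(ev, led$transitions)
}
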