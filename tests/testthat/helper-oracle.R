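# Independent fine-step forward-Euler oracle for the Izhikevich equations,
# deliberately sharing no code with the package implementation.
euler_oracle <- function(params, I, dt, duration) {
  n <- as.integer(round(duration / dt))
  a <- params$a; b <- params$b; cr <- params$c; d <- params$d
  v <- params$v_init; u <- params$u_init
  spikes <- numeric(0)
  for (i in seq_len(n)) {
    vn <- v + dt * (0.04 * v * v + 5 * v + 140 - u + I)
    un <- u + dt * a * (b * v - u)
    if (vn > 30) {
      v <- cr; u <- un + d
      spikes <- c(spikes, i * dt)
    } else {
      v <- vn; u <- un
    }
  }
  list(spikes = spikes, v = v, u = u)
}

# closed-form accumulator after a sequence of arrivals (t_i, w_i), evaluated
# at time t: sum of w_i * exp(-(t - t_i)/tau)
exp_superposition <- function(times, weights, tau, at) {
  sum(weights[times <= at] * exp(-(at - times[times <= at]) / tau))
}

# analysis chain with the packaged defaults, series sampled at 10 kHz
default_chain <- function(series) {
  welch_psd(preprocess(series), fs = 1000, seg_len = 1000, overlap = 0.5,
            pad_factor = 4)
}

# synthetic power spectrum with lines at given frequencies over a flat floor
synthetic_psd <- function(line_freqs, line_powers, floor_power = 1e-6,
                          fmax = 500, df = 0.25) {
  freq <- seq(0, fmax, by = df)
  power <- rep(floor_power, length(freq))
  for (i in seq_along(line_freqs))
    power[which.min(abs(freq - line_freqs[i]))] <- line_powers[i]
  structure(data.frame(freq = freq, power = power),
            class = c("power_spectrum", "data.frame"),
            fs = 2 * fmax, resolution = df)
}
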