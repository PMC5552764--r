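#' Spike event set
#'
#' Timestamped events on indexed channels, used for stimuli, emulated-retina
#' output and recorded spikes.  Events are kept sorted by time (stable sort).
#'
#' @param channel integer channel indices (1-based, <= `n_channels`).
#' @param time_ms event times, ms, within `[0, duration)`.
#' @param n_channels number of channels.
#' @param duration stream duration, ms.
#' @param polarity optional integer vector (+1 ON / -1 OFF) for event-camera
#'   streams.
#' @return Object of class `spike_events` (a data frame with attributes
#'   `n_channels` and `duration`).
#' @export
spike_events <- function(channel, time_ms, n_channels, duration,
                         polarity = NULL) {
  channel <- as.integer(channel)
  if (length(channel) != length(time_ms))
    stop("spike_events: channel and time_ms lengths differ")
  if (length(channel) && (min(channel) < 1L || max(channel) > n_channels))
    stop("spike_events: channel index outside 1..n_channels")
  if (length(time_ms) && (min(time_ms) < 0 || max(time_ms) >= duration))
    stop("spike_events: times must lie within [0, duration)")
  df <- data.frame(channel = channel, time_ms = as.numeric(time_ms))
  if (!is.null(polarity)) df$polarity <- as.integer(polarity)
  ord <- order(df$time_ms, method = "radix")   # stable
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  structure(df, n_channels = as.integer(n_channels),
            duration = as.numeric(duration),
            class = c("spike_events", "data.frame"))
}

#' @export
print.spike_events <- function(x, ...) {
  cat(sprintf("spike_events: %d events on %d channels over %g ms\n",
              nrow(x), attr(x, "n_channels"), attr(x, "duration")))
  if (nrow(x)) print(utils::head(as.data.frame(x), 5))
  invisible(x)
}

#' Periodic stimulus spike trains
#'
#' Every channel emits simultaneous spikes at times `k * 1000/freq` for
#' `k = 0, 1, ...` within the duration (the spike at t = 0 is included).
#' An optional seeded per-channel Gaussian jitter is available; by default
#' the trains are exactly coincident across channels.
#'
#' @param freq stimulus frequency, Hz (> 0).
#' @param duration ms.
#' @param n_channels number of channels.
#' @param jitter_sd per-event jitter standard deviation, ms (default 0).
#' @param seed seed for the jitter draw (required when `jitter_sd > 0`).
#' @return A [spike_events()] set.
#' @examples
#' periodic_train(10, 1000, 1)   # spikes at 0, 100, ..., 900 ms
#' @export
periodic_train <- function(freq, duration, n_channels = 144, jitter_sd = 0,
                           seed = NULL) {
  if (freq <= 0) stop("periodic_train: freq must be > 0")
  if (duration <= 0) stop("periodic_train: duration must be > 0")
  period <- 1000 / freq
  n_spk <- ceiling(duration / period - 1e-12)   # k * period < duration
  times <- (seq_len(n_spk) - 1) * period
  if (freq * duration / 1000 < 1)
    warning("periodic_train: duration shorter than one stimulus period; ",
            "the train carries only the t = 0 spike")
  ch <- rep(seq_len(n_channels), each = length(times))
  tm <- rep(times, times = n_channels)
  if (jitter_sd > 0) {
    if (is.null(seed)) stop("periodic_train: jitter requires a seed")
    tm <- with_local_seed(seed, tm + rnorm(length(tm), sd = jitter_sd))
    tm <- pmin(pmax(tm, 0), duration - 1e-9)
  }
  spike_events(ch, tm, n_channels, duration)
}

#' Homogeneous Poisson stimulus spike trains
#'
#' Each channel is an independent homogeneous Poisson process at the given
#' rate, deterministic given the seed.
#'
#' @param rate events per second per channel, Hz (>= 0).
#' @param duration ms.
#' @param n_channels number of channels.
#' @param seed integer seed.
#' @return A [spike_events()] set.
#' @export
poisson_trains <- function(rate, duration, n_channels = 144, seed) {
  if (rate < 0) stop("poisson_trains: rate must be >= 0")
  if (rate == 0)
    return(spike_events(integer(0), numeric(0), n_channels, duration))
  with_local_seed(seed, {
    ch <- integer(0); tm <- numeric(0)
    mean_isi <- 1000 / rate
    for (c in seq_len(n_channels)) {
      # draw interspike intervals past the duration
      n_guess <- max(10, ceiling(1.5 * duration / mean_isi + 10))
      t <- cumsum(rexp(n_guess, rate = 1 / mean_isi))
      while (length(t) && t[length(t)] < duration)
        t <- c(t, t[length(t)] + cumsum(rexp(n_guess, rate = 1 / mean_isi)))
      t <- t[t < duration]
      ch <- c(ch, rep.int(c, length(t)))
      tm <- c(tm, t)
    }
    spike_events(ch, tm, n_channels, duration)
  })
}

#' Write / read spike events as tab-separated text
#'
#' Two-column (or three with polarity) tab-separated format: `channel`,
#' `time_ms`[, `polarity`].  Header line records `n_channels` and `duration`.
#'
#' @param events a [spike_events()] set.
#' @param path file path.
#' @return `path` invisibly (writer); a [spike_events()] set (reader).
#' @export
write_events <- function(events, path) {
  stopifnot(inherits(events, "spike_events"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# n_channels=%d duration=%g",
                     attr(events, "n_channels"), attr(events, "duration")),
             con)
  write.table(as.data.frame(events), con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  hdr <- readLines(path, n = 1)
  m <- regmatches(hdr, regexec("n_channels=(\\d+) duration=([0-9.eE+-]+)", hdr))[[1]]
  if (length(m) != 3) stop("read_events: malformed header in ", path)
  df <- read.delim(path, skip = 1)
  spike_events(df$channel, df$time_ms, as.integer(m[2]), as.numeric(m[3]),
               polarity = df$polarity)
}

#' Write / read an AER-style binary event record
#'
#' Address-event representation record for event-camera streams: per event,
#' little-endian 16-bit `x`, `y` (0-based pixel coordinates on the grid),
#' 8-bit polarity (1 ON, 0 OFF) and 32-bit timestamp in microseconds.
#'
#' @param events a [spike_events()] set with a `polarity` column; channels
#'   are mapped to pixel coordinates column-major on `grid`.
#' @param path file path.
#' @param grid `c(rows, cols)` pixel grid.
#' @return `path` invisibly (writer); a [spike_events()] set (reader).
#' @export
write_aer <- function(events, path, grid = c(12, 12)) {
  stopifnot(inherits(events, "spike_events"))
  pol <- if (is.null(events$polarity)) rep(1L, nrow(events)) else events$polarity
  x <- (events$channel - 1L) %/% grid[1]
  y <- (events$channel - 1L) %% grid[1]
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.integer(c(grid, nrow(events))), con, size = 4,
           endian = "little")
  for (i in seq_len(nrow(events))) {
    writeBin(as.integer(c(x[i], y[i])), con, size = 2, endian = "little")
    writeBin(as.integer(pol[i] > 0), con, size = 1)
    writeBin(as.integer(round(events$time_ms[i] * 1000)), con, size = 4,
             endian = "little")
  }
  invisible(path)
}

#' @rdname write_aer
#' @export
read_aer <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, integer(), n = 3, size = 4, endian = "little")
  grid <- hdr[1:2]; n <- hdr[3]
  x <- integer(n); y <- integer(n); pol <- integer(n); ts <- integer(n)
  for (i in seq_len(n)) {
    xy <- readBin(con, integer(), n = 2, size = 2, endian = "little")
    x[i] <- xy[1]; y[i] <- xy[2]
    pol[i] <- readBin(con, integer(), n = 1, size = 1)
    ts[i] <- readBin(con, integer(), n = 1, size = 4, endian = "little")
  }
  tm <- ts / 1000
  spike_events(x * grid[1] + y + 1L, tm, prod(grid),
               duration = if (n) max(tm) + 1e-6 else 1,
               polarity = ifelse(pol > 0, 1L, -1L))
}
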