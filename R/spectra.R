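#' Design a Butterworth bandpass as second-order sections
#'
#' Digital Butterworth bandpass of prototype order `n` (2n poles) designed
#' from the analog lowpass prototype via the lowpass-to-bandpass transform
#' and the bilinear transform, returned as cascaded biquads.  The cascade
#' realization keeps the filter numerically stable at high order with a band
#' edge close to DC, where a single transfer-function polynomial pair is
#' unusable.  The overall gain is normalized to unit magnitude at the
#' geometric center frequency.
#'
#' @param n prototype order (the bandpass has `2n` poles, `n` sections).
#' @param band `c(low, high)` corner frequencies, Hz.
#' @param fs sampling rate, Hz.
#' @return List of `n` sections, each `list(b = , a = )` of length-3
#'   coefficient vectors, class `sos_filter`.
#' @export
butter_bandpass_sos <- function(n, band, fs) {
  stopifnot(length(band) == 2, band[1] > 0, band[2] > band[1],
            band[2] < fs / 2)
  # prewarped analog corner frequencies
  W <- 2 * fs * tan(pi * band / fs)
  W0 <- sqrt(W[1] * W[2])
  BW <- W[2] - W[1]
  # Butterworth analog lowpass prototype poles (unit cutoff, left half-plane)
  k <- seq_len(n)
  p_proto <- exp(1i * pi * (2 * k + n - 1) / (2 * n))
  # lowpass -> bandpass: each prototype pole p maps to the two roots of
  # s^2 - p*BW*s + W0^2 = 0
  pb <- p_proto * BW
  disc <- sqrt(pb^2 - 4 * W0^2)
  poles <- c((pb + disc) / 2, (pb - disc) / 2)
  # bilinear transform of poles; zeros map to z = +1 (n) and z = -1 (n)
  fs2 <- 2 * fs
  zp <- (fs2 + poles) / (fs2 - poles)
  # pair poles into conjugate biquads, innermost-to-unit-circle last
  zp <- zp[order(-abs(zp))]
  used <- rep(FALSE, length(zp))
  sos <- list()
  for (i in seq_along(zp)) {
    if (used[i]) next
    used[i] <- TRUE
    j <- which(!used & abs(zp - Conj(zp[i])) <
                 1e-8 * (1 + abs(zp[i])))[1]
    if (is.na(j)) stop("butter_bandpass_sos: unpaired complex pole")
    used[j] <- TRUE
    a <- c(1, -Re(zp[i] + zp[j]), Re(zp[i] * zp[j]))
    sos[[length(sos) + 1]] <- list(b = c(1, 0, -1), a = a)
  }
  if (any(vapply(sos, function(s) max(abs(polyroot(rev(s$a)))), 1) >= 1))
    stop("butter_bandpass_sos: unstable realization")
  # normalize every section to unit gain at the geometric band center so
  # intermediate signals in the cascade stay O(1)
  f0 <- sqrt(band[1] * band[2])
  for (i in seq_along(sos)) {
    gi <- abs(sos_response(sos[i], f0, fs))
    sos[[i]]$b <- sos[[i]]$b / gi
  }
  structure(sos, class = "sos_filter", fs = fs, band = band, order = n)
}

# complex frequency response of an SOS cascade at frequencies f (Hz)
sos_response <- function(sos, f, fs) {
  z <- exp(-1i * 2 * pi * f / fs)
  H <- rep(1 + 0i, length(z))
  for (s in sos)
    H <- H * (s$b[1] + s$b[2] * z + s$b[3] * z^2) /
             (s$a[1] + s$a[2] * z + s$a[3] * z^2)
  H
}

# Zero-phase (forward-backward) application of an SOS cascade.  The signal
# is extended by odd reflection long enough for the slowest section (pole
# radius ~0.999 at the 1 Hz edge, settle ~1000 samples) to absorb its edge
# transient; sections run with zero initial conditions.
sos_filtfilt <- function(sos, x, pad = NULL) {
  n <- length(x)
  if (is.null(pad)) pad <- min(n - 1L, 4000L)
  left <- 2 * x[1] - x[seq(pad + 1L, 2L)]
  right <- 2 * x[n] - x[seq(n - 1L, n - pad)]
  # constant lead-in/out beyond the reflections lets the slow sections settle
  ext <- as.integer(pad)
  y <- c(rep(left[1], ext), left, x, right, rep(right[pad], ext))
  pad <- pad + ext
  for (s in sos) y <- as.numeric(signal::filter(s$b, s$a, y))
  y <- rev(y)
  for (s in sos) y <- as.numeric(signal::filter(s$b, s$a, y))
  y <- rev(y)
  y[(pad + 1L):(pad + n)]
}

#' Preprocess an output series for spectral analysis
#'
#' The analysis chain applied to the averaged membrane series before the
#' Welch periodogram: extract the epoch, remove the mean, downsample by
#' plain stride to `fs_out`, and bandpass with a zero-phase order-`order`
#' Butterworth cascade.  With the defaults a 6 s series at 10 kHz becomes a
#' 5000-sample, 1 kHz series bandlimited to 1-100 Hz.
#'
#' @param series numeric series sampled at `fs_in` (sample `i` at time
#'   `(i-1)/fs_in` s).
#' @param fs_in input sampling rate, Hz.
#' @param epoch `c(start, stop)` window, ms.
#' @param fs_out output sampling rate, Hz (`fs_in` must be a multiple).
#' @param band bandpass corners, Hz.
#' @param order Butterworth prototype order.
#' @param antialias apply an order-8 lowpass at `0.4 fs_out` before the
#'   stride decimation (default off: the stated chain downsamples first).
#' @return Numeric vector with attributes `fs` and `dt`.
#' @export
preprocess <- function(series, fs_in = 10000, epoch = c(500, 5500),
                       fs_out = 1000, band = c(1, 100), order = 10,
                       antialias = FALSE) {
  n <- length(series)
  i0 <- as.integer(round(epoch[1] / 1000 * fs_in)) + 1L
  i1 <- as.integer(round(epoch[2] / 1000 * fs_in))
  if (i0 < 1 || i1 > n || i1 <= i0)
    stop("preprocess: epoch outside the series extent")
  x <- series[i0:i1]
  x <- x - mean(x)
  stride <- fs_in / fs_out
  if (stride != round(stride))
    stop("preprocess: fs_in must be an integer multiple of fs_out")
  if (antialias) {
    lp <- signal::butter(8, 0.4 * fs_out / (fs_in / 2), type = "low")
    x <- signal::filtfilt(lp, x)
  }
  x <- x[seq(1, length(x), by = stride)]
  sos <- butter_bandpass_sos(order, band, fs_out)
  x <- sos_filtfilt(sos, x)
  attr(x, "fs") <- fs_out
  attr(x, "dt") <- 1000 / fs_out
  x
}

#' Welch power spectral density
#'
#' Averaged Hann-windowed periodogram over overlapping segments, each
#' mean-detrended and zero-padded to `pad_factor` times the segment length
#' (frequency resolution `fs / (pad_factor * seg_len)`), one-sided and
#' density-scaled (units^2/Hz).
#'
#' @param series numeric series.
#' @param fs sampling rate, Hz.
#' @param seg_len segment length, samples (<= series length).
#' @param overlap segment overlap fraction in `[0, 1)`.
#' @param pad_factor zero-padding factor of the transform length.
#' @return Object of class `power_spectrum`: data frame with `freq` (Hz,
#'   strictly increasing) and `power` (>= 0), attributes `fs`, `resolution`.
#' @examples
#' x <- sin(2 * pi * 10 * seq(0, 5, by = 1e-3))
#' psd <- welch_psd(x, fs = 1000)
#' peak_frequency(psd)
#' @export
welch_psd <- function(series, fs = 1000, seg_len = 1000, overlap = 0.5,
                      pad_factor = 4) {
  x <- as.numeric(series)
  if (seg_len > length(x)) stop("welch_psd: seg_len exceeds series length")
  if (overlap < 0 || overlap >= 1) stop("welch_psd: overlap must be in [0, 1)")
  step <- max(1L, as.integer(round(seg_len * (1 - overlap))))
  starts <- seq(1L, length(x) - seg_len + 1L, by = step)
  L <- as.integer(seg_len)
  w <- 0.5 * (1 - cos(2 * pi * seq(0, L - 1) / L))   # periodic Hann
  nfft <- as.integer(pad_factor * seg_len)
  scale <- 1 / (fs * sum(w^2))
  acc <- numeric(nfft %/% 2 + 1)
  for (s in starts) {
    seg <- x[s:(s + L - 1L)]
    seg <- (seg - mean(seg)) * w
    X <- fft(c(seg, numeric(nfft - L)))
    P <- (Mod(X)^2 * scale)[seq_len(nfft %/% 2 + 1)]
    acc <- acc + P
  }
  acc <- acc / length(starts)
  # one-sided: double all bins except DC and (even nfft) Nyquist
  acc[2:(length(acc) - 1)] <- 2 * acc[2:(length(acc) - 1)]
  structure(data.frame(freq = (seq_along(acc) - 1) * fs / nfft,
                       power = acc),
            class = c("power_spectrum", "data.frame"),
            fs = fs, resolution = fs / nfft, seg_len = seg_len,
            pad_factor = pad_factor)
}

#' Peak frequency of a spectrum
#'
#' Frequency of maximal power density within the search band; ties break
#' toward the lower frequency.
#'
#' @param psd a `power_spectrum`.
#' @param band `c(low, high)` search band, Hz (inclusive).
#' @return Frequency, Hz.
#' @export
peak_frequency <- function(psd, band = c(1, 100)) {
  stopifnot(inherits(psd, "power_spectrum"))
  sel <- psd$freq >= band[1] & psd$freq <= band[2]
  if (!any(sel)) stop("peak_frequency: empty search band")
  f <- psd$freq[sel]; p <- psd$power[sel]
  f[which.max(p)]   # which.max returns the first (lowest-frequency) maximum
}

#' Harmonic and subharmonic profile
#'
#' Measures spectral components at the harmonics `k f0` (k = 1..5) and the
#' half-integer subharmonics `(2k-1) f0 / 2` (k = 1..4, i.e. f0/2, 3f0/2,
#' 5f0/2, 7f0/2) of a fundamental.  For each candidate the maximal power
#' within `tol` of the nominal frequency is compared against the local
#' background (median power in a +-5 Hz annulus excluding the +-`tol`
#' core); the component is flagged present when it is a local peak (its
#' maximizing bin exceeds the power just outside the core on both sides —
#' this rejects a merely sloping noise floor) whose power reaches
#' `prominence_factor` times the background and a fraction `rel_floor` of
#' the spectrum's maximal power — the latter mirrors how presence is read
#' off a log-power spectrum, where components orders of magnitude below the
#' dominant one are not visible.  Candidates beyond the spectrum's range are
#' flagged absent.
#'
#' @param psd a `power_spectrum`.
#' @param f0 fundamental frequency, Hz (> 0).
#' @param tol search half-width around each nominal frequency, Hz.
#' @param prominence_factor presence threshold over local background.
#' @param rel_floor minimal power relative to the spectrum's maximum (over
#'   frequencies >= 1 Hz) for a component to count as present.
#' @return Object of class `harmonic_profile`: data frame with `component`
#'   (e.g. `"1f"`, `"2f"`, `"1/2f"`, `"3/2f"`), `freq`, `power`,
#'   `background`, `present`.
#' @export
harmonic_profile <- function(psd, f0, tol = 1.0, prominence_factor = 3.0,
                             rel_floor = 0.02) {
  stopifnot(inherits(psd, "power_spectrum"))
  if (f0 <= 0) stop("harmonic_profile: f0 must be > 0")
  comp <- data.frame(
    component = c(paste0(1:5, "f"), paste0(2 * (1:4) - 1, "/2f")),
    freq = c((1:5) * f0, (2 * (1:4) - 1) * f0 / 2),
    stringsAsFactors = FALSE)
  fmax <- max(psd$freq)
  p_ref <- max(psd$power[psd$freq >= 1])
  comp$power <- NA_real_
  comp$background <- NA_real_
  comp$present <- FALSE
  for (i in seq_len(nrow(comp))) {
    fc <- comp$freq[i]
    if (fc > fmax) next
    core <- which(abs(psd$freq - fc) <= tol)
    annulus <- abs(psd$freq - fc) <= 5 & abs(psd$freq - fc) > tol
    if (!length(core) || !any(annulus)) next
    imax <- core[which.max(psd$power[core])]
    comp$power[i] <- psd$power[imax]
    comp$background[i] <- median(psd$power[annulus])
    lo <- core[1] - 1L; hi <- core[length(core)] + 1L
    is_peak <- lo >= 1L && hi <= nrow(psd) &&
      psd$power[imax] > psd$power[lo] && psd$power[imax] > psd$power[hi]
    comp$present[i] <- is_peak &&
      comp$power[i] >= prominence_factor * comp$background[i] &&
      comp$power[i] >= rel_floor * p_ref
  }
  structure(comp, class = c("harmonic_profile", "data.frame"), f0 = f0,
            tol = tol, prominence_factor = prominence_factor,
            rel_floor = rel_floor)
}

#' Input-frequency sweep of the output spectrum
#'
#' Runs the full pipeline (multi-trial simulation, preprocessing, Welch
#' PSD) once per input frequency and stacks the spectra into a matrix of
#' output power versus stimulus frequency — the model analogue of the
#' SSVEP stimulus-frequency sweep plots.
#'
#' @param network an `lgn_network`.
#' @param freqs input frequencies, Hz (full protocol: 10-50 Hz step 1).
#' @param stimulus_type `"periodic"` or `"poisson"` (for Poisson, each
#'   frequency is the process rate).
#' @param n_trials trials per frequency.
#' @param base_seed seed of the first trial of each frequency.
#' @param duration,dt simulation extent and step, ms.
#' @param out_band output frequency range retained, Hz.
#' @param analysis named list overriding analysis defaults (epoch, fs_out,
#'   band, order, seg_len, overlap, pad_factor).
#' @return Object of class `sweep_image`: `input_freqs`, `output_freqs`,
#'   `power` (output freqs x input freqs matrix), `peaks` (per-column peak
#'   frequency), `profiles` (per-column [harmonic_profile()]).
#' @export
sweep_psd <- function(network, freqs = 10:50,
                      stimulus_type = c("periodic", "poisson"),
                      n_trials = 10, base_seed = 1, duration = 6000,
                      dt = 0.1, out_band = c(1, 100), analysis = list()) {
  stimulus_type <- match.arg(stimulus_type)
  an <- modifyList(lgn_defaults()$analysis, analysis)
  cols <- vector("list", length(freqs))
  peaks <- numeric(length(freqs))
  profiles <- vector("list", length(freqs))
  for (i in seq_along(freqs)) {
    spec <- if (stimulus_type == "periodic")
      list(type = "periodic", freq = freqs[i])
    else list(type = "poisson", rate = freqs[i])
    avg <- run_trials(network, spec, n_trials = n_trials,
                      base_seed = base_seed, duration = duration, dt = dt)
    x <- preprocess(model_output(avg), fs_in = 1000 / dt,
                    epoch = unlist(an$epoch), fs_out = an$fs_out,
                    band = unlist(an$band), order = an$order)
    psd <- welch_psd(x, fs = an$fs_out, seg_len = an$seg_len,
                     overlap = an$overlap, pad_factor = an$pad_factor)
    sel <- psd$freq >= out_band[1] & psd$freq <= out_band[2]
    cols[[i]] <- psd$power[sel]
    if (i == 1) out_freqs <- psd$freq[sel]
    peaks[i] <- peak_frequency(psd, out_band)
    profiles[[i]] <- harmonic_profile(psd, freqs[i])
  }
  structure(list(input_freqs = freqs, output_freqs = out_freqs,
                 power = do.call(cbind, cols), peaks = peaks,
                 profiles = profiles, stimulus_type = stimulus_type,
                 n_trials = n_trials, base_seed = base_seed),
            class = "sweep_image")
}

#' Write a sweep image as a CSV matrix
#'
#' Rows are output frequencies, columns input frequencies.
#'
#' @param sweep a `sweep_image`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_sweep_csv <- function(sweep, path) {
  m <- cbind(output_freq = sweep$output_freqs, sweep$power)
  colnames(m) <- c("output_freq", paste0("in_", sweep$input_freqs, "Hz"))
  write.table(m, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Render a sweep image to a PNG
#'
#' Log-power rendering of output power versus input frequency.
#'
#' @param sweep a `sweep_image`.
#' @param path PNG path.
#' @return `path`, invisibly.
#' @export
plot_sweep <- function(sweep, path) {
  grDevices::png(path, width = 800, height = 600)
  on.exit(grDevices::dev.off())
  graphics::image(x = sweep$input_freqs, y = sweep$output_freqs,
                  z = t(log10(sweep$power + 1e-12)),
                  xlab = "input frequency (Hz)",
                  ylab = "output frequency (Hz)",
                  main = sprintf("model output power (log10), %s input",
                                 sweep$stimulus_type),
                  col = grDevices::hcl.colors(64, "viridis"))
  invisible(path)
}
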