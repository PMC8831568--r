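# Spike detection from raw voltage traces: 100-Hz high-pass filtering,
# robust baseline-noise estimation during quiescent periods, and amplitude
# thresholding at +/- k*sigma (k = 5.3 by default).

#' High-pass filter a raw trace
#'
#' Fourth-order zero-phase Butterworth response: a second-order high-pass
#' filter applied forward and backward ([signal::filtfilt()]), which removes
#' the DC/low-frequency field-potential component without phase distortion
#' of spike waveforms.
#'
#' @param trace A [raw_trace()].
#' @param cutoff_hz Cutoff frequency in Hz (default 100).
#' @return A filtered [raw_trace()] of the same length.
#' @export
highpass_filter <- function(trace, cutoff_hz = 100) {
  .assert(inherits(trace, "raw_trace"), "raw_trace required")
  .assert(all(is.finite(trace$samples)), "trace contains non-finite samples")
  nyq <- trace$sampling_rate / 2
  .assert(cutoff_hz > 0 && cutoff_hz < nyq,
          "cutoff %g Hz must lie in (0, Nyquist = %g Hz)", cutoff_hz, nyq)
  bf <- signal::butter(2, cutoff_hz / nyq, type = "high")
  y <- signal::filtfilt(bf, trace$samples)
  raw_trace(trace$electrode_index, y, trace$sampling_rate)
}

#' Estimate baseline noise sigma of a filtered trace
#'
#' Quiescent-period identification is iterative: the standard deviation is
#' computed over the whole trace, samples exceeding 4 sigma are masked
#' together with +/- 2 ms around them, and sigma is recomputed; two
#' iterations. This makes the estimate robust to a minority of spike
#' deflections without requiring an explicit quiescence annotation.
#'
#' @param trace A high-pass-filtered [raw_trace()].
#' @return Noise standard deviation (volts). An all-zero trace yields 0 with
#'   a warning.
#' @export
estimate_noise_sigma <- function(trace) {
  .assert(inherits(trace, "raw_trace"), "raw_trace required")
  x <- trace$samples
  n <- length(x)
  .assert(n >= 2, "trace too short")
  if (all(x == 0)) {
    warning("all-zero trace: returning sigma = 0")
    return(0)
  }
  half_ms2 <- max(1L, round(0.002 * trace$sampling_rate))
  sigma <- stats::sd(x)
  for (iter in 1:2) {
    bad <- which(abs(x) > 4 * sigma)
    if (length(bad) == 0) break
    starts <- pmax(1L, bad - half_ms2)
    ends <- pmin(n, bad + half_ms2)
    # run-length mask via difference array; tabulate handles repeats
    d <- c(tabulate(starts, n), 0L) - c(0L, tabulate(ends, n))
    masked <- cumsum(d)[seq_len(n)] > 0
    if (all(masked)) break  # nothing quiescent left; keep last estimate
    sigma <- stats::sd(x[!masked])
  }
  sigma
}

#' Detect spikes by amplitude thresholding
#'
#' A spike is counted when the filtered signal strictly exceeds
#' `+/- k * sigma`. An event is a maximal contiguous run of supra-threshold
#' samples; the spike time is the sample of extreme absolute amplitude
#' within the event. Consecutive accepted spikes are separated by at least
#' `dead_time_s`.
#'
#' @param trace High-pass-filtered [raw_trace()].
#' @param sigma Baseline noise standard deviation (see
#'   [estimate_noise_sigma()]).
#' @param k Threshold multiple of sigma (default 5.3).
#' @param dead_time_s Minimum separation between spikes in seconds
#'   (default 0.001).
#' @return A [spike_train()] for the trace's electrode.
#' @export
detect_spikes <- function(trace, sigma, k = 5.3, dead_time_s = 0.001) {
  .assert(inherits(trace, "raw_trace"), "raw_trace required")
  .assert(is.numeric(k) && length(k) == 1 && k > 0, "k must be > 0")
  .assert(is.numeric(sigma) && sigma > 0, "sigma must be > 0")
  x <- trace$samples
  fs <- trace$sampling_rate
  dur <- length(x) / fs
  above <- abs(x) > k * sigma           # strict crossing convention
  if (!any(above))
    return(spike_train(trace$electrode_index, numeric(), duration_s = dur))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  starts <- starts[keep]; ends <- ends[keep]
  peak_idx <- mapply(function(s, e) s - 1L + which.max(abs(x[s:e])),
                     starts, ends)
  times <- (peak_idx - 1) / fs
  # dead-time enforcement: greedy in time order
  acc <- numeric(length(times))
  nacc <- 0L
  last <- -Inf
  for (t in times) {
    if (t - last >= dead_time_s) {
      nacc <- nacc + 1L
      acc[nacc] <- t
      last <- t
    }
  }
  spike_train(trace$electrode_index, acc[seq_len(nacc)], duration_s = dur)
}
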