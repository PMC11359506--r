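# ---------------------------------------------------------------------------
# Stimulation protocols and the IEC-style safe-current limit.
# ---------------------------------------------------------------------------

#' Safe stimulation current limit
#'
#' Root-mean-square current limit as a function of excitation frequency:
#' 100 uA below 1 kHz, 100 uA x (f / 1 kHz) between 1 kHz and 100 kHz, and
#' 10 mA above 100 kHz.  At the branch boundaries the lower adjacent branch
#' applies.
#'
#' @param frequency excitation frequency (Hz), must exceed 0.1 Hz.
#' @return limit in amperes (rms).
#' @export
safe_current_limit <- function(frequency) {
  if (any(frequency <= 0.1)) {
    stop("frequency out of range: the limit is defined for f > 0.1 Hz")
  }
  ifelse(frequency <= 1e3, 100e-6,
         ifelse(frequency <= 1e5, 100e-6 * frequency / 1e3, 10e-3))
}

#' Build a stimulation / measurement protocol
#'
#' Drive pattern `"opposite"`: pattern i injects current through electrodes
#' (i, i + n/2 mod n), i = 1..n (1-based).  For every pattern, differential
#' voltages are measured between consecutive electrodes of the remaining
#' n - 2 non-driving electrodes taken in cyclic order, giving n - 3
#' measurements per pattern (13 for n = 16, 208 in total).
#'
#' @param n_electrodes number of belt electrodes (even).
#' @param pattern_name drive pattern; only `"opposite"` is defined.
#' @param amplitude drive current (A rms); checked against
#'   [safe_current_limit()].
#' @param frequency excitation frequency (Hz).
#' @return a `stim_protocol` object with `patterns` (tibble: pattern, src,
#'   snk, amplitude) and `measurements` (tibble: pattern, meas, e_pos, e_neg).
#' @export
build_protocol <- function(n_electrodes = 16L, pattern_name = "opposite",
                           amplitude = 10e-3, frequency = 1e5) {
  pattern_name <- match.arg(pattern_name, "opposite")
  if (n_electrodes %% 2L != 0L) {
    stop("the opposite drive pattern requires an even electrode count")
  }
  lim <- safe_current_limit(frequency)
  if (amplitude > lim + 1e-12) {
    stop(sprintf("amplitude %.4g A exceeds the safe limit %.4g A at %g Hz",
                 amplitude, lim, frequency))
  }
  n <- as.integer(n_electrodes)
  src <- seq_len(n)
  snk <- (src - 1L + n %/% 2L) %% n + 1L
  patterns <- tibble::tibble(pattern = seq_len(n), src = src, snk = snk,
                             amplitude = amplitude)
  meas <- vector("list", n)
  for (p in seq_len(n)) {
    others <- setdiff(((src[p] - 1L) + seq_len(n) - 1L) %% n + 1L,
                      c(src[p], snk[p]))
    m <- base::length(others) - 1L
    meas[[p]] <- tibble::tibble(pattern = p, meas = seq_len(m),
                                e_pos = others[seq_len(m)],
                                e_neg = others[seq_len(m) + 1L])
  }
  measurements <- dplyr::bind_rows(meas)
  structure(list(patterns = patterns, measurements = measurements,
                 n_electrodes = n, pattern_name = pattern_name,
                 amplitude = amplitude, frequency = frequency,
                 ground_electrode = n + 1L),
            class = "stim_protocol")
}

#' @export
print.stim_protocol <- function(x, ...) {
  cat(sprintf(
    "stim_protocol: %d electrodes, %s drive, %.3g mA at %.3g kHz, %d measurements\n",
    x$n_electrodes, x$pattern_name, 1000 * x$amplitude, x$frequency / 1000,
    nrow(x$measurements)))
  invisible(x)
}
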