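#' Step-forward spike encoding of one channel
#'
#' Delta-style encoding against an adapting baseline: at each frame, if the
#' value exceeds `baseline + threshold` a positive event is emitted and the
#' baseline moves up by `threshold`; if it falls below
#' `baseline - threshold` a negative event is emitted and the baseline
#' moves down by `threshold`; otherwise nothing is emitted. The channels of
#' a cochleogram are encoded independently. The default threshold of 0.005
#' suits unit-normalized cochleograms.
#'
#' @param signal Numeric intensity sequence (one channel).
#' @param threshold Positive detection threshold (default 0.005).
#' @param baseline_init `"first-sample"` (default; avoids a spurious onset
#'   burst) or `"zero"`.
#' @return Integer sequence in `{-1, 0, 1}` with attribute
#'   `final_baseline`.
#' @examples
#' step_forward_encode(c(0, 0.3, 0.4, 0.1), threshold = 0.25,
#'                     baseline_init = "zero") # 0 +1 0 0
#' @export
step_forward_encode <- function(signal, threshold = 0.005,
                                baseline_init = c("first-sample", "zero")) {
  baseline_init <- match.arg(baseline_init)
  stopifnot(threshold > 0)
  if (!all(is.finite(signal))) abort("`signal` must be finite.")
  b <- if (baseline_init == "zero") 0 else signal[1]
  out <- integer(length(signal))
  for (i in seq_along(signal)) {
    x <- signal[i]
    if (x > b + threshold) {
      out[i] <- 1L
      b <- b + threshold
    } else if (x < b - threshold) {
      out[i] <- -1L
      b <- b - threshold
    }
  }
  attr(out, "final_baseline") <- b
  out
}

#' Split a bipolar encoding into unipolar channels
#'
#' Doubles the channel count: input channel c's `+1` events land on output
#' channel c, its `-1` events on channel `c + n_channels`, so the first and
#' last halves of the output carry the positive and negative events.
#'
#' @param bipolar A channels x frames matrix over `{-1, 0, 1}`.
#' @return A `(2 * channels) x frames` binary matrix.
#' @export
bipolar_to_unipolar <- function(bipolar) {
  bipolar <- as.matrix(bipolar)
  if (!all(bipolar %in% c(-1, 0, 1))) {
    abort("`bipolar` may only contain -1, 0, 1.")
  }
  rbind(1 * (bipolar == 1), 1 * (bipolar == -1))
}

#' Align an event stream to a fixed duration and bin it
#'
#' Events after `target_duration_ms` are cut; shorter recordings are
#' implicitly zero-padded. Each (channel, bin) cell is 1 when at least one
#' event falls in `[bin * bin_ms, (bin + 1) * bin_ms)`. Aligning to 1 s
#' and binning at 4 ms yields the standard 250-step samples.
#'
#' @param events A [spike_raster()].
#' @param target_duration_ms Common duration after alignment.
#' @param bin_ms Bin width (> 0), default 4.
#' @return A channels x bins binary matrix.
#' @export
align_and_bin <- function(events, target_duration_ms, bin_ms = 4) {
  stopifnot(inherits(events, "spike_raster"), bin_ms > 0)
  n_bins <- as.integer(ceiling(target_duration_ms / bin_ms))
  out <- matrix(0L, n_sources(events), n_bins)
  keep <- events$t_ms < target_duration_ms
  if (any(keep)) {
    bin <- floor(events$t_ms[keep] / bin_ms) + 1L
    out[cbind(events$source[keep], bin)] <- 1L
  }
  out
}

#' Encode a cochleogram into a unipolar spike raster
#'
#' The full preprocessing chain for float matrices: per-channel
#' step-forward encoding, bipolar-to-unipolar doubling, and conversion to
#' a [spike_raster()] with one spike at the start of each active frame.
#'
#' @param cochleogram A channels x frames matrix with values in `[0, 1]`.
#' @param frame_ms Frame period in ms (default 4).
#' @param threshold,baseline_init Passed to [step_forward_encode()].
#' @return A [spike_raster()] with `2 * nrow(cochleogram)` sources.
#' @export
encode_cochleogram <- function(cochleogram, frame_ms = 4, threshold = 0.005,
                               baseline_init = "first-sample") {
  cochleogram <- as.matrix(cochleogram)
  if (any(cochleogram < 0) || any(cochleogram > 1)) {
    abort("Cochleogram values must lie in [0, 1]; normalize first.")
  }
  bipolar <- t(apply(cochleogram, 1, step_forward_encode,
                     threshold = threshold, baseline_init = baseline_init))
  raster_from_binned(bipolar_to_unipolar(bipolar), bin_ms = frame_ms)
}
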