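#' Construct a raw multichannel EEG recording
#'
#' Bundles a channels-by-time sample matrix with its sampling rate, channel
#' names, an optional pre-trial baseline recording of the same montage, and an
#' optional class label. This is the common input container for the feature
#' pipeline and the synthetic generator.
#'
#' @param samples Numeric matrix, channels in rows, time points in columns.
#' @param sampling_rate Sampling rate in Hz (positive scalar).
#' @param channel_names Character vector of electrode labels, one per row of
#'   `samples`. Defaults to `"ch1" ... "chK"`.
#' @param baseline Optional numeric matrix with the same number of rows as
#'   `samples`, holding a baseline (pre-stimulus) signal to be subtracted at
#'   the differential-entropy level.
#' @param label Optional class label attached to the recording.
#'
#' @return An object of class `eeg_recording`.
#' @examples
#' rec <- eeg_recording(matrix(rnorm(2 * 400), 2), sampling_rate = 200)
#' rec
#' @export
eeg_recording <- function(samples, sampling_rate, channel_names = NULL,
                          baseline = NULL, label = NULL) {
  samples <- as.matrix(samples)
  if (!is.numeric(samples)) stop("`samples` must be a numeric matrix")
  if (!all(is.finite(samples))) stop("`samples` must contain only finite values")
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L || sampling_rate <= 0) {
    stop("`sampling_rate` must be a positive scalar (Hz)")
  }
  if (is.null(channel_names)) {
    channel_names <- paste0("ch", seq_len(nrow(samples)))
  }
  channel_names <- as.character(channel_names)
  if (length(channel_names) != nrow(samples)) {
    stop("length(channel_names) must equal nrow(samples): ",
         length(channel_names), " vs ", nrow(samples))
  }
  if (anyDuplicated(channel_names)) stop("channel names must be unique")
  if (!is.null(baseline)) {
    baseline <- as.matrix(baseline)
    if (nrow(baseline) != nrow(samples)) {
      stop("baseline must have the same number of channels as samples")
    }
    if (!all(is.finite(baseline))) stop("baseline must contain only finite values")
  }
  rownames(samples) <- channel_names
  structure(
    list(samples = samples, sampling_rate = sampling_rate,
         channel_names = channel_names, baseline = baseline, label = label),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  dur <- ncol(x$samples) / x$sampling_rate
  cat(sprintf("<eeg_recording> %d channels x %d samples (%.2f s @ %g Hz)\n",
              nrow(x$samples), ncol(x$samples), dur, x$sampling_rate))
  if (!is.null(x$baseline)) {
    cat(sprintf("  baseline: %.2f s\n", ncol(x$baseline) / x$sampling_rate))
  }
  if (!is.null(x$label)) cat("  label:", format(x$label), "\n")
  invisible(x)
}

#' Recording duration in seconds
#' @param rec An `eeg_recording`.
#' @return Duration in seconds.
#' @export
recording_duration <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  ncol(rec$samples) / rec$sampling_rate
}

#' Resample a recording to a working rate
#'
#' Polyphase resampling of every channel (and the baseline, if present) to a
#' common working rate so that section sample counts are exact integers. The
#' rate ratio must be rational; both rates are taken to the nearest 1/1000 Hz.
#'
#' @param rec An `eeg_recording`.
#' @param rate Target sampling rate in Hz (default 200, which covers the 51 Hz
#'   upper band edge of the gamma band).
#' @return An `eeg_recording` at the new rate.
#' @export
resample_recording <- function(rec, rate = 200) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (rate <= 0) stop("`rate` must be positive")
  if (isTRUE(all.equal(rate, rec$sampling_rate))) return(rec)
  p <- round(rate * 1000)
  q <- round(rec$sampling_rate * 1000)
  g <- .gcd(p, q)
  p <- p / g; q <- q / g
  res <- function(m) {
    out <- t(apply(m, 1L, function(ch) signal::resample(ch, p = p, q = q)))
    storage.mode(out) <- "double"
    out
  }
  eeg_recording(res(rec$samples), rate, rec$channel_names,
                baseline = if (!is.null(rec$baseline)) res(rec$baseline),
                label = rec$label)
}

.gcd <- function(a, b) if (b == 0) a else .gcd(b, a %% b)
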