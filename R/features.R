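#' Default frequency bands
#'
#' The four canonical EEG bands used by the feature pipeline: theta (4-8 Hz),
#' alpha (8-14 Hz), beta (14-31 Hz) and gamma (31-51 Hz).
#'
#' @return A tibble with columns `name`, `low`, `high` (Hz).
#' @export
default_bands <- function() {
  tibble::tibble(
    name = c("theta", "alpha", "beta", "gamma"),
    low  = c(4, 8, 14, 31),
    high = c(8, 14, 31, 51)
  )
}

validate_bands <- function(bands, fs) {
  if (!is.data.frame(bands) || !all(c("name", "low", "high") %in% names(bands))) {
    stop("`bands` must be a data frame with columns name, low, high")
  }
  nyq <- fs / 2
  for (i in seq_len(nrow(bands))) {
    if (!(bands$low[i] > 0 && bands$low[i] < bands$high[i])) {
      stop("band '", bands$name[i], "' must satisfy 0 < low < high")
    }
    if (bands$high[i] >= nyq) {
      stop("band '", bands$name[i], "' upper edge ", bands$high[i],
           " Hz is at or above the Nyquist frequency (", nyq, " Hz)")
    }
  }
  invisible(bands)
}

#' Split a recording into non-overlapping segments
#'
#' Cuts the sample matrix into consecutive windows of `T` seconds. A trailing
#' remainder shorter than one segment is discarded; a recording shorter than
#' one segment is an error.
#'
#' @param rec An `eeg_recording`.
#' @param T Segment length in seconds. `T * sampling_rate` must be a whole
#'   number of samples.
#' @return A list of channels-by-samples matrices, one per segment.
#' @export
segment_signal <- function(rec, T = 3) {
  stopifnot(inherits(rec, "eeg_recording"))
  spt <- T * rec$sampling_rate
  if (abs(spt - round(spt)) > 1e-9) {
    stop("T * sampling_rate must be a whole number of samples (T = ", T,
         ", rate = ", rec$sampling_rate, ")")
  }
  spt <- as.integer(round(spt))
  n <- floor(ncol(rec$samples) / spt)
  if (n < 1L) {
    stop("recording too short: ", ncol(rec$samples) / rec$sampling_rate,
         " s is less than one segment of ", T, " s")
  }
  lapply(seq_len(n), function(i) {
    rec$samples[, ((i - 1L) * spt + 1L):(i * spt), drop = FALSE]
  })
}

#' Split a segment into its 2T half-second sections
#'
#' @param segment Channels-by-samples matrix covering `T` seconds.
#' @param T Segment length in seconds; `2 * T` must be an integer.
#' @param fs Sampling rate in Hz.
#' @return A list of `2T` channels-by-samples matrices whose concatenation
#'   reproduces the segment.
#' @export
split_sections <- function(segment, T, fs) {
  two_T <- 2 * T
  if (abs(two_T - round(two_T)) > 1e-9) {
    stop("2*T must be an integer (T = ", T, ")")
  }
  two_T <- as.integer(round(two_T))
  L <- fs / 2
  if (abs(L - round(L)) > 1e-9) stop("fs/2 must be a whole number of samples")
  L <- as.integer(round(L))
  if (ncol(segment) != two_T * L) {
    stop("segment has ", ncol(segment), " samples; expected ", two_T * L)
  }
  lapply(seq_len(two_T), function(s) {
    segment[, ((s - 1L) * L + 1L):(s * L), drop = FALSE]
  })
}

# Butterworth band-pass coefficients, order 4 (8th-order polynomials after
# the band transform).
.butter_coefs <- function(low, high, fs, order = 4L) {
  bt <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  list(b = bt$b, a = bt$a)
}

# Zero-phase IIR filtering of matrix columns (each column one signal).
# Odd-reflection padding on both ends limits edge transients, then the filter
# runs forward and backward (direct-form II transposed, vectorized across
# columns).
.filtfilt_mat <- function(x, b, a) {
  x <- as.matrix(x)
  n <- nrow(x)
  nf <- max(length(a), length(b))
  pad <- min(3L * (nf - 1L), n - 1L)
  if (pad > 0L) {
    top <- 2 * matrix(x[1L, ], pad, ncol(x), byrow = TRUE) -
      x[(pad + 1L):2L, , drop = FALSE]
    bot <- 2 * matrix(x[n, ], pad, ncol(x), byrow = TRUE) -
      x[(n - 1L):(n - pad), , drop = FALSE]
    xe <- rbind(top, x, bot)
  } else xe <- x
  y <- .lfilter_mat(xe, b, a)
  y <- y[nrow(y):1L, , drop = FALSE]
  y <- .lfilter_mat(y, b, a)
  y <- y[nrow(y):1L, , drop = FALSE]
  if (pad > 0L) y <- y[(pad + 1L):(pad + n), , drop = FALSE]
  y
}

.lfilter_mat <- function(x, b, a) {
  b <- b / a[1L]; a <- a / a[1L]
  nf <- max(length(a), length(b))
  b <- c(b, rep(0, nf - length(b)))
  a <- c(a, rep(0, nf - length(a)))
  n <- nrow(x); m <- ncol(x)
  y <- matrix(0, n, m)
  z <- matrix(0, nf - 1L, m)
  for (t in seq_len(n)) {
    xt <- x[t, ]
    yt <- b[1L] * xt + z[1L, ]
    if (nf > 2L) {
      z[1L:(nf - 2L), ] <- z[2L:(nf - 1L), , drop = FALSE] +
        outer(b[2L:(nf - 1L)], xt) - outer(a[2L:(nf - 1L)], yt)
    }
    z[nf - 1L, ] <- b[nf] * xt - a[nf] * yt
    y[t, ] <- yt
  }
  y
}

#' Decompose a section into frequency bands
#'
#' Applies a zero-phase Butterworth band-pass (order 4, forward-backward) for
#' each band. All channels are filtered in one vectorized pass.
#'
#' @param section Channels-by-samples matrix (or a numeric vector).
#' @param bands Band table as from [default_bands()].
#' @param fs Sampling rate in Hz.
#' @return A named list of filtered matrices, one per band, same shape as the
#'   input.
#' @export
band_decompose <- function(section, bands = default_bands(), fs) {
  vec <- is.null(dim(section))
  m <- if (vec) matrix(section, nrow = 1L) else as.matrix(section)
  validate_bands(bands, fs)
  out <- lapply(seq_len(nrow(bands)), function(i) {
    cf <- .butter_coefs(bands$low[i], bands$high[i], fs)
    f <- t(.filtfilt_mat(t(m), cf$b, cf$a))
    if (vec) drop(f) else f
  })
  names(out) <- bands$name
  out
}

#' Differential entropy of a band-limited section
#'
#' Gaussian-form differential entropy `0.5 * log(2 * pi * e * var(x))` in
#' nats, with the unbiased sample variance floored at 1e-12. For a fixed-length
#' band-passed section this is the log band-power feature used throughout the
#' pipeline.
#'
#' @param values Numeric vector, length at least 2.
#' @return Differential entropy in nats.
#' @examples
#' set.seed(1)
#' differential_entropy(rnorm(1e4))  # ~ 0.5 * log(2 * pi * exp(1)) = 1.4189
#' @export
differential_entropy <- function(values) {
  if (length(values) < 2L) stop("need at least 2 values to estimate variance")
  if (!all(is.finite(values))) stop("values must be finite")
  v <- stats::var(values)
  if (v < 1e-12) {
    warning("variance below floor (constant input?); flooring at 1e-12")
    v <- 1e-12
  }
  0.5 * log(2 * pi * exp(1) * v)
}

# Vectorized DE over matrix columns (no warning path; used internally).
.de_cols <- function(m) {
  n <- nrow(m)
  v <- (colSums(m^2) - colSums(m)^2 / n) / (n - 1)
  v[v < 1e-12] <- 1e-12
  0.5 * log(2 * pi * exp(1) * v)
}

#' Convert a recording into the 4D differential-entropy tensor
#'
#' Implements the full input conversion: the recording is (optionally)
#' resampled to a working rate, cut into `N` non-overlapping segments of `T`
#' seconds, each segment into `2T` half-second sections, each section
#' band-passed into the four bands; the DE of every (channel, band, section)
#' is computed and arranged onto the 9x8 electrode grid. The result is an
#' `N x 9 x 8 x 4 x 2T` array.
#'
#' If the recording carries a baseline and `use_baseline` is `TRUE`, the mean
#' baseline DE per (cell, band) is subtracted from every section (see
#' [subtract_baseline()]).
#'
#' @param rec An `eeg_recording`.
#' @param T Segment length in seconds (default 3; `2T` must be an integer).
#' @param bands Band table as from [default_bands()].
#' @param grid A `grid_map`; electrodes present in the recording but not in
#'   the grid raise an error.
#' @param working_rate Common sampling rate the recording is resampled to
#'   before segmentation (default 200 Hz).
#' @param use_baseline Subtract the baseline DE if the recording has one.
#' @return A `feature_tensor_4d` object with fields `values` (the 5D array),
#'   `T`, `bands`, `label`.
#' @export
build_4d_features <- function(rec, T = 3, bands = default_bands(),
                              grid = default_grid_map("seed62"),
                              working_rate = 200,
                              use_baseline = !is.null(rec$baseline)) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(grid, "grid_map"))
  two_T <- 2 * T
  if (abs(two_T - round(two_T)) > 1e-9) stop("2*T must be an integer (T = ", T, ")")
  two_T <- as.integer(round(two_T))
  rec <- resample_recording(rec, working_rate)
  fs <- rec$sampling_rate
  validate_bands(bands, fs)
  missing <- setdiff(rec$channel_names, grid$entries$electrode)
  if (length(missing)) {
    stop("recording channel(s) missing from grid map: ",
         paste(missing, collapse = ", "))
  }
  spt <- as.integer(round(T * fs))
  N <- floor(ncol(rec$samples) / spt)
  if (N < 1L) {
    stop("recording too short: ", ncol(rec$samples) / fs,
         " s is less than one segment of ", T, " s")
  }
  de <- .section_de(rec$samples[, seq_len(N * spt), drop = FALSE], fs, bands)
  # de: [n_sections_total x n_channels x n_bands]
  vals <- .grid_stack(de, rec$channel_names, grid, N, two_T, nrow(bands))
  out <- structure(
    list(values = vals, T = T, bands = bands, label = rec$label),
    class = "feature_tensor_4d"
  )
  if (use_baseline && !is.null(rec$baseline)) {
    bl <- baseline_de_map(rec, bands = bands, grid = grid, working_rate = fs)
    out <- subtract_baseline(out, bl)
  }
  out
}

# DE per (section, channel, band) for a channels x samples matrix cut into
# half-second sections. Returns array [n_sections x n_channels x n_bands].
.section_de <- function(samples, fs, bands) {
  L <- as.integer(round(fs / 2))
  ns <- ncol(samples) / L
  if (abs(ns - round(ns)) > 1e-9) stop("sample count not a whole number of sections")
  ns <- as.integer(round(ns))
  C <- nrow(samples)
  # columns ordered: section fastest, then channel
  secmat <- matrix(array(t(samples), dim = c(L, ns, C)), nrow = L)
  de <- array(0, dim = c(ns, C, nrow(bands)))
  for (b in seq_len(nrow(bands))) {
    cf <- .butter_coefs(bands$low[b], bands$high[b], fs)
    filt <- .filtfilt_mat(secmat, cf$b, cf$a)
    de[, , b] <- matrix(.de_cols(filt), nrow = ns)
  }
  de
}

# Stack DE values onto the grid: returns [N x rows x cols x bands x 2T].
.grid_stack <- function(de, channel_names, grid, N, two_T, n_bands) {
  vals <- array(0, dim = c(N, grid$n_rows, grid$n_cols, n_bands, two_T))
  idx <- match(channel_names, grid$entries$electrode)
  rows <- grid$entries$row[idx] + 1L
  cols <- grid$entries$col[idx] + 1L
  seg_of <- rep(seq_len(N), each = two_T)
  sec_of <- rep(seq_len(two_T), times = N)
  for (ch in seq_along(channel_names)) {
    for (b in seq_len(n_bands)) {
      vals[cbind(seg_of, rows[ch], cols[ch], b, sec_of)] <- de[, ch, b]
    }
  }
  vals
}

#' Mean baseline DE map of a recording
#'
#' Computes the DE of every half-second baseline section per (channel, band)
#' and averages over sections, returning a rows x cols x bands array aligned
#' with the grid.
#'
#' @inheritParams build_4d_features
#' @return A numeric array `[n_rows x n_cols x n_bands]`.
#' @export
baseline_de_map <- function(rec, bands = default_bands(),
                            grid = default_grid_map("seed62"),
                            working_rate = 200) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (is.null(rec$baseline)) stop("recording has no baseline")
  rec <- resample_recording(rec, working_rate)
  fs <- rec$sampling_rate
  L <- as.integer(round(fs / 2))
  ns <- floor(ncol(rec$baseline) / L)
  if (ns < 1L) stop("baseline shorter than one 0.5 s section")
  de <- .section_de(rec$baseline[, seq_len(ns * L), drop = FALSE], fs, bands)
  mean_de <- apply(de, c(2L, 3L), mean)  # channels x bands
  out <- array(0, dim = c(grid$n_rows, grid$n_cols, nrow(bands)))
  for (b in seq_len(nrow(bands))) {
    out[, , b] <- assemble_grid(stats::setNames(mean_de[, b], rec$channel_names), grid)
  }
  out
}

#' Subtract a baseline DE map from a feature tensor
#'
#' Removes the per-(cell, band) mean baseline DE from every segment and
#' section of the trial tensor, eliminating the pre-stimulus activity offset.
#'
#' @param tensor A `feature_tensor_4d`.
#' @param baseline_map Array `[rows x cols x bands]` as from
#'   [baseline_de_map()].
#' @return The adjusted `feature_tensor_4d`.
#' @export
subtract_baseline <- function(tensor, baseline_map) {
  stopifnot(inherits(tensor, "feature_tensor_4d"))
  d <- dim(tensor$values)
  if (!all(dim(baseline_map) == d[2:4])) {
    stop("baseline map dimensions ", paste(dim(baseline_map), collapse = "x"),
         " do not match tensor grid/bands ", paste(d[2:4], collapse = "x"))
  }
  sweep_arr <- aperm(array(baseline_map, dim = c(d[2:4], d[1], d[5])),
                     c(4L, 1L, 2L, 3L, 5L))
  tensor$values <- tensor$values - sweep_arr
  tensor
}

#' @export
print.feature_tensor_4d <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<feature_tensor_4d> %d segments x %dx%d grid x %d bands x %d sections (T = %g s)\n",
              d[1], d[2], d[3], d[4], d[5], x$T))
  invisible(x)
}
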