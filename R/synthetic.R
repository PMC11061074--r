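#' Define a synthetic EEG generation profile
#'
#' Describes a family of band-limited multichannel signals whose class label
#' modulates oscillation amplitude in chosen (channel group, band) pairs, on
#' top of broadband Gaussian noise. A `drift` knob adds a linear within-window
#' amplitude ramp that emulates non-stationary segments, the condition the
#' temporal-difference loss is designed to counteract.
#'
#' Every channel carries one oscillator per band at the band-center frequency
#' (optionally jittered) with random phase; the class effect multiplies the
#' amplitude of its designated band on its designated channel group by
#' `class_gain`.
#'
#' @param n_classes Number of classes (default 3).
#' @param n_channels Number of channels (default 62; 62/32/14 pick up the
#'   matching built-in montage names).
#' @param fs Sampling rate in Hz (default 200).
#' @param bands Band table as from [default_bands()].
#' @param base_amplitude Oscillation amplitude common to all channels/bands.
#' @param class_gain Multiplicative amplitude gain of the class-specific
#'   (group, band) pair (default 2).
#' @param noise_sigma Standard deviation of the additive white noise.
#' @param drift Within-window amplitude ramp: amplitudes sweep linearly from
#'   `1 - drift/2` to `1 + drift/2` times their nominal value across each
#'   `drift_period` window (default 0 = stationary).
#' @param drift_period Length in seconds of the drift ramp window (default 3,
#'   matching the default segment length).
#' @param freq_jitter Fraction of the band half-width used to jitter each
#'   oscillator frequency away from the band center (default 0).
#' @param class_effects Optional data frame `(class, band, ch_from, ch_to)`
#'   overriding the automatic assignment (class k -> k-th band in
#'   beta/alpha/gamma/theta order on the k-th contiguous channel group).
#' @return A `synthetic_profile` object.
#' @export
synthetic_profile <- function(n_classes = 3, n_channels = 62, fs = 200,
                              bands = default_bands(), base_amplitude = 1,
                              class_gain = 2, noise_sigma = 1,
                              drift = 0, drift_period = 3, freq_jitter = 0,
                              class_effects = NULL) {
  stopifnot(n_classes >= 2, n_channels >= n_classes, fs > 0,
            base_amplitude >= 0, class_gain >= 0, noise_sigma >= 0,
            drift >= 0, drift_period > 0, freq_jitter >= 0)
  validate_bands(bands, fs)
  channel_names <- switch(as.character(n_channels),
    "62" = default_grid_map("seed62")$entries$electrode,
    "32" = default_grid_map("deap32")$entries$electrode,
    "14" = default_grid_map("dreamer14")$entries$electrode,
    paste0("ch", seq_len(n_channels))
  )
  if (is.null(class_effects)) {
    band_order <- intersect(c("beta", "alpha", "gamma", "theta"), bands$name)
    if (length(band_order) < n_classes) band_order <- rep_len(bands$name, n_classes)
    grp <- floor(n_channels / n_classes)
    class_effects <- tibble::tibble(
      class = seq_len(n_classes),
      band = band_order[seq_len(n_classes)],
      ch_from = (seq_len(n_classes) - 1L) * grp + 1L,
      ch_to = seq_len(n_classes) * grp
    )
  }
  if (anyDuplicated(paste(class_effects$band, class_effects$ch_from))) {
    stop("class effect specs must be distinct")
  }
  structure(
    list(n_classes = as.integer(n_classes), n_channels = as.integer(n_channels),
         fs = fs, bands = bands, channel_names = channel_names,
         base_amplitude = base_amplitude, class_gain = class_gain,
         noise_sigma = noise_sigma, drift = drift, drift_period = drift_period,
         freq_jitter = freq_jitter, class_effects = class_effects),
    class = "synthetic_profile"
  )
}

#' @export
print.synthetic_profile <- function(x, ...) {
  cat(sprintf("<synthetic_profile> %d classes, %d channels @ %g Hz, gain %g, noise %g, drift %g\n",
              x$n_classes, x$n_channels, x$fs, x$class_gain, x$noise_sigma, x$drift))
  invisible(x)
}

# Run expr with a private RNG state, restoring the caller's state after.
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate one synthetic recording
#'
#' @param profile A `synthetic_profile`.
#' @param class_id Class label in `1..n_classes`.
#' @param duration Recording length in seconds.
#' @param seed Integer seed; the recording is a pure function of
#'   (profile, class_id, duration, seed).
#' @return An `eeg_recording` with `label = class_id`.
#' @export
generate_recording <- function(profile, class_id, duration, seed = 1L) {
  stopifnot(inherits(profile, "synthetic_profile"))
  if (!(class_id %in% seq_len(profile$n_classes))) {
    stop("invalid class_id ", class_id, "; profile has ", profile$n_classes, " classes")
  }
  fs <- profile$fs
  n <- as.integer(round(duration * fs))
  if (n < 1L) stop("duration too short")
  tt <- (seq_len(n) - 1L) / fs
  # within-window linear amplitude ramp
  mod <- if (profile$drift > 0) {
    1 + profile$drift * ((tt %% profile$drift_period) / profile$drift_period - 0.5)
  } else rep(1, n)
  bands <- profile$bands
  eff <- profile$class_effects[profile$class_effects$class == class_id, , drop = FALSE]
  .with_seed(seed, {
    x <- matrix(stats::rnorm(profile$n_channels * n, sd = profile$noise_sigma),
                profile$n_channels, n)
    for (ch in seq_len(profile$n_channels)) {
      for (b in seq_len(nrow(bands))) {
        amp <- profile$base_amplitude
        hit <- which(eff$band == bands$name[b] & eff$ch_from <= ch & ch <= eff$ch_to)
        if (length(hit)) amp <- amp * profile$class_gain
        ctr <- (bands$low[b] + bands$high[b]) / 2
        half <- (bands$high[b] - bands$low[b]) / 2
        f <- ctr + profile$freq_jitter * half * stats::runif(1, -1, 1)
        phi <- stats::runif(1, 0, 2 * pi)
        x[ch, ] <- x[ch, ] + amp * mod * sin(2 * pi * f * tt + phi)
      }
    }
    eeg_recording(x, fs, profile$channel_names, label = class_id)
  })
}

#' Generate a balanced labeled dataset of synthetic recordings
#'
#' @param profile A `synthetic_profile`.
#' @param n_per_class Recordings per class.
#' @param duration Length of each recording in seconds.
#' @param seed Master seed; each recording uses a distinct derived seed.
#' @return A list with `recordings` (list of `eeg_recording`) and `labels`
#'   (integer vector).
#' @export
generate_dataset <- function(profile, n_per_class, duration, seed = 1L) {
  stopifnot(inherits(profile, "synthetic_profile"), n_per_class >= 1)
  labels <- rep(seq_len(profile$n_classes), each = n_per_class)
  recordings <- lapply(seq_along(labels), function(i) {
    generate_recording(profile, labels[i], duration, seed = seed + 1000L * i)
  })
  list(recordings = recordings, labels = labels)
}
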