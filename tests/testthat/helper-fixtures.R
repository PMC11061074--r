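# Shared fixtures: a tiny network spec for fast exact checks, and small
# synthetic datasets built in code.

tiny_spec <- function(n_classes = 3, ...) {
  network_spec(n_classes, conv_filters = c(3L, 4L, 4L, 3L),
               conv_kernels = c(5L, 4L, 4L, 1L), cnn_output_dim = 10L,
               lstm_units = 6L, ...)
}

# A model with biases pushed off zero so that no ReLU pre-activation sits
# exactly on its kink (keeps finite-difference gradient checks clean).
tiny_model_offkink <- function(seed = 7, n_classes = 3, ...) {
  m <- init_network(tiny_spec(n_classes, ...), seed = seed)
  set.seed(seed + 1)
  for (l in seq_along(m$params$conv)) {
    m$params$conv[[l]]$b <- rnorm(length(m$params$conv[[l]]$b), sd = 0.3)
  }
  m$params$fc$b <- rnorm(length(m$params$fc$b), sd = 0.3)
  m
}

small_profile <- function(...) {
  synthetic_profile(n_channels = 14, ...)
}

small_grid <- function() default_grid_map("dreamer14")

# Small labeled feature set: n_per_class recordings x 12 s -> 4 segments each
# at T = 3 on the 14-channel montage.
small_features <- function(n_per_class = 5, drift = 0, seed = 11, T = 3,
                           duration = 12) {
  ds <- generate_dataset(small_profile(drift = drift), n_per_class, duration,
                         seed = seed)
  dataset_features(ds$recordings, ds$labels, T = T, grid = small_grid())
}

quick_config <- function(...) {
  args <- list(...)
  if (!"learning_rate" %in% names(args)) args$learning_rate <- 0.005
  do.call(train_config, args)
}
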