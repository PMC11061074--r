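#' Load and validate an experiment configuration
#'
#' Reads a YAML configuration file and merges it over the package defaults.
#' An empty or missing file yields the full default configuration (T = 3 s,
#' batch 64, 150 epochs, Adam lr 0.001, 3 branches, linear kernel, fivefold
#' CV, 200 Hz working rate, the four canonical bands, the 62-channel grid).
#' Invalid combinations (non-integer `2T`, band edges at or above Nyquist,
#' unknown fields) are rejected at load time with the offending field named.
#'
#' Recognized top-level sections: `train` (any [train_config()] argument),
#' `mmd` (`kernel`, `bandwidth`, `squared`, `weight`, `plan_refresh`),
#' `network` (any [network_spec()] argument except `n_classes`), `bands`
#' (list of `name`/`low`/`high`), `grid` (montage name or CSV path),
#' `working_rate`.
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @return A list with elements `train` (a `train_config`), `network`
#'   (argument list for [network_spec()]), `bands`, `grid` (a `grid_map`),
#'   `working_rate`.
#' @export
load_config <- function(path = NULL) {
  user <- if (is.null(path)) list() else {
    if (!file.exists(path)) stop("config file not found: ", path)
    out <- yaml::read_yaml(path)
    if (is.null(out)) list() else out
  }
  known <- c("train", "mmd", "network", "bands", "grid", "working_rate")
  unknown <- setdiff(names(user), known)
  if (length(unknown)) {
    stop("unknown config section(s): ", paste(unknown, collapse = ", "))
  }

  train_args <- user$train %||% list()
  bad <- setdiff(names(train_args), names(formals(train_config)))
  if (length(bad)) stop("unknown train config field(s): train.", paste(bad, collapse = ", train."))
  mmd_args <- user$mmd %||% list()
  bad <- setdiff(names(mmd_args), c("kernel", "bandwidth", "squared", "weight", "plan_refresh"))
  if (length(bad)) stop("unknown mmd config field(s): mmd.", paste(bad, collapse = ", mmd."))
  if (!is.null(mmd_args$kernel)) train_args$kernel <- mmd_args$kernel
  if (!is.null(mmd_args$bandwidth)) train_args$bandwidth <- mmd_args$bandwidth
  if (!is.null(mmd_args$squared)) train_args$squared <- mmd_args$squared
  if (!is.null(mmd_args$weight)) train_args$mmd_weight <- mmd_args$weight
  if (!is.null(mmd_args$plan_refresh)) train_args$plan_refresh <- mmd_args$plan_refresh
  train <- do.call(train_config, train_args)

  network <- user$network %||% list()
  bad <- setdiff(names(network), setdiff(names(formals(network_spec)), "n_classes"))
  if (length(bad)) stop("unknown network config field(s): network.", paste(bad, collapse = ", network."))

  working_rate <- user$working_rate %||% 200
  if (!is.numeric(working_rate) || working_rate <= 0) {
    stop("working_rate must be a positive number")
  }

  bands <- if (is.null(user$bands)) default_bands() else {
    df <- do.call(rbind, lapply(user$bands, function(b) {
      if (is.null(b$name) || is.null(b$low) || is.null(b$high)) {
        stop("each bands entry needs name, low, high")
      }
      data.frame(name = b$name, low = b$low, high = b$high)
    }))
    tibble::as_tibble(df)
  }
  validate_bands(bands, working_rate)

  grid_field <- user$grid %||% "seed62"
  grid <- if (grid_field %in% c("seed62", "deap32", "dreamer14")) {
    default_grid_map(grid_field)
  } else {
    read_grid_map(grid_field)
  }

  list(train = train, network = network, bands = bands, grid = grid,
       working_rate = working_rate)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
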