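#' Read an electrode-to-grid mapping
#'
#' The spatial map places electrodes onto a 9-row by 8-column scalp grid.
#' Mappings are plain CSV files with header `electrode,row,col` (0-based rows
#' 0-8, cols 0-7); cells without an electrode are implicit zeros in assembled
#' maps.
#'
#' @param path Path to a CSV file with columns `electrode,row,col`.
#' @param n_rows,n_cols Grid dimensions (defaults 9 and 8).
#' @return A `grid_map` object: a tibble of entries plus dimensions.
#' @export
read_grid_map <- function(path, n_rows = 9L, n_cols = 8L) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("electrode", "row", "col")
  if (!all(need %in% names(df))) {
    stop("grid map file must have columns electrode,row,col: ", path)
  }
  grid_map(df$electrode, df$row, df$col, n_rows = n_rows, n_cols = n_cols)
}

#' Build an electrode grid map from vectors
#'
#' @param electrode Character vector of electrode labels.
#' @param row,col Integer 0-based grid coordinates.
#' @param n_rows,n_cols Grid dimensions.
#' @return A `grid_map` object.
#' @export
grid_map <- function(electrode, row, col, n_rows = 9L, n_cols = 8L) {
  electrode <- as.character(electrode)
  row <- as.integer(row); col <- as.integer(col)
  if (length(electrode) != length(row) || length(row) != length(col)) {
    stop("electrode, row, col must have equal lengths")
  }
  if (anyDuplicated(electrode)) stop("duplicate electrode labels in grid map")
  if (any(row < 0L | row >= n_rows)) stop("grid rows must lie in [0, ", n_rows - 1L, "]")
  if (any(col < 0L | col >= n_cols)) stop("grid cols must lie in [0, ", n_cols - 1L, "]")
  cell <- row * n_cols + col
  if (anyDuplicated(cell)) {
    dup <- electrode[duplicated(cell) | duplicated(cell, fromLast = TRUE)]
    stop("electrodes share a grid cell: ", paste(dup, collapse = ", "))
  }
  structure(
    list(entries = tibble::tibble(electrode = electrode, row = row, col = col),
         n_rows = as.integer(n_rows), n_cols = as.integer(n_cols)),
    class = "grid_map"
  )
}

#' Built-in grid maps for common montages
#'
#' Ships synthetic 9x8 arrangements following the 10-20 topography for a
#' 62-channel (SEED-style), 32-channel (DEAP-style) and 14-channel
#' (DREAMER-style) montage. The exact electrode-to-cell assignment is a
#' package choice; supply your own CSV via [read_grid_map()] to override.
#'
#' @param montage One of `"seed62"`, `"deap32"`, `"dreamer14"`.
#' @return A `grid_map`.
#' @export
default_grid_map <- function(montage = c("seed62", "deap32", "dreamer14")) {
  montage <- match.arg(montage)
  path <- system.file("extdata", paste0("grid_", montage, ".csv"),
                      package = "tdmnet", mustWork = TRUE)
  read_grid_map(path)
}

#' @export
print.grid_map <- function(x, ...) {
  cat(sprintf("<grid_map> %d electrodes on a %dx%d grid\n",
              nrow(x$entries), x$n_rows, x$n_cols))
  invisible(x)
}

#' Arrange per-electrode values onto the 2D scalp grid
#'
#' @param channel_values Named numeric vector, names are electrode labels.
#' @param grid A `grid_map`.
#' @return A numeric `n_rows` x `n_cols` matrix; unmapped cells are 0.
#' @examples
#' g <- grid_map("Cz", 4, 3)
#' assemble_grid(c(Cz = 1.5), g)[5, 4]
#' @export
assemble_grid <- function(channel_values, grid) {
  stopifnot(inherits(grid, "grid_map"))
  out <- matrix(0, grid$n_rows, grid$n_cols)
  if (length(channel_values) == 0L) return(out)
  nm <- names(channel_values)
  if (is.null(nm)) stop("`channel_values` must be named by electrode")
  missing <- setdiff(nm, grid$entries$electrode)
  if (length(missing)) {
    stop("electrode(s) not in grid map: ", paste(missing, collapse = ", "))
  }
  idx <- match(nm, grid$entries$electrode)
  out[cbind(grid$entries$row[idx] + 1L, grid$entries$col[idx] + 1L)] <- channel_values
  out
}
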