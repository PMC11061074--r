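# Recording I/O: a plain-text array container (single TSV file with a JSON
# header line) and a minimal 16-bit EDF reader/writer. EDF stores the trial
# signal only; the container round-trips baseline and label as well.

#' Write a recording to disk
#'
#' @param rec An `eeg_recording`.
#' @param path Output file path.
#' @param format `"container"` (default): a TSV matrix (channels in rows)
#'   preceded by one `#tdmnet` JSON header line; or `"edf"`: 16-bit EDF
#'   (quantized; baseline and label are not representable).
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, format = c("container", "edf")) {
  stopifnot(inherits(rec, "eeg_recording"))
  format <- match.arg(format)
  if (format == "edf") return(.write_edf(rec, path))
  meta <- list(
    type = "tdmnet-recording",
    sampling_rate = rec$sampling_rate,
    channel_names = rec$channel_names,
    n_samples = ncol(rec$samples),
    n_baseline = if (is.null(rec$baseline)) 0L else ncol(rec$baseline),
    label = rec$label
  )
  block <- if (is.null(rec$baseline)) rec$samples else cbind(rec$samples, rec$baseline)
  header <- paste0("#tdmnet ", jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA))
  writeLines(header, path)
  data.table::fwrite(data.table::as.data.table(block), path, sep = "\t",
                     col.names = FALSE, append = TRUE)
  invisible(path)
}

#' Read a recording from disk
#'
#' @param path File path.
#' @param format `"auto"` (default; decided by file content), `"container"`
#'   or `"edf"`.
#' @return An `eeg_recording`.
#' @export
read_recording <- function(path, format = c("auto", "container", "edf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    first <- readBin(path, "raw", 8L)
    format <- if (identical(rawToChar(first[1:8]), "#tdmnet ")) "container" else "edf"
  }
  if (format == "edf") return(.read_edf(path))
  header <- readLines(path, n = 1L)
  if (!startsWith(header, "#tdmnet ")) {
    stop("not a tdmnet recording container (missing #tdmnet header): ", path)
  }
  meta <- jsonlite::fromJSON(sub("^#tdmnet ", "", header))
  if (is.null(meta$sampling_rate)) stop("container header missing field: sampling_rate")
  if (is.null(meta$channel_names)) stop("container header missing field: channel_names")
  block <- as.matrix(data.table::fread(path, sep = "\t", skip = 1L, header = FALSE))
  if (!all(is.finite(block))) stop("recording contains non-finite sample values")
  n <- meta$n_samples
  samples <- block[, seq_len(n), drop = FALSE]
  baseline <- if (meta$n_baseline > 0L) {
    block[, (n + 1L):(n + meta$n_baseline), drop = FALSE]
  }
  eeg_recording(samples, meta$sampling_rate, meta$channel_names,
                baseline = baseline, label = meta$label)
}

.pad_ascii <- function(x, width) {
  x <- substr(format(x), 1L, width)
  formatC(x, width = -width)
}

.write_edf <- function(rec, path) {
  C <- nrow(rec$samples); n <- ncol(rec$samples)
  dur <- n / rec$sampling_rate
  pmin_ <- apply(rec$samples, 1L, min); pmax_ <- apply(rec$samples, 1L, max)
  flat <- pmax_ - pmin_ < 1e-12
  pmax_[flat] <- pmin_[flat] + 1
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    .pad_ascii("0", 8L), .pad_ascii("X X X X", 80L), .pad_ascii("Startdate X X X X", 80L),
    .pad_ascii("01.01.26", 8L), .pad_ascii("00.00.00", 8L),
    .pad_ascii(256L * (1L + C), 8L), .pad_ascii("", 44L),
    .pad_ascii(1L, 8L), .pad_ascii(format(dur, digits = 8), 8L), .pad_ascii(C, 4L)
  )
  sig <- paste0(
    paste(vapply(rec$channel_names, .pad_ascii, "", width = 16L), collapse = ""),
    paste(rep(.pad_ascii("", 80L), C), collapse = ""),
    paste(rep(.pad_ascii("uV", 8L), C), collapse = ""),
    paste(vapply(format(pmin_, digits = 7), .pad_ascii, "", width = 8L), collapse = ""),
    paste(vapply(format(pmax_, digits = 7), .pad_ascii, "", width = 8L), collapse = ""),
    paste(rep(.pad_ascii("-32768", 8L), C), collapse = ""),
    paste(rep(.pad_ascii("32767", 8L), C), collapse = ""),
    paste(rep(.pad_ascii("", 80L), C), collapse = ""),
    paste(rep(.pad_ascii(n, 8L), C), collapse = ""),
    paste(rep(.pad_ascii("", 32L), C), collapse = "")
  )
  writeChar(paste0(hdr, sig), con, eos = NULL)
  for (ch in seq_len(C)) {
    scaled <- round((rec$samples[ch, ] - pmin_[ch]) / (pmax_[ch] - pmin_[ch]) * 65535 - 32768)
    writeBin(as.integer(scaled), con, size = 2L, endian = "little")
  }
  invisible(path)
}

.read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  version <- rd(8L); rd(80L); rd(80L); rd(8L); rd(8L)
  hbytes <- as.integer(rd(8L)); rd(44L)
  n_rec <- as.integer(rd(8L)); dur <- as.numeric(rd(8L))
  C <- as.integer(rd(4L))
  if (is.na(C) || C < 1L) stop("EDF header missing signal count")
  labels <- vapply(seq_len(C), function(i) rd(16L), "")
  for (i in seq_len(C)) rd(80L)             # transducer
  for (i in seq_len(C)) rd(8L)              # dimension
  pmin_ <- vapply(seq_len(C), function(i) as.numeric(rd(8L)), 0)
  pmax_ <- vapply(seq_len(C), function(i) as.numeric(rd(8L)), 0)
  dmin_ <- vapply(seq_len(C), function(i) as.numeric(rd(8L)), 0)
  dmax_ <- vapply(seq_len(C), function(i) as.numeric(rd(8L)), 0)
  for (i in seq_len(C)) rd(80L)             # prefilter
  spr <- vapply(seq_len(C), function(i) as.integer(rd(8L)), 0L)
  for (i in seq_len(C)) rd(32L)             # reserved
  if (any(!is.finite(dur)) || dur <= 0) stop("EDF header missing record duration")
  if (length(unique(spr / dur)) > 1L) {
    stop("EDF with per-signal sampling rates is not supported")
  }
  fs <- spr[1L] / dur
  x <- matrix(0, C, spr[1L] * n_rec)
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(C)) {
      raw <- readBin(con, "integer", spr[ch], size = 2L, endian = "little")
      phys <- pmin_[ch] + (raw - dmin_[ch]) / (dmax_[ch] - dmin_[ch]) * (pmax_[ch] - pmin_[ch])
      x[ch, ((r - 1L) * spr[ch] + 1L):(r * spr[ch])] <- phys
    }
  }
  eeg_recording(x, fs, labels)
}

#' Save / load a trained model checkpoint
#'
#' The checkpoint bundles the weights with their `network_spec` (and, for a
#' `tdmnet_fit`, the history, plan and config) so it can be reloaded and used
#' for prediction as-is.
#'
#' @param model A `tdmnet_model` or `tdmnet_fit`.
#' @param path Destination file.
#' @return `path` (for `save_model`) or the restored object (`load_model`).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "tdmnet_model") || inherits(model, "tdmnet_fit"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  if (!(inherits(obj, "tdmnet_model") || inherits(obj, "tdmnet_fit"))) {
    stop("file does not contain a tdmnet model: ", path)
  }
  obj
}
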