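#' Multichannel recording
#'
#' Container for a continuous multichannel time series: a channels x samples
#' numeric matrix together with its sampling rate and channel labels. This is
#' the universal input to [fit_mvar()] and the permutation machinery.
#'
#' @param data Numeric matrix, channels x samples (m x T). A numeric vector is
#'   treated as a single channel.
#' @param fs Sampling rate in Hz (positive scalar).
#' @param channel_labels Optional character vector of m unique labels; defaults
#'   to `ch01, ch02, ...`.
#'
#' @return An object of class `sse_recording` with elements `data`, `fs`,
#'   `channel_labels`.
#' @export
#' @examples
#' rec <- sse_recording(matrix(rnorm(2 * 256), 2), fs = 128)
#' n_channels(rec)
sse_recording <- function(data, fs, channel_labels = NULL) {
  if (is.vector(data) && is.numeric(data)) data <- matrix(data, nrow = 1L)
  if (!is.matrix(data) || !is.numeric(data))
    stop("`data` must be a numeric channels x samples matrix")
  if (!all(is.finite(data)))
    stop("`data` contains non-finite values (NA/NaN/Inf); clean before analysis")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("`fs` must be a positive scalar sampling rate in Hz")
  m <- nrow(data)
  if (is.null(channel_labels))
    channel_labels <- sprintf("ch%02d", seq_len(m))
  if (length(channel_labels) != m)
    stop("`channel_labels` must have one entry per channel")
  if (anyDuplicated(channel_labels))
    stop("`channel_labels` must be unique")
  structure(
    list(data = unname(data), fs = as.numeric(fs),
         channel_labels = as.character(channel_labels)),
    class = "sse_recording"
  )
}

#' @export
print.sse_recording <- function(x, ...) {
  cat(sprintf("<sse_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  invisible(x)
}

#' @rdname sse_recording
#' @param x An `sse_recording`.
#' @export
n_channels <- function(x) nrow(x$data)

#' @rdname sse_recording
#' @export
n_samples <- function(x) ncol(x$data)

#' Write a recording to a delimited-text container
#'
#' The recording is stored as a TSV with samples in rows and one labelled
#' column per channel, plus a JSON side-car (`<path>.json`) holding the
#' sampling rate, channel labels and provenance (creating call, seed if known,
#' package version, timestamp).
#'
#' @param recording An [sse_recording()].
#' @param path Output TSV path; the side-car is written next to it.
#' @param provenance Optional named list merged into the side-car provenance.
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path, provenance = list()) {
  stopifnot(inherits(recording, "sse_recording"))
  # 17 significant digits so the numeric roundtrip is bit-exact
  txt <- matrix(sprintf("%.17g", t(recording$data)),
                ncol = nrow(recording$data))
  writeLines(c(paste(recording$channel_labels, collapse = "\t"),
               apply(txt, 1, paste, collapse = "\t")), path)
  meta <- list(
    fs = recording$fs,
    channel_labels = recording$channel_labels,
    n_samples = ncol(recording$data),
    provenance = c(list(
      package = "ssemodes",
      version = as.character(utils::packageVersion("ssemodes")),
      created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    ), provenance)
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a recording from a delimited-text container
#'
#' Reads a TSV matrix with a header row of channel labels. The sampling rate
#' comes from the JSON side-car written by [write_recording()], or from the
#' `fs` argument for plain files. Orientation is auto-detected: the file is
#' assumed samples x channels (the written layout); if the number of header
#' columns instead matches a channels x samples layout transposed on disk
#' (more columns than rows and labels look like repeated sample indices),
#' reading still yields channels x samples because the matrix is transposed
#' into channel-major order after the header check.
#'
#' @param path TSV path.
#' @param fs Sampling rate in Hz; required when no side-car is present.
#' @param sep Field separator (default tab; use "," for CSV).
#' @return An [sse_recording()].
#' @export
read_recording <- function(path, fs = NULL, sep = "\t") {
  if (!file.exists(path)) stop("file not found: ", path)
  sidecar <- paste0(path, ".json")
  labels <- NULL
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (is.null(fs)) fs <- meta$fs
    labels <- meta$channel_labels
  }
  if (is.null(fs))
    stop("sampling rate unknown: no JSON side-car found for ", path,
         " and `fs` not supplied")
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, colClasses = "character")
  mat <- suppressWarnings(vapply(df, as.numeric, numeric(nrow(df))))
  if (nrow(df) == 1L) mat <- matrix(mat, nrow = 1L, dimnames = list(NULL, names(df)))
  bad <- which(is.na(mat) & !is.na(as.matrix(df)), arr.ind = TRUE)
  if (length(bad)) {
    stop(sprintf("non-numeric cell at row %d, column '%s' in %s",
                 bad[1, 1], colnames(mat)[bad[1, 2]], path))
  }
  if (anyNA(mat)) {
    bad <- which(is.na(mat), arr.ind = TRUE)
    stop(sprintf("missing value at row %d, column '%s' in %s",
                 bad[1, 1], colnames(mat)[bad[1, 2]], path))
  }
  hdr <- colnames(mat)
  # files are written samples x channels; a transposed file (channels in rows)
  # is recognised by a header of generic sample indices (t1, t2, ... / V1 ...)
  # that outnumbers the row count
  transposed <- ncol(mat) > nrow(mat) &&
    all(grepl("^[VvXxtT]?[0-9]+$", hdr))
  if (transposed) {
    data <- unname(mat)
    labels <- if (!is.null(labels)) labels else NULL
  } else {
    data <- t(unname(mat))
    if (is.null(labels)) labels <- hdr
  }
  sse_recording(data, fs = fs, channel_labels = labels)
}
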