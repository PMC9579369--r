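#' Multichannel recording container
#'
#' A `phnet_recording` holds a channels-by-samples signal matrix together
#' with its sampling rate, channel labels and a band tag. It is the common
#' currency of the signal-level half of the package: the synthetic generator
#' produces one, [band_filter()] transforms one, and [pearson_matrix()]
#' consumes one.
#'
#' @param signals numeric matrix, channels in rows, samples in columns.
#' @param srate sampling rate in Hz (single positive number).
#' @param labels character vector of channel labels; defaults to
#'   `"ch01"`, `"ch02"`, ...
#' @param band band tag (character); `"full"` marks an unfiltered record.
#' @return An object of class `phnet_recording`.
#' @examples
#' rec <- recording(matrix(rnorm(200), nrow = 4), srate = 100)
#' n_channels(rec)
#' @export
recording <- function(signals, srate, labels = NULL, band = "full") {
  signals <- as.matrix(signals)
  if (!is.numeric(signals)) stop("`signals` must be a numeric matrix")
  if (!is.numeric(srate) || length(srate) != 1L || srate <= 0)
    stop("`srate` must be a single positive number (Hz)")
  if (is.null(labels)) labels <- sprintf("ch%02d", seq_len(nrow(signals)))
  if (length(labels) != nrow(signals))
    stop("`labels` length (", length(labels), ") must equal the number of ",
         "channels (", nrow(signals), ")")
  rownames(signals) <- labels
  structure(list(signals = signals, srate = as.numeric(srate),
                 labels = as.character(labels), band = band),
            class = "phnet_recording")
}

#' @rdname recording
#' @param rec a `phnet_recording`.
#' @export
n_channels <- function(rec) nrow(rec$signals)

#' @rdname recording
#' @export
n_samples <- function(rec) ncol(rec$signals)

#' @export
print.phnet_recording <- function(x, ...) {
  cat(sprintf("<phnet_recording> %d channels x %d samples @ %g Hz, band '%s'\n",
              n_channels(x), n_samples(x), x$srate, x$band))
  invisible(x)
}

#' Read a multichannel recording
#'
#' Reads either a delimited text matrix written by [write_recording_text()]
#' (channels in rows; sampling rate and labels carried in `#`-comment header
#' lines) or a European Data Format (EDF) file. Text files without a rate in
#' the header require the `srate` argument.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"text"` or `"edf"`.
#' @param srate sampling rate in Hz; overrides/supplies the rate for text
#'   input lacking a header.
#' @return A [recording()].
#' @export
read_recording <- function(path, format = c("auto", "text", "edf"),
                           srate = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "text"
  }
  if (format == "edf") return(read_edf(path))

  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (!length(body)) stop("no numeric data found in ", path)
  rate_line <- grep("^#\\s*srate:", hdr, value = TRUE)
  file_rate <- if (length(rate_line))
    as.numeric(sub("^#\\s*srate:\\s*", "", rate_line[1])) else NULL
  if (is.null(srate)) srate <- file_rate
  if (is.null(srate) || is.na(srate))
    stop("sampling rate missing: supply `srate` or a '# srate: <Hz>' header ",
         "line in ", path)
  lab_line <- grep("^#\\s*labels:", hdr, value = TRUE)
  labels <- if (length(lab_line))
    strsplit(sub("^#\\s*labels:\\s*", "", lab_line[1]), "[ \t]+")[[1]] else NULL
  band_line <- grep("^#\\s*band:", hdr, value = TRUE)
  band <- if (length(band_line))
    sub("^#\\s*band:\\s*", "", band_line[1]) else "full"
  rows <- lapply(seq_along(body), function(i) {
    x <- suppressWarnings(as.numeric(strsplit(trimws(body[i]), "[ \t,]+")[[1]]))
    if (anyNA(x))
      stop("malformed numeric data at data line ", i, " of ", path)
    x
  })
  if (length(unique(lengths(rows))) != 1L)
    stop("ragged rows in ", path, ": all channels must have the same number ",
         "of samples")
  recording(do.call(rbind, rows), srate = srate, labels = labels, band = band)
}

#' Write a recording as delimited text
#'
#' Channels in rows, tab-separated samples in columns; sampling rate, labels
#' and band tag are stored in `#`-comment header lines so the file round-trips
#' through [read_recording()].
#'
#' @param rec a [recording()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_recording_text <- function(rec, path) {
  stopifnot(inherits(rec, "phnet_recording"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# srate: %.10g", rec$srate),
               paste("# labels:", paste(rec$labels, collapse = " ")),
               paste("# band:", rec$band)), con)
  utils::write.table(format(rec$signals, digits = 15, trim = TRUE,
                            scientific = FALSE),
                     con, sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

# ---- minimal EDF codec ------------------------------------------------------
# EDF stores 16-bit integers with a per-signal physical/digital calibration;
# one data record per file here (record duration = whole recording). Amplitude
# resolution is therefore (physical range)/65535 per channel.

edf_field <- function(x, width) {
  s <- as.character(x)
  if (nchar(s) > width) s <- substr(s, 1, width)
  formatC(s, width = -width, flag = " ")
}

edf_num <- function(x, width) {
  for (dg in 7:1) {                      # most precision that fits the field
    s <- formatC(x, format = "g", digits = dg)
    if (nchar(s) <= width) break
  }
  edf_field(s, width)
}

#' Write a recording as EDF
#'
#' Minimal European Data Format writer: a single data record holding the whole
#' recording, 16-bit samples with per-channel physical calibration. Readable
#' by [read_edf()] and by standard EDF tools.
#'
#' @inheritParams write_recording_text
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "phnet_recording"))
  ns <- n_channels(rec)
  nsamp <- n_samples(rec)
  sig <- rec$signals
  pmin <- apply(sig, 1, min)
  pmax <- apply(sig, 1, max)
  flat <- pmax - pmin < .Machine$double.eps
  pmin[flat] <- pmin[flat] - 1
  pmax[flat] <- pmax[flat] + 1
  # quantize against the calibration exactly as serialized in the 8-char
  # header fields, so reader and writer agree to the last digit
  pmin <- as.numeric(vapply(pmin, edf_num, "", width = 8))
  pmax <- as.numeric(vapply(pmax, edf_num, "", width = 8))
  dmin <- -32767; dmax <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s) writeChar(s, con, nchar(s), eos = NULL)
  wr(edf_field("0", 8))
  wr(edf_field("synthetic recording", 80))
  wr(edf_field(paste("phnet band", rec$band), 80))
  wr(edf_field("01.01.00", 8))
  wr(edf_field("00.00.00", 8))
  wr(edf_field(256 * (ns + 1), 8))
  wr(edf_field("", 44))
  wr(edf_field(1, 8))                       # one data record
  wr(edf_num(nsamp / rec$srate, 8))         # record duration in seconds
  wr(edf_field(ns, 4))
  wr(paste(vapply(rec$labels, edf_field, "", width = 16), collapse = ""))
  wr(strrep(" ", 80 * ns))                  # transducer
  wr(paste(rep(edf_field("uV", 8), ns), collapse = ""))
  wr(paste(vapply(pmin, edf_num, "", width = 8), collapse = ""))
  wr(paste(vapply(pmax, edf_num, "", width = 8), collapse = ""))
  wr(paste(rep(edf_field(dmin, 8), ns), collapse = ""))
  wr(paste(rep(edf_field(dmax, 8), ns), collapse = ""))
  wr(strrep(" ", 80 * ns))                  # prefiltering
  wr(paste(rep(edf_field(nsamp, 8), ns), collapse = ""))
  wr(strrep(" ", 32 * ns))
  for (i in seq_len(ns)) {
    scale <- (dmax - dmin) / (pmax[i] - pmin[i])
    dig <- round((sig[i, ] - pmin[i]) * scale + dmin)
    dig <- as.integer(pmax(dmin, pmin(dmax, dig)))   # clamp: header values
    writeBin(dig, con, size = 2, endian = "little")  # are 8-char truncated
  }
  invisible(path)
}

#' Read an EDF recording
#'
#' Counterpart of [write_edf()]; handles multi-record files with a common
#' per-signal sample count.
#'
#' @param path EDF file path.
#' @return A [recording()].
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) readChar(con, n, useBytes = TRUE)
  rd(8)                                    # version
  rd(80); band_id <- trimws(rd(80))
  rd(8); rd(8); rd(8); rd(44)
  nrec <- as.integer(trimws(rd(8)))
  dur <- as.numeric(trimws(rd(8)))
  ns <- as.integer(trimws(rd(4)))
  if (is.na(ns) || ns < 1) stop("malformed EDF header in ", path)
  labels <- trimws(vapply(seq_len(ns), function(i) rd(16), ""))
  rd(80 * ns); rd(8 * ns)
  pmin <- as.numeric(trimws(vapply(seq_len(ns), function(i) rd(8), "")))
  pmax <- as.numeric(trimws(vapply(seq_len(ns), function(i) rd(8), "")))
  dmin <- as.numeric(trimws(vapply(seq_len(ns), function(i) rd(8), "")))
  dmax <- as.numeric(trimws(vapply(seq_len(ns), function(i) rd(8), "")))
  rd(80 * ns)
  spr <- as.integer(trimws(vapply(seq_len(ns), function(i) rd(8), "")))
  rd(32 * ns)
  chans <- vector("list", ns)
  for (i in seq_len(ns)) chans[[i]] <- numeric(0)
  for (r in seq_len(nrec)) {
    for (i in seq_len(ns)) {
      dig <- readBin(con, integer(), n = spr[i], size = 2, endian = "little")
      phys <- (dig - dmin[i]) * (pmax[i] - pmin[i]) / (dmax[i] - dmin[i]) +
        pmin[i]
      chans[[i]] <- c(chans[[i]], phys)
    }
  }
  srate <- spr[1] / dur                    # samples per record / record secs
  band <- sub("^phnet band ", "", band_id)
  if (identical(band, band_id) || !nzchar(band)) band <- "full"
  recording(do.call(rbind, chans), srate = srate, labels = labels, band = band)
}
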