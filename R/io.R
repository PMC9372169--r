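#' Write / read a time series as two-column delimited text
#'
#' Plain-text interchange: a header line then `time_s<TAB>value` rows at
#' full double precision, so a write-read round trip is lossless.
#' Reading checks that the sampling is uniform (worst relative gap
#' deviation within 1e-6) and infers the rate from the median spacing.
#'
#' @param ts A [time_series()].
#' @param path File path.
#' @param sep Field separator (default tab).
#' @return `read_text_ts` returns a `time_series`; `write_text_ts`
#'   returns `path` invisibly.
#' @export
write_text_ts <- function(ts, path, sep = "\t") {
  stopifnot_time_series(ts)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("time_s", "value", sep = sep), con)
  writeLines(paste(sprintf("%.17g", ts_times(ts)),
                   sprintf("%.17g", ts$samples), sep = sep), con)
  invisible(path)
}

#' @rdname write_text_ts
#' @param label Channel label to attach on read.
#' @export
read_text_ts <- function(path, sep = "\t", label = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "numeric")
  if (ncol(df) < 2L || nrow(df) < 2L) {
    stop("expected two columns (time_s, value) with >= 2 rows",
         call. = FALSE)
  }
  t <- df[[1L]]
  gaps <- diff(t)
  med <- stats::median(gaps)
  worst <- max(abs(gaps - med))
  if (worst > 1e-6 * med) {
    stop(sprintf(
      "non-uniform sampling: worst gap deviates by %.3g s from the median %.3g s",
      worst, med), call. = FALSE)
  }
  time_series(df[[2L]], rate = 1 / med,
              label = if (is.null(label)) basename(path) else label,
              t0 = t[1L])
}

# ---- EDF (European Data Format) ------------------------------------------
# Minimal EDF writer/reader: standard 256-byte fixed header, 256 bytes
# per signal, data records of 16-bit little-endian integers with
# physical/digital linear scaling.  Covers uncompressed single-rate and
# multi-rate EDF; EDF+ annotations are ignored on read.

.edf_pad <- function(s, n) {
  s <- substr(as.character(s), 1L, n)
  sprintf("%-*s", n, s)
}

#' Write time series to an EDF file
#'
#' Channels may have different rates but must share the same duration
#' (within one data record).  Physical scaling maps each channel's
#' range onto the full 16-bit digital range, so values are stored to
#' 16-bit resolution of the channel's own dynamic range; signals are
#' processed at full double precision internally and only quantized at
#' this export boundary.
#'
#' @param ts_list A [time_series()] or list of them.
#' @param path Output path.
#' @param record_duration_s Data-record length in seconds (default 1);
#'   `rate * record_duration_s` must be a whole number for every
#'   channel.
#' @return `path`, invisibly.
#' @export
write_edf <- function(ts_list, path, record_duration_s = 1) {
  if (inherits(ts_list, "time_series")) ts_list <- list(ts_list)
  stopifnot(length(ts_list) >= 1L)
  ns <- length(ts_list)
  spr <- vapply(ts_list, function(s) s$rate * record_duration_s, 1)
  if (any(abs(spr - round(spr)) > 1e-9)) {
    stop("rate * record_duration_s must be an integer for every channel",
         call. = FALSE)
  }
  spr <- as.integer(round(spr))
  durs <- vapply(ts_list, ts_duration, 1)
  n_rec <- as.integer(ceiling(max(durs) / record_duration_s))

  pmin_ <- pmax_ <- numeric(ns)
  dig <- vector("list", ns)
  for (j in seq_len(ns)) {
    x <- ts_list[[j]]$samples
    need <- n_rec * spr[j]
    if (length(x) < need) x <- c(x, rep(x[length(x)], need - length(x)))
    lo <- min(x); hi <- max(x)
    if (hi <= lo) hi <- lo + 1
    pmin_[j] <- lo; pmax_[j] <- hi
    dig[[j]] <- as.integer(round((x - lo) / (hi - lo) * 65535 - 32768))
  }

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    .edf_pad("0", 8L),
    .edf_pad("X X X X", 80L),
    .edf_pad("Startdate X X X X", 80L),
    "01.01.00", "00.00.00",
    .edf_pad(256L * (1L + ns), 8L),
    .edf_pad("", 44L),
    .edf_pad(n_rec, 8L),
    .edf_pad(format(record_duration_s, digits = 8), 8L),
    .edf_pad(ns, 4L)
  )
  writeChar(hdr, con, eos = NULL)
  field <- function(get, n) {
    for (j in seq_len(ns)) writeChar(.edf_pad(get(j), n), con, eos = NULL)
  }
  field(function(j) ts_list[[j]]$label, 16L)
  field(function(j) "", 80L)                       # transducer
  field(function(j) "au", 8L)                      # physical dimension
  field(function(j) format(pmin_[j], digits = 7), 8L)
  field(function(j) format(pmax_[j], digits = 7), 8L)
  field(function(j) "-32768", 8L)
  field(function(j) "32767", 8L)
  field(function(j) "", 80L)                       # prefiltering
  field(function(j) spr[j], 8L)
  field(function(j) "", 32L)
  for (r in seq_len(n_rec)) {
    for (j in seq_len(ns)) {
      idx <- ((r - 1L) * spr[j] + 1L):(r * spr[j])
      writeBin(dig[[j]][idx], con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}

#' Read channels from an EDF file
#'
#' @param path EDF/EDF+ file.
#' @param channels Optional character vector of channel labels (or
#'   integer indices); default all ordinary channels.
#' @return A named list of [time_series()], physical scaling applied.
#' @export
read_edf <- function(path, channels = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) trimws(readChar(con, n, useBytes = TRUE))
  ver <- rd(8L)
  if (!identical(ver, "0")) stop("not an EDF file: ", path, call. = FALSE)
  rd(80L); rd(80L); rd(8L); rd(8L); rd(8L); rd(44L)
  n_rec <- as.integer(rd(8L))
  rec_dur <- as.numeric(rd(8L))
  ns <- as.integer(rd(4L))
  rdn <- function(n) vapply(seq_len(ns), function(j) rd(n), "")
  labels <- rdn(16L)
  rdn(80L); rdn(8L)
  pmin_ <- as.numeric(rdn(8L)); pmax_ <- as.numeric(rdn(8L))
  dmin_ <- as.numeric(rdn(8L)); dmax_ <- as.numeric(rdn(8L))
  rdn(80L)
  spr <- as.integer(rdn(8L))
  rdn(32L)

  want <- if (is.null(channels)) {
    which(labels != "EDF Annotations")
  } else if (is.numeric(channels)) {
    as.integer(channels)
  } else {
    idx <- match(channels, labels)
    if (anyNA(idx)) {
      stop("channel(s) not found: ",
           paste(channels[is.na(idx)], collapse = ", "),
           "; available: ", paste(labels, collapse = ", "), call. = FALSE)
    }
    idx
  }
  raw <- lapply(seq_len(ns), function(j) vector("list", n_rec))
  for (r in seq_len(n_rec)) {
    for (j in seq_len(ns)) {
      v <- readBin(con, "integer", n = spr[j], size = 2L, signed = TRUE,
                   endian = "little")
      if (j %in% want) raw[[j]][[r]] <- v
    }
  }
  out <- list()
  for (j in want) {
    d <- unlist(raw[[j]])
    scale <- (pmax_[j] - pmin_[j]) / (dmax_[j] - dmin_[j])
    x <- pmin_[j] + (d - dmin_[j]) * scale
    out[[labels[j]]] <- time_series(x, rate = spr[j] / rec_dur,
                                    label = labels[j])
  }
  out
}
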