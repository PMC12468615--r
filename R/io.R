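## Readers and writers for the two recording formats the pipeline consumes:
## single-column ASCII sample files (the classic single-channel benchmark
## layout, 4097 samples at 173.61 Hz) and EDF (16-bit, standard header).
## The EDF code is a minimal self-contained implementation of the format's
## fixed-layout ASCII header plus little-endian 16-bit data records.

#' Read a single-column ASCII sample file
#'
#' One numeric sample per line; CR/LF line endings and trailing blank lines
#' are tolerated.  A warning (not an error) is issued when the file does not
#' hold the canonical 4097 samples.
#'
#' @param path File path.
#' @param fs Sampling rate attached to the result (default 173.61 Hz).
#' @param expected_length Length that triggers the warning check (default
#'   4097; `NA` disables it).
#' @return Numeric vector with attribute `fs`.
#' @export
read_bonn_file <- function(path, fs = 173.61, expected_length = 4097L) {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  keep <- trimws(lines) != ""
  lines <- lines[keep]
  x <- suppressWarnings(as.numeric(lines))
  if (anyNA(x)) {
    bad <- which(keep)[which(is.na(x))[1L]]
    stop(sprintf("non-numeric sample at line %d of '%s'", bad, path), call. = FALSE)
  }
  if (!is.na(expected_length) && length(x) != expected_length)
    warning(sprintf("'%s' holds %d samples (expected %d)",
                    path, length(x), expected_length), call. = FALSE)
  structure(x, fs = fs)
}

#' Write samples as a single-column ASCII file
#'
#' Values are written with 17 significant digits, so reading the file back
#' reproduces the samples exactly.
#'
#' @param x Numeric vector.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_bonn_file <- function(x, path) {
  writeLines(sprintf("%.17g", as.numeric(x)), path)
  invisible(path)
}

## ---- EDF ----------------------------------------------------------------

edf_field <- function(x, width) {
  s <- formatC(as.character(x), width = -width)
  substr(s, 1L, width)
}

## Shortest representation of a number fitting the 8-character EDF field.
edf_num8 <- function(v) {
  for (d in 7:1) {
    s <- sprintf("%.*g", d, v)
    if (nchar(s) <= 8L) return(s)
  }
  stop("cannot represent value in an 8-character EDF field", call. = FALSE)
}

#' Write channels to an EDF file
#'
#' Minimal standard-compliant writer: one data record holding the full
#' recording, 16-bit samples scaled to each channel's physical range.
#'
#' @param signals Named list of numeric vectors (equal lengths); names are
#'   the channel labels (e.g. `"P8-O2"`).
#' @param path Output file.
#' @param fs Sampling rate in Hz.
#' @param physical_dim Physical dimension string (default `"uV"`).
#' @return `path`, invisibly.
#' @export
write_edf <- function(signals, path, fs = 256, physical_dim = "uV") {
  stopifnot(is.list(signals), length(signals) >= 1L, !is.null(names(signals)))
  n <- unique(lengths(signals))
  if (length(n) != 1L) stop("all channels must have the same length", call. = FALSE)
  ns <- length(signals)
  duration <- n / fs
  pmin_ <- vapply(signals, min, numeric(1))
  pmax_ <- vapply(signals, max, numeric(1))
  flat <- pmax_ - pmin_ < .Machine$double.eps
  pmax_[flat] <- pmin_[flat] + 1
  # pad the range so header rounding can never push samples outside it,
  # then store-and-reparse so the scaling matches the 8-char header fields
  pad <- 1e-3 * (pmax_ - pmin_)
  pmin_ <- pmin_ - pad
  pmax_ <- pmax_ + pad
  pmin_str <- vapply(pmin_, edf_num8, "")
  pmax_str <- vapply(pmax_, edf_num8, "")
  pmin_ <- as.numeric(pmin_str)
  pmax_ <- as.numeric(pmax_str)
  bad <- pmax_ <= pmin_
  if (any(bad)) { pmax_[bad] <- pmin_[bad] + 1; pmax_str[bad] <- vapply(pmax_[bad], edf_num8, "") }
  dmin <- -32768L; dmax <- 32767L
  header <- paste0(
    edf_field("0", 8L), edf_field("synthetic subject", 80L),
    edf_field("synthetic recording", 80L),
    edf_field("01.01.00", 8L), edf_field("00.00.00", 8L),
    edf_field(256L + 256L * ns, 8L), edf_field("", 44L),
    edf_field(1L, 8L), edf_field(format(duration, digits = 7), 8L),
    edf_field(ns, 4L))
  sig_fields <- function(values, width) paste(vapply(values, edf_field, "", width = width), collapse = "")
  header <- paste0(header,
    sig_fields(names(signals), 16L),
    sig_fields(rep("", ns), 80L),
    sig_fields(rep(physical_dim, ns), 8L),
    sig_fields(pmin_str, 8L),
    sig_fields(pmax_str, 8L),
    sig_fields(rep(dmin, ns), 8L),
    sig_fields(rep(dmax, ns), 8L),
    sig_fields(rep("", ns), 80L),
    sig_fields(rep(n, ns), 8L),
    sig_fields(rep("", ns), 32L))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(header, con, eos = NULL)
  for (i in seq_len(ns)) {
    x <- as.numeric(signals[[i]])
    d <- round((x - pmin_[i]) / (pmax_[i] - pmin_[i]) * (dmax - dmin) + dmin)
    d <- pmin(pmax(d, dmin), dmax)
    writeBin(as.integer(d), con, size = 2L, endian = "little")
  }
  invisible(path)
}

read_edf_header <- function(con) {
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  h <- list(version = rd(8L), patient = rd(80L), recording = rd(80L),
            startdate = rd(8L), starttime = rd(8L),
            header_bytes = as.integer(rd(8L)), reserved = rd(44L),
            n_records = as.integer(rd(8L)), record_duration = as.numeric(rd(8L)),
            ns = as.integer(rd(4L)))
  ns <- h$ns
  per <- function(width) vapply(seq_len(ns), function(i) rd(width), "")
  h$labels <- per(16L); h$transducer <- per(80L); h$phys_dim <- per(8L)
  h$phys_min <- as.numeric(per(8L)); h$phys_max <- as.numeric(per(8L))
  h$dig_min <- as.numeric(per(8L)); h$dig_max <- as.numeric(per(8L))
  h$prefilter <- per(80L); h$samples_per_record <- as.integer(per(8L))
  h$sig_reserved <- per(32L)
  h
}

#' Read one named channel from an EDF file
#'
#' @param path EDF file.
#' @param channel Channel label as stored in the header (e.g. `"P8-O2"`).
#' @return Numeric vector of physical values with attributes `fs` (from the
#'   header) and `channel`.
#' @export
read_edf_channel <- function(path, channel) {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path), call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  h <- read_edf_header(con)
  j <- match(channel, h$labels)
  if (is.na(j))
    stop(sprintf("channel '%s' not found; available channels: %s",
                 channel, paste(h$labels, collapse = ", ")), call. = FALSE)
  out <- numeric(0)
  for (r in seq_len(h$n_records)) {
    for (i in seq_len(h$ns)) {
      d <- readBin(con, integer(), n = h$samples_per_record[i], size = 2L,
                   endian = "little", signed = TRUE)
      if (i == j) {
        phys <- (d - h$dig_min[i]) / (h$dig_max[i] - h$dig_min[i]) *
          (h$phys_max[i] - h$phys_min[i]) + h$phys_min[i]
        out <- c(out, phys)
      }
    }
  }
  fs <- h$samples_per_record[j] / h$record_duration
  structure(out, fs = fs, channel = channel)
}

#' List the channel labels of an EDF file
#' @param path EDF file.
#' @return Character vector of labels.
#' @export
edf_channels <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  read_edf_header(con)$labels
}

## ---- segmentation -------------------------------------------------------

#' Split a signal into fixed-length windows
#'
#' Non-overlapping by default (`step_s = window_s`); a trailing window that
#' would run past the end of the signal is dropped.
#'
#' @param x Numeric vector, ideally carrying an `fs` attribute.
#' @param window_s Window length in seconds.
#' @param step_s Hop between window starts in seconds (default: the window
#'   length, i.e. no overlap).
#' @param fs Sampling rate; defaults to `attr(x, "fs")`.
#' @return A list of numeric vectors, each with the `fs` attribute.
#' @export
segment_signal <- function(x, window_s, step_s = NULL, fs = NULL) {
  if (is.null(fs)) fs <- attr(x, "fs")
  if (is.null(fs)) stop("sampling rate unknown: pass fs", call. = FALSE)
  if (is.null(step_s)) step_s <- window_s
  wlen <- round(window_s * fs)
  step <- round(step_s * fs)
  if (wlen > length(x)) stop("window longer than the signal", call. = FALSE)
  starts <- seq(1L, length(x) - wlen + 1L, by = step)
  lapply(starts, function(a) structure(as.numeric(x)[a:(a + wlen - 1L)], fs = fs))
}

## ---- run configuration --------------------------------------------------

#' Default pipeline configuration
#'
#' Entropy block: embedding dimension 3, delay 1, maximum scale 10, db4
#' wavelet at level 4, maximum lag 10.  Classifier block: pathway width 16,
#' fusion width 32, 50 BFGS iterations, 1e6 function-evaluation budget.
#' Cross-validation: 10 folds.
#'
#' @return Nested list with blocks `entropy`, `classifier`, `cv` and `seed`.
#' @export
default_run_config <- function() {
  list(entropy = list(m = 3L, tau = 1L, s_max = 10L, basis = "db4",
                      level = 4L, k_max = 10L),
       classifier = list(hidden_pathway = 16L, hidden_fusion = 32L,
                         max_iter = 50L, max_feval = 1e6),
       cv = list(n_folds = 10L, shuffle = FALSE),
       seed = 1L)
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Unknown fields are rejected with their path; missing fields fall back to
#' [default_run_config()].
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return Validated nested configuration list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: '%s'", path), call. = FALSE)
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  defaults <- default_run_config()
  merge_block <- function(user, def, prefix) {
    if (is.null(user)) return(def)
    extra <- setdiff(names(user), names(def))
    if (length(extra))
      stop(sprintf("unknown config field(s): %s",
                   paste0(prefix, extra, collapse = ", ")), call. = FALSE)
    utils::modifyList(def, user)
  }
  top_extra <- setdiff(names(cfg), names(defaults))
  if (length(top_extra))
    stop(sprintf("unknown config block(s): %s", paste(top_extra, collapse = ", ")),
         call. = FALSE)
  out <- defaults
  out$entropy <- merge_block(cfg$entropy, defaults$entropy, "entropy.")
  out$classifier <- merge_block(cfg$classifier, defaults$classifier, "classifier.")
  out$cv <- merge_block(cfg$cv, defaults$cv, "cv.")
  if (!is.null(cfg$seed)) out$seed <- cfg$seed
  for (f in c("m", "tau", "s_max", "level", "k_max"))
    out$entropy[[f]] <- as.integer(out$entropy[[f]])
  for (f in c("hidden_pathway", "hidden_fusion", "max_iter"))
    out$classifier[[f]] <- as.integer(out$classifier[[f]])
  out$cv$n_folds <- as.integer(out$cv$n_folds)
  out$seed <- as.integer(out$seed)
  out
}
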