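## Seed-deterministic generator of EEG-like signals.
##
## Background activity is zero-mean 1/f^alpha colored noise (alpha ~ 1, the
## standard stylized spectral fact for resting EEG).  Ictal-like activity
## superimposes a ~3 Hz spike-and-wave train at a configurable amplitude
## ratio, emulating the transition from broadband disorder to high-amplitude
## rhythmic order that seizure detectors must pick up.  Interictal-like
## activity adds sparse isolated spikes to the background.  None of this is
## a physiological simulation; it provides class structure sufficient to
## exercise every stage of the pipeline without recorded data.

#' Synthetic background (non-ictal) EEG-like signal
#'
#' Zero-mean unit-variance `1/f^alpha` colored noise generated in the
#' frequency domain, deterministic per seed.
#'
#' @param fs Sampling rate in Hz (default 173.61, a common benchmark rate).
#' @param duration_s Duration in seconds (default 23.6, giving 4097 samples
#'   at the default rate).
#' @param alpha Spectral exponent (default 1; 0 gives white noise).
#' @param seed Integer seed.
#' @return Numeric vector of `round(fs * duration_s)` samples (4097 at the
#'   defaults) with attributes `fs` and `label = "background"`.
#' @export
generate_background <- function(fs = 173.61, duration_s = 23.6, alpha = 1,
                                seed = 1L) {
  if (!is.finite(alpha) || alpha < 0) stop("invalid spectral exponent", call. = FALSE)
  n <- as.integer(round(fs * duration_s))
  set.seed(seed)
  z <- stats::rnorm(n)
  zf <- stats::fft(z)
  freq <- c(0, seq_len(n - 1L)) / n * fs
  freq <- pmin(freq, fs - freq)  # two-sided frequency axis
  scale <- c(0, (freq[-1L])^(-alpha / 2))  # kill DC: zero-mean by construction
  xf <- zf * scale
  x <- Re(stats::fft(xf, inverse = TRUE)) / n
  x <- x / stats::sd(x)
  structure(x, fs = fs, label = "background")
}

## Unit-RMS 3 Hz-style spike-and-wave template evaluated on a time grid:
## a slow sine plus a sharp gaussian spike once per cycle.
spike_wave_template <- function(t, freq) {
  phase <- (t * freq) %% 1
  wave <- sin(2 * pi * phase)
  spike <- 2.5 * exp(-((phase - 0.5)^2) / (2 * 0.02^2))
  s <- wave + spike
  s / sqrt(mean(s^2))
}

#' Synthetic ictal (seizure-like) EEG-like signal
#'
#' Colored-noise background plus a rhythmic spike-and-wave train whose RMS
#' amplitude is `amplitude_ratio` times the background RMS.  The rhythmic
#' order lowers every entropy feature relative to the background class.
#'
#' @inheritParams generate_background
#' @param sw_freq Spike-wave repetition frequency in Hz (default 3, the
#'   classic generalized spike-wave rate).
#' @param amplitude_ratio RMS of the rhythmic component relative to the
#'   background (default 3; 0 reproduces the background exactly).
#' @return Numeric vector with attributes `fs` and `label = "ictal"`.
#' @export
generate_ictal <- function(fs = 173.61, duration_s = 23.6, alpha = 1,
                           sw_freq = 3, amplitude_ratio = 3, seed = 1L) {
  if (sw_freq >= fs / 2) stop("rhythm frequency above Nyquist", call. = FALSE)
  if (amplitude_ratio < 0) stop("amplitude ratio must be >= 0", call. = FALSE)
  bg <- generate_background(fs, duration_s, alpha, seed)
  if (amplitude_ratio == 0) {
    attr(bg, "label") <- "ictal"
    return(bg)
  }
  t <- (seq_along(bg) - 1L) / fs
  x <- as.numeric(bg) + amplitude_ratio * spike_wave_template(t, sw_freq)
  structure(x, fs = fs, label = "ictal")
}

#' Synthetic interictal EEG-like signal
#'
#' Background noise with sparse isolated epileptiform spikes at a Poisson
#' rate, emulating between-seizure recordings from an epileptic focus.
#'
#' @inheritParams generate_background
#' @param spike_rate Expected isolated spikes per second (default 1).
#' @param spike_amplitude Spike peak height in background standard
#'   deviations (default 4).
#' @return Numeric vector with attributes `fs` and `label = "interictal"`.
#' @export
generate_interictal <- function(fs = 173.61, duration_s = 23.6, alpha = 1,
                                spike_rate = 1, spike_amplitude = 4, seed = 1L) {
  bg <- generate_background(fs, duration_s, alpha, seed)
  x <- as.numeric(bg)
  n <- length(x)
  set.seed(seed + 1L)
  n_spikes <- stats::rpois(1L, spike_rate * duration_s)
  if (n_spikes > 0) {
    centers <- sort(stats::runif(n_spikes, 0, duration_s))
    t <- (seq_len(n) - 1L) / fs
    width <- 0.02  # 20 ms sharp transients
    for (ct in centers) x <- x + spike_amplitude * exp(-((t - ct)^2) / (2 * width^2))
  }
  structure(x, fs = fs, label = "interictal")
}

#' Generate a labeled synthetic dataset
#'
#' Produces `n_per_class` signals for each class of the chosen preset with
#' per-signal seeds derived deterministically from `seed`, plus a manifest
#' sufficient to regenerate every signal bit-identically.
#'
#' @inheritParams generate_background
#' @param n_per_class Signals per class (default 100).
#' @param classes `"two-class"` (background vs. ictal, the default) or
#'   `"three-class"` (healthy-like background, interictal with sparse
#'   spikes, sustained ictal spike-wave).
#' @param amplitude_ratio,sw_freq Ictal-signal parameters, see
#'   [generate_ictal()].
#' @param spike_rate,spike_amplitude Interictal parameters (three-class
#'   preset), see [generate_interictal()].
#' @return A list of class `"mde_dataset"`: `signals` (list of numeric
#'   vectors), `labels` (factor), `manifest` (data frame with class,
#'   per-signal seed and generator parameters), `config`.
#' @export
generate_dataset <- function(n_per_class = 100L, classes = c("two-class", "three-class"),
                             fs = 173.61, duration_s = 23.6, alpha = 1,
                             sw_freq = 3, amplitude_ratio = 3,
                             spike_rate = 1, spike_amplitude = 4, seed = 1L) {
  classes <- match.arg(classes)
  stopifnot(n_per_class >= 1L)
  class_names <- if (classes == "two-class") c("background", "ictal")
                 else c("background", "interictal", "ictal")
  recs <- list(); signals <- list(); k <- 0L
  for (ci in seq_along(class_names)) {
    for (i in seq_len(n_per_class)) {
      k <- k + 1L
      sseed <- (as.integer(seed) + 7919L * (k - 1L)) %% 2147483647L
      cl <- class_names[ci]
      signals[[k]] <- switch(cl,
        background = generate_background(fs, duration_s, alpha, sseed),
        interictal = generate_interictal(fs, duration_s, alpha, spike_rate,
                                         spike_amplitude, sseed),
        ictal = generate_ictal(fs, duration_s, alpha, sw_freq,
                               amplitude_ratio, sseed))
      recs[[k]] <- data.frame(index = k, class = cl, seed = sseed)
    }
  }
  manifest <- do.call(rbind, recs)
  config <- list(n_per_class = as.integer(n_per_class), classes = classes,
                 fs = fs, duration_s = duration_s, alpha = alpha,
                 sw_freq = sw_freq, amplitude_ratio = amplitude_ratio,
                 spike_rate = spike_rate, spike_amplitude = spike_amplitude,
                 seed = as.integer(seed))
  structure(list(signals = signals, labels = factor(manifest$class,
                                                    levels = class_names),
                 manifest = manifest, config = config),
            class = "mde_dataset")
}

#' @export
print.mde_dataset <- function(x, ...) {
  cat(sprintf("Synthetic EEG-like dataset: %d signals (%s), %d samples each, fs = %g Hz\n",
              length(x$signals), paste(levels(x$labels), collapse = "/"),
              length(x$signals[[1L]]), x$config$fs))
  print(table(x$labels))
  invisible(x)
}

#' Write a dataset as single-column ASCII files with a JSON manifest
#'
#' One plain-text file per signal (one sample per line, the layout of the
#' classic single-channel benchmark distribution) plus `manifest.json`
#' holding labels, per-signal seeds and the generator configuration, from
#' which [generate_dataset()] reproduces the signals bit-identically.
#'
#' @param dataset An [generate_dataset()] result.
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "mde_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(length(dataset$signals))
  for (i in seq_along(dataset$signals)) {
    files[i] <- sprintf("sig_%03d_%s.txt", i, dataset$manifest$class[i])
    write_bonn_file(dataset$signals[[i]], file.path(dir, files[i]))
  }
  doc <- list(format = "mde-dataset-manifest", version = 1L,
              config = dataset$config,
              records = cbind(dataset$manifest, file = files))
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a dataset directory written by [write_dataset()]
#' @param dir Dataset directory containing `manifest.json`.
#' @return An `"mde_dataset"` (signals read back from the ASCII files).
#' @export
read_dataset <- function(dir) {
  path <- file.path(dir, "manifest.json")
  if (!file.exists(path)) stop(sprintf("no manifest.json in '%s'", dir), call. = FALSE)
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  recs <- doc$records
  signals <- lapply(file.path(dir, recs$file), function(f)
    as.numeric(read_bonn_file(f, fs = doc$config$fs, expected_length = NA)))
  lev <- unique(recs$class)
  structure(list(signals = signals,
                 labels = factor(recs$class, levels = lev),
                 manifest = recs[c("index", "class", "seed")],
                 config = doc$config),
            class = "mde_dataset")
}
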