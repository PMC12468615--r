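## Multiscale extensions of ASPE.
##
## Two scale families: refined composite coarse-graining (window averages at
## every phase, pattern distributions averaged before the entropy is taken)
## and time-shift subsampling (strided subsequences, entropies averaged).

#' Composite coarse-grained subsequences at one scale
#'
#' At scale `s` the series is averaged over non-overlapping windows of width
#' `s`, once for each of the `s` possible window phases.  Subsequence `k`
#' (k = 1..s) has element `j = mean(x[(j-1)s+k], ..., x[js+k-1])`; trailing
#' samples that do not fill a window are dropped.
#'
#' @param x Numeric vector.
#' @param s Scale factor, integer >= 1.
#' @param min_length Minimum admissible subsequence length (callers pass the
#'   embedding minimum `(m-1)*tau + 1`).
#' @return A list of `s` numeric vectors.
#' @examples
#' composite_coarse_grain(1:6, 2)  # list(c(1.5, 3.5, 5.5), c(2.5, 4.5))
#' @export
composite_coarse_grain <- function(x, s, min_length = 2L) {
  if (s < 1L || s != round(s)) stop("scale s must be a positive integer", call. = FALSE)
  n <- length(x)
  shortest <- floor((n - s + 1) / s)
  if (shortest < min_length)
    stop(sprintf("scale %d too large for series of length %d: shortest coarse-grained subsequence has %d < %d samples",
                 s, n, shortest, min_length), call. = FALSE)
  if (s == 1L) return(list(x))
  cs <- c(0, cumsum(x))
  lapply(seq_len(s), function(k) {
    len <- floor((n - k + 1) / s)
    starts <- (seq_len(len) - 1L) * s + k
    (cs[starts + s] - cs[starts]) / s
  })
}

#' Refined composite multiscale ASPE profile
#'
#' For each scale `s = 1..s_max` the weighted ordinal-pattern distributions
#' of the `s` coarse-grained subsequences are averaged bin-wise (absent
#' patterns contribute 0) and the normalized Shannon entropy of the averaged
#' distribution is returned.  Averaging distributions before taking the
#' entropy is what makes the composite estimate stable on short series.
#'
#' @inheritParams pattern_distribution
#' @param s_max Maximum scale factor (default 10).
#' @return Numeric vector of length `s_max`, entries in `[0, 1]`; entry 1
#'   equals `aspe(x)` exactly.
#' @export
rcmaspe <- function(x, m = 3L, tau = 1L, s_max = 10L, weighted = TRUE,
                    sd_denom = "sample") {
  check_embedding(m, tau)
  min_len <- (m - 1L) * tau + 1L
  vapply(seq_len(s_max), function(s) {
    subs <- composite_coarse_grain(x, s, min_length = min_len)
    dists <- lapply(subs, function(z)
      pattern_distribution(z, m, tau, weighted = weighted, sd_denom = sd_denom)$probs)
    avg <- average_distributions(dists)
    normalized_entropy(avg, m)
  }, numeric(1))
}

## Bin-wise mean of sparse named probability vectors over the m! patterns.
average_distributions <- function(dists) {
  keys <- unique(unlist(lapply(dists, names)))
  acc <- stats::setNames(numeric(length(keys)), keys)
  for (d in dists) acc[names(d)] <- acc[names(d)] + d
  acc / length(dists)
}

#' Time-shifted subsequences at one lag
#'
#' Subsequence `j` (j = 1..k) is the decimated series
#' `(x[j], x[j+k], x[j+2k], ...)` up to the last index within the series.
#'
#' @param x Numeric vector.
#' @param k Lag factor, integer >= 1.
#' @param min_length Minimum admissible subsequence length.
#' @return A list of `k` numeric vectors.
#' @examples
#' time_shift_subsequences(1:6, 2)  # list(c(1, 3, 5), c(2, 4, 6))
#' @export
time_shift_subsequences <- function(x, k, min_length = 2L) {
  if (k < 1L || k != round(k)) stop("lag k must be a positive integer", call. = FALSE)
  n <- length(x)
  shortest <- floor((n - k) / k) + 1L
  if (shortest < min_length)
    stop(sprintf("lag %d too large for series of length %d: shortest subsequence has %d < %d samples",
                 k, n, shortest, min_length), call. = FALSE)
  lapply(seq_len(k), function(j) x[seq(j, n, by = k)])
}

#' Time-shift multiscale ASPE profile
#'
#' Entry `k` is the mean ASPE over the `k` time-shifted subsequences at lag
#' `k`, probing deterministic structure at different sampling strides.
#'
#' @inheritParams pattern_distribution
#' @param k_max Maximum lag factor (default 10).
#' @return Numeric vector of length `k_max`, entries in `[0, 1]`; entry 1
#'   equals `aspe(x)` exactly.
#' @export
tsmaspe <- function(x, m = 3L, tau = 1L, k_max = 10L, weighted = TRUE,
                    sd_denom = "sample") {
  check_embedding(m, tau)
  min_len <- (m - 1L) * tau + 1L
  vapply(seq_len(k_max), function(k) {
    subs <- time_shift_subsequences(x, k, min_length = min_len)
    mean(vapply(subs, aspe, numeric(1), m = m, tau = tau,
                weighted = weighted, sd_denom = sd_denom))
  }, numeric(1))
}
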