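## Amplitude-sensitive permutation entropy (ASPE).
##
## A series is embedded into delay vectors, each vector is reduced to its
## ordinal pattern (the permutation that sorts it), and pattern frequencies
## are weighted by each vector's coefficient of variation so that
## high-amplitude excursions count more than flat stretches.  The normalized
## Shannon entropy of the weighted pattern distribution is the ASPE value.

#' Delay embedding of a univariate series
#'
#' Reconstructs the phase space of a scalar series: row `i` of the result is
#' `(x[i], x[i+tau], ..., x[i+(m-1)*tau])`.
#'
#' @param x Numeric vector, the signal samples (finite).
#' @param m Embedding dimension, integer >= 2.
#' @param tau Time delay in samples, integer >= 1.
#' @return A numeric matrix with `length(x) - (m-1)*tau` rows and `m` columns.
#' @examples
#' embed_series(c(1, 2, 3, 4), m = 2, tau = 1)
#' @export
embed_series <- function(x, m = 3L, tau = 1L) {
  check_embedding(m, tau)
  x <- as.numeric(x)
  if (anyNA(x) || any(!is.finite(x)))
    stop("signal contains non-finite samples", call. = FALSE)
  tmin <- (m - 1L) * tau + 1L
  n <- length(x)
  if (n < tmin)
    stop(sprintf("series of length %d too short for embedding: need at least (m-1)*tau+1 = %d samples",
                 n, tmin), call. = FALSE)
  n_vec <- n - (m - 1L) * tau
  idx <- outer(seq_len(n_vec), (seq_len(m) - 1L) * tau, `+`)
  matrix(x[idx], nrow = n_vec, ncol = m)
}

check_embedding <- function(m, tau) {
  if (length(m) != 1L || m < 2L || m != round(m))
    stop("embedding dimension m must be a single integer >= 2", call. = FALSE)
  if (m > 10L)
    stop("embedding dimension m must be <= 10 (m! must stay representable)", call. = FALSE)
  if (length(tau) != 1L || tau < 1L || tau != round(tau))
    stop("time delay tau must be a single integer >= 1", call. = FALSE)
  invisible(TRUE)
}

#' Ordinal pattern of an embedded vector
#'
#' Returns the 0-based index sequence that sorts `y` ascending.  Ties are
#' broken by the earlier original index (stable), the dominant convention in
#' the permutation-entropy literature.
#'
#' @param y Numeric vector of length `m`.
#' @return Integer vector, a permutation of `0:(length(y)-1)`.
#' @examples
#' ordinal_pattern(c(1, 3, 2))  # 0 2 1
#' ordinal_pattern(c(2, 2, 1))  # 2 0 1
#' @export
ordinal_pattern <- function(y) {
  if (any(!is.finite(y))) stop("vector contains non-finite elements", call. = FALSE)
  order(y) - 1L
}

#' Amplitude weight of an embedded vector
#'
#' The coefficient of variation `sd(y) / |mean(y)|` of the vector's elements,
#' with the denominator floored at a small epsilon so zero-mean vectors
#' (ubiquitous in zero-mean EEG) get a finite, nonnegative weight.
#'
#' @param y Numeric vector with at least 2 finite elements.
#' @param eps Denominator floor; defaults to `1e-12` (callers working on a
#'   whole signal scale it by the signal range, see [aspe()]).
#' @param sd_denom `"sample"` for the n-1 standard deviation (default, the
#'   convention of the numerical environment the method was developed in) or
#'   `"population"` for n.
#' @return A single nonnegative finite number.
#' @examples
#' amplitude_weight(c(1, 2, 3))  # sd 1, mean 2 -> 0.5
#' @export
amplitude_weight <- function(y, eps = 1e-12, sd_denom = c("sample", "population")) {
  sd_denom <- match.arg(sd_denom)
  if (length(y) < 2L) stop("vector must have at least 2 elements", call. = FALSE)
  if (any(!is.finite(y))) stop("vector contains non-finite elements", call. = FALSE)
  s <- stats::sd(y)
  if (sd_denom == "population") s <- s * sqrt((length(y) - 1) / length(y))
  s / max(abs(mean(y)), eps)
}

## Vectorised weights for an embedding matrix.
amplitude_weights <- function(Y, eps, sd_denom = "sample") {
  m <- ncol(Y)
  mu <- rowMeans(Y)
  ss <- rowSums((Y - mu)^2)
  s <- sqrt(ss / (m - 1))
  if (sd_denom == "population") s <- sqrt(ss / m)
  s / pmax(abs(mu), eps)
}

## Integer-free pattern codes: per-row ranks with stable ties, packed in base
## m.  Two rows share a code iff they share an ordinal pattern.  Exact for
## m <= 10 (codes < m^m < 2^53).
pattern_codes <- function(Y) {
  m <- ncol(Y)
  r <- matrix(1, nrow(Y), m)
  for (j in seq_len(m)) {
    for (k in seq_len(m)) {
      if (k == j) next
      if (k < j) r[, j] <- r[, j] + (Y[, k] <= Y[, j])
      else       r[, j] <- r[, j] + (Y[, k] <  Y[, j])
    }
  }
  codes <- numeric(nrow(Y))
  for (j in seq_len(m)) codes <- codes + (r[, j] - 1) * m^(j - 1)
  codes
}

## Decode a packed rank code back into the 0-based sorting permutation label.
decode_pattern <- function(code, m) {
  r <- integer(m)
  for (j in seq_len(m)) {
    r[j] <- code %% m
    code <- (code - r[j]) / m
  }
  paste(order(r) - 1L, collapse = "-")
}

#' Weighted ordinal-pattern distribution of a series
#'
#' Embeds the series, weights every embedded vector by its coefficient of
#' variation and tallies the weighted relative frequency of each ordinal
#' pattern.  If the total weight is zero (a constant signal) the distribution
#' falls back to plain (unweighted) relative frequencies.
#'
#' @inheritParams embed_series
#' @param weighted Logical; `FALSE` gives ordinary permutation-entropy
#'   frequencies.
#' @param sd_denom Passed to the amplitude weights, see [amplitude_weight()].
#' @return An object of class `"pattern_distribution"`: a list with `probs`
#'   (named numeric vector, names are 0-based patterns such as `"0-2-1"`),
#'   `m`, `n_vectors` and `total_weight`.
#' @seealso [aspe()]
#' @export
pattern_distribution <- function(x, m = 3L, tau = 1L, weighted = TRUE,
                                 sd_denom = "sample") {
  Y <- embed_series(x, m, tau)
  rng <- diff(range(x))
  eps <- 1e-12 * if (rng > 0) rng else 1
  w <- if (weighted) amplitude_weights(Y, eps, sd_denom) else rep(1, nrow(Y))
  if (any(w < 0)) stop("negative amplitude weight", call. = FALSE)
  codes <- pattern_codes(Y)
  tw <- sum(w)
  if (tw <= 0) {  # constant signal: unweighted fallback
    w <- rep(1, nrow(Y))
    tw <- sum(w)
  }
  agg <- rowsum(w, group = codes)
  probs <- as.numeric(agg) / tw
  names(probs) <- vapply(as.numeric(rownames(agg)), decode_pattern, "", m = m)
  structure(list(probs = probs, m = m, n_vectors = nrow(Y), total_weight = tw),
            class = "pattern_distribution")
}

#' @export
print.pattern_distribution <- function(x, ...) {
  cat(sprintf("Weighted ordinal-pattern distribution (m = %d, N = %d vectors)\n",
              x$m, x$n_vectors))
  print(round(x$probs, 4))
  invisible(x)
}

## Normalized Shannon entropy of a probability vector over m! patterns,
## clamped into [0, 1] against rounding residue (a single-pattern
## distribution must score exactly 0, never -1e-16).
normalized_entropy <- function(p, m) {
  p <- p[p > 0]
  h <- -sum(p * log2(p))
  min(max(h / log2(factorial(m)), 0), 1)
}

#' Amplitude-sensitive permutation entropy
#'
#' The normalized Shannon entropy (base 2, `0 * log 0 = 0`) of the weighted
#' ordinal-pattern distribution, divided by `log2(m!)` so the result lies in
#' `[0, 1]`.  A strictly monotone series scores exactly 0; iid noise scores
#' close to 1.  The value is invariant under positive rescaling of the signal.
#'
#' @inheritParams pattern_distribution
#' @return A single number in `[0, 1]`.
#' @examples
#' aspe(sin(seq(0, 20, by = 0.1)))
#' aspe(1:100)  # monotone: exactly 0
#' @export
aspe <- function(x, m = 3L, tau = 1L, weighted = TRUE, sd_denom = "sample") {
  d <- pattern_distribution(x, m, tau, weighted = weighted, sd_denom = sd_denom)
  normalized_entropy(d$probs, m)
}
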