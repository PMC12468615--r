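# Independent brute-force oracles: explicit loops and dictionary tallies,
# sharing no code with the package internals they check.

oracle_aspe <- function(x, m = 3L, tau = 1L) {
  n_vec <- length(x) - (m - 1L) * tau
  rng <- diff(range(x))
  eps <- 1e-12 * if (rng > 0) rng else 1
  tally <- new.env()
  wtot <- 0
  for (i in seq_len(n_vec)) {
    y <- x[i + (0:(m - 1L)) * tau]
    w <- stats::sd(y) / max(abs(mean(y)), eps)
    key <- paste(order(y) - 1L, collapse = "-")
    prev <- if (is.null(tally[[key]])) 0 else tally[[key]]
    tally[[key]] <- prev + w
    wtot <- wtot + w
  }
  if (wtot <= 0) {  # constant signal: unweighted tally
    for (k in ls(tally)) tally[[k]] <- NULL
    for (i in seq_len(n_vec)) {
      y <- x[i + (0:(m - 1L)) * tau]
      key <- paste(order(y) - 1L, collapse = "-")
      prev <- if (is.null(tally[[key]])) 0 else tally[[key]]
      tally[[key]] <- prev + 1
    }
    wtot <- n_vec
  }
  p <- unlist(as.list(tally)) / wtot
  p <- p[p > 0]
  -sum(p * log2(p)) / log2(factorial(m))
}

# sparse named probability distribution by the same explicit tally
oracle_distribution <- function(x, m = 3L, tau = 1L) {
  n_vec <- length(x) - (m - 1L) * tau
  rng <- diff(range(x))
  eps <- 1e-12 * if (rng > 0) rng else 1
  tally <- list()
  wtot <- 0
  for (i in seq_len(n_vec)) {
    y <- x[i + (0:(m - 1L)) * tau]
    w <- stats::sd(y) / max(abs(mean(y)), eps)
    key <- paste(order(y) - 1L, collapse = "-")
    tally[[key]] <- (if (is.null(tally[[key]])) 0 else tally[[key]]) + w
    wtot <- wtot + w
  }
  unlist(tally) / wtot
}

oracle_rcmaspe_scale <- function(x, s, m = 3L, tau = 1L) {
  n <- length(x)
  dists <- list()
  for (k in seq_len(s)) {
    len <- floor((n - k + 1) / s)
    sub <- numeric(len)
    for (j in seq_len(len)) sub[j] <- mean(x[((j - 1) * s + k):(j * s + k - 1)])
    dists[[k]] <- oracle_distribution(sub, m, tau)
  }
  keys <- unique(unlist(lapply(dists, names)))
  avg <- stats::setNames(numeric(length(keys)), keys)
  for (d in dists) avg[names(d)] <- avg[names(d)] + d
  avg <- avg / s
  avg <- avg[avg > 0]
  -sum(avg * log2(avg)) / log2(factorial(m))
}

oracle_tsmaspe_lag <- function(x, k, m = 3L, tau = 1L) {
  vals <- numeric(k)
  for (j in seq_len(k)) vals[j] <- oracle_aspe(x[seq(j, length(x), by = k)], m, tau)
  mean(vals)
}

random_series <- function(seed, n) {
  set.seed(seed)
  stats::rnorm(n)
}
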