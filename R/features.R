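## Assembly of the multi-domain entropy (MDE) feature set.
##
## Three grouped pathway inputs per signal:
##   x_m  multiscale pathway: ASPE followed by the RCMASPE profile (1 + s_max)
##   x_h  hierarchical pathway: HASPE-DWT over the L+1 wavelet bands
##   x_t  time-invariant pathway: TSMASPE profile (k_max)

#' MDE extraction configuration
#'
#' Bundles every entropy parameter with its default: embedding dimension 3,
#' delay 1, maximum coarse-graining scale 10, db4 wavelet at depth 4
#' (appropriate for 173.61 Hz single-channel recordings; use `level = 5` for
#' 256 Hz recordings), maximum time-lag factor 10.
#'
#' @param m,tau Embedding dimension and delay.
#' @param s_max Maximum coarse-graining scale.
#' @param level,basis Wavelet decomposition depth and family.
#' @param extension Wavelet boundary extension, see [dwt_decompose()].
#' @param k_max Maximum time-lag factor.
#' @param weighted,sd_denom Passed through to [aspe()].
#' @return A list of class `"mde_config"`.
#' @export
mde_config <- function(m = 3L, tau = 1L, s_max = 10L, level = 4L,
                       basis = "db4", extension = "smooth", k_max = 10L,
                       weighted = TRUE, sd_denom = "sample") {
  check_embedding(m, tau)
  stopifnot(s_max >= 1L, k_max >= 1L, level >= 1L)
  structure(list(m = as.integer(m), tau = as.integer(tau),
                 s_max = as.integer(s_max), level = as.integer(level),
                 basis = basis, extension = extension,
                 k_max = as.integer(k_max),
                 weighted = isTRUE(weighted), sd_denom = sd_denom),
            class = "mde_config")
}

#' Dimensions of the three pathway inputs for a configuration
#' @param config An [mde_config()].
#' @return Named integer vector `c(d_m, d_h, d_t)`.
#' @export
mde_dims <- function(config = mde_config()) {
  c(d_m = 1L + config$s_max, d_h = config$level + 1L, d_t = config$k_max)
}

#' Extract the grouped MDE features of one signal
#'
#' Deterministic, pure function of the samples and configuration.  All
#' entries are normalized entropies in `[0, 1]` and the whole vector is
#' invariant under positive rescaling of the signal.
#'
#' @param x Numeric vector of samples.
#' @param config An [mde_config()].
#' @return An object of class `"mde_features"`: list with `x_m`, `x_h`,
#'   `x_t` (named numeric vectors) and the `config`.
#' @examples
#' f <- extract_mde(generate_ictal(seed = 1), mde_config())
#' lengths(f[c("x_m", "x_h", "x_t")])
#' @export
extract_mde <- function(x, config = mde_config()) {
  cfg <- config
  wrap <- function(what, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("%s extraction failed: %s", what, conditionMessage(e)),
           call. = FALSE))
  }
  a <- wrap("ASPE", aspe(x, cfg$m, cfg$tau, cfg$weighted, cfg$sd_denom))
  r <- wrap("RCMASPE", rcmaspe(x, cfg$m, cfg$tau, cfg$s_max, cfg$weighted, cfg$sd_denom))
  h <- wrap("HASPE-DWT", haspe_dwt(x, cfg$m, cfg$tau, cfg$level, cfg$basis,
                                   cfg$extension, cfg$weighted, cfg$sd_denom))
  t_ <- wrap("TSMASPE", tsmaspe(x, cfg$m, cfg$tau, cfg$k_max, cfg$weighted, cfg$sd_denom))
  x_m <- stats::setNames(c(a, r), paste0("m_", 0:cfg$s_max))
  x_h <- stats::setNames(as.numeric(h), paste0("h_", 0:cfg$level))
  x_t <- stats::setNames(t_, paste0("t_", seq_len(cfg$k_max)))
  structure(list(x_m = x_m, x_h = x_h, x_t = x_t, config = cfg),
            class = "mde_features")
}

#' @export
print.mde_features <- function(x, ...) {
  cat("MDE features\n")
  cat("  x_m:", paste(round(x$x_m, 3), collapse = " "), "\n")
  cat("  x_h:", paste(round(x$x_h, 3), collapse = " "), "\n")
  cat("  x_t:", paste(round(x$x_t, 3), collapse = " "), "\n")
  invisible(x)
}

#' Flatten grouped MDE features to a single named vector
#' @param x An `"mde_features"` object.
#' @param ... Unused.
#' @return Named numeric vector `[x_m, x_h, x_t]`.
#' @export
as.double.mde_features <- function(x, ...) c(x$x_m, x$x_h, x$x_t)

#' MDE feature matrix for a collection of signals
#'
#' @param signals A list of numeric vectors (e.g. from [generate_dataset()]).
#' @param config An [mde_config()].
#' @return Numeric matrix, one row per signal, columns `m_0..`, `h_0..`,
#'   `t_1..`, with attribute `"dims"` holding [mde_dims()].
#' @export
mde_feature_matrix <- function(signals, config = mde_config()) {
  rows <- lapply(signals, function(s) as.numeric(extract_mde(s, config)))
  X <- do.call(rbind, rows)
  dims <- mde_dims(config)
  colnames(X) <- c(paste0("m_", 0:config$s_max), paste0("h_", 0:config$level),
                   paste0("t_", seq_len(config$k_max)))
  attr(X, "dims") <- dims
  X
}

#' Fit per-feature standardization statistics on training data
#'
#' Location and scale (mean and standard deviation) per feature, with the
#' scale floored at `1e-12` so constant features map to zero rather than NaN.
#' Fit on training folds only and applied unchanged to test folds.
#'
#' @param X Numeric training feature matrix (rows = samples).
#' @return A list of class `"mde_standardizer"` with `center` and `scale`.
#' @export
fit_standardizer <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop("need at least 2 training samples", call. = FALSE)
  center <- colMeans(X)
  scale <- apply(X, 2L, stats::sd)
  degenerate <- scale < 1e-12
  if (any(degenerate)) scale[degenerate] <- 1e-12
  structure(list(center = center, scale = scale, degenerate = degenerate),
            class = "mde_standardizer")
}

#' Apply fitted standardization statistics
#' @param X Numeric feature matrix.
#' @param stats An [fit_standardizer()] result.
#' @return Standardized matrix of the same shape.
#' @export
apply_standardizer <- function(X, stats) {
  stopifnot(inherits(stats, "mde_standardizer"))
  X <- as.matrix(X)
  Z <- sweep(sweep(X, 2L, stats$center, `-`), 2L, stats$scale, `/`)
  Z[, stats$degenerate] <- 0
  Z
}

#' Write / read a labeled feature table as CSV
#'
#' Plain CSV with the feature columns followed by a `label` column; numeric
#' values round-trip losslessly (written with 17 significant digits).
#'
#' @param X Feature matrix.
#' @param labels Vector of class labels, one per row.
#' @param path Output file.
#' @return `write_feature_table` returns `path` invisibly;
#'   `read_feature_table` returns a list with `X` (matrix) and `labels`.
#' @export
write_feature_table <- function(X, labels, path) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(labels))
  df <- as.data.frame(matrix(sprintf("%.17g", X), nrow(X), ncol(X)),
                      stringsAsFactors = FALSE)
  colnames(df) <- colnames(X)
  df$label <- as.character(labels)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"label" %in% colnames(df))
    stop("feature table has no 'label' column", call. = FALSE)
  labels <- df$label
  df$label <- NULL
  X <- as.matrix(as.data.frame(lapply(df, as.numeric)))
  colnames(X) <- colnames(df)
  list(X = X, labels = labels)
}
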