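## The dynamic synapse classifier (DySC).
##
## Three parallel pathways, each multiplicatively modulated by a gate whose
## form matches the semantics of its feature group:
##   hierarchical   G_h = tanh(x_h * W_h_att), x_h' = x_h * G_h
##                  (frequency-band attention, input-dependent)
##   time-invariant g_t = exp(-gamma * Var(x_t)), x_t' = g_t * x_t
##                  (stability gain: consistent lag profiles pass through)
##   multiscale     x_m' = x_m * W_m_att  (learned static mask)
## Each modulated group is compressed by a tanh layer of width
## `hidden_pathway`, the three representations are concatenated, passed
## through one tanh fusion layer of width `hidden_fusion`, then a linear
## softmax output.  All parameters are trained jointly by full-batch BFGS on
## the cross-entropy loss with an analytic gradient.

softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))
softplus_inv <- function(y) ifelse(y > 30, y, log(expm1(y)))

#' Hierarchical (frequency-band attention) gate
#'
#' @param x_h Numeric vector of hierarchical-pathway features.
#' @param w_att Learnable attention vector, same length as `x_h`.
#' @return List with `gate` (`tanh(x_h * w_att)`, entries in (-1, 1)) and
#'   `x_mod` (`x_h * gate`).
#' @export
gate_hierarchical <- function(x_h, w_att) {
  if (length(x_h) != length(w_att))
    stop("attention vector length must match the feature vector", call. = FALSE)
  g <- tanh(x_h * w_att)
  list(gate = g, x_mod = x_h * g)
}

#' Time-invariant (stability) gate
#'
#' A scalar gain `exp(-gamma * Var(x_t))` (sample variance, n-1 denominator):
#' near 1 when the lag profile is flat/consistent, shrinking toward 0 as the
#' profile becomes erratic.
#'
#' @param x_t Numeric vector of time-invariant-pathway features (length >= 2).
#' @param gamma Positive sensitivity scalar.
#' @return List with `gate` (scalar in (0, 1]) and `x_mod` (`gate * x_t`).
#' @export
gate_time_invariant <- function(x_t, gamma) {
  if (gamma <= 0) stop("gamma must be positive", call. = FALSE)
  if (length(x_t) < 2L) stop("x_t must have at least 2 elements", call. = FALSE)
  g <- exp(-gamma * stats::var(x_t))
  list(gate = g, x_mod = g * x_t)
}

#' Multiscale (static mask) gate
#' @param x_m Numeric vector of multiscale-pathway features.
#' @param w_att Learned input-independent mask, same length.
#' @return `x_m * w_att`.
#' @export
gate_multiscale <- function(x_m, w_att) {
  if (length(x_m) != length(w_att))
    stop("mask length must match the feature vector", call. = FALSE)
  x_m * w_att
}

#' Pathway fusion layer
#' @param x Modulated pathway input (vector, or matrix of rows).
#' @param W Weight matrix (`length(x)` x width).
#' @param b Bias vector (width).
#' @return `tanh(x %*% W + b)`, entries in (-1, 1).
#' @export
pathway_fuse <- function(x, W, b) {
  x <- if (is.matrix(x)) x else matrix(x, nrow = 1L)
  if (ncol(x) != nrow(W) || ncol(W) != length(b))
    stop("fusion layer shape mismatch", call. = FALSE)
  tanh(sweep(x %*% W, 2L, b, `+`))
}

## Row-wise softmax with max subtraction.
softmax_rows <- function(Z) {
  Zs <- Z - apply(Z, 1L, max)
  E <- exp(Zs)
  E / rowSums(E)
}

#' Multi-class cross-entropy loss
#'
#' Mean negative log-probability of the true class (natural log, predicted
#' probabilities floored at `1e-15`).
#'
#' @param P Matrix of class probabilities, one row per sample.
#' @param y Integer class labels in `1..ncol(P)` (or a factor).
#' @return A single nonnegative number.
#' @export
cross_entropy <- function(P, y) {
  P <- if (is.matrix(P)) P else matrix(P, nrow = 1L)
  y <- if (is.factor(y)) as.integer(y) else as.integer(y)
  if (length(y) != nrow(P)) stop("batch size mismatch", call. = FALSE)
  if (any(y < 1L | y > ncol(P))) stop("label outside 1..K", call. = FALSE)
  p_true <- pmax(P[cbind(seq_len(nrow(P)), y)], 1e-15)
  -mean(log(p_true))
}

## ---- parameter plumbing -------------------------------------------------

dysc_layout <- function(dims) {
  with(dims, {
    sizes <- c(w_h_att = dh, gamma_raw = 1L, w_m_att = dm,
               W_m = dm * Hp, b_m = Hp, W_h = dh * Hp, b_h = Hp,
               W_t = dt * Hp, b_t = Hp,
               W_f = 3L * Hp * Hf, b_f = Hf, W_o = Hf * K, b_o = K)
    ends <- cumsum(sizes)
    starts <- ends - sizes + 1L
    list(sizes = sizes, starts = starts, ends = ends, total = sum(sizes))
  })
}

dysc_unpack <- function(flat, dims) {
  lay <- dysc_layout(dims)
  g <- function(nm) flat[lay$starts[[nm]]:lay$ends[[nm]]]
  with(dims, list(
    w_h_att = g("w_h_att"), gamma_raw = g("gamma_raw"), w_m_att = g("w_m_att"),
    W_m = matrix(g("W_m"), dm, Hp), b_m = g("b_m"),
    W_h = matrix(g("W_h"), dh, Hp), b_h = g("b_h"),
    W_t = matrix(g("W_t"), dt, Hp), b_t = g("b_t"),
    W_f = matrix(g("W_f"), 3L * Hp, Hf), b_f = g("b_f"),
    W_o = matrix(g("W_o"), Hf, K), b_o = g("b_o")))
}

dysc_pack <- function(th) {
  c(th$w_h_att, th$gamma_raw, th$w_m_att,
    as.numeric(th$W_m), th$b_m, as.numeric(th$W_h), th$b_h,
    as.numeric(th$W_t), th$b_t, as.numeric(th$W_f), th$b_f,
    as.numeric(th$W_o), th$b_o)
}

## Neutral gates (all-ones attention and mask, gamma = 1), fan-in scaled
## uniform fusion/output weights, zero biases.
dysc_init <- function(dims, seed = 1L, init_scale = NULL) {
  set.seed(seed)
  uni <- function(nr, nc) {
    a <- if (is.null(init_scale)) 1 / sqrt(nr) else init_scale
    matrix(stats::runif(nr * nc, -a, a), nr, nc)
  }
  with(dims, list(
    w_h_att = rep(1, dh), gamma_raw = softplus_inv(1), w_m_att = rep(1, dm),
    W_m = uni(dm, Hp), b_m = numeric(Hp),
    W_h = uni(dh, Hp), b_h = numeric(Hp),
    W_t = uni(dt, Hp), b_t = numeric(Hp),
    W_f = uni(3L * Hp, Hf), b_f = numeric(Hf),
    W_o = uni(Hf, K), b_o = numeric(K)))
}

## ---- forward / backward -------------------------------------------------

## Batched forward pass; keeps every intermediate needed by the backward
## pass.  Xm, Xh, Xt are n x d matrices.
dysc_forward <- function(th, Xm, Xh, Xt) {
  n <- nrow(Xm)
  gamma <- softplus(th$gamma_raw)
  Xm1 <- sweep(Xm, 2L, th$w_m_att, `*`)
  Gh <- tanh(sweep(Xh, 2L, th$w_h_att, `*`))
  Xh1 <- Xh * Gh
  mu <- rowMeans(Xt)
  vart <- rowSums((Xt - mu)^2) / (ncol(Xt) - 1L)
  g <- exp(-gamma * vart)
  Xt1 <- Xt * g
  Fm <- tanh(sweep(Xm1 %*% th$W_m, 2L, th$b_m, `+`))
  Fh <- tanh(sweep(Xh1 %*% th$W_h, 2L, th$b_h, `+`))
  Ft <- tanh(sweep(Xt1 %*% th$W_t, 2L, th$b_t, `+`))
  Fc <- cbind(Fm, Fh, Ft)
  Hh <- tanh(sweep(Fc %*% th$W_f, 2L, th$b_f, `+`))
  Z <- sweep(Hh %*% th$W_o, 2L, th$b_o, `+`)
  P <- softmax_rows(Z)
  list(P = P, Z = Z, Hh = Hh, Fc = Fc, Fm = Fm, Fh = Fh, Ft = Ft,
       Gh = Gh, g = g, vart = vart, gamma = gamma,
       Xm1 = Xm1, Xh1 = Xh1, Xt1 = Xt1, n = n)
}

## Loss and analytic gradient of the cross-entropy through the whole network
## with respect to the flat parameter vector.
dysc_loss_grad <- function(flat, dims, Xm, Xh, Xt, y) {
  th <- dysc_unpack(flat, dims)
  fw <- dysc_forward(th, Xm, Xh, Xt)
  n <- fw$n
  K <- dims$K
  Hp <- dims$Hp
  loss <- cross_entropy(fw$P, y)
  if (!is.finite(loss))
    stop("non-finite loss; parameter vector may have diverged", call. = FALSE)
  Yoh <- matrix(0, n, K)
  Yoh[cbind(seq_len(n), as.integer(y))] <- 1
  dZ <- (fw$P - Yoh) / n
  gW_o <- crossprod(fw$Hh, dZ)
  gb_o <- colSums(dZ)
  dAu <- (dZ %*% t(th$W_o)) * (1 - fw$Hh^2)
  gW_f <- crossprod(fw$Fc, dAu)
  gb_f <- colSums(dAu)
  dFc <- dAu %*% t(th$W_f)
  dAm <- dFc[, 1:Hp, drop = FALSE] * (1 - fw$Fm^2)
  dAh <- dFc[, (Hp + 1L):(2L * Hp), drop = FALSE] * (1 - fw$Fh^2)
  dAt <- dFc[, (2L * Hp + 1L):(3L * Hp), drop = FALSE] * (1 - fw$Ft^2)
  gW_m <- crossprod(fw$Xm1, dAm); gb_m <- colSums(dAm)
  gW_h <- crossprod(fw$Xh1, dAh); gb_h <- colSums(dAh)
  gW_t <- crossprod(fw$Xt1, dAt); gb_t <- colSums(dAt)
  dXm1 <- dAm %*% t(th$W_m)
  dXh1 <- dAh %*% t(th$W_h)
  dXt1 <- dAt %*% t(th$W_t)
  g_w_m_att <- colSums(dXm1 * Xm)
  g_w_h_att <- colSums(dXh1 * Xh * Xh * (1 - fw$Gh^2))
  dg <- rowSums(dXt1 * Xt)
  g_gamma <- sum(dg * (-fw$vart) * fw$g)
  g_gamma_raw <- g_gamma * stats::plogis(th$gamma_raw)
  grad <- dysc_pack(list(
    w_h_att = g_w_h_att, gamma_raw = g_gamma_raw, w_m_att = g_w_m_att,
    W_m = gW_m, b_m = gb_m, W_h = gW_h, b_h = gb_h, W_t = gW_t, b_t = gb_t,
    W_f = gW_f, b_f = gb_f, W_o = gW_o, b_o = gb_o))
  list(loss = loss, grad = grad)
}

split_groups <- function(X, dims) {
  dm <- dims$dm; dh <- dims$dh; dt <- dims$dt
  if (ncol(X) != dm + dh + dt)
    stop(sprintf("feature matrix has %d columns; expected d_m + d_h + d_t = %d",
                 ncol(X), dm + dh + dt), call. = FALSE)
  list(Xm = X[, 1:dm, drop = FALSE],
       Xh = X[, (dm + 1L):(dm + dh), drop = FALSE],
       Xt = X[, (dm + dh + 1L):(dm + dh + dt), drop = FALSE])
}

## ---- fitting ------------------------------------------------------------

#' Fit the dynamic synapse classifier
#'
#' Trains the three-pathway gated network on a labeled MDE feature matrix by
#' full-batch BFGS minimization of the cross-entropy loss, using the analytic
#' gradient.  Deterministic for a fixed `seed` (initialization of the fusion
#' and output weights is the only randomness; gates start neutral so early
#' optimization sees undistorted features).
#'
#' @param x Numeric feature matrix, one row per sample, columns grouped as
#'   `[x_m, x_h, x_t]`.  Group widths are taken from `attr(x, "dims")` (as
#'   set by [mde_feature_matrix()]) unless `dims` is given.
#' @param y Class labels (factor or coercible); at least 2 classes.
#' @param dims Optional integer vector `c(d_m, d_h, d_t)`.
#' @param hidden_pathway Width of each pathway's compression layer (default 16).
#' @param hidden_fusion Width of the cross-pathway fusion layer (default 32).
#' @param max_iter BFGS iteration cap (default 50).
#' @param max_feval Function-evaluation budget recorded with the model
#'   (default 1e6; the iteration cap binds first in practice).
#' @param standardize Z-score features with training statistics before the
#'   network (default `TRUE`; the gates are scale-sensitive).
#' @param seed Integer seed for weight initialization.
#' @param init_scale Optional half-width of the uniform weight
#'   initialization; default `1/sqrt(fan-in)` per layer.
#' @return An object of class `"dysc"` with components `params`, `dims`,
#'   `levels`, `standardizer`, `loss`, `initial_loss`, `counts`,
#'   `convergence` and `seed`.  Methods: [predict.dysc()], `print`,
#'   `summary`, `coef`, `plot`.
#' @examples
#' set.seed(1)
#' X <- cbind(matrix(rnorm(60 * 4), 60), matrix(rnorm(60 * 3), 60),
#'            matrix(rnorm(60 * 3), 60))
#' X[31:60, 1] <- X[31:60, 1] + 3
#' fit <- dysc(X, rep(c("a", "b"), each = 30), dims = c(4, 3, 3),
#'             hidden_pathway = 4, hidden_fusion = 8, seed = 2)
#' table(predict(fit, X), rep(c("a", "b"), each = 30))
#' @export
dysc <- function(x, y, dims = NULL, hidden_pathway = 16L, hidden_fusion = 32L,
                 max_iter = 50L, max_feval = 1e6, standardize = TRUE,
                 seed = 1L, init_scale = NULL) {
  X <- as.matrix(x)
  if (is.null(dims)) dims <- attr(x, "dims")
  if (is.null(dims))
    stop("feature group dimensions unknown: pass dims = c(d_m, d_h, d_t)",
         call. = FALSE)
  y <- factor(y)
  if (nlevels(y) < 2L) stop("need at least 2 classes", call. = FALSE)
  if (nrow(X) < nlevels(y)) stop("need at least as many samples as classes", call. = FALSE)
  if (nrow(X) != length(y)) stop("x and y lengths differ", call. = FALSE)
  d <- list(dm = as.integer(dims[1L]), dh = as.integer(dims[2L]),
            dt = as.integer(dims[3L]), Hp = as.integer(hidden_pathway),
            Hf = as.integer(hidden_fusion), K = nlevels(y))
  std <- NULL
  if (isTRUE(standardize)) {
    std <- fit_standardizer(X)
    X <- apply_standardizer(X, std)
  }
  gr <- split_groups(X, d)
  yi <- as.integer(y)
  th0 <- dysc_init(d, seed = seed, init_scale = init_scale)
  flat0 <- dysc_pack(th0)
  fn <- function(p) dysc_loss_grad(p, d, gr$Xm, gr$Xh, gr$Xt, yi)$loss
  grd <- function(p) dysc_loss_grad(p, d, gr$Xm, gr$Xh, gr$Xt, yi)$grad
  loss0 <- fn(flat0)
  opt <- stats::optim(flat0, fn, grd, method = "BFGS",
                      control = list(maxit = as.integer(max_iter),
                                     reltol = 1e-10))
  structure(list(params = dysc_unpack(opt$par, d), flat = opt$par, dims = d,
                 levels = levels(y), standardizer = std, loss = opt$value,
                 initial_loss = loss0, counts = opt$counts,
                 convergence = opt$convergence, seed = as.integer(seed),
                 max_iter = as.integer(max_iter), max_feval = max_feval,
                 call = match.call()),
            class = "dysc")
}

#' Predict classes or class probabilities from a fitted DySC model
#'
#' @param object A fitted [dysc()] model.
#' @param newdata Feature matrix with the same column layout used for
#'   fitting (standardization statistics stored in the model are applied).
#' @param type `"class"` (default) for labels, `"prob"` for the softmax
#'   probability matrix.
#' @param ... Unused.
#' @return A factor of predicted labels, or a probability matrix with one
#'   column per class.  Ties in the probabilities resolve to the
#'   lower-indexed class.
#' @export
predict.dysc <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  X <- as.matrix(newdata)
  if (!is.null(object$standardizer)) X <- apply_standardizer(X, object$standardizer)
  gr <- split_groups(X, object$dims)
  P <- dysc_forward(object$params, gr$Xm, gr$Xh, gr$Xt)$P
  colnames(P) <- object$levels
  if (type == "prob") return(P)
  factor(object$levels[max.col(P, ties.method = "first")], levels = object$levels)
}

#' @export
print.dysc <- function(x, ...) {
  d <- x$dims
  cat("Dynamic synapse classifier\n")
  cat(sprintf("  pathways: d_m = %d, d_h = %d, d_t = %d -> %d -> fusion %d -> %d classes\n",
              d$dm, d$dh, d$dt, d$Hp, d$Hf, d$K))
  cat(sprintf("  classes: %s\n", paste(x$levels, collapse = ", ")))
  cat(sprintf("  cross-entropy: %.6f (from %.6f at initialization), %s\n",
              x$loss, x$initial_loss,
              if (x$convergence == 0) "converged" else
                sprintf("stopped at iteration cap %d", x$max_iter)))
  invisible(x)
}

#' @export
summary.dysc <- function(object, ...) {
  p <- object$params
  cat("Dynamic synapse classifier -- gate summary\n")
  cat("  hierarchical attention w_h_att:", paste(round(p$w_h_att, 3), collapse = " "), "\n")
  cat(sprintf("  stability sensitivity gamma: %.4f\n", softplus(p$gamma_raw)))
  cat("  multiscale mask w_m_att:", paste(round(p$w_m_att, 3), collapse = " "), "\n")
  cat(sprintf("  parameters: %d  |  final loss %.6f  |  gradient/function evals: %d/%d\n",
              length(object$flat), object$loss,
              object$counts[["gradient"]], object$counts[["function"]]))
  invisible(object)
}

#' @export
coef.dysc <- function(object, ...) {
  lay <- dysc_layout(object$dims)
  nm <- unlist(lapply(names(lay$sizes), function(k)
    if (lay$sizes[[k]] == 1L) k else paste0(k, "[", seq_len(lay$sizes[[k]]), "]")))
  stats::setNames(object$flat, nm)
}

#' Plot the learned gate parameters of a DySC model
#'
#' Shows the hierarchical attention vector and the multiscale mask as bar
#' charts (the stability sensitivity gamma is given in the title), the
#' model's main interpretable quantities: which wavelet bands and which
#' coarse-graining scales the classifier relies on.
#'
#' @param x A fitted [dysc()] model.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.dysc <- function(x, ...) {
  p <- x$params
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::barplot(p$w_h_att, names.arg = paste0("h", seq_along(p$w_h_att) - 1L),
                    main = sprintf("hierarchical attention (gamma = %.3f)",
                                   softplus(p$gamma_raw)),
                    ylab = "w_h_att", ...)
  graphics::barplot(p$w_m_att, names.arg = paste0("m", seq_along(p$w_m_att) - 1L),
                    main = "multiscale mask", ylab = "w_m_att", ...)
  invisible(x)
}

## ---- serialization ------------------------------------------------------

#' Save / load a fitted DySC model as versioned JSON
#'
#' All parameter arrays, dimensions, class levels, standardization
#' statistics and the training seed are stored at full precision, so a
#' load -> save round trip is stable.
#'
#' @param object A fitted [dysc()] model.
#' @param path JSON file path.
#' @return `dysc_save` returns `path` invisibly; `dysc_load` returns the
#'   restored `"dysc"` object.
#' @export
dysc_save <- function(object, path) {
  stopifnot(inherits(object, "dysc"))
  # doubles stored as 17-significant-digit strings: exact round trip
  num <- function(v) sprintf("%.17g", as.numeric(v))
  doc <- list(
    format = "dysc-model", version = 1L,
    dims = object$dims, levels = as.list(object$levels),
    flat = num(object$flat), seed = object$seed,
    max_iter = object$max_iter, max_feval = object$max_feval,
    loss = num(object$loss), initial_loss = num(object$initial_loss),
    convergence = object$convergence,
    standardizer = if (is.null(object$standardizer)) NULL else
      list(center = num(object$standardizer$center),
           scale = num(object$standardizer$scale),
           degenerate = as.logical(object$standardizer$degenerate),
           names = names(object$standardizer$center)))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname dysc_save
#' @export
dysc_load <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "dysc-model"))
    stop("not a dysc model file", call. = FALSE)
  dims <- lapply(doc$dims, as.integer)
  flat <- as.numeric(doc$flat)
  std <- NULL
  if (!is.null(doc$standardizer)) {
    std <- structure(list(
      center = stats::setNames(as.numeric(doc$standardizer$center),
                               doc$standardizer$names),
      scale = stats::setNames(as.numeric(doc$standardizer$scale),
                              doc$standardizer$names),
      degenerate = as.logical(doc$standardizer$degenerate)),
      class = "mde_standardizer")
  }
  structure(list(params = dysc_unpack(flat, dims), flat = flat, dims = dims,
                 levels = as.character(unlist(doc$levels)), standardizer = std,
                 loss = as.numeric(doc$loss),
                 initial_loss = as.numeric(doc$initial_loss),
                 counts = NULL, convergence = doc$convergence,
                 seed = as.integer(doc$seed),
                 max_iter = as.integer(doc$max_iter),
                 max_feval = doc$max_feval, call = NULL),
            class = "dysc")
}
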