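# The gated three-pathway classifier: gates, forward pass, loss, analytic
# gradient, training and serialization.

make_blob_features <- function(n_per_class, dims = c(4, 3, 3), K = 2,
                               shift = 2.5, seed = 1) {
  set.seed(seed)
  D <- sum(dims)
  X <- matrix(rnorm(n_per_class * K * D), n_per_class * K, D)
  y <- rep(seq_len(K), each = n_per_class)
  for (k in 2:K) X[y == k, seq_len(D) %% K == (k - 1)] <-
    X[y == k, seq_len(D) %% K == (k - 1)] + shift
  list(X = X, y = factor(letters[y]), dims = dims)
}

test_that("gates respect their defining ranges and identities", {
  x <- c(0.2, -0.4, 0.9)
  g0 <- gate_hierarchical(x, c(0, 0, 0))
  expect_equal(g0$gate, c(0, 0, 0)); expect_equal(g0$x_mod, c(0, 0, 0))
  g <- gate_hierarchical(rnorm(5), rnorm(5))
  expect_true(all(abs(g$gate) < 1))
  # tanh saturates to 1.0 in floating point for huge arguments but never beyond
  expect_true(all(abs(gate_hierarchical(rnorm(5) * 100, rnorm(5) * 100)$gate) <= 1))
  expect_error(gate_hierarchical(x, c(1, 2)), "length")

  gt <- gate_time_invariant(c(0.5, 0.5, 0.5), gamma = 2)
  expect_equal(gt$gate, 1)                    # zero variance passes through
  expect_equal(gt$x_mod, c(0.5, 0.5, 0.5))
  gt2 <- gate_time_invariant(c(0, 1), gamma = 1e6)
  expect_lt(gt2$gate, 1e-10)                  # high sensitivity shuts the gate
  for (s in 1:20) {
    g_ <- gate_time_invariant(rnorm(6), gamma = exp(rnorm(1)))
    expect_true(g_$gate > 0 && g_$gate <= 1)
  }
  expect_error(gate_time_invariant(c(1, 2), gamma = -1), "positive")

  expect_equal(gate_multiscale(x, rep(1, 3)), x)  # neutral mask (initialization)
  expect_equal(gate_multiscale(x, rep(0, 3)), c(0, 0, 0))
  expect_equal(gate_multiscale(3 * x, c(1, 2, 3)), 3 * gate_multiscale(x, c(1, 2, 3)))
})

test_that("pathway fusion is a bounded tanh layer", {
  W <- matrix(rnorm(12), 3, 4)
  expect_equal(as.numeric(pathway_fuse(c(0, 0, 0), W, numeric(4))), rep(0, 4))
  b <- rnorm(4)
  expect_equal(as.numeric(pathway_fuse(c(0, 0, 0), W, b)), tanh(b))
  expect_true(all(abs(pathway_fuse(rnorm(3) * 5, W, b)) < 1))
  expect_error(pathway_fuse(c(1, 2), W, b), "mismatch")
})

test_that("softmax probabilities normalize and are shift-invariant", {
  sm <- dyscmde:::softmax_rows
  expect_equal(as.numeric(sm(matrix(c(0, 0), 1))), c(0.5, 0.5))
  set.seed(10)
  for (i in 1:200) {
    z <- matrix(rnorm(3, sd = 5), 1)
    p <- sm(z)
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_equal(sm(z + 7), p, tolerance = 1e-12)
  }
})

test_that("cross-entropy has its closed-form values", {
  P <- rbind(c(1, 0), c(0, 1))
  expect_equal(cross_entropy(P, c(1, 2)), 0, tolerance = 1e-12)
  K <- 4
  Pu <- matrix(1 / K, 3, K)
  expect_equal(cross_entropy(Pu, c(1, 3, 4)), log(K))
  expect_gte(cross_entropy(matrix(runif(10), 5, 2), c(1, 2, 1, 2, 1)), 0)
  expect_error(cross_entropy(Pu, c(1, 5, 2)), "label")
})

test_that("analytic gradient agrees with central finite differences", {
  lg <- dyscmde:::dysc_loss_grad
  set.seed(33)
  for (rep in 1:4) {
    d <- list(dm = sample(3:5, 1), dh = sample(2:4, 1), dt = sample(3:4, 1),
              Hp = 4L, Hf = 5L, K = sample(2:3, 1))
    n <- 6L
    Xm <- matrix(rnorm(n * d$dm), n); Xh <- matrix(rnorm(n * d$dh), n)
    Xt <- matrix(rnorm(n * d$dt), n)
    y <- c(seq_len(d$K), sample(seq_len(d$K), n - d$K, replace = TRUE))
    flat <- dyscmde:::dysc_pack(dyscmde:::dysc_init(d, seed = rep)) +
      rnorm(dyscmde:::dysc_layout(d)$total, 0, 0.3)
    got <- lg(flat, d, Xm, Xh, Xt, y)
    h <- 1e-6
    fd <- vapply(seq_along(flat), function(i) {
      e <- numeric(length(flat)); e[i] <- h
      (lg(flat + e, d, Xm, Xh, Xt, y)$loss -
         lg(flat - e, d, Xm, Xh, Xt, y)$loss) / (2 * h)
    }, numeric(1))
    # denominator floored at the central-difference noise scale
    expect_lt(max(abs(got$grad - fd) / pmax(abs(fd), 1e-4)), 1e-5)
  }
})

test_that("a mask entry feeding an always-zero feature has zero gradient", {
  lg <- dyscmde:::dysc_loss_grad
  d <- list(dm = 3L, dh = 2L, dt = 3L, Hp = 3L, Hf = 4L, K = 2L)
  set.seed(4)
  n <- 8L
  Xm <- cbind(0, matrix(rnorm(n * 2), n))  # first multiscale feature dead
  Xh <- matrix(rnorm(n * 2), n); Xt <- matrix(rnorm(n * 3), n)
  flat <- dyscmde:::dysc_pack(dyscmde:::dysc_init(d, seed = 5))
  g <- lg(flat, d, Xm, Xh, Xt, rep(1:2, 4))$grad
  lay <- dyscmde:::dysc_layout(d)
  w_m_grad <- g[lay$starts[["w_m_att"]]:lay$ends[["w_m_att"]]]
  expect_identical(w_m_grad[1], 0)
})

test_that("training separates separable classes, descends and is seed-deterministic", {
  blob <- make_blob_features(100)
  fit <- dysc(blob$X, blob$y, dims = blob$dims, hidden_pathway = 8,
              hidden_fusion = 8, seed = 2)
  expect_gte(mean(predict(fit, blob$X) == blob$y), 0.99)
  expect_lte(fit$loss, fit$initial_loss)
  fit2 <- dysc(blob$X, blob$y, dims = blob$dims, hidden_pathway = 8,
               hidden_fusion = 8, seed = 2)
  expect_identical(fit$flat, fit2$flat)
  # first-order condition at the optimum found
  gr <- dyscmde:::dysc_loss_grad
  st <- fit$standardizer
  Z <- apply_standardizer(blob$X, st)
  sp <- dyscmde:::split_groups(Z, fit$dims)
  g <- gr(fit$flat, fit$dims, sp$Xm, sp$Xh, sp$Xt, as.integer(blob$y))$grad
  expect_lte(max(abs(g)), 1e-4)
  expect_error(dysc(blob$X, rep("a", nrow(blob$X)), dims = blob$dims), "2 classes")
})

test_that("prediction breaks probability ties toward the lower class index", {
  blob <- make_blob_features(20)
  fit <- dysc(blob$X, blob$y, dims = blob$dims, hidden_pathway = 4,
              hidden_fusion = 4, max_iter = 2, seed = 1)
  P <- predict(fit, blob$X, type = "prob")
  expect_equal(unname(rowSums(P)), rep(1, nrow(P)), tolerance = 1e-12)
  expect_identical(colnames(P), fit$levels)
  # force an exact tie through the internal argmax rule
  expect_identical(max.col(matrix(c(0.5, 0.5), 1), ties.method = "first"), 1L)
})

test_that("models survive a JSON save/load round trip bit-stably", {
  blob <- make_blob_features(15)
  fit <- dysc(blob$X, blob$y, dims = blob$dims, hidden_pathway = 4,
              hidden_fusion = 4, max_iter = 10, seed = 7)
  p1 <- withr::local_tempfile(fileext = ".json")
  p2 <- withr::local_tempfile(fileext = ".json")
  dysc_save(fit, p1)
  back <- dysc_load(p1)
  expect_identical(back$flat, fit$flat)
  expect_identical(back$levels, fit$levels)
  expect_identical(predict(back, blob$X), predict(fit, blob$X))
  dysc_save(back, p2)
  expect_identical(readLines(p1), readLines(p2))  # load -> save stability
})
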