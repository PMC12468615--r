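# Multilevel db4 analysis, per-band reconstruction and the hierarchical
# band-entropy feature.

test_that("db4 coefficients match the frozen multiresolution reference", {
  # deterministic test signal; reference computed with an independent
  # wavelet implementation (PyWavelets 1.9.0, symmetric mode) and frozen
  i <- 1:32
  x <- sin(0.3 * i) + 0.1 * cos(1.7 * i)
  dec <- dwt_decompose(x, level = 2, basis = "db4", extension = "symmetric")
  A2 <- c(1.6232741592065008, 0.8610298509079706, 2.118425596602427,
          1.139316114536658, 1.2633691958217863, 1.9267267421835035,
          0.20415137265891353, -1.778938945120319, -1.4939490232666497,
          0.6865566115552447, 2.0754054883630033, 0.4508562235672199,
          -0.20217476915695132)
  D2 <- c(-0.12636902776411085, -0.3549175200960804, 0.3359597103363183,
          -0.1962458232217323, -0.13359517017491765, -0.06880066639508822,
          -0.03768898783413208, -0.0761126690978785, -0.11203558964960261,
          -0.29103215821529177, 0.4812654217176805, -0.07548588918166596,
          0.02135730200231462)
  D1 <- c(0.04744942075762981, 0.07858595585604342, -0.12171976858193921,
          0.1078307657540733, -0.11557070621601247, 0.10368491919565737,
          -0.09008572946307644, 0.0739192414028466, -0.04203601812397607,
          0.021787566472631005, 0.01291220126099089, -0.039714442501481186,
          0.062495864748949304, -0.09045137419807515, 0.09839329972947908,
          -0.1135989394679327, 0.04633002338858569, 0.0927173239625229,
          -0.12698628075691376)
  expect_equal(dec$a, A2, tolerance = 1e-10)
  expect_equal(dec$d[[1]], D2, tolerance = 1e-10)
  expect_equal(dec$d[[2]], D1, tolerance = 1e-10)

  # linear-extrapolation boundary mode, same reference implementation
  dec_s <- dwt_decompose(x, level = 2, basis = "db4", extension = "smooth")
  A2s <- c(-5.0140200767330612, -3.5232379556527187, -2.0112158404891418,
           -0.61212014410510418, 1.2033405906880108, 1.9267267421835035,
           0.20415137265891353, -1.778938945120319, -1.4939287107933659,
           0.69691745871303712, 1.9966207782564633, 0.7618256302722598,
           -1.7777744142811143)
  D2s <- c(3.4694469519536142e-17, -0.044277122814899227, 0.12307386396139826,
           -0.13127757105452148, -0.13083384850915933, -0.068800666395088222,
           -0.037688987834132083, -0.076112669097878505, -0.11159401507567004,
           -0.063302486360485646, 0.046588279683608291, 0.0036815107067108502,
           5.0523821237824507e-16)
  expect_equal(dec_s$a, A2s, tolerance = 1e-10)
  expect_equal(dec_s$d[[1]], D2s, tolerance = 1e-10)
})

test_that("linear-extrapolation mode annihilates polynomial trends in the details", {
  ramp <- as.numeric(1:500)
  dec <- dwt_decompose(ramp, level = 3)  # smooth is the default
  expect_lt(max(abs(unlist(dec$d))), 1e-10)
  # and so the detail-band entropies of a ramp are exactly zero
  expect_equal(unname(haspe_dwt(ramp, level = 3)), rep(0, 4))
})

test_that("zero signals decompose to zero and infeasible depths error", {
  dec <- dwt_decompose(numeric(64), level = 3)
  expect_true(all(dec$a == 0) && all(unlist(dec$d) == 0))
  expect_error(dwt_decompose(numeric(64), level = 6), "at most")
  expect_error(band_reconstruct(dwt_decompose(numeric(64), 2), "D9"), "unknown band")
})

test_that("band reconstructions have length T and sum to the signal", {
  set.seed(5)
  lengths_ <- round(seq(256, 4097, length.out = 50))
  worst <- 0
  for (n in lengths_) {
    x <- rnorm(n)
    dec <- dwt_decompose(x, level = 4)
    ids <- c("A4", paste0("D", 4:1))
    total <- numeric(n)
    for (b in ids) {
      r <- band_reconstruct(dec, b)
      expect_identical(length(r), as.integer(n))
      total <- total + r
    }
    worst <- max(worst, max(abs(total - x)) / max(abs(x)))
  }
  expect_lt(worst, 1e-8)
})

test_that("a slow sinusoid concentrates its energy in the approximation band", {
  fs <- 100
  t <- seq(0, 20, by = 1 / fs)
  x <- sin(2 * pi * 0.5 * t)  # period 2 s >> 2^4 samples
  dec <- dwt_decompose(x, level = 4)
  e_a <- sum(band_reconstruct(dec, "A4")^2)
  expect_gte(e_a / sum(x^2), 0.90)
})

test_that("hierarchical band entropies follow the [A_L, D_L..D_1] layout", {
  set.seed(6)
  x <- rnorm(1024)
  h <- haspe_dwt(x, level = 4)
  expect_identical(names(h), c("A4", "D4", "D3", "D2", "D1"))
  expect_length(h, 5L)
  expect_true(all(h >= 0 & h <= 1))
  expect_equal(unname(haspe_dwt(rep(2, 512), level = 3)), rep(0, 4))

  # step-by-step oracle: decomposition, zero-padded inversion and entropy
  # performed as separate explicit calls
  x3 <- random_series(77, 512)
  dec <- dwt_decompose(x3, level = 3)
  manual <- vapply(c("A3", "D3", "D2", "D1"),
                   function(b) aspe(band_reconstruct(dec, b)), numeric(1))
  expect_equal(haspe_dwt(x3, level = 3), manual, tolerance = 1e-15)
})
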