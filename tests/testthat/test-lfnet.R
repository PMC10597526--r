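test_that("stft places DC energy in bin 0 and period-3 energy in its bin", {
  cfg <- lfnetConfig(windowLength = 8L, hiddenDim = 1L)
  H <- matrix(1, 24, 1)
  fr <- stftMatrix(H, cfg)
  for (f in seq_len(dim(fr)[1])) {
    mags <- Mod(fr[f, , 1])
    expect_equal(which.max(mags), 1L)
  }

  # pure period-3 sinusoid, window divisible by 3: closed-form DFT argmax
  cfg <- lfnetConfig(windowLength = 12L, hiddenDim = 1L)
  x <- cos(2 * pi * (0:35) / 3)
  fr <- stftMatrix(matrix(x, ncol = 1), cfg)
  bin3 <- 12L / 3L + 1L       # 1-based index of the period-3 bin
  mags <- Mod(fr[2, , 1])     # interior frame (no zero padding)
  expect_equal(which.max(mags), bin3)

  # centered framing: ceiling(L / hop) + 1 zero-padded frames
  fr <- stftMatrix(matrix(rnorm(5), 5, 1), cfg)
  expect_equal(dim(fr)[1], 2L)
  fr <- stftMatrix(matrix(rnorm(13), 13, 1), cfg)
  expect_equal(dim(fr)[1], 4L)
})

test_that("istft(stft(x)) is the identity across lengths and dims", {
  set.seed(91)
  for (L in c(2L, 9L, 27L, 54L, 71L, 160L)) {
    D <- sample(1:6, 1)
    cfg <- lfnetConfig(windowLength = 54L, hiddenDim = D)
    H <- matrix(rnorm(L * D), L, D)
    err <- max(abs(istftMatrix(stftMatrix(H, cfg), cfg, L) - H))
    expect_lt(err, 1e-5)
  }
  # reconstruction error does not depend on L being a hop multiple
  cfg <- lfnetConfig(windowLength = 10L, hiddenDim = 2L)
  errs <- vapply(11:20, function(L) {
    H <- matrix(rnorm(L * 2), L, 2)
    max(abs(istftMatrix(stftMatrix(H, cfg), cfg, L) - H))
  }, 0)
  expect_true(all(errs < 1e-5))
})

test_that("filtering identities: all-ones, all-zeros and period-3 negation", {
  cfg <- lfnetConfig(windowLength = 12L, hiddenDim = 2L)
  H <- matrix(rnorm(12 * 2), 12, 2)
  fr <- stftMatrix(H, cfg)
  W1 <- matrix(1 + 0i, cfg$nBins, 2L)
  expect_equal(applyFilter(fr, W1, 0), fr)
  W0 <- matrix(0i, cfg$nBins, 2L)
  expect_true(all(applyFilter(fr, W0, 0) == 0))

  # a -1+0i weight at the period-3 bin negates exactly that bin's content
  Wm <- W1; Wm[5L, ] <- -1 + 0i
  out <- applyFilter(fr, Wm, 0)
  expect_equal(out[, 5L, ], -fr[, 5L, ])
  expect_equal(out[, -5L, ], fr[, -5L, ])

  expect_error(applyFilter(fr, matrix(1 + 0i, 3, 2), 0), "does not match")
})

test_that("soft-shrink acts elementwise on real and imaginary parts", {
  cfg <- lfnetConfig(windowLength = 8L, hiddenDim = 1L,
                     softshrinkThreshold = 0.5)
  fr <- array(complex(real = c(1, 0.3, -2), imaginary = c(-0.2, 4, 0)),
              dim = c(1, 3, 1))
  W <- matrix(1 + 0i, 3, 1)
  out <- applyFilter(fr, W, 0.5)
  expect_equal(Re(out[1, , 1]), c(0.5, 0, -1.5))
  expect_equal(Im(out[1, , 1]), c(0, 3.5, 0))
})

test_that("frame filtering equals a time-domain circular-convolution oracle", {
  # isolate one frame: its filtered time-domain content must equal the
  # brute-force circular convolution of the Hann-windowed frame with the
  # filter's inverse transform
  set.seed(17)
  W <- 12L; hop <- 6L
  cfg <- lfnetConfig(windowLength = W, hiddenDim = 1L)
  x <- rnorm(W)                       # frame 2 covers exactly positions 1..W
  Wc <- matrix(complex(real = rnorm(cfg$nBins), imaginary = rnorm(cfg$nBins)),
               cfg$nBins, 1L)
  # real (Hermitian-representable) kernel: DC and Nyquist imaginary parts 0
  Wc[1, 1] <- Re(Wc[1, 1]); Wc[cfg$nBins, 1] <- Re(Wc[cfg$nBins, 1])
  full <- complex(length.out = W)
  full[1:cfg$nBins] <- Wc[, 1]
  full[W:(cfg$nBins + 1)] <- Conj(Wc[2:(cfg$nBins - 1), 1])
  kern <- Re(fft(full, inverse = TRUE)) / W
  hann <- lfnetr:::.hann(W)
  xw <- x * hann
  conv <- vapply(0:(W - 1), function(n)
    sum(xw * kern[((n - (0:(W - 1))) %% W) + 1L]), 0)
  frames <- applyFilter(stftMatrix(matrix(x), cfg), Wc, 0)
  frames[-2L, , ] <- 0i               # keep only frame 2's contribution
  out <- istftMatrix(frames, cfg, W)
  expect_lt(max(abs(out[, 1] - conv)), 1e-5)
})

test_that("lfnet forward: identity filter doubles, zero filter passes through", {
  cfg <- lfnetConfig(windowLength = 8L, hiddenDim = 3L)
  H <- matrix(rnorm(30 * 3), 30, 3)
  W1 <- matrix(1 + 0i, cfg$nBins, 3L)
  expect_lt(max(abs(lfnetForward(H, W1, cfg) - 2 * H)), 1e-8)
  W0 <- matrix(0i, cfg$nBins, 3L)
  expect_equal(lfnetForward(H, W0, cfg), H)
})

test_that("lfnet gradients match finite differences", {
  set.seed(23)
  cfg <- lfnetConfig(windowLength = 8L, hiddenDim = 2L,
                     softshrinkThreshold = 0.05)
  H <- matrix(rnorm(11 * 2), 11, 2)
  Wc <- matrix(complex(real = rnorm(cfg$nBins * 2, sd = 0.5),
                       imaginary = rnorm(cfg$nBins * 2, sd = 0.5)),
               cfg$nBins, 2L)
  loss <- function(H, Wc) sum(sin(lfnetForward(H, Wc, cfg)))
  cc <- lfnetr:::.lfnetForwardCache(H, Wc, cfg)
  bk <- lfnetr:::.lfnetBackward(cos(cc$out), cc, Wc, cfg)
  eps <- 1e-6
  for (probe in list(c(1, 1), c(5, 2), c(11, 1))) {
    i <- probe[1]; j <- probe[2]
    Hp <- H; Hp[i, j] <- Hp[i, j] + eps
    Hm <- H; Hm[i, j] <- Hm[i, j] - eps
    expect_lt(abs((loss(Hp, Wc) - loss(Hm, Wc)) / (2 * eps) - bk$dH[i, j]),
              1e-4)
  }
  i <- 3L; j <- 2L
  Wp <- Wc; Wp[i, j] <- Wp[i, j] + eps
  Wm <- Wc; Wm[i, j] <- Wm[i, j] - eps
  expect_lt(abs((loss(H, Wp) - loss(H, Wm)) / (2 * eps) - Re(bk$dW[i, j])),
            1e-4)
})

test_that("filter spectra export polar form with period annotations", {
  W <- matrix(c(1 + 0i, -1 + 0i, 0 + 1i), 3, 1)
  sp <- filterSpectra(W, windowLength = 4L)
  expect_equal(sp$magnitude, c(1, 1, 1))
  expect_equal(sp$phase[1], 0)
  expect_equal(abs(sp$phase[2]), pi)
  expect_equal(sp$period, c(Inf, 4, 2))
  # polar identity: z reconstructable from magnitude and phase
  z <- complex(modulus = sp$magnitude, argument = sp$phase)
  expect_lt(max(abs(z - as.vector(W))), 1e-6)
})

test_that("lfnet compute scales near-linearly with length", {
  cfg <- lfnetConfig(windowLength = 54L, hiddenDim = 8L)
  W <- matrix(0.5 + 0i, cfg$nBins, 8L)
  t1 <- system.time(for (k in 1:3)
    lfnetForward(matrix(rnorm(200 * 8), 200, 8), W, cfg))[3]
  t2 <- system.time(for (k in 1:3)
    lfnetForward(matrix(rnorm(1600 * 8), 1600, 8), W, cfg))[3]
  # 8x the length should cost well under 64x (quadratic) the time
  expect_lt(t2, max(16 * t1, 0.5))
})
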