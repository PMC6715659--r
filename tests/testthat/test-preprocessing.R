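test_that("dark-frame averaging is the pixelwise mean", {
  f1 <- matrix(10, 8, 8); f2 <- matrix(20, 8, 8)
  expect_equal(average_dark_frames(list(f1)), f1)
  expect_equal(average_dark_frames(list(f1, f2)), matrix(15, 8, 8))
  expect_error(average_dark_frames(list()), "non-empty")
  expect_error(average_dark_frames(list(f1, matrix(0, 4, 4))), "mismatch")
  # averaging n noisy darks shrinks the error like sigma/sqrt(n)
  set.seed(21)
  b <- 100; sdev <- 8; n <- 20
  darks <- lapply(seq_len(n), function(i) b + matrix(rnorm(64 * 64, sd = sdev), 64))
  bkg <- average_dark_frames(darks)
  expect_true(max(abs(bkg - b)) < 5 * sdev / sqrt(n))
})

test_that("illumination estimate recovers a known smooth vignette", {
  n <- 256L; k <- 31L
  V <- known_vignette(n)
  raw <- 700 * V + 100                    # uniform signal x vignette + bkg
  ill <- estimate_illumination(raw, filter_size = k)
  expect_equal(mean(ill), 1, tolerance = 1e-9)
  inner <- (k + 1):(n - k)
  target <- raw / mean(raw)               # ILL of a pure smooth frame
  rms <- sqrt(mean((ill[inner, inner] - target[inner, inner])^2))
  expect_lt(rms, 0.02)
})

test_that("flat frames give a flat unit illumination field", {
  expect_equal(estimate_illumination(matrix(5, 64, 64), filter_size = 9L),
               matrix(1, 64, 64))
  expect_error(estimate_illumination(matrix(1, 10, 10), filter_size = 11L),
               "exceeds")
  expect_error(estimate_illumination(matrix(1, 10, 10), filter_size = 4L), "odd")
})

test_that("dark particles smaller than the window do not disturb ILL", {
  n <- 256L; k <- 31L
  V <- known_vignette(n)
  clean <- 700 * V + 100
  dirty <- clean
  set.seed(22)                            # isolated dark disks, diameter < k
  for (i in 1:12) {
    ctr <- runif(2, 40, n - 40); r <- runif(1, 3, 9)
    ij <- expand.grid(r = seq_len(n), c = seq_len(n))
    inside <- (ij$r - ctr[1])^2 + (ij$c - ctr[2])^2 <= r^2
    dirty[matrix(inside, n)] <- 100
  }
  ill_clean <- estimate_illumination(clean, filter_size = k)
  ill_dirty <- estimate_illumination(dirty, filter_size = k)
  inner <- (k + 1):(n - k)
  rms <- sqrt(mean((ill_clean[inner, inner] - ill_dirty[inner, inner])^2))
  expect_lt(rms, 0.02)
})

test_that("the opening -> closing -> mean order is the implemented order", {
  # open-then-close and close-then-open differ on structures comparable
  # to the window; guard against an accidentally commuted pipeline
  n <- 96L; k <- 15L
  set.seed(23)
  blocks <- matrix(rbinom((n / 8)^2, 1, 0.5), n / 8)
  im <- 100 + 500 * blocks[rep(seq_len(n / 8), each = 8),
                           rep(seq_len(n / 8), each = 8)]
  open_first <- estimate_illumination(im, filter_size = k, normalize = FALSE)
  close_first <- gelmob:::.cpp_mean_filter(
    gelmob:::.cpp_dilate(gelmob:::.cpp_erode(
      gelmob:::.cpp_erode(gelmob:::.cpp_dilate(im, k), k), k), k), k)
  expect_gt(max(abs(open_first - close_first)), 10)
  # opening acts first: an isolated bright speck never survives
  speck <- matrix(100, n, n); speck[20:24, 20:24] <- 600
  expect_lt(max(estimate_illumination(speck, filter_size = k,
                                      normalize = FALSE)), 101)
})

test_that("shading correction inverts the image formation model", {
  n <- 64L
  set.seed(24)
  bkg <- matrix(100, n, n)
  ill <- known_vignette(n); ill <- ill / mean(ill)
  model <- shading_model(bkg, ill)
  expect_equal(shading_correct(bkg, model), matrix(0, n, n))
  k <- 432.1
  expect_equal(shading_correct(bkg + k * ill, model), matrix(k, n, n))
  # identity on an already flat frame with trivial model
  flat_model <- shading_model(matrix(0, n, n), matrix(1, n, n))
  fr <- matrix(runif(n * n, 500, 900), n)
  expect_equal(shading_correct(fr, flat_model), fr)
  expect_error(shading_correct(matrix(1, 4, 4), model), "shapes differ")
})

test_that("shading model validates its invariants", {
  n <- 16L
  expect_error(shading_model(matrix(-1, n, n), matrix(1, n, n)), "non-negative")
  expect_error(shading_model(matrix(0, n, n), matrix(0, n, n)), "positive")
  expect_error(shading_model(matrix(0, n, n), matrix(2, n, n)), "unit mean")
  m <- shading_model(matrix(0, n, n), matrix(2, n, n), check_unit_mean = FALSE)
  expect_s3_class(m, "shading_model")
})

test_that("end-to-end: pipeline-estimated model flattens a noiseless render", {
  # raw = gain * c * V + b; the estimated ILL absorbs V, so the corrected
  # frame is uniform at gain * c * mean(V) within the filter border
  n <- 256L; k <- 31L
  V <- known_vignette(n)
  gain_c <- 700; b <- 100
  raw <- gain_c * V + b
  darks <- list(matrix(b, n, n), matrix(b, n, n))
  model <- build_shading_model(darks, raw, filter_size = k)
  corr <- shading_correct(raw, model)
  inner <- (k + 1):(n - k)
  # unit-mean normalization over the full frame carries a small border
  # bias into the interior; 2% is the documented recovery tolerance
  expect_equal(mean(corr[inner, inner]), gain_c * mean(V), tolerance = 0.02)
  expect_lt(stats::sd(corr[inner, inner]) / mean(corr[inner, inner]), 0.01)
})

test_that("unit-mean ILL preserves the count scale of a corrected frame", {
  n <- 128L
  set.seed(25)
  V <- known_vignette(n); illn <- V / mean(V)
  model <- shading_model(matrix(50, n, n), illn)
  raw <- 50 + 640 * illn
  corr <- shading_correct(raw, model)
  expect_equal(mean(corr), mean(raw - 50), tolerance = 0.01)
})
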