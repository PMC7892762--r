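test_that("DoG kernels are zero-sum difference of normalized Gaussians", {
  for (size in c(3, 5, 7)) {
    for (sig in list(c(0.5, 1), c(1, 2), c(1.5, 3))) {
      k <- dog_kernel(size, sig[1], sig[2])
      expect_equal(dim(k), c(size, size))
      expect_lt(abs(sum(k)), 1e-12)
    }
  }
  # centre entry of the (3, 0.5, 1) kernel from direct evaluation of both
  # discrete Gaussians on the 3x3 grid
  d2 <- outer((-1:1)^2, (-1:1)^2, "+")
  g1 <- exp(-d2 / (2 * 0.5^2)); g2 <- exp(-d2 / (2 * 1^2))
  expect_equal(dog_kernel(3, 0.5, 1)[2, 2],
               g1[2, 2] / sum(g1) - g2[2, 2] / sum(g2), tolerance = 1e-12)
})

test_that("invalid DoG parameters are rejected", {
  expect_error(dog_kernel(4, 1, 2), "odd")
  expect_error(dog_kernel(7, 2, 2), "smaller")
  expect_error(dog_kernel(7, 2, 1), "smaller")
  expect_error(dog_kernel(7, 0, 1))
})

test_that("DoG filtering matches a brute-force correlation oracle", {
  k <- dog_kernel(7, 1, 2)
  # constant image: interior response exactly zero (zero-sum kernel)
  const <- matrix(0.7, 28, 28)
  out <- apply_dog(const, k)
  expect_true(all(abs(out[4:25, 4:25]) < 1e-12))
  # centred impulse reproduces the flipped kernel
  imp <- matrix(0, 9, 9); imp[5, 5] <- 1
  expect_equal(apply_dog(imp, k)[2:8, 2:8], k[7:1, 7:1], tolerance = 1e-12)
  # vertical step edge against the double-loop oracle
  step <- matrix(0, 28, 28); step[, 15:28] <- 1
  expect_equal(apply_dog(step, k), oracle_correlate(step, k), tolerance = 1e-12)
  expect_error(apply_dog(matrix(0, 3, 3), k), "larger")
})

test_that("Poisson coding has the stated rate map and determinism", {
  cfg <- encoder_config()
  expect_equal(cfg$max_rate * cfg$dt / 1000, 0.064)
  zero <- poisson_encode(matrix(0, 5, 5), cfg, seed = 1)
  expect_equal(sum(zero), 0)
  img <- make_shape_image("vline", x = 3, dims = c(8, 8))
  expect_identical(unclass(poisson_encode(img, cfg, seed = 9)),
                   unclass(poisson_encode(img, cfg, seed = 9)))
  expect_false(identical(unclass(poisson_encode(img, cfg, seed = 9)),
                         unclass(poisson_encode(img, cfg, seed = 10))))
})

test_that("a max-intensity pixel spikes 160/s * 0.64 s = 102.4 times on average", {
  cfg <- encoder_config()
  counts <- vapply(1:400, function(s) {
    sum(poisson_encode(matrix(1, 1, 1), cfg, seed = s))
  }, numeric(1))
  # mean 102.4, per-raster sd ~9.8 -> standard error ~0.49 over 400 seeds
  expect_equal(mean(counts), 102.4, tolerance = 0.02)
  expect_true(all(counts <= cfg$n_steps))
})

test_that("spike rate is monotone in intensity and bounded by max_rate * dt", {
  cfg <- encoder_config(n_steps = 200)
  img <- matrix(c(0, 0.25, 0.5, 0.75, 1), 5, 1)
  mean_counts <- rowMeans(vapply(1:100, function(s) {
    rowSums(poisson_encode(img, cfg, seed = s))
  }, numeric(5)))
  expect_true(all(diff(mean_counts) >= 0))
  expect_lte(max(mean_counts) / cfg$n_steps, cfg$max_rate * cfg$dt / 1000 + 0.02)
})

test_that("negative DoG values are rectified, or split into an OFF channel", {
  signed <- matrix(c(-1, 0.5, 1, -0.2), 2, 2)
  on_only <- poisson_encode(signed, encoder_config(n_steps = 500), seed = 3)
  expect_equal(nrow(on_only), 4)
  expect_equal(sum(on_only[1, ]), 0)  # negative pixel never spikes
  two_ch <- poisson_encode(signed, encoder_config(n_steps = 500,
                                                  rectify_negatives = FALSE),
                           seed = 3)
  expect_equal(nrow(two_ch), 8)
  expect_gt(sum(two_ch[5, ]), 0)  # OFF channel carries the negative part
})

test_that("input white noise is seeded, scaled to the image sd, and clipped", {
  img <- matrix(runif(784, 0.3, 0.7), 28, 28)
  expect_identical(add_input_noise(img, 0), img)
  expect_identical(add_input_noise(img, 0.2, seed = 5),
                   add_input_noise(img, 0.2, seed = 5))
  expect_error(add_input_noise(img, -0.1))
  diffs <- vapply(1:200, function(s) {
    stats::sd(add_input_noise(img, 0.2, seed = s, clip = FALSE) - img)
  }, numeric(1))
  expect_equal(mean(diffs), 0.2 * stats::sd(img), tolerance = 0.02)
  noisy <- add_input_noise(img, 2, seed = 1)
  expect_true(all(noisy >= 0 & noisy <= 1))
})

test_that("spike rasters round-trip through the CSV event-list format", {
  img <- make_shape_image("circle", center = c(10, 10), r = 5, dims = c(20, 20))
  ras <- poisson_encode(img, encoder_config(n_steps = 50), seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_spike_raster(ras, path)
  back <- read_spike_raster(path)
  expect_identical(unclass(back), unclass(ras))
  expect_equal(attr(back, "dt"), attr(ras, "dt"))
  expect_equal(attr(back, "settle_steps"), attr(ras, "settle_steps"))
})
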