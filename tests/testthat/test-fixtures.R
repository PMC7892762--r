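test_that("stroke images render the expected pixels", {
  v <- make_shape_image("vline", x = 5)
  expect_equal(sum(v > 0), 28)
  expect_true(all(which(v > 0, arr.ind = TRUE)[, "col"] == 6))  # 0-based x = 5
  h <- make_shape_image("hline", y = 3)
  expect_true(all(which(h > 0, arr.ind = TRUE)[, "row"] == 4))
  circ <- make_shape_image("circle", center = c(13, 13), r = 5)
  pts <- which(circ > 0, arr.ind = TRUE)
  expect_equal(nrow(pts), 12)  # the 12 lattice points at squared distance 25
  d2 <- (pts[, "col"] - 1 - 13)^2 + (pts[, "row"] - 1 - 13)^2
  expect_true(all(d2 == 25))
  expect_error(make_shape_image("vline", x = 40), "bounds")
})

test_that("stroke width dilates and jitter is seeded", {
  v2 <- make_shape_image("vline", x = 5, width = 2)
  expect_equal(sum(v2 > 0), 56)
  j1 <- make_shape_image("vline", x = 5, jitter = 0.5, seed = 3)
  expect_identical(j1, make_shape_image("vline", x = 5, jitter = 0.5, seed = 3))
  expect_false(identical(j1, make_shape_image("vline", x = 5, jitter = 0.5, seed = 4)))
})

test_that("toy datasets are balanced and a deterministic function of the seed", {
  ds <- make_toy_dataset(2, 10, jitter = 0, seed = 11, stroke_width = 1)
  expect_length(ds$images, 20)
  expect_equal(as.vector(table(ds$labels)), c(10, 10))
  ds2 <- make_toy_dataset(2, 10, jitter = 0, seed = 11, stroke_width = 1)
  expect_identical(ds, ds2)
  ds3 <- make_toy_dataset(4, 3, jitter = 0.1, seed = 11)
  expect_identical(ds3$labels, rep(0:3, each = 3L))
  expect_error(make_toy_dataset(5, 2), "between")
})

write_idx_fixture <- function(images, labels, img_path, lab_path,
                              truncate_img = FALSE, n_override = NULL) {
  con <- file(img_path, "wb")
  writeBin(c(2051L, n_override %||% length(images),
             nrow(images[[1]]), ncol(images[[1]])), con, size = 4, endian = "big")
  bytes <- unlist(lapply(images, function(m) as.integer(t(m))))
  if (truncate_img) bytes <- bytes[-length(bytes)]
  writeBin(as.raw(bytes), con); close(con)
  con <- file(lab_path, "wb")
  writeBin(c(2049L, length(labels)), con, size = 4, endian = "big")
  writeBin(as.raw(labels), con); close(con)
}

test_that("IDX files round-trip exactly and corrupt files fail loudly", {
  imgs <- list(matrix(0:24, 5, 5, byrow = TRUE),
               matrix(rev(0:24), 5, 5, byrow = TRUE))
  ip <- withr::local_tempfile(); lp <- withr::local_tempfile()
  write_idx_fixture(imgs, c(3L, 7L), ip, lp)
  got <- load_idx(ip, lp)
  expect_equal(got$images[[1]], imgs[[1]] / 255)
  expect_equal(got$images[[2]], imgs[[2]] / 255)
  expect_identical(got$labels, c(3L, 7L))

  # magic-number mismatch: feeding the label file as images
  expect_error(load_idx(lp), "magic 2049")
  # truncated pixel data
  ip2 <- withr::local_tempfile()
  write_idx_fixture(imgs, c(3L, 7L), ip2, withr::local_tempfile(),
                    truncate_img = TRUE)
  expect_error(load_idx(ip2), "truncated")
  # image/label count mismatch
  lp3 <- withr::local_tempfile()
  con <- file(lp3, "wb")
  writeBin(c(2049L, 1L), con, size = 4, endian = "big")
  writeBin(as.raw(3L), con); close(con)
  expect_error(load_idx(ip, lp3), "mismatch")
})

test_that("PGM images round-trip in both ASCII and binary form", {
  img <- make_shape_image("diag", offset = 2, dims = c(12, 12))
  for (ascii in c(TRUE, FALSE)) {
    p <- withr::local_tempfile(fileext = ".pgm")
    write_pgm(img, p, ascii = ascii)
    expect_equal(read_pgm(p), img, tolerance = 1 / 255)
  }
})
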