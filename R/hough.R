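# Hough-transform input synapses: fixed binary connection maps from image
# pixels to accumulator-cell neurons, so that the firing rates of the first
# reservoir modules realize the line / circle Hough transform of the input.

#' Line-Hough accumulator grid
#'
#' The line parameterization is `rho = x*cos(theta) + y*sin(theta)` with
#' 0-based pixel coordinates (`x` = column, `y` = row, origin top-left).
#' Defaults give the 16 rho-bin by 12 theta-bin grid (192 accumulator
#' neurons): theta evenly spaced on `[0, pi)` and rho bin centres spanning
#' `[-27*sqrt(2), 27*sqrt(2)]`, the attainable range for 28x28 images.
#'
#' In `"nearest"` quantization (the default, as in classical Hough voting) a
#' pixel connects, for each theta, to the cell whose rho bin centre is
#' nearest to its rho value (within half a bin width). `"strict"` mode
#' connects only on exact equality and is used by enumeration oracles.
#'
#' @param n_rho,n_theta Grid dimensions.
#' @param rho_range Range spanned by the rho bin centres.
#' @param rho_values,theta_values Explicit bin centres (override the ranges).
#' @param mode Quantization mode, `"nearest"` or `"strict"`.
#' @return An object of class `hough_line_grid`.
#' @export
hough_line_grid <- function(n_rho = 16, n_theta = 12,
                            rho_range = c(-27 * sqrt(2), 27 * sqrt(2)),
                            rho_values = NULL, theta_values = NULL,
                            mode = c("nearest", "strict")) {
  mode <- match.arg(mode)
  if (is.null(rho_values)) rho_values <- seq(rho_range[1], rho_range[2], length.out = n_rho)
  if (is.null(theta_values)) theta_values <- seq(0, pi, length.out = n_theta + 1)[1:n_theta]
  if (length(rho_values) < 1 || length(theta_values) < 1) abort("empty Hough grid.")
  if (is.unsorted(theta_values, strictly = TRUE) || any(theta_values < 0) ||
      any(theta_values >= pi)) {
    abort("`theta_values` must be strictly increasing within [0, pi).")
  }
  structure(list(rho_values = rho_values, theta_values = theta_values, mode = mode),
            class = "hough_line_grid")
}

#' Circle-Hough accumulator grid
#'
#' Cells are `(a, b, r)` triples: circle centre `(a, b)` and radius `r`, all
#' in pixel units. Defaults give the 6 x 6 x 6 grid (216 accumulator
#' neurons): centres evenly spaced across the image and radii from 3 to 13
#' pixels. `"nearest"` mode connects a pixel to the radius bin nearest its
#' Euclidean distance from each centre (within half a bin width); `"strict"`
#' mode requires `r^2 == (x - a)^2 + (y - b)^2` exactly.
#'
#' @param n_a,n_b,n_r Grid dimensions.
#' @param a_values,b_values,r_values Explicit cell coordinates.
#' @param mode Quantization mode.
#' @return An object of class `hough_circle_grid`.
#' @export
hough_circle_grid <- function(n_a = 6, n_b = 6, n_r = 6,
                              a_values = seq(0, 27, length.out = n_a),
                              b_values = seq(0, 27, length.out = n_b),
                              r_values = seq(3, 13, length.out = n_r),
                              mode = c("nearest", "strict")) {
  mode <- match.arg(mode)
  if (!length(a_values) || !length(b_values) || !length(r_values)) abort("empty Hough grid.")
  structure(list(a_values = a_values, b_values = b_values, r_values = r_values,
                 mode = mode), class = "hough_circle_grid")
}

# 0-based pixel (x = col, y = row) -> 1-based column-major index, matching
# as.vector(image) and the poisson_encode() neuron ordering.
pixel_index <- function(x, y, image_dims) x * image_dims[1] + y + 1L

#' Build line-Hough input synapses
#'
#' Creates a binary synapse for every (pixel, accumulator cell) pair that the
#' grid's quantization rule accepts, so that the per-cell count of spikes
#' arriving from a binary image equals the image's line-Hough accumulator.
#' Accumulator neurons are numbered rho-fastest:
#' `id = (i_theta - 1) * n_rho + i_rho`.
#'
#' @param grid A [hough_line_grid()].
#' @param image_dims Image dimensions `c(rows, cols)`.
#' @param weight Synaptic weight given to every connection (the input gain).
#' @return A [synapse_set()] from the `nrow * ncol` pixel population to the
#'   `n_rho * n_theta` accumulator population.
#' @export
build_line_hough <- function(grid, image_dims = c(28, 28), weight = 1) {
  stopifnot(inherits(grid, "hough_line_grid"))
  h <- image_dims[1]; w <- image_dims[2]
  if (h < 1 || w < 1) abort("`image_dims` must be positive.")
  n_rho <- length(grid$rho_values)
  px <- expand.grid(y = 0:(h - 1), x = 0:(w - 1))  # column-major pixel order
  pre <- integer(0); post <- integer(0)
  half_bin <- if (n_rho > 1) min(diff(grid$rho_values)) / 2 else Inf
  for (it in seq_along(grid$theta_values)) {
    v <- px$x * cos(grid$theta_values[it]) + px$y * sin(grid$theta_values[it])
    if (grid$mode == "strict") {
      hit <- outer(v, grid$rho_values, function(a, b) abs(a - b) < 1e-9)
      idx <- which(hit, arr.ind = TRUE)
      pre <- c(pre, pixel_index(px$x[idx[, 1]], px$y[idx[, 1]], image_dims))
      post <- c(post, (it - 1L) * n_rho + idx[, 2])
    } else {
      k <- vapply(v, function(vv) which.min(abs(grid$rho_values - vv)), integer(1))
      ok <- abs(grid$rho_values[k] - v) <= half_bin + 1e-9
      pre <- c(pre, pixel_index(px$x[ok], px$y[ok], image_dims))
      post <- c(post, (it - 1L) * n_rho + k[ok])
    }
  }
  synapse_set(pre, post, weight = weight,
              n_pre = h * w, n_post = n_rho * length(grid$theta_values),
              pre_pop = "pixels", post_pop = "hough_line")
}

#' Build circle-Hough input synapses
#'
#' As [build_line_hough()] for the circle parameter space: pixel `(x, y)`
#' connects to cell `(a, b, r)` when its distance from `(a, b)` matches `r`
#' under the grid's quantization mode. Cells are numbered a-fastest:
#' `id = ((i_r - 1) * n_b + (i_b - 1)) * n_a + i_a`.
#'
#' @inheritParams build_line_hough
#' @param grid A [hough_circle_grid()].
#' @export
build_circle_hough <- function(grid, image_dims = c(28, 28), weight = 1) {
  stopifnot(inherits(grid, "hough_circle_grid"))
  h <- image_dims[1]; w <- image_dims[2]
  if (h < 1 || w < 1) abort("`image_dims` must be positive.")
  n_a <- length(grid$a_values); n_b <- length(grid$b_values)
  n_r <- length(grid$r_values)
  px <- expand.grid(y = 0:(h - 1), x = 0:(w - 1))
  pre <- integer(0); post <- integer(0)
  half_bin <- if (n_r > 1) min(diff(grid$r_values)) / 2 else Inf
  for (ib in seq_len(n_b)) {
    for (ia in seq_len(n_a)) {
      d2 <- (px$x - grid$a_values[ia])^2 + (px$y - grid$b_values[ib])^2
      if (grid$mode == "strict") {
        hit <- outer(d2, grid$r_values^2, function(a, b) abs(a - b) < 1e-9)
        idx <- which(hit, arr.ind = TRUE)
        pre <- c(pre, pixel_index(px$x[idx[, 1]], px$y[idx[, 1]], image_dims))
        post <- c(post, ((idx[, 2] - 1L) * n_b + (ib - 1L)) * n_a + ia)
      } else {
        d <- sqrt(d2)
        k <- vapply(d, function(dd) which.min(abs(grid$r_values - dd)), integer(1))
        ok <- abs(grid$r_values[k] - d) <= half_bin + 1e-9
        pre <- c(pre, pixel_index(px$x[ok], px$y[ok], image_dims))
        post <- c(post, ((k[ok] - 1L) * n_b + (ib - 1L)) * n_a + ia)
      }
    }
  }
  synapse_set(pre, post, weight = weight,
              n_pre = h * w, n_post = n_a * n_b * n_r,
              pre_pop = "pixels", post_pop = "hough_circle")
}

#' Hough accumulator response of an input image
#'
#' Sums, per accumulator cell, the intensities of its connected pixels —
#' what the post-synaptic spike counts realize for a binary image driven
#' deterministically through the synapse map.
#'
#' @param synapses A Hough [synapse_set()] built by [build_line_hough()] or
#'   [build_circle_hough()].
#' @param image Image matrix with `n_pre` pixels.
#' @return Numeric vector of per-cell accumulated intensity.
#' @export
hough_response <- function(synapses, image) {
  stopifnot(inherits(synapses, "synapse_set"))
  check_image(image)
  if (length(image) != n_pre(synapses)) abort("image size does not match pixel population.")
  as.vector(as_weight_matrix(synapses) %*% as.vector(image))
}
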