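# Image -> spike train encoding: difference-of-Gaussians filtering, Poisson
# rate coding, and white input noise. The spike raster (neurons x time steps,
# entries 0/1) is the lingua franca passed between encoding, simulation and
# feature extraction.

#' Encoder configuration
#'
#' Defaults reproduce the study conditions used throughout the package: a
#' maximum input firing rate of 160 spikes/s, 1,600 simulation steps of
#' 0.4 ms, and a 50 ms silent settle phase (125 steps) prepended before the
#' stimulus so all membrane voltages relax to rest.
#'
#' @param max_rate Maximum firing rate of an input neuron, spikes/s.
#' @param n_steps Number of stimulus time steps.
#' @param dt Time step in ms.
#' @param settle_steps Silent steps prepended before the stimulus.
#' @param rectify_negatives Clip negative (DoG) intensities to 0 before rate
#'   scaling; when `FALSE`, ON and OFF channels are encoded as two stacked
#'   populations.
#' @return An object of class `encoder_config`.
#' @export
encoder_config <- function(max_rate = 160, n_steps = 1600, dt = 0.4,
                           settle_steps = 125, rectify_negatives = TRUE) {
  check_scalar_number(max_rate, "max_rate", lower = 0)
  check_scalar_number(n_steps, "n_steps", lower = 1)
  check_scalar_number(dt, "dt", lower = 1e-9)
  check_scalar_number(settle_steps, "settle_steps", lower = 0)
  if (max_rate * dt / 1000 >= 1) {
    abort("max_rate * dt must be below 1 so the per-step spike probability is valid.")
  }
  structure(list(max_rate = max_rate, n_steps = as.integer(n_steps), dt = dt,
                 settle_steps = as.integer(settle_steps),
                 rectify_negatives = isTRUE(rectify_negatives)),
            class = "encoder_config")
}

#' Difference-of-Gaussians kernel
#'
#' Builds the centre–surround band-pass kernel used to preprocess images,
#' approximating the receptive field of retinal ganglion cells: a narrow
#' Gaussian (sd `sigma1`) minus a wide one (sd `sigma2`), each individually
#' normalized to sum to one, so the kernel entries sum to zero.
#'
#' @param size Odd kernel width in pixels (default 7).
#' @param sigma1,sigma2 Standard deviations of the centre and surround
#'   Gaussians; must satisfy `0 < sigma1 < sigma2`.
#' @return A `size x size` numeric matrix summing to zero.
#' @examples
#' k <- dog_kernel(7, 1, 2)
#' abs(sum(k)) < 1e-12
#' @export
dog_kernel <- function(size = 7, sigma1 = 1, sigma2 = 2) {
  check_scalar_number(size, "size", lower = 1)
  if (size %% 2 != 1) abort("`size` must be odd.")
  check_scalar_number(sigma1, "sigma1", lower = 1e-12)
  check_scalar_number(sigma2, "sigma2", lower = 1e-12)
  if (sigma1 >= sigma2) abort("`sigma1` must be strictly smaller than `sigma2`.")
  half <- (size - 1) / 2
  d2 <- outer((-half:half)^2, (-half:half)^2, "+")
  g1 <- exp(-d2 / (2 * sigma1^2)); g1 <- g1 / sum(g1)
  g2 <- exp(-d2 / (2 * sigma2^2)); g2 <- g2 / sum(g2)
  g1 - g2
}

#' Apply a filter kernel to an image
#'
#' 2D cross-correlation with zero padding at the borders (configurable to
#' `"replicate"`); the output has the same shape as the input.
#'
#' @param image Numeric matrix (intensities).
#' @param kernel Filter kernel, smaller than the image in both dimensions.
#' @param border `"zero"` (default) or `"replicate"` padding.
#' @return Filtered matrix of the same shape as `image`.
#' @export
apply_dog <- function(image, kernel, border = c("zero", "replicate")) {
  check_image(image); check_image(kernel, "kernel")
  border <- match.arg(border)
  kh <- nrow(kernel); kw <- ncol(kernel)
  if (kh %% 2 != 1 || kw %% 2 != 1) abort("`kernel` dimensions must be odd.")
  if (kh > nrow(image) || kw > ncol(image)) abort("`kernel` larger than `image`.")
  hh <- (kh - 1) / 2; hw <- (kw - 1) / 2
  h <- nrow(image); w <- ncol(image)
  pad <- matrix(0, h + 2 * hh, w + 2 * hw)
  pad[(hh + 1):(hh + h), (hw + 1):(hw + w)] <- image
  if (border == "replicate") {
    pad[1:hh, ] <- pad[rep(hh + 1, hh), ]
    pad[(hh + h + 1):(hh + h + hh), ] <- pad[rep(hh + h, hh), ]
    pad[, 1:hw] <- pad[, rep(hw + 1, hw)]
    pad[, (hw + w + 1):(hw + w + hw)] <- pad[, rep(hw + w, hw)]
  }
  out <- matrix(0, h, w)
  # correlation as a sum of shifted copies; exact and fast for small kernels
  for (di in seq_len(kh)) {
    for (dj in seq_len(kw)) {
      out <- out + kernel[di, dj] * pad[(di):(di + h - 1), (dj):(dj + w - 1)]
    }
  }
  out
}

#' Poisson rate coding of an image
#'
#' Maps pixel intensities linearly to firing rates — the brightest pixel to
#' `config$max_rate` — and draws, for every pixel and stimulus step, an
#' independent Bernoulli spike with probability `rate * dt`. Negative
#' intensities (from DoG filtering) are clipped to zero beforehand unless the
#' config selects the two-channel ON/OFF mode, in which case the OFF channel
#' encodes the rectified negative part as a second stacked population.
#'
#' @param image Numeric matrix of (possibly signed) intensities.
#' @param config An [encoder_config()].
#' @param seed Integer seed; identical image + seed gives a bit-identical
#'   raster.
#' @return A `spike_raster`: integer matrix of 0/1 with one row per input
#'   neuron (pixels in column-major order) and `config$n_steps` columns, with
#'   attributes `dt` (ms), `seed` and `settle_steps`.
#' @export
poisson_encode <- function(image, config = encoder_config(), seed = NULL) {
  check_image(image)
  stopifnot(inherits(config, "encoder_config"))
  if (config$rectify_negatives) {
    vals <- pmax(as.vector(image), 0)
  } else {
    vals <- c(pmax(as.vector(image), 0), pmax(-as.vector(image), 0))
  }
  peak <- max(vals)
  p <- if (peak > 0) (vals / peak) * config$max_rate * config$dt / 1000 else rep(0, length(vals))
  raster <- with_seed_(seed, {
    matrix(as.integer(stats::runif(length(p) * config$n_steps) < p),
           nrow = length(p), ncol = config$n_steps)
  })
  spike_raster(raster, dt = config$dt, seed = seed, settle_steps = config$settle_steps)
}

#' Spike raster container
#'
#' A binary neurons-by-time matrix with its time step attached. `tidy()`
#' converts it to an event table (`neuron_id`, `time_step`).
#'
#' @param spikes Integer 0/1 matrix, neurons in rows, time steps in columns.
#' @param dt Time step in ms.
#' @param seed Seed recorded for provenance (may be `NULL`).
#' @param settle_steps Silent settle steps this raster assumes are prepended
#'   at simulation time (0 for rasters that already include them).
#' @return An integer matrix of class `spike_raster`.
#' @export
spike_raster <- function(spikes, dt, seed = NULL, settle_steps = 0L) {
  stopifnot(is.matrix(spikes))
  storage.mode(spikes) <- "integer"
  if (length(spikes)) {
    r <- range(spikes)
    if (is.na(r[1]) || r[1] < 0L || r[2] > 1L) abort("raster entries must be 0/1.")
  }
  structure(spikes, dt = dt, seed = if (!is.null(seed)) as.integer(seed),
            settle_steps = as.integer(settle_steps),
            class = c("spike_raster", class(spikes)))
}

#' @export
print.spike_raster <- function(x, ...) {
  cat(sprintf("<spike_raster> %d neurons x %d steps (dt = %g ms, %d spikes)\n",
              nrow(x), ncol(x), attr(x, "dt"), sum(x)))
  invisible(x)
}

#' @export
tidy.spike_raster <- function(x, ...) {
  ev <- which(x == 1L, arr.ind = TRUE)
  tibble(neuron_id = as.integer(ev[, 1]), time_step = as.integer(ev[, 2])) |>
    arrange(.data$time_step, .data$neuron_id)
}

#' @export
autoplot.spike_raster <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$time_step * attr(object, "dt"),
                                 y = .data$neuron_id)) +
    ggplot2::geom_point(shape = ".", ...) +
    ggplot2::labs(x = "time (ms)", y = "neuron") +
    ggplot2::theme_minimal()
}

#' Write / read a spike raster as a CSV event list
#'
#' The event list has columns `neuron_id,time_step`; a JSON sidecar
#' (`<path>.json`) records `dt`, `n_neurons`, `n_steps`, `settle_steps` and
#' the seed so the raster round-trips exactly.
#'
#' @param raster A [spike_raster()].
#' @param path CSV output path.
#' @export
write_spike_raster <- function(raster, path) {
  stopifnot(inherits(raster, "spike_raster"))
  utils::write.csv(tidy(raster), path, row.names = FALSE, quote = FALSE)
  meta <- list(dt = attr(raster, "dt"), n_neurons = nrow(raster),
               n_steps = ncol(raster), settle_steps = attr(raster, "settle_steps"),
               seed = attr(raster, "seed"))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_spike_raster
#' @export
read_spike_raster <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  ev <- utils::read.csv(path)
  m <- matrix(0L, meta$n_neurons, meta$n_steps)
  if (nrow(ev)) m[cbind(ev$neuron_id, ev$time_step)] <- 1L
  spike_raster(m, dt = meta$dt, seed = meta$seed, settle_steps = meta$settle_steps)
}

#' Add white noise to an image
#'
#' Adds zero-mean Gaussian noise whose standard deviation is
#' `noise_level` times the standard deviation of the clean image's pixels
#' (a noise-to-signal amplitude ratio: `0.2` means "20% white noise"), then
#' clips to `[0, 1]`.
#'
#' @param image Numeric matrix in `[0, 1]`.
#' @param noise_level Non-negative fraction `sd(noise) / sd(image)`.
#' @param seed Integer seed.
#' @param clip Clip the result to `[0, 1]` (default); set `FALSE` to inspect
#'   the raw noisy values.
#' @return Noisy image matrix.
#' @export
add_input_noise <- function(image, noise_level, seed = NULL, clip = TRUE) {
  check_image(image)
  check_scalar_number(noise_level, "noise_level", lower = 0)
  if (noise_level == 0) return(image)
  s <- stats::sd(as.vector(image))
  noisy <- with_seed_(seed, image + matrix(stats::rnorm(length(image), 0, noise_level * s),
                                           nrow(image), ncol(image)))
  if (clip) noisy <- pmin(pmax(noisy, 0), 1)
  noisy
}
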