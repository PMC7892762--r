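# Shared fixtures: hand-built miniature networks and brute-force oracles.

# Brute-force 2D correlation with zero padding (independent of apply_dog).
oracle_correlate <- function(image, kernel) {
  h <- nrow(image); w <- ncol(image)
  kh <- nrow(kernel); kw <- ncol(kernel)
  hh <- (kh - 1) / 2; hw <- (kw - 1) / 2
  out <- matrix(0, h, w)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      acc <- 0
      for (a in seq_len(kh)) {
        for (b in seq_len(kw)) {
          ii <- i + a - 1 - hh; jj <- j + b - 1 - hw
          if (ii >= 1 && ii <= h && jj >= 1 && jj <= w) {
            acc <- acc + kernel[a, b] * image[ii, jj]
          }
        }
      }
      out[i, j] <- acc
    }
  }
  out
}

# Brute-force line-Hough accumulator under strict quantization: count, per
# (rho, theta) cell, the active pixels with x*cos(theta) + y*sin(theta) == rho.
oracle_line_hough <- function(image, rho_values, theta_values) {
  acc <- matrix(0, length(rho_values), length(theta_values))
  for (yy in 0:(nrow(image) - 1)) {
    for (xx in 0:(ncol(image) - 1)) {
      v <- image[yy + 1, xx + 1]
      if (v == 0) next
      for (it in seq_along(theta_values)) {
        r <- xx * cos(theta_values[it]) + yy * sin(theta_values[it])
        for (ir in seq_along(rho_values)) {
          if (abs(r - rho_values[ir]) < 1e-9) acc[ir, it] <- acc[ir, it] + v
        }
      }
    }
  }
  acc
}

# Brute-force circle-Hough accumulator under strict quantization.
oracle_circle_hough <- function(image, a_values, b_values, r_values) {
  acc <- array(0, c(length(a_values), length(b_values), length(r_values)))
  for (yy in 0:(nrow(image) - 1)) {
    for (xx in 0:(ncol(image) - 1)) {
      v <- image[yy + 1, xx + 1]
      if (v == 0) next
      for (ia in seq_along(a_values)) for (ib in seq_along(b_values)) {
        d2 <- (xx - a_values[ia])^2 + (yy - b_values[ib])^2
        for (ir in seq_along(r_values)) {
          if (abs(d2 - r_values[ir]^2) < 1e-9) acc[ia, ib, ir] <- acc[ia, ib, ir] + v
        }
      }
    }
  }
  acc
}

# Minimal hand-wired network: `n` neurons of the given types, explicit input
# and recurrent synapse tables with explicit weights/delays (in steps).
make_micro_network <- function(types, n_in, input_df, recurrent_df = NULL,
                               dt = 0.4, params = lif_params()) {
  n <- length(types)
  input <- synapse_set(input_df$pre, input_df$post, weight = input_df$weight,
                       delay = input_df$delay, n_pre = n_in, n_post = n,
                       pre_pop = "pixels", post_pop = "reservoir")
  if (is.null(recurrent_df)) {
    recurrent_df <- data.frame(pre = integer(0), post = integer(0),
                               weight = double(0), delay = integer(0))
  }
  recurrent <- synapse_set(recurrent_df$pre, recurrent_df$post,
                           weight = recurrent_df$weight, delay = recurrent_df$delay,
                           n_pre = n, n_post = n,
                           pre_pop = "reservoir", post_pop = "reservoir")
  recurrent$kind <- rep("intra", nrow(recurrent))
  modlsm:::new_lsm_network(
    neurons = tibble::tibble(id = seq_len(n), module = 1L, type = types),
    input = input, recurrent = recurrent, graph = NULL,
    modules = tibble::tibble(id = 1L, size = n, role = "micro"),
    config = topology_config("random"), dt = dt, params = params,
    syn = synapse_params())
}

# A 3-module chain (1 -> 2 -> 3) of 9-neuron small-world modules with input
# into module 1 only: the small oracle fixture for the divide-and-conquer
# scheduler.
make_chain_network <- function(seed = 1, n_in = 16, dt = 0.4) {
  withr::with_seed(seed, {
    syn <- synapse_params()
    sizes <- c(9L, 9L, 9L)
    offsets <- c(0L, 9L, 18L)
    n <- sum(sizes)
    types <- c(modlsm:::sample_types(9, 0.8), modlsm:::sample_types(9, 0.8),
               modlsm:::sample_types(9, 0.8))
    rec <- list()
    for (m in 1:3) {
      sw <- generate_small_world(3, 3, p_rewire = 0.2)
      pre <- offsets[m] + sw$pre; post <- offsets[m] + sw$post
      rec[[m]] <- data.frame(
        pre = pre, post = post,
        weight = modlsm:::weight_for_types(types[pre], types[post], syn),
        delay = modlsm:::delay_steps_for_types(types[pre], types[post], syn, dt),
        kind = "intra")
    }
    for (e in list(c(1, 2), c(2, 3))) {
      cm <- connect_modules(9, 9, fan_out = 3, weight = 20)
      pre <- offsets[e[1]] + cm$pre; post <- offsets[e[2]] + cm$post
      rec[[length(rec) + 1L]] <- data.frame(
        pre = pre, post = post, weight = 20,
        delay = modlsm:::delay_steps_for_types(types[pre], types[post],
                                               syn, dt),
        kind = "inter")
    }
    rec <- do.call(rbind, rec)
    recurrent <- synapse_set(rec$pre, rec$post, weight = rec$weight,
                             delay = rec$delay, n_pre = n, n_post = n,
                             pre_pop = "reservoir", post_pop = "reservoir")
    recurrent$kind <- rec$kind
    inp <- random_input_synapses(n_in, 9, fan_out = 4, weight = 25)
    input <- synapse_set(inp$pre, inp$post, weight = inp$weight,
                         delay = modlsm:::delay_steps_for_types(
                           "ex", types[inp$post], synapse_params(), dt),
                         n_pre = n_in, n_post = n,
                         pre_pop = "pixels", post_pop = "reservoir")
    graph <- structure(list(n_modules = 3L, input_modules = 1L,
                            edges = tibble::tibble(from = c(1L, 2L), to = c(2L, 3L))),
                       class = "module_graph")
    modlsm:::new_lsm_network(
      neurons = tibble::tibble(id = seq_len(n),
                               module = rep(1:3, each = 9L), type = types),
      input = input, recurrent = recurrent, graph = graph,
      modules = tibble::tibble(id = 1:3, size = sizes, role = "small_world"),
      config = topology_config("modular"), dt = dt, params = lif_params(),
      syn = synapse_params())
  })
}

# A dense constant input raster (every pixel spikes with probability p).
make_drive_raster <- function(n_in, n_steps, p = 0.2, seed = 1, dt = 0.4,
                              settle = 25L) {
  withr::with_seed(seed, {
    spike_raster(matrix(as.integer(stats::runif(n_in * n_steps) < p),
                        n_in, n_steps),
                 dt = dt, settle_steps = settle)
  })
}

# Scaled-down toy study conditions shared by the end-to-end acceptance runs.
toy_encoder <- function() encoder_config(n_steps = 400)
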