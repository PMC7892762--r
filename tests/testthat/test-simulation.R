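test_that("zero-input decay follows the closed-form exponential", {
  p <- lif_params()
  # iterate the exponential-Euler update from 14.5 mV for 30 ms (75 steps)
  V <- 14.5
  for (i in 1:75) V <- lif_update(V, 0, p, dt = 0.4)$V
  expect_equal(V, 13.5 + 1 * exp(-1), tolerance = 1e-9)
  # rest is a fixed point
  fix <- lif_update(p$v_rest, 0, p, dt = 0.4)
  expect_equal(fix$V, p$v_rest)
  expect_false(fix$spiked)
  # threshold crossing resets to 13.5 mV
  up <- lif_update(14.9, 200, p, dt = 0.4)
  expect_true(up$spiked)
  expect_equal(up$V, 13.5)
  expect_error(lif_update(14, NaN, p), "non-finite")
})

test_that("the compiled kernel reproduces the closed-form decay after a kick", {
  # one excitatory neuron, one input pixel, weight 20, delay 4 steps
  net <- make_micro_network(types = "ex", n_in = 1,
                            input_df = data.frame(pre = 1, post = 1,
                                                  weight = 20, delay = 4L))
  ras <- spike_raster(matrix(c(1L, rep(0L, 59)), 1, 60), dt = 0.4,
                      settle_steps = 0L)
  sim <- simulate_network(net, ras, record_v = TRUE)
  v <- sim$voltage[1, ]
  p <- lif_params(); decay <- exp(-0.4 / 30)
  # current from the step-1 spike arrives at step 5 (1.5 ms -> 4 steps)
  expect_true(all(v[1:4] == p$v_rest))
  kick <- p$v_rest + 20 * (1 - decay)
  expect_equal(v[5], kick, tolerance = 1e-12)
  # subsequent free decay matches the analytic solution to 1e-9
  expect_equal(v[5 + (1:40)],
               p$v_rest + (kick - p$v_rest) * decay^(1:40), tolerance = 1e-9)
})

test_that("sub-millisecond delays and refractory periods convert by ceiling", {
  expect_equal(modlsm:::delay_to_steps(1.5, 0.4), 4L)
  expect_equal(modlsm:::delay_to_steps(0.8, 0.4), 2L)
  expect_equal(modlsm:::refrac_steps_for(c("ex", "in"), lif_params(), 0.4),
               c(13L, 5L))
})

test_that("refractory neurons cannot spike within their dead time", {
  for (ty in c("ex", "in")) {
    net <- make_micro_network(types = ty, n_in = 1,
                              input_df = data.frame(pre = 1, post = 1,
                                                    weight = 500, delay = 1L))
    drive <- spike_raster(matrix(1L, 1, 120), dt = 0.4, settle_steps = 0L)
    sim <- simulate_network(net, drive)
    isi <- diff(which(sim$raster[1, ] == 1))
    gap <- if (ty == "ex") 13L else 5L
    expect_true(all(isi >= gap + 1L))
    expect_gt(sum(sim$raster), 0)
  }
})

test_that("a silent input yields a silent reservoir", {
  net <- make_chain_network(seed = 2)
  ras <- spike_raster(matrix(0L, 16, 80), dt = 0.4, settle_steps = 10L)
  sim <- simulate_network(net, ras)
  expect_equal(sum(sim$raster), 0)
})

test_that("simulation is deterministic and its raster covers settle + stimulus", {
  net <- make_chain_network(seed = 3)
  ras <- make_drive_raster(16, 100, p = 0.25, seed = 8)
  a <- simulate_network(net, ras)
  b <- simulate_network(net, ras)
  expect_identical(unclass(a$raster), unclass(b$raster))
  expect_equal(ncol(a$raster), 25 + 100)
  expect_gt(sum(a$raster), 0)
})

test_that("modular and monolithic simulation agree bit-exactly on a 3-module chain", {
  for (s in 1:3) {
    net <- make_chain_network(seed = s)
    ras <- make_drive_raster(16, 150, p = 0.3, seed = 20 + s)
    mono <- simulate_network(net, ras, mode = "monolithic", record_v = TRUE)
    modu <- simulate_network(net, ras, mode = "modular", record_v = TRUE)
    expect_identical(unclass(mono$raster), unclass(modu$raster))
    expect_identical(mono$voltage, modu$voltage)
    expect_gt(sum(mono$raster), 0)
  }
})

test_that("a cyclic module graph is rejected with the offending edge named", {
  net <- make_chain_network(seed = 1)
  net$graph$edges <- tibble::add_row(net$graph$edges, from = 3L, to = 2L)
  ras <- make_drive_raster(16, 20, seed = 1)
  expect_error(simulate_network(net, ras, mode = "modular"), "3 -> 2")
})

test_that("removing an excitatory synapse never adds spikes in a purely excitatory net", {
  withr::with_seed(42, {
    types <- rep("ex", 12)
    rec <- generate_small_world(3, 4, p_rewire = 0.2)
    rec_df <- data.frame(pre = rec$pre, post = rec$post, weight = 20, delay = 4L)
    inp <- data.frame(pre = 1:6, post = 2 * (1:6), weight = 30, delay = 4L)
    net <- make_micro_network(types, n_in = 6, input_df = inp, recurrent_df = rec_df)
    ras <- make_drive_raster(6, 200, p = 0.3, seed = 5)
    full <- sum(simulate_network(net, ras)$raster)
    for (drop in c(1, 5, 10)) {
      cut <- net
      cut$recurrent$alive[drop] <- FALSE
      expect_lte(sum(simulate_network(cut, ras)$raster), full)
    }
  })
})

test_that("firing-rate features are spike counts over the stimulus window", {
  # hand-built raster: 160 spikes in 1,600 steps of 0.4 ms -> 250 spikes/s
  m <- matrix(0L, 2, 1600)
  m[1, seq_len(160)] <- 1L
  f <- extract_features(spike_raster(m, dt = 0.4))
  expect_equal(f$rate, c(250, 0))
  # a neuron spiking every step codes at 1/dt = 2,500 spikes/s
  every <- matrix(1L, 1, 100)
  expect_equal(extract_features(spike_raster(every, dt = 0.4))$rate, 2500)
  # settle-phase spikes are excluded from sim_result features
  net <- make_chain_network(seed = 4)
  ras <- make_drive_raster(16, 100, p = 0.3, seed = 9)
  sim <- simulate_network(net, ras)
  f2 <- extract_features(sim)
  stim <- sim$raster[, sim$settle_steps + seq_len(100), drop = FALSE]
  expect_equal(f2$rate, rowSums(stim) / (100 * 0.4 / 1000))
})
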