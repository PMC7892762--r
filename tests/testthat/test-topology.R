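test_that("strict line-Hough synapses realize the exact accumulator", {
  grid <- hough_line_grid(rho_values = 0:15, theta_values = c(0, pi / 4),
                          mode = "strict")
  syn <- build_line_hough(grid, c(28, 28))
  # all 28 pixels of column x = 5 hit cell (rho = 5, theta = 0)
  img <- make_shape_image("vline", x = 5)
  resp <- hough_response(syn, img)
  cell <- which(grid$rho_values == 5)  # theta index 1 -> id = rho index
  expect_equal(resp[cell], 28)
  # the full response equals the brute-force double-loop accumulator
  acc <- oracle_line_hough(img, grid$rho_values, grid$theta_values)
  expect_equal(resp, as.vector(acc))
  # empty image -> all-zero accumulator
  expect_equal(hough_response(syn, matrix(0, 28, 28)), rep(0, 32))
})

test_that("default Hough grids size the two input modules", {
  expect_equal(n_post(build_line_hough(hough_line_grid())), 192)
  expect_equal(n_post(build_circle_hough(hough_circle_grid())), 216)
  expect_error(hough_line_grid(theta_values = c(0.5, 0.2)), "increasing")
  expect_error(build_line_hough(hough_line_grid(rho_values = numeric(0))), "empty")
})

test_that("strict circle-Hough synapses enumerate exact lattice circles", {
  grid <- hough_circle_grid(a_values = 13, b_values = 13, r_values = c(0, 5),
                            mode = "strict")
  syn <- build_circle_hough(grid, c(28, 28))
  # r = 0: only the centre pixel connects
  r0 <- syn[syn$post == 1, ]
  expect_equal(nrow(r0), 1)
  expect_equal(r0$pre, modlsm:::pixel_index(13, 13, c(28, 28)))
  # r = 5: exactly the 12 Pythagorean lattice points
  r5 <- syn[syn$post == 2, ]
  expect_equal(nrow(r5), 12)
  img <- make_shape_image("circle", center = c(13, 13), r = 5)
  expect_equal(hough_response(syn, img)[2], 12)
  # against the brute-force accumulator oracle
  acc <- oracle_circle_hough(img, grid$a_values, grid$b_values, grid$r_values)
  expect_equal(hough_response(syn, img), as.vector(acc))
})

test_that("nearest-bin quantization connects each pixel-theta pair at most once", {
  syn <- build_line_hough(hough_line_grid(), c(28, 28))
  pair <- paste(syn$pre, (syn$post - 1) %/% 16)
  expect_equal(anyDuplicated(pair), 0)
})

test_that("the un-rewired 9x15 king lattice has 940 directed edges", {
  sw <- generate_small_world(9, 15, p_rewire = 0)
  # enumeration: 2 * (horizontal 9*14 + vertical 8*15 + diagonal 2*8*14)
  expect_equal(nrow(sw), 2 * (9 * 14 + 15 * 8 + 2 * 8 * 14))
  expect_true(all(sw$pre != sw$post))
})

test_that("rewiring preserves out-degrees, avoids duplicates, and is seeded", {
  base <- generate_small_world(9, 15, p_rewire = 0)
  for (p in c(0.35, 1)) {
    sw <- generate_small_world(9, 15, p_rewire = p, seed = 4)
    expect_equal(table(factor(sw$pre, levels = 1:135)),
                 table(factor(base$pre, levels = 1:135)))
    expect_equal(anyDuplicated(sw[c("pre", "post")]), 0)
    expect_true(all(sw$pre != sw$post))
  }
  expect_identical(as.data.frame(generate_small_world(9, 15, 8, 1, seed = 7)),
                   as.data.frame(generate_small_world(9, 15, 8, 1, seed = 7)))
})

test_that("metric connection probability follows the Gaussian distance kernel", {
  C_map <- c("ex-ex" = 0.3, "ex-in" = 0.2, "in-ex" = 0.4, "in-in" = 0.1)
  expect_equal(modlsm:::metric_prob(1, "ex", "ex", C_map, 2), 0.3 * exp(-1 / 4))
  expect_equal(modlsm:::metric_prob(0, "in", "ex", C_map, 2), 0.4)
  # lambda -> 0: all probabilities vanish at D >= 1
  expect_lt(modlsm:::metric_prob(1, "ex", "ex", C_map, 1e-3), 1e-12)
  expect_error(generate_metric(c(2, 2, 2), C_map = c("ex-ex" = 0.3)), "type pair")
})

test_that("metric generator respects types, excludes self-connections, is seeded", {
  g <- generate_metric(c(4, 4, 4), seed = 5)
  expect_true(all(g$pre != g$post))
  types <- attr(g, "types")
  expect_equal(sum(types == "ex"), round(0.8 * 64))
  expect_identical(as.data.frame(generate_metric(c(4, 4, 4), seed = 5)),
                   as.data.frame(g))
})

test_that("random generator hits its density limits", {
  expect_equal(nrow(generate_random(50, 0, seed = 1)), 0)
  full <- generate_random(20, 1, seed = 1)
  expect_equal(nrow(full), 20 * 19)
  expect_equal(as.vector(table(full$pre)), rep(19L, 20))
})

test_that("module DAG generation matches its candidate-edge enumeration", {
  expect_equal(nrow(generate_dag(10, 0, seed = 1)$edges), 0)
  # p = 1: all sum_{i=3..10} (i-1) = 44 candidate edges
  g1 <- generate_dag(10, 1, seed = 1)
  expect_equal(nrow(g1$edges), 44)
  expect_true(all(g1$edges$from < g1$edges$to))
  expect_false(any(g1$edges$to %in% g1$input_modules))
  expect_error(generate_dag(10, 1.5), "\\[0, 1\\]")
  expect_error(generate_dag(10, 0.2, input_modules = c(2L, 3L)), "first")
})

test_that("generated DAGs pass an independent igraph acyclicity check", {
  for (s in 1:10) {
    g <- generate_dag(10, 0.25, seed = s)
    if (nrow(g$edges)) {
      ig <- igraph::graph_from_edgelist(as.matrix(g$edges), directed = TRUE)
      expect_true(igraph::is_dag(ig))
    }
    d <- module_depths(g)
    expect_equal(d[1:2], c(0L, 0L))
  }
})

test_that("mean DAG edge count matches the binomial expectation 0.25 * 44 = 11", {
  counts <- vapply(1:1000, function(s) nrow(generate_dag(10, 0.25, seed = s)$edges),
                   numeric(1))
  # binomial sd sqrt(44 * .25 * .75) ~ 2.87 -> se ~ 0.09 over 1000 seeds
  expect_equal(mean(counts), 11, tolerance = 0.03)
})

test_that("inter-module wiring gives every presynaptic neuron its exact fan-out", {
  cm <- connect_modules(135, 135, fan_out = 10, weight = 20, seed = 2)
  expect_equal(nrow(cm), 1350)
  expect_equal(as.vector(table(cm$pre)), rep(10L, 135))
  expect_equal(anyDuplicated(cm[c("pre", "post")]), 0)
  expect_true(all(cm$weight == 20))
  # fan-out truncated to a small post module
  small <- connect_modules(5, 3, fan_out = 10, seed = 2)
  expect_equal(as.vector(table(small$pre)), rep(3L, 5))
  expect_identical(as.data.frame(connect_modules(20, 30, 10, 1, seed = 9)),
                   as.data.frame(connect_modules(20, 30, 10, 1, seed = 9)))
})

test_that("assembled reservoirs have the configured population structure", {
  mod <- assemble_reservoir(topology_config("modular"), seed = 3)
  expect_equal(nrow(mod$neurons), 1488)
  expect_equal(mod$modules$size, c(192, 216, rep(135, 8)))
  expect_true(all(mod$neurons$type[mod$neurons$module <= 2] == "ex"))
  # small-world modules have the exact 80/20 split
  m3 <- mod$neurons$type[mod$neurons$module == 3]
  expect_equal(sum(m3 == "ex"), 108)
  # input synapses only reach the two Hough modules
  expect_true(all(mod$input$post <= 192 + 216))
  # recurrent weights follow the type map
  rec <- mod$recurrent
  pt <- mod$neurons$type[rec$pre]; qt <- mod$neurons$type[rec$post]
  intra <- rec$kind == "intra"
  expect_true(all(rec$weight[intra & pt == "in"] == -17))
  expect_true(all(rec$weight[intra & pt == "ex" & qt == "ex"] == 20))
  expect_true(all(rec$weight[intra & pt == "ex" & qt == "in"] == 45))
  expect_true(all(rec$weight[rec$kind == "inter"] == 20))
  # delays: ex-ex 1.5 ms -> 4 steps at 0.4 ms; otherwise 0.8 ms -> 2 steps
  expect_true(all(rec$delay[pt == "ex" & qt == "ex"] == 4L))
  expect_true(all(rec$delay[!(pt == "ex" & qt == "ex")] == 2L))

  sw <- assemble_reservoir(topology_config("small_world"), seed = 3)
  expect_equal(nrow(sw$neurons), 1500)
  expect_equal(nrow(sw$modules), 1)
  expect_null(sw$graph)
})

test_that("assembly is bit-reproducible under a fixed seed", {
  a <- assemble_reservoir(topology_config("modular"), seed = 17)
  b <- assemble_reservoir(topology_config("modular"), seed = 17)
  expect_identical(as.data.frame(a$recurrent), as.data.frame(b$recurrent))
  expect_identical(a$graph$edges, b$graph$edges)
  expect_identical(a$neurons, b$neurons)
})

test_that("synapse sets validate their invariants and export to Matrix Market", {
  expect_error(synapse_set(1, 1, n_pre = 3, n_post = 3,
                           pre_pop = "r", post_pop = "r"), "self")
  expect_error(synapse_set(c(1, 1), c(2, 2), n_pre = 3, n_post = 3), "duplicate")
  expect_error(synapse_set(1, 5, n_pre = 3, n_post = 3), "bounds")
  s <- synapse_set(c(1, 2), c(2, 3), weight = c(1.5, -2), delay = c(1L, 2L),
                   n_pre = 3, n_post = 3, pre_pop = "a", post_pop = "b")
  W <- as_weight_matrix(s)
  expect_equal(dim(W), c(3, 3))
  expect_equal(W[2, 1], 1.5)
  base <- withr::local_tempfile()
  export_synapses(s, base)
  expect_identical(as.data.frame(import_synapses(base)), as.data.frame(s))
})
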