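# Reservoir generators (random, small-world, metric), the module DAG, and
# assembly of complete typed networks.

#' Random (Erdos–Renyi) reservoir connectivity
#'
#' Connects each ordered pair of distinct neurons independently with
#' probability `p`. At the reference configuration (`n = 1500`,
#' `p = 0.01`) the mean out-degree is about 15.
#'
#' @param n Number of neurons (>= 2).
#' @param p Connection probability.
#' @param seed Integer seed.
#' @return A structural [synapse_set()] (unit weights, delays unset).
#' @export
generate_random <- function(n = 1500, p = 0.01, seed = NULL) {
  check_scalar_number(n, "n", lower = 2)
  check_scalar_number(p, "p", lower = 0, upper = 1)
  n <- as.integer(n)
  with_seed_(seed, {
    keep <- stats::runif(n * n) < p
    pre <- rep(seq_len(n), each = n)[keep]
    post <- rep(seq_len(n), times = n)[keep]
    offdiag <- pre != post
    synapse_set(pre[offdiag], post[offdiag], n_pre = n, n_post = n,
                pre_pop = "reservoir", post_pop = "reservoir")
  })
}

# Directed king-lattice (8-neighbour, no wraparound) edge list for an
# r x c grid, neurons numbered row-major.
king_lattice_edges <- function(rows, cols) {
  id <- function(r, c) (r - 1L) * cols + c
  offs <- expand.grid(dr = -1:1, dc = -1:1)
  offs <- offs[!(offs$dr == 0 & offs$dc == 0), ]
  pre <- integer(0); post <- integer(0)
  for (k in seq_len(nrow(offs))) {
    r <- rep(seq_len(rows), times = cols); c <- rep(seq_len(cols), each = rows)
    r2 <- r + offs$dr[k]; c2 <- c + offs$dc[k]
    ok <- r2 >= 1 & r2 <= rows & c2 >= 1 & c2 <= cols
    pre <- c(pre, id(r[ok], c[ok])); post <- c(post, id(r2[ok], c2[ok]))
  }
  cbind(pre = pre, post = post)
}

#' Small-world reservoir connectivity
#'
#' Starts from a 2D regular lattice in which every neuron is connected to its
#' 8 neighbours (Moore / king moves, no wraparound) and rewires each directed
#' edge, independently with probability `p_rewire`, to a uniformly random
#' other destination (no self-loops, no duplicate `(pre, post)` pairs;
#' collisions are resampled). Rewiring moves targets only, so every neuron's
#' out-degree is preserved exactly. The in-module configuration is a 9 x 15
#' lattice rewired with probability 0.35.
#'
#' @param rows,cols Lattice dimensions.
#' @param n_neighbors Number of lattice neighbours (only 8 supported).
#' @param p_rewire Rewiring probability in `[0, 1]`.
#' @param seed Integer seed.
#' @return A structural [synapse_set()] with lattice coordinates attached as
#'   attribute `coords` (tibble `id`, `row`, `col`).
#' @export
generate_small_world <- function(rows = 9, cols = 15, n_neighbors = 8,
                                 p_rewire = 0.35, seed = NULL) {
  check_scalar_number(rows, "rows", lower = 2)
  check_scalar_number(cols, "cols", lower = 2)
  if (n_neighbors != 8) abort("only the 8-neighbour (king) lattice is supported.")
  check_scalar_number(p_rewire, "p_rewire", lower = 0, upper = 1)
  n <- rows * cols
  edges <- king_lattice_edges(rows, cols)
  with_seed_(seed, {
    rewire <- stats::runif(nrow(edges)) < p_rewire
    if (any(rewire)) {
      targets <- split(edges[, "post"], edges[, "pre"])
      for (e in which(rewire)) {
        pre <- edges[e, "pre"]
        key <- as.character(pre)
        # valid new destinations: not the source, not an existing target;
        # when the neuron already reaches every other node, keep the edge
        avail <- setdiff(seq_len(n), c(pre, targets[[key]]))
        if (!length(avail)) next
        cand <- avail[sample.int(length(avail), 1)]
        targets[[key]][match(edges[e, "post"], targets[[key]])] <- cand
        edges[e, "post"] <- cand
      }
    }
    out <- synapse_set(edges[, "pre"], edges[, "post"], n_pre = n, n_post = n,
                       pre_pop = "reservoir", post_pop = "reservoir")
    attr(out, "coords") <- tibble(id = seq_len(n),
                                  row = ((seq_len(n) - 1L) %/% cols) + 1L,
                                  col = ((seq_len(n) - 1L) %% cols) + 1L)
    out
  })
}

metric_prob <- function(d2, pre_type, post_type, C_map, lam) {
  C <- C_map[paste(pre_type, post_type, sep = "-")]
  unname(C * exp(-d2 / lam^2))
}

#' Metric (distance-dependent) reservoir connectivity
#'
#' Neurons sit on the integer points of a 3D lattice; an ordered pair `(a, b)`
#' at Euclidean distance `D` is connected with probability
#' `C(type_a -> type_b) * exp(-D^2 / lambda^2)`. With the reference
#' parameters (15 x 10 x 10 lattice, `lambda = 2`, `C` of 0.3/0.2/0.4/0.1 for
#' ex-ex/ex-in/in-ex/in-in and an 80% excitatory population) the mean
#' out-degree is about 9.4.
#'
#' @param dims Lattice dimensions (product = number of neurons).
#' @param lam Length scale `lambda` of the connection probability.
#' @param C_map Named vector of base probabilities for the four ordered type
#'   pairs `"ex-ex"`, `"ex-in"`, `"in-ex"`, `"in-in"` (pre-post order).
#' @param exc_fraction Fraction of excitatory neurons (assigned at random,
#'   exact count).
#' @param seed Integer seed.
#' @return A structural [synapse_set()] with attributes `types` (per-neuron
#'   `"ex"`/`"in"`) and `coords` (tibble of lattice positions).
#' @export
generate_metric <- function(dims = c(15, 10, 10), lam = 2,
                            C_map = c("ex-ex" = 0.3, "ex-in" = 0.2,
                                      "in-ex" = 0.4, "in-in" = 0.1),
                            exc_fraction = 0.8, seed = NULL) {
  n <- prod(dims)
  needed <- c("ex-ex", "ex-in", "in-ex", "in-in")
  if (!all(needed %in% names(C_map))) abort("`C_map` must name all four ordered type pairs.")
  check_scalar_number(lam, "lam", lower = 1e-12)
  check_scalar_number(exc_fraction, "exc_fraction", lower = 0, upper = 1)
  pts <- as.matrix(expand.grid(x = 0:(dims[1] - 1), y = 0:(dims[2] - 1),
                               z = 0:(dims[3] - 1)))
  with_seed_(seed, {
    types <- rep("in", n)
    types[sample.int(n, round(exc_fraction * n))] <- "ex"
    d2 <- as.matrix(stats::dist(pts))^2
    P <- C_map[paste(rep(types, times = n), rep(types, each = n), sep = "-")] *
      exp(-as.vector(d2) / lam^2)      # vectorized over the full pre x post grid
    keep <- stats::runif(n * n) < P
    pre <- rep(seq_len(n), times = n)[keep]
    post <- rep(seq_len(n), each = n)[keep]
    offdiag <- pre != post
    out <- synapse_set(pre[offdiag], post[offdiag], n_pre = n, n_post = n,
                       pre_pop = "reservoir", post_pop = "reservoir")
    attr(out, "types") <- types
    attr(out, "coords") <- as_tibble(pts) |> mutate(id = dplyr::row_number(), .before = 1)
    out
  })
}

#' Random module DAG
#'
#' Generates the directed acyclic graph of reservoir modules: modules are
#' labelled in topological order with the input modules first, and each
#' candidate edge `j -> i` with `i > j` and `i` not an input module is
#' included independently with probability `p`. The result is acyclic by
#' construction and input modules never receive inter-module edges.
#'
#' @param n_modules Number of modules (default 10).
#' @param p Edge probability (default 0.25).
#' @param input_modules Indices of the input modules (must be the first
#'   labels).
#' @param seed Integer seed.
#' @return An object of class `module_graph`: list with `n_modules`,
#'   `input_modules` and an `edges` tibble (`from`, `to`).
#' @export
generate_dag <- function(n_modules = 10, p = 0.25, input_modules = c(1L, 2L),
                         seed = NULL) {
  check_scalar_number(p, "p", lower = 0, upper = 1)
  check_scalar_number(n_modules, "n_modules", lower = 1)
  input_modules <- as.integer(input_modules)
  if (length(input_modules) && !identical(input_modules, seq_along(input_modules))) {
    abort("`input_modules` must be the first module labels (1, 2, ...).")
  }
  cand <- expand.grid(to = seq_len(n_modules), from = seq_len(n_modules)) |>
    filter(.data$to > .data$from, !(.data$to %in% input_modules))
  edges <- with_seed_(seed, cand[stats::runif(nrow(cand)) < p, c("from", "to")])
  structure(list(n_modules = as.integer(n_modules),
                 input_modules = input_modules,
                 edges = as_tibble(edges)),
            class = "module_graph")
}

#' @export
print.module_graph <- function(x, ...) {
  cat(sprintf("<module_graph> %d modules (%d input), %d inter-module edges\n",
              x$n_modules, length(x$input_modules), nrow(x$edges)))
  invisible(x)
}

#' Module depths in the DAG
#'
#' Breadth-first depth of each module from the input layer: input modules are
#' depth 0 and every other module sits one level below its deepest
#' predecessor. Modules of equal depth are independent given their
#' predecessors and could be simulated in parallel.
#'
#' @param graph A [generate_dag()] result.
#' @return Integer vector of depths, one per module (modules with no path
#'   from an input module get depth `NA`).
#' @export
module_depths <- function(graph) {
  stopifnot(inherits(graph, "module_graph"))
  depth <- rep(NA_integer_, graph$n_modules)
  depth[graph$input_modules] <- 0L
  for (m in seq_len(graph$n_modules)) {
    preds <- graph$edges$from[graph$edges$to == m]
    if (length(preds) && all(!is.na(depth[preds]))) {
      depth[m] <- max(depth[preds]) + 1L
    }
  }
  depth
}

#' Random inter-module wiring
#'
#' Connects every neuron of the presynaptic module to `fan_out` distinct
#' neurons of the post-synaptic module, sampled uniformly without
#' replacement (truncated to the post-module size), all with one constant
#' weight.
#'
#' @param n_pre,n_post Module sizes.
#' @param fan_out Targets per presynaptic neuron (default 10).
#' @param weight Constant synaptic weight.
#' @param seed Integer seed.
#' @return A [synapse_set()] with local (1-based within-module) indices.
#' @export
connect_modules <- function(n_pre, n_post, fan_out = 10, weight = 1, seed = NULL) {
  check_scalar_number(fan_out, "fan_out", lower = 0)
  k <- min(fan_out, n_post)
  with_seed_(seed, {
    post <- unlist(lapply(seq_len(n_pre), function(i) sample.int(n_post, k)))
    synapse_set(rep(seq_len(n_pre), each = k), post, weight = weight,
                n_pre = n_pre, n_post = n_post,
                pre_pop = "pre_module", post_pop = "post_module")
  })
}
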