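# Assembly of complete, typed LSM networks from the structural generators:
# neuron metadata (type, module), input synapses, weighted and delayed
# recurrent synapses, and (for the modular topology) the module DAG.

#' LIF neuron parameters
#'
#' Membrane constants of the leaky integrate-and-fire neurons. The defaults
#' are the classical cortical-microcircuit values: threshold 15 mV, reset and
#' rest at 13.5 mV, membrane time constant 30 ms, refractory periods of 5 ms
#' (excitatory) and 2 ms (inhibitory). `R` is a dimensionless input gain; the
#' synaptic weights absorb the physical scaling.
#'
#' @param v_th Spike threshold (mV).
#' @param v_reset Reset voltage (mV).
#' @param v_rest Resting voltage (mV).
#' @param tau_mem Membrane time constant (ms).
#' @param R Input resistance / current gain.
#' @param refractory_ex,refractory_in Refractory periods (ms) by neuron type.
#' @return An object of class `lif_params`.
#' @export
lif_params <- function(v_th = 15, v_reset = 13.5, v_rest = 13.5, tau_mem = 30,
                       R = 1, refractory_ex = 5, refractory_in = 2) {
  if (v_reset >= v_th) abort("`v_reset` must be below `v_th`.")
  check_scalar_number(tau_mem, "tau_mem", lower = 1e-9)
  structure(list(v_th = v_th, v_reset = v_reset, v_rest = v_rest,
                 tau_mem = tau_mem, R = R,
                 refractory_ex = refractory_ex, refractory_in = refractory_in),
            class = "lif_params")
}

#' Synapse parameters
#'
#' Weights and conduction delays by ordered (pre, post) neuron-type pair:
#' weight 20 for ex->ex, 45 for ex->in, and -17 for any inhibitory
#' presynaptic neuron; delay 1.5 ms for ex->ex and 0.8 ms otherwise. Delays
#' are converted to integer steps by `max(1, ceiling(delay / dt))`.
#'
#' @param w_ex_ex,w_ex_in,w_in Weights (ex->ex, ex->in, in->anything).
#' @param delay_ex_ex,delay_other Delays in ms.
#' @return An object of class `synapse_params`.
#' @export
synapse_params <- function(w_ex_ex = 20, w_ex_in = 45, w_in = -17,
                           delay_ex_ex = 1.5, delay_other = 0.8) {
  structure(list(w_ex_ex = w_ex_ex, w_ex_in = w_ex_in, w_in = w_in,
                 delay_ex_ex = delay_ex_ex, delay_other = delay_other),
            class = "synapse_params")
}

delay_to_steps <- function(ms, dt) max(1L, as.integer(ceiling(ms / dt - 1e-9)))

weight_for_types <- function(pre_type, post_type, sp) {
  ifelse(pre_type == "in", sp$w_in,
         ifelse(post_type == "ex", sp$w_ex_ex, sp$w_ex_in))
}

delay_steps_for_types <- function(pre_type, post_type, sp, dt) {
  ifelse(pre_type == "ex" & post_type == "ex",
         delay_to_steps(sp$delay_ex_ex, dt), delay_to_steps(sp$delay_other, dt))
}

#' Reservoir topology configuration
#'
#' Collects the parameters of the four reference reservoir configurations:
#'
#' * `"random"`: 1,500 neurons, pairwise connection probability 0.01.
#' * `"small_world"`: 1,500 neurons on a 30 x 50 king lattice, 8 neighbours,
#'   rewiring probability 0.35.
#' * `"metric"`: 1,500 neurons on a 15 x 10 x 10 integer lattice,
#'   distance-dependent connection probabilities (`lambda = 2`).
#' * `"modular"`: 10 modules in a random DAG — module 1 the 192-neuron
#'   line-Hough layer, module 2 the 216-neuron circle-Hough layer, modules
#'   3–10 internally small-world 9 x 15 lattices (135 neurons each); 1,488
#'   neurons in total, inter-module fan-out 10 at constant weight.
#'
#' @param topology One of `"modular"`, `"small_world"`, `"metric"`,
#'   `"random"`.
#' @param exc_fraction Excitatory fraction for typed populations (Hough
#'   modules are all-excitatory).
#' @param input_gain Weight of every input synapse.
#' @param inter_weight Constant weight of inter-module synapses.
#' @param fan_out Inter-module (and, for non-modular topologies, input)
#'   fan-out per presynaptic neuron.
#' @param dag_p Edge probability of the module DAG.
#' @param n_modules Number of modules in the modular topology.
#' @param sw_rewire Small-world rewiring probability.
#' @param module_lattice Lattice dimensions of one small-world module.
#' @param sw_lattice Lattice dimensions of the stand-alone small-world
#'   reservoir.
#' @param random_n,random_p Size and density of the random reservoir.
#' @param metric_dims,metric_lambda,metric_C Metric-generator parameters.
#' @param line_grid,circle_grid Hough grids for the two input modules.
#' @return An object of class `topology_config`.
#' @export
topology_config <- function(topology = c("modular", "small_world", "metric", "random"),
                            exc_fraction = 0.8, input_gain = 20,
                            inter_weight = 20, fan_out = 10,
                            dag_p = 0.25, n_modules = 10, sw_rewire = 0.35,
                            module_lattice = c(9, 15), sw_lattice = c(30, 50),
                            random_n = 1500, random_p = 0.01,
                            metric_dims = c(15, 10, 10), metric_lambda = 2,
                            metric_C = c("ex-ex" = 0.3, "ex-in" = 0.2,
                                         "in-ex" = 0.4, "in-in" = 0.1),
                            line_grid = hough_line_grid(),
                            circle_grid = hough_circle_grid()) {
  topology <- match.arg(topology)
  check_scalar_number(exc_fraction, "exc_fraction", lower = 0, upper = 1)
  check_scalar_number(dag_p, "dag_p", lower = 0, upper = 1)
  structure(list(topology = topology, exc_fraction = exc_fraction,
                 input_gain = input_gain, inter_weight = inter_weight,
                 fan_out = fan_out, dag_p = dag_p, n_modules = n_modules,
                 sw_rewire = sw_rewire, module_lattice = module_lattice,
                 sw_lattice = sw_lattice, random_n = random_n,
                 random_p = random_p, metric_dims = metric_dims,
                 metric_lambda = metric_lambda, metric_C = metric_C,
                 line_grid = line_grid, circle_grid = circle_grid),
            class = "topology_config")
}

# Exact 80/20 (or configured) excitatory/inhibitory split.
sample_types <- function(n, exc_fraction) {
  types <- rep("in", n)
  types[sample.int(n, round(exc_fraction * n))] <- "ex"
  types
}

#' Random input synapses
#'
#' For reservoirs without Hough input maps: each input neuron (pixel) is
#' connected to `fan_out` distinct reservoir neurons chosen uniformly at
#' random, all at the constant input gain.
#'
#' @param n_in Number of input neurons.
#' @param n_out Reservoir size.
#' @param fan_out Targets per input neuron.
#' @param weight Input gain.
#' @param seed Integer seed.
#' @return A [synapse_set()].
#' @export
random_input_synapses <- function(n_in, n_out, fan_out = 10, weight = 20,
                                  seed = NULL) {
  k <- min(fan_out, n_out)
  with_seed_(seed, {
    post <- unlist(lapply(seq_len(n_in), function(i) sample.int(n_out, k)))
    synapse_set(rep(seq_len(n_in), each = k), post, weight = weight,
                n_pre = n_in, n_post = n_out,
                pre_pop = "pixels", post_pop = "reservoir")
  })
}

#' Assemble a complete reservoir network
#'
#' Builds the typed, weighted, delayed network for one topology
#' configuration. For the modular topology this wires the line- and
#' circle-Hough input layers as modules 1 and 2, small-world recurrence
#' inside modules 3–10, and the inter-module synapses realized from a fresh
#' module DAG; for the other topologies it wires random input fan-out into a
#' single module.
#'
#' @param config A [topology_config()].
#' @param seed Integer seed controlling types, structure and the DAG.
#' @param image_dims Input image dimensions.
#' @param params A [lif_params()] (for delay conversion bookkeeping).
#' @param syn A [synapse_params()].
#' @param dt Simulation time step in ms (fixes the integer delays).
#' @return An object of class `lsm_network`: list with `neurons` (tibble
#'   `id`, `module`, `type`), `input` and `recurrent` [synapse_set()]s (the
#'   latter with a `kind` column, `"intra"` or `"inter"`), `graph` (a
#'   `module_graph` or `NULL`), `modules` (tibble `id`, `size`, `role`) and
#'   the configuration.
#' @export
assemble_reservoir <- function(config = topology_config(), seed = NULL,
                               image_dims = c(28, 28), params = lif_params(),
                               syn = synapse_params(), dt = 0.4) {
  stopifnot(inherits(config, "topology_config"))
  n_in <- prod(image_dims)
  with_seed_(seed, {
    if (config$topology == "modular") {
      assemble_modular(config, image_dims, syn, dt, params)
    } else {
      str <- switch(config$topology,
        small_world = generate_small_world(config$sw_lattice[1], config$sw_lattice[2],
                                           p_rewire = config$sw_rewire),
        metric = generate_metric(config$metric_dims, config$metric_lambda,
                                 config$metric_C, config$exc_fraction),
        random = generate_random(config$random_n, config$random_p)
      )
      n <- n_post(str)
      types <- attr(str, "types") %||% sample_types(n, config$exc_fraction)
      neurons <- tibble(id = seq_len(n), module = 1L, type = types)
      wt <- weight_for_types(types[str$pre], types[str$post], syn)
      dl <- delay_steps_for_types(types[str$pre], types[str$post], syn, dt)
      recurrent <- synapse_set(str$pre, str$post, weight = wt, delay = dl,
                               n_pre = n, n_post = n,
                               pre_pop = "reservoir", post_pop = "reservoir")
      recurrent$kind <- "intra"  # $<- keeps the synapse_set attributes
      input <- random_input_synapses(n_in, n, config$fan_out, config$input_gain)
      input$delay <- delay_steps_for_types("ex", types[input$post], syn, dt)
      new_lsm_network(neurons, input, recurrent, graph = NULL,
                      modules = tibble(id = 1L, size = n, role = config$topology),
                      config = config, dt = dt, params = params, syn = syn)
    }
  })
}

assemble_modular <- function(config, image_dims, syn, dt, params) {
  n_in <- prod(image_dims)
  line <- build_line_hough(config$line_grid, image_dims, weight = config$input_gain)
  circ <- build_circle_hough(config$circle_grid, image_dims, weight = config$input_gain)
  sizes <- c(n_post(line), n_post(circ),
             rep(prod(config$module_lattice), config$n_modules - 2L))
  offsets <- cumsum(c(0L, sizes[-length(sizes)]))
  n_total <- sum(sizes)
  roles <- c("hough_line", "hough_circle", rep("small_world", config$n_modules - 2L))

  neurons <- purrr::map2_dfr(seq_along(sizes), roles, function(m, role) {
    types <- if (role == "small_world") sample_types(sizes[m], config$exc_fraction)
             else rep("ex", sizes[m])
    tibble(id = offsets[m] + seq_len(sizes[m]), module = as.integer(m), type = types)
  })

  # Input synapses: Hough maps into modules 1 and 2 (all-excitatory posts)
  input <- synapse_set(c(line$pre, circ$pre),
                       c(line$post, offsets[2] + circ$post),
                       weight = config$input_gain,
                       delay = delay_to_steps(syn$delay_ex_ex, dt),
                       n_pre = n_in, n_post = n_total,
                       pre_pop = "pixels", post_pop = "reservoir")

  # Intra-module small-world recurrence (modules 3..n); Hough modules are
  # feed-forward encoding layers with no internal recurrence.
  rec <- list()
  for (m in seq_along(sizes)) {
    if (roles[m] != "small_world") next
    sw <- generate_small_world(config$module_lattice[1], config$module_lattice[2],
                               p_rewire = config$sw_rewire)
    pre <- offsets[m] + sw$pre; post <- offsets[m] + sw$post
    pt <- neurons$type[pre]; qt <- neurons$type[post]
    rec[[length(rec) + 1L]] <- tibble(
      pre = pre, post = post,
      weight = weight_for_types(pt, qt, syn),
      delay = delay_steps_for_types(pt, qt, syn, dt),
      kind = "intra")
  }

  graph <- generate_dag(config$n_modules, config$dag_p, input_modules = c(1L, 2L))
  if (nrow(graph$edges)) {
    for (e in seq_len(nrow(graph$edges))) {
      from <- graph$edges$from[e]; to <- graph$edges$to[e]
      cm <- connect_modules(sizes[from], sizes[to], config$fan_out,
                            weight = config$inter_weight)
      pre <- offsets[from] + cm$pre; post <- offsets[to] + cm$post
      rec[[length(rec) + 1L]] <- tibble(
        pre = pre, post = post, weight = config$inter_weight,
        delay = delay_steps_for_types(neurons$type[pre], neurons$type[post], syn, dt),
        kind = "inter")
    }
  }
  rec <- bind_rows(rec)
  recurrent <- synapse_set(rec$pre, rec$post, weight = rec$weight, delay = rec$delay,
                           n_pre = n_total, n_post = n_total,
                           pre_pop = "reservoir", post_pop = "reservoir")
  recurrent$kind <- rec$kind
  new_lsm_network(neurons, input, recurrent, graph = graph,
                  modules = tibble(id = seq_along(sizes), size = sizes, role = roles),
                  config = config, dt = dt, params = params, syn = syn)
}

new_lsm_network <- function(neurons, input, recurrent, graph, modules, config,
                            dt, params, syn) {
  structure(list(neurons = neurons, input = input, recurrent = recurrent,
                 graph = graph, modules = modules, config = config,
                 dt = dt, params = params, syn = syn),
            class = "lsm_network")
}

#' @export
print.lsm_network <- function(x, ...) {
  cat(sprintf("<lsm_network> topology '%s': %d neurons in %d module(s), %d input + %d recurrent synapses\n",
              x$config$topology, nrow(x$neurons), nrow(x$modules),
              nrow(x$input), nrow(x$recurrent)))
  if (!is.null(x$graph)) print(x$graph)
  invisible(x)
}

#' @export
glance.lsm_network <- function(x, ...) {
  tibble(topology = x$config$topology,
         n_neurons = nrow(x$neurons),
         n_modules = nrow(x$modules),
         n_input_synapses = nrow(x$input),
         n_recurrent_synapses = nrow(x$recurrent),
         n_alive = sum(x$recurrent$alive),
         mean_out_degree = nrow(x$recurrent) / nrow(x$neurons))
}
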