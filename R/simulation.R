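# LIF network simulation: exponential-Euler membrane update, delayed typed
# synapses, a whole-network (monolithic) run and the divide-and-conquer
# modular scheduler that reproduces it bit-exactly on DAG-coupled networks.

#' One exponential-Euler LIF update
#'
#' Vectorized single-step membrane update used by the network simulator:
#' `V <- v_rest + (V - v_rest) * exp(-dt/tau) + R * I * (1 - exp(-dt/tau))`,
#' followed by threshold, reset and refractory entry. Exposed for analytic
#' tests and didactic use; the network loop runs the identical arithmetic in
#' compiled code.
#'
#' @param V Membrane voltages (mV).
#' @param I Per-neuron input current for this step.
#' @param params A [lif_params()].
#' @param dt Time step (ms).
#' @param refractory Integer vector of remaining refractory steps (default
#'   none); refractory neurons are not integrated and their counter is
#'   decremented instead.
#' @return A list with `V`, `spiked` (logical) and `refractory` (updated
#'   counters, refractory lengths in steps left to the caller's bookkeeping).
#' @export
lif_update <- function(V, I, params = lif_params(), dt = 0.4,
                       refractory = rep(0L, length(V))) {
  if (any(!is.finite(I))) abort("non-finite input current.")
  decay <- exp(-dt / params$tau_mem)
  active <- refractory <= 0L
  refractory[!active] <- refractory[!active] - 1L
  V[active] <- params$v_rest + (V[active] - params$v_rest) * decay +
    params$R * I[active] * (1 - decay)
  spiked <- active & V >= params$v_th
  V[spiked] <- params$v_reset
  list(V = V, spiked = spiked, refractory = refractory)
}

refrac_steps_for <- function(types, params, dt) {
  as.integer(ifelse(types == "ex",
                    ceiling(params$refractory_ex / dt - 1e-9),
                    ceiling(params$refractory_in / dt - 1e-9)))
}

#' Compile a network for simulation
#'
#' Collapses the input and recurrent synapse tables (alive synapses only)
#' into sparse weight matrices grouped by integer conduction delay, with the
#' presynaptic axis ordered `[input pixels | reservoir neurons]`. The
#' compiled form is reusable across stimuli, so batch runs pay the assembly
#' cost once.
#'
#' @param network An [assemble_reservoir()] result.
#' @return An object of class `compiled_lsm`.
#' @export
compile_network <- function(network) {
  stopifnot(inherits(network, "lsm_network"))
  n <- nrow(network$neurons)
  n_exo <- n_pre(network$input)
  inp <- network$input[network$input$alive, ]
  rec <- network$recurrent[network$recurrent$alive, ]
  all_syn <- tibble(pre = c(inp$pre, n_exo + rec$pre),
                    post = c(inp$post, rec$post),
                    weight = c(inp$weight, rec$weight),
                    delay = c(inp$delay, rec$delay))
  if (any(is.na(all_syn$delay))) abort("synapse delays are unset; assemble with a time step.")
  groups <- lapply(sort(unique(all_syn$delay)), function(d) {
    s <- all_syn[all_syn$delay == d, ]
    W <- Matrix::sparseMatrix(i = s$post, j = s$pre, x = s$weight,
                              dims = c(n, n_exo + n))
    list(delay = as.integer(d), W = W)
  })
  structure(list(groups = groups, n = n, n_exo = n_exo,
                 refrac = refrac_steps_for(network$neurons$type, network$params, network$dt),
                 params = network$params, dt = network$dt,
                 neurons = network$neurons, modules = network$modules,
                 graph = network$graph, topology = network$config$topology),
            class = "compiled_lsm")
}

group_slots <- function(g) list(delay = g$delay, p = g$W@p, i = g$W@i, x = g$W@x)

#' Simulate a network on an encoded stimulus
#'
#' Runs the LIF dynamics on an input spike raster: a silent settle phase
#' (the raster's `settle_steps` attribute, 50 ms by default) is prepended so
#' voltages start from rest, then the stimulus steps are presented. The
#' dynamics are fully deterministic given the network and input.
#'
#' `mode = "monolithic"` integrates the whole network jointly.
#' `mode = "modular"` (DAG networks only) simulates the modules one at a
#' time in topological order, feeding each module the recorded spike rasters
#' of its predecessor modules — the divide-and-conquer schedule. Modules of
#' equal DAG depth are mutually independent given their predecessors (see
#' [module_depths()]); correctness is defined by the sequential topological
#' order, and the two modes produce bit-identical rasters.
#'
#' @param network An [assemble_reservoir()] result or a [compile_network()]
#'   output.
#' @param input_raster A [spike_raster()] over the input (pixel) population.
#' @param mode `"monolithic"` or `"modular"`.
#' @param record_v Also record the membrane voltage traces.
#' @return An object of class `sim_result`: list with `raster` (reservoir
#'   [spike_raster()] covering settle + stimulus steps), `settle_steps`,
#'   `voltage` (matrix or `NULL`), `mode` and `topology`.
#' @export
simulate_network <- function(network, input_raster,
                             mode = c("monolithic", "modular"),
                             record_v = FALSE) {
  mode <- match.arg(mode)
  cn <- if (inherits(network, "compiled_lsm")) network else compile_network(network)
  stopifnot(inherits(input_raster, "spike_raster"))
  if (nrow(input_raster) != cn$n_exo) {
    abort(sprintf("input raster has %d neurons; network expects %d input neurons.",
                  nrow(input_raster), cn$n_exo))
  }
  settle <- attr(input_raster, "settle_steps") %||% 0L
  T_total <- settle + ncol(input_raster)
  exo <- cbind(matrix(0L, cn$n_exo, settle), unclass(input_raster))
  decay <- exp(-cn$dt / cn$params$tau_mem)
  gain <- cn$params$R * (1 - decay)

  if (mode == "monolithic") {
    res <- lif_sim_cpp(lapply(cn$groups, group_slots), exo, cn$n, T_total,
                       cn$refrac, decay, gain,
                       cn$params$v_rest, cn$params$v_reset, cn$params$v_th,
                       record_v)
    spikes <- res$spikes
    voltage <- res$voltage
  } else {
    if (is.null(cn$graph)) abort("modular simulation requires a module DAG.")
    bad <- which(cn$graph$edges$from >= cn$graph$edges$to)
    if (length(bad)) {
      abort(sprintf("module graph is not acyclic: edge %d -> %d violates the topological labelling.",
                    cn$graph$edges$from[bad[1]], cn$graph$edges$to[bad[1]]))
    }
    spikes <- matrix(0L, cn$n, T_total)
    voltage <- if (record_v) matrix(0, cn$n, T_total) else NULL
    sizes <- cn$modules$size
    offsets <- cumsum(c(0L, sizes[-length(sizes)]))
    for (m in cn$modules$id) {  # ascending id = topological order
      rows <- offsets[m] + seq_len(sizes[m])
      preds <- sort(cn$graph$edges$from[cn$graph$edges$to == m])
      has_input <- m %in% (cn$graph$input_modules %||% integer(0))
      # presynaptic column blocks in global order: pixels, predecessor
      # modules ascending, then the module itself
      cols <- integer(0); exo_m <- NULL
      if (has_input) { cols <- seq_len(cn$n_exo); exo_m <- exo }
      for (pm in preds) {
        cols <- c(cols, cn$n_exo + offsets[pm] + seq_len(sizes[pm]))
        exo_m <- rbind(exo_m, spikes[offsets[pm] + seq_len(sizes[pm]), , drop = FALSE])
      }
      if (is.null(exo_m)) exo_m <- matrix(0L, 0L, T_total)
      self_cols <- cn$n_exo + rows
      groups_m <- lapply(cn$groups, function(g) {
        Wm <- g$W[rows, c(cols, self_cols), drop = FALSE]
        list(delay = g$delay, p = Wm@p, i = Wm@i, x = Wm@x)
      })
      res <- lif_sim_cpp(groups_m, exo_m, length(rows), T_total,
                         cn$refrac[rows], decay, gain,
                         cn$params$v_rest, cn$params$v_reset, cn$params$v_th,
                         record_v)
      spikes[rows, ] <- res$spikes
      if (record_v) voltage[rows, ] <- res$voltage
    }
  }
  structure(list(
    raster = spike_raster(spikes, dt = cn$dt, settle_steps = 0L),
    settle_steps = as.integer(settle),
    n_stimulus_steps = ncol(input_raster),
    voltage = voltage, mode = mode, topology = cn$topology,
    modules = cn$modules, neurons = cn$neurons),
    class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("<sim_result> %s/%s: %d neurons x %d steps (%d settle), %d spikes\n",
              x$topology, x$mode, nrow(x$raster), ncol(x$raster),
              x$settle_steps, sum(x$raster)))
  invisible(x)
}

#' Firing-rate features of a simulation
#'
#' Per-neuron mean firing rate over the stimulus window (the settle phase is
#' excluded): spike count divided by `n_steps * dt`, in spikes/s.
#'
#' @param result A [simulate_network()] result, or a bare [spike_raster()]
#'   (then taken to contain stimulus steps only).
#' @return A tibble with `neuron_id`, `module` (when known) and `rate`.
#' @export
extract_features <- function(result) {
  if (inherits(result, "sim_result")) {
    stim <- result$raster[, result$settle_steps + seq_len(result$n_stimulus_steps),
                          drop = FALSE]
    dt <- attr(result$raster, "dt")
    module <- result$neurons$module
  } else if (inherits(result, "spike_raster")) {
    stim <- unclass(result)
    dt <- attr(result, "dt")
    module <- NA_integer_
  } else {
    abort("`result` must be a sim_result or spike_raster.")
  }
  dur_s <- ncol(stim) * dt / 1000
  tibble(neuron_id = seq_len(nrow(stim)), module = module,
         rate = rowSums(stim) / dur_s)
}

#' @export
autoplot.sim_result <- function(object, ...) {
  autoplot(object$raster, ...) +
    ggplot2::geom_vline(xintercept = object$settle_steps * attr(object$raster, "dt"),
                        linetype = "dashed", colour = "grey50")
}
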