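# System-noise experiments: disable an exact fraction of reservoir synapses
# and measure how classification accuracy degrades across topologies.

#' Disable a fraction of reservoir synapses
#'
#' Marks exactly `round(fraction * E)` of the eligible synapses dead
#' (sampled uniformly without replacement), where `E` is the number of
#' currently alive eligible synapses. Dead synapses contribute no current
#' but stay in the table, and the input network object is never modified.
#' By default only reservoir-internal and inter-module synapses are
#' eligible — ablation models damage inside the system, not to its sensory
#' afferents — but the scope is configurable.
#'
#' @param network An [assemble_reservoir()] result.
#' @param fraction Fraction of eligible synapses to disable, in `[0, 1]`.
#' @param scope Synapse sets eligible for ablation: any subset of
#'   `c("recurrent", "input")`.
#' @param seed Integer seed.
#' @return A copy of `network` with the selected synapses marked dead.
#' @export
ablate_synapses <- function(network, fraction, scope = "recurrent", seed = NULL) {
  stopifnot(inherits(network, "lsm_network"))
  check_scalar_number(fraction, "fraction", lower = 0, upper = 1)
  if (!all(scope %in% c("recurrent", "input"))) abort("unknown ablation scope.")
  if (fraction == 0) return(network)
  with_seed_(seed, {
    for (set in scope) {
      alive_idx <- which(network[[set]]$alive)
      n_kill <- round(fraction * length(alive_idx))
      if (n_kill > 0) {
        dead <- sample(alive_idx, n_kill)
        network[[set]]$alive[dead] <- FALSE
      }
    }
    network
  })
}

#' Robustness sweep over ablation fractions
#'
#' For every topology, ablation fraction and seed: build the network, encode
#' the toy dataset, disable the given fraction of reservoir synapses,
#' simulate, extract firing-rate features, train the linear readout on the
#' training split and evaluate on the held-out split. Fraction 0 rows are the
#' unperturbed reference for the same seed.
#'
#' @param topologies Character vector of topology names (see
#'   [topology_config()]).
#' @param fractions Ablation fractions to test.
#' @param n_seeds Number of independent replicates; replicate `s` uses seed
#'   `base_seed + s` for the dataset, encoding, network build and ablation.
#' @param dataset_spec List of arguments to [make_toy_dataset()] (class
#'   count, images per class, jitter); train/test split sizes are
#'   `n_train`/`n_test` images per class.
#' @param n_train,n_test Images per class in the training and test splits.
#' @param encoder An [encoder_config()]; the default study conditions can be
#'   scaled down here for quick sweeps.
#' @param base_seed Base of the per-replicate seeds.
#' @param config_args Extra arguments passed to [topology_config()].
#' @return A tibble with one row per (topology, fraction, seed):
#'   `accuracy`, plus a summary attribute-free tidy layout ready for
#'   [plot_robustness()].
#' @export
robustness_sweep <- function(topologies = c("modular", "small_world"),
                             fractions = c(0, 0.05, 0.1, 0.2),
                             n_seeds = 10,
                             dataset_spec = list(n_classes = 4, jitter = 0.1),
                             n_train = 12, n_test = 8,
                             encoder = encoder_config(), base_seed = 100,
                             config_args = list()) {
  rows <- list()
  for (s in seq_len(n_seeds)) {
    seed <- base_seed + s
    ds <- prepare_split(dataset_spec, n_train, n_test, encoder, seed)
    for (topo in topologies) {
      config <- do.call(topology_config, c(list(topology = topo), config_args))
      network <- assemble_reservoir(config, seed = seed, dt = encoder$dt)
      for (f in fractions) {
        net_f <- ablate_synapses(network, f, seed = seed)
        acc <- pipeline_accuracy(net_f, ds)
        rows[[length(rows) + 1L]] <- tibble(topology = topo, fraction = f,
                                            seed = seed, accuracy = acc)
      }
    }
  }
  bind_rows(rows)
}

# Encode a balanced toy dataset once per seed and split it.
prepare_split <- function(dataset_spec, n_train, n_test, encoder, seed) {
  n_per_class <- n_train + n_test
  ds <- do.call(make_toy_dataset,
                c(dataset_spec, list(n_per_class = n_per_class, seed = seed)))
  rasters <- lapply(seq_along(ds$images), function(i) {
    poisson_encode(ds$images[[i]], encoder, seed = seed * 10000 + i)
  })
  idx_by_class <- split(seq_along(ds$labels), ds$labels)
  train_idx <- unlist(lapply(idx_by_class, function(ii) ii[seq_len(n_train)]))
  test_idx <- setdiff(seq_along(ds$labels), train_idx)
  list(rasters = rasters, labels = ds$labels,
       train_idx = unname(train_idx), test_idx = test_idx)
}

# Simulate every raster through the network, fit on the training split and
# return held-out accuracy.
pipeline_accuracy <- function(network, ds, mode = "monolithic") {
  cn <- compile_network(network)
  feats <- features_table(cn, ds$rasters, ds$labels, mode = mode)
  model <- fit_readout(feats[ds$train_idx, ])
  evaluate_readout(model, feats[ds$test_idx, ])$accuracy
}

# Wide sample x neuron feature table with a label column.
features_table <- function(cn, rasters, labels, mode = "monolithic") {
  X <- vapply(rasters, function(r) {
    extract_features(simulate_network(cn, r, mode = mode))$rate
  }, numeric(cn$n))
  out <- as_tibble(t(X), .name_repair = ~ sprintf("f%04d", seq_len(cn$n)))
  out$label <- labels
  out
}

#' @rdname robustness_sweep
#' @param sweep A [robustness_sweep()] result.
#' @export
summarize_robustness <- function(sweep) {
  sweep |>
    group_by(.data$topology, .data$fraction) |>
    summarize(mean_accuracy = mean(.data$accuracy),
              sd_accuracy = stats::sd(.data$accuracy),
              n_seeds = dplyr::n(), .groups = "drop") |>
    arrange(.data$topology, .data$fraction)
}

#' Plot a robustness sweep
#'
#' Mean accuracy (with one-standard-deviation ribbons) against the ablation
#' fraction, one line per topology.
#'
#' @param sweep A [robustness_sweep()] result.
#' @return A ggplot object.
#' @export
plot_robustness <- function(sweep) {
  summarize_robustness(sweep) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$fraction, y = .data$mean_accuracy,
                                 colour = .data$topology, fill = .data$topology)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_accuracy - .data$sd_accuracy,
                                      ymax = .data$mean_accuracy + .data$sd_accuracy),
                         alpha = 0.15, colour = NA) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "fraction of reservoir synapses disabled",
                  y = "mean test accuracy") +
    ggplot2::theme_minimal()
}
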