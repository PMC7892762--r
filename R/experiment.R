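# End-to-end experiment orchestration: learning curves and topology
# comparisons (including the SVM-only control) from a single configuration.

#' Experiment configuration
#'
#' Bundles every knob of an end-to-end run: the toy dataset, the topologies
#' to compare, the encoder and readout settings, the learning-curve training
#' sizes, the test-set size and the seeds. All seeds are explicit so reruns
#' are bit-identical.
#'
#' @param topologies Topology names (see [topology_config()]); the SVM-only
#'   control is always added.
#' @param train_sizes Training samples per class for each learning-curve
#'   point.
#' @param n_test Test samples per class (the held-out split).
#' @param dataset_spec Arguments to [make_toy_dataset()] (`n_classes`,
#'   `jitter`, ...).
#' @param encoder An [encoder_config()].
#' @param seeds Integer vector of replicate seeds.
#' @param readout_cost SVM regularization constant.
#' @param config_args Extra arguments for [topology_config()].
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(topologies = c("modular", "small_world", "metric", "random"),
                              train_sizes = c(4, 12), n_test = 8,
                              dataset_spec = list(n_classes = 4, jitter = 0.1),
                              encoder = encoder_config(), seeds = 1:5,
                              readout_cost = 1, config_args = list()) {
  if (!length(train_sizes) || any(train_sizes < 1)) {
    abort("`train_sizes` must be positive.")
  }
  if (n_test < 1) abort("`n_test` must be positive.")
  structure(list(topologies = topologies, train_sizes = sort(train_sizes),
                 n_test = n_test, dataset_spec = dataset_spec,
                 encoder = encoder, seeds = as.integer(seeds),
                 readout_cost = readout_cost, config_args = config_args),
            class = "experiment_config")
}

config_fingerprint <- function(config) {
  # structural hash over the deparsed configuration; stable across sessions
  txt <- paste(deparse(config[order(names(config))]), collapse = "")
  sprintf("%08x", sum(utf8ToInt(txt) * (seq_along(utf8ToInt(txt)) %% 97 + 1)) %% .Machine$integer.max)
}

#' Run a full experiment
#'
#' For every (topology, training size, seed): build the reservoir, encode
#' the dataset, simulate, extract firing-rate features, train the linear
#' readout on the first `train_size` samples per class and evaluate on the
#' held-out split. An SVM-only control — the readout fitted directly on the
#' per-pixel mean firing rates of the encoded input, i.e. the same
#' information without the reservoir — is run alongside.
#'
#' @param config An [experiment_config()].
#' @return An object of class `lsm_experiment`: list with `results` (tidy
#'   tibble: `topology`, `train_size`, `seed`, `accuracy`, `config_hash`)
#'   and `evals` (the per-run `lsm_eval` reports at the largest training
#'   size).
#' @export
run_lsm_experiment <- function(config = experiment_config()) {
  stopifnot(inherits(config, "experiment_config"))
  hash <- config_fingerprint(unclass(config))
  max_train <- max(config$train_sizes)
  rows <- list(); evals <- list()
  for (seed in config$seeds) {
    ds <- prepare_split(config$dataset_spec, max_train, config$n_test,
                        config$encoder, seed)
    # SVM-only control: per-pixel rates of the encoded input raster
    pix <- features_table_input(ds$rasters, ds$labels)
    run_one <- function(topo, feats) {
      for (ts in config$train_sizes) {
        tr <- train_subset(ds, feats, ts)
        model <- fit_readout(tr, cost = config$readout_cost)
        ev <- evaluate_readout(model, feats[ds$test_idx, ])
        rows[[length(rows) + 1L]] <<- tibble(
          topology = topo, train_size = ts, seed = seed,
          accuracy = ev$accuracy, config_hash = hash)
        if (ts == max_train) evals[[paste(topo, seed, sep = "_")]] <<- ev
      }
    }
    run_one("svm_only", pix)
    for (topo in config$topologies) {
      tc <- do.call(topology_config, c(list(topology = topo), config$config_args))
      network <- assemble_reservoir(tc, seed = seed, dt = config$encoder$dt)
      cn <- compile_network(network)
      feats <- features_table(cn, ds$rasters, ds$labels)
      run_one(topo, feats)
    }
  }
  structure(list(results = bind_rows(rows) |>
                   arrange(.data$topology, .data$train_size, .data$seed),
                 evals = evals, config = config, config_hash = hash),
            class = "lsm_experiment")
}

# Training rows: the first `per_class` training samples of every class.
train_subset <- function(ds, feats, per_class) {
  tr_labels <- ds$labels[ds$train_idx]
  keep <- unlist(lapply(split(seq_along(tr_labels), tr_labels),
                        function(ii) ii[seq_len(min(per_class, length(ii)))]))
  feats[ds$train_idx[sort(keep)], ]
}

features_table_input <- function(rasters, labels) {
  X <- vapply(rasters, function(r) extract_features(r)$rate,
              numeric(nrow(rasters[[1]])))
  out <- as_tibble(t(X), .name_repair = ~ sprintf("f%04d", seq_len(nrow(rasters[[1]]))))
  out$label <- labels
  out
}

#' @export
print.lsm_experiment <- function(x, ...) {
  cat(sprintf("<lsm_experiment> %d runs (hash %s)\n", nrow(x$results), x$config_hash))
  print(learning_curve(x))
  invisible(x)
}

#' Aggregate an experiment into a learning curve
#'
#' Mean and standard deviation of accuracy per (topology, training size),
#' sorted deterministically.
#'
#' @param experiment An [run_lsm_experiment()] result, or its `results`
#'   tibble.
#' @return A tibble with `topology`, `train_size`, `mean_accuracy`,
#'   `sd_accuracy`, `n_seeds`.
#' @export
learning_curve <- function(experiment) {
  results <- if (inherits(experiment, "lsm_experiment")) experiment$results else experiment
  if (length(unique(results$train_size)) < 1) abort("no learning-curve points.")
  results |>
    group_by(.data$topology, .data$train_size) |>
    summarize(mean_accuracy = mean(.data$accuracy),
              sd_accuracy = ifelse(dplyr::n() > 1, stats::sd(.data$accuracy), 0),
              n_seeds = dplyr::n(), .groups = "drop") |>
    arrange(.data$topology, .data$train_size)
}

#' @export
autoplot.lsm_experiment <- function(object, ...) {
  learning_curve(object) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$train_size, y = .data$mean_accuracy,
                                 colour = .data$topology)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "training samples per class", y = "mean test accuracy") +
    ggplot2::theme_minimal()
}
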