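# Float-operation accounting per simulation iteration: monolithic versus
# divide-and-conquer modular execution of the same network.

#' Count float operations per simulation iteration
#'
#' Accounts for the per-step cost of the network update under an explicit
#' counting convention: a multiply-add is 2 operations; each neuron's LIF
#' update costs a fixed `c_update` operations; synaptic propagation costs
#' either `2 * N_pre * N_post` per weight-matrix product (`"dense"` mode) or
#' 2 operations per alive synapse (`"sparse"` mode).
#'
#' Under dense counting a monolithic run of `N` neurons costs
#' `2 N^2 + c N` per iteration, while the modular schedule costs
#' `sum_m 2 N_m^2` for the intra-module products plus `2 N_pre N_post` per
#' realized inter-module edge plus `c N` — strictly less for any
#' non-trivial partition, which is the computational argument for the
#' modular design (`O(L N^k)` against `O((L N)^k)` for `L` modules of `N`
#' neurons).
#'
#' @param network An [assemble_reservoir()] result.
#' @param mode `"dense"` or `"sparse"` counting.
#' @param c_update Operations per neuron LIF update (default 6).
#' @param modular Count the modular schedule (requires a module DAG) or the
#'   monolithic one. Default counts modular when the network has a DAG.
#' @return A `cost_report` tibble with one row per execution scheme:
#'   `scheme`, `recurrent_ops`, `update_ops`, `flops_per_iteration`.
#' @export
count_flops <- function(network, mode = c("dense", "sparse"), c_update = 6,
                        modular = !is.null(network$graph)) {
  stopifnot(inherits(network, "lsm_network"))
  mode <- match.arg(mode)
  n <- nrow(network$neurons)
  mono_rec <- if (mode == "dense") 2 * n^2 else 2 * sum(network$recurrent$alive)
  rows <- tibble(scheme = "monolithic", recurrent_ops = mono_rec,
                 update_ops = c_update * n,
                 flops_per_iteration = mono_rec + c_update * n)
  if (modular) {
    if (is.null(network$graph)) abort("modular cost accounting requires a module DAG.")
    sizes <- network$modules$size
    if (mode == "dense") {
      intra <- sum(2 * sizes^2)
      inter <- sum(2 * sizes[network$graph$edges$from] * sizes[network$graph$edges$to])
    } else {
      alive <- network$recurrent[network$recurrent$alive, ]
      intra <- 2 * sum(alive$kind == "intra")
      inter <- 2 * sum(alive$kind == "inter")
    }
    rows <- bind_rows(rows, tibble(scheme = "modular",
                                   recurrent_ops = intra + inter,
                                   update_ops = c_update * n,
                                   flops_per_iteration = intra + inter + c_update * n))
  }
  structure(rows, mode = mode, c_update = c_update,
            class = c("cost_report", class(rows)))
}

#' Accuracy per million float operations
#'
#' Combines a cost report with an evaluation report into the
#' accuracy-per-MFLOP efficiency score: accuracy in percent divided by the
#' per-iteration cost in millions of operations.
#'
#' @param cost A [count_flops()] report.
#' @param eval An `lsm_eval` report (or a bare accuracy fraction).
#' @return A tibble with `scheme`, `flops_per_iteration`,
#'   `accuracy_percent` and `accuracy_per_mflop`.
#' @export
efficiency_report <- function(cost, eval) {
  stopifnot(inherits(cost, "cost_report"))
  acc <- if (inherits(eval, "lsm_eval")) eval$accuracy else eval
  check_scalar_number(acc, "accuracy", lower = 0, upper = 1)
  as_tibble(cost) |>
    transmute(.data$scheme, .data$flops_per_iteration,
              accuracy_percent = 100 * acc,
              accuracy_per_mflop = 100 * acc / (.data$flops_per_iteration / 1e6))
}
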