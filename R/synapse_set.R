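# Sparse typed connectivity: every connection structure in the package is a
# tibble of (pre, post, weight, delay, alive) rows plus population sizes kept
# as attributes, so synapse tables compose with ordinary dplyr verbs.

#' Construct a synapse set
#'
#' A synapse set is a tibble with one row per directed synapse (`pre`,
#' `post`, `weight`, `delay` in integer time steps, `alive`) and attributes
#' recording the pre- and post-population sizes and names. Within a recurrent
#' set (same pre and post population) self-connections are disallowed, and
#' duplicate `(pre, post)` pairs are disallowed everywhere.
#'
#' @param pre,post 1-based neuron indices within their populations.
#' @param weight Synaptic weights (finite).
#' @param delay Integer conduction delays in simulation steps (`NA` until a
#'   time step is chosen).
#' @param n_pre,n_post Population sizes.
#' @param pre_pop,post_pop Population names.
#' @param alive Logical; dead synapses are kept in the table but contribute
#'   no current (see [ablate_synapses()]).
#' @return A tibble of class `synapse_set`.
#' @export
synapse_set <- function(pre, post, weight = 1, delay = NA_integer_,
                        n_pre, n_post, pre_pop = "pre", post_pop = "post",
                        alive = TRUE) {
  tb <- tibble(pre = as.integer(pre), post = as.integer(post),
               weight = as.double(weight), delay = as.integer(delay),
               alive = alive)
  if (nrow(tb)) {
    if (any(tb$pre < 1 | tb$pre > n_pre) || any(tb$post < 1 | tb$post > n_post)) {
      abort("synapse indices outside population bounds.")
    }
    if (identical(pre_pop, post_pop) && any(tb$pre == tb$post)) {
      abort("self-connections are not allowed within one population.")
    }
    if (anyDuplicated(tb[c("pre", "post")])) {
      abort("duplicate (pre, post) pairs in synapse set.")
    }
    if (any(!is.finite(tb$weight))) abort("weights must be finite.")
  }
  structure(tb, n_pre = as.integer(n_pre), n_post = as.integer(n_post),
            pre_pop = pre_pop, post_pop = post_pop,
            class = c("synapse_set", class(tb)))
}

n_pre <- function(x) attr(x, "n_pre")
n_post <- function(x) attr(x, "n_post")

#' @export
print.synapse_set <- function(x, ...) {
  cat(sprintf("<synapse_set> %s (%d) -> %s (%d): %d synapses (%d alive)\n",
              attr(x, "pre_pop"), n_pre(x), attr(x, "post_pop"), n_post(x),
              nrow(x), sum(x$alive)))
  NextMethod()
}

#' Convert a synapse set to a sparse weight matrix
#'
#' @param x A [synapse_set()].
#' @param alive_only Drop dead synapses (default `TRUE`).
#' @return A `dgCMatrix` of dimension `n_post x n_pre` (rows index
#'   post-synaptic neurons, so `W %*% s` gives per-neuron input current from a
#'   pre-synaptic spike vector `s`).
#' @export
as_weight_matrix <- function(x, alive_only = TRUE) {
  stopifnot(inherits(x, "synapse_set"))
  keep <- if (alive_only) x$alive else rep(TRUE, nrow(x))
  Matrix::sparseMatrix(i = x$post[keep], j = x$pre[keep], x = x$weight[keep],
                       dims = c(n_post(x), n_pre(x)))
}

#' Export / import a synapse set
#'
#' The weight matrix is written in Matrix Market coordinate format
#' (`<path>.mtx`) and a CSV sidecar (`<path>.csv`) carries per-synapse delays
#' and liveness together with the population metadata in a JSON header file.
#'
#' @param x A [synapse_set()].
#' @param path Base path (without extension).
#' @export
export_synapses <- function(x, path) {
  stopifnot(inherits(x, "synapse_set"))
  Matrix::writeMM(as_weight_matrix(x, alive_only = FALSE), paste0(path, ".mtx"))
  utils::write.csv(as.data.frame(x), paste0(path, ".csv"), row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(n_pre = n_pre(x), n_post = n_post(x),
                            pre_pop = attr(x, "pre_pop"), post_pop = attr(x, "post_pop")),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname export_synapses
#' @export
import_synapses <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  tb <- utils::read.csv(paste0(path, ".csv"))
  synapse_set(tb$pre, tb$post, tb$weight, tb$delay,
              n_pre = meta$n_pre, n_post = meta$n_post,
              pre_pop = meta$pre_pop, post_pop = meta$post_pop,
              alive = as.logical(tb$alive))
}
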