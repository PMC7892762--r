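# Linear max-margin readout on firing-rate features, with accuracy and
# row-percentage confusion reporting.

#' Train the linear readout
#'
#' Fits a linear support-vector readout (regularization `cost = 1` by
#' default) on a feature table. The multiclass scheme is one-vs-rest: one
#' binary machine per class, prediction by the largest decision value
#' (ties broken toward the earlier class level); `scheme = "ovo"` uses the
#' native one-vs-one voting instead. Features are used raw — all are firing
#' rates on a common spikes/s scale — unless `standardize = TRUE`.
#'
#' @param data Data frame with one row per sample: a `label` column plus
#'   numeric feature columns.
#' @param label_col Name of the label column (default `"label"`).
#' @param cost Soft-margin regularization constant `C`.
#' @param scheme `"ovr"` (one-vs-rest, default) or `"ovo"` (one-vs-one).
#' @param standardize Standardize features before fitting.
#' @return An object of class `lsm_readout`.
#' @export
fit_readout <- function(data, label_col = "label", cost = 1,
                        scheme = c("ovr", "ovo"), standardize = FALSE) {
  scheme <- match.arg(scheme)
  check_scalar_number(cost, "cost", lower = 1e-12)
  if (!label_col %in% names(data)) abort(sprintf("no `%s` column in `data`.", label_col))
  y <- factor(data[[label_col]])
  if (nlevels(y) < 2) abort("training data must contain at least two classes.")
  if (any(table(y) < 1)) abort("every class needs at least one sample.")
  X <- as.matrix(data[setdiff(names(data), label_col)])
  if (!is.numeric(X)) abort("feature columns must be numeric.")
  center <- scale_sd <- NULL
  if (standardize) {
    center <- colMeans(X)
    scale_sd <- pmax(apply(X, 2, stats::sd), 1e-12)
    X <- sweep(sweep(X, 2, center), 2, scale_sd, "/")
  }
  machines <- if (scheme == "ovr") {
    lapply(levels(y), function(cl) {
      yy <- factor(ifelse(y == cl, "pos", "rest"), levels = c("pos", "rest"))
      e1071::svm(X, yy, kernel = "linear", cost = cost, scale = FALSE)
    })
  } else {
    list(e1071::svm(X, y, kernel = "linear", cost = cost, scale = FALSE))
  }
  structure(list(machines = machines, scheme = scheme, levels = levels(y),
                 cost = cost, label_col = label_col,
                 feature_names = colnames(X),
                 center = center, scale = scale_sd),
            class = "lsm_readout")
}

readout_features <- function(model, data) {
  missing <- setdiff(model$feature_names, names(data))
  if (length(missing)) abort(sprintf("missing %d feature columns.", length(missing)))
  X <- as.matrix(data[model$feature_names])
  if (!is.null(model$center)) {
    X <- sweep(sweep(X, 2, model$center), 2, model$scale, "/")
  }
  X
}

#' @export
predict.lsm_readout <- function(object, newdata, ...) {
  X <- readout_features(object, newdata)
  if (object$scheme == "ovr") {
    dec <- vapply(object$machines, function(m) {
      dv <- attr(stats::predict(m, X, decision.values = TRUE), "decision.values")
      # orient so positive always favours the "pos" class
      sgn <- if (identical(colnames(dv)[1], "pos/rest")) 1 else -1
      sgn * as.vector(dv)
    }, numeric(nrow(X)))
    dec <- matrix(dec, nrow = nrow(X))
    factor(object$levels[max.col(dec, ties.method = "first")], levels = object$levels)
  } else {
    factor(as.character(stats::predict(object$machines[[1]], X)), levels = object$levels)
  }
}

#' @export
glance.lsm_readout <- function(x, ...) {
  tibble(scheme = x$scheme, cost = x$cost, n_classes = length(x$levels),
         n_machines = length(x$machines),
         n_support_vectors = sum(vapply(x$machines, function(m) m$tot.nSV, numeric(1))),
         n_features = length(x$feature_names))
}

#' @export
tidy.lsm_readout <- function(x, ...) {
  purrr::map_dfr(seq_along(x$machines), function(k) {
    m <- x$machines[[k]]
    w <- as.vector(t(m$coefs) %*% m$SV)
    tibble(machine = if (x$scheme == "ovr") x$levels[k] else "ovo",
           term = c("(intercept)", x$feature_names),
           estimate = c(-m$rho, w))
  })
}

#' Tally predictions into an evaluation report
#'
#' @param truth,predicted Vectors of true and predicted class labels (same
#'   length, same label universe).
#' @param levels Optional explicit class levels.
#' @return An `lsm_eval` object: `accuracy` (fraction), `counts` (K x K
#'   integer matrix, rows = true), `confusion` (row-normalized percentages)
#'   and `n`.
#' @export
confusion_report <- function(truth, predicted, levels = NULL) {
  if (length(truth) != length(predicted)) abort("`truth` and `predicted` differ in length.")
  if (!length(truth)) abort("empty evaluation set.")
  levels <- levels %||% sort(unique(c(as.character(truth), as.character(predicted))))
  truth <- factor(as.character(truth), levels = levels)
  predicted <- factor(as.character(predicted), levels = levels)
  counts <- table(truth = truth, predicted = predicted)
  conf <- 100 * prop.table(counts + 0, margin = 1)
  conf[is.nan(conf)] <- 0
  structure(list(accuracy = sum(diag(counts)) / length(truth),
                 counts = unclass(counts), confusion = unclass(conf),
                 n = length(truth), levels = levels),
            class = "lsm_eval")
}

#' Evaluate a readout on held-out samples
#'
#' @param model An [fit_readout()] result.
#' @param newdata Data frame with the model's feature columns and the label
#'   column.
#' @return An `lsm_eval` report (see [confusion_report()]).
#' @export
evaluate_readout <- function(model, newdata) {
  stopifnot(inherits(model, "lsm_readout"))
  if (!nrow(newdata)) abort("empty evaluation set.")
  pred <- predict(model, newdata)
  confusion_report(newdata[[model$label_col]], pred, levels = model$levels)
}

#' @export
print.lsm_eval <- function(x, ...) {
  cat(sprintf("<lsm_eval> accuracy %.1f%% on %d samples, %d classes\n",
              100 * x$accuracy, x$n, length(x$levels)))
  print(round(x$confusion, 1))
  invisible(x)
}

#' @export
glance.lsm_eval <- function(x, ...) {
  tibble(accuracy = x$accuracy, n = x$n, n_classes = length(x$levels))
}

#' @export
tidy.lsm_eval <- function(x, ...) {
  as_tibble(as.data.frame.table(x$confusion, responseName = "percent")) |>
    mutate(count = as.vector(x$counts)) |>
    rename(truth = 1, predicted = 2)
}

#' @export
autoplot.lsm_eval <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$predicted, y = .data$truth,
                                 fill = .data$percent)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.0f", .data$percent)),
                       size = 3) +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "predicted", y = "true", fill = "%") +
    ggplot2::theme_minimal()
}
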