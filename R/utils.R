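#' @importFrom rlang abort warn %||%
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom Rcpp sourceCpp
#' @useDynLib modlsm, .registration = TRUE
NULL

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

# Evaluate `code` under a local, seeded RNG when `seed` is given; the caller's
# RNG state is untouched either way.
with_seed_ <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  withr::with_seed(as.integer(seed), code)
}

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single finite number in [%s, %s].",
                  name, format(lower), format(upper)))
  }
  invisible(x)
}

check_image <- function(image, name = "image") {
  if (!is.matrix(image) || !is.numeric(image)) {
    abort(sprintf("`%s` must be a numeric matrix.", name))
  }
  if (any(!is.finite(image))) abort(sprintf("`%s` contains non-finite values.", name))
  invisible(image)
}
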