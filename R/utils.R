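#' @keywords internal
"_PACKAGE"

#' @importFrom rlang abort warn inform %||% .data
#' @importFrom tibble tibble as_tibble
#' @importFrom stats rnorm runif predict var sd cor complete.cases setNames
#' @importFrom utils head modifyList
NULL

# numerically safe ELU (alpha = 1); NaN inputs propagate so a diverged
# optimizer surfaces as a non-finite loss rather than an index error
elu <- function(x) {
  neg <- which(x < 0)
  x[neg] <- exp(x[neg]) - 1
  x
}

elu_grad <- function(x) {
  g <- rep(1, length(x))
  g[is.na(x)] <- NaN
  neg <- which(x < 0)
  g[neg] <- exp(x[neg])
  g
}

leaky_relu <- function(x, slope = 0.2) pmax(x, 0) + slope * pmin(x, 0)

leaky_relu_grad <- function(x, slope = 0.2) ifelse(x > 0, 1, slope)

relu <- function(x) pmax(x, 0)

stop_bk <- function(msg, class, ...) {
  abort(msg, class = c(class, "bkscore_error"), ...)
}

check_scalar_number <- function(x, name, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || (finite && !is.finite(x))) {
    stop_bk(sprintf("`%s` must be a single finite number.", name),
            "bkscore_config_error")
  }
  invisible(x)
}

# group maxima for a numeric vector given a precomputed index split
group_max <- function(x, split_idx) {
  vapply(split_idx, function(ix) max(x[ix]), numeric(1))
}
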