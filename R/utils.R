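#' @keywords internal
"_PACKAGE"

#' @import data.table
#' @importFrom stats rnorm runif rpois rlnorm sd setNames
#' @importFrom utils head tail
NULL

# Classed error helper: every user-facing failure mode gets a distinct class
# ("touchkin_<what>") so callers and tests can condition on it.
tk_stop <- function(class, msg, ...) {
  stop(errorCondition(sprintf(msg, ...), class = c(class, "touchkin_error")))
}

tk_warn <- function(class, msg, ...) {
  warning(warningCondition(sprintf(msg, ...), class = c(class, "touchkin_warning")))
}

#' Derive a child seed from a master seed and a tag
#'
#' A single master seed is fanned out to per-stage / per-subject seeds so that
#' any stage can be re-run in isolation and still reproduce its slice of the
#' randomness. The derivation is a plain polynomial rolling hash of the tag
#' string folded into the master seed, reduced modulo 2^31 - 1 (R seeds are
#' 32-bit signed).
#'
#' @param master integer master seed.
#' @param ... tag components (coerced to character, joined with "/").
#' @return an integer in \[1, 2^31 - 2\], deterministic in its arguments.
#' @export
derive_seed <- function(master, ...) {
  tag <- paste(vapply(list(...), as.character, character(1)), collapse = "/")
  m <- 2147483647 # 2^31 - 1, prime
  h <- as.numeric(master) %% m
  for (code in utf8ToInt(tag)) {
    h <- (h * 31 + code) %% m
  }
  as.integer(h %% (m - 2) + 1)
}

# Wrap angles to the half-open interval (-pi, pi].
wrap_angle <- function(x) {
  x - 2 * pi * ceiling((x - pi) / (2 * pi))
}

# Sample standard deviation (n - 1 denominator) used everywhere: for the
# Table-1 SD features and for the standardizer.
sample_sd <- function(x) stats::sd(x)

point_in_rect <- function(x, y, rect) {
  x >= rect[["xmin"]] & x <= rect[["xmax"]] & y >= rect[["ymin"]] & y <= rect[["ymax"]]
}

rect_center <- function(rect) {
  c(x = (rect[["xmin"]] + rect[["xmax"]]) / 2, y = (rect[["ymin"]] + rect[["ymax"]]) / 2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
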