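#' @importFrom rlang .data abort warn inform %||%
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   left_join inner_join distinct bind_rows rename n across pull slice if_else
#' @importFrom tibble tibble as_tibble is_tibble
#' @importFrom purrr map map_dbl map_chr map_int map2 pmap keep
#' @importFrom stats pf pt qt qnorm pnorm qbeta phyper dhyper rexp rnorm runif
#'   setNames complete.cases
NULL

#' Round half-up to a fixed number of decimals
#'
#' Report percentages in this package are rounded half away from zero to the
#' printed precision (base `round()` rounds half to even, which disagrees with
#' how summary percentages are conventionally typeset).
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 1).
#' @return numeric vector rounded half-up.
#' @examples
#' round_half_up(c(18.329, 13.077, 38.333), 1)
#' @export
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Percentage of a count over a denominator, rounded half-up
#'
#' @param count numerator count(s).
#' @param denominator denominator count(s); must be positive.
#' @param digits decimals to keep (default 1, matching typical report style).
#' @return numeric percentage(s) on the 0-100 scale.
#' @examples
#' percent_of(599, 3268)   # 18.3
#' percent_of(146, 1356)   # 10.8
#' @export
percent_of <- function(count, denominator, digits = 1) {
  stopifnot(all(denominator > 0))
  round_half_up(100 * count / denominator, digits)
}

# Case-insensitive gene-symbol key: human symbols are conventionally
# upper-case, mouse title-case (Foxm1 vs FOXM1); matching is on the
# upper-cased form while the original casing is preserved for display.
symbol_key <- function(x) toupper(trimws(x))

# Run code with a temporary RNG state so simulators are deterministic given
# their seed without clobbering the caller's stream.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed)) {
    abort("`seed` must be a single finite number.", class = "concord_config_error")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      suppressWarnings(rm(".Random.seed", envir = globalenv()))
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

stop_config <- function(msg) abort(msg, class = "concord_config_error")
stop_data <- function(msg) abort(msg, class = "concord_data_error")
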