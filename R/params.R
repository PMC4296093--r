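#' Model parameters for the AAEI recursion
#'
#' Bundles the three constants of the index together with the numerical
#' truncation threshold used when the history coefficient is evaluated as an
#' explicit attenuated sum.
#'
#' @param k Positive scale constant applied to the daily net term
#'   `MT - E`. With `k = 1` the index directly reads in MET-minutes.
#' @param w Attenuation constant, `0 < |w| < 1`: the weight by which a past
#'   day's influence on the history coefficient decays per day. The default
#'   `0.5` halves the influence of each day every following day.
#' @param c Expectance base, `> 0`: controls how sharply the exercise
#'   expectance grows as the history coefficient drops on rest days.
#' @param tail_epsilon Positive truncation threshold: attenuation weights
#'   `w^(i-1)` below this value are dropped from the explicit history sum.
#'
#' @details
#' The constants must jointly satisfy `k * c^(1/(1-w)) <= 7`. The worst-case
#' expectance after unbounded rest is `A * c^(1/(1-w))` where `A = AAEI/7` is
#' the basic value, so this condition guarantees that a single day can never
#' drive the index below zero and the non-negativity clamp in the update is
#' provably inactive.
#'
#' @return An object of class `aaei_params`.
#' @examples
#' aaei_params()          # defaults k = 1, w = 0.5, c = 2
#' aaei_params(c = 1.5)
#' @export
aaei_params <- function(k = 1, w = 0.5, c = 2, tail_epsilon = 1e-9) {
  stopifnot(is.numeric(k), length(k) == 1L, is.finite(k),
            is.numeric(w), length(w) == 1L, is.finite(w),
            is.numeric(c), length(c) == 1L, is.finite(c),
            is.numeric(tail_epsilon), length(tail_epsilon) == 1L)
  if (k <= 0) stop("'k' must be > 0", call. = FALSE)
  if (abs(w) >= 1 || w == 0) stop("'w' must satisfy 0 < |w| < 1", call. = FALSE)
  if (c <= 0) stop("'c' must be > 0", call. = FALSE)
  if (tail_epsilon <= 0) stop("'tail_epsilon' must be > 0", call. = FALSE)
  if (k * c^(1 / (1 - w)) > 7 + 1e-12) {
    stop("invalid parameters: k * c^(1/(1-w)) must be <= 7 ",
         "(got ", format(k * c^(1 / (1 - w))), "); ",
         "otherwise a rest day could drive the index below zero",
         call. = FALSE)
  }
  structure(list(k = k, w = w, c = c, tail_epsilon = tail_epsilon),
            class = "aaei_params")
}

#' @export
print.aaei_params <- function(x, ...) {
  cat(sprintf("AAEI parameters: k = %g, W = %g, C = %g (tail_epsilon = %g)\n",
              x$k, x$w, x$c, x$tail_epsilon))
  invisible(x)
}

as_aaei_params <- function(params) {
  if (inherits(params, "aaei_params")) return(params)
  stop("'params' must be created with aaei_params()", call. = FALSE)
}
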