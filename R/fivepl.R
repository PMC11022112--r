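#' Five-parameter logistic (5-PL) curve
#'
#' Evaluates the asymmetric sigmoid
#' \deqn{f(x) = d + \frac{a - d}{\left[1 + (x/c)^b\right]^g}}
#' used to describe a participant's valence rating as a function of an
#' image's normative valence. As `x` approaches 0 the curve approaches the
#' lower asymptote `a` (the rating of the most negative images); as `x`
#' grows it approaches the upper asymptote `d` (the rating of neutral
#' images). `b` is the Hill slope — the rate of transition between the two
#' states — `c` locates the inflection region on the norm-valence scale,
#' and `g` is the asymmetry factor (`g = 1` gives the symmetric 4-PL curve,
#' for which `f(c) = (a + d) / 2`).
#'
#' @param x numeric vector of normative valence values, strictly positive
#'   (the term `(x/c)^b` requires `x > 0`).
#' @param a lower asymptote.
#' @param b Hill slope.
#' @param c inflection-scale parameter, strictly positive.
#' @param d upper asymptote.
#' @param g asymmetry factor, strictly positive.
#'
#' @return numeric vector of predicted ratings, same length as `x`.
#' @examples
#' five_pl(2.5, a = 0, b = 2, c = 2.5, d = 0.5, g = 1) # midpoint 0.25
#' @export
five_pl <- function(x, a, b, c, d, g) {
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop("`x` must be finite and strictly positive", call. = FALSE)
  }
  if (any(c <= 0) || any(g <= 0)) {
    stop("`c` and `g` must be strictly positive", call. = FALSE)
  }
  d + (a - d) / (1 + (x / c)^b)^g
}

#' Validate a 5-PL parameter tuple against the model's support
#'
#' Checks a parameter tuple against the truncation bounds of the
#' hierarchical model's participant-level priors: `a` in (0, 1) (beta
#' support), `b >= 0.5`, `c` in \[0.5, 5\], `d >= 0.5`, `g >= 0.8`.
#'
#' @param p named list or vector with elements `a`, `b`, `c`, `d`, `g`.
#' @return the parameters as a named list, invisibly; errors if invalid.
#' @export
validate_fivepl_params <- function(p) {
  p <- as.list(p)
  need <- c("a", "b", "c", "d", "g")
  if (!all(need %in% names(p))) {
    stop("parameters must be named a, b, c, d, g", call. = FALSE)
  }
  p <- lapply(p[need], as.numeric)
  ok <- p$a > 0 && p$a < 1 && p$b >= 0.5 && p$c >= 0.5 && p$c <= 5 &&
    p$d >= 0.5 && p$g >= 0.8
  if (!ok) stop("parameters outside the model's truncation bounds", call. = FALSE)
  invisible(p)
}
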