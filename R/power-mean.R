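#' Generalized (power) mean of a sample of nonnegative values
#'
#' Computes the generalized mean (also called power or Hölder mean) of degree
#' `p`:
#' \deqn{M_p(x_1,\dots,x_n) = \left(\frac{1}{n}\sum_{k=1}^n x_k^p\right)^{1/p}}
#' extended continuously to the whole extended real line. Special cases are the
#' minimum (`p = -Inf`), harmonic mean (`p = -1`), geometric mean (`p = 0`),
#' arithmetic mean (`p = 1`), quadratic mean / RMS (`p = 2`) and maximum
#' (`p = Inf`).
#'
#' Finite nonzero `p` always goes through the single defining formula; only
#' `p = 0` and `p = +/-Inf` are special-cased as their limits. Computation is
#' rescaled by the row extremum (max for `p > 0`, min for `p < 0`) so that no
#' intermediate `x^p` term overflows even for values up to `1e6` and `|p|` up
#' to 100.
#'
#' Zeros in `x` sit on the boundary of the power mean's natural domain
#' (positive reals). For `p > 0` they enter the formula as ordinary values; for
#' `p <= 0` any zero forces \eqn{M_p = 0}, which is the mathematical limit of
#' \eqn{M_p} as a value tends to zero from above. This continuous extension
#' keeps the mean defined on real distance data containing ties or duplicate
#' objects.
#'
#' @param x Numeric vector of nonnegative, finite values; length at least 1.
#' @param p A single exponent on the extended real line; `-Inf` and `Inf` are
#'   accepted, as are the string tokens `"-inf"` and `"inf"` (see [parse_p()]).
#'
#' @return A single nonnegative number, always within `[min(x), max(x)]`.
#'
#' @examples
#' power_mean(c(1, 4), 1)       # arithmetic: 2.5
#' power_mean(c(1, 4), 0)       # geometric:  2
#' power_mean(c(2, 3, 6), -1)   # harmonic:   3
#' power_mean(c(1, 7), 2)       # quadratic:  5
#' power_mean(c(1, 4), -Inf)    # minimum:    1
#' power_mean(c(1, 4), "inf")   # maximum:    4
#' @export
power_mean <- function(x, p) {
  p <- parse_p(p)
  if (length(x) < 1L) {
    stop("`x` must contain at least one value.", call. = FALSE)
  }
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    stop("`x` must be finite and numeric.", call. = FALSE)
  }
  if (any(x < 0)) {
    stop("`x` must be nonnegative.", call. = FALSE)
  }
  if (p == -Inf) {
    return(min(x))
  }
  if (p == Inf) {
    return(max(x))
  }
  if (p <= 0 && any(x == 0)) {
    return(0)
  }
  if (p == 0) {
    return(exp(mean(log(x))))
  }
  sc <- if (p > 0) max(x) else min(x)
  if (sc == 0) {
    return(0) # all zeros, p > 0
  }
  sc * mean((x / sc)^p)^(1 / p)
}

#' Parse and format extended-real exponents
#'
#' `parse_p()` converts an exponent given as a number or as a string (decimal
#' literal or the tokens `"inf"`, `"+inf"`, `"-inf"`, case-insensitive, with
#' `"Inf"`/`"-Inf"` also accepted) to a numeric scalar. `format_p()` is its
#' inverse, rendering `-Inf`/`Inf` as `"-inf"`/`"inf"` so grids of exponents
#' round-trip losslessly through delimited text.
#'
#' @param p A single exponent: numeric, or a string representation.
#' @return `parse_p()`: a numeric scalar (possibly infinite); `format_p()`: a
#'   character vector.
#' @examples
#' parse_p("-inf")
#' format_p(c(-Inf, 0, 2.5, Inf))
#' @export
parse_p <- function(p) {
  if (length(p) != 1L) {
    stop("`p` must be a single exponent.", call. = FALSE)
  }
  if (is.character(p)) {
    tok <- tolower(trimws(p))
    p <- switch(tok,
      "inf" = ,
      "+inf" = Inf,
      "-inf" = -Inf,
      suppressWarnings(as.numeric(tok))
    )
  }
  if (!is.numeric(p) || is.na(p)) {
    stop("`p` must be a number, \"inf\" or \"-inf\".", call. = FALSE)
  }
  as.numeric(p)
}

#' @rdname parse_p
#' @export
format_p <- function(p) {
  out <- as.character(p)
  out[p == Inf] <- "inf"
  out[p == -Inf] <- "-inf"
  out
}

#' Default grid of power-mean exponents
#'
#' Covers every special case of the generalized mean (minimum, harmonic,
#' geometric, arithmetic, quadratic, maximum) and is spread evenly across
#' values near zero: `c(-Inf, -3, -2, -1, 0, 1, 2, 3, Inf)`.
#'
#' @return A numeric vector of exponents.
#' @export
default_p_grid <- function() {
  c(-Inf, -3, -2, -1, 0, 1, 2, 3, Inf)
}

# Row-wise power means of a nonnegative matrix, NA entries excluded.
# Rows must have at least one non-NA entry. Shares the scalar conventions of
# power_mean(): rescaled by the row extremum, zero short-circuit for p <= 0.
pm_rows <- function(M, p) {
  cols <- as.data.frame(M)
  if (is.infinite(p)) {
    f <- if (p > 0) pmax else pmin
    return(do.call(f, c(cols, na.rm = TRUE)))
  }
  if (p == 0) {
    return(exp(rowMeans(log(M), na.rm = TRUE))) # log(0) -> -Inf -> exp -> 0
  }
  f <- if (p > 0) pmax else pmin
  sc <- do.call(f, c(cols, na.rm = TRUE))
  out <- numeric(nrow(M))
  ok <- !is.na(sc) & sc > 0
  if (any(ok)) {
    R <- (M[ok, , drop = FALSE] / sc[ok])^p
    out[ok] <- sc[ok] * rowMeans(R, na.rm = TRUE)^(1 / p)
  }
  out
}
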