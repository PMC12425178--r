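#' Wrap a function of a feature as a feature function with a known domain
#'
#' A feature function couples an evaluator with its domain `[lo, hi]` and the
#' knots (break points) of the underlying interpolant, which the quadrature
#' routines use to split integrals at non-smooth points. Evaluation outside
#' the domain is constant (the value at the nearest domain end): flat
#' extrapolation avoids spline overshoot at open-ended feature groups.
#'
#' @param fun function of one numeric vector argument, finite on `[lo, hi]`.
#' @param lo,hi domain bounds, `lo < hi`.
#' @param knots optional numeric vector of interior break points.
#' @return an object of class `"feature_function"`, itself callable.
#' @export
feature_function <- function(fun, lo, hi, knots = numeric()) {
  stopifnot(is.function(fun), is.finite(lo), is.finite(hi), lo < hi)
  knots <- sort(unique(as.numeric(knots)))
  knots <- knots[knots > lo & knots < hi]
  f <- function(x) fun(pmin(pmax(x, lo), hi))
  structure(f, class = c("feature_function", "function"),
            lo = lo, hi = hi, knots = knots)
}

fn_domain <- function(ff) c(attr(ff, "lo"), attr(ff, "hi"))
fn_knots <- function(ff) attr(ff, "knots")

#' @export
print.feature_function <- function(x, ...) {
  d <- fn_domain(x)
  cat(sprintf("<feature_function> on [%g, %g] with %d knots\n",
              d[1L], d[2L], length(fn_knots(x))))
  invisible(x)
}

check_table <- function(table, value_col) {
  table <- as.data.frame(table)
  if (ncol(table) < 2L) stop("a feature table needs two columns")
  x <- as.numeric(table[[1L]])
  y <- as.numeric(table[[2L]])
  if (anyNA(x) || anyNA(y) || any(!is.finite(x)) || any(!is.finite(y))) {
    stop("feature tables must be finite and free of missing values")
  }
  ord <- order(x)
  x <- x[ord]; y <- y[ord]
  dup <- duplicated(x)
  if (any(dup)) {
    conflicting <- vapply(unique(x[dup]), function(xi) {
      length(unique(y[x == xi])) > 1L
    }, logical(1))
    if (any(conflicting)) {
      stop("duplicate feature values with conflicting ", value_col, " values")
    }
    keep <- !dup
    x <- x[keep]; y <- y[keep]
  }
  if (length(x) < 2L) stop("a feature table needs at least 2 distinct rows")
  list(x = x, y = y)
}

#' Interpolate a tabulated parameter into a smooth feature function
#'
#' Builds a monotonicity-preserving cubic interpolant (Fritsch--Carlson
#' Hermite spline) through the `(feature, value)` points, with constant
#' extrapolation beyond the tabulated range. Shape-preserving interpolation
#' is used rather than a natural cubic spline because the latter can
#' overshoot into negative values between points of, e.g., an
#' infection-fatality-ratio curve.
#'
#' @param table two-column table (`feature`, `value`); at least two rows with
#'   distinct features. Duplicated features must carry identical values.
#' @return a [feature_function()] over the tabulated feature range.
#' @examples
#' f <- interpolate_parameter(data.frame(feature = c(0, 100), value = 0.3))
#' f(50) # 0.3
#' @export
interpolate_parameter <- function(table) {
  tb <- check_table(table, "parameter")
  sp <- stats::splinefun(tb$x, tb$y, method = "monoH.FC")
  feature_function(sp, lo = tb$x[1L], hi = tb$x[length(tb$x)], knots = tb$x)
}

#' Interpolate tabulated population counts into a normalised density
#'
#' Builds a piecewise-linear interpolant through the `(feature, count)`
#' points and rescales it to integrate to 1 over the tabulated range. The
#' aggregation and disaggregation formulas are ratios and therefore invariant
#' to the scale of the density, so normalisation is always safe; it also
#' makes population conservation directly testable.
#'
#' @param table two-column table (`feature`, `population`); counts must be
#'   non-negative with positive total mass.
#' @return a [feature_function()] integrating to 1 over its domain.
#' @export
interpolate_density <- function(table) {
  tb <- check_table(table, "population")
  if (any(tb$y < 0)) stop("population counts must be non-negative")
  # exact trapezoid mass of the piecewise-linear interpolant
  total <- sum(diff(tb$x) * (tb$y[-length(tb$y)] + tb$y[-1L]) / 2)
  if (total <= 0) stop("population table has zero total mass")
  ap <- stats::approxfun(tb$x, tb$y / total, rule = 2)
  feature_function(ap, lo = tb$x[1L], hi = tb$x[length(tb$x)], knots = tb$x)
}

# Coerce a user-supplied parameter (function, feature_function or table) to a
# feature_function on [lo, hi].
as_parameter_function <- function(parameter, lo, hi) {
  if (inherits(parameter, "feature_function")) return(parameter)
  if (is.function(parameter)) return(feature_function(parameter, lo, hi))
  interpolate_parameter(parameter)
}

# Coerce a user-supplied density (function, feature_function or table) to a
# normalised feature_function on [lo, hi].
as_density_function <- function(density, lo, hi) {
  if (is.function(density) && !inherits(density, "feature_function")) {
    density <- feature_function(density, lo, hi)
  }
  if (inherits(density, "feature_function")) {
    total <- quad_interval(density, lo, hi, knots = fn_knots(density))
    if (!is.finite(total) || total <= 0) stop("density has non-positive mass")
    raw <- density
    return(feature_function(function(x) raw(x) / total, lo, hi,
                            knots = fn_knots(density)))
  }
  interpolate_density(density)
}
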