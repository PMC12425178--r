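# Adaptive quadrature over one interval, split at interior knots so that
# piecewise interpolants are integrated piece by smooth piece. Falls back to
# composite Simpson on a fine grid if the adaptive rule fails to converge
# (can happen for barely-smooth integrands).
quad_interval <- function(f, lo, hi, knots = numeric(),
                          abs_tol = 1e-9, simpson_step = 0.01) {
  if (hi <= lo) return(0)
  pts <- sort(unique(c(lo, knots[knots > lo & knots < hi], hi)))
  total <- 0
  for (k in seq_len(length(pts) - 1L)) {
    a <- pts[k]; b <- pts[k + 1L]
    piece <- tryCatch({
      r <- stats::integrate(f, a, b, abs.tol = abs_tol, rel.tol = abs_tol,
                            stop.on.error = FALSE)
      if (!r$message %in% c("OK", "the integral is probably divergent")) {
        stop(r$message)
      }
      r$value
    }, error = function(e) simpson(f, a, b, step = simpson_step))
    total <- total + piece
  }
  total
}

simpson <- function(f, a, b, step = 0.01) {
  n <- max(2L, 2L * ceiling((b - a) / (2 * step)))
  x <- seq(a, b, length.out = n + 1L)
  y <- f(x)
  h <- (b - a) / n
  h / 3 * (y[1L] + y[n + 1L] +
             4 * sum(y[seq(2L, n, by = 2L)]) +
             2 * sum(y[seq(3L, n - 1L, by = 2L)]))
}

#' Build the mixing table linking a model and an output partition
#'
#' The mixing partition is the union of the model and output boundaries.
#' For each mixing interval `[c_i, c_{i+1})` the table stores the weighted
#' parameter integral
#' \deqn{weight_i = \int_{c_i}^{c_{i+1}} parameter(x)\,\rho(x)\,dx}
#' and the population mass
#' \deqn{population_i = \int_{c_i}^{c_{i+1}} \rho(x)\,dx,}
#' where \eqn{\rho} is the population density normalised to integrate to 1
#' over the common support. Each mixing interval lies within exactly one
#' model interval and one output interval; the table records both indices.
#' These weights drive both directions of the resolution change:
#' aggregation via [blend()] and disaggregation via [distill()].
#'
#' @param parameter the parameter curve: a function, a [feature_function()],
#'   or a two-column table (`feature`, `value`) passed to
#'   [interpolate_parameter()].
#' @param density the population density: a function, a [feature_function()],
#'   or a two-column table (`feature`, `population`) passed to
#'   [interpolate_density()]. Always renormalised to unit mass.
#' @param model,output partitions (boundary vectors) sharing the same overall
#'   support.
#' @param abs_tol absolute quadrature tolerance per mixing interval.
#' @return a `data.table` of class `"mixing_table"` with columns `lower`,
#'   `upper`, `weight`, `population`, `model_group`, `output_group`, and the
#'   two partitions stored as attributes.
#' @examples
#' mx <- build_mixing_table(function(x) x, function(x) rep(1, length(x)),
#'                          model = c(0, 10), output = c(0, 5, 10))
#' blend(mx)
#' @export
build_mixing_table <- function(parameter, density, model, output,
                               abs_tol = 1e-9) {
  model <- make_partition(model)
  output <- make_partition(output)
  mixing <- union_partition(model, output)
  lo <- mixing[1L]; hi <- mixing[length(mixing)]

  dens <- as_density_function(density, lo, hi)
  par_fn <- as_parameter_function(parameter, lo, hi)
  knots <- sort(unique(c(fn_knots(dens), fn_knots(par_fn))))

  lower <- unclass(mixing)[-length(mixing)]
  upper <- unclass(mixing)[-1L]
  weight <- numeric(length(lower))
  population <- numeric(length(lower))
  for (i in seq_along(lower)) {
    weight[i] <- quad_interval(function(x) par_fn(x) * dens(x),
                               lower[i], upper[i], knots, abs_tol)
    population[i] <- quad_interval(dens, lower[i], upper[i], knots, abs_tol)
    if (population[i] <= 0) {
      stop(sprintf("non-positive population mass in mixing interval [%g, %g)",
                   lower[i], upper[i]))
    }
  }

  tab <- data.table::data.table(
    lower = lower,
    upper = upper,
    weight = weight,
    population = population,
    model_group = interval_index(lower, model),
    output_group = interval_index(lower, output)
  )
  data.table::setattr(tab, "model_partition", model)
  data.table::setattr(tab, "output_partition", output)
  data.table::setattr(tab, "class",
                      c("mixing_table", class(data.table::data.table())))
  tab
}

model_partition <- function(mixing) attr(mixing, "model_partition")
output_partition <- function(mixing) attr(mixing, "output_partition")

#' @export
print.mixing_table <- function(x, ...) {
  mp <- model_partition(x); op <- output_partition(x)
  cat(sprintf(
    "<mixing_table> %d mixing intervals; %d model groups x %d output groups on [%g, %g]\n",
    nrow(x), n_intervals(mp), n_intervals(op), mp[1L], mp[length(mp)]))
  print(data.table::as.data.table(x))
  invisible(x)
}
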