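#' Aggregate a mixing table into per-model-group parameter values
#'
#' The blended value for model group `j` is the population-density-weighted
#' mean of the parameter over the group interval:
#' \deqn{parameter_j = \sum_k weight_k / \sum_k population_k,}
#' summing over the mixing intervals contained in the group. The result
#' always lies between the infimum and supremum of the parameter over the
#' group.
#'
#' @param mixing a [build_mixing_table()] result.
#' @return a `data.table` with one row per model group: `model_group`,
#'   `group_lo`, `group_hi`, `value`.
#' @export
blend <- function(mixing) {
  stopifnot(inherits(mixing, "mixing_table"))
  mp <- model_partition(mixing)
  agg <- mixing[, list(weight = sum(weight), population = sum(population)),
                by = "model_group"]
  data.table::setorderv(agg, "model_group")
  if (any(agg$population <= 0)) {
    stop("model group with zero total population")
  }
  data.table::data.table(
    model_group = agg$model_group,
    group_lo = unclass(mp)[agg$model_group],
    group_hi = unclass(mp)[agg$model_group + 1L],
    value = agg$weight / agg$population
  )
}

#' Redistribution weights from model groups to output groups
#'
#' The entry `omega[j, i]` is the share of model group `j`'s outcomes
#' apportioned to output group `i`: by Bayes' rule this is the weighted
#' parameter mass of the intersection of the two intervals over the weighted
#' parameter mass of the whole model group,
#' \deqn{\omega_{ji} = \sum_{c_k \in b_i \cap a_j} weight_k /
#'   \sum_{c_k \in a_j} weight_k.}
#' Rows sum to 1; entries are 0 where the intervals do not intersect. A model
#' group whose total weight is zero (parameter identically zero there) has no
#' parameter information to apportion by; such rows fall back to
#' population-proportional shares, with a warning, so that outcome mass is
#' still conserved.
#'
#' @param mixing a [build_mixing_table()] result.
#' @return a numeric matrix, model groups in rows, output groups in columns.
#' @export
redistribution_weights <- function(mixing) {
  stopifnot(inherits(mixing, "mixing_table"))
  n_model <- n_intervals(model_partition(mixing))
  n_output <- n_intervals(output_partition(mixing))
  omega <- matrix(0, nrow = n_model, ncol = n_output)
  for (j in seq_len(n_model)) {
    rows <- mixing$model_group == j
    w <- mixing$weight[rows]
    denom <- sum(w)
    if (denom <= 0) {
      warning(sprintf(
        "model group %d has zero total weight; using population-proportional shares",
        j))
      w <- mixing$population[rows]
      denom <- sum(w)
    }
    shares <- w / denom
    og <- mixing$output_group[rows]
    for (k in seq_along(og)) omega[j, og[k]] <- omega[j, og[k]] + shares[k]
  }
  omega
}

#' Disaggregate model-group outcomes onto the output partition
#'
#' Applies the redistribution weights: `Y_i = sum_j omega[j, i] * X_j`. Total
#' outcome mass is conserved because each weight row sums to 1. With the
#' model partition equal to the output partition this is the identity map.
#'
#' @param mixing a [build_mixing_table()] result.
#' @param outcomes non-negative numeric vector of per-model-group outcomes
#'   (e.g. deaths), one entry per model group.
#' @return a `data.table` with one row per output group: `output_group`,
#'   `group_lo`, `group_hi`, `value`.
#' @export
distill <- function(mixing, outcomes) {
  stopifnot(inherits(mixing, "mixing_table"))
  op <- output_partition(mixing)
  n_model <- n_intervals(model_partition(mixing))
  outcomes <- as_outcome_vector(outcomes, n_model)
  omega <- redistribution_weights(mixing)
  y <- as.vector(crossprod(omega, outcomes))
  data.table::data.table(
    output_group = seq_len(n_intervals(op)),
    group_lo = unclass(op)[-length(op)],
    group_hi = unclass(op)[-1L],
    value = y
  )
}

as_outcome_vector <- function(outcomes, n_groups) {
  if (is.data.frame(outcomes)) {
    vcol <- intersect(c("value", "count", "deaths"), names(outcomes))
    if (length(vcol) == 0L) stop("outcome table needs a value/count column")
    outcomes <- outcomes[[vcol[1L]]]
  }
  outcomes <- as.numeric(outcomes)
  if (length(outcomes) != n_groups) {
    stop(sprintf("expected %d outcome entries, got %d",
                 n_groups, length(outcomes)))
  }
  if (anyNA(outcomes) || any(outcomes < 0)) {
    stop("outcomes must be non-negative and free of missing values")
  }
  outcomes
}

#' Aggregation by parameter value at the group midpoint
#'
#' Evaluates the parameter at `(lo + hi) / 2` of each model group; the
#' simplest of the aggregation approaches, ignoring the population structure
#' entirely. Open-ended terminal groups must be given an explicit upper
#' bound in the partition (e.g. 101 for a 65+ age group) so the midpoint is
#' defined.
#'
#' @param parameter a function, [feature_function()] or parameter table.
#' @param model a partition.
#' @return a `data.table` as in [blend()].
#' @export
aggregate_midpoint <- function(parameter, model) {
  model <- make_partition(model)
  par_fn <- as_parameter_function(parameter, model[1L], model[length(model)])
  mids <- interval_midpoints(model)
  data.table::data.table(
    model_group = seq_along(mids),
    group_lo = unclass(model)[-length(model)],
    group_hi = unclass(model)[-1L],
    value = par_fn(mids)
  )
}

# Density-weighted mean feature value per model group.
group_mean_feature <- function(density, model) {
  model <- make_partition(model)
  lo <- model[1L]; hi <- model[length(model)]
  dens <- as_density_function(density, lo, hi)
  knots <- fn_knots(dens)
  vapply(seq_len(n_intervals(model)), function(j) {
    a <- model[j]; b <- model[j + 1L]
    mass <- quad_interval(dens, a, b, knots)
    if (mass <= 0) stop(sprintf("zero population mass in group [%g, %g)", a, b))
    quad_interval(function(x) x * dens(x), a, b, knots) / mass
  }, numeric(1))
}

#' Aggregation by parameter value at the group's mean feature
#'
#' Evaluates the parameter at the density-weighted mean feature value of each
#' model group, `E[x | group] = int x rho(x) dx / int rho(x) dx`. Exact for
#' parameters affine in the feature; under- or over-shoots curved parameters
#' (Jensen's inequality) relative to [blend()].
#'
#' @inheritParams aggregate_midpoint
#' @param density a function, [feature_function()] or population table.
#' @return a `data.table` as in [blend()].
#' @export
aggregate_mean_age <- function(parameter, density, model) {
  model <- make_partition(model)
  par_fn <- as_parameter_function(parameter, model[1L], model[length(model)])
  means <- group_mean_feature(density, model)
  data.table::data.table(
    model_group = seq_len(n_intervals(model)),
    group_lo = unclass(model)[-length(model)],
    group_hi = unclass(model)[-1L],
    value = par_fn(means)
  )
}

output_table <- function(output, values) {
  output <- make_partition(output)
  data.table::data.table(
    output_group = seq_len(n_intervals(output)),
    group_lo = unclass(output)[-length(output)],
    group_hi = unclass(output)[-1L],
    value = values
  )
}

# Intersection lengths between one model interval and all output intervals.
overlap_lengths <- function(a_lo, a_hi, output) {
  lo <- pmax(a_lo, unclass(output)[-length(output)])
  hi <- pmin(a_hi, unclass(output)[-1L])
  pmax(0, hi - lo)
}

#' Disaggregation: uniform spread across each model group
#'
#' Each model group's outcome mass is spread over the intersecting output
#' intervals proportionally to interval length, i.e. outcomes are assumed
#' uniformly distributed over the group.
#'
#' @param outcomes per-model-group outcome vector (or table with a `value`
#'   column).
#' @param model,output partitions sharing the same overall support.
#' @return a `data.table` as in [distill()].
#' @export
distribute_uniform <- function(outcomes, model, output) {
  model <- make_partition(model)
  output <- make_partition(output)
  union_partition(model, output) # validates matching support
  x <- as_outcome_vector(outcomes, n_intervals(model))
  y <- numeric(n_intervals(output))
  for (j in seq_len(n_intervals(model))) {
    lens <- overlap_lengths(model[j], model[j + 1L], output)
    if (sum(lens) <= 0) stop("model group does not overlap the output partition")
    y <- y + x[j] * lens / sum(lens)
  }
  output_table(output, y)
}

#' Disaggregation: all outcomes at the group's mean feature value
#'
#' Assigns each model group's entire outcome mass to the single output
#' interval containing the group's density-weighted mean feature value
#' (half-open convention: a mean exactly on a boundary goes to the upper
#' interval).
#'
#' @inheritParams distribute_uniform
#' @param density a function, [feature_function()] or population table.
#' @return a `data.table` as in [distill()].
#' @export
distribute_mean_age <- function(outcomes, density, model, output) {
  model <- make_partition(model)
  output <- make_partition(output)
  union_partition(model, output)
  x <- as_outcome_vector(outcomes, n_intervals(model))
  means <- group_mean_feature(density, model)
  # snap means to output boundaries within quadrature noise so the half-open
  # tie-break (boundary value goes to the upper interval) is deterministic
  tol <- 1e-9 * diff(range(output))
  for (b in unclass(output)) means[abs(means - b) < tol] <- b
  idx <- interval_index(means, output)
  y <- numeric(n_intervals(output))
  for (j in seq_along(x)) y[idx[j]] <- y[idx[j]] + x[j]
  output_table(output, y)
}

#' Disaggregation proportional to the population density
#'
#' Within each model group, outcome mass is apportioned to the intersecting
#' output intervals proportionally to their population integrals -- the
#' Bayes-rule redistribution with the parameter held constant. Reduces to
#' [distribute_uniform()] for a uniform density, and coincides with
#' [distill()] when the parameter curve is constant.
#'
#' @inheritParams distribute_mean_age
#' @return a `data.table` as in [distill()].
#' @export
distribute_density <- function(outcomes, density, model, output) {
  model <- make_partition(model)
  output <- make_partition(output)
  x <- as_outcome_vector(outcomes, n_intervals(model))
  mixing <- build_mixing_table(function(z) rep(1, length(z)), density,
                               model, output)
  y <- as.vector(crossprod(redistribution_weights(mixing), x))
  output_table(output, y)
}

#' Compare aggregation approaches side by side
#'
#' Computes per-model-group parameter values under the midpoint, mean-feature
#' and blended (density-weighted mean) approaches, in one long table.
#'
#' @inheritParams aggregate_mean_age
#' @return a `data.table` with columns `group_lo`, `group_hi`, `approach`
#'   (one of `"midpoint"`, `"mean_age"`, `"blend"`) and `value`; one row per
#'   model group and approach.
#' @export
parameter_summary <- function(parameter, density, model) {
  model <- make_partition(model)
  mixing <- build_mixing_table(parameter, density, model, model)
  pieces <- list(
    midpoint = aggregate_midpoint(parameter, model),
    mean_age = aggregate_mean_age(parameter, density, model),
    blend = blend(mixing)
  )
  data.table::rbindlist(lapply(names(pieces), function(nm) {
    data.table::data.table(
      group_lo = pieces[[nm]]$group_lo,
      group_hi = pieces[[nm]]$group_hi,
      approach = nm,
      value = pieces[[nm]]$value
    )
  }))
}

#' Compare disaggregation approaches side by side
#'
#' Disaggregates the same per-model-group outcomes under the uniform,
#' mean-feature, density-proportional and parameter-weighted (distill)
#' approaches. Every approach conserves the outcome total.
#'
#' @inheritParams distribute_mean_age
#' @param parameter a function, [feature_function()] or parameter table.
#' @return a `data.table` with columns `group_lo`, `group_hi`, `approach`
#'   (one of `"uniform"`, `"mean_age"`, `"density"`, `"distill"`) and
#'   `value`; one row per output group and approach.
#' @export
distill_summary <- function(outcomes, parameter, density, model, output) {
  model <- make_partition(model)
  output <- make_partition(output)
  mixing <- build_mixing_table(parameter, density, model, output)
  pieces <- list(
    uniform = distribute_uniform(outcomes, model, output),
    mean_age = distribute_mean_age(outcomes, density, model, output),
    density = distribute_density(outcomes, density, model, output),
    distill = distill(mixing, outcomes)
  )
  data.table::rbindlist(lapply(names(pieces), function(nm) {
    data.table::data.table(
      group_lo = pieces[[nm]]$group_lo,
      group_hi = pieces[[nm]]$group_hi,
      approach = nm,
      value = pieces[[nm]]$value
    )
  }))
}
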