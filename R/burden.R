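#' Piecewise-constant density from a single-year population table
#'
#' Row `age = x` of a demography table represents the interval `[x, x + 1)`,
#' so the natural density is the step function with value `population_x`
#' there, normalised to unit mass over `[0, max_age + 1]`. Group population
#' integrals of this density agree exactly with sums over the table, which
#' keeps the mixing-table bookkeeping and the SEIR group populations
#' consistent.
#'
#' @param demography table with `age` (integers from 0) and `population`
#'   columns.
#' @return a [feature_function()] with knots at every integer age.
#' @export
demography_density <- function(demography) {
  age <- as.numeric(demography$age)
  pop <- as.numeric(demography$population)
  stopifnot(length(age) >= 2, all(pop >= 0), sum(pop) > 0)
  ord <- order(age)
  age <- age[ord]; pop <- pop[ord]
  hi <- age[length(age)] + 1
  dens <- pop / sum(pop) # each interval has width 1
  step <- stats::stepfun(age[-1L], dens, right = FALSE)
  feature_function(step, lo = age[1L], hi = hi, knots = age[-1L])
}

#' Linear interpolant of remaining life expectancy from a life table
#'
#' @param life_table table with `age` and `ex` columns.
#' @return a function of age; evaluation outside the tabulated range is an
#'   error.
#' @export
life_expectancy_function <- function(life_table) {
  age <- as.numeric(life_table$age)
  ex <- as.numeric(life_table$ex)
  stopifnot(length(age) >= 2, all(ex > 0))
  fn <- stats::approxfun(age, ex)
  lo <- min(age); hi <- max(age)
  function(x) {
    if (any(x < lo | x > hi)) stop("age outside the life table range")
    fn(x)
  }
}

#' Years of life lost from deaths by age
#'
#' The YLL total is the sum over deaths of the remaining life expectancy at
#' the age of death: `sum_i deaths_i * e(age_i)`. For output groups wider
#' than a point, the representative age is the group's lower bound,
#' consistent with the lower-bound convention used for single-year IFR
#' assignment.
#'
#' @param deaths a [distill()]-style table (columns `group_lo`, `value`) or a
#'   numeric vector accompanied by `ages`.
#' @param life_table table with `age` and `ex` columns.
#' @param ages representative ages, required when `deaths` is a bare vector.
#' @return total years of life lost.
#' @export
compute_ylls <- function(deaths, life_table, ages = NULL) {
  if (is.data.frame(deaths)) {
    ages <- deaths$group_lo
    deaths <- deaths$value
  }
  if (is.null(ages)) stop("ages are required when deaths is a bare vector")
  deaths <- as.numeric(deaths)
  if (any(deaths < 0)) stop("deaths must be non-negative")
  efn <- life_expectancy_function(life_table)
  sum(deaths * efn(ages))
}

#' Outcomes averted by a scenario relative to a baseline
#'
#' @param baseline,scenario outcome totals (e.g. deaths or YLLs) under the
#'   no-intervention baseline and the intervention scenario.
#' @return `baseline - scenario`; positive when the scenario averts outcomes.
#' @export
deaths_averted <- function(baseline, scenario) baseline - scenario

#' Percentage over- or under-estimation relative to a reference
#'
#' `100 * (value - reference) / reference`; e.g. an approach returning 2.73
#' times the reference overestimates by 173%.
#'
#' @param value the approach's estimate.
#' @param reference the reference estimate (> 0).
#' @return a percentage.
#' @export
overestimation_pct <- function(value, reference) {
  if (any(reference <= 0)) stop("reference must be positive")
  100 * (value - reference) / reference
}

default_scenarios <- function(model) {
  model <- make_partition(model)
  n <- length(model)
  targets <- lapply(seq_len(n - 2L), function(j) c(model[j + 1L], model[j + 2L]))
  names(targets) <- vapply(targets, function(tg) {
    sprintf("%g-%g", tg[1L], tg[2L])
  }, character(1))
  c(list(none = NULL), targets)
}

#' Run the full vaccination-scenario comparison of approaches
#'
#' For each vaccination scenario this runs the coarse (model-partition) SEIR
#' once -- trajectories do not depend on the IFR -- and computes deaths under
#' each aggregation approach (midpoint, mean-age, blend), plus a single-year
#' high-resolution run as benchmark. YLL comparisons hold the model-group
#' deaths fixed at the blend-based estimates and vary only the disaggregation
#' approach (uniform, mean-age, density-proportional, distill) onto
#' single-year output groups; the benchmark YLLs come directly from the
#' high-resolution deaths. Doses default to the number needed to cover 75%
#' of the terminal (oldest) model group and are fixed across scenarios, so
#' coverage in larger target groups is correspondingly lower; vaccination is
#' all-or-nothing with 50% efficacy by default.
#'
#' @param demography single-year `age`/`population` table.
#' @param life_table `age`/`ex` table for the YLL computation.
#' @param pathogen a [pathogen_params()] object.
#' @param contacts coarse contact matrix matching `model`.
#' @param model coarse model partition (default the 0-4, 5-19, 20-64, 65+
#'   grouping with terminal bound 101).
#' @param scenarios named list of vaccination targets (`NULL` for none, or
#'   `c(lo, hi)` feature ranges); must include a `none` baseline.
#' @param doses doses available per scenario; default 75% of the terminal
#'   group's population.
#' @param efficacy all-or-nothing vaccine efficacy.
#' @param horizon simulation days.
#' @return a list of class `"burden_report"` with elements `deaths` (columns
#'   `scenario`, `approach`, `deaths`, `deaths_averted`; approaches
#'   `midpoint`, `mean_age`, `blend`, `high_res`) and `ylls` (columns
#'   `scenario`, `approach`, `ylls`, `ylls_averted`; approaches `uniform`,
#'   `mean_age`, `density`, `distill`, `high_res`).
#' @export
compare_approaches <- function(demography, life_table, pathogen, contacts,
                               model = c(0, 5, 20, 65, 101),
                               scenarios = default_scenarios(model),
                               doses = NULL, efficacy = 0.5, horizon = 365) {
  model <- make_partition(model)
  if (!"none" %in% names(scenarios)) {
    stop("scenarios must include a 'none' baseline")
  }
  density <- demography_density(demography)
  lo <- model[1L]; hi <- model[length(model)]
  output <- make_partition(seq(lo, hi, by = 1))
  fine <- output
  ages_fine <- unclass(fine)[-length(fine)]

  pop_model <- group_populations(demography, model)
  pop_fine <- group_populations(demography, fine)
  contacts_fine <- expand_contact_matrix(contacts, model, fine, pop_fine)
  if (is.null(doses)) {
    doses <- 0.75 * pop_model[n_intervals(model)]
  }

  mixing <- build_mixing_table(pathogen$ifr, density, model, output)
  ifr_by <- list(
    midpoint = aggregate_midpoint(pathogen$ifr, model)$value,
    mean_age = aggregate_mean_age(pathogen$ifr, density, model)$value,
    blend = blend(mixing)$value
  )
  ifr_fine <- pathogen$ifr(ages_fine) # lower-bound convention

  run_scenario <- function(target, populations, partition, cmat) {
    st <- initial_state(populations, partition = partition)
    st <- apply_vaccination(st, target, doses, efficacy)
    st <- seed_epidemic(st)
    run_seir(st, pathogen, cmat, horizon = horizon)
  }

  agg_names <- c(names(ifr_by), "high_res")
  disagg_names <- c("uniform", "mean_age", "density", "distill", "high_res")
  deaths_tab <- list(); ylls_tab <- list()
  for (sc in names(scenarios)) {
    target <- scenarios[[sc]]
    run_lo <- run_scenario(target, pop_model, model, contacts)
    run_hi <- run_scenario(target, pop_fine, fine, contacts_fine)
    deaths_hi <- compute_deaths(run_hi, ifr_fine)
    deaths_lo <- lapply(ifr_by, function(v) compute_deaths(run_lo, v))

    dvals <- c(vapply(deaths_lo, sum, numeric(1)), high_res = sum(deaths_hi))
    deaths_tab[[sc]] <- data.table::data.table(
      scenario = sc, approach = agg_names, deaths = as.numeric(dvals))

    x_blend <- deaths_lo$blend
    by_age <- list(
      uniform = distribute_uniform(x_blend, model, output),
      mean_age = distribute_mean_age(x_blend, density, model, output),
      density = distribute_density(x_blend, density, model, output),
      distill = distill(mixing, x_blend)
    )
    yvals <- c(
      vapply(by_age, compute_ylls, numeric(1), life_table = life_table),
      high_res = compute_ylls(deaths_hi, life_table, ages = ages_fine)
    )
    ylls_tab[[sc]] <- data.table::data.table(
      scenario = sc, approach = disagg_names, ylls = as.numeric(yvals))
  }

  deaths_dt <- data.table::rbindlist(deaths_tab)
  ylls_dt <- data.table::rbindlist(ylls_tab)
  base_d <- deaths_dt[deaths_dt$scenario == "none", ]
  base_y <- ylls_dt[ylls_dt$scenario == "none", ]
  deaths_dt$deaths_averted <- deaths_averted(
    base_d$deaths[match(deaths_dt$approach, base_d$approach)], deaths_dt$deaths)
  ylls_dt$ylls_averted <- deaths_averted(
    base_y$ylls[match(ylls_dt$approach, base_y$approach)], ylls_dt$ylls)

  structure(list(deaths = deaths_dt, ylls = ylls_dt,
                 pathogen = pathogen$name, doses = doses,
                 model = model),
            class = "burden_report")
}

#' @export
print.burden_report <- function(x, ...) {
  cat(sprintf("<burden_report> %s; %g doses per scenario\n",
              x$pathogen, x$doses))
  cat("Deaths by aggregation approach:\n")
  print(x$deaths)
  cat("YLLs by disaggregation approach:\n")
  print(x$ylls)
  invisible(x)
}
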