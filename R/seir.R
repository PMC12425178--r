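#' Pathogen parameters for the age-stratified SEIR model
#'
#' @param beta per-contact, per-day transmissibility (> 0).
#' @param latent_period mean days in the exposed compartment (`1/tau`).
#' @param infectious_period mean days in the infectious compartment
#'   (`1/gamma`).
#' @param ifr infection-fatality ratio as a function of the stratifying
#'   feature (age), returning values in `[0, 1]`.
#' @param name optional label.
#' @return a list of class `"pathogen_params"`.
#' @export
pathogen_params <- function(beta, latent_period, infectious_period, ifr,
                            name = "pathogen") {
  stopifnot(beta > 0, latent_period > 0, infectious_period > 0,
            is.function(ifr))
  structure(list(beta = beta, tau = 1 / latent_period,
                 gamma = 1 / infectious_period, ifr = ifr, name = name),
            class = "pathogen_params")
}

#' COVID-like infection-fatality ratio by age
#'
#' Log-linear IFR, `10^(-3.27 + 0.0524 * age) / 100`, strictly increasing in
#' age; it crosses 1% at about age 62.4.
#'
#' @param age age in years (vectorised).
#' @return IFR as a fraction.
#' @export
covid_ifr <- function(age) 10^(-3.27 + 0.0524 * age) / 100

#' Flu-like infection-fatality ratio proportional to all-cause mortality
#'
#' Returns `scale * m(age)` clipped to `[0, 1]`, where `m` is an all-cause
#' mortality rate curve. Because mortality is U-shaped in age, the resulting
#' IFR rises at very young as well as old ages, unlike the monotone
#' COVID-like curve.
#'
#' @param age age in years (vectorised).
#' @param mortality function giving the all-cause mortality rate at an age.
#' @param scale positive proportionality constant (see
#'   [calibrate_flu_scale()]).
#' @return IFR as a fraction.
#' @export
flu_ifr <- function(age, mortality, scale) {
  pmin(1, pmax(0, scale * mortality(age)))
}

#' COVID-like pathogen parameterisation
#'
#' Transmissibility 0.1 per contact-day, 3-day latent and 5-day infectious
#' periods, with the log-linear [covid_ifr()].
#'
#' @return a [pathogen_params()] object.
#' @export
covid_params <- function() {
  pathogen_params(beta = 0.1, latent_period = 3, infectious_period = 5,
                  ifr = covid_ifr, name = "covid_like")
}

#' Flu-like pathogen parameterisation
#'
#' Transmissibility 0.15 per contact-day, 1-day latent and 2-day infectious
#' periods, with an IFR proportional to all-cause mortality.
#'
#' @param mortality all-cause mortality rate function of age.
#' @param scale IFR proportionality constant (see [calibrate_flu_scale()]).
#' @return a [pathogen_params()] object.
#' @export
flu_params <- function(mortality, scale = 1) {
  pathogen_params(beta = 0.15, latent_period = 1, infectious_period = 2,
                  ifr = function(age) flu_ifr(age, mortality, scale),
                  name = "flu_like")
}

#' Fully susceptible initial state for given group populations
#'
#' @param populations positive per-group population sizes; names (or the
#'   `partition` attribute set by callers) identify groups.
#' @param partition optional partition whose intervals label the groups.
#' @return a list of class `"seir_state"` with vectors `S`, `E`, `I`, `R`.
#' @export
initial_state <- function(populations, partition = NULL) {
  populations <- as.numeric(populations)
  stopifnot(all(populations > 0))
  n <- length(populations)
  structure(list(S = populations, E = numeric(n), I = numeric(n),
                 R = numeric(n), partition = partition),
            class = "seir_state")
}

state_totals <- function(state) state$S + state$E + state$I + state$R

#' Move effectively vaccinated individuals to the recovered compartment
#'
#' All-or-nothing vaccination: a fraction `coverage * efficacy` of each
#' targeted group is fully protected and moved from S to R before the
#' simulation starts. Coverage is `min(1, doses / target population)`.
#' `target` is a feature range `[lo, hi)`; every group interval contained in
#' it shares the doses proportionally to its population, which makes the same
#' call work at low and high resolution.
#'
#' @param state a [initial_state()] (pre-seeding) state with a `partition`.
#' @param target `NULL` (no vaccination) or `c(lo, hi)` bounds of the
#'   targeted feature range, which must align with group boundaries.
#' @param doses number of doses available.
#' @param efficacy all-or-nothing efficacy in `[0, 1]`.
#' @return the updated state.
#' @export
apply_vaccination <- function(state, target, doses, efficacy = 0.5) {
  stopifnot(inherits(state, "seir_state"), doses >= 0,
            efficacy >= 0, efficacy <= 1)
  if (is.null(target) || doses == 0) return(state)
  partition <- state$partition
  if (is.null(partition)) stop("state has no partition; cannot resolve target")
  partition <- make_partition(partition)
  lo <- unclass(partition)[-length(partition)]
  hi <- unclass(partition)[-1L]
  in_target <- lo >= target[1L] & hi <= target[2L]
  if (!any(in_target)) stop("unknown vaccination target group")
  totals <- state_totals(state)
  coverage <- min(1, doses / sum(totals[in_target]))
  protected <- numeric(length(totals))
  protected[in_target] <- coverage * efficacy * totals[in_target]
  state$S <- state$S - protected
  state$R <- state$R + protected
  if (any(state$S < 0)) stop("vaccination exceeds susceptible population")
  state
}

#' Seed the epidemic in every group
#'
#' Moves a fraction (default 0.001%) of each group's population from S to E.
#' Seeding every group at the same fraction is automatically
#' population-proportional within any coarser grouping, so low- and
#' high-resolution runs are seeded consistently.
#'
#' @param state a [initial_state()] state.
#' @param fraction seeded fraction of each group (default `1e-5`).
#' @return the updated state.
#' @export
seed_epidemic <- function(state, fraction = 1e-5) {
  stopifnot(inherits(state, "seir_state"), fraction >= 0, fraction < 1)
  seeds <- fraction * state_totals(state)
  state$E <- state$E + seeds
  state$S <- state$S - seeds
  if (any(state$S < 0)) stop("seeding exceeds susceptible population")
  state
}

#' Force of infection per group
#'
#' `lambda_i = beta * sum_j c[i, j] * I_j / N_j`, where `c[i, j]` is the
#' daily number of contacts an individual in group `i` has with group `j` and
#' `N_j` the (constant) group population.
#'
#' @param state a `"seir_state"`.
#' @param params a [pathogen_params()] object.
#' @param contacts square non-negative contact matrix, one row/column per
#'   group.
#' @return numeric vector of per-group infection rates (per day).
#' @export
force_of_infection <- function(state, params, contacts) {
  totals <- state_totals(state)
  if (any(totals <= 0)) stop("zero group total population")
  as.vector(params$beta * contacts %*% (state$I / totals))
}

#' Integrate the age-stratified SEIR model
#'
#' Deterministic ODE system per group: `dS = -lambda S`, `dE = lambda S -
#' tau E`, `dI = tau E - gamma I`, `dR = gamma I`, with cumulative infections
#' tracked as an auxiliary integrated state (`d cumI = lambda S`) rather than
#' by differencing S, to avoid cancellation error. There is no demography
#' (no ageing, births or background deaths), so group totals are conserved.
#' Fatalities are post-processing (see [compute_deaths()]) and do not feed
#' back into the dynamics, which is equivalent to survivors proportionally
#' reducing their contact rates.
#'
#' @param state a seeded `"seir_state"`.
#' @param params a [pathogen_params()] object.
#' @param contacts square contact matrix (daily contacts).
#' @param horizon simulation length in days (default 365).
#' @param rtol,atol solver tolerances (adaptive `lsoda`).
#' @return a list of class `"epidemic_run"`: `times`, matrices `S`, `E`, `I`,
#'   `R` (time x group), `cumulative_infections` (final per-group counts),
#'   `populations`, and the state's `partition`.
#' @export
run_seir <- function(state, params, contacts, horizon = 365,
                     rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(state, "seir_state"), inherits(params, "pathogen_params"))
  n <- length(state$S)
  contacts <- as.matrix(contacts)
  stopifnot(nrow(contacts) == n, ncol(contacts) == n, all(contacts >= 0))
  totals <- state_totals(state)
  y0 <- c(state$S, state$E, state$I, state$R, numeric(n))
  idx <- function(k) ((k - 1L) * n + 1L):(k * n)

  derivs <- function(t, y, parms) {
    S <- y[idx(1L)]; E <- y[idx(2L)]; I <- y[idx(3L)]
    lambda <- as.vector(params$beta * contacts %*% (I / totals))
    inf <- lambda * S
    list(c(-inf,
           inf - params$tau * E,
           params$tau * E - params$gamma * I,
           params$gamma * I,
           inf))
  }

  sol <- deSolve::ode(y = y0, times = seq(0, horizon, by = 1), func = derivs,
                      parms = NULL, method = "lsoda", rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1L] < 0) stop("ODE solver failed")
  sol <- unclass(sol)
  dimnames(sol) <- NULL
  grab <- function(k) sol[, 1L + idx(k), drop = FALSE]
  structure(list(
    times = sol[, 1L],
    S = grab(1L), E = grab(2L), I = grab(3L), R = grab(4L),
    cumulative_infections = sol[nrow(sol), 1L + idx(5L)],
    populations = totals,
    partition = state$partition,
    pathogen = params$name
  ), class = "epidemic_run")
}

#' @export
print.epidemic_run <- function(x, ...) {
  cat(sprintf(
    "<epidemic_run> %s: %d groups, %d days; attack rate %.1f%%\n",
    x$pathogen, length(x$populations), max(x$times),
    100 * sum(x$cumulative_infections) / sum(x$populations)))
  invisible(x)
}

#' Deaths per model group from cumulative infections
#'
#' `deaths_j = ifr_j * cumulative_infections_j`. Deaths are post-processing:
#' the trajectories are identical across IFR choices.
#'
#' @param run an [run_seir()] result.
#' @param ifr_values per-group IFR values (numeric vector, or a [blend()]
#'   style table with a `value` column).
#' @return numeric vector of per-group deaths.
#' @export
compute_deaths <- function(run, ifr_values) {
  if (is.data.frame(ifr_values)) ifr_values <- ifr_values$value
  ifr_values <- as.numeric(ifr_values)
  if (length(ifr_values) != length(run$cumulative_infections)) {
    stop("one IFR value is required per model group")
  }
  ifr_values * run$cumulative_infections
}

#' Expand a coarse contact matrix to a finer partition
#'
#' Given `c[I, J]` daily contacts between coarse groups, an individual in a
#' fine group inside block `I` keeps `c[I, J]` total contacts with block `J`,
#' spread over the fine groups of `J` proportionally to their populations:
#' `c_fine[i, j] = c[I, J] * pop_j / pop_J`. If prevalence is uniform within
#' blocks, the fine model then reproduces the coarse force of infection
#' exactly, which makes high- and low-resolution runs comparable.
#'
#' @param contacts coarse square contact matrix.
#' @param model coarse partition matching `contacts`.
#' @param fine fine partition (same support); every fine interval must lie
#'   within one coarse interval.
#' @param fine_populations population of each fine group.
#' @return a fine square contact matrix.
#' @export
expand_contact_matrix <- function(contacts, model, fine, fine_populations) {
  model <- make_partition(model)
  fine <- make_partition(fine)
  contacts <- as.matrix(contacts)
  stopifnot(nrow(contacts) == n_intervals(model),
            length(fine_populations) == n_intervals(fine))
  block <- interval_index(unclass(fine)[-length(fine)], model)
  block_pop <- as.vector(tapply(fine_populations, block, sum))[block]
  share <- fine_populations / block_pop
  contacts[block, block, drop = FALSE] *
    matrix(share, nrow = n_intervals(fine), ncol = n_intervals(fine),
           byrow = TRUE)
}

#' Sum a fine-resolution population table into partition groups
#'
#' @param demography table with `age` and `population` columns at 1-unit
#'   resolution (row `age = x` represents `[x, x + 1)`).
#' @param partition the grouping partition.
#' @return numeric vector of per-group populations.
#' @export
group_populations <- function(demography, partition) {
  partition <- make_partition(partition)
  idx <- interval_index(demography$age, partition)
  as.vector(tapply(demography$population, factor(idx, seq_len(n_intervals(partition))), sum))
}

#' Calibrate the flu-like IFR scale to match COVID-like total mortality
#'
#' Finds the proportionality constant for [flu_ifr()] such that total deaths
#' in a reference run (by convention: no vaccination, high-resolution) equal
#' those of the COVID-like pathogen in the same setting. Because trajectories
#' do not depend on the IFR, deaths are linear in the scale and the
#' calibration is an exact ratio; the clip at IFR = 1 is checked afterwards.
#'
#' @param mortality all-cause mortality rate function of age.
#' @param reference_flu_run [run_seir()] result for the flu-like pathogen in
#'   the reference setting.
#' @param reference_covid_run matching run for the COVID-like pathogen.
#' @param ages representative age (lower bound) of each group in the
#'   reference runs.
#' @return the positive scalar scale.
#' @export
calibrate_flu_scale <- function(mortality, reference_flu_run,
                                reference_covid_run, ages) {
  covid_deaths <- sum(covid_ifr(ages) * reference_covid_run$cumulative_infections)
  unit_deaths <- sum(mortality(ages) * reference_flu_run$cumulative_infections)
  if (unit_deaths <= 0) stop("mortality curve yields no deaths to scale")
  scale <- covid_deaths / unit_deaths
  if (any(scale * mortality(ages) > 1)) {
    warning("calibrated flu-like IFR clips at 1 for some ages")
  }
  scale
}
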