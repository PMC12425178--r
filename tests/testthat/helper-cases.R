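# Shared generators and oracles for property-style tests.

random_partition <- function(lo = 0, hi = 100, n_groups = sample(2:5, 1)) {
  inner <- sort(stats::runif(n_groups - 1, lo, hi))
  make_partition(c(lo, inner, hi))
}

random_parameter_table <- function(lo = 0, hi = 100) {
  x <- seq(lo, hi, length.out = sample(5:9, 1))
  data.frame(feature = x, value = 0.2 + stats::runif(length(x)))
}

random_density_table <- function(lo = 0, hi = 100) {
  x <- seq(lo, hi, length.out = sample(4:8, 1))
  data.frame(feature = x, population = 0.5 + stats::runif(length(x), 0, 5))
}

# Brute-force midpoint Riemann sum for the blended (density-weighted mean)
# parameter per model group; independent of the quadrature implementation.
riemann_blend <- function(par_fn, dens_fn, model, step = 1e-3) {
  model <- make_partition(model)
  vapply(seq_len(length(model) - 1L), function(j) {
    a <- model[j]; b <- model[j + 1L]
    n <- ceiling((b - a) / step)
    h <- (b - a) / n
    mids <- a + (seq_len(n) - 0.5) * h
    sum(par_fn(mids) * dens_fn(mids)) / sum(dens_fn(mids))
  }, numeric(1))
}

# Reference inputs for the demonstration pipeline, built once per test run.
demo_inputs <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    model <- make_partition(c(0, 5, 20, 65, 101))
    out <- list(model = model)
    for (shape in c("rectangular", "young")) {
      d <- make_demography(shape, total_population = 5e7)
      out[[shape]] <- list(
        demography = d,
        life_table = make_life_table(shape),
        contacts = make_contact_matrix(model,
          populations = group_populations(d, model))
      )
    }
    out$mortality <- stats::approxfun(out$rectangular$life_table$age,
                                      out$rectangular$life_table$mx, rule = 2)
    cache <<- out
    cache
  }
})

# Calibrated flu-like pathogen: the IFR scale is set so total deaths in the
# no-vaccination, HIC-like, high-resolution run match the COVID-like run.
calibrated_flu <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    inp <- demo_inputs()
    fine <- make_partition(seq(0, 101))
    popf <- group_populations(inp$rectangular$demography, fine)
    cmf <- expand_contact_matrix(inp$rectangular$contacts, inp$model, fine, popf)
    ref_run <- function(p) {
      run_seir(seed_epidemic(initial_state(popf, partition = fine)), p, cmf)
    }
    ages <- unclass(fine)[-length(fine)]
    s <- calibrate_flu_scale(inp$mortality, ref_run(flu_params(inp$mortality, 1)),
                             ref_run(covid_params()), ages)
    cache <<- flu_params(inp$mortality, s)
    cache
  }
})
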