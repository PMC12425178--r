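uniform_fn <- function(x) rep(1, length(x))

test_that("blend computes density-weighted group means", {
  mx <- build_mixing_table(function(x) rep(0.3, length(x)), uniform_fn,
                           c(0, 5, 20, 65, 101), c(0, 5, 20, 65, 101))
  expect_equal(blend(mx)$value, rep(0.3, 4), tolerance = 1e-9)

  mx2 <- build_mixing_table(function(x) x, uniform_fn, c(0, 10), c(0, 10))
  expect_equal(blend(mx2)$value, 5, tolerance = 1e-8)

  # triangular density: E[x * x] / E[x] = (1000/3) / 50 = 20/3
  mx3 <- build_mixing_table(function(x) x, function(x) x, c(0, 10), c(0, 10))
  expect_equal(blend(mx3)$value, 20 / 3, tolerance = 1e-8)
})

test_that("blended values stay within the parameter range per group", {
  set.seed(11)
  for (i in 1:20) {
    par_tb <- random_parameter_table()
    model <- random_partition(n_groups = 4)
    mx <- build_mixing_table(par_tb, random_density_table(), model, model)
    bl <- blend(mx)
    f <- interpolate_parameter(par_tb)
    for (j in seq_len(nrow(bl))) {
      xs <- seq(bl$group_lo[j], bl$group_hi[j], length.out = 500)
      expect_gte(bl$value[j], min(f(xs)) - 1e-7)
      expect_lte(bl$value[j], max(f(xs)) + 1e-7)
    }
  }
})

test_that("redistribution weights are row-stochastic Bayes shares", {
  # identical partitions: identity matrix
  p <- c(0, 5, 20, 65, 101)
  mx <- build_mixing_table(covid_ifr, uniform_fn, p, p)
  expect_equal(redistribution_weights(mx), diag(4), tolerance = 1e-12)

  # parameter x, uniform density: weights 1.25 vs 3.75 give shares 0.25/0.75
  mx2 <- build_mixing_table(function(x) x, uniform_fn, c(0, 10), c(0, 5, 10))
  expect_equal(redistribution_weights(mx2), matrix(c(0.25, 0.75), 1),
               tolerance = 1e-8)

  # crossing partitions: an output group straddling two model groups draws
  # from both
  mx3 <- build_mixing_table(function(x) 1 + x, uniform_fn,
                            c(0, 10, 20), c(0, 5, 15, 20))
  om <- redistribution_weights(mx3)
  expect_true(all(om[, 2] > 0))
  expect_equal(rowSums(om), c(1, 1), tolerance = 1e-9)
  expect_equal(om[1, 3], 0) # no overlap between [0,10) and [15,20)
})

test_that("zero-weight model groups fall back to population shares", {
  mx <- build_mixing_table(function(x) as.numeric(x >= 10), uniform_fn,
                           c(0, 10, 20), c(0, 5, 10, 15, 20))
  expect_warning(om <- redistribution_weights(mx), "zero total weight")
  expect_equal(om[1, 1:2], c(0.5, 0.5), tolerance = 1e-8)
  expect_equal(rowSums(om), c(1, 1), tolerance = 1e-9)
})

test_that("distill redistributes outcomes and conserves their total", {
  mx <- build_mixing_table(function(x) x, uniform_fn, c(0, 10), c(0, 5, 10))
  expect_equal(distill(mx, 0)$value, c(0, 0))
  expect_equal(distill(mx, 100)$value, c(25, 75), tolerance = 1e-8)

  mxu <- build_mixing_table(uniform_fn, uniform_fn, c(0, 10), c(0, 5, 10))
  expect_equal(distill(mxu, 100)$value, c(50, 50), tolerance = 1e-9)

  expect_error(distill(mx, c(1, 2)), "expected 1")
  expect_error(distill(mx, -1), "non-negative")
})

test_that("midpoint aggregation evaluates at interval midpoints", {
  got <- aggregate_midpoint(function(x) x, c(0, 5, 20, 65, 101))
  expect_equal(got$value, c(2.5, 12.5, 42.5, 83))
  # open-ended 65+ group closed at 101: midpoint age 83
  cov <- aggregate_midpoint(covid_ifr, c(0, 5, 20, 65, 101))
  expect_equal(cov$value[4], covid_ifr(83))
  const <- aggregate_midpoint(function(x) rep(2, length(x)), c(0, 5, 10))
  expect_equal(const$value, c(2, 2))
})

test_that("mean-age aggregation evaluates at the density-weighted mean", {
  expect_equal(aggregate_mean_age(function(x) x, uniform_fn, c(0, 10))$value,
               5, tolerance = 1e-8)
  expect_equal(aggregate_mean_age(function(x) x, function(x) x,
                                  c(0, 10))$value, 20 / 3, tolerance = 1e-8)
  # for an affine parameter, mean-age equals blend for any density
  set.seed(3)
  for (i in 1:5) {
    dens <- random_density_table()
    model <- random_partition(n_groups = 3)
    aff <- function(x) 2 + 0.5 * x
    mx <- build_mixing_table(aff, dens, model, model)
    expect_equal(aggregate_mean_age(aff, dens, model)$value,
                 blend(mx)$value, tolerance = 1e-6)
  }
})

test_that("uniform distribution spreads mass by interval length", {
  expect_equal(distribute_uniform(100, c(0, 10), c(0, 5, 10))$value, c(50, 50))
  expect_equal(distribute_uniform(100, c(0, 10), c(0, 2, 10))$value, c(20, 80))
  expect_equal(distribute_uniform(0, c(0, 10), c(0, 2, 10))$value, c(0, 0))
})

test_that("mean-age distribution puts all mass in the containing interval", {
  # mean exactly on a boundary goes to the upper interval (half-open rule)
  got <- distribute_mean_age(100, uniform_fn, c(0, 10), c(0, 5, 10))
  expect_equal(got$value, c(0, 100))
  # density concentrated near zero pulls the mean into the lower interval
  got2 <- distribute_mean_age(100, function(x) exp(-2 * x), c(0, 10),
                              c(0, 5, 10))
  expect_equal(got2$value, c(100, 0))
  # groups land independently
  got3 <- distribute_mean_age(c(60, 40), uniform_fn, c(0, 10, 20),
                              c(0, 5, 10, 15, 20))
  expect_equal(got3$value, c(0, 60, 0, 40))
})

test_that("density-proportional distribution uses population integrals", {
  expect_equal(distribute_density(100, uniform_fn, c(0, 10),
                                  c(0, 5, 10))$value, c(50, 50),
               tolerance = 1e-9)
  # density proportional to x: masses 12.5 vs 37.5
  expect_equal(distribute_density(100, function(x) x, c(0, 10),
                                  c(0, 5, 10))$value, c(25, 75),
               tolerance = 1e-8)
  # coincides with distill when the parameter is constant
  dens <- random_density_table
  set.seed(5)
  tb <- dens()
  model <- c(0, 30, 100); output <- c(0, 10, 50, 100)
  mx <- build_mixing_table(function(x) rep(0.7, length(x)), tb, model, output)
  expect_equal(distill(mx, c(40, 60))$value,
               distribute_density(c(40, 60), tb, model, output)$value,
               tolerance = 1e-10)
})

test_that("parameter_summary compares the three aggregation approaches", {
  model <- c(0, 5, 20, 65, 101)
  sm <- parameter_summary(function(x) rep(0.1, length(x)), uniform_fn, model)
  expect_equal(nrow(sm), 4 * 3)
  expect_equal(sm$value, rep(0.1, 12), tolerance = 1e-9)

  # strictly convex parameter with uniform density: blend >= mean-age
  # (Jensen's inequality)
  sm2 <- parameter_summary(function(x) (x / 100)^2, uniform_fn, model)
  wide <- split(sm2$value, sm2$approach)
  expect_true(all(wide$blend >= wide$mean_age - 1e-10))
})

test_that("distill_summary conserves totals under every approach", {
  deaths <- c(5, 50, 400, 900)
  model <- c(0, 5, 20, 65, 101)
  output <- seq(0, 101)
  sm <- distill_summary(deaths, covid_ifr, uniform_fn, model, output)
  expect_equal(nrow(sm), 101 * 4)
  totals <- tapply(sm$value, sm$approach, sum)
  expect_equal(as.numeric(totals), rep(sum(deaths), 4), tolerance = 1e-10)

  # a parameter increasing in age shifts distill mass to older groups than
  # density-proportional: its cumulative distribution is everywhere lower
  cum_distill <- cumsum(sm$value[sm$approach == "distill"])
  cum_density <- cumsum(sm$value[sm$approach == "density"])
  expect_true(all(cum_distill <= cum_density + 1e-8))
})

test_that("distilling onto the union partition and re-summing is lossless", {
  set.seed(13)
  for (i in 1:5) {
    model <- random_partition(n_groups = 3)
    output <- random_partition(n_groups = 4)
    mx <- build_mixing_table(random_parameter_table(), random_density_table(),
                             model, union_partition(model, output))
    x <- stats::runif(3, 0, 100)
    y <- distill(mx, x)
    back <- tapply(y$value, interval_index(y$group_lo, model), sum)
    expect_equal(as.numeric(back), x, tolerance = 1e-9)
  }
})
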