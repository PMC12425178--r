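#' Synthetic population age structure
#'
#' Parametric single-year-of-age pyramids: `"rectangular"` (near-flat counts
#' with a logistic taper at old age, like many high-income countries) or
#' `"young"` (exponentially decreasing counts with age, like many low- and
#' middle-income countries). Row `age = x` represents the interval
#' `[x, x + 1)`; counts are rescaled to the requested total. Deterministic
#' given its arguments; an optional multiplicative log-normal jitter
#' (governed by `seed`) roughens the pyramid while preserving the total.
#'
#' @param shape `"rectangular"` or `"young"`.
#' @param max_age upper support bound; ages run `0 .. max_age - 1`.
#' @param total_population total count to which the pyramid is scaled.
#' @param seed integer seed for the jitter (ignored when `jitter_sd = 0`).
#' @param jitter_sd standard deviation of the log-normal jitter (default 0:
#'   fully deterministic).
#' @return a `data.table` with columns `age`, `population`.
#' @export
make_demography <- function(shape = c("rectangular", "young"),
                            max_age = 101, total_population = 1e6,
                            seed = 1L, jitter_sd = 0) {
  shape <- match.arg(shape)
  stopifnot(max_age >= 2, total_population > 0, jitter_sd >= 0)
  age <- seq_len(max_age) - 1
  w <- switch(shape,
    rectangular = 1 / (1 + exp((age - 0.7 * max_age) / 7)),
    young = exp(-0.04 * age)
  )
  if (jitter_sd > 0) {
    w <- w * exp(local_rnorm(seed, length(w), sd = jitter_sd))
  }
  data.table::data.table(age = age,
                         population = total_population * w / sum(w))
}

# Draw n normal deviates under a local RNG state, leaving the global state
# untouched so fixture generation never perturbs user simulations.
local_rnorm <- function(seed, n, sd) {
  state <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(state)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", state, envir = globalenv())
    }
  })
  set.seed(seed)
  stats::rnorm(n, sd = sd)
}

#' Synthetic life table with remaining life expectancy and mortality
#'
#' Builds an all-cause mortality curve `m(x)` as the sum of a decaying infant
#' component and a Gompertz old-age component -- hence U-shaped in age -- and
#' derives remaining life expectancy `e(x)` from the implied survival curve
#' by numerical integration. The `"rectangular"` (HIC-like) shape has lower
#' mortality and a higher life expectancy at birth than the `"young"`
#' (LMIC-like) shape.
#'
#' @param shape `"rectangular"` or `"young"`.
#' @param max_age last tabulated age (rows at `0 .. max_age`).
#' @return a `data.table` with columns `age`, `ex` (remaining life
#'   expectancy, years) and `mx` (all-cause mortality rate, per year).
#' @export
make_life_table <- function(shape = c("rectangular", "young"), max_age = 100) {
  shape <- match.arg(shape)
  pars <- switch(shape,
    rectangular = list(infant = 0.003, infant_decay = 2.0,
                       gomp_a = 2.5e-5, gomp_b = 0.095),
    young = list(infant = 0.04, infant_decay = 1.5,
                 gomp_a = 2e-4, gomp_b = 0.075)
  )
  mx_fun <- function(x) {
    pars$infant * exp(-x / pars$infant_decay) +
      pars$gomp_a * exp(pars$gomp_b * x)
  }
  # survival and e(x) on a fine grid extended past max_age so the tail of
  # the e(x) integral is captured
  h <- 0.25
  grid <- seq(0, max_age + 30, by = h)
  m <- mx_fun(grid)
  cumhaz <- c(0, cumsum((m[-length(m)] + m[-1L]) / 2 * h))
  surv <- exp(-cumhaz)
  # trapezoid tail integral of survival from each grid point
  seg <- (surv[-length(surv)] + surv[-1L]) / 2 * h
  tail_int <- rev(cumsum(rev(c(seg, 0))))
  ex_grid <- tail_int / surv
  ages <- 0:max_age
  ex <- stats::approx(grid, ex_grid, xout = ages)$y
  data.table::data.table(age = ages, ex = ex, mx = mx_fun(ages))
}

#' Synthetic age-assortative contact matrix
#'
#' A convex combination of proportional mixing (`c[i, j]` proportional to the
#' population share of group `j`; rank one) and fully assortative mixing
#' (diagonal). Each individual makes `total_contacts` contacts per day in
#' either limit. Satisfies contact reciprocity
#' (`pop_i * c[i, j] = pop_j * c[j, i]`) and is deterministic.
#'
#' @param model partition defining the groups.
#' @param assortativity mixing parameter in `[0, 1]`: 0 gives proportional
#'   mixing, 1 a diagonal matrix.
#' @param total_contacts daily contacts per individual.
#' @param populations per-group population sizes; defaults to interval
#'   lengths (uniform population).
#' @return a square matrix of daily contact rates.
#' @export
make_contact_matrix <- function(model, assortativity = 0.4,
                                total_contacts = 8, populations = NULL) {
  model <- make_partition(model)
  n <- n_intervals(model)
  if (assortativity < 0 || assortativity > 1) {
    stop("assortativity must be in [0, 1]")
  }
  if (is.null(populations)) populations <- interval_lengths(model)
  stopifnot(length(populations) == n, all(populations > 0))
  shares <- populations / sum(populations)
  proportional <- matrix(shares, nrow = n, ncol = n, byrow = TRUE)
  assortativity * total_contacts * diag(n) +
    (1 - assortativity) * total_contacts * proportional
}

#' Read a delimited table against a column schema
#'
#' Tolerant reader for the package's CSV interfaces: required columns are
#' checked by name and coerced to numeric; extra columns are preserved
#' untouched.
#'
#' @param path file path of a delimited text file with a header row.
#' @param columns character vector of required column names.
#' @return a `data.table`.
#' @export
load_table <- function(path, columns) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- data.table::fread(path)
  if (nrow(tab) == 0L) stop("empty table: ", path)
  missing_cols <- setdiff(columns, names(tab))
  if (length(missing_cols) > 0L) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  for (col in columns) {
    v <- suppressWarnings(as.numeric(tab[[col]]))
    if (anyNA(v)) stop("non-numeric values in column: ", col)
    data.table::set(tab, j = col, value = v)
  }
  tab
}

#' Write a table as CSV
#'
#' @param table a data.frame-like object.
#' @param path destination path.
#' @return the path, invisibly.
#' @export
write_table <- function(table, path) {
  data.table::fwrite(data.table::as.data.table(table), path)
  invisible(path)
}
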