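#' Construct a partition of a continuous feature axis
#'
#' A partition is a strictly increasing vector of interval boundaries
#' `b_1 < b_2 < ... < b_n` defining the half-open intervals `[b_i, b_{i+1})`;
#' the terminal interval is closed at its upper end so the boundaries tile
#' `[b_1, b_n]` exactly. Input boundaries are sorted and deduplicated.
#'
#' @param boundaries numeric vector of at least two distinct, finite feature
#'   values (e.g. ages in years).
#' @return a numeric vector of class `"partition"`.
#' @examples
#' make_partition(c(0, 5, 20, 65, 101))
#' make_partition(c(5, 0, 5, 20)) # sorted and deduplicated to 0, 5, 20
#' @export
make_partition <- function(boundaries) {
  b <- as.numeric(boundaries)
  if (length(b) == 0L || anyNA(b) || any(!is.finite(b))) {
    stop("partition boundaries must be finite numeric values")
  }
  b <- sort(unique(b))
  if (length(b) < 2L) {
    stop("a partition requires at least 2 distinct boundaries")
  }
  structure(b, class = "partition")
}

#' @export
print.partition <- function(x, ...) {
  cat(sprintf("<partition> %d intervals on [%g, %g]\n",
              length(x) - 1L, x[1L], x[length(x)]))
  invisible(x)
}

n_intervals <- function(partition) length(partition) - 1L

#' Union of a model and an output partition
#'
#' The mixing partition is the sorted union of the model and output
#' boundaries. Both partitions must span the same overall support; a
#' mismatch is an error rather than a silent clip, because clipping would
#' hide population mass.
#'
#' @param model,output partitions (or boundary vectors) sharing the same
#'   first and last boundary.
#' @return a `"partition"` containing every boundary of both inputs.
#' @examples
#' union_partition(c(0, 10, 20), c(0, 7, 20))
#' @export
union_partition <- function(model, output) {
  model <- make_partition(model)
  output <- make_partition(output)
  if (model[1L] != output[1L] ||
      model[length(model)] != output[length(output)]) {
    stop(sprintf(
      "model support [%g, %g] and output support [%g, %g] differ",
      model[1L], model[length(model)], output[1L], output[length(output)]
    ))
  }
  make_partition(c(unclass(model), unclass(output)))
}

#' Locate feature values within a partition
#'
#' Returns, for each value, the index of the interval `[b_i, b_{i+1})`
#' containing it; the terminal interval is closed so the upper support bound
#' belongs to the last interval. Values outside the support are an error.
#'
#' @param x numeric feature values.
#' @param partition a partition or boundary vector.
#' @return integer interval indices in `1..(length(partition) - 1)`.
#' @export
interval_index <- function(x, partition) {
  partition <- make_partition(partition)
  n <- length(partition)
  if (any(x < partition[1L] | x > partition[n])) {
    stop("feature values outside the partition support")
  }
  idx <- findInterval(x, partition, rightmost.closed = TRUE)
  as.integer(idx)
}

interval_midpoints <- function(partition) {
  partition <- make_partition(partition)
  (partition[-length(partition)] + partition[-1L]) / 2
}

interval_lengths <- function(partition) {
  partition <- make_partition(partition)
  diff(unclass(partition))
}
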