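#' Equidistant discretization specification
#'
#' Splits the range [x_min, x_max] of a continuous variable into \code{r}
#' intervals of equal width d = (x_max - x_min)/r.  A value x is assigned the
#' level index j (0 <= j <= r - 1) with x_min + j*d < x <= x_min + (j+1)*d;
#' the minimum x = x_min is assigned level 0.  Intervals are open below and
#' closed above so the map is total and single-valued on the range.
#'
#' @param x_min,x_max range of the variable (in its own units).
#' @param r number of intervals (>= 2).
#' @export
discretization_spec <- function(x_min, x_max, r) {
  if (!(x_max > x_min)) stop("x_max must exceed x_min")
  if (r < 2 || r != floor(r)) stop("r must be an integer >= 2")
  structure(list(x_min = x_min, x_max = x_max, r = as.integer(r),
                 d = (x_max - x_min) / r),
            class = "discretization_spec")
}

#' Discretize values by the equidistant method
#'
#' @param values numeric vector; every value must lie in
#'   [\code{spec$x_min}, \code{spec$x_max}].
#' @param spec a [discretization_spec()].
#' @return integer vector of level indices in 0 .. r-1.
#' @examples
#' sp <- discretization_spec(0, 10, 4)
#' equidistant_discretize(c(0, 2.5, 2.5 + 1e-9, 10), sp)  # 0 0 1 3
#' @export
equidistant_discretize <- function(values, spec) {
  stopifnot(inherits(spec, "discretization_spec"))
  out <- range_check(values, spec)
  j <- ceiling((values - spec$x_min) / spec$d) - 1L
  j[values == spec$x_min] <- 0L
  # guard against floating-point ties at interval edges
  pmin(pmax(as.integer(j), 0L), spec$r - 1L)
}

range_check <- function(values, spec) {
  bad <- which(values < spec$x_min | values > spec$x_max | is.na(values))
  if (length(bad))
    stop(sprintf("value %g outside discretization range [%g, %g]",
                 values[bad[1]], spec$x_min, spec$x_max))
  invisible(values)
}

#' Discretize the continuous columns of a cohort
#'
#' Applies [equidistant_discretize()] to each named column, returning a
#' cohort in which every variable is a factor (levels "1" .. "r"), ready for
#' the discrete Bayesian-network learner.
#'
#' @param cohort data.frame.
#' @param specs named list of [discretization_spec()] (names = columns).
#' @return the cohort with the listed columns replaced by factors.
#' @export
discretize_cohort <- function(cohort, specs) {
  for (v in names(specs)) {
    if (!v %in% names(cohort)) stop("column '", v, "' not in cohort")
    j <- equidistant_discretize(cohort[[v]], specs[[v]])
    cohort[[v]] <- factor(j + 1L, levels = seq_len(specs[[v]]$r))
  }
  cohort
}
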