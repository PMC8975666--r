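#' Conditional association statistic between two discrete variables
#'
#' Likelihood-ratio (G-squared) measure of the dependence of X and T given a
#' conditioning set Z, computed from the joint cell counts:
#' 2 * sum over cells (a, b, c) of N_abc * ln(N_abc * N_c / (N_ac * N_bc)),
#' with empty cells contributing 0.  Degrees of freedom are
#' (|X|-1)(|T|-1) * prod |Z_i|; the p-value is the chi-square upper tail.
#' Empty conditioning strata contribute 0 and do not reduce the degrees of
#' freedom.
#'
#' A test with fewer than 5 samples per degree of freedom is flagged
#' unreliable (\code{reliable = FALSE}); callers that honour the reliability
#' rule treat such a test as non-significant.  The statistic itself is always
#' computed exactly.
#'
#' @param data data.frame of factors (unused factor levels count toward the
#'   degrees of freedom).
#' @param x,t column names of the two variables (disjoint).
#' @param z character vector of conditioning column names (possibly empty).
#' @return object of class \code{"assoc"}: list with \code{statistic},
#'   \code{df}, \code{p}, \code{reliable}, \code{x}, \code{t}, \code{z}.
#' @examples
#' d <- data.frame(a = factor(rep(0:1, 50)), b = factor(rep(0:1, 50)))
#' assoc(d, "a", "b")$statistic     # 2 * 100 * log(2)
#' @export
assoc <- function(data, x, t, z = character(0)) {
  if (nrow(data) == 0L) stop("empty data")
  vars <- c(x, t, z)
  if (anyDuplicated(vars)) stop("x, t and z must be pairwise disjoint")
  cd <- lapply(data[vars], function(col)
    if (is.factor(col)) col else factor(col))
  sizes <- vapply(cd, nlevels, 1L)
  if (any(sizes < 1L)) stop("variables must have at least one level")
  codes <- vapply(cd, as.integer, integer(nrow(data)))
  if (!is.matrix(codes)) codes <- matrix(codes, nrow = 1L)
  sx <- sizes[1L]; st <- sizes[2L]
  nz <- if (length(z)) prod(sizes[-(1:2)]) else 1L
  cz <- rep(1L, nrow(data))
  if (length(z)) {
    for (i in seq_along(z)) cz <- (cz - 1L) * sizes[2L + i] + codes[, 2L + i]
  }
  code <- ((cz - 1L) * st + (codes[, 2L] - 1L)) * sx + codes[, 1L]
  cnt <- array(tabulate(code, nbins = sx * st * nz), dim = c(sx, st, nz))
  n_c <- apply(cnt, 3L, sum)
  n_ac <- apply(cnt, c(1L, 3L), sum)
  n_bc <- apply(cnt, c(2L, 3L), sum)
  stat <- 0
  for (k in seq_len(nz)) {
    m <- cnt[, , k]
    pos <- which(m > 0)
    if (!length(pos)) next
    a <- ((pos - 1L) %% sx) + 1L
    b <- ((pos - 1L) %/% sx) + 1L
    stat <- stat + sum(m[pos] * log(m[pos] * n_c[k] / (n_ac[a, k] * n_bc[b, k])))
  }
  stat <- 2 * stat
  df <- unname((sx - 1L) * (st - 1L) * nz)
  structure(list(
    statistic = stat, df = df,
    p = if (df > 0) stats::pchisq(stat, df, lower.tail = FALSE) else 1,
    reliable = df > 0 && nrow(data) / df >= 5,
    x = x, t = t, z = z
  ), class = "assoc")
}

#' @export
print.assoc <- function(x, ...) {
  cat(sprintf("Assoc(%s, %s | %s) = %.4f  df = %d  p = %.4g%s\n",
              x$x, x$t,
              if (length(x$z)) paste(x$z, collapse = ", ") else "{}",
              x$statistic, x$df, x$p,
              if (x$reliable) "" else "  [unreliable: n/df < 5]"))
  invisible(x)
}

# All subsets of `z` up to size maxk, smallest first, lexicographic within
# a size (the documented tie-break order).
subsets_upto <- function(z, maxk) {
  z <- sort(z)
  out <- list(character(0))
  for (k in seq_len(min(maxk, length(z)))) {
    cmb <- utils::combn(z, k, simplify = FALSE)
    out <- c(out, cmb)
  }
  out
}

#' Minimum conditional association over conditioning subsets
#'
#' Evaluates [assoc()] for every subset S of Z up to size \code{maxk} and
#' returns the weakest dependence: the subset with the largest p-value, ties
#' broken by smallest subset then lexicographic order.  When
#' \code{reliability = TRUE}, tests flagged unreliable are treated as
#' non-significant (effective p = 1).
#'
#' @inheritParams assoc
#' @param maxk cap on the conditioning-subset size (default: |Z|).
#' @param reliability honour the samples-per-df reliability rule.
#' @return list with \code{assoc} (the minimizing [assoc()] result),
#'   \code{subset}, and \code{p} (the effective p-value used for the
#'   minimization).
#' @export
min_assoc <- function(data, x, t, z = character(0), maxk = length(z),
                      reliability = TRUE) {
  best <- NULL
  for (s in subsets_upto(z, maxk)) {
    a <- assoc(data, x, t, s)
    eff_p <- if (reliability && !a$reliable) 1 else a$p
    if (is.null(best) || eff_p > best$p + 1e-15) {
      best <- list(assoc = a, subset = s, p = eff_p)
    }
  }
  best
}
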