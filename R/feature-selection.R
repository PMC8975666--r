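#' Chi-square screen of candidate prognostic variables
#'
#' Pearson chi-square test of each candidate against the binary outcome on
#' the variable x outcome contingency table; a variable is kept when
#' p < alpha.  Continuous candidates are pre-binned with the supplied
#' equidistant spec (default: r = 4 over the observed range) before testing.
#'
#' @param cohort data.frame of candidates plus the outcome column.
#' @param outcome name of the binary outcome column.
#' @param alpha significance level (default 0.05).
#' @param candidates variable names to screen (default: all other columns).
#' @param specs named list of [discretization_spec()] for continuous
#'   candidates; missing entries fall back to r = 4 over the observed range.
#' @param correct apply the Yates continuity correction on 2x2 tables
#'   (default FALSE; see the methods vignette).
#' @return data.frame with columns \code{variable}, \code{statistic},
#'   \code{df}, \code{p}, \code{kept}.  Variables with a degenerate
#'   (zero-margin) table are skipped with a warning and appear with
#'   \code{NA} statistics and \code{kept = FALSE}.
#' @export
chi_square_screen <- function(cohort, outcome, alpha = 0.05,
                              candidates = setdiff(names(cohort), outcome),
                              specs = list(), correct = FALSE) {
  y <- droplevels(factor(cohort[[outcome]]))
  if (nlevels(y) != 2L) stop("outcome must be binary")
  res <- lapply(candidates, function(v) {
    x <- cohort[[v]]
    if (is.numeric(x)) {
      sp <- specs[[v]] %||% discretization_spec(min(x), max(x) + 1e-9, 4)
      x <- factor(equidistant_discretize(x, sp))
    }
    x <- droplevels(factor(x))
    tab <- table(x, y)
    if (nlevels(x) < 2L || any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
      warning("variable '", v, "' skipped: degenerate contingency table",
              call. = FALSE)
      return(data.frame(variable = v, statistic = NA_real_, df = NA_integer_,
                        p = NA_real_, kept = FALSE))
    }
    ct <- suppressWarnings(
      stats::chisq.test(tab, correct = correct && all(dim(tab) == 2L)))
    data.frame(variable = v, statistic = unname(ct$statistic),
               df = unname(ct$parameter), p = unname(ct$p.value),
               kept = unname(ct$p.value) < alpha)
  })
  do.call(rbind, res)
}

#' Logistic-regression filter of screened variables
#'
#' Maximum-likelihood logistic fit of the binary outcome on the candidate
#' variables (IRLS, convergence when the deviance change is below 1e-8, at
#' most 100 iterations).  A variable is retained when any of its terms has
#' Wald p < alpha.  Reported per term: coefficient B, its standard error,
#' p-value, exp(B) and the Wald 95% interval exp(B +/- 1.96 SE).
#'
#' @param cohort data.frame; rows with missing values in the model columns
#'   are dropped (the count is reported in the result).
#' @param candidates character vector of predictor names.
#' @param outcome name of the binary outcome column.
#' @param alpha retention threshold on the Wald p-value (default 0.05).
#' @return object of class \code{"logistic_filter"}: a list with
#'   \code{table} (one row per non-intercept term), \code{retained}
#'   (variable names), \code{converged}, \code{n_used}, \code{n_dropped}.
#' @export
logistic_filter <- function(cohort, candidates, outcome, alpha = 0.05) {
  dat <- cohort[, c(candidates, outcome)]
  cc <- stats::complete.cases(dat)
  n_dropped <- sum(!cc)
  dat <- dat[cc, , drop = FALSE]
  dat[[outcome]] <- droplevels(factor(dat[[outcome]]))
  if (nlevels(dat[[outcome]]) != 2L) stop("outcome must be binary")
  fml <- stats::reformulate(candidates, response = outcome)
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    stats::glm(fml, family = stats::binomial(), data = dat,
               control = stats::glm.control(epsilon = 1e-8, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep_warn <<- TRUE
      invokeRestart("muffleWarning")
    })
  co <- summary(fit)$coefficients
  if (sep_warn || any(abs(co[, "Estimate"]) > 15)) {
    worst <- rownames(co)[which.max(abs(co[, "Estimate"]))]
    bad <- candidates[vapply(candidates, function(v) startsWith(worst, v), TRUE)]
    stop("perfect (or quasi-perfect) separation involving variable '",
         if (length(bad)) bad[1] else worst, "'", call. = FALSE)
  }
  co <- co[rownames(co) != "(Intercept)", , drop = FALSE]
  tab <- data.frame(
    term = rownames(co),
    variable = vapply(rownames(co), function(tr) {
      hit <- candidates[vapply(candidates, function(v) startsWith(tr, v), TRUE)]
      if (length(hit)) hit[which.max(nchar(hit))] else tr
    }, ""),
    B = co[, "Estimate"], se = co[, "Std. Error"],
    p = co[, "Pr(>|z|)"],
    exp_b = exp(co[, "Estimate"]),
    ci_lo = exp(co[, "Estimate"] - 1.96 * co[, "Std. Error"]),
    ci_hi = exp(co[, "Estimate"] + 1.96 * co[, "Std. Error"]),
    row.names = NULL)
  structure(list(
    table = tab,
    retained = unique(tab$variable[tab$p < alpha]),
    converged = fit$converged,
    n_used = nrow(dat), n_dropped = n_dropped, fit = fit
  ), class = "logistic_filter")
}

#' @export
print.logistic_filter <- function(x, digits = 3, ...) {
  cat(sprintf("Logistic filter: %d rows used (%d dropped), %s\n",
              x$n_used, x$n_dropped,
              if (x$converged) "converged" else "NOT converged"))
  tab <- x$table
  tab$B <- round(tab$B, digits); tab$se <- round(tab$se, digits)
  tab$p <- signif(tab$p, digits)
  tab$exp_b <- round(tab$exp_b, digits)
  tab$ci_lo <- round(tab$ci_lo, digits); tab$ci_hi <- round(tab$ci_hi, digits)
  print(tab, row.names = FALSE)
  cat("Retained (p <", formatC(0.05), "):",
      paste(x$retained, collapse = ", "), "\n")
  invisible(x)
}
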