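#' Fit conditional probability tables for a given structure
#'
#' Maximum a-posteriori CPT rows with a Dirichlet pseudocount:
#' each row entry is (count + pseudocount) / (row total + pseudocount *
#' levels).  Pseudocount 0 gives the maximum-likelihood estimate (empty
#' parent configurations then yield a uniform row).
#'
#' @param graph a [bn] object (structure) or named parent list.
#' @param data data.frame of factors covering every node.
#' @param pseudocount Dirichlet smoothing count per cell (default 1).
#' @return a [bn] with fitted CPTs; the fitting-sample size is attached as
#'   attribute \code{"n"}.
#' @export
fit_parameters <- function(graph, data, pseudocount = 1) {
  if (inherits(graph, "bn")) {
    parents <- graph$parents
    nodes <- graph$nodes
  } else {
    nodes <- sort(unique(c(names(graph), unlist(graph))))
    parents <- stats::setNames(lapply(nodes, function(v)
      as.character(graph[[v]] %||% character(0))), nodes)
  }
  miss <- setdiff(nodes, names(data))
  if (length(miss))
    stop("node(s) absent from data: ", paste(miss, collapse = ", "))
  data <- as.data.frame(lapply(data[nodes], function(col)
    if (is.factor(col)) col else factor(col)))
  levels <- lapply(data, levels)
  cpts <- lapply(stats::setNames(nodes, nodes), function(v) {
    pa <- parents[[v]]
    r <- length(levels[[v]])
    sizes <- vapply(pa, function(p) length(levels[[p]]), 1L)
    q <- prod(sizes)
    ci <- rep(1L, nrow(data))
    for (i in seq_along(pa))
      ci <- (ci - 1L) * sizes[i] + as.integer(data[[pa[i]]])
    cnt <- matrix(tabulate((ci - 1L) * r + as.integer(data[[v]]),
                           nbins = q * r), nrow = q, byrow = TRUE)
    m <- (cnt + pseudocount) / (rowSums(cnt) + pseudocount * r)
    if (pseudocount == 0) {
      zero <- rowSums(cnt) == 0
      m[zero, ] <- 1 / r                       # undefined rows -> uniform
    }
    dimnames(m) <- list(NULL, levels[[v]])
    m
  })
  out <- bn(levels, parents, cpts,
            outcome = if (inherits(graph, "bn")) graph$outcome else NULL)
  attr(out, "n") <- nrow(data)
  out
}

#' Learn a prognosis Bayesian network by max-min hill-climbing
#'
#' The hybrid MMHC procedure: (1) discover the undirected skeleton with
#' per-node MMPC (conditional-independence search using the G-squared
#' association statistic, symmetry-corrected); (2) orient edges by greedy
#' hill-climbing over add/delete/reverse moves restricted to the skeleton,
#' maximizing a decomposable score (BIC by default); (3) fit CPTs with a
#' Dirichlet pseudocount.  Survival-status prediction for new patients is
#' then available through [predict.bn()] (exact inference by enumeration).
#'
#' @param data data.frame of discrete (factor) variables, one row per
#'   patient.
#' @param outcome optional name of the outcome node (recorded on the fitted
#'   object and used as the default prediction target).
#' @param alpha significance threshold of the independence tests (default
#'   0.05).
#' @param maxk maximum conditioning-set size in MMPC (default 3).
#' @param score \code{"bic"} (default) or \code{"bdeu"}.
#' @param ess equivalent sample size for BDeu.
#' @param pseudocount CPT smoothing count (default 1).
#' @param reliability honour the samples-per-df test-reliability rule.
#' @return object of class \code{c("mmhc", "bn")} with the learned graph and
#'   CPTs; components \code{cpc} (per-node MMPC results), \code{skeleton},
#'   \code{score}, \code{score_trace} and \code{call} are attached.
#' @examples
#' truth <- make_ground_truth()
#' cohort <- attr(sample_cohort(truth, 800, seed = 7), "levels")
#' fit <- mmhc(cohort, outcome = "survival_status")
#' print(fit)
#' @export
mmhc <- function(data, outcome = NULL, alpha = 0.05, maxk = 3,
                 score = "bic", ess = 10, pseudocount = 1,
                 reliability = TRUE) {
  data <- as.data.frame(lapply(data, function(col)
    if (is.factor(col)) col else factor(col)))
  skel <- mmpc_skeleton(data, alpha = alpha, maxk = maxk,
                        reliability = reliability)
  g <- hill_climb(data, skeleton = skel, score = score, ess = ess)
  fit <- fit_parameters(g, data, pseudocount = pseudocount)
  if (!is.null(outcome)) {
    if (!outcome %in% fit$nodes) stop("outcome '", outcome, "' not in data")
    fit$outcome <- outcome
  }
  fit$cpc <- attr(skel, "cpc")
  fit$skeleton <- skel
  fit$score <- attr(g, "score")
  fit$score_trace <- attr(g, "trace")
  fit$settings <- list(alpha = alpha, maxk = maxk, score = score, ess = ess,
                       pseudocount = pseudocount)
  fit$call <- match.call()
  class(fit) <- c("mmhc", "bn")
  fit
}

#' @export
print.mmhc <- function(x, ...) {
  cat("Max-min hill-climbing Bayesian network fit\n")
  if (!is.null(x$call)) { cat("Call: "); print(x$call) }
  cat(sprintf("Settings: alpha = %g, maxk = %d, score = %s\n",
              x$settings$alpha, x$settings$maxk, x$settings$score))
  cat(sprintf("Network score: %.2f (after %d accepted moves)\n",
              x$score, length(x$score_trace) - 1L))
  NextMethod()
}

#' Residual diagnostics for a fitted network
#'
#' Per-row deviance residuals of the outcome node: sign(observed != modal
#' prediction) * sqrt(-2 log P(observed outcome | other variables)).
#'
#' @param object a fitted \code{mmhc}/[bn] with an outcome node.
#' @param data data.frame of observed rows.
#' @param ... unused.
#' @return numeric vector of deviance residuals.
#' @export
residuals.mmhc <- function(object, data, ...) {
  if (is.null(object$outcome)) stop("object has no outcome node")
  post <- predict(object, data, type = "posterior")
  obs <- as.character(data[[object$outcome]])
  p_obs <- post[cbind(seq_len(nrow(post)), match(obs, colnames(post)))]
  modal <- colnames(post)[max.col(post, ties.method = "first")]
  sgn <- ifelse(obs == modal, 1, -1)
  sgn * sqrt(pmax(0, -2 * log(pmax(p_obs, 1e-300))))
}
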