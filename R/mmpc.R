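#' Max-min parents-and-children discovery for one target
#'
#' Two-phase MMPC.  Forward: repeatedly admit into the CPC the variable with
#' the largest minimum association with the target given the current CPC
#' (MinAssoc over conditioning subsets up to \code{maxk}), provided its
#' minimizing p-value is below \code{alpha}; stop when every remaining
#' variable is conditionally independent of the target.  Backward: remove
#' any member X for which some subset S of CPC\\{X} renders the association
#' non-significant.  With \code{symmetry = TRUE} the correction is applied:
#' X is dropped from CPC(T) when T is not in CPC(X).
#'
#' @param data data.frame of factors.
#' @param target target variable name.
#' @param alpha significance threshold (default 0.05).
#' @param maxk maximum conditioning-subset size (default 3).
#' @param candidates variables to consider (default: all other columns).
#' @param symmetry apply the symmetry correction (default TRUE).
#' @param reliability honour the samples-per-df rule (default TRUE).
#' @return object of class \code{"cpc"}: list with \code{target},
#'   \code{cpc} (sorted names) and \code{trace} of admissions/removals.
#' @export
mmpc <- function(data, target, alpha = 0.05, maxk = 3,
                 candidates = setdiff(names(data), target),
                 symmetry = TRUE, reliability = TRUE) {
  if (!target %in% names(data)) stop("target '", target, "' not in data")
  candidates <- setdiff(candidates, target)
  cpc <- character(0)
  trace <- character(0)
  # forward phase
  repeat {
    remaining <- setdiff(candidates, cpc)
    if (!length(remaining)) break
    ma <- lapply(remaining, function(v)
      min_assoc(data, v, target, cpc, maxk = maxk, reliability = reliability))
    dep <- vapply(ma, function(m) m$p < alpha, TRUE)
    if (!any(dep)) break
    stat <- vapply(ma, function(m) m$assoc$statistic, 0)
    stat[!dep] <- -Inf
    ord <- order(-stat, remaining)          # lexicographic tie-break
    pick <- remaining[ord[1L]]
    cpc <- c(cpc, pick)
    trace <- c(trace, paste0("+", pick))
  }
  # backward phase
  for (x in cpc) {
    ma <- min_assoc(data, x, target, setdiff(cpc, x), maxk = maxk,
                    reliability = reliability)
    if (ma$p >= alpha) {
      cpc <- setdiff(cpc, x)
      trace <- c(trace, paste0("-", x))
    }
  }
  # symmetry correction
  if (symmetry) {
    for (x in cpc) {
      back <- mmpc(data, x, alpha = alpha, maxk = maxk,
                   candidates = c(setdiff(candidates, x), target),
                   symmetry = FALSE, reliability = reliability)
      if (!target %in% back$cpc) {
        cpc <- setdiff(cpc, x)
        trace <- c(trace, paste0("-", x, " (symmetry)"))
      }
    }
  }
  structure(list(target = target, cpc = sort(cpc), trace = trace),
            class = "cpc")
}

#' @export
print.cpc <- function(x, ...) {
  cat(sprintf("CPC(%s) = {%s}\n", x$target, paste(x$cpc, collapse = ", ")))
  invisible(x)
}

#' Undirected skeleton from per-node MMPC runs
#'
#' Runs [mmpc()] for every variable and joins the results with the symmetry
#' (AND) rule: the pair \{X, Y\} is a skeleton edge when X is in CPC(Y) and
#' Y is in CPC(X).
#'
#' @inheritParams mmpc
#' @return symmetric 0/1 adjacency matrix over the columns of \code{data},
#'   with the per-target [mmpc()] results attached as attribute
#'   \code{"cpc"}.
#' @export
mmpc_skeleton <- function(data, alpha = 0.05, maxk = 3, reliability = TRUE) {
  nodes <- names(data)
  cpcs <- lapply(stats::setNames(nodes, nodes), function(v)
    mmpc(data, v, alpha = alpha, maxk = maxk, symmetry = FALSE,
         reliability = reliability))
  a <- matrix(0L, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  for (v in nodes) for (w in cpcs[[v]]$cpc) {
    if (v %in% cpcs[[w]]$cpc) { a[v, w] <- 1L; a[w, v] <- 1L }
  }
  attr(a, "cpc") <- cpcs
  a
}
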