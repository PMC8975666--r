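#' Exact posterior of a node given evidence
#'
#' Computes P(node | evidence) by summing the Markov factorization
#' prod_i P(X_i | Pa(X_i)) over every configuration of the unobserved
#' variables, then normalizing.  Intended for small networks (enumeration is
#' exponential in the number of unobserved nodes).
#'
#' @param net a [bn] with CPTs.
#' @param evidence named list or character vector assigning level labels to
#'   a subset of nodes (must not include the queried node).
#' @param node queried node (default: the network's outcome node).
#' @return named probability vector over the node's levels with attributes
#'   \code{class_level} (arg-max level, ties resolved to the
#'   lexicographically first level) and \code{tie} (logical flag).
#' @examples
#' net <- make_ground_truth()
#' predict_outcome(net, c(tumor_stage = "IV", histological_grade = "G3"))
#' @export
predict_outcome <- function(net, evidence = NULL, node = net$outcome) {
  if (is.null(node)) stop("no query node given and network has no outcome")
  if (is.null(net$cpts)) stop("network has no CPTs")
  ev <- as.list(evidence %||% list())
  if (node %in% names(ev)) stop("evidence must not include the queried node")
  bad <- setdiff(names(ev), net$nodes)
  if (length(bad)) stop("evidence for unknown node(s): ",
                        paste(bad, collapse = ", "))
  ev_idx <- integer(0)
  for (v in names(ev)) {
    i <- match(as.character(ev[[v]]), net$levels[[v]])
    if (is.na(i))
      stop(sprintf("evidence value '%s' is not a level of node '%s'",
                   as.character(ev[[v]]), v))
    ev_idx[v] <- i
  }
  free <- setdiff(net$nodes, c(names(ev), node))
  sizes <- vapply(free, function(v) length(net$levels[[v]]), 1L)
  grid_free <- config_grid(sizes)
  k <- length(net$levels[[node]])
  # one joint-probability evaluation per (free configuration, node level)
  nfree <- nrow(grid_free)
  full <- matrix(0L, nfree * k, length(net$nodes),
                 dimnames = list(NULL, net$nodes))
  for (v in names(ev)) full[, v] <- ev_idx[[v]]
  if (length(free))
    full[, free] <- grid_free[rep(seq_len(nfree), times = k), , drop = FALSE]
  full[, node] <- rep(seq_len(k), each = nfree)
  p <- joint_probability(net, full)
  post <- vapply(seq_len(k), function(l)
    sum(p[full[, node] == l]), 0)
  tot <- sum(post)
  if (tot <= 0) stop("evidence has probability zero under the network")
  post <- stats::setNames(post / tot, net$levels[[node]])
  best <- which(post >= max(post) - 1e-12)
  structure(post,
            class_level = net$levels[[node]][min(best)],
            tie = length(best) > 1L)
}

#' Predict survival status (or any node) for new patients
#'
#' Applies [predict_outcome()] row by row: each row's values on the network
#' nodes (other than the queried node) are taken as evidence; columns absent
#' from the network, and \code{NA} entries, are ignored.
#'
#' @param object a fitted [bn] / \code{mmhc} object.
#' @param newdata data.frame of evidence rows.
#' @param node queried node (default: the outcome node).
#' @param type \code{"posterior"} for a rows x levels probability matrix,
#'   \code{"class"} for the arg-max level as a factor.
#' @param ... unused.
#' @export
predict.bn <- function(object, newdata, node = object$outcome,
                       type = c("posterior", "class"), ...) {
  type <- match.arg(type)
  use <- intersect(setdiff(object$nodes, node), names(newdata))
  post <- t(vapply(seq_len(nrow(newdata)), function(i) {
    row <- lapply(newdata[i, use, drop = FALSE], as.character)
    row <- row[!vapply(row, is.na, TRUE)]
    as.numeric(predict_outcome(object, row, node = node))
  }, numeric(length(object$levels[[node]]))))
  colnames(post) <- object$levels[[node]]
  if (type == "posterior") return(post)
  factor(colnames(post)[max.col(post, ties.method = "first")],
         levels = object$levels[[node]])
}
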