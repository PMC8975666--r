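# Decomposable network scores and the greedy hill-climbing search.

# Per-node score of `v` with parent set `parents` on factor data.
# BIC: log-likelihood - 0.5 log(n) * (r-1) * q  (q = parent configurations).
# BDeu: Dirichlet-multinomial marginal likelihood, equivalent sample size ess.
node_score <- function(data, v, parents, score = "bic", ess = 10) {
  n <- nrow(data)
  r <- nlevels(data[[v]])
  sizes <- vapply(parents, function(p) nlevels(data[[p]]), 1L)
  q <- prod(sizes)
  vi <- as.integer(data[[v]])
  ci <- rep(1L, n)
  for (i in seq_along(parents))
    ci <- (ci - 1L) * sizes[i] + as.integer(data[[parents[i]]])
  cnt <- matrix(tabulate((ci - 1L) * r + vi, nbins = q * r), nrow = r)
  rowtot <- colSums(cnt)
  if (score == "bic") {
    pos <- cnt > 0
    ll <- sum(cnt[pos] * log(cnt[pos] /
                               rep(rowtot, each = r)[as.vector(pos)]))
    ll - 0.5 * log(n) * (r - 1) * q
  } else if (score == "bdeu") {
    aq <- ess / q; aqr <- ess / (q * r)
    sum(lgamma(aq) - lgamma(aq + rowtot)) +
      sum(lgamma(aqr + cnt) - lgamma(aqr))
  } else stop("unknown score '", score, "'")
}

# TRUE if a directed path `from` -> ... -> `to` exists in the parents list.
has_path <- function(parents, from, to) {
  seen <- from
  frontier <- from
  children <- function(v) names(parents)[vapply(parents, function(p)
    v %in% p, TRUE)]
  while (length(frontier)) {
    nxt <- unique(unlist(lapply(frontier, children)))
    if (to %in% nxt) return(TRUE)
    frontier <- setdiff(nxt, seen)
    seen <- c(seen, frontier)
  }
  FALSE
}

#' Greedy hill-climbing DAG search over a skeleton
#'
#' Searches add/delete/reverse single-edge moves, with additions restricted
#' to skeleton pairs and cycles forbidden, accepting the best strictly
#' score-improving move until none improves.  The score is decomposable and
#' cached per (node, parent set).
#'
#' @param data data.frame of factors.
#' @param skeleton symmetric 0/1 adjacency matrix of allowed edges (e.g.
#'   from [mmpc_skeleton()]); \code{NULL} allows every pair.
#' @param score \code{"bic"} (default) or \code{"bdeu"}.
#' @param ess equivalent sample size for BDeu (default 10).
#' @param max_iter safety cap on accepted moves.
#' @return a structure-only [bn] (no CPTs) whose levels are taken from the
#'   data, with attributes \code{score} (final total score) and
#'   \code{trace} (the strictly increasing score after each accepted move).
#' @export
hill_climb <- function(data, skeleton = NULL, score = "bic", ess = 10,
                       max_iter = 1000L) {
  nodes <- names(data)
  data <- as.data.frame(lapply(data, function(col)
    if (is.factor(col)) col else factor(col)))
  if (is.null(skeleton)) {
    skeleton <- matrix(1L, length(nodes), length(nodes),
                       dimnames = list(nodes, nodes))
    diag(skeleton) <- 0L
  }
  skeleton <- skeleton[nodes, nodes]
  parents <- stats::setNames(rep(list(character(0)), length(nodes)), nodes)
  cache <- new.env(parent = emptyenv())
  sc <- function(v, pa) {
    key <- paste(v, paste(sort(pa), collapse = ","), sep = "|")
    got <- cache[[key]]
    if (is.null(got)) {
      got <- node_score(data, v, sort(pa), score = score, ess = ess)
      cache[[key]] <- got
    }
    got
  }
  nsc <- vapply(nodes, function(v) sc(v, character(0)), 0)
  total <- sum(nsc)
  trace <- total
  for (iter in seq_len(max_iter)) {
    best <- list(delta = 1e-10)
    for (i in nodes) for (j in nodes) {
      if (i == j) next
      if (i %in% parents[[j]]) {
        # delete i -> j
        d <- sc(j, setdiff(parents[[j]], i)) - nsc[[j]]
        if (d > best$delta) best <- list(delta = d, op = "delete", i = i, j = j)
        # reverse i -> j  (becomes j -> i)
        if (!has_path_excluding(parents, i, j)) {
          d <- (sc(j, setdiff(parents[[j]], i)) - nsc[[j]]) +
            (sc(i, c(parents[[i]], j)) - nsc[[i]])
          if (d > best$delta)
            best <- list(delta = d, op = "reverse", i = i, j = j)
        }
      } else if (skeleton[i, j] == 1L && !j %in% parents[[i]]) {
        # add i -> j
        if (!has_path(parents, j, i)) {
          d <- sc(j, c(parents[[j]], i)) - nsc[[j]]
          if (d > best$delta) best <- list(delta = d, op = "add", i = i, j = j)
        }
      }
    }
    if (is.null(best$op)) break
    i <- best$i; j <- best$j
    if (best$op == "add") {
      parents[[j]] <- c(parents[[j]], i)
    } else if (best$op == "delete") {
      parents[[j]] <- setdiff(parents[[j]], i)
    } else {
      parents[[j]] <- setdiff(parents[[j]], i)
      parents[[i]] <- c(parents[[i]], j)
      nsc[[i]] <- sc(i, parents[[i]])
    }
    nsc[[j]] <- sc(j, parents[[j]])
    total <- total + best$delta
    trace <- c(trace, total)
  }
  out <- bn(lapply(data, levels), parents)
  attr(out, "score") <- total
  attr(out, "trace") <- trace
  out
}

# Cycle check for reversing i -> j: after removing that edge, a path
# i ~> j through other nodes would make j -> i cyclic.
has_path_excluding <- function(parents, i, j) {
  parents[[j]] <- setdiff(parents[[j]], i)
  has_path(parents, i, j)
}
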