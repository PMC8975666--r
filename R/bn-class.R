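#' Discrete Bayesian network objects
#'
#' A \code{bn} object is the two-tuple (G, Theta): a directed acyclic graph
#' over discrete variables together with one conditional probability table
#' (CPT) per node.  The same class carries a hand-specified ground-truth
#' network (see [make_ground_truth()]) and a network learned from data (see
#' [mmhc()] and [fit_parameters()]).
#'
#' CPTs are stored as matrices with one row per parent configuration (the
#' last listed parent varies fastest) and one column per level of the node.
#' Every row is a probability distribution over the node's levels.
#'
#' @param levels named list; one character vector of level labels per node.
#' @param parents named list; for each node, the character vector of its
#'   parent node names (may be empty).  Nodes absent from the list have no
#'   parents.
#' @param cpts named list of CPT matrices, one per node; \code{NULL} rows are
#'   not allowed.  Row order follows the parent order in \code{parents}, last
#'   parent varying fastest.
#' @param outcome optional name of the outcome (sink) node; if given it must
#'   have no children.
#'
#' @return An object of class \code{"bn"} with elements \code{nodes},
#'   \code{levels}, \code{parents}, \code{cpts}, \code{outcome}.
#' @examples
#' net <- bn(
#'   levels  = list(a = c("0", "1"), b = c("0", "1")),
#'   parents = list(a = character(0), b = "a"),
#'   cpts    = list(a = matrix(c(0.4, 0.6), 1),
#'                  b = rbind(c(0.9, 0.1), c(0.2, 0.8)))
#' )
#' print(net)
#' @export
bn <- function(levels, parents = list(), cpts = NULL, outcome = NULL) {
  if (!is.list(levels) || is.null(names(levels)) || any(names(levels) == ""))
    stop("'levels' must be a named list of level-label vectors")
  nodes <- names(levels)
  levels <- lapply(levels, as.character)
  pa <- stats::setNames(vector("list", length(nodes)), nodes)
  for (v in nodes) pa[[v]] <- as.character(parents[[v]] %||% character(0))
  bad <- setdiff(unlist(pa), nodes)
  if (length(bad))
    stop("unknown parent node(s): ", paste(bad, collapse = ", "))
  ord <- topo_sort(nodes, pa)
  if (is.null(ord))
    stop("cycle in edges: the parent sets do not define an acyclic graph")
  obj <- structure(
    list(nodes = nodes, levels = levels, parents = pa, cpts = NULL,
         outcome = outcome),
    class = "bn"
  )
  if (!is.null(cpts)) {
    obj$cpts <- lapply(stats::setNames(nodes, nodes), function(v) {
      m <- cpts[[v]]
      if (is.null(m)) stop("missing CPT for node '", v, "'")
      m <- as.matrix(m)
      nr <- prod(vapply(pa[[v]], function(p) length(levels[[p]]), 1L))
      if (nrow(m) != nr || ncol(m) != length(levels[[v]]))
        stop(sprintf("CPT for '%s' must be %d x %d", v, nr,
                     length(levels[[v]])))
      if (any(m < 0) || any(abs(rowSums(m) - 1) > 1e-9))
        stop("CPT rows for '", v, "' must be distributions summing to 1")
      dimnames(m) <- list(NULL, levels[[v]])
      m
    })
  }
  if (!is.null(outcome)) {
    if (!outcome %in% nodes) stop("outcome node '", outcome, "' not in nodes")
    kids <- nodes[vapply(nodes, function(v) outcome %in% pa[[v]], TRUE)]
    if (length(kids))
      stop("outcome node '", outcome, "' must be a sink but has children: ",
           paste(kids, collapse = ", "))
  }
  obj
}

# Kahn topological sort; NULL if the graph has a cycle.
topo_sort <- function(nodes, parents) {
  indeg <- vapply(nodes, function(v) length(parents[[v]]), 1L)
  out <- character(0)
  avail <- nodes[indeg == 0L]
  indeg <- stats::setNames(indeg, nodes)
  while (length(avail)) {
    v <- sort(avail)[1L]           # lexicographic tie-break for determinism
    avail <- setdiff(avail, v)
    out <- c(out, v)
    for (w in nodes) {
      if (v %in% parents[[w]]) {
        indeg[w] <- indeg[w] - 1L
        if (indeg[w] == 0L) avail <- c(avail, w)
      }
    }
  }
  if (length(out) != length(nodes)) NULL else out
}

#' @export
print.bn <- function(x, ...) {
  ne <- sum(lengths(x$parents))
  cat(sprintf("Discrete Bayesian network: %d nodes, %d edges%s\n",
              length(x$nodes), ne,
              if (is.null(x$cpts)) " (structure only)" else ""))
  for (v in x$nodes) {
    p <- x$parents[[v]]
    cat(sprintf("  %s [%d levels]%s\n", v, length(x$levels[[v]]),
                if (length(p)) paste0(" <- ", paste(p, collapse = ", ")) else ""))
  }
  if (!is.null(x$outcome)) cat("Outcome node:", x$outcome, "\n")
  invisible(x)
}

#' @export
summary.bn <- function(object, ...) {
  npar <- sum(vapply(object$nodes, function(v) {
    if (is.null(object$cpts)) return(0)
    nrow(object$cpts[[v]]) * (length(object$levels[[v]]) - 1L)
  }, 1))
  structure(
    list(nodes = length(object$nodes),
         edges = sum(lengths(object$parents)),
         free_parameters = npar,
         outcome = object$outcome,
         max_in_degree = max(lengths(object$parents))),
    class = "summary.bn"
  )
}

#' @export
print.summary.bn <- function(x, ...) {
  cat("Bayesian network summary\n")
  cat("  nodes:          ", x$nodes, "\n")
  cat("  edges:          ", x$edges, "\n")
  cat("  max in-degree:  ", x$max_in_degree, "\n")
  cat("  free parameters:", x$free_parameters, "\n")
  if (!is.null(x$outcome)) cat("  outcome node:   ", x$outcome, "\n")
  invisible(x)
}

#' Plot a network's directed graph
#'
#' Circular-layout base-graphics rendering; directed edges are drawn as
#' arrows from parent to child.
#'
#' @param x a \code{bn} object.
#' @param ... passed to [graphics::plot.default()].
#' @export
plot.bn <- function(x, ...) {
  n <- length(x$nodes)
  th <- seq(0, 2 * pi, length.out = n + 1L)[seq_len(n)]
  px <- cos(th); py <- sin(th)
  graphics::plot(px, py, xlim = c(-1.4, 1.4), ylim = c(-1.4, 1.4),
                 axes = FALSE, xlab = "", ylab = "", type = "n", asp = 1, ...)
  for (v in seq_along(x$nodes)) {
    for (p in x$parents[[x$nodes[v]]]) {
      i <- match(p, x$nodes)
      dx <- px[v] - px[i]; dy <- py[v] - py[i]
      len <- sqrt(dx^2 + dy^2)
      sh <- 0.12 / len
      graphics::arrows(px[i] + dx * sh, py[i] + dy * sh,
                       px[v] - dx * sh, py[v] - dy * sh,
                       length = 0.08, col = "grey40")
    }
  }
  graphics::text(px * 1.18, py * 1.18, x$nodes, cex = 0.8)
  invisible(x)
}

# Adjacency matrix with amat[i, j] = 1 for edge i -> j.
bn_amat <- function(net) {
  nodes <- net$nodes
  a <- matrix(0L, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  for (v in nodes) for (p in net$parents[[v]]) a[p, v] <- 1L
  a
}

edges_of <- function(parents) {
  out <- NULL
  for (v in names(parents)) for (p in parents[[v]])
    out <- rbind(out, c(p, v))
  out
}

#' Structural Hamming distance between two graphs
#'
#' The number of single-edge edits (insert, delete, reverse an edge; for
#' partially directed graphs also orient/unorient) needed to turn one graph
#' into the other.  Each node pair contributes at most 1.
#'
#' @param g1,g2 \code{bn} objects, named parent lists, or adjacency matrices
#'   over the same node set (an undirected edge in a pattern has both
#'   \code{a[i,j]} and \code{a[j,i]} set).
#' @return non-negative integer count.
#' @examples
#' structural_hamming_distance(list(b = "a"), list(a = "b"))  # 1: reversal
#' @export
structural_hamming_distance <- function(g1, g2) {
  a1 <- as_amat(g1); a2 <- as_amat(g2)
  if (!setequal(rownames(a1), rownames(a2)))
    stop("graphs are over different node sets")
  a2 <- a2[rownames(a1), rownames(a1)]
  nodes <- rownames(a1)
  d <- 0L
  for (i in seq_along(nodes)) for (j in seq_along(nodes)) {
    if (j <= i) next
    s1 <- c(a1[i, j], a1[j, i]); s2 <- c(a2[i, j], a2[j, i])
    if (!identical(s1, s2)) d <- d + 1L
  }
  d
}

as_amat <- function(g) {
  if (inherits(g, "bn")) return(bn_amat(g))
  if (is.matrix(g)) {
    if (is.null(rownames(g))) {
      nm <- paste0("V", seq_len(nrow(g)))
      dimnames(g) <- list(nm, nm)
    }
    storage.mode(g) <- "integer"
    return(g)
  }
  if (is.list(g)) {
    nodes <- sort(unique(c(names(g), unlist(g))))
    a <- matrix(0L, length(nodes), length(nodes),
                dimnames = list(nodes, nodes))
    for (v in names(g)) for (p in g[[v]]) a[p, v] <- 1L
    return(a)
  }
  stop("cannot interpret graph argument")
}

#' Completed partially directed graph (pattern) of a DAG
#'
#' Returns the CPDAG representing the Markov-equivalence class: skeleton plus
#' compelled edge orientations (v-structures propagated by the standard
#' orientation rules).  Undirected edges have both adjacency entries set.
#'
#' @param net a \code{bn} object or a named parent list.
#' @return integer adjacency matrix; \code{a[i,j]=1, a[j,i]=0} for a
#'   compelled edge i->j, both 1 for an undirected (reversible) edge.
#' @export
cpdag <- function(net) {
  a <- as_amat(net)
  nodes <- rownames(a)
  n <- length(nodes)
  skel <- (a + t(a)) > 0
  # start with everything undirected, then compel v-structures
  p <- matrix(0L, n, n, dimnames = dimnames(a))
  p[skel] <- 1L
  for (y in seq_len(n)) {
    pa <- which(a[, y] == 1L)
    if (length(pa) < 2L) next
    for (ii in seq_along(pa)) for (jj in seq_along(pa)) {
      if (jj <= ii) next
      x <- pa[ii]; z <- pa[jj]
      if (!skel[x, z]) {          # unshielded collider x -> y <- z
        p[y, x] <- 0L; p[x, y] <- 1L
        p[y, z] <- 0L; p[z, y] <- 1L
      }
    }
  }
  # Meek rules until fixed point
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j || !(p[i, j] == 1L && p[j, i] == 1L)) next   # i - j undirected
      # R1: k -> i, k not adjacent j  =>  i -> j
      for (k in seq_len(n)) {
        if (p[k, i] == 1L && p[i, k] == 0L && !skel[k, j]) {
          p[j, i] <- 0L; changed <- TRUE; break
        }
      }
      if (p[j, i] == 0L) next
      # R2: directed path i -> k -> j  =>  i -> j
      for (k in seq_len(n)) {
        if (p[i, k] == 1L && p[k, i] == 0L &&
            p[k, j] == 1L && p[j, k] == 0L) {
          p[j, i] <- 0L; changed <- TRUE; break
        }
      }
      if (p[j, i] == 0L) next
      # R3: i - k -> j and i - l -> j with k, l non-adjacent  =>  i -> j
      ks <- which(p[i, ] == 1L & p[, i] == 1L & p[, j] == 1L & p[j, ] == 0L)
      if (length(ks) >= 2L) {
        for (ii2 in seq_along(ks)) for (jj2 in seq_along(ks)) {
          if (jj2 <= ii2) next
          if (!skel[ks[ii2], ks[jj2]]) {
            p[j, i] <- 0L; changed <- TRUE
          }
        }
      }
    }
    if (!changed) break
  }
  p
}
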