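# Independent oracles and small fixtures shared across the suite.
# Each oracle recomputes the target quantity by a route separate from the
# package implementation (direct cell sums, full-joint enumeration,
# exhaustive search), so agreement is evidence and not tautology.

# Brute-force G2: loop over every joint cell of the realized table.
g2_oracle <- function(data, x, t, z = character(0)) {
  xs <- factor(data[[x]]); ts <- factor(data[[t]])
  zkey <- if (length(z)) interaction(data[z], drop = FALSE) else
    factor(rep("all", nrow(data)))
  stat <- 0
  for (zl in levels(zkey)) {
    sel <- zkey == zl
    nc <- sum(sel)
    if (nc == 0) next
    for (a in levels(xs)) for (b in levels(ts)) {
      nabc <- sum(sel & xs == a & ts == b)
      if (nabc == 0) next
      nac <- sum(sel & xs == a)
      nbc <- sum(sel & ts == b)
      stat <- stat + nabc * log(nabc * nc / (nac * nbc))
    }
  }
  2 * stat
}

# Exhaustive MinAssoc: literal double loop over all subsets.
min_assoc_oracle <- function(data, x, t, z, maxk = length(z)) {
  best_p <- -Inf; best_s <- NULL
  all_s <- list(character(0))
  for (k in seq_len(min(maxk, length(z))))
    all_s <- c(all_s, utils::combn(sort(z), k, simplify = FALSE))
  for (s in all_s) {
    a <- assoc(data, x, t, s)
    p <- if (!a$reliable) 1 else a$p
    if (p > best_p + 1e-15) { best_p <- p; best_s <- s }
  }
  list(p = best_p, subset = best_s)
}

# Full-joint posterior by building the complete joint table from scratch
# (explicit loop over every configuration, no shared code path).
posterior_oracle <- function(net, evidence, node) {
  sizes <- vapply(net$nodes, function(v) length(net$levels[[v]]), 1L)
  grid <- expand.grid(lapply(sizes, seq_len), KEEP.OUT.ATTRS = FALSE)
  names(grid) <- net$nodes
  probs <- apply(grid, 1L, function(row) {
    p <- 1
    for (v in net$nodes) {
      pa <- net$parents[[v]]
      cpt <- net$cpts[[v]]
      if (length(pa) == 0L) {
        p <- p * cpt[1L, row[[v]]]
      } else {
        # recompute the row index by naive positional arithmetic
        ridx <- 1L
        for (q in pa)
          ridx <- (ridx - 1L) * length(net$levels[[q]]) + row[[q]]
        p <- p * cpt[ridx, row[[v]]]
      }
    }
    p
  })
  keep <- rep(TRUE, nrow(grid))
  for (v in names(evidence)) {
    li <- match(evidence[[v]], net$levels[[v]])
    keep <- keep & grid[[v]] == li
  }
  post <- vapply(seq_len(sizes[[node]]), function(l)
    sum(probs[keep & grid[[node]] == l]), 0)
  post / sum(post)
}

# Random small network with random CPTs (for inference and SHD tests).
random_small_bn <- function(n_nodes, seed, max_levels = 3L, edge_p = 0.4) {
  set.seed(seed)
  nodes <- paste0("v", seq_len(n_nodes))
  levels <- lapply(stats::setNames(nodes, nodes), function(v)
    as.character(seq_len(sample(2:max_levels, 1))))
  parents <- stats::setNames(rep(list(character(0)), n_nodes), nodes)
  for (j in seq_len(n_nodes)) for (i in seq_len(n_nodes)) {
    if (i < j && stats::runif(1) < edge_p)
      parents[[nodes[j]]] <- c(parents[[nodes[j]]], nodes[i])
  }
  cpts <- lapply(stats::setNames(nodes, nodes), function(v) {
    q <- prod(vapply(parents[[v]], function(p) length(levels[[p]]), 1L))
    k <- length(levels[[v]])
    m <- matrix(stats::rgamma(q * k, 1) + 0.05, q, k)
    m / rowSums(m)
  })
  bn(levels, parents, cpts)
}

# Exhaustive edit-distance oracle: breadth-first search over graphs,
# applying single-edge insertions, deletions and reversals until the target
# is reached.  Only feasible for a handful of nodes.
shd_oracle <- function(a1, a2) {
  key <- function(a) paste(a, collapse = "")
  target <- key(a2)
  frontier <- list(a1)
  seen <- new.env(parent = emptyenv())
  assign(key(a1), TRUE, envir = seen)
  if (key(a1) == target) return(0L)
  n <- nrow(a1)
  for (depth in 1:4) {
    nxt <- list()
    for (g in frontier) {
      for (i in seq_len(n)) for (j in seq_len(n)) {
        if (i == j) next
        cands <- list()
        if (g[i, j] == 1L) {
          del <- g; del[i, j] <- 0L; cands <- c(cands, list(del))
          rev <- g; rev[i, j] <- 0L; rev[j, i] <- 1L
          cands <- c(cands, list(rev))
        } else if (g[j, i] == 0L) {
          add <- g; add[i, j] <- 1L; cands <- c(cands, list(add))
        }
        for (cnd in cands) {
          k <- key(cnd)
          if (k == target) return(depth)
          if (is.null(seen[[k]])) {
            assign(k, TRUE, envir = seen)
            nxt <- c(nxt, list(cnd))
          }
        }
      }
    }
    frontier <- nxt
    if (!length(frontier)) break
  }
  stop("shd oracle: graphs farther apart than the search budget")
}

dice_coef <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# Two well-separated Gaussian blobs in feature space (separable fixture).
two_blob_fixture <- function(n_per = 120, seed = 4) {
  set.seed(seed)
  x <- rbind(cbind(stats::rnorm(n_per, 0.25, 0.06),
                   stats::rnorm(n_per, 0.25, 0.06)),
             cbind(stats::rnorm(n_per, 0.75, 0.06),
                   stats::rnorm(n_per, 0.75, 0.06)))
  list(x = x, y = rep(c(0L, 1L), each = n_per))
}
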