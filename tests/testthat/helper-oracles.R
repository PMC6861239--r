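# Independent oracles used to cross-check the package's numerics.
# Everything here is deliberately written from first principles (no calls
# into the package's own algorithms): exhaustive path enumeration for Wang
# S-values, binomial-coefficient sums for hypergeometric/Fisher tails, and
# plain-R BFS for graph distances.

# --- Wang S-values by exhaustive path enumeration ---------------------------
# dag_edges: data.frame(child, parent, relation); weights: named vector.
# S(anchor -> t) = max over all directed child->parent paths of the product
# of edge weights; S(anchor) = 1.
oracle_svalues <- function(dag_edges, anchor, weights = c(is_a = 0.8,
                                                          part_of = 0.6)) {
  s <- new.env(parent = emptyenv())
  assign(anchor, 1, envir = s)
  walk <- function(node, prod) {
    up <- dag_edges[dag_edges$child == node, , drop = FALSE]
    for (i in seq_len(nrow(up))) {
      p <- up$parent[i]
      val <- prod * weights[[up$relation[i]]]
      prev <- if (exists(p, envir = s)) get(p, envir = s) else -Inf
      if (val > prev) assign(p, val, envir = s)
      walk(p, val)   # enumerate every path, no memoization
    }
  }
  walk(anchor, 1)
  out <- sapply(ls(s), function(k) get(k, envir = s))
  out[order(names(out))]
}

oracle_term_similarity <- function(dag_edges, a, b,
                                   weights = c(is_a = 0.8, part_of = 0.6)) {
  sa <- oracle_svalues(dag_edges, a, weights)
  sb <- oracle_svalues(dag_edges, b, weights)
  common <- intersect(names(sa), names(sb))
  if (!length(common)) return(0)
  sum(sa[common] + sb[common]) / (sum(sa) + sum(sb))
}

# Best-Match Average by explicit row/column enumeration
oracle_bma <- function(m) {
  row_max <- vapply(seq_len(nrow(m)), function(i) max(m[i, ]), 1.0)
  col_max <- vapply(seq_len(ncol(m)), function(j) max(m[, j]), 1.0)
  (sum(row_max) + sum(col_max)) / (nrow(m) + ncol(m))
}

# --- exact hypergeometric / Fisher by binomial-coefficient summation --------
# P[X >= k] where X ~ Hypergeom(N, K, n): K successes in N, n drawn.
oracle_hyper_upper <- function(k, N, K, n) {
  lo <- max(0L, n - (N - K))
  hi <- min(K, n)
  probs <- vapply(lo:hi, function(i) {
    choose(K, i) * choose(N - K, n - i) / choose(N, n)
  }, 1.0)
  sum(probs[(lo:hi) >= k])
}

# two-sided Fisher p for table rbind(c(a, b), c(c, d)): sum of probabilities
# of all tables with the same margins that are no more probable than the
# observed one (with the standard relative tolerance).
oracle_fisher_two_sided <- function(a, b, c_, d) {
  m <- a + c_; n2 <- b + d; k <- a + b; N <- m + n2
  lo <- max(0L, k - n2); hi <- min(k, m)
  prob <- vapply(lo:hi, function(x) {
    choose(m, x) * choose(n2, k - x) / choose(N, k)
  }, 1.0)
  p_obs <- prob[a - lo + 1L]
  sum(prob[prob <= p_obs * (1 + 1e-7)])
}

# --- plain-R BFS ------------------------------------------------------------
# edges: 2-column character matrix/data.frame; returns named distance vector
# from `from` over all reachable nodes (Inf for unreachable).
oracle_bfs <- function(edges, nodes, from) {
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  for (i in seq_len(nrow(edges))) {
    u <- edges[i, 1]; v <- edges[i, 2]
    adj[[u]] <- c(adj[[u]], v)
    adj[[v]] <- c(adj[[v]], u)
  }
  dist <- stats::setNames(rep(Inf, length(nodes)), nodes)
  dist[from] <- 0
  queue <- from
  while (length(queue)) {
    cur <- queue[1L]; queue <- queue[-1L]
    for (nb in adj[[cur]]) {
      if (is.infinite(dist[nb])) {
        dist[nb] <- dist[cur] + 1
        queue <- c(queue, nb)
      }
    }
  }
  dist
}

oracle_closest_distance <- function(edges, nodes, t_set, s_set) {
  mins <- vapply(t_set, function(t) {
    d <- oracle_bfs(edges, nodes, t)
    min(d[s_set])
  }, 1.0)
  mean(mins)
}

# igraph -> plain edge matrix for the oracles
graph_edges <- function(g) igraph::as_edgelist(g)
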