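# Independent brute-force oracles used across the suite. These deliberately
# avoid igraph and the package's own code paths.

# All-pairs BFS distances and shortest-path counts from an adjacency list.
bfs_counts <- function(adj, s, n) {
  dist <- rep(Inf, n)
  sigma <- rep(0, n)
  dist[s] <- 0
  sigma[s] <- 1
  frontier <- s
  while (length(frontier)) {
    nxt <- integer()
    for (v in frontier) {
      for (w in adj[[v]]) {
        if (is.infinite(dist[w])) {
          dist[w] <- dist[v] + 1
          nxt <- c(nxt, w)
        }
        if (dist[w] == dist[v] + 1) {
          sigma[w] <- sigma[w] + sigma[v]
        }
      }
    }
    frontier <- unique(nxt)
  }
  list(dist = dist, sigma = sigma)
}

# Degree, betweenness (endpoints excluded, normalized by (n-1)(n-2)/2) and
# component-restricted closeness, straight from the combinatorial
# definitions.
oracle_centralities <- function(n, edges) {
  adj <- vector("list", n)
  for (i in seq_len(nrow(edges))) {
    a <- edges[i, 1]; b <- edges[i, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  bfs <- lapply(seq_len(n), function(s) bfs_counts(adj, s, n))
  D <- do.call(rbind, lapply(bfs, `[[`, "dist"))
  S <- do.call(rbind, lapply(bfs, `[[`, "sigma"))

  degree <- lengths(adj)
  closeness <- vapply(seq_len(n), function(v) {
    d <- D[v, -v]
    d <- d[is.finite(d)]
    if (!length(d)) 0 else 1 / mean(d)
  }, numeric(1))

  btw <- vapply(seq_len(n), function(v) {
    tot <- 0
    for (s in seq_len(n)) for (t in seq_len(n)) {
      if (s >= t || s == v || t == v) next
      if (!is.finite(D[s, t])) next
      if (D[s, v] + D[v, t] == D[s, t]) {
        tot <- tot + S[s, v] * S[v, t] / S[s, t]
      }
    }
    if (n > 2) tot * 2 / ((n - 1) * (n - 2)) else 0
  }, numeric(1))

  data.frame(node = seq_len(n), degree = degree, betweenness = btw,
             closeness = closeness)
}

# Oracle over exactly the nodes incident to an edge (an edge-list graph has
# no isolated nodes), labelled N<original index>.
oracle_for_edges <- function(edges) {
  present <- sort(unique(as.vector(edges)))
  remap <- match(edges, present)
  dim(remap) <- dim(edges)
  out <- oracle_centralities(length(present), remap)
  out$gene_symbol <- sprintf("N%d", present)
  out
}

# Exact hypergeometric upper tail by combinatorial enumeration.
oracle_hypergeom <- function(k, K, n, N) {
  i <- seq(k, min(K, n))
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Independent BH step-up: sort, apply m/i factor, cumulative minimum from
# the largest p down, cap at 1, restore input order.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Random simple undirected graph on n nodes as an edge matrix.
random_graph_edges <- function(n, p = 0.4) {
  pairs <- t(combn(n, 2))
  pairs[runif(nrow(pairs)) < p, , drop = FALSE]
}

# A drug-like descriptor row for screen tests.
drug_like_descriptors <- function(n = 1) {
  data.frame(MW = rep(300, n), ALOGP = rep(2.5, n), HBA = rep(3, n),
             HBD = rep(1, n), PSA = rep(60, n), ROTB = rep(3, n),
             AROM = rep(2, n), ALERT = rep(0, n))
}
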