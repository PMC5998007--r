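# Brute-force graph oracles, independent of the package implementation
# (and of igraph): hand-written BFS, combinatorial path counting and
# exhaustive shortest-path enumeration. Graphs are adjacency lists:
# list(n = <int>, adj = list of integer neighbour vectors).

oracle_graph <- function(n, edges) {
  # edges: 2-column integer matrix
  adj <- vector("list", n)
  for (i in seq_len(n)) adj[[i]] <- integer(0)
  if (length(edges) > 0) {
    for (k in seq_len(nrow(edges))) {
      a <- edges[k, 1]; b <- edges[k, 2]
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
    }
  }
  list(n = n, adj = lapply(adj, unique))
}

oracle_bfs <- function(g, s) {
  d <- rep(Inf, g$n)
  d[s] <- 0
  frontier <- s
  while (length(frontier) > 0) {
    nxt <- integer(0)
    for (u in frontier) {
      for (v in g$adj[[u]]) {
        if (!is.finite(d[v])) {
          d[v] <- d[u] + 1
          nxt <- c(nxt, v)
        }
      }
    }
    frontier <- nxt
  }
  d
}

oracle_distmat <- function(g) {
  t(vapply(seq_len(g$n), function(s) oracle_bfs(g, s), numeric(g$n)))
}

oracle_aspl <- function(g) {
  if (g$n < 2) stop("need >= 2 nodes")
  d <- oracle_distmat(g)
  v <- d[upper.tri(d)]
  v <- v[is.finite(v)]
  if (length(v) == 0) 0 else mean(v)
}

oracle_subgraph <- function(g, drop) {
  keep <- setdiff(seq_len(g$n), drop)
  remap <- match(seq_len(g$n), keep)
  adj <- lapply(keep, function(u) {
    nb <- setdiff(g$adj[[u]], drop)
    remap[nb]
  })
  list(n = length(keep), adj = adj)
}

oracle_rca_raw <- function(g) {
  base <- oracle_aspl(g)
  vapply(seq_len(g$n), function(v) oracle_aspl(oracle_subgraph(g, v)) - base,
         numeric(1))
}

# BFS also counting shortest paths (sigma) from one source
oracle_bfs_sigma <- function(g, s) {
  d <- rep(Inf, g$n); sigma <- rep(0, g$n)
  d[s] <- 0; sigma[s] <- 1
  frontier <- s
  while (length(frontier) > 0) {
    nxt <- integer(0)
    for (u in frontier) {
      for (v in g$adj[[u]]) {
        if (!is.finite(d[v])) {
          d[v] <- d[u] + 1
          nxt <- c(nxt, v)
        }
        if (d[v] == d[u] + 1) sigma[v] <- sigma[v] + sigma[u]
      }
    }
    frontier <- unique(nxt)
  }
  list(d = d, sigma = sigma)
}

# betweenness from the pair-counting identity: paths through v between
# s and t number sigma_s(v) * sigma_t(v) when d(s,v) + d(v,t) = d(s,t)
oracle_betweenness <- function(g) {
  runs <- lapply(seq_len(g$n), function(s) oracle_bfs_sigma(g, s))
  D <- t(vapply(runs, `[[`, numeric(g$n), "d"))
  S <- t(vapply(runs, `[[`, numeric(g$n), "sigma"))
  b <- rep(0, g$n)
  for (s in seq_len(g$n - 1)) {
    for (t in (s + 1):g$n) {
      if (!is.finite(D[s, t])) next
      for (v in seq_len(g$n)) {
        if (v == s || v == t) next
        if (is.finite(D[s, v]) && is.finite(D[v, t]) &&
            D[s, v] + D[v, t] == D[s, t]) {
          b[v] <- b[v] + S[s, v] * S[t, v] / S[s, t]
        }
      }
    }
  }
  b
}

# exhaustive enumeration of every shortest path (small n only)
oracle_betweenness_enum <- function(g) {
  D <- oracle_distmat(g)
  b <- rep(0, g$n)
  paths_to <- function(s, t) {
    if (s == t) return(list(s))
    out <- list()
    for (u in g$adj[[t]]) {
      if (is.finite(D[s, u]) && D[s, u] == D[s, t] - 1) {
        for (p in paths_to(s, u)) out[[length(out) + 1]] <- c(p, t)
      }
    }
    out
  }
  for (s in seq_len(g$n - 1)) {
    for (t in (s + 1):g$n) {
      if (!is.finite(D[s, t])) next
      ps <- paths_to(s, t)
      for (p in ps) {
        inner <- setdiff(p, c(s, t))
        b[inner] <- b[inner] + 1 / length(ps)
      }
    }
  }
  b
}

oracle_closeness <- function(g) {
  D <- oracle_distmat(g)
  vapply(seq_len(g$n), function(v) {
    d <- D[v, -v]
    d <- d[is.finite(d)]
    if (length(d) == 0) 0 else length(d) / sum(d)
  }, numeric(1))
}

oracle_zscores <- function(x) {
  s <- sqrt(mean((x - mean(x))^2))
  if (s < 1e-12) x * 0 else (x - mean(x)) / s
}

# seeded random connected graph on n nodes (Erdos-Renyi, redrawn until
# connected; a spanning-path fallback guarantees termination)
random_connected_graph <- function(n, p = NULL, seed = 1) {
  set.seed(seed)
  if (is.null(p)) p <- min(1, 2.5 / n + 0.05)
  for (try in 1:50) {
    pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    pick <- stats::runif(nrow(pairs)) < p
    g <- oracle_graph(n, pairs[pick, , drop = FALSE])
    if (all(is.finite(oracle_bfs(g, 1)))) return(g)
  }
  path <- cbind(seq_len(n - 1), 2:n)
  oracle_graph(n, rbind(pairs[pick, , drop = FALSE], path))
}
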