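# Brute-force graph oracles, independent of the igraph-backed implementation.

# Erdos-Renyi adjacency (uses the caller's RNG stream)
random_adjacency <- function(d, p = 0.4) {
  a <- matrix(0, d, d)
  up <- upper.tri(a)
  a[up] <- as.numeric(runif(sum(up)) < p)
  a + t(a)
}

graph_is_connected <- function(a) {
  d <- nrow(a)
  reach <- diag(d) + a
  for (i in seq_len(d)) reach <- (reach %*% (diag(d) + a)) > 0
  all(reach[1, ] > 0)
}

random_connected_adjacency <- function(d, p = 0.5) {
  repeat {
    a <- random_adjacency(d, p)
    if (sum(a) > 0 && graph_is_connected(a)) return(a)
  }
}

brute_degree <- function(a) rowSums(a)

# triangle enumeration over all node triples
brute_clustering <- function(a) {
  d <- nrow(a)
  vapply(seq_len(d), function(i) {
    nb <- which(a[i, ] == 1)
    k <- length(nb)
    if (k < 2) return(0)
    tri <- 0
    for (x in seq_len(k - 1)) for (y in (x + 1):k)
      tri <- tri + a[nb[x], nb[y]]
    2 * tri / (k * (k - 1))
  }, numeric(1))
}

# shortest-path counting via matrix powers: the number of walks of length
# equal to the s-t distance is the number of shortest s-t paths
brute_betweenness <- function(a) {
  d <- nrow(a)
  dist <- matrix(Inf, d, d); diag(dist) <- 0
  cnt <- matrix(0, d, d); diag(cnt) <- 1
  pw <- diag(d)
  for (L in seq_len(d)) {
    pw <- pw %*% a
    new <- is.infinite(dist) & pw > 0
    dist[new] <- L
    cnt[new] <- pw[new]
  }
  bc <- numeric(d)
  for (s in seq_len(d - 1)) for (t in (s + 1):d) {
    if (!is.finite(dist[s, t])) next
    for (v in seq_len(d)[-c(s, t)]) {
      if (is.finite(dist[s, v]) && is.finite(dist[v, t]) &&
          dist[s, v] + dist[v, t] == dist[s, t])
        bc[v] <- bc[v] + cnt[s, v] * cnt[v, t] / cnt[s, t]
    }
  }
  bc
}

# all set partitions of n elements as membership vectors (restricted
# growth strings); Bell(8) = 4140
all_partitions <- local({
  cache <- list()
  function(n) {
    key <- as.character(n)
    if (!is.null(cache[[key]])) return(cache[[key]])
    out <- list()
    grow <- function(memb) {
      k <- length(memb)
      if (k == n) { out[[length(out) + 1L]] <<- memb; return() }
      for (c in seq_len(max(memb) + 1L)) grow(c(memb, c))
    }
    grow(1L)
    res <- do.call(rbind, out)
    cache[[key]] <<- res
    res
  }
})

partition_q <- function(a, memb) {
  m <- sum(a) / 2
  k <- rowSums(a)
  b <- a - outer(k, k) / (2 * m)
  sum(b[outer(memb, memb, "==")]) / (2 * m)
}

# exhaustive maximum modularity over every partition
brute_max_modularity <- function(a) {
  parts <- all_partitions(nrow(a))
  best_q <- -Inf; best <- NULL
  for (i in seq_len(nrow(parts))) {
    q <- partition_q(a, parts[i, ])
    if (q > best_q) { best_q <- q; best <- parts[i, ] }
  }
  list(Q = best_q, membership = best)
}

adjacency_from_matrix <- function(a, atlas = NULL) {
  d <- nrow(a)
  if (is.null(atlas)) atlas <- region_atlas(paste0("n", seq_len(d)))
  cm <- connectivity_matrix(a, atlas, "s", "x")
  positive_adjacency(cm, 0)
}
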