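#' Nodal graph metrics of a binary adjacency
#'
#' Computes one of the three nodal metrics used as classification features:
#'
#' * `degree` — number of links attached to each node.
#' * `clustering` — local clustering coefficient, the fraction of a node's
#'   neighbour pairs that are themselves connected
#'   (`2 t_i / (k_i (k_i - 1))`); defined as 0 for nodes of degree < 2.
#' * `betweenness` — the number of shortest paths between other node pairs
#'   that pass through the node (unweighted, endpoints excluded, unordered
#'   pairs; unreachable pairs contribute 0).  With `normalized = TRUE` it is
#'   divided by `(d - 1)(d - 2) / 2`, the number of other pairs.
#'
#' @param adj An [positive_adjacency()] object.
#' @param metric One of `"degree"`, `"clustering"`, `"betweenness"`.
#' @param normalized Normalize betweenness to `[0, 1]`?  Default `FALSE`
#'   (raw path counts).  Ignored for the other metrics.
#' @return A named numeric vector of length d (names = region labels).
#' @examples
#' atl <- region_atlas(c("A", "B", "C", "D"))
#' star <- matrix(0, 4, 4); star[1, 2:4] <- star[2:4, 1] <- 1
#' cm <- connectivity_matrix(star, atl, "s1", "low")  # z doubles as toy matrix
#' nodal_metric(positive_adjacency(cm), "degree")
#' @export
nodal_metric <- function(adj, metric = c("degree", "clustering", "betweenness"),
                         normalized = FALSE) {
  stopifnot(inherits(adj, "adjacency"))
  metric <- match.arg(metric)
  g <- igraph::graph_from_adjacency_matrix(adj$a, mode = "undirected",
                                           diag = FALSE)
  v <- switch(metric,
    degree      = igraph::degree(g),
    clustering  = igraph::transitivity(g, type = "localundirected",
                                       isolates = "zero"),
    betweenness = {
      b <- igraph::betweenness(g, directed = FALSE, normalized = FALSE)
      if (normalized) {
        d <- adj$atlas$d
        b <- b / ((d - 1) * (d - 2) / 2)
      }
      b
    })
  v <- as.numeric(v)
  names(v) <- adj$atlas$names
  v
}

#' @rdname nodal_metric
#' @export
nodal_degree <- function(adj) nodal_metric(adj, "degree")

#' @rdname nodal_metric
#' @export
nodal_clustering <- function(adj) nodal_metric(adj, "clustering")

#' @rdname nodal_metric
#' @param ... Passed on to [nodal_metric()] (`normalized`).
#' @export
nodal_betweenness <- function(adj, ...) nodal_metric(adj, "betweenness", ...)

#' Newman modularity partition
#'
#' Community detection by Newman's leading-eigenvector spectral method on the
#' positive-edge graph, the descriptive companion of the nodal metrics.  The
#' partition quality is
#' `Q = sum_c (e_c / m - (d_c / 2m)^2)` where `e_c` is the number of edges
#' inside community c, `d_c` the total degree of its nodes and `m` the total
#' edge count.
#'
#' @param x A [connectivity_matrix()] (thresholded internally at `tau`) or an
#'   [positive_adjacency()] object.
#' @param tau Positive-edge threshold used when `x` is a connectivity matrix.
#' @return An object of class `"modularity_partition"`: list with
#'   `assignment` (integer community index per region, contiguous from 1),
#'   `Q`, `n_communities`, and the atlas.
#' @export
newman_modularity <- function(x, tau = 0) {
  adj <- if (inherits(x, "connectivity_matrix")) positive_adjacency(x, tau)
         else if (inherits(x, "adjacency")) x
         else stop("'x' must be a connectivity_matrix or adjacency")
  if (sum(adj$a) == 0)
    stop("modularity is undefined on an edgeless graph")
  g <- igraph::graph_from_adjacency_matrix(adj$a, mode = "undirected",
                                           diag = FALSE)
  cl <- igraph::cluster_leading_eigen(g)
  memb <- as.integer(igraph::membership(cl))
  memb <- match(memb, unique(memb))  # contiguous from 1
  q <- modularity_value(adj$a, memb)
  structure(list(assignment = stats::setNames(memb, adj$atlas$names),
                 Q = q, n_communities = max(memb), atlas = adj$atlas),
            class = "modularity_partition")
}

#' Modularity Q of a given partition
#'
#' @param a Binary symmetric adjacency matrix (zero diagonal).
#' @param membership Integer community index per node.
#' @return The scalar Q.
#' @export
modularity_value <- function(a, membership) {
  a <- as.matrix(a)
  m <- sum(a) / 2
  if (m == 0) stop("modularity is undefined on an edgeless graph")
  k <- rowSums(a)
  q <- 0
  for (c in unique(membership)) {
    idx <- membership == c
    e_c <- sum(a[idx, idx]) / 2
    d_c <- sum(k[idx])
    q <- q + e_c / m - (d_c / (2 * m))^2
  }
  q
}

#' @export
print.modularity_partition <- function(x, ...) {
  cat(sprintf("Newman modularity partition: %d communities, Q = %.4f\n",
              x$n_communities, x$Q))
  print(table(community = x$assignment))
  invisible(x)
}

#' Write a modularity partition as two-column text
#'
#' @param part A [newman_modularity()] result.
#' @param path Output path (TSV: region, community).
#' @export
write_partition <- function(part, path) {
  stopifnot(inherits(part, "modularity_partition"))
  utils::write.table(
    data.frame(region = names(part$assignment),
               community = as.integer(part$assignment)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
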