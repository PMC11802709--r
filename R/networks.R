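#' Weighted undirected social network
#'
#' @param weights symmetric numeric matrix with entries in [0, 1], zero
#'   diagonal, dimnames giving the node identifiers.
#' @return A `social_network` object (`nodes`, `weights`).
#' @export
social_network <- function(weights) {
  weights <- as.matrix(weights)
  if (nrow(weights) != ncol(weights)) stopf("weights must be square")
  if (nrow(weights) && max(abs(weights - t(weights))) > 1e-12)
    stopf("weights must be symmetric")
  if (nrow(weights) && (min(weights) < 0 || max(weights) > 1))
    stopf("weights must lie in [0, 1]")
  diag(weights) <- 0
  if (is.null(rownames(weights)))
    dimnames(weights) <- list(sprintf("n%d", seq_len(nrow(weights))),
                              sprintf("n%d", seq_len(nrow(weights))))
  structure(list(nodes = rownames(weights), weights = weights),
            class = "social_network")
}

#' @export
print.social_network <- function(x, ...) {
  s <- network_summary(x)
  cat(sprintf("<social_network> V=%d E=%d D=%.3f\n", s$V, s$E, s$D))
  invisible(x)
}

#' Build a simple-ratio-index network from a GBI
#'
#' The simple ratio index (SRI) of a dyad (a, b) is x / (x + y), where x is
#' the number of grouping events containing both a and b, and y the number
#' containing exactly one of them. Equivalently x / (n_a + n_b - x) with
#' n_a the number of events containing a. Dyads that never co-occur get
#' weight 0 (no edge).
#'
#' @param gbi a [gbi].
#' @return A [social_network] over all individuals in the GBI.
#' @export
build_sri_network <- function(gbi) {
  stopifnot(inherits(gbi, "gbi"))
  inc <- gbi$incidence
  if (!ncol(inc)) return(social_network(matrix(numeric(), 0, 0)))
  x <- crossprod(inc)                 # co-occurrence counts
  n <- diag(x)                        # per-individual event counts
  denom <- outer(n, n, "+") - x
  w <- ifelse(denom > 0, x / denom, 0)
  diag(w) <- 0
  social_network(w)
}

#' Remove degree-zero individuals
#'
#' Individuals with no positive-weight edge are dropped from the network
#' (they were detected but never associated). Idempotent.
#'
#' @param net a [social_network].
#' @return The pruned [social_network].
#' @export
prune_isolates <- function(net) {
  stopifnot(inherits(net, "social_network"))
  keep <- rowSums(net$weights > 0) > 0
  social_network(net$weights[keep, keep, drop = FALSE])
}

#' Network cardinality summary
#'
#' @param net a [social_network].
#' @return List with `V` (vertices), `E` (edges, i.e. positive-weight
#'   dyads) and `D` (density, E over V(V-1)/2).
#' @export
network_summary <- function(net) {
  stopifnot(inherits(net, "social_network"))
  V <- length(net$nodes)
  E <- sum(net$weights[upper.tri(net$weights)] > 0)
  list(V = V, E = E, D = if (V > 1) E / (V * (V - 1) / 2) else 0)
}

as_igraph <- function(net) {
  igraph::graph_from_adjacency_matrix(net$weights, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}

#' Node-level network metrics
#'
#' Degree (number of unique associates), strength (summed edge weights) and
#' weighted betweenness (number of geodesics through the node, with edge
#' cost the reciprocal of the association weight, unnormalised, equal-cost
#' geodesics split fractionally).
#'
#' @param net a [social_network].
#' @return data.frame (individual, degree, strength, betweenness).
#' @export
node_metrics <- function(net) {
  stopifnot(inherits(net, "social_network"))
  if (!length(net$nodes))
    return(data.frame(individual = character(), degree = integer(),
                      strength = numeric(), betweenness = numeric()))
  w <- net$weights
  data.frame(individual = net$nodes,
             degree = as.integer(rowSums(w > 0)),
             strength = rowSums(w),
             betweenness = node_betweenness(net),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' @rdname node_metrics
#' @export
node_betweenness <- function(net) {
  stopifnot(inherits(net, "social_network"))
  g <- as_igraph(net)
  if (igraph::vcount(g) == 0) return(numeric())
  wt <- igraph::E(g)$weight
  b <- igraph::betweenness(g, directed = FALSE,
                           weights = if (length(wt)) 1 / wt else NULL,
                           normalized = FALSE)
  as.numeric(b)
}

#' Write / read a network as weighted edge-list CSV
#'
#' Columns `i, j, weight`, one row per positive dyad (i < j in node order);
#' isolated nodes are recorded as a `node, NA, NA` stub so the node set
#' round-trips.
#'
#' @param net a [social_network]. @param path file path.
#' @return `path` (write) or a [social_network] (read).
#' @export
write_network <- function(net, path) {
  w <- net$weights
  up <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
  edges <- data.frame(i = net$nodes[up[, 1]], j = net$nodes[up[, 2]],
                      weight = w[up], stringsAsFactors = FALSE)
  iso <- setdiff(net$nodes, unique(c(edges$i, edges$j)))
  if (length(iso))
    edges <- rbind(edges, data.frame(i = iso, j = NA, weight = NA))
  utils::write.csv(edges, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  e <- utils::read.csv(path, stringsAsFactors = FALSE)
  ids <- sort(unique(stats::na.omit(c(e$i, e$j))))
  w <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  real <- !is.na(e$j)
  w[cbind(match(e$i[real], ids), match(e$j[real], ids))] <- e$weight[real]
  w <- pmax(w, t(w))
  social_network(w)
}
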