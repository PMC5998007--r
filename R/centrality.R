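# Centrality analyses on one RIN: RCA (change of average shortest path
# length under single-node removal), BCA (betweenness) and CCA
# (closeness), each standardized to a per-network Z-score.

.methods <- c("RCA", "BCA", "CCA")

.as_graph <- function(x) {
  if (inherits(x, "rin")) as_igraph(x) else x
}

.aspl_from_graph <- function(g) {
  d <- igraph::distances(g, weights = NA)
  v <- d[upper.tri(d)]
  v <- v[is.finite(v)]
  if (length(v) == 0) 0 else mean(v)
}

# network efficiency: mean of 1/d over all unordered pairs, disconnected
# pairs contributing 0 (used by the harmonic RCA mode)
.efficiency_from_graph <- function(g) {
  d <- igraph::distances(g, weights = NA)
  v <- d[upper.tri(d)]
  if (length(v) == 0) return(0)
  mean(ifelse(is.finite(v), 1 / v, 0))
}

#' Average shortest path length of a RIN
#'
#' Mean unweighted shortest-path length over all unordered node pairs
#' that are connected; pairs in different components are excluded from
#' both numerator and denominator. Returns 0 when no pair is connected.
#'
#' @param rin A `rin` object (or an igraph graph).
#' @return A single number (graph distance units).
#' @export
aspl <- function(rin) {
  g <- .as_graph(rin)
  if (igraph::vcount(g) < 2) stop("ASPL requires at least 2 nodes")
  .aspl_from_graph(g)
}

#' Z-score standardization over one network's nodes
#'
#' `z = (x - mean) / population-sd`. When the population standard
#' deviation is below 1e-12 (constant scores), every Z is 0.
#'
#' @param values Numeric vector of per-node raw scores (length >= 2).
#' @return Numeric vector of Z-scores, same names/order.
#' @export
zscores <- function(values) {
  if (length(values) < 2) stop("Z-scores require at least 2 values")
  m <- mean(values)
  s <- sqrt(mean((values - m)^2))
  if (s < 1e-12) return(values * 0)
  (values - m) / s
}

new_centrality_result <- function(method, rin, raw, zscore, graph_aspl = NA_real_,
                                  disconnects = NULL, mode = NA_character_) {
  df <- data.frame(node_id = rin$nodes$node_id,
                   ResChain = rin$nodes$ResChain,
                   ResIndex = rin$nodes$ResIndex,
                   icode = rin$nodes$icode,
                   ResType = rin$nodes$ResType,
                   raw = as.numeric(raw), zscore = as.numeric(zscore),
                   stringsAsFactors = FALSE)
  if (!is.null(disconnects)) df$disconnects <- disconnects
  structure(df, method = method, network = rin$name, graph_aspl = graph_aspl,
            mode = mode, class = c("centrality_result", "data.frame"))
}

#' @export
print.centrality_result <- function(x, n = 10, ...) {
  cat(sprintf("%s on network '%s' (%d nodes)", attr(x, "method"),
              attr(x, "network"), nrow(x)))
  if (is.finite(attr(x, "graph_aspl"))) {
    cat(sprintf(", intact ASPL %.4f", attr(x, "graph_aspl")))
  }
  cat("\nTop nodes by Z-score:\n")
  o <- order(-x$zscore, x$ResIndex)
  print.data.frame(utils::head(as.data.frame(x)[o, ], n), row.names = FALSE)
  invisible(x)
}

.check_rin_size <- function(rin, min_nodes = 3) {
  stopifnot(inherits(rin, "rin"))
  if (nrow(rin$nodes) < min_nodes) {
    stop("centrality analysis requires at least ", min_nodes, " nodes")
  }
}

#' Residue centrality analysis (ASPL change under node removal)
#'
#' The ASPL of the intact network is computed first; then, for each node
#' `v`, the ASPL of the network with `v` removed. The raw score is
#' `aspl(G - v) - aspl(G)`: higher means removal lengthens shortest
#' paths, i.e. the residue is more central. Raw scores are standardized
#' to Z-scores over the network.
#'
#' In the default `"connected"` mode the ASPL convention (connected pairs
#' only) applies after removal as well, so cut vertices can show a
#' deceptively small raw change; they are flagged in the `disconnects`
#' column (TRUE iff removal increases the number of components). The
#' `"harmonic"` mode uses network efficiency (mean of 1/d, disconnected
#' pairs contributing 0) with the sign inverted so that higher still
#' means more central.
#'
#' @param rin A `rin` object with at least 3 nodes.
#' @param mode `"connected"` (default) or `"harmonic"`.
#' @return A `centrality_result` data.frame (node_id, ResChain, ResIndex,
#'   icode, ResType, raw, zscore, disconnects) with attributes `method`,
#'   `network`, `graph_aspl`, `mode`.
#' @export
rca <- function(rin, mode = c("connected", "harmonic")) {
  mode <- match.arg(mode)
  .check_rin_size(rin)
  g <- as_igraph(rin)
  score_fun <- if (mode == "connected") .aspl_from_graph else .efficiency_from_graph
  base <- score_fun(g)
  vs <- igraph::V(g)
  raw <- vapply(seq_along(vs), function(i) {
    gi <- igraph::delete_vertices(g, vs[i])
    if (mode == "connected") score_fun(gi) - base else base - score_fun(gi)
  }, numeric(1))
  arts <- names(igraph::articulation_points(g))
  disconnects <- rin$nodes$node_id %in% arts
  new_centrality_result("RCA", rin, raw, zscores(raw),
                        graph_aspl = .aspl_from_graph(g),
                        disconnects = disconnects, mode = mode)
}

#' Betweenness centrality analysis
#'
#' Classical unnormalized shortest-path betweenness (undirected,
#' equal-length paths split evenly), followed by Z-score
#' standardization. Since Z-scores are invariant to positive scaling,
#' the normalization choice does not affect the Z column.
#'
#' @inheritParams rca
#' @return A `centrality_result`.
#' @export
bca <- function(rin) {
  .check_rin_size(rin)
  g <- as_igraph(rin)
  raw <- igraph::betweenness(g, directed = FALSE, weights = NA)
  new_centrality_result("BCA", rin, raw, zscores(raw))
}

#' Closeness centrality analysis
#'
#' Component-local closeness: for node `v`, the number of nodes reachable
#' from `v` divided by the sum of shortest-path distances to them
#' (isolated nodes score 0), followed by Z-score standardization.
#' Closeness Z-scores rarely exceed 2 on protein networks, so the raw
#' column should be inspected alongside the Z column.
#'
#' @inheritParams rca
#' @return A `centrality_result`.
#' @export
cca <- function(rin) {
  .check_rin_size(rin)
  g <- as_igraph(rin)
  raw <- suppressWarnings(igraph::closeness(g, mode = "all", weights = NA,
                                            normalized = TRUE))
  raw[!is.finite(raw)] <- 0
  new_centrality_result("CCA", rin, raw, zscores(raw))
}

#' Run one centrality method by name
#'
#' @param rin A `rin` object.
#' @param method One of `"RCA"`, `"BCA"`, `"CCA"`.
#' @param ... Passed on to the method function.
#' @return A `centrality_result`.
#' @export
centrality <- function(rin, method, ...) {
  if (length(method) != 1 || !(method %in% .methods)) {
    stop("unknown centrality method '", paste(method, collapse = ","),
         "'; must be one of: ", paste(.methods, collapse = ", "))
  }
  switch(method, RCA = rca(rin, ...), BCA = bca(rin, ...), CCA = cca(rin, ...))
}

#' Append a centrality result to the RIN node table
#'
#' Adds `<method>_raw` and `<method>_zscore` columns (and
#' `<method>_disconnects` for RCA) so they travel with the node TSV.
#'
#' @param rin A `rin` object.
#' @param result A `centrality_result` computed on the same RIN.
#' @return The `rin` with appended node attribute columns.
#' @export
apply_scores <- function(rin, result) {
  stopifnot(inherits(rin, "rin"), inherits(result, "centrality_result"))
  i <- match(rin$nodes$node_id, result$node_id)
  if (anyNA(i)) stop("result does not cover the RIN's node set")
  m <- attr(result, "method")
  rin$nodes[[paste0(m, "_raw")]] <- result$raw[i]
  rin$nodes[[paste0(m, "_zscore")]] <- result$zscore[i]
  if (!is.null(result$disconnects)) {
    rin$nodes[[paste0(m, "_disconnects")]] <- result$disconnects[i]
  }
  rin
}
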