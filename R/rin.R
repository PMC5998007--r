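# Residue interaction networks: undirected residue graphs under a
# heavy-atom distance contact criterion, with the three node-attribute
# columns (ResType, ResIndex, ResChain) every downstream analysis needs.

.rin_required_cols <- c("ResType", "ResIndex", "ResChain")

new_rin <- function(name, nodes, edges) {
  stopifnot(all(c("node_id", .rin_required_cols, "icode") %in% names(nodes)))
  rownames(nodes) <- NULL
  rownames(edges) <- NULL
  structure(list(name = name, nodes = nodes, edges = edges), class = "rin")
}

#' @export
print.rin <- function(x, ...) {
  cat(sprintf("RIN '%s': %d nodes, %d edges, chain(s) %s\n",
              x$name, nrow(x$nodes), nrow(x$edges),
              paste(sort(unique(x$nodes$ResChain)), collapse = ",")))
  invisible(x)
}

.node_id <- function(chain, resno, icode, resid) {
  paste0(chain, ":", resno, icode, ":", resid)
}

#' Build a residue interaction network from a model
#'
#' Nodes are residues; an edge joins two distinct residues whenever some
#' heavy-atom (non-hydrogen) pair lies within `cutoff` angstroms, subject
#' to a minimum sequence separation for same-chain pairs. The smallest
#' qualifying atom distance is stored on each edge. Isolated residues
#' remain as nodes.
#'
#' @param model A model (atom table) from [read_pdb()] or a fixture
#'   generator.
#' @param chains Optional character vector restricting the network to a
#'   chain subset.
#' @param cutoff Contact distance cutoff in angstroms (default 5.0).
#' @param min_seq_sep Minimum |ResIndex difference| for same-chain edges
#'   (default 1, i.e. sequence neighbours allowed).
#' @param name Network label; defaults to `"model<id>"`.
#' @return An object of class `rin` with `nodes` (node_id, ResType,
#'   ResIndex, ResChain, icode) and `edges` (from, to, min_distance).
#' @export
build_rin <- function(model, chains = NULL, cutoff = 5.0, min_seq_sep = 1L,
                      name = NULL) {
  stopifnot(inherits(model, "rin_model"))
  if (!is.numeric(cutoff) || length(cutoff) != 1 || cutoff <= 0) {
    stop("cutoff must be a positive distance in angstroms")
  }
  if (min_seq_sep < 0) stop("min_seq_sep must be >= 0")
  at <- as.data.frame(model)
  if (!is.null(chains)) at <- at[at$chain %in% chains, , drop = FALSE]
  if (nrow(at) == 0) stop("no atoms left after chain selection")
  if (is.null(name)) name <- paste0("model", attr(model, "model_id"))

  rkey <- .residue_key(at$chain, at$resno, at$icode)
  first <- !duplicated(rkey)
  nodes <- data.frame(node_id = .node_id(at$chain[first], at$resno[first],
                                         at$icode[first], at$resid[first]),
                      ResType = at$resid[first], ResIndex = at$resno[first],
                      ResChain = at$chain[first], icode = at$icode[first],
                      stringsAsFactors = FALSE)
  ridx <- match(rkey, rkey[first])   # residue index per atom

  # hydrogens (and deuterium) ignored even when present; fall back to the
  # atom-name convention when the element column is blank
  elesy <- toupper(at$elesy)
  heavy <- ifelse(nzchar(elesy), !(elesy %in% c("H", "D")),
                  !grepl("^[0-9]*[HD]", at$elety))
  xyz <- as.matrix(at[heavy, c("x", "y", "z")])
  ridx <- ridx[heavy]

  edges <- data.frame(from = character(0), to = character(0),
                      min_distance = numeric(0), stringsAsFactors = FALSE)
  if (nrow(xyz) >= 2) {
    d <- as.matrix(stats::dist(xyz))
    hit <- which(upper.tri(d) & d <= cutoff, arr.ind = TRUE)
    if (nrow(hit) > 0) {
      ra <- ridx[hit[, 1]]; rb <- ridx[hit[, 2]]
      keep <- ra != rb
      ra <- ra[keep]; rb <- rb[keep]; dd <- d[hit][keep]
      lo <- pmin(ra, rb); hi <- pmax(ra, rb)
      same_chain <- nodes$ResChain[lo] == nodes$ResChain[hi]
      sep_ok <- !same_chain |
        abs(nodes$ResIndex[lo] - nodes$ResIndex[hi]) >= min_seq_sep
      lo <- lo[sep_ok]; hi <- hi[sep_ok]; dd <- dd[sep_ok]
      if (length(lo) > 0) {
        pkey <- paste(lo, hi)
        mins <- tapply(dd, pkey, min)
        pl <- as.integer(sub(" .*", "", names(mins)))
        ph <- as.integer(sub(".* ", "", names(mins)))
        o <- order(pl, ph)
        edges <- data.frame(from = nodes$node_id[pl[o]],
                            to = nodes$node_id[ph[o]],
                            min_distance = as.numeric(mins)[o],
                            stringsAsFactors = FALSE)
      }
    }
  }
  new_rin(name, nodes, edges)
}

#' Convert a RIN to an igraph graph
#'
#' Node attributes (including any appended score columns) become vertex
#' attributes; `min_distance` becomes an edge attribute. The graph is
#' undirected and never edge-weighted for path purposes.
#'
#' @param rin A `rin` object.
#' @return An igraph object with vertices named by `node_id`.
#' @export
as_igraph <- function(rin) {
  stopifnot(inherits(rin, "rin"))
  igraph::graph_from_data_frame(rin$edges, directed = FALSE,
                                vertices = rin$nodes)
}

#' Export a RIN as node and edge tables
#'
#' @param rin A `rin` object.
#' @return List with `nodes` (node_id, ResType, ResIndex, ResChain, icode
#'   and any appended attribute columns) and `edges` (from, to,
#'   min_distance) data.frames.
#' @export
rin_to_edge_table <- function(rin) {
  stopifnot(inherits(rin, "rin"))
  list(nodes = rin$nodes, edges = rin$edges)
}

#' Write a RIN to TSV node/edge tables (and optionally GraphML)
#'
#' @param rin A `rin` object.
#' @param prefix Path prefix; writes `<prefix>_nodes.tsv` and
#'   `<prefix>_edges.tsv`.
#' @param graphml Also write `<prefix>.graphml`?
#' @return Character vector of written paths, invisibly.
#' @export
write_rin <- function(rin, prefix, graphml = FALSE) {
  tabs <- rin_to_edge_table(rin)
  paths <- paste0(prefix, c("_nodes.tsv", "_edges.tsv"))
  utils::write.table(tabs$nodes, paths[1], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(tabs$edges, paths[2], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (graphml) {
    gpath <- paste0(prefix, ".graphml")
    igraph::write_graph(as_igraph(rin), gpath, format = "graphml")
    paths <- c(paths, gpath)
  }
  invisible(paths)
}

#' Reconstruct a RIN from node and edge tables
#'
#' Accepts data.frames or TSV paths. The node table must carry the three
#' required columns ResType, ResIndex and ResChain; extra columns are
#' preserved as node attributes. Edges referencing unknown nodes are an
#' error.
#'
#' @param node_table data.frame or TSV path.
#' @param edge_table data.frame or TSV path (columns from, to, optional
#'   min_distance).
#' @param name Network label.
#' @return A `rin` object.
#' @export
read_rin <- function(node_table, edge_table, name = "rin") {
  rd <- function(x) {
    if (is.character(x)) {
      utils::read.delim(x, stringsAsFactors = FALSE, check.names = FALSE,
                        colClasses = NA)
    } else as.data.frame(x)
  }
  nodes <- rd(node_table)
  edges <- rd(edge_table)
  miss <- setdiff(.rin_required_cols, names(nodes))
  if (length(miss) > 0) {
    stop("node table is missing required column(s): ",
         paste(miss, collapse = ", "))
  }
  if (is.null(nodes$icode)) nodes$icode <- ""
  nodes$icode[is.na(nodes$icode)] <- ""
  if (is.null(nodes$node_id)) {
    nodes$node_id <- .node_id(nodes$ResChain, nodes$ResIndex, nodes$icode,
                              nodes$ResType)
  }
  front <- c("node_id", .rin_required_cols, "icode")
  nodes <- nodes[, c(front, setdiff(names(nodes), front)), drop = FALSE]
  if (nrow(edges) > 0) {
    if (!all(c("from", "to") %in% names(edges))) {
      stop("edge table must have 'from' and 'to' columns")
    }
    unknown <- setdiff(c(edges$from, edges$to), nodes$node_id)
    if (length(unknown) > 0) {
      stop("edge table references unknown node(s): ",
           paste(utils::head(unknown, 5), collapse = ", "))
    }
    if (is.null(edges$min_distance)) edges$min_distance <- NA_real_
  } else {
    edges <- data.frame(from = character(0), to = character(0),
                        min_distance = numeric(0))
  }
  new_rin(name, nodes, edges[, c("from", "to", "min_distance")])
}

#' Read a RIN from a `<prefix>_nodes.tsv` / `<prefix>_edges.tsv` pair
#'
#' @param prefix Path prefix used by [write_rin()].
#' @param name Network label; defaults to the prefix basename.
#' @return A `rin` object.
#' @export
read_rin_prefix <- function(prefix, name = basename(prefix)) {
  read_rin(paste0(prefix, "_nodes.tsv"), paste0(prefix, "_edges.tsv"),
           name = name)
}
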