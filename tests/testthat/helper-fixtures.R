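# Shared test fixtures: RINs built directly from edge lists (for graph
# math), tiny inline PDB texts (for parser corner cases), and the
# oracle-side adjacency view of a package RIN.

# RIN on nodes 1..n (chain A, residue i, type GLY) with the given edges
# (2-column matrix of node indices)
rin_from_edges <- function(n, edges, name = "test") {
  nodes <- data.frame(ResType = "GLY", ResIndex = seq_len(n), ResChain = "A",
                      stringsAsFactors = FALSE)
  nodes$node_id <- paste0("A:", nodes$ResIndex, ":GLY")
  ed <- if (length(edges) == 0) {
    data.frame(from = character(0), to = character(0))
  } else {
    data.frame(from = nodes$node_id[edges[, 1]],
               to = nodes$node_id[edges[, 2]], stringsAsFactors = FALSE)
  }
  read_rin(nodes, ed, name = name)
}

edges_K4 <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
edges_K4_minus <- edges_K4[-1, ]                 # drop edge (1,2)
edges_C5 <- rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 5), c(5, 1))
edges_P4 <- rbind(c(1, 2), c(2, 3), c(3, 4))
edges_P3 <- rbind(c(1, 2), c(2, 3))
edges_S4 <- rbind(c(1, 2), c(1, 3), c(1, 4))     # star, centre = 1

# graph (oracle view) of a package RIN
rin_as_oracle <- function(rin) {
  n <- nrow(rin$nodes)
  ia <- match(rin$edges$from, rin$nodes$node_id)
  ib <- match(rin$edges$to, rin$nodes$node_id)
  oracle_graph(n, cbind(ia, ib))
}

# one PDB line (fixed columns)
pdb_line <- function(type = "ATOM", serial, name, resn, chain, resno,
                     x, y, z, occ = 1, alt = "", icode = "", elem = NULL) {
  if (is.null(elem)) elem <- substr(name, 1, 1)
  sprintf("%-6s%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          type, serial, name, alt, resn, chain, resno, icode, x, y, z,
          occ, 0, elem)
}

write_tmp_pdb <- function(lines) {
  f <- tempfile(fileext = ".pdb")
  writeLines(lines, f)
  f
}

# single-model fixture: 3 protein residues + 1 HETATM ligand + 1 water
mixed_pdb <- function() {
  write_tmp_pdb(c(
    pdb_line("ATOM", 1, "CA", "ALA", "A", 1, 0, 0, 0),
    pdb_line("ATOM", 2, "CA", "GLY", "A", 2, 3.8, 0, 0),
    pdb_line("ATOM", 3, "CA", "ASN", "A", 3, 7.6, 0, 0),
    pdb_line("HETATM", 4, "C1", "LIG", "A", 90, 2.0, 2.0, 0),
    pdb_line("HETATM", 5, "O", "HOH", "A", 99, 9.0, 9.0, 9.0),
    "END"))
}

expect_rin_equal <- function(a, b) {
  expect_equal(a$nodes[order(a$nodes$node_id), c("node_id", "ResType",
                                                 "ResIndex", "ResChain")],
               b$nodes[order(b$nodes$node_id), c("node_id", "ResType",
                                                 "ResIndex", "ResChain")],
               ignore_attr = TRUE)
  ekey <- function(r) {
    k <- paste(pmin(r$edges$from, r$edges$to), pmax(r$edges$from, r$edges$to))
    sort(k)
  }
  expect_equal(ekey(a), ekey(b))
}
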