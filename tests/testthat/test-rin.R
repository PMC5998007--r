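# helper: model of single-CA residues at given coordinates
ca_model <- function(xyz, chain = "A", resno = seq_len(nrow(xyz))) {
  rintools:::new_rin_model(data.frame(
    chain = chain, resno = resno, icode = "", resid = "GLY", elety = "CA",
    elesy = "C", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], het = FALSE,
    stringsAsFactors = FALSE))
}

test_that("contact detection follows the distance cutoff exactly", {
  m <- ca_model(rbind(c(0, 0, 0), c(4, 0, 0)))
  rin <- build_rin(m, cutoff = 5.0, min_seq_sep = 1)
  expect_equal(nrow(rin$edges), 1)
  expect_equal(rin$edges$min_distance, 4.0)
  expect_equal(nrow(build_rin(m, cutoff = 3.0)$edges), 0)
  # boundary: exactly at the cutoff counts as a contact
  expect_equal(nrow(build_rin(m, cutoff = 4.0)$edges), 1)
  one <- build_rin(ca_model(rbind(c(0, 0, 0))), cutoff = 5)
  expect_equal(nrow(one$nodes), 1)
  expect_equal(nrow(one$edges), 0)
})

test_that("build_rin validates its inputs", {
  m <- ca_model(rbind(c(0, 0, 0), c(4, 0, 0)))
  expect_error(build_rin(m, cutoff = 0), "positive")
  expect_error(build_rin(m, cutoff = -1), "positive")
  expect_error(build_rin(m, min_seq_sep = -1), "min_seq_sep")
  expect_error(build_rin(m, chains = "Z"), "chain")
})

test_that("min_seq_sep suppresses near-in-sequence same-chain contacts only", {
  xyz <- rbind(c(0, 0, 0), c(4, 0, 0), c(8, 0, 0))
  m <- ca_model(xyz)
  expect_equal(nrow(build_rin(m, cutoff = 5, min_seq_sep = 1)$edges), 2)
  expect_equal(nrow(build_rin(m, cutoff = 5, min_seq_sep = 2)$edges), 0)
  # different chains are exempt from the separation rule
  m2 <- ca_model(rbind(c(0, 0, 0), c(4, 0, 0)), chain = c("A", "B"),
                 resno = c(1, 1))
  expect_equal(nrow(build_rin(m2, cutoff = 5, min_seq_sep = 10)$edges), 1)
})

test_that("hydrogens are ignored even when present", {
  df <- data.frame(chain = "A", resno = c(1, 1, 2), icode = "",
                   resid = "GLY", elety = c("CA", "H", "CA"),
                   elesy = c("C", "H", "C"),
                   x = c(0, 3, 8), y = 0, z = 0, het = FALSE,
                   stringsAsFactors = FALSE)
  m <- rintools:::new_rin_model(df)
  # the H atom at x=3 is within 5 A of residue 2's CA; heavy atoms are not
  expect_equal(nrow(build_rin(m, cutoff = 5.5)$edges), 0)
  expect_equal(nrow(build_rin(m, cutoff = 8.0)$edges), 1)
})

test_that("chain filter drops unselected chains entirely", {
  m <- ca_model(rbind(c(0, 0, 0), c(4, 0, 0), c(0, 4, 0)),
                chain = c("A", "A", "B"), resno = c(1, 2, 1))
  rin <- build_rin(m, chains = "A", cutoff = 5)
  expect_equal(unique(rin$nodes$ResChain), "A")
  expect_equal(nrow(rin$nodes), 2)
})

test_that("edge sets grow monotonically with the cutoff", {
  m <- select_model(make_ensemble(25, 1, noise_sigma = 0, seed = 1), 1)
  prev <- character(0)
  for (cutoff in c(3, 4, 5, 6.5, 8)) {
    rin <- build_rin(m, cutoff = cutoff)
    cur <- paste(rin$edges$from, rin$edges$to)
    expect_true(all(prev %in% cur),
                info = sprintf("cutoff %.1f lost edges", cutoff))
    prev <- cur
  }
})

test_that("build_rin matches a brute-force atom-pair oracle", {
  for (seed in 1:3) {
    m <- select_model(make_ensemble(30, 1, noise_sigma = 1.5, seed = seed), 1)
    cutoff <- 5.0
    rin <- build_rin(m, cutoff = cutoff, min_seq_sep = 1)
    # oracle: all heavy-atom pairs, residue by residue
    df <- as.data.frame(m)
    rt <- residue_table(m)
    expected <- list()
    for (i in seq_len(nrow(rt) - 1)) {
      for (j in (i + 1):nrow(rt)) {
        if (abs(rt$resno[i] - rt$resno[j]) < 1) next
        ai <- df[df$resno == rt$resno[i], c("x", "y", "z")]
        aj <- df[df$resno == rt$resno[j], c("x", "y", "z")]
        d2 <- outer(rowSums(ai^2), rowSums(aj^2), "+") -
          2 * as.matrix(ai) %*% t(as.matrix(aj))
        dmin <- min(sqrt(pmax(d2, 0)))
        if (dmin <= cutoff) {
          expected[[paste(rt$resno[i], rt$resno[j])]] <- dmin
        }
      }
    }
    got <- stats::setNames(rin$edges$min_distance,
                           paste(rin$nodes$ResIndex[match(rin$edges$from, rin$nodes$node_id)],
                                 rin$nodes$ResIndex[match(rin$edges$to, rin$nodes$node_id)]))
    expect_setequal(names(got), names(expected))
    expect_equal(got[names(expected)], unlist(expected), tolerance = 1e-9)
  }
})

test_that("RIN adjacency is symmetric with no self-edges", {
  m <- select_model(make_ensemble(20, 1, noise_sigma = 1, seed = 4), 1)
  rin <- build_rin(m)
  expect_false(any(rin$edges$from == rin$edges$to))
  expect_false(anyDuplicated(paste(pmin(rin$edges$from, rin$edges$to),
                                   pmax(rin$edges$from, rin$edges$to))) > 0)
  g <- as_igraph(rin)
  expect_equal(sum(igraph::degree(g)), 2 * nrow(rin$edges))
})

test_that("RIN tables round-trip through TSV and GraphML", {
  m <- select_model(make_ensemble(15, 1, noise_sigma = 0.8, seed = 5), 1)
  rin <- build_rin(m, name = "rt")
  tabs <- rin_to_edge_table(rin)
  expect_equal(nrow(tabs$edges), nrow(rin$edges))
  expect_true(all(c("node_id", "ResType", "ResIndex", "ResChain") %in%
                    names(tabs$nodes)))

  prefix <- file.path(withr::local_tempdir(), "rt")
  paths <- write_rin(rin, prefix, graphml = TRUE)
  back <- read_rin_prefix(prefix, name = "rt")
  expect_rin_equal(back, rin)
  expect_equal(back$edges$min_distance[order(back$edges$from, back$edges$to)],
               rin$edges$min_distance[order(rin$edges$from, rin$edges$to)],
               tolerance = 1e-9)
  g <- igraph::read_graph(paste0(prefix, ".graphml"), format = "graphml")
  expect_equal(igraph::vcount(g), nrow(rin$nodes))
  expect_equal(igraph::ecount(g), nrow(rin$edges))
})

test_that("an edgeless RIN still writes a full node table", {
  rin <- rin_from_edges(3, matrix(numeric(0), 0, 2))
  prefix <- file.path(withr::local_tempdir(), "empty")
  write_rin(rin, prefix)
  back <- read_rin_prefix(prefix)
  expect_equal(nrow(back$nodes), 3)
  expect_equal(nrow(back$edges), 0)
})

test_that("read_rin enforces the three-column node schema", {
  nodes <- data.frame(ResType = "GLY", ResIndex = 1:3, ResChain = "A")
  nodes$node_id <- paste0("A:", 1:3, ":GLY")
  edges <- data.frame(from = nodes$node_id[1], to = nodes$node_id[2])
  expect_s3_class(read_rin(nodes, edges), "rin")
  expect_error(read_rin(nodes[, setdiff(names(nodes), "ResChain")], edges),
               "ResChain")
  expect_error(read_rin(nodes[, "ResIndex", drop = FALSE], edges),
               "ResType.*ResChain")
  bad_edges <- data.frame(from = "A:9:GLY", to = nodes$node_id[1])
  expect_error(read_rin(nodes, bad_edges), "unknown node")
})

test_that("extra node-table columns are preserved as attributes", {
  nodes <- data.frame(ResType = "GLY", ResIndex = 1:3, ResChain = "A",
                      conservation = c(0.1, 0.9, 0.5))
  rin <- read_rin(nodes, data.frame(from = character(0), to = character(0)))
  expect_equal(rin$nodes$conservation, c(0.1, 0.9, 0.5))
})
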