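test_that("PDB round-trip preserves residue keys, atom names and coordinates", {
  for (s in list(make_helix(10), make_ensemble(12, n_models = 10,
                                               noise_sigma = 0.5, seed = 7))) {
    f <- withr::local_tempfile(fileext = ".pdb")
    write_pdb(s, f)
    s2 <- read_pdb(f)
    expect_length(s2$models, length(s$models))
    for (k in seq_along(s$models)) {
      a <- s$models[[k]]; b <- s2$models[[k]]
      expect_equal(b[, c("chain", "resno", "icode", "resid", "elety")],
                   a[, c("chain", "resno", "icode", "resid", "elety")],
                   ignore_attr = TRUE)
      # coordinates survive to the PDB fixed-column precision (3 d.p.)
      expect_lt(max(abs(as.matrix(b[, c("x", "y", "z")]) -
                          as.matrix(a[, c("x", "y", "z")]))), 5.01e-4)
    }
  }
  # the 10-model ensemble writes 10 MODEL blocks
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(make_ensemble(5, n_models = 10, seed = 1), f)
  expect_length(grep("^MODEL", readLines(f)), 10)
})

test_that("helix fixture parses to one model of pure alanine", {
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(make_helix(10), f)
  s <- read_pdb(f)
  expect_length(s$models, 1)
  rt <- residue_table(s$models[[1]])
  expect_equal(nrow(rt), 10)
  expect_true(all(rt$resid == "ALA"))
  expect_false(any(rt$het))
})

test_that("water is always dropped; ligands follow include_hetero", {
  f <- mixed_pdb()
  s_with <- read_pdb(f, include_hetero = TRUE)
  rt <- residue_table(s_with$models[[1]])
  expect_true("LIG" %in% rt$resid)
  expect_false("HOH" %in% rt$resid)
  expect_true(rt$het[rt$resid == "LIG"])

  s_without <- read_pdb(f, include_hetero = FALSE)
  rt2 <- residue_table(s_without$models[[1]])
  expect_false(any(rt2$het))
  expect_equal(rt2$resid, c("ALA", "GLY", "ASN"))
})

test_that("read_pdb rejects missing files and files without ATOM records", {
  expect_error(read_pdb(tempfile()), "not found")
  f <- write_tmp_pdb(c("HEADER test", "END"))
  expect_error(read_pdb(f), "no ATOM records")
  expect_match(tryCatch(read_pdb(f), error = conditionMessage), basename(f))
})

test_that("altLoc keeps the highest-occupancy record, ties to first in file", {
  f <- write_tmp_pdb(c(
    pdb_line("ATOM", 1, "CA", "SER", "A", 1, 0, 0, 0, occ = 0.4, alt = "A"),
    pdb_line("ATOM", 2, "CA", "SER", "A", 1, 9, 9, 9, occ = 0.6, alt = "B"),
    pdb_line("ATOM", 3, "CA", "SER", "A", 2, 3.8, 0, 0, occ = 0.5, alt = "A"),
    pdb_line("ATOM", 4, "CA", "SER", "A", 2, 8, 8, 8, occ = 0.5, alt = "B"),
    "END"))
  m <- read_pdb(f)$models[[1]]
  expect_equal(nrow(m), 2)
  expect_equal(m$x[m$resno == 1], 9)      # occupancy 0.6 wins
  expect_equal(m$x[m$resno == 2], 3.8)    # tie: first in file wins
})

test_that("select_model returns the requested conformer and checks bounds", {
  s <- make_ensemble(6, n_models = 10, noise_sigma = 0.3, seed = 2)
  expect_equal(attr(select_model(s, 1), "model_id"), 1L)
  expect_equal(attr(select_model(s, 10), "model_id"), 10L)
  expect_identical(select_model(s, 3), s$models[[3]])
  expect_error(select_model(s, 11), "available models.*10")
})

test_that("alanine mutation truncates ASN to exactly N, CA, C, O, CB", {
  wt <- select_model(make_mutant_set(12, sites = 6)$WT, 1)
  asn <- wt[wt$resno == 6, ]
  expect_setequal(asn$elety, c("N", "CA", "C", "O", "CB", "CG", "OD1", "ND2"))
  mut <- mutate_to_alanine(wt, "A", 6)
  kept <- mut[mut$resno == 6, ]
  expect_setequal(kept$elety, c("N", "CA", "C", "O", "CB"))
  expect_equal(unique(kept$resid), "ALA")
  # coordinates of retained atoms bit-identical, all other residues untouched
  for (nm in kept$elety) {
    expect_identical(unlist(kept[kept$elety == nm, c("x", "y", "z")]),
                     unlist(asn[asn$elety == nm, c("x", "y", "z")]))
  }
  strip <- function(df) { df <- as.data.frame(df); rownames(df) <- NULL; df }
  expect_equal(strip(mut[mut$resno != 6, ]), strip(wt[wt$resno != 6, ]),
               ignore_attr = TRUE)
  expect_equal(nrow(residue_table(mut)), nrow(residue_table(wt)))
})

test_that("mutating an alanine is a no-op and errors are informative", {
  m <- select_model(make_helix(8), 1)
  expect_equal(as.data.frame(mutate_to_alanine(m, "A", 4)),
               as.data.frame(m))
  expect_error(mutate_to_alanine(m, "A", 99), "not found")
  expect_error(mutate_to_alanine(m, "B", 4), "not found")
  broken <- m[!(m$resno == 4 & m$elety == "O"), ]
  broken <- rintools:::new_rin_model(broken)
  expect_error(mutate_to_alanine(broken, "A", 4), "backbone atom.*O")
})

test_that("multi-site mutation is order-independent", {
  wt <- select_model(make_mutant_set(15, sites = c(4, 8, 12))$WT, 1)
  perms <- list(c(4, 8, 12), c(12, 4, 8), c(8, 12, 4))
  outs <- lapply(perms, function(p) {
    m <- wt
    for (i in p) m <- mutate_to_alanine(m, "A", i)
    df <- as.data.frame(m)
    df[order(df$resno, df$elety), ]
  })
  expect_equal(outs[[2]], outs[[1]], ignore_attr = TRUE)
  expect_equal(outs[[3]], outs[[1]], ignore_attr = TRUE)
})

test_that("list_point_mutants labels singles and the combined mutant", {
  wt <- select_model(make_mutant_set(30, sites = c(5, 9, 13, 17, 21))$WT, 1)
  sites <- data.frame(chain = "A", index = c(5, 9, 13, 17, 21))
  muts <- list_point_mutants(wt, sites, combine = TRUE)
  expect_length(muts, 6)    # five singles + one combined
  expect_equal(names(muts)[1:5], c("N5A", "N9A", "N13A", "N17A", "N21A"))
  expect_equal(names(muts)[6], "N5A+N9A+N13A+N17A+N21A")
  named <- list_point_mutants(wt, sites, combine = TRUE,
                              combined_label = "5N5A")
  expect_equal(names(named)[6], "5N5A")
  expect_length(list_point_mutants(wt, sites[1, , drop = FALSE]), 1)
  expect_length(list_point_mutants(wt, sites[0, , drop = FALSE]), 0)
  expect_error(list_point_mutants(wt, sites[c(1, 1), ]), "duplicate")
  # combined mutant equals sequential application
  seq5 <- Reduce(function(m, i) mutate_to_alanine(m, "A", i), sites$index, wt)
  expect_equal(as.data.frame(muts[[6]]), as.data.frame(seq5))
})

test_that("mutant structures survive a PDB round-trip as alanine", {
  ms <- make_mutant_set(12, sites = c(4, 9))
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(ms$N4A, f)
  back <- read_pdb(f)
  rt <- residue_table(back$models[[1]])
  expect_equal(rt$resid[rt$resno == 4], "ALA")
  expect_equal(rt$resid[rt$resno == 9], "ASN")
})
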