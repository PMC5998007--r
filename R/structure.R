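# Atom-level columns carried by every model. A model is an atom table
# (data.frame, one row per atom, file order); a structure is a list of models.
.model_cols <- c("chain", "resno", "icode", "resid", "elety", "elesy",
                 "x", "y", "z", "het")

.water_codes <- c("HOH", "WAT", "DOD")
.backbone_atoms <- c("N", "CA", "C", "O")
.ala_atoms <- c("N", "CA", "C", "O", "CB")

new_rin_model <- function(df, model_id = 1L) {
  df <- as.data.frame(df)[, .model_cols]
  rownames(df) <- NULL
  stopifnot(all(is.finite(df$x)), all(is.finite(df$y)), all(is.finite(df$z)))
  df$elety <- trimws(df$elety)
  stopifnot(all(nzchar(df$elety)))
  df$resid <- toupper(trimws(df$resid))
  attr(df, "model_id") <- as.integer(model_id)
  class(df) <- c("rin_model", "data.frame")
  df
}

new_rin_structure <- function(id, models) {
  stopifnot(length(models) >= 1)
  structure(list(id = id, models = models), class = "rin_structure")
}

#' @export
print.rin_structure <- function(x, ...) {
  nres <- vapply(x$models, function(m) nrow(residue_table(m)), integer(1))
  cat(sprintf("Structure '%s': %d model(s), %s residue(s), %d atoms in model 1\n",
              x$id, length(x$models),
              paste(unique(range(nres)), collapse = "-"), nrow(x$models[[1]])))
  invisible(x)
}

#' @export
print.rin_model <- function(x, ...) {
  rt <- residue_table(x)
  cat(sprintf("Model %d: %d residues, %d atoms, chain(s) %s\n",
              attr(x, "model_id"), nrow(rt), nrow(x),
              paste(sort(unique(x$chain)), collapse = ",")))
  invisible(x)
}

.residue_key <- function(chain, resno, icode) paste0(chain, ":", resno, icode)

#' Table of residues in a model
#'
#' One row per residue, in file order, with the chain, residue serial
#' number, insertion code, three-letter type and hetero flag.
#'
#' @param model A model (atom table) from [read_pdb()] / [select_model()].
#' @return data.frame with columns chain, resno, icode, resid, het.
#' @export
residue_table <- function(model) {
  key <- .residue_key(model$chain, model$resno, model$icode)
  keep <- !duplicated(key)
  out <- data.frame(chain = model$chain[keep], resno = model$resno[keep],
                    icode = model$icode[keep], resid = model$resid[keep],
                    het = model$het[keep], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# Parse one MODEL block with bio3d, keeping all altLocs, then resolve
# altLocs by highest occupancy (ties: first in file).
.parse_block <- function(lines, model_id, include_hetero) {
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp))
  writeLines(c(lines, "END"), tmp)
  pdb <- bio3d::read.pdb(tmp, rm.alt = FALSE, verbose = FALSE)
  at <- pdb$atom
  at$insert[is.na(at$insert)] <- ""
  at$chain[is.na(at$chain)] <- " "
  at$elesy[is.na(at$elesy)] <- ""
  at$o[is.na(at$o)] <- 1

  # altLoc resolution: per (chain, resno, icode, atom name) keep the
  # highest-occupancy record, ties broken by file order
  akey <- paste(at$chain, at$resno, at$insert, trimws(at$elety), sep = "\r")
  best <- tapply(seq_len(nrow(at)), akey, function(i) i[which.max(at$o[i])])
  at <- at[sort(unlist(best, use.names = FALSE)), , drop = FALSE]

  at <- at[!(at$resid %in% .water_codes), , drop = FALSE]
  het <- at$type == "HETATM"
  if (!include_hetero) {
    at <- at[!het, , drop = FALSE]
    het <- rep(FALSE, nrow(at))
  }
  if (nrow(at) == 0) return(NULL)
  new_rin_model(data.frame(chain = at$chain, resno = at$resno, icode = at$insert,
                           resid = at$resid, elety = trimws(at$elety),
                           elesy = trimws(at$elesy),
                           x = at$x, y = at$y, z = at$z, het = het,
                           stringsAsFactors = FALSE),
                model_id = model_id)
}

#' Read a (multi-model) PDB file
#'
#' Parses standard fixed-column PDB, honouring MODEL/ENDMDL blocks (one
#' model per conformer; a single implicit model when absent). Water (HOH)
#' is always dropped; other HETATM residues are kept with a hetero flag or
#' dropped entirely when `include_hetero = FALSE`. Alternate locations are
#' resolved to the highest-occupancy record. Residue numbering is taken
#' verbatim from the file.
#'
#' @param path Path to a PDB file.
#' @param include_hetero Keep non-water HETATM residues (ligands)?
#' @return An object of class `rin_structure`: a list with `id` and
#'   `models` (each model an atom-level data.frame).
#' @export
read_pdb <- function(path, include_hetero = TRUE) {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  if (!any(startsWith(rec, "ATOM"))) {
    stop("no ATOM records found in PDB file: ", path)
  }
  starts <- which(startsWith(rec, "MODEL"))
  models <- list()
  if (length(starts) == 0) {
    m <- .parse_block(lines, 1L, include_hetero)
    if (!is.null(m)) models <- list(m)
  } else {
    ends <- which(startsWith(rec, "ENDMDL"))
    for (k in seq_along(starts)) {
      to <- if (k <= length(ends)) ends[k] - 1L else length(lines)
      mid <- suppressWarnings(as.integer(substr(lines[starts[k]], 7, 20)))
      if (is.na(mid)) mid <- k
      m <- .parse_block(lines[(starts[k] + 1L):to], mid, include_hetero)
      if (!is.null(m)) models[[length(models) + 1L]] <- m
    }
  }
  if (length(models) == 0) {
    stop("no residues survived parsing of PDB file: ", path)
  }
  if (length(models) > 1) {
    keys <- lapply(models, function(m) {
      rt <- residue_table(m)
      paste(rt$chain, rt$resno, rt$icode, rt$resid, sep = "\r")
    })
    same <- vapply(keys[-1], function(k) identical(sort(k), sort(keys[[1]])),
                   logical(1))
    if (!all(same)) {
      warning("models of '", path,
              "' do not all share the same residue keys; ",
              "treating as a heterogeneous multi-model file")
    }
  }
  new_rin_structure(tools::file_path_sans_ext(basename(path)), models)
}

# Format one model's records through bio3d (no END line)
.format_model <- function(m) {
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp))
  bio3d::write.pdb(file = tmp,
                   xyz = as.numeric(t(as.matrix(m[, c("x", "y", "z")]))),
                   type = ifelse(m$het, "HETATM", "ATOM"),
                   resno = m$resno, resid = m$resid, chain = m$chain,
                   insert = m$icode, elety = m$elety, elesy = m$elesy,
                   o = rep(1, nrow(m)), b = rep(0, nrow(m)), end = FALSE)
  readLines(tmp, warn = FALSE)
}

#' Write a structure as a PDB file
#'
#' Multi-model structures are written with MODEL/ENDMDL wrappers.
#' Coordinates use the PDB fixed-column precision (3 decimals), so
#' `read_pdb(write_pdb(s))` reproduces residue keys, atom names and
#' coordinates to 3 d.p.
#'
#' @param structure An `rin_structure`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(structure, path) {
  stopifnot(inherits(structure, "rin_structure"))
  models <- structure$models
  if (length(models) == 1) {
    out <- c(.format_model(models[[1]]), "END")
  } else {
    out <- unlist(lapply(seq_along(models), function(k) {
      c(sprintf("MODEL     %4d", attr(models[[k]], "model_id")),
        .format_model(models[[k]]), "ENDMDL")
    }))
    out <- c(out, "END")
  }
  writeLines(out, path)
  invisible(path)
}

#' Select one conformer from a structure
#'
#' @param structure An `rin_structure`.
#' @param model_id Model number as recorded in the MODEL record.
#' @return The matching model (atom table).
#' @export
select_model <- function(structure, model_id) {
  stopifnot(inherits(structure, "rin_structure"))
  ids <- vapply(structure$models, attr, integer(1), "model_id")
  i <- which(ids == model_id)
  if (length(i) != 1) {
    stop("model ", model_id, " not found; available models: ",
         paste(ids, collapse = ", "))
  }
  structure$models[[i]]
}

#' Truncate one residue's side chain to alanine
#'
#' In-silico point mutation by PDB editing: the target residue keeps
#' exactly the intersection of its atoms with N, CA, C, O, CB (glycine
#' gains no CB), its type becomes ALA, and no coordinate of any retained
#' atom changes. Backbone atoms N, CA, C and O must be present.
#'
#' @param model A model (atom table).
#' @param chain Chain identifier of the target residue.
#' @param index Residue serial number of the target residue.
#' @param icode Insertion code (default blank).
#' @return A new model with the mutation applied.
#' @export
mutate_to_alanine <- function(model, chain, index, icode = "") {
  stopifnot(inherits(model, "rin_model"))
  rows <- which(model$chain == chain & model$resno == index &
                  model$icode == icode)
  if (length(rows) == 0) {
    stop("residue ", chain, ":", index, icode, " not found in model")
  }
  names <- model$elety[rows]
  missing <- setdiff(.backbone_atoms, names)
  if (length(missing) > 0) {
    stop("residue ", chain, ":", index, icode,
         " lacks backbone atom(s): ", paste(missing, collapse = ", "))
  }
  drop <- rows[!(names %in% .ala_atoms)]
  out <- model
  out$resid[rows] <- "ALA"
  if (length(drop) > 0) out <- out[-drop, , drop = FALSE]
  new_rin_model(out, model_id = attr(model, "model_id"))
}

#' Generate alanine point mutants of a model
#'
#' One single-site mutant per entry of `sites`, each labelled
#' `"<wild-type one-letter><index>A"` (e.g. `"N322A"`); with
#' `combine = TRUE`, one additional mutant carrying every site, labelled
#' by joining the single labels with `"+"` unless `combined_label` is
#' given. Multi-site mutation is order-independent.
#'
#' @param model A model (atom table).
#' @param sites data.frame with columns `chain` and `index` (optional
#'   `icode`), one row per mutation site.
#' @param combine Also produce the all-sites combined mutant?
#' @param combined_label Optional explicit label for the combined mutant.
#' @return Named list of mutant models.
#' @export
list_point_mutants <- function(model, sites, combine = FALSE,
                               combined_label = NULL) {
  sites <- as.data.frame(sites)
  if (nrow(sites) == 0) return(list())
  if (is.null(sites$icode)) sites$icode <- ""
  skey <- paste(sites$chain, sites$index, sites$icode)
  if (anyDuplicated(skey)) stop("duplicate mutation sites: ",
                                paste(skey[duplicated(skey)], collapse = "; "))
  rt <- residue_table(model)
  labels <- character(nrow(sites))
  mutants <- vector("list", nrow(sites))
  for (i in seq_len(nrow(sites))) {
    hit <- rt$chain == sites$chain[i] & rt$resno == sites$index[i] &
      rt$icode == sites$icode[i]
    if (!any(hit)) stop("residue ", sites$chain[i], ":", sites$index[i],
                        sites$icode[i], " not found in model")
    wt1 <- suppressWarnings(bio3d::aa321(rt$resid[hit][1]))
    if (is.na(wt1)) wt1 <- "X"
    labels[i] <- paste0(wt1, sites$index[i], sites$icode[i], "A")
    mutants[[i]] <- mutate_to_alanine(model, sites$chain[i], sites$index[i],
                                      sites$icode[i])
  }
  names(mutants) <- labels
  if (combine && nrow(sites) > 1) {
    combined <- model
    for (i in seq_len(nrow(sites))) {
      combined <- mutate_to_alanine(combined, sites$chain[i], sites$index[i],
                                    sites$icode[i])
    }
    lab <- if (is.null(combined_label)) paste(labels, collapse = "+") else combined_label
    mutants[[lab]] <- combined
  }
  mutants
}
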