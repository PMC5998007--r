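# Deterministic synthetic structures shaped like the two study designs:
# an N-conformer NMR-style ensemble of one chain, and a wild-type chain
# plus asparagine->alanine point mutants with an optional ligand. All
# geometry is an ideal poly-alanine alpha-helix (rise 1.5 A per residue,
# 100 degrees per residue, 2.3 A helix radius) carrying backbone + CB
# only, plus ideal-geometry ASN side chains at designated sites — tiny,
# but enough to exercise heavy-atom contacts and side-chain truncation.

.helix_rise <- 1.5
.helix_turn <- 100 * pi / 180
.helix_radius <- 2.3

.unit <- function(v) v / sqrt(sum(v^2))
.cross <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                           a[3] * b[1] - a[1] * b[3],
                           a[1] * b[2] - a[2] * b[1])

# local frame at residue i: tangent along the helix, outward radial,
# binormal completing the triad
.helix_frames <- function(n) {
  th <- (seq_len(n) - 1) * .helix_turn
  ca <- cbind(.helix_radius * cos(th), .helix_radius * sin(th),
              .helix_rise * seq_len(n))
  lapply(seq_len(n), function(i) {
    lo <- max(1L, i - 1L); hi <- min(n, i + 1L)
    t <- .unit(ca[hi, ] - ca[lo, ])
    r <- .unit(c(cos(th[i]), sin(th[i]), 0))
    b <- .unit(.cross(t, r))
    list(ca = ca[i, ], t = t, out = r, b = b)
  })
}

.residue_atoms <- function(fr, res_type) {
  ca <- fr$ca; t <- fr$t; out <- fr$out; b <- fr$b
  pos <- list(
    N  = ca - 1.10 * t - 0.55 * out + 0.45 * b,
    CA = ca,
    C  = ca + 1.10 * t - 0.45 * out - 0.45 * b,
    CB = ca + 1.53 * .unit(0.90 * out + 0.30 * b - 0.30 * t))
  pos$O <- pos$C + 1.23 * .unit(-0.60 * out - 0.70 * b + 0.20 * t)
  if (res_type == "ASN") {
    u <- .unit(0.90 * out + 0.40 * t)
    pos$CG  <- pos$CB + 1.52 * u
    pos$OD1 <- pos$CG + 1.23 * .unit(u + 0.8 * b)
    pos$ND2 <- pos$CG + 1.33 * .unit(u - 0.8 * b)
  }
  order <- c("N", "CA", "C", "O", "CB", "CG", "OD1", "ND2")
  nm <- order[order %in% names(pos)]
  el <- substr(nm, 1, 1)
  m <- do.call(rbind, pos[nm])
  data.frame(elety = nm, elesy = el, x = m[, 1], y = m[, 2], z = m[, 3],
             stringsAsFactors = FALSE)
}

.helix_model <- function(n_residues, asn_sites = integer(0), chain = "A",
                         model_id = 1L) {
  frames <- .helix_frames(n_residues)
  parts <- lapply(seq_len(n_residues), function(i) {
    rt <- if (i %in% asn_sites) "ASN" else "ALA"
    a <- .residue_atoms(frames[[i]], rt)
    data.frame(chain = chain, resno = i, icode = "", resid = rt,
               elety = a$elety, elesy = a$elesy, x = a$x, y = a$y, z = a$z,
               het = FALSE, stringsAsFactors = FALSE)
  })
  new_rin_model(do.call(rbind, parts), model_id = model_id)
}

# small rigid hetero group parked one contact-distance off the helix
# midpoint, to exercise ligand inclusion/exclusion
.ligand_atoms <- function(n_residues, chain = "A") {
  zmid <- .helix_rise * (n_residues + 1) / 2
  base <- c(.helix_radius + 3.5, 0, zmid)
  offs <- rbind(C1 = c(0, 0, 0), C2 = c(1.5, 0, 0), O1 = c(0.7, 1.2, 0))
  data.frame(chain = chain, resno = n_residues + 10L, icode = "",
             resid = "LIG", elety = rownames(offs),
             elesy = substr(rownames(offs), 1, 1),
             x = base[1] + offs[, 1], y = base[2] + offs[, 2],
             z = base[3] + offs[, 3], het = TRUE, stringsAsFactors = FALSE)
}

#' Ideal poly-alanine helix structure
#'
#' Single chain A, residues 1..n, backbone (N, CA, C, O) plus CB on an
#' ideal alpha-helix (1.5 A rise, 100 degrees twist, 2.3 A radius), so
#' consecutive CA-CA distances are ~3.8 A. Fully deterministic.
#'
#' @param n_residues Number of residues (>= 3).
#' @param seed Accepted for interface symmetry with the noisy
#'   generators; the ideal helix does not use randomness.
#' @return An `rin_structure` with one model.
#' @export
make_helix <- function(n_residues, seed = 1L) {
  if (n_residues < 3) stop("a helix fixture needs at least 3 residues")
  new_rin_structure(sprintf("helix%d", n_residues),
                    list(.helix_model(n_residues)))
}

#' Synthetic NMR-style conformer ensemble
#'
#' `n_models` copies of the ideal helix, each perturbed by iid Gaussian
#' coordinate noise (sd `noise_sigma` angstroms) with a per-model RNG
#' stream derived from `seed`, so all models share identical residue
#' keys and the whole structure is reproducible from the seed.
#'
#' @param n_residues Residues per model (>= 3).
#' @param n_models Number of conformers (>= 1).
#' @param noise_sigma Coordinate noise sd in angstroms (0 = identical
#'   models).
#' @param seed Integer seed; fully determines the output.
#' @return An `rin_structure` with `n_models` models.
#' @export
make_ensemble <- function(n_residues = 30, n_models = 10, noise_sigma = 0.5,
                          seed = 1L) {
  stopifnot(n_models >= 1, noise_sigma >= 0)
  base <- .helix_model(n_residues)
  models <- lapply(seq_len(n_models), function(m) {
    out <- base
    if (noise_sigma > 0) {
      set.seed((as.integer(seed) %% 1000000L) * 1009L + m)
      xyz <- as.matrix(out[, c("x", "y", "z")])
      xyz <- xyz + matrix(stats::rnorm(length(xyz), sd = noise_sigma),
                          ncol = 3)
      out$x <- xyz[, 1]; out$y <- xyz[, 2]; out$z <- xyz[, 3]
    }
    attr(out, "model_id") <- m
    out
  })
  new_rin_structure(sprintf("ensemble%dx%d", n_residues, n_models), models)
}

#' Synthetic wild-type + alanine-mutant structure set
#'
#' A wild-type helix with ideal-geometry ASN side chains at `sites`
#' (chain A residue numbers), plus one single alanine mutant per site
#' and, when `combine = TRUE` and there are several sites, one combined
#' mutant carrying them all — the wild-type-plus-mutant-panel design
#' used for alanine-scanning comparisons. An optional rigid HETATM
#' ligand exercises ligand exclusion downstream.
#'
#' @param n_residues Residues in the helix (>= 3).
#' @param sites Integer vector of ASN positions to mutate (chain A).
#' @param combine Also generate the all-sites combined mutant?
#' @param ligand Append a small HETATM ligand to every structure?
#' @param seed Accepted for interface symmetry; the set is deterministic.
#' @return Named list of `rin_structure`s: `WT` first, then one per
#'   mutant label (e.g. `"N7A"`), then the combined mutant.
#' @export
make_mutant_set <- function(n_residues = 30, sites = integer(0),
                            combine = TRUE, ligand = FALSE, seed = 1L) {
  if (length(sites) > 0 &&
      (any(sites < 1) || any(sites > n_residues) || anyDuplicated(sites))) {
    stop("mutation sites must be distinct residue numbers in 1..",
         n_residues)
  }
  wt <- .helix_model(n_residues, asn_sites = sites)
  lig <- if (ligand) .ligand_atoms(n_residues) else NULL
  wrap <- function(m, id) {
    if (!is.null(lig)) m <- new_rin_model(rbind(as.data.frame(m), lig),
                                          model_id = attr(m, "model_id"))
    new_rin_structure(id, list(m))
  }
  out <- list(WT = wrap(wt, "WT"))
  if (length(sites) > 0) {
    muts <- list_point_mutants(wt, data.frame(chain = "A", index = sites),
                               combine = combine)
    for (lab in names(muts)) out[[lab]] <- wrap(muts[[lab]], lab)
  }
  out
}
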