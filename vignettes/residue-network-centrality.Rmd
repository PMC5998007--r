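---
title: "Comparing central residues across conformers and mutants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing central residues across conformers and mutants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rintools)
```

## The problem

A protein structure can be abstracted into a residue interaction network
(RIN): amino acids are nodes, detected inter-residue contacts are edges.
Network centrality then gives a residue-level readout of structural
importance — residues whose removal stretches the network, or that sit on
many shortest paths, are frequently the ones critical for folding,
function or allostery, and make good mutagenesis targets. Two comparison
settings come up constantly in practice: the conformers of an NMR
ensemble (is a residue central in every conformer, or only in some?) and
a wild-type structure against a panel of point mutants (which mutations
reshuffle the central residues, and how does each mutation change the
predicted backbone flexibility?). `rintools` implements the full
pipeline for both: PDB in, RINs, three centrality analyses with
Z-scores, flexibility scores, and cross-network recap tables out.

## From structure to network

`read_pdb()` parses standard fixed-column PDB, one model per
MODEL/ENDMDL block. Water is always removed; other HETATM residues
(ligands, cofactors) are kept with a hetero flag or dropped wholesale
with `include_hetero = FALSE`, which is how ligand-free networks are
built for mutant panels. Alternate locations collapse to the
highest-occupancy copy (ties: first in file), and residue numbering is
taken verbatim from the file, so a residue numbered 322 stays 322 in
every table downstream.

`build_rin()` turns one model into an undirected graph: two residues are
in contact when any heavy-atom pair lies within `cutoff` angstroms
(default 5.0), with same-chain pairs additionally required to be at
least `min_seq_sep` apart in sequence (default 1, i.e. sequence
neighbours count). Hydrogens are ignored even when present — NMR entries
deposit them, X-ray entries mostly do not, and a heavy-atom criterion
keeps the two comparable. Both knobs are exposed because there is no
single canonical contact definition; 5.0 Å over heavy atoms is a common,
reproducible middle ground, and the cutoff is deliberately the only
geometric parameter so that edge sets grow monotonically with it. RINs
built elsewhere can be imported with `read_rin()` as long as the node
table carries the three required columns `ResType` (3-letter code),
`ResIndex` (residue serial number) and `ResChain` (chain id).

Node identity throughout is `"<chain>:<index><icode>:<restype>"`, and
cross-network joins use only chain + index (+ insertion code): that is
what lets an N322A mutant's row land on the wild type's row 322, with
the type change surfaced as an annotation rather than a mismatch.

## The three centrality analyses

For a network \(G\) with average shortest path length
\(\mathrm{ASPL}(G)\) (mean unweighted shortest-path length over
connected unordered pairs), the residue centrality analysis (RCA) scores
each node \(v\) by

\[ \Delta_v = \mathrm{ASPL}(G - v) - \mathrm{ASPL}(G), \]

then standardizes the \(\Delta_v\) across the network to Z-scores
\(z_v = (\Delta_v - \bar\Delta)/\sigma_\Delta\). High \(z_v\) means
removing the residue lengthens paths network-wide. BCA and CCA are the
classical betweenness and closeness centralities, each followed by the
same Z-scoring. By convention Z ≥ 2 is treated as "relevant" (the
threshold is an exposed parameter, default 2.0).

Choices the definitions leave open, and what this package does:

* **Disconnection under removal.** ASPL is defined over connected pairs
  only, with the empty case scored 0. Removing a cut vertex therefore
  *shrinks* the pair set instead of producing infinities, which can make
  its raw ΔASPL deceptively small; RCA flags such nodes in a
  `disconnects` column (true iff removal increases the component count).
  An alternative `mode = "harmonic"` scores nodes by the drop in network
  efficiency (mean of 1/d with disconnected pairs contributing 0, sign
  flipped so higher is still more central), which penalizes
  fragmentation smoothly. The connected-pairs mode is the default
  because it is the transparent reading of "ASPL change".
* **Z-score denominator.** The population standard deviation, since the
  network's node set is the entire population being standardized; a
  zero-variance score vector (e.g. any vertex-transitive graph) yields
  all-zero Z by convention rather than 0/0.
* **Betweenness normalization.** Raw betweenness is left unnormalized.
  Z-scores are invariant to positive scaling, so this choice cannot
  affect the Z column (asserted by a test).
* **Closeness.** Component-local: reachable-count divided by summed
  distance, isolated nodes scoring 0. Closeness Z-scores rarely reach 2
  on compact protein networks — their distribution is too narrow — so
  the raw closeness column is always reported alongside and is the
  better column to rank by if closeness is the measurement of interest.

All three implementations are cross-checked in the test suite against
brute-force oracles written independently of the graph library:
all-pairs breadth-first search for ASPL/RCA/closeness, combinatorial
path counting plus (at small sizes) exhaustive shortest-path
enumeration for betweenness, at tolerance 1e-9 over a fixed seeded set
of 50 random connected graphs up to 40 nodes.

## Alanine mutagenesis in silico

`mutate_to_alanine()` edits the structure the way one edits a PDB file
by hand: the target residue's atom set is intersected with
{N, CA, C, O, CB}, its type is renamed ALA, and no coordinate changes —
side-chain truncation at Cβ, with no rebuilding, repacking or
minimization. Truncation is deterministic, exactly testable, and does
not pretend to model relaxation; glycine targets gain no Cβ. Multi-site
mutants commute (any application order gives the identical structure),
which `list_point_mutants()` relies on to produce the
five-singles-plus-combined panel shape in one call. Combined mutants
are labelled by joining the single labels with `+` unless an explicit
label is supplied.

## Backbone flexibility

`rin_sequence()` rebuilds the chain sequence from the RIN sorted by
residue index. Residues missing from the structure are *skipped*, never
gap-filled — the index map carries the original serial numbers so S²
scores line up with the structure, and a plotted trace simply has a gap
where density was missing. `predict_flexibility()` scores the sequence
with one S² value per position in [0, 1] (higher = more rigid backbone)
from one of two backends:

* `remote` speaks a DynaMine-style JSON API (sequence in the request
  body, per-position predictions in the response; both list- and
  map-shaped payloads are tolerated because deployments differ). It
  requires the network and is never exercised by the test suite.
* `mock` is a pure deterministic local function: mean Kyte–Doolittle
  hydropathy over a ±2-residue window, mapped affinely onto
  [0.30, 0.95]. It is **not** a flexibility predictor — it exists so
  that the entire pipeline, including mutation-locality behaviour
  (a point substitution can only move scores within the window radius),
  runs reproducibly offline. Treat its values as plumbing, not biology.

`plot_flexibility()` overlays one trace per network with red vertical
markers at mutated positions and a grey horizontal band for the
context-dependent S² zone. The band defaults to [0.69, 0.80]; published
flexibility plots draw such a zone but the bounds are a display
convention, so they are configurable arguments, not constants.

## Recap tables and styles

`run_batch()` + `recap()` produce the comparison artifact: rows are the
union of residues across networks joined on chain + index, columns are
networks, cells are Z-scores (or S² via `flexibility_table()`). Rows
sort by descending score in the *first* network's column — the first
conformer, or the wild type — with empty cells last and ties broken by
ascending residue index, so the table is deterministic. Cells at or
above the threshold are flagged relevant and rendered with a pink
background in the HTML output; `style_attributes()` exports per-node
color (linear yellow→red ramp over Z ∈ [2, 4], clipped, neutral grey
below), node size and label size (monotone linear ramps) for external
network viewers.

## Synthetic structures and what they do (not) show

All tests and the acceptance script run on generated structures, shaped
like the two study designs: `make_ensemble()` (an N-model single-chain
ensemble, default 10 models, Gaussian coordinate noise of sd 0.5 Å
around an ideal helix, per-model seeded streams) and
`make_mutant_set()` (wild type with ideal-geometry ASN side chains at
chosen sites, the single alanine mutants, the combined mutant, and an
optional rigid ligand to exercise hetero exclusion). The geometry is an
ideal poly-alanine α-helix — 1.5 Å rise, 100° twist, 2.3 Å radius,
backbone + Cβ — so consecutive Cα–Cα distances are the physical
~3.8 Å and contact networks are protein-like in degree. The 0.5 Å noise
default gives conformer RINs that overlap heavily but differ in edge
detail, qualitatively like a well-converged NMR bundle; 25–30 residues
keeps every test and the acceptance run comfortably fast while leaving
the graphs large enough for non-trivial path structure.

What passing on these fixtures demonstrates: the graph math is exact,
the conventions are honoured end-to-end, mutation and ligand handling
are correct, and every table has the documented shape and ordering.
What it does not demonstrate: anything about real proteins — a
noise-perturbed helix has no tertiary fold, no long-range contact order
and no real side-chain packing, and the mock S² backend has no
predictive value. Conclusions about a real system require real PDB
input and, for flexibility, the remote backend.

## Numerical and degenerate-input conventions

* Zero-variance raw scores → all-zero Z (threshold 1e-12 on the
  population sd).
* ASPL of an edgeless graph is 0 (documented convention); ASPL needs
  ≥ 2 nodes, centrality ≥ 3.
* Isolated nodes: closeness 0; they stay in every node table.
* Edge distances are carried as metadata only — all path computations
  are unweighted.
* Ties everywhere break by ascending residue index, insertion codes
  ordering alphabetically after their base index.

## Command line and service

The installed `rintools` script drives the same functions from a shell
(`build`, `mutate`, `centrality`, `dynamine`, `recap`, `serve`), logging
parameters and package version per run. `serve()` exposes the two-command
POST API used by Cytoscape-side automation
(`/v1/commands/rinspector/centrality` with a method name in the body,
`/v1/commands/rinspector/dynamine` with a chain id), answering
`{"data": {node_id: score, ...}, "errors": []}` on success and an empty
`data` with a populated `errors` list on failure. The handler is a pure
function (`handle_command()`), so the contract is testable without
sockets; the socket layer itself is a minimal blocking HTTP loop meant
for localhost use, default port 1234. Service responses key scores by
RIN node ids rather than any session-specific numeric ids, so they are
meaningful outside the originating session.

## Known limitations

Contact detection is purely geometric (no interaction typing, no
solvent-accessibility pruning); only alanine substitutions are
implemented; mmCIF is not read; RCA is O(n · (n + m)) BFS work per node
and is the slow analysis on large networks — for many large RINs, run
BCA/CCA first and reserve RCA for the networks that matter.
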