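# Backbone-flexibility (S2) integration: build the chain sequence from a
# RIN (missing residues skipped, never interpolated), score it with a
# DynaMine-compatible JSON backend or a deterministic offline mock, and
# key the scores back to residue serial numbers.

# Kyte-Doolittle hydropathy, used only by the offline mock
.kd <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
         E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
         M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
         Y = -1.3, V = 4.2, X = 0)

.mock_window <- 2L     # mock smoothing half-width (residues)
.mock_range <- c(0.30, 0.95)

#' Chain sequence of a RIN
#'
#' Residues of one chain sorted by (ResIndex, icode), converted to
#' one-letter code (unknown types map to `"X"`). Residues missing from
#' the RIN are simply skipped — the index map records which serial
#' numbers each sequence position corresponds to, and gaps stay gaps.
#'
#' @param rin A `rin` object.
#' @param chain Chain identifier.
#' @return List with `sequence` (one-letter string) and `index_map`
#'   (integer ResIndex per position).
#' @export
rin_sequence <- function(rin, chain) {
  stopifnot(inherits(rin, "rin"))
  avail <- sort(unique(rin$nodes$ResChain))
  if (!(chain %in% avail)) {
    stop("chain '", chain, "' not present in RIN; available chains: ",
         paste(avail, collapse = ", "))
  }
  sel <- rin$nodes[rin$nodes$ResChain == chain, , drop = FALSE]
  sel <- sel[order(sel$ResIndex, sel$icode), , drop = FALSE]
  one <- suppressWarnings(bio3d::aa321(sel$ResType))
  one[is.na(one) | !(one %in% names(.kd))] <- "X"
  list(sequence = paste(one, collapse = ""),
       index_map = as.integer(sel$ResIndex))
}

# Deterministic stand-in scorer: mean Kyte-Doolittle hydropathy over a
# +/-2-residue window, mapped affinely onto [0.30, 0.95]. Local (a point
# mutation can only move scores within the window radius), deterministic
# and mutation-sensitive; it is NOT a flexibility predictor.
.mock_s2 <- function(sequence) {
  aa <- strsplit(sequence, "")[[1]]
  h <- unname(.kd[aa])
  n <- length(h)
  s <- vapply(seq_len(n), function(i) {
    w <- max(1L, i - .mock_window):min(n, i + .mock_window)
    mean(h[w])
  }, numeric(1))
  lo <- .mock_range[1]; hi <- .mock_range[2]
  pmin(hi, pmax(lo, lo + (hi - lo) * (s + 4.5) / 9))
}

# DynaMine-style JSON client over the system curl binary. Tolerates both
# list-shaped ([s2, s2, ...]) and map-shaped ({"1": s2, ...} or
# per-residue records) prediction payloads.
.remote_s2 <- function(sequence, url, timeout = 30) {
  body <- jsonlite::toJSON(list(sequence = sequence), auto_unbox = TRUE)
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  status <- system2("curl",
                    c("-sS", "-m", as.character(timeout), "-X", "POST",
                      "-H", shQuote("Content-Type: application/json"),
                      "-d", shQuote(body), "-o", shQuote(tmp), shQuote(url)),
                    stdout = TRUE, stderr = TRUE)
  code <- attr(status, "status")
  if (!is.null(code) && code != 0) {
    stop("flexibility backend request failed: ",
         paste(status, collapse = " "))
  }
  resp <- jsonlite::fromJSON(tmp, simplifyVector = TRUE)
  pred <- resp
  for (key in c("predictions", "backbone", "results", "data", "s2")) {
    if (is.list(pred) && !is.null(pred[[key]])) pred <- pred[[key]]
  }
  vals <- if (is.numeric(pred)) as.numeric(pred)
  else if (is.list(pred)) as.numeric(unlist(pred, use.names = FALSE))
  else stop("unrecognized flexibility backend response shape")
  if (length(vals) != nchar(sequence)) {
    stop("flexibility backend returned ", length(vals),
         " scores for a sequence of length ", nchar(sequence))
  }
  if (any(vals < 0 | vals > 1)) {
    warning("remote S2 scores outside [0, 1] were clipped")
    vals <- pmin(1, pmax(0, vals))
  }
  vals
}

#' Per-residue backbone flexibility (S2) scores
#'
#' Scores one chain sequence position-by-position and re-keys the scores
#' by the residue serial numbers in `index_map`. The `"mock"` backend is
#' a pure deterministic function of a window around each position
#' (windowed mean hydropathy mapped into \[0.30, 0.95\]), suitable for
#' offline pipelines and tests; the `"remote"` backend speaks a
#' DynaMine-style JSON API. Higher S2 means the backbone is predicted
#' more rigid.
#'
#' @param sequence One-letter amino-acid string (standard letters or X).
#' @param index_map Integer vector, one ResIndex per sequence position.
#' @param backend `"mock"` (default, offline) or `"remote"`.
#' @param url Remote endpoint (remote backend only).
#' @param chain Optional chain label stored on the result.
#' @return A `flexibility_result` data.frame (ResIndex, aa, s2) with
#'   attributes `backend` and `chain`.
#' @export
predict_flexibility <- function(sequence, index_map,
                                backend = c("mock", "remote"),
                                url = "http://localhost:8000/dynamine",
                                chain = NA_character_) {
  backend <- match.arg(backend)
  if (!is.character(sequence) || length(sequence) != 1 || nchar(sequence) == 0) {
    stop("sequence must be a non-empty one-letter string")
  }
  aa <- strsplit(sequence, "")[[1]]
  bad <- setdiff(unique(aa), names(.kd))
  if (length(bad) > 0) {
    stop("sequence contains non-standard letter(s): ",
         paste(bad, collapse = ", "))
  }
  if (length(index_map) != nchar(sequence)) {
    stop("index_map length must equal the sequence length")
  }
  s2 <- switch(backend, mock = .mock_s2(sequence),
               remote = .remote_s2(sequence, url))
  structure(data.frame(ResIndex = as.integer(index_map), aa = aa,
                       s2 = as.numeric(s2), stringsAsFactors = FALSE),
            backend = backend, chain = chain,
            class = c("flexibility_result", "data.frame"))
}

#' Flexibility scores for one chain of a RIN
#'
#' Convenience wrapper: [rin_sequence()] then [predict_flexibility()].
#'
#' @inheritParams rin_sequence
#' @inheritParams predict_flexibility
#' @return A `flexibility_result`.
#' @export
rin_flexibility <- function(rin, chain, backend = c("mock", "remote"),
                            url = "http://localhost:8000/dynamine") {
  sq <- rin_sequence(rin, chain)
  predict_flexibility(sq$sequence, sq$index_map, backend = backend,
                      url = url, chain = chain)
}

#' @export
print.flexibility_result <- function(x, ...) {
  cat(sprintf("S2 flexibility (%s backend), chain %s: %d residues, S2 in [%.3f, %.3f]\n",
              attr(x, "backend"), attr(x, "chain"), nrow(x),
              min(x$s2), max(x$s2)))
  invisible(x)
}

#' Recap table of S2 scores across networks
#'
#' Rows are the union of residue serial numbers across all results
#' (sorted ascending), columns are the network labels, cells the S2
#' scores (NA where a network lacks that residue). All results must
#' share one chain.
#'
#' @param results Named list of `flexibility_result` objects (names are
#'   the network labels).
#' @return A `recap_table` with `kind = "s2"`; see [recap()].
#' @export
flexibility_table <- function(results) {
  stopifnot(length(results) >= 1, !is.null(names(results)))
  chains <- unique(vapply(results, attr, character(1), "chain"))
  chains <- chains[!is.na(chains)]
  if (length(chains) > 1) {
    stop("flexibility results span multiple chains: ",
         paste(chains, collapse = ", "))
  }
  idx <- sort(unique(unlist(lapply(results, `[[`, "ResIndex"))))
  vals <- sapply(results, function(r) r$s2[match(idx, r$ResIndex)])
  vals <- matrix(vals, nrow = length(idx),
                 dimnames = list(NULL, names(results)))
  aa_ref <- results[[1]]$aa[match(idx, results[[1]]$ResIndex)]
  rows <- data.frame(ResChain = if (length(chains)) chains else NA_character_,
                     ResIndex = idx, icode = "",
                     ResType = ifelse(is.na(aa_ref), "", aa_ref),
                     stringsAsFactors = FALSE)
  new_recap_table(rows, vals, threshold = NA_real_, kind = "s2",
                  sort_column = NA_character_)
}

#' Plot S2 flexibility traces across networks
#'
#' One trace per network against the residue serial number, with an
#' optional shaded context-dependent S2 band and vertical markers at
#' mutated positions.
#'
#' @param table A `recap_table` with `kind = "s2"` from
#'   [flexibility_table()].
#' @param sites Optional integer vector of mutated ResIndex positions
#'   (red vertical lines).
#' @param band Numeric length-2: the context-dependent S2 zone (grey
#'   band); default `c(0.69, 0.80)`.
#' @param ... Passed to [graphics::matplot()].
#' @return The table, invisibly.
#' @export
plot_flexibility <- function(table, sites = NULL, band = c(0.69, 0.80), ...) {
  stopifnot(inherits(table, "recap_table"), attr(table, "kind") == "s2")
  x <- table$rows$ResIndex
  graphics::matplot(x, table$values, type = "l", lty = 1,
                    col = seq_len(ncol(table$values)),
                    xlab = "sequence index", ylab = expression(S^2),
                    ylim = c(0, 1), ...)
  if (!is.null(band)) graphics::abline(h = band, col = "grey50", lty = 1)
  if (!is.null(sites)) graphics::abline(v = sites, col = "red", lty = 1)
  graphics::legend("bottomright", legend = colnames(table$values),
                   col = seq_len(ncol(table$values)), lty = 1, cex = 0.7,
                   bg = "white")
  invisible(table)
}
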