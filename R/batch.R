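# Batch runs over many RINs and the cross-network recap table: residues
# as rows (joined on chain + index so mutants align with the wild type),
# networks as columns, Z-scores (or S2) as cells, sorted by the first
# network with relevance flags at Z >= threshold.

new_recap_table <- function(rows, values, threshold = 2,
                            sort_column = colnames(values)[1],
                            kind = "zscore", annotations = NULL) {
  stopifnot(nrow(rows) == nrow(values))
  relevant <- if (is.na(threshold)) {
    matrix(FALSE, nrow(values), ncol(values), dimnames = dimnames(values))
  } else {
    !is.na(values) & values >= threshold
  }
  structure(list(rows = rows, labels = colnames(values), values = values,
                 relevant = relevant, annotations = annotations),
            threshold = threshold, sort_column = sort_column, kind = kind,
            class = "recap_table")
}

#' @export
print.recap_table <- function(x, n = 15, ...) {
  kind <- attr(x, "kind")
  cat(sprintf("Recap table (%s): %d residues x %d networks",
              kind, nrow(x$rows), length(x$labels)))
  if (!is.na(attr(x, "sort_column"))) {
    cat(sprintf(", sorted by '%s' descending", attr(x, "sort_column")))
  }
  if (!is.na(attr(x, "threshold"))) {
    cat(sprintf(", relevant at >= %.2g", attr(x, "threshold")))
  }
  cat("\n")
  df <- cbind(x$rows, round(x$values, 3))
  print(utils::head(df, n), row.names = FALSE)
  if (nrow(df) > n) cat("... (", nrow(df) - n, " more rows)\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.recap_table <- function(x, ...) {
  cbind(x$rows, as.data.frame(x$values, check.names = FALSE))
}

#' Run one centrality method over many RINs
#'
#' Each RIN is analysed independently, in order; a failure on any RIN
#' aborts the whole batch with the offending network's label in the
#' error message rather than silently skipping it.
#'
#' @param rins Named list of `rin` objects (names are network labels; a
#'   missing name falls back to the RIN's own name).
#' @param method One of `"RCA"`, `"BCA"`, `"CCA"`.
#' @param ... Passed to the method function (e.g. `mode` for RCA).
#' @return Named list of `centrality_result` objects, same order.
#' @export
run_batch <- function(rins, method, ...) {
  stopifnot(length(rins) >= 1)
  if (length(method) != 1 || !(method %in% .methods)) {
    stop("unknown centrality method '", paste(method, collapse = ","),
         "'; must be one of: ", paste(.methods, collapse = ", "))
  }
  labels <- names(rins)
  if (is.null(labels)) labels <- rep("", length(rins))
  fallback <- vapply(rins, function(r) r$name, character(1))
  labels <- ifelse(nzchar(labels), labels, fallback)
  out <- vector("list", length(rins))
  for (i in seq_along(rins)) {
    out[[i]] <- tryCatch(centrality(rins[[i]], method, ...),
                         error = function(e) {
                           stop("centrality failed on network '", labels[i],
                                "': ", conditionMessage(e), call. = FALSE)
                         })
  }
  names(out) <- labels
  out
}

#' Assemble the cross-network recap table of Z-scores
#'
#' Rows are joined on (ResChain, ResIndex, icode) across networks so a
#' mutated residue aligns with its wild-type position; the displayed
#' ResType comes from the first network that carries the residue, and a
#' per-cell annotation (e.g. `"ASN->ALA"`) marks networks whose type
#' differs. Rows are sorted by descending score in the first network's
#' column, empty cells last, ties broken by ascending ResIndex. Cells
#' present and `>= threshold` are flagged relevant.
#'
#' @param results Named list of `centrality_result` objects from
#'   [run_batch()].
#' @param threshold Relevance threshold on the Z-score (default 2).
#' @return A `recap_table`: list with `rows` (ResChain, ResIndex, icode,
#'   ResType), `labels`, `values` matrix, `relevant` mask and
#'   `annotations` matrix; attributes `threshold`, `sort_column`, `kind`.
#' @export
recap <- function(results, threshold = 2) {
  if (length(results) == 0) stop("recap requires at least one result")
  stopifnot(!is.null(names(results)), all(nzchar(names(results))))
  labels <- names(results)
  keys <- lapply(results, function(r) {
    paste(r$ResChain, r$ResIndex, r$icode, sep = "\r")
  })
  all_keys <- unique(unlist(keys))
  # reference residue info: first network that carries the key
  rows <- data.frame(ResChain = NA_character_, ResIndex = NA_integer_,
                     icode = NA_character_, ResType = NA_character_,
                     stringsAsFactors = FALSE)[rep(1, length(all_keys)), ]
  for (r in rev(results)) {
    i <- match(paste(r$ResChain, r$ResIndex, r$icode, sep = "\r"), all_keys)
    rows$ResChain[i] <- r$ResChain
    rows$ResIndex[i] <- r$ResIndex
    rows$icode[i] <- r$icode
    rows$ResType[i] <- r$ResType
  }
  values <- matrix(NA_real_, length(all_keys), length(labels),
                   dimnames = list(NULL, labels))
  annotations <- matrix(NA_character_, length(all_keys), length(labels),
                        dimnames = list(NULL, labels))
  for (j in seq_along(results)) {
    r <- results[[j]]
    i <- match(paste(r$ResChain, r$ResIndex, r$icode, sep = "\r"), all_keys)
    values[i, j] <- r$zscore
    differs <- r$ResType != rows$ResType[i]
    annotations[i[differs], j] <- paste0(rows$ResType[i][differs], "->",
                                         r$ResType[differs])
  }
  sort_key <- values[, 1]
  sort_key[is.na(sort_key)] <- -Inf
  o <- order(-sort_key, rows$ResIndex, rows$icode)
  rows <- rows[o, , drop = FALSE]
  rownames(rows) <- NULL
  new_recap_table(rows, values[o, , drop = FALSE], threshold = threshold,
                  sort_column = labels[1], kind = "zscore",
                  annotations = annotations[o, , drop = FALSE])
}

#' Visual-style attributes from Z-scores
#'
#' Colors interpolate linearly from yellow at `z_low` to red at `z_high`
#' (clipped: full red above `z_high`); nodes below `z_low` get a neutral
#' grey. Node size and label size are monotone linear ramps of the same
#' clipped Z, flat at the base value below `z_low`. The output table can
#' be fed to external network-visualization tools.
#'
#' @param result A `centrality_result`.
#' @param z_low Z-score mapped to pure yellow (default 2).
#' @param z_high Z-score mapped to pure red (default 4).
#' @return data.frame: node_id, zscore, color (hex), size, label_size.
#' @export
style_attributes <- function(result, z_low = 2, z_high = 4) {
  stopifnot(inherits(result, "centrality_result"))
  if (z_low >= z_high) stop("z_low must be strictly below z_high")
  z <- result$zscore
  t <- pmin(1, pmax(0, (z - z_low) / (z_high - z_low)))
  color <- ifelse(z < z_low, "#C8C8C8", grDevices::rgb(1, 1 - t, 0))
  data.frame(node_id = result$node_id, zscore = z, color = color,
             size = 30 + 40 * t, label_size = 12 + 12 * t,
             stringsAsFactors = FALSE)
}

#' Write a recap table as TSV and styled HTML
#'
#' The TSV holds the key columns (ResChain, ResIndex, icode, ResType)
#' followed by one column per network, rows in the table's sort order;
#' the HTML rendering highlights relevant cells with a pink background
#' and appends any type-mismatch annotation to the cell.
#'
#' @param table A `recap_table`.
#' @param prefix Output path prefix; writes `<prefix>.tsv` and
#'   `<prefix>.html`.
#' @param top Optional: render only the first `top` rows in the HTML
#'   (the TSV always carries all rows).
#' @return Character vector of written paths, invisibly.
#' @export
write_recap <- function(table, prefix, top = NULL) {
  stopifnot(inherits(table, "recap_table"))
  tsv <- paste0(prefix, ".tsv")
  html <- paste0(prefix, ".html")
  df <- as.data.frame(table)
  utils::write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)

  show <- if (is.null(top)) seq_len(nrow(df)) else
    seq_len(min(top, nrow(df)))
  esc <- function(s) gsub("<", "&lt;", gsub("&", "&amp;", s))
  header <- paste0("<tr>", paste0("<th>", esc(names(df)), "</th>",
                                  collapse = ""), "</tr>")
  body <- vapply(show, function(i) {
    keys <- paste0("<td>", esc(as.character(unlist(df[i, 1:4]))), "</td>",
                   collapse = "")
    cells <- vapply(seq_along(table$labels), function(j) {
      v <- table$values[i, j]
      txt <- if (is.na(v)) "" else sprintf("%.3f", v)
      if (!is.null(table$annotations) && !is.na(table$annotations[i, j])) {
        txt <- paste0(txt, " (", esc(table$annotations[i, j]), ")")
      }
      bg <- if (table$relevant[i, j]) " style=\"background-color:#FFC0CB\"" else ""
      paste0("<td", bg, ">", txt, "</td>")
    }, character(1))
    paste0("<tr>", keys, paste0(cells, collapse = ""), "</tr>")
  }, character(1))
  writeLines(c("<!DOCTYPE html><html><head><meta charset=\"utf-8\">",
               "<style>table{border-collapse:collapse}td,th{border:1px solid #999;padding:2px 6px;font-family:monospace}</style>",
               "</head><body><table>", header, body,
               "</table></body></html>"), html)
  invisible(c(tsv, html))
}

#' Read back a recap table written by [write_recap()]
#'
#' @param path Path to the `.tsv` file.
#' @param threshold Relevance threshold to re-apply (default 2).
#' @param kind `"zscore"` or `"s2"`.
#' @return A `recap_table` with the same rows, labels and values.
#' @export
read_recap <- function(path, threshold = 2, kind = "zscore") {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  keys <- c("ResChain", "ResIndex", "icode", "ResType")
  miss <- setdiff(keys, names(df))
  if (length(miss) > 0) {
    stop("recap TSV is missing column(s): ", paste(miss, collapse = ", "))
  }
  labels <- setdiff(names(df), keys)
  rows <- df[, keys]
  rows$icode[is.na(rows$icode)] <- ""
  rows$ResType <- as.character(rows$ResType)
  vals <- as.matrix(df[, labels, drop = FALSE])
  storage.mode(vals) <- "double"
  if (is.na(threshold)) kind <- "s2"
  new_recap_table(rows, vals, threshold = threshold,
                  sort_column = labels[1], kind = kind)
}
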