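# Localhost command service compatible with the Cytoscape-app command
# API: POST /v1/commands/rinspector/centrality (body: RCA/BCA/CCA) and
# POST /v1/commands/rinspector/dynamine (body: chain id), each answered
# with {"data": {node_id: score, ...}, "errors": []}. The handler is a
# pure function; serve() is a minimal HTTP/1.1 loop over base-R sockets,
# bound to the loopback interface only.

.service_paths <- c(centrality = "/v1/commands/rinspector/centrality",
                    dynamine = "/v1/commands/rinspector/dynamine")

#' Create a service session
#'
#' A session holds the RINs the service can analyse and the "current
#' network" selection commands operate on.
#'
#' @param rins Named list of `rin` objects.
#' @param current Label of the current network (default: first).
#' @param backend Flexibility backend, `"mock"` or `"remote"`.
#' @return A `rin_session` list.
#' @export
new_session <- function(rins, current = names(rins)[1], backend = "mock") {
  stopifnot(length(rins) >= 1, !is.null(names(rins)))
  structure(list(rins = rins, current = current, backend = backend),
            class = "rin_session")
}

.command_response <- function(data = NULL, errors = character(0)) {
  if (is.null(data) || length(data) == 0) {
    data <- stats::setNames(list(), character(0))
  } else {
    data <- as.list(data)
  }
  list(data = data, errors = as.list(errors))
}

# body may be a bare string, a JSON-encoded string, or a small JSON
# object carrying "method"/"chain"
.parse_body <- function(body) {
  body <- trimws(body)
  parsed <- tryCatch(jsonlite::fromJSON(body, simplifyVector = TRUE),
                     error = function(e) NULL)
  if (is.null(parsed)) return(gsub("^\"|\"$", "", body))
  if (is.list(parsed)) {
    for (key in c("method", "chain", "body")) {
      if (!is.null(parsed[[key]])) return(as.character(parsed[[key]]))
    }
    if (length(parsed) >= 1) return(as.character(parsed[[1]]))
    return("")
  }
  as.character(parsed[1])
}

#' Handle one service command
#'
#' Pure request handler shared by [serve()] and usable directly in
#' tests: runs the named command against the session's current network
#' and wraps the scores in the two-key response contract
#' (`data` mapping node id to score, `errors` empty on success; on
#' failure `data` is empty and `errors` carries the message).
#'
#' @param session A `rin_session`.
#' @param command `"centrality"` or `"dynamine"`.
#' @param body Request body: the method name (RCA/BCA/CCA) for
#'   centrality, the chain id for dynamine.
#' @return List with `status` (HTTP status code) and `response` (the
#'   `data`/`errors` list).
#' @export
handle_command <- function(session, command, body) {
  stopifnot(inherits(session, "rin_session"))
  fail <- function(msg, status = 400) {
    list(status = status, response = .command_response(errors = msg))
  }
  if (!(command %in% names(.service_paths))) {
    return(fail(paste0("unknown command '", command, "'"), status = 404))
  }
  if (is.null(session$current) || !(session$current %in% names(session$rins))) {
    return(fail("no current network selected"))
  }
  rin <- session$rins[[session$current]]
  arg <- .parse_body(body)
  if (command == "centrality") {
    if (!(arg %in% .methods)) {
      return(fail(paste0("unknown centrality method '", arg,
                         "'; must be one of: ",
                         paste(.methods, collapse = ", "))))
    }
    res <- tryCatch(centrality(rin, arg), error = function(e) e)
    if (inherits(res, "error")) return(fail(conditionMessage(res), 500))
    scores <- stats::setNames(as.list(res$zscore), res$node_id)
  } else {
    chains <- sort(unique(rin$nodes$ResChain))
    if (!(arg %in% chains)) {
      return(fail(paste0("chain '", arg, "' not present; available: ",
                         paste(chains, collapse = ", "))))
    }
    res <- tryCatch(rin_flexibility(rin, arg, backend = session$backend),
                    error = function(e) e)
    if (inherits(res, "error")) return(fail(conditionMessage(res), 500))
    sel <- rin$nodes[rin$nodes$ResChain == arg, , drop = FALSE]
    ids <- sel$node_id[match(res$ResIndex, sel$ResIndex)]
    scores <- stats::setNames(as.list(res$s2), ids)
  }
  list(status = 200, response = .command_response(data = scores))
}

.http_response <- function(status, body_json) {
  msg <- c(`200` = "OK", `400` = "Bad Request", `404` = "Not Found",
           `500` = "Internal Server Error")[as.character(status)]
  paste0("HTTP/1.1 ", status, " ", msg, "\r\n",
         "Content-Type: application/json\r\n",
         "Content-Length: ", nchar(body_json, type = "bytes"), "\r\n",
         "Connection: close\r\n\r\n", body_json)
}

#' Serve the command API over HTTP on localhost
#'
#' Minimal blocking HTTP/1.1 server answering POST requests on the two
#' command endpoints. Meant for local-machine use only (the usual
#' deployment queries `http://localhost:<port>`); it speaks just enough
#' HTTP for the command contract and offers no authentication.
#'
#' @param session A `rin_session`.
#' @param port TCP port (default 1234).
#' @param max_requests Stop after this many requests (default Inf; handy
#'   for scripted runs).
#' @return Number of requests served, invisibly.
#' @export
serve <- function(session, port = 1234, max_requests = Inf) {
  srv <- serverSocket(port)
  on.exit(close(srv), add = TRUE)
  served <- 0
  while (served < max_requests) {
    con <- socketAccept(srv, blocking = TRUE, open = "r+")
    req <- character(0)
    repeat {
      line <- readLines(con, n = 1, warn = FALSE)
      if (length(line) == 0 || !nzchar(trimws(line))) break
      req <- c(req, trimws(line))
    }
    if (length(req) == 0) { close(con); next }
    parts <- strsplit(req[1], " +")[[1]]
    path <- if (length(parts) >= 2) parts[2] else ""
    clen <- 0
    hl <- grep("^content-length:", tolower(req))
    if (length(hl) > 0) {
      clen <- suppressWarnings(as.integer(sub("^[^:]+: *", "", req[hl[1]])))
      if (is.na(clen)) clen <- 0
    }
    body <- if (clen > 0) readChar(con, clen, useBytes = TRUE) else ""
    cmd <- names(.service_paths)[match(path, .service_paths)]
    out <- if (is.na(cmd)) {
      list(status = 404,
           response = .command_response(errors = paste0("unknown path '",
                                                        path, "'")))
    } else {
      handle_command(session, cmd, body)
    }
    json <- jsonlite::toJSON(out$response, auto_unbox = TRUE, digits = NA,
                             null = "null")
    writeChar(.http_response(out$status, as.character(json)), con,
              eos = NULL)
    flush(con)
    close(con)
    served <- served + 1
  }
  invisible(served)
}
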