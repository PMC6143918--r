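# Graph data model and edge-list I/O.
#
# A weighted_graph stores an undirected weighted simple graph: a sorted
# character vector of node ids, an edge table with canonical (from < to)
# unordered pairs, and a named vector of self-loop weights. Node ids are
# opaque strings, ordered lexicographically wherever a deterministic order
# is needed.

#' Construct an undirected weighted graph
#'
#' @param nodes character vector of node identifiers (duplicates removed).
#' @param edges `data.frame` with columns `from`, `to`, `weight`
#'   (weight optional, defaults to 1). A row with `from == to` is turned
#'   into a self-loop. Duplicate unordered pairs are a validation error.
#' @param self_loops named numeric vector of self-loop weights.
#'
#' @return an object of class `weighted_graph` with fields `nodes`,
#'   `edges` (canonicalized so `from < to`, sorted), and `self_loops`.
#'
#' @details Edge weights must be non-negative. `nodes` may contain isolated
#'   nodes; every edge endpoint must appear in `nodes` (endpoints mentioned
#'   only in `edges` are added automatically).
#' @export
#' @examples
#' g <- weighted_graph(edges = data.frame(from = c("a", "b"),
#'                                        to = c("b", "c"),
#'                                        weight = c(0.5, 0.25)))
#' total_weight(g)
weighted_graph <- function(nodes = character(), edges = NULL, self_loops = NULL) {
  if (is.null(edges)) {
    edges <- data.frame(from = character(), to = character(),
                        weight = numeric(), stringsAsFactors = FALSE)
  }
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (!"weight" %in% names(edges)) edges$weight <- rep(1, nrow(edges))
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  edges$weight <- as.numeric(edges$weight)
  if (anyNA(edges$weight) || any(edges$weight < 0)) {
    stop_modrec("edge weights must be non-negative numbers",
                class = "modrec_validation_error")
  }

  # rows with identical endpoints become self-loops
  loop_rows <- edges$from == edges$to
  sl <- if (is.null(self_loops)) numeric() else self_loops
  if (any(loop_rows)) {
    extra <- tapply(edges$weight[loop_rows], edges$from[loop_rows], sum)
    for (v in names(extra)) sl[v] <- (if (v %in% names(sl)) sl[[v]] else 0) + extra[[v]]
    edges <- edges[!loop_rows, , drop = FALSE]
  }
  if (length(sl) && (anyNA(sl) || any(sl < 0))) {
    stop_modrec("self-loop weights must be non-negative",
                class = "modrec_validation_error")
  }

  # canonical unordered pairs: from < to lexicographically
  swap <- edges$from > edges$to
  if (any(swap)) {
    tmp <- edges$from[swap]
    edges$from[swap] <- edges$to[swap]
    edges$to[swap] <- tmp
  }
  key <- paste(edges$from, edges$to, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1L]
    stop_modrec("duplicate undirected edge: ",
                gsub("\r", " -- ", dup, fixed = TRUE),
                class = "modrec_validation_error")
  }
  ord <- order(edges$from, edges$to, method = "radix")
  edges <- edges[ord, , drop = FALSE]
  rownames(edges) <- NULL

  nodes <- sort(unique(c(as.character(nodes), edges$from, edges$to, names(sl))),
                method = "radix")
  if (length(sl)) sl <- sl[sort(names(sl), method = "radix")] else sl <- stats::setNames(numeric(), character())

  structure(list(nodes = nodes, edges = edges, self_loops = sl),
            class = "weighted_graph")
}

#' Construct a directed weighted graph
#'
#' Ordered arcs `(u, v)` and `(v, u)` may both exist with different weights.
#' Used only as the input of [to_undirected()].
#'
#' @param nodes character vector of node identifiers.
#' @param arcs `data.frame` with columns `from`, `to`, `weight`.
#' @return object of class `directed_weighted_graph`.
#' @export
directed_weighted_graph <- function(nodes = character(), arcs = NULL) {
  if (is.null(arcs)) {
    arcs <- data.frame(from = character(), to = character(),
                       weight = numeric(), stringsAsFactors = FALSE)
  }
  arcs <- as.data.frame(arcs, stringsAsFactors = FALSE)
  if (!"weight" %in% names(arcs)) arcs$weight <- rep(1, nrow(arcs))
  arcs$from <- as.character(arcs$from)
  arcs$to <- as.character(arcs$to)
  arcs$weight <- as.numeric(arcs$weight)
  if (anyNA(arcs$weight) || any(arcs$weight < 0)) {
    stop_modrec("arc weights must be non-negative numbers",
                class = "modrec_validation_error")
  }
  key <- paste(arcs$from, arcs$to, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1L]
    stop_modrec("duplicate arc: ", gsub("\r", " -> ", dup, fixed = TRUE),
                class = "modrec_validation_error")
  }
  ord <- order(arcs$from, arcs$to, method = "radix")
  arcs <- arcs[ord, , drop = FALSE]
  rownames(arcs) <- NULL
  nodes <- sort(unique(c(as.character(nodes), arcs$from, arcs$to)),
                method = "radix")
  structure(list(nodes = nodes, arcs = arcs),
            class = "directed_weighted_graph")
}

#' @export
print.weighted_graph <- function(x, ...) {
  cat(sprintf("weighted_graph: %d nodes, %d edges, %d self-loops, m = %g\n",
              length(x$nodes), nrow(x$edges), length(x$self_loops),
              total_weight(x)))
  invisible(x)
}

#' @export
print.directed_weighted_graph <- function(x, ...) {
  cat(sprintf("directed_weighted_graph: %d nodes, %d arcs\n",
              length(x$nodes), nrow(x$arcs)))
  invisible(x)
}

#' Total weight m of a graph
#'
#' Sum of all edge weights plus all self-loop weights.
#' @param g a `weighted_graph`.
#' @return non-negative scalar.
#' @export
total_weight <- function(g) {
  stopifnot(inherits(g, "weighted_graph"))
  sum(g$edges$weight) + sum(g$self_loops)
}

#' Node strength
#'
#' The weighted analog of degree: the sum of the weights of a node's incident
#' edges, with self-loops counted twice so that strengths sum to `2 m`
#' exactly (the standard modularity convention).
#'
#' @param g a `weighted_graph`.
#' @param v node id(s); `NULL` returns the strength of every node.
#' @return named numeric vector of strengths.
#' @export
#' @examples
#' g <- weighted_graph(edges = data.frame(from = "a", to = "b", weight = 0.5),
#'                     self_loops = c(a = 0.25))
#' node_strength(g, "a") # 0.5 + 2 * 0.25 = 1
node_strength <- function(g, v = NULL) {
  stopifnot(inherits(g, "weighted_graph"))
  s <- stats::setNames(numeric(length(g$nodes)), g$nodes)
  if (nrow(g$edges)) {
    acc <- rowsum(c(g$edges$weight, g$edges$weight),
                  c(g$edges$from, g$edges$to))
    s[rownames(acc)] <- acc[, 1L]
  }
  if (length(g$self_loops)) {
    s[names(g$self_loops)] <- s[names(g$self_loops)] + 2 * g$self_loops
  }
  if (is.null(v)) return(s)
  v <- as.character(v)
  missing <- setdiff(v, g$nodes)
  if (length(missing)) {
    stop_modrec("unknown node(s): ", paste(missing, collapse = ", "),
                class = "modrec_lookup_error")
  }
  s[v]
}

#' Induced subgraph
#'
#' Extracts the subgraph on `members`: exactly those nodes plus every edge
#' and self-loop whose endpoints all lie in `members`. Weights are kept
#' unchanged; normalization is a one-time global preprocessing step and is
#' never reapplied at extraction.
#'
#' @param g a `weighted_graph`.
#' @param members subset of `g`'s nodes.
#' @return a `weighted_graph`.
#' @export
induced_subgraph <- function(g, members) {
  stopifnot(inherits(g, "weighted_graph"))
  members <- unique(as.character(members))
  missing <- setdiff(members, g$nodes)
  if (length(missing)) {
    stop_modrec("members not in graph: ", paste(missing, collapse = ", "),
                class = "modrec_lookup_error")
  }
  keep <- g$edges$from %in% members & g$edges$to %in% members
  sl <- g$self_loops[names(g$self_loops) %in% members]
  weighted_graph(nodes = members,
                 edges = g$edges[keep, , drop = FALSE],
                 self_loops = sl)
}

#' Read a weighted edge list
#'
#' Parses the tab-separated interchange format, one edge per line:
#' `node_a<TAB>node_b<TAB>weight`. Any whitespace is tolerated as a
#' separator on read; a missing weight field defaults to 1. Blank lines and
#' lines starting with `#` are skipped. A line with identical endpoints
#' becomes a self-loop. For undirected input a duplicate unordered pair is
#' an error (the format gives no sanctioned way to merge them); directed
#' input allows both `(u,v)` and `(v,u)`.
#'
#' @param path path to the edge-list file.
#' @param directed read as a directed graph of ordered arcs?
#' @return a `weighted_graph`, or a `directed_weighted_graph` when
#'   `directed = TRUE`.
#' @export
read_edge_list <- function(path, directed = FALSE) {
  if (!file.exists(path)) {
    stop_modrec("file not found: ", path, class = "modrec_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  from <- character(0); to <- character(0); w <- numeric(0)
  for (i in seq_along(lines)) {
    line <- trimws(lines[[i]])
    if (!nzchar(line) || startsWith(line, "#")) next
    fields <- strsplit(line, "[ \t]+")[[1L]]
    if (length(fields) < 2L || length(fields) > 3L) {
      stop_modrec("line ", i, ": expected 2 or 3 fields, got ",
                  length(fields), class = "modrec_parse_error")
    }
    wt <- if (length(fields) == 3L) suppressWarnings(as.numeric(fields[[3L]])) else 1
    if (is.na(wt)) {
      stop_modrec("line ", i, ": unparsable weight '", fields[[3L]], "'",
                  class = "modrec_parse_error")
    }
    if (wt < 0) {
      stop_modrec("line ", i, ": negative weight ", wt,
                  class = "modrec_parse_error")
    }
    from <- c(from, fields[[1L]]); to <- c(to, fields[[2L]]); w <- c(w, wt)
  }
  tab <- data.frame(from = from, to = to, weight = w, stringsAsFactors = FALSE)
  if (directed) directed_weighted_graph(arcs = tab) else weighted_graph(edges = tab)
}

#' Write a weighted edge list
#'
#' Emits tab-separated `node_a<TAB>node_b<TAB>weight` lines, weights with 6
#' significant digits, edges sorted by `(node_a, node_b)`, then self-loops
#' as `v<TAB>v<TAB>weight`. Round-trips through [read_edge_list()].
#'
#' @param g a `weighted_graph`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(g, path) {
  stopifnot(inherits(g, "weighted_graph"))
  lines <- sprintf("%s\t%s\t%s", g$edges$from, g$edges$to,
                   formatC(g$edges$weight, digits = 6, format = "g"))
  if (length(g$self_loops)) {
    lines <- c(lines, sprintf("%s\t%s\t%s",
                              names(g$self_loops), names(g$self_loops),
                              formatC(g$self_loops, digits = 6, format = "g")))
  }
  writeLines(lines, path)
  invisible(path)
}
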