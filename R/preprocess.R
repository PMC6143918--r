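# Network standardization: every downstream step assumes an undirected
# graph with weights in [0, 1]. Heterogeneous collections (signalling
# networks are directed, homology scores unbounded) get converted here,
# once, before any clustering.

#' Convert a directed graph to an undirected one by arc-weight averaging
#'
#' Every unordered pair `{u, v}` touched by at least one arc receives the
#' average of the two directed weights, `(w(u,v) + w(v,u)) / 2`; a missing
#' reverse arc contributes 0, so a one-directional arc of weight `w` becomes
#' an undirected edge of weight `w / 2`. Self-arcs become self-loops with
#' their weight unchanged. Pairs whose average is exactly 0 are dropped: a
#' zero-weight edge is indistinguishable from no edge under weighted
#' modularity and weighted PageRank.
#'
#' @param g a `directed_weighted_graph`.
#' @return a `weighted_graph` on the same node set.
#' @export
#' @examples
#' d <- directed_weighted_graph(arcs = data.frame(
#'   from = c("a", "b"), to = c("b", "a"), weight = c(0.8, 0.4)))
#' to_undirected(d)$edges # single edge a-b with weight 0.6
to_undirected <- function(g) {
  stopifnot(inherits(g, "directed_weighted_graph"))
  arcs <- g$arcs
  loop <- arcs$from == arcs$to
  sl <- numeric()
  if (any(loop)) {
    acc <- tapply(arcs$weight[loop], arcs$from[loop], sum)
    sl <- stats::setNames(as.numeric(acc), names(acc))
    arcs <- arcs[!loop, , drop = FALSE]
  }
  if (nrow(arcs)) {
    a <- pmin(arcs$from, arcs$to)
    b <- pmax(arcs$from, arcs$to)
    key <- paste(a, b, sep = "\r")
    half <- rowsum(arcs$weight / 2, key) # sum of both directions, halved
    parts <- strsplit(rownames(half), "\r", fixed = TRUE)
    edges <- data.frame(from = vapply(parts, `[[`, "", 1L),
                        to = vapply(parts, `[[`, "", 2L),
                        weight = half[, 1L], stringsAsFactors = FALSE)
    edges <- edges[edges$weight > 0, , drop = FALSE]
  } else {
    edges <- NULL
  }
  weighted_graph(nodes = g$nodes, edges = edges, self_loops = sl[sl > 0])
}

#' Rescale all weights so the maximum weight is exactly 1
#'
#' Divides every edge and self-loop weight by the maximum weight in the
#' graph, preserving all weight ratios. Idempotent. A graph with no edges,
#' or with all-zero weights, has no defined normalization and raises a
#' validation error.
#'
#' @param g a `weighted_graph`.
#' @return a `weighted_graph` with weights in `[0, 1]` and max exactly 1.
#' @export
normalize_weights <- function(g) {
  stopifnot(inherits(g, "weighted_graph"))
  wmax <- max(c(g$edges$weight, g$self_loops, 0))
  if (wmax <= 0) {
    stop_modrec("cannot normalize: graph has no positive weight",
                class = "modrec_validation_error")
  }
  edges <- g$edges
  edges$weight <- edges$weight / wmax
  weighted_graph(nodes = g$nodes, edges = edges,
                 self_loops = g$self_loops / wmax)
}
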