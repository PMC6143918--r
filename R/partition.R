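# Partitions: a full assignment of nodes to community labels. Labels are
# opaque strings; blocks are the label -> member-set view.

#' Construct a partition
#'
#' @param assignment named character vector: `names` are node ids, values
#'   are community labels (opaque strings).
#' @return object of class `partition`.
#' @export
partition <- function(assignment) {
  if (is.null(names(assignment)) || anyNA(assignment) ||
      anyDuplicated(names(assignment))) {
    stop_modrec("assignment must be a named vector, one label per node",
                class = "modrec_validation_error")
  }
  assignment <- stats::setNames(as.character(assignment), names(assignment))
  assignment <- assignment[sort(names(assignment), method = "radix")]
  structure(list(assignment = assignment), class = "partition")
}

#' All-singletons partition of a graph
#'
#' The classic Louvain start: every node its own community, labelled by its
#' own id.
#'
#' @param g a `weighted_graph`.
#' @return a `partition`.
#' @export
singleton_partition <- function(g) {
  stopifnot(inherits(g, "weighted_graph"))
  partition(stats::setNames(g$nodes, g$nodes))
}

#' Blocks of a partition
#'
#' @param p a `partition`.
#' @return named list: label -> character vector of member node ids (sorted).
#' @export
partition_blocks <- function(p) {
  stopifnot(inherits(p, "partition"))
  split(names(p$assignment), p$assignment)
}

#' @export
print.partition <- function(x, ...) {
  b <- partition_blocks(x)
  cat(sprintf("partition: %d nodes in %d blocks (sizes %s)\n",
              length(x$assignment), length(b),
              paste(sort(lengths(b), decreasing = TRUE), collapse = ", ")))
  invisible(x)
}

# labels of p restricted to the nodes of g, erroring on gaps
partition_labels_for <- function(p, g) {
  stopifnot(inherits(p, "partition"), inherits(g, "weighted_graph"))
  missing <- setdiff(g$nodes, names(p$assignment))
  if (length(missing)) {
    stop_modrec("partition missing node(s): ",
                paste(utils::head(missing, 5L), collapse = ", "),
                class = "modrec_validation_error")
  }
  p$assignment[g$nodes]
}
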