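# Weighted PageRank and the derived seed partition.
#
# The random walker at node u follows edge (u, v) with probability
# w(u,v) / s_u, where s_u is the node strength (self-loops count twice, so
# a self-loop at v carries transition weight 2 * loop / s_v and rows stay
# stochastic). Dangling nodes (strength 0) teleport uniformly.

#' Weighted PageRank by power iteration
#'
#' Computes the stationary distribution of a damped random walk whose
#' transition probabilities are proportional to edge weights:
#' `PR(v) = (1 - d)/N + d * sum_u PR(u) * w(u,v) / s_u`,
#' iterated from the uniform vector until the L1 change drops below `tol`.
#' Zero-strength nodes redistribute their mass uniformly over all nodes,
#' the standard stochastic completion; this matters because subnetworks
#' extracted during recursion may contain isolated nodes.
#'
#' @param g a `weighted_graph` with at least one node.
#' @param damping damping factor `d` in (0, 1); default 0.85.
#' @param tol L1 convergence tolerance; default 1e-9.
#' @param max_iter iteration cap; on non-convergence the result is returned
#'   with `converged = FALSE` and a warning, and the caller decides.
#' @return object of class `pagerank_vector`: list with `scores` (named,
#'   sums to 1), `damping`, `iterations_used`, `converged`.
#' @export
#' @examples
#' g <- weighted_graph(edges = data.frame(
#'   from = c("a", "b", "c"), to = c("b", "c", "a")))
#' weighted_pagerank(g)$scores # ring: uniform 1/3
weighted_pagerank <- function(g, damping = 0.85, tol = 1e-9, max_iter = 200L) {
  stopifnot(inherits(g, "weighted_graph"))
  n <- length(g$nodes)
  if (n == 0L) {
    stop_modrec("PageRank of an empty graph is undefined",
                class = "modrec_validation_error")
  }
  check_number(damping, "damping", lower = 1e-12, upper = 1 - 1e-12)
  s <- node_strength(g)
  dangling <- s <= 0
  # arcs in both directions; self-loop v->v carries weight 2*loop
  src <- c(match(g$edges$from, g$nodes), match(g$edges$to, g$nodes))
  dst <- c(match(g$edges$to, g$nodes), match(g$edges$from, g$nodes))
  w <- c(g$edges$weight, g$edges$weight)
  if (length(g$self_loops)) {
    li <- match(names(g$self_loops), g$nodes)
    src <- c(src, li); dst <- c(dst, li); w <- c(w, 2 * g$self_loops)
  }
  trans <- w / s[src] # transition probability of each arc

  pr <- rep(1 / n, n)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    inflow <- numeric(n)
    if (length(src)) {
      acc <- rowsum(pr[src] * trans, dst)
      inflow[as.integer(rownames(acc))] <- acc[, 1L]
    }
    d_mass <- sum(pr[dangling])
    new <- (1 - damping) / n + damping * (inflow + d_mass / n)
    delta <- sum(abs(new - pr))
    pr <- new
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    warning("weighted_pagerank did not converge in ", max_iter, " iterations")
  }
  structure(list(scores = stats::setNames(pr, g$nodes),
                 damping = damping,
                 iterations_used = iter,
                 converged = converged),
            class = "pagerank_vector")
}

#' @export
print.pagerank_vector <- function(x, ...) {
  cat(sprintf("pagerank_vector: %d nodes, damping %g, %d iterations%s\n",
              length(x$scores), x$damping, x$iterations_used,
              if (x$converged) "" else " (NOT converged)"))
  invisible(x)
}

#' Build the PageRank seed partition
#'
#' Each node picks a representative: its highest-PageRank neighbor if that
#' neighbor's score is strictly greater than its own, otherwise itself.
#' Ties among equally scored neighbors go to the lexicographically smallest
#' node id; an exactly equal-scored neighbor does not capture the node
#' (self wins). The partition is the set of connected components of the
#' undirected pointer graph `{(v, r(v))}` — a node joins the module of the
#' neighbor it chose, which may itself point onward. Isolated nodes become
#' singletons. The resulting blocks are handed to Louvain as its starting
#' communities.
#'
#' @param g a `weighted_graph`.
#' @param pr a `pagerank_vector` covering every node of `g`.
#' @return a `partition`; each block is labelled by its lexicographically
#'   smallest member.
#' @export
seed_partition <- function(g, pr) {
  stopifnot(inherits(g, "weighted_graph"), inherits(pr, "pagerank_vector"))
  missing <- setdiff(g$nodes, names(pr$scores))
  if (length(missing)) {
    stop_modrec("pagerank vector missing node(s): ",
                paste(utils::head(missing, 5L), collapse = ", "),
                class = "modrec_validation_error")
  }
  n <- length(g$nodes)
  score <- as.numeric(pr$scores[g$nodes])

  rep_of <- seq_len(n) # pointer r(v), default self
  if (nrow(g$edges)) {
    ei <- match(g$edges$from, g$nodes)
    ej <- match(g$edges$to, g$nodes)
    src <- c(ei, ej); nbr <- c(ej, ei)
    # per node: neighbor with max score, ties to smallest id; nodes are
    # sorted, so the smallest index wins
    ord <- order(src, -score[nbr], nbr, method = "radix")
    first <- !duplicated(src[ord])
    best_src <- src[ord][first]
    best_nbr <- nbr[ord][first]
    take <- score[best_nbr] > score[best_src] # strict: equal score keeps self
    rep_of[best_src[take]] <- best_nbr[take]
  }

  # connected components of the pointer graph via union-find
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (v in seq_len(n)) {
    a <- find(v); b <- find(rep_of[v])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  root <- vapply(seq_len(n), find, 0L)
  # label each component by its smallest member id (deterministic)
  partition(stats::setNames(g$nodes[root], g$nodes))
}
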