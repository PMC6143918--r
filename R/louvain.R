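# Louvain modularity optimization (Newman-Girvan criterion) accepting an
# arbitrary initial partition.
#
# The quality function is
#   Q = (1/2m) sum_ij [A_ij - s_i s_j / 2m] delta(c_i, c_j),
# with A_ii = 2 * self-loop weight, so strengths sum to 2m and Q of the
# one-community partition is exactly 0. Bookkeeping uses per-community
# accumulators Sigma_tot (member strength) and Sigma_in (intra-community
# adjacency counted as sum_{i,j in C} A_ij).

# threshold below which a modularity gain is treated as zero (guards
# against floating-point livelock)
Q_EPS <- 1e-12

# Flatten a weighted_graph to index space: integer endpoints, adjacency
# lists, strengths. All inner-loop work happens on this form.
index_graph <- function(g) {
  n <- length(g$nodes)
  ei <- match(g$edges$from, g$nodes)
  ej <- match(g$edges$to, g$nodes)
  w <- g$edges$weight
  self <- numeric(n)
  if (length(g$self_loops)) {
    self[match(names(g$self_loops), g$nodes)] <- g$self_loops
  }
  src <- c(ei, ej)
  fac <- factor(src, levels = seq_len(n))
  adj <- split(c(ej, ei), fac)
  adjw <- split(c(w, w), fac)
  strength <- vapply(adjw, sum, 0) + 2 * self
  list(nodes = g$nodes, n = n, ei = ei, ej = ej, w = w, self = self,
       adj = adj, adjw = adjw, strength = unname(strength),
       m = sum(w) + sum(self))
}

# community accumulators for integer community labels comm (values 1..n)
accumulators <- function(ig, comm) {
  sigma_tot <- numeric(ig$n)
  acc <- rowsum(ig$strength, comm)
  sigma_tot[as.integer(rownames(acc))] <- acc[, 1L]
  sigma_in <- numeric(ig$n)
  if (length(ig$ei)) {
    intra <- comm[ig$ei] == comm[ig$ej]
    if (any(intra)) {
      acc2 <- rowsum(2 * ig$w[intra], comm[ig$ei][intra])
      sigma_in[as.integer(rownames(acc2))] <- acc2[, 1L]
    }
  }
  if (any(ig$self > 0)) {
    acc3 <- rowsum(2 * ig$self, comm)
    sigma_in[as.integer(rownames(acc3))] <-
      sigma_in[as.integer(rownames(acc3))] + acc3[, 1L]
  }
  list(sigma_tot = sigma_tot, sigma_in = sigma_in)
}

q_from_acc <- function(acc, m) {
  sum(acc$sigma_in) / (2 * m) - sum((acc$sigma_tot / (2 * m))^2)
}

#' Newman-Girvan modularity of a partition
#'
#' `Q = (1/2m) * sum_ij [A_ij - s_i * s_j / (2m)] * delta(c_i, c_j)`,
#' where `A` is the weighted adjacency with `A_ii` twice the self-loop
#' weight, `s` the node strengths and `m` the total weight. Ranges over
#' `[-1, 1]`; the all-in-one partition scores exactly 0.
#'
#' @param g a `weighted_graph` with `m > 0`.
#' @param p a `partition` covering all nodes of `g`.
#' @return scalar modularity.
#' @export
#' @examples
#' tri <- weighted_graph(edges = data.frame(
#'   from = c("a", "a", "b"), to = c("b", "c", "c")))
#' modularity(tri, singleton_partition(tri)) # -1/3
modularity <- function(g, p) {
  m <- total_weight(g)
  if (m <= 0) {
    stop_modrec("modularity undefined for a graph with m = 0",
                class = "modrec_validation_error")
  }
  lab <- partition_labels_for(p, g)
  intra <- sum(g$edges$weight[lab[g$edges$from] == lab[g$edges$to]]) +
    sum(g$self_loops)
  s <- node_strength(g)
  sigma_tot <- rowsum(as.numeric(s), lab)[, 1L]
  2 * intra / (2 * m) - sum((sigma_tot / (2 * m))^2)
}

# Core greedy sweep on the indexed graph. comm is modified greedily; the
# visit order is reshuffled every sweep when shuffle = TRUE (sorted order
# otherwise). on_move, if given, is called after every accepted move with
# (comm, q) where q is the accumulator-maintained modularity.
#
# Destinations considered for a node: the communities of its neighbors,
# its own community, and a fresh empty community (gain 0 after removal).
# The escape-to-singleton option matters only for coarse initial
# partitions: without it a seed block covering a whole connected
# subnetwork could never be split, because joining a neighbor's community
# is then the only move and all neighbors share the block. Ties prefer an
# existing neighbor community over the fresh one, and the smallest label
# among neighbors.
local_move_core <- function(ig, comm, shuffle = TRUE, on_move = NULL) {
  acc <- accumulators(ig, comm)
  sigma_tot <- acc$sigma_tot
  sigma_in <- acc$sigma_in
  m <- ig$m
  q <- q_from_acc(acc, m)
  comm_size <- tabulate(comm, nbins = ig$n)
  moved_any <- FALSE
  repeat {
    moved <- FALSE
    order_v <- if (shuffle) sample.int(ig$n) else seq_len(ig$n)
    for (v in order_v) {
      sv <- ig$strength[v]
      cv <- comm[v]
      nbrs <- ig$adj[[v]]
      if (!length(nbrs)) next
      ncomm <- comm[nbrs]
      kvc <- rowsum(ig$adjw[[v]], ncomm)
      cand <- as.integer(rownames(kvc))
      kvc <- kvc[, 1L]
      k_own <- if (cv %in% cand) kvc[[match(cv, cand)]] else 0
      # remove v from its community
      sigma_tot[cv] <- sigma_tot[cv] - sv
      # gain of joining C (constant terms dropped): k_vC/m - s_v*Sigma_tot(C)/(2m^2)
      gain <- kvc / m - sv * sigma_tot[cand] / (2 * m * m)
      gain_own <- k_own / m - sv * sigma_tot[cv] / (2 * m * m)
      best <- which.max(gain) # candidates sorted by label; first max wins ties
      gain_best <- gain[[best]]
      to_fresh <- FALSE
      if (comm_size[cv] > 1L && 0 > gain_best + Q_EPS) {
        # leaving for a fresh singleton beats every existing destination
        gain_best <- 0
        to_fresh <- TRUE
      }
      dq <- gain_best - gain_own
      if (dq > Q_EPS && (to_fresh || cand[[best]] != cv)) {
        cb <- if (to_fresh) which(comm_size == 0L)[1L] else cand[[best]]
        k_new <- if (to_fresh) 0 else kvc[[best]]
        comm[v] <- cb
        comm_size[cv] <- comm_size[cv] - 1L
        comm_size[cb] <- comm_size[cb] + 1L
        sigma_tot[cb] <- sigma_tot[cb] + sv
        sigma_in[cv] <- sigma_in[cv] - 2 * k_own - 2 * ig$self[v]
        sigma_in[cb] <- sigma_in[cb] + 2 * k_new + 2 * ig$self[v]
        q <- q + dq
        moved <- TRUE
        moved_any <- TRUE
        if (!is.null(on_move)) on_move(comm, q)
      } else {
        sigma_tot[cv] <- sigma_tot[cv] + sv
      }
    }
    if (!moved) break
  }
  list(comm = comm, q = q, moved = moved_any)
}

# map an initial partition to integer labels such that lexicographically
# smaller labels get smaller integers (keeps tie-breaks deterministic)
comm_from_partition <- function(ig, p, g) {
  lab <- partition_labels_for(p, g)
  levels <- sort(unique(lab), method = "radix")
  match(lab, levels)
}

#' Louvain phase one: greedy local node moves
#'
#' Sweeps the nodes repeatedly (order reshuffled each sweep from a seeded
#' RNG; `shuffle = FALSE` gives the sorted deterministic order), moving
#' each node to the neighboring community with the largest strictly
#' positive modularity gain, computed incrementally from the community
#' accumulators. Ties among equally good destinations go to the smallest
#' community label. Stops when a full sweep makes no move; the returned
#' partition never has lower modularity than the input.
#'
#' @param g a `weighted_graph` with `m > 0`.
#' @param p starting `partition`.
#' @param rng_seed integer seed for the sweep shuffles (`NULL`: use the
#'   current RNG stream).
#' @param shuffle reshuffle the visit order every sweep?
#' @param on_move optional callback `function(partition, q)` invoked after
#'   every accepted move with the current partition and the incrementally
#'   maintained modularity (used to audit the accumulator bookkeeping).
#' @return a `partition`.
#' @export
local_move_phase <- function(g, p, rng_seed = NULL, shuffle = TRUE,
                             on_move = NULL) {
  stopifnot(inherits(g, "weighted_graph"))
  if (total_weight(g) <= 0) {
    stop_modrec("local moves undefined for a graph with m = 0",
                class = "modrec_validation_error")
  }
  ig <- index_graph(g)
  comm <- comm_from_partition(ig, p, g)
  lab0 <- partition_labels_for(p, g)
  levels <- sort(unique(lab0), method = "radix")
  # communities born from escape-to-singleton moves need labels of their
  # own; make them collision-free against the input labels
  fresh <- paste0(".m", seq_len(ig$n))
  while (any(fresh %in% levels)) fresh <- paste0(".", fresh)
  levels <- c(levels, fresh)[seq_len(ig$n)]
  cb <- if (is.null(on_move)) NULL else function(comm_now, q_now) {
    on_move(partition(stats::setNames(levels[comm_now], g$nodes)), q_now)
  }
  res <- with_seed(rng_seed, local_move_core(ig, comm, shuffle, cb))
  partition(stats::setNames(levels[res$comm], g$nodes))
}

#' Louvain phase two: aggregate communities into supernodes
#'
#' Each community becomes one supernode named after its community label.
#' Supernodes are connected if at least one edge runs between their
#' communities, with weight the total inter-community weight; intra
#' weight (including member self-loops) becomes the supernode self-loop.
#' Total weight `m` is preserved exactly.
#'
#' @param g a `weighted_graph`.
#' @param p a `partition` of `g`.
#' @return list with `graph` (the aggregated `weighted_graph`) and
#'   `mapping` (named character vector community label -> supernode id,
#'   here the identity).
#' @export
aggregate_communities <- function(g, p) {
  stopifnot(inherits(g, "weighted_graph"))
  lab <- partition_labels_for(p, g)
  labs <- sort(unique(lab), method = "radix")

  sl <- stats::setNames(numeric(length(labs)), labs)
  edges <- NULL
  if (nrow(g$edges)) {
    cf <- lab[g$edges$from]
    ct <- lab[g$edges$to]
    intra <- cf == ct
    if (any(intra)) {
      acc <- rowsum(g$edges$weight[intra], cf[intra])
      sl[rownames(acc)] <- sl[rownames(acc)] + acc[, 1L]
    }
    if (any(!intra)) {
      a <- pmin(cf[!intra], ct[!intra])
      b <- pmax(cf[!intra], ct[!intra])
      acc <- rowsum(g$edges$weight[!intra], paste(a, b, sep = "\r"))
      parts <- strsplit(rownames(acc), "\r", fixed = TRUE)
      edges <- data.frame(from = vapply(parts, `[[`, "", 1L),
                          to = vapply(parts, `[[`, "", 2L),
                          weight = acc[, 1L], stringsAsFactors = FALSE)
    }
  }
  if (length(g$self_loops)) {
    lsl <- lab[names(g$self_loops)]
    acc <- rowsum(as.numeric(g$self_loops), lsl)
    sl[rownames(acc)] <- sl[rownames(acc)] + acc[, 1L]
  }
  ag <- weighted_graph(nodes = labs, edges = edges, self_loops = sl[sl > 0])
  list(graph = ag, mapping = stats::setNames(labs, labs))
}

#' Louvain community detection from an arbitrary initial partition
#'
#' Alternates [local_move_phase()] and [aggregate_communities()], carrying
#' the induced partition up through supernode levels, until an iteration
#' no longer increases modularity; returns the final flat partition of the
#' original nodes. The initial partition is honored as-is at level 0 — the
#' seed blocks are the starting communities before any move — which is
#' what lets a PageRank seed steer the optimization. With a fixed
#' `rng_seed` the result is reproducible; different seeds may legitimately
#' return different partitions.
#'
#' @param g a `weighted_graph` with `m > 0`.
#' @param init initial `partition`; default all singletons.
#' @param rng_seed integer seed controlling sweep shuffles.
#' @param shuffle reshuffle node order every sweep? (`FALSE` for fully
#'   deterministic sorted sweeps.)
#' @return a `partition` `p` with `modularity(g, p) >= modularity(g, init)`.
#' @export
#' @examples
#' g <- planted_partition(c(4, 4), p_in = 1, p_out = 0, seed = 1)$graph
#' p <- louvain(g, rng_seed = 1)
#' modularity(g, p) # 0.5: the two planted cliques
louvain <- function(g, init = NULL, rng_seed = NULL, shuffle = TRUE) {
  stopifnot(inherits(g, "weighted_graph"))
  if (total_weight(g) <= 0) {
    stop_modrec("louvain undefined for a graph with m = 0",
                class = "modrec_validation_error")
  }
  if (is.null(init)) init <- singleton_partition(g)
  partition_labels_for(init, g) # validates coverage
  # original node -> node of the current (aggregated) graph
  flat <- stats::setNames(g$nodes, g$nodes)
  cur_g <- g
  cur_p <- init
  q_prev <- modularity(g, init)
  level <- 0L
  repeat {
    seed_l <- if (is.null(rng_seed)) NULL else child_seed(rng_seed, level)
    p1 <- local_move_phase(cur_g, cur_p, rng_seed = seed_l, shuffle = shuffle)
    q1 <- modularity(cur_g, p1)
    flat <- stats::setNames(as.character(p1$assignment[flat]), names(flat)) # node -> new label
    if (q1 - q_prev <= Q_EPS) break
    q_prev <- q1
    agg <- aggregate_communities(cur_g, p1)
    if (length(agg$graph$nodes) == length(cur_g$nodes)) break
    cur_g <- agg$graph
    cur_p <- singleton_partition(cur_g)
    level <- level + 1L
  }
  partition(flat)
}
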