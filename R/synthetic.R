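# Synthetic benchmarks with known ground truth, plus partition comparison.
# These play the role of the restricted-access benchmark networks in the
# test suite: every contract in the package is exercised against graphs
# whose community structure is planted and therefore known.

planted_node_ids <- function(n) {
  sprintf("n%0*d", max(3L, nchar(n)), seq_len(n))
}

# Bernoulli edges over the given candidate pairs (two integer vectors),
# weights uniform in [weight_low, weight_high]. Returns a data.frame.
sample_edges <- function(i, j, p, weight_low, weight_high, ids) {
  keep <- stats::runif(length(i)) < p
  i <- i[keep]; j <- j[keep]
  w <- stats::runif(length(i), weight_low, weight_high)
  data.frame(from = ids[i], to = ids[j], weight = w, stringsAsFactors = FALSE)
}

all_pairs <- function(idx) {
  n <- length(idx)
  if (n < 2L) return(list(i = integer(), j = integer()))
  pairs <- utils::combn(idx, 2L)
  list(i = pairs[1L, ], j = pairs[2L, ])
}

cross_pairs <- function(idx_a, idx_b) {
  list(i = rep(idx_a, each = length(idx_b)),
       j = rep(idx_b, times = length(idx_a)))
}

#' Generate a planted-partition network
#'
#' Nodes are split into blocks of the given sizes; each intra-block pair is
#' an edge with probability `p_in`, each inter-block pair with probability
#' `p_out`, and edge weights are drawn uniformly from
#' `[weight_low, weight_high]`. The ground-truth partition is the blocks.
#' Identical parameters and seed always regenerate the identical network.
#'
#' @param block_sizes integer vector of block sizes (each >= 1).
#' @param p_in,p_out intra- and inter-block edge probabilities in `[0, 1]`.
#' @param weight_low,weight_high weight range, `0 <= low <= high <= 1`.
#' @param seed integer RNG seed.
#' @return object of class `planted_network`: list with `graph`
#'   (`weighted_graph`), `truth` (`partition`, blocks labelled
#'   `"b1", "b2", ...`) and `params`.
#' @export
#' @examples
#' pn <- planted_partition(c(4, 4), p_in = 1, p_out = 0, seed = 1)
#' pn$graph # two disjoint K4
planted_partition <- function(block_sizes, p_in, p_out,
                              weight_low = 1, weight_high = 1, seed = 1L) {
  if (any(block_sizes < 1L)) {
    stop_modrec("block sizes must be >= 1", class = "modrec_validation_error")
  }
  check_number(p_in, "p_in", 0, 1)
  check_number(p_out, "p_out", 0, 1)
  check_number(weight_low, "weight_low", 0, 1)
  check_number(weight_high, "weight_high", weight_low, 1)
  n <- sum(block_sizes)
  ids <- planted_node_ids(n)
  block_of <- rep(seq_along(block_sizes), block_sizes)
  idx_by_block <- split(seq_len(n), block_of)

  edges <- with_seed(seed, {
    parts <- list()
    for (b in seq_along(block_sizes)) {
      pp <- all_pairs(idx_by_block[[b]])
      parts[[length(parts) + 1L]] <-
        sample_edges(pp$i, pp$j, p_in, weight_low, weight_high, ids)
    }
    nb <- length(block_sizes)
    if (nb > 1L) {
      for (a in seq_len(nb - 1L)) {
        for (b in seq((a + 1L), nb)) {
          cp <- cross_pairs(idx_by_block[[a]], idx_by_block[[b]])
          parts[[length(parts) + 1L]] <-
            sample_edges(cp$i, cp$j, p_out, weight_low, weight_high, ids)
        }
      }
    }
    do.call(rbind, parts)
  })

  structure(list(
    graph = weighted_graph(nodes = ids, edges = edges),
    truth = partition(stats::setNames(paste0("b", block_of), ids)),
    params = list(block_sizes = block_sizes, p_in = p_in, p_out = p_out,
                  weight_low = weight_low, weight_high = weight_high,
                  seed = seed)),
    class = "planted_network")
}

#' Generate a nested two-level planted network
#'
#' Super-blocks of sub-blocks with three-tier edge probabilities: within a
#' sub-block (`p_sub`), between sub-blocks of the same super-block
#' (`p_super`), and across super-blocks (`p_bg`), with
#' `p_sub > p_super > p_bg` required. This is the structure that defeats a
#' single community-detection pass when the super-blocks exceed the size
#' cap: the interesting modules hide inside an oversized community, and
#' only recursion into the extracted super-block can recover them.
#'
#' @param super_blocks number of super-blocks.
#' @param sub_blocks_per sub-blocks per super-block.
#' @param sub_size nodes per sub-block.
#' @param p_sub,p_super,p_bg the three tier probabilities.
#' @param weight_low,weight_high weight range, defaults to unit weights.
#' @param seed integer RNG seed.
#' @return a `planted_network` whose `truth` is the sub-block partition and
#'   which carries `truth_super` (the super-block partition) as an extra
#'   field.
#' @export
nested_planted <- function(super_blocks, sub_blocks_per, sub_size,
                           p_sub, p_super, p_bg,
                           weight_low = 1, weight_high = 1, seed = 1L) {
  check_number(p_sub, "p_sub", 0, 1)
  check_number(p_super, "p_super", 0, 1)
  check_number(p_bg, "p_bg", 0, 1)
  if (!(p_sub >= p_super && p_super >= p_bg)) {
    stop_modrec("tier probabilities must satisfy p_sub >= p_super >= p_bg",
                class = "modrec_validation_error")
  }
  n <- super_blocks * sub_blocks_per * sub_size
  ids <- planted_node_ids(n)
  sub_of <- rep(seq_len(super_blocks * sub_blocks_per), each = sub_size)
  super_of <- rep(seq_len(super_blocks), each = sub_blocks_per * sub_size)
  idx_by_sub <- split(seq_len(n), sub_of)
  n_sub <- length(idx_by_sub)

  edges <- with_seed(seed, {
    parts <- list()
    for (s in seq_len(n_sub)) {
      pp <- all_pairs(idx_by_sub[[s]])
      parts[[length(parts) + 1L]] <-
        sample_edges(pp$i, pp$j, p_sub, weight_low, weight_high, ids)
    }
    if (n_sub > 1L) {
      sup_of_sub <- super_of[vapply(idx_by_sub, `[[`, 0L, 1L)]
      for (a in seq_len(n_sub - 1L)) {
        for (b in seq((a + 1L), n_sub)) {
          p <- if (sup_of_sub[a] == sup_of_sub[b]) p_super else p_bg
          if (p <= 0) next
          cp <- cross_pairs(idx_by_sub[[a]], idx_by_sub[[b]])
          parts[[length(parts) + 1L]] <-
            sample_edges(cp$i, cp$j, p, weight_low, weight_high, ids)
        }
      }
    }
    do.call(rbind, parts)
  })

  out <- structure(list(
    graph = weighted_graph(nodes = ids, edges = edges),
    truth = partition(stats::setNames(paste0("s", sub_of), ids)),
    params = list(super_blocks = super_blocks,
                  sub_blocks_per = sub_blocks_per, sub_size = sub_size,
                  p_sub = p_sub, p_super = p_super, p_bg = p_bg,
                  weight_low = weight_low, weight_high = weight_high,
                  seed = seed)),
    class = "planted_network")
  out$truth_super <- partition(stats::setNames(paste0("S", super_of), ids))
  out
}

#' @export
print.planted_network <- function(x, ...) {
  cat("planted_network\n")
  print(x$graph)
  print(x$truth)
  invisible(x)
}

#' Normalized mutual information between two partitions
#'
#' Mutual information of the block contingency table, normalized by the
#' arithmetic mean of the two block entropies (natural logs; the
#' normalization cancels the base). Ranges over `[0, 1]`; equals 1 iff the
#' partitions are identical up to relabeling. When both partitions are the
#' single whole-set block, both entropies vanish and the value is defined
#' as 1 (they are identical).
#'
#' @param p,q `partition` objects covering the same node set.
#' @return scalar in `[0, 1]`.
#' @export
#' @examples
#' a <- partition(c(x = "1", y = "1", z = "2"))
#' b <- partition(c(x = "A", y = "A", z = "B"))
#' nmi(a, b) # 1: identical up to relabeling
nmi <- function(p, q) {
  stopifnot(inherits(p, "partition"), inherits(q, "partition"))
  np <- names(p$assignment)
  nq <- names(q$assignment)
  if (!identical(np, nq)) {
    stop_modrec("partitions must cover the same node set",
                class = "modrec_validation_error")
  }
  n <- length(np)
  tab <- table(p$assignment, q$assignment[np])
  pij <- tab / n
  pi_ <- rowSums(pij)
  p_j <- colSums(pij)
  hp <- -sum(ifelse(pi_ > 0, pi_ * log(pi_), 0))
  hq <- -sum(ifelse(p_j > 0, p_j * log(p_j), 0))
  if (hp + hq == 0) return(1) # both single-block
  expect <- outer(pi_, p_j)
  nz <- pij > 0
  mi <- sum(pij[nz] * log(pij[nz] / expect[nz]))
  val <- mi / ((hp + hq) / 2)
  min(max(val, 0), 1)
}

#' Write the ground truth of a planted network
#'
#' Emits `node<TAB>block` lines for benchmarking against external tools.
#'
#' @param pn a `planted_network`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(pn, path) {
  stopifnot(inherits(pn, "planted_network"))
  a <- pn$truth$assignment
  writeLines(sprintf("%s\t%s", names(a), a), path)
  invisible(path)
}
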