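# Top-level recursive extraction: run PageRank-seeded Louvain, keep
# communities of 3..k nodes, recurse into anything bigger, drop anything
# smaller. Every subnetwork pushed onto the work list is strictly smaller
# than its parent (an oversized community equal to the whole subnetwork is
# discarded instead of re-queued), so the recursion always terminates.

#' Construct a module set
#'
#' @param members list of character vectors, one per module, in emission
#'   order; module ids are assigned 1, 2, ... in that order.
#' @param depth integer vector: recursion depth at which each module was
#'   emitted.
#' @param stats optional list of run diagnostics.
#' @return object of class `module_set` with fields `modules` (list of
#'   `list(id, members)`), `provenance` (id -> depth) and `stats`.
#' @export
module_set <- function(members = list(), depth = integer(length(members)),
                       stats = list()) {
  if (length(members) != length(depth)) {
    stop_modrec("one depth per module required",
                class = "modrec_validation_error")
  }
  members <- lapply(members, function(m) sort(as.character(m), method = "radix"))
  if (length(members) > 1L) {
    all_m <- unlist(members)
    if (anyDuplicated(all_m)) {
      stop_modrec("modules must be pairwise disjoint",
                  class = "modrec_validation_error")
    }
  }
  mods <- lapply(seq_along(members), function(i) {
    list(id = i, members = members[[i]])
  })
  structure(list(modules = mods,
                 provenance = stats::setNames(as.integer(depth),
                                              seq_along(members)),
                 stats = stats),
            class = "module_set")
}

#' @export
print.module_set <- function(x, ...) {
  sizes <- vapply(x$modules, function(m) length(m$members), 0L)
  cat(sprintf("module_set: %d modules covering %d nodes\n",
              length(x$modules), sum(sizes)))
  if (length(sizes)) {
    cat("  sizes: ", paste(sizes, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Recursively extract modules of 3 to k nodes
#'
#' Maintains a work list initialized with the input network. For each
#' network popped: compute weighted PageRank, build the seed partition, run
#' Louvain. Each resulting community is then routed by size: within
#' `[3, k]` it is emitted as a module; below 3 it is discarded; above `k`
#' its induced subgraph is pushed back onto the work list. A subnetwork
#' that Louvain cannot split (the result is a single community equal to the
#' whole subnetwork) is discarded rather than re-queued — the policy that
#' both guarantees termination and never emits an oversized module.
#' PageRank and seeding are recomputed on every subnetwork, never inherited
#' from the parent. Child RNG seeds are derived deterministically from the
#' run seed and each subnetwork's emission index, so a whole run is
#' reproducible from one seed.
#'
#' @param g a standardized `weighted_graph` (undirected, weights in
#'   `[0, 1]`).
#' @param k maximum module size, in `[3, 100]`.
#' @param rng_seed integer seed for the whole run.
#' @param max_depth recursion-depth guard; hitting it discards the
#'   remaining work list with a warning (defense in depth — the strict
#'   shrinkage argument above means it should never trigger).
#' @param damping,tol,max_iter passed to [weighted_pagerank()].
#' @return a `module_set`; its `stats` field records `module_count`,
#'   `sizes`, `depth_histogram`, `discarded_nodes` (nodes of discarded
#'   communities, counted with multiplicity across levels is avoided:
#'   each node counted once, at the level it was finally dropped) and
#'   `unsplittable_discards`.
#' @export
#' @examples
#' pn <- planted_partition(c(5, 5), p_in = 1, p_out = 0, seed = 7)
#' extract_modules(pn$graph, k = 6, rng_seed = 1)
extract_modules <- function(g, k, rng_seed = 1L, max_depth = 50L,
                            damping = 0.85, tol = 1e-9, max_iter = 200L) {
  stopifnot(inherits(g, "weighted_graph"))
  if (!is.numeric(k) || length(k) != 1L || k < 3 || k > 100) {
    stop_modrec("k must be in [3, 100]", class = "modrec_validation_error")
  }
  k <- as.integer(k)

  emitted <- list()
  emitted_depth <- integer()
  discarded_nodes <- character()
  unsplittable <- 0L
  depth_hist <- integer()

  # work list of (graph, depth, seed); FIFO
  queue <- list()
  if (total_weight(g) > 0) {
    queue[[1L]] <- list(graph = g, depth = 0L, seed = rng_seed)
  } else {
    discarded_nodes <- g$nodes
  }
  emission_index <- 0L
  truncated <- FALSE

  while (length(queue)) {
    item <- queue[[1L]]
    queue <- queue[-1L]
    if (item$depth > max_depth) {
      warning("max_depth ", max_depth, " exceeded; discarding remaining work")
      truncated <- TRUE
      discarded_nodes <- c(discarded_nodes, item$graph$nodes)
      next
    }
    d <- item$depth + 1L
    depth_hist[d] <- (if (length(depth_hist) >= d) depth_hist[d] else 0L) + 1L

    sub <- item$graph
    pr <- weighted_pagerank(sub, damping = damping, tol = tol,
                            max_iter = max_iter)
    seed_p <- seed_partition(sub, pr)
    part <- louvain(sub, init = seed_p, rng_seed = item$seed)
    blocks <- partition_blocks(part)
    if (length(blocks) == 1L && length(sub$nodes) > k) {
      # Degenerate seed: when the PageRank pointer components collapse to a
      # single block, that block is a fixed point of local moves (removing
      # any one node from the all-in-one partition always lowers Q). Retry
      # from the classic all-singletons start before giving up on the
      # subnetwork; truly cohesive graphs (cliques) still come back whole.
      part <- louvain(sub, rng_seed = child_seed(item$seed, 2147480000))
      blocks <- partition_blocks(part)
    }

    for (b in blocks[sort(names(blocks), method = "radix")]) {
      size <- length(b)
      if (size >= 3L && size <= k) {
        emitted[[length(emitted) + 1L]] <- b
        emitted_depth <- c(emitted_depth, item$depth)
      } else if (size < 3L) {
        discarded_nodes <- c(discarded_nodes, b)
      } else if (size == length(sub$nodes)) {
        # Louvain returned the whole subnetwork as one oversized community:
        # unsplittable, discard
        unsplittable <- unsplittable + 1L
        discarded_nodes <- c(discarded_nodes, b)
      } else {
        child <- induced_subgraph(sub, b)
        if (total_weight(child) <= 0) {
          discarded_nodes <- c(discarded_nodes, b)
          next
        }
        emission_index <- emission_index + 1L
        queue[[length(queue) + 1L]] <- list(
          graph = child, depth = item$depth + 1L,
          seed = child_seed(item$seed, emission_index))
      }
    }
  }

  sizes <- vapply(emitted, length, 0L)
  module_set(emitted, emitted_depth, stats = list(
    module_count = length(emitted),
    sizes = sizes,
    depth_histogram = depth_hist,
    discarded_nodes = length(unique(discarded_nodes)),
    unsplittable_discards = unsplittable,
    truncated_at_max_depth = truncated,
    k = k, rng_seed = rng_seed))
}

#' Write a module set in the submission format
#'
#' One line per module: `<module_id><TAB>1.0<TAB><node ids joined by TAB>`,
#' members in lexicographic order, modules in id order. The constant `1.0`
#' is the per-module confidence slot of the interchange format.
#'
#' @param ms a `module_set`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_module_set <- function(ms, path) {
  stopifnot(inherits(ms, "module_set"))
  lines <- vapply(ms$modules, function(m) {
    paste(c(m$id, "1.0", m$members), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a module set written by [write_module_set()]
#'
#' @param path path to a submission-format file.
#' @return a `module_set` (provenance depths are unknown on read and set
#'   to `NA`).
#' @export
read_module_set <- function(path) {
  if (!file.exists(path)) {
    stop_modrec("file not found: ", path, class = "modrec_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  members <- lapply(lines, function(line) {
    fields <- strsplit(line, "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L) {
      stop_modrec("malformed module line: ", line,
                  class = "modrec_parse_error")
    }
    fields[-(1:2)]
  })
  module_set(members, depth = rep(NA_integer_, length(members)))
}

#' Convert a module set to a full partition over a node universe
#'
#' Nodes not covered by any module become singleton blocks; useful for
#' comparing a module set against a ground-truth partition with [nmi()].
#'
#' @param ms a `module_set`.
#' @param nodes the full node universe (superset of the module members).
#' @return a `partition`.
#' @export
modules_as_partition <- function(ms, nodes) {
  stopifnot(inherits(ms, "module_set"))
  nodes <- sort(unique(as.character(nodes)), method = "radix")
  lab <- stats::setNames(paste0("unassigned:", nodes), nodes)
  for (m in ms$modules) {
    extra <- setdiff(m$members, nodes)
    if (length(extra)) {
      stop_modrec("module members outside node universe: ",
                  paste(utils::head(extra, 5L), collapse = ", "),
                  class = "modrec_validation_error")
    }
    lab[m$members] <- paste0("module:", m$id)
  }
  partition(lab)
}
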