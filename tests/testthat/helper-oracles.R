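# Independent oracles: dense-matrix implementations that share no code
# with the package internals they check.

# dense weighted adjacency with A_ii = 2 * self-loop weight
oracle_adjacency <- function(g) {
  n <- length(g$nodes)
  A <- matrix(0, n, n, dimnames = list(g$nodes, g$nodes))
  for (r in seq_len(nrow(g$edges))) {
    i <- g$edges$from[r]; j <- g$edges$to[r]; w <- g$edges$weight[r]
    A[i, j] <- A[i, j] + w
    A[j, i] <- A[j, i] + w
  }
  for (v in names(g$self_loops)) A[v, v] <- A[v, v] + 2 * g$self_loops[[v]]
  A
}

# direct evaluation of Q = (1/2m) sum_ij [A_ij - s_i s_j / 2m] delta(c_i c_j)
oracle_modularity <- function(g, labels) {
  A <- oracle_adjacency(g)
  s <- rowSums(A)
  m2 <- sum(A) # = 2m
  lab <- labels[rownames(A)]
  same <- outer(lab, lab, "==")
  sum((A - outer(s, s) / m2)[same]) / m2
}

# all set partitions of n items as restricted-growth strings
oracle_all_partitions <- function(n) {
  out <- list()
  rec <- function(prefix, maxlab) {
    if (length(prefix) == n) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible())
    }
    for (lab in seq_len(maxlab + 1L)) {
      rec(c(prefix, lab), max(maxlab, lab))
    }
  }
  rec(integer(), 0L)
  out
}

# exhaustive maximum of Q over every partition of g's nodes (n <= 9)
oracle_max_modularity <- function(g) {
  n <- length(g$nodes)
  stopifnot(n <= 9)
  best <- -Inf
  best_labels <- NULL
  for (rg in oracle_all_partitions(n)) {
    labels <- stats::setNames(as.character(rg), g$nodes)
    q <- oracle_modularity(g, labels)
    if (q > best) {
      best <- q
      best_labels <- labels
    }
  }
  list(q = best, labels = best_labels)
}

# dense power iteration on the explicit Google matrix
oracle_pagerank <- function(g, damping = 0.85, tol = 1e-13, max_iter = 10000) {
  A <- oracle_adjacency(g)
  n <- nrow(A)
  s <- rowSums(A)
  P <- matrix(1 / n, n, n) # dangling rows: uniform
  ok <- s > 0
  P[ok, ] <- A[ok, , drop = FALSE] / s[ok]
  G <- damping * P + (1 - damping) / n
  pr <- rep(1 / n, n)
  for (i in seq_len(max_iter)) {
    new <- as.vector(crossprod(G, pr))
    if (sum(abs(new - pr)) < tol) {
      pr <- new
      break
    }
    pr <- new
  }
  stats::setNames(pr, rownames(A))
}

# contingency-table NMI, arithmetic-mean normalization
oracle_nmi <- function(lab_p, lab_q) {
  n <- length(lab_p)
  tab <- table(lab_p, lab_q)
  pij <- tab / n
  pi_ <- rowSums(pij); p_j <- colSums(pij)
  h <- function(x) -sum(x[x > 0] * log(x[x > 0]))
  if (h(pi_) + h(p_j) == 0) return(1)
  mi <- 0
  for (i in seq_along(pi_)) {
    for (j in seq_along(p_j)) {
      if (pij[i, j] > 0) {
        mi <- mi + pij[i, j] * log(pij[i, j] / (pi_[i] * p_j[j]))
      }
    }
  }
  as.numeric(mi / ((h(pi_) + h(p_j)) / 2))
}

# random partition of the given nodes with <= kmax blocks
random_labels <- function(nodes, kmax = 4) {
  stats::setNames(as.character(sample.int(kmax, length(nodes), replace = TRUE)),
                  nodes)
}
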