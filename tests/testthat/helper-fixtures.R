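# Fixture graphs built in code. Kept tiny: the exhaustive-enumeration
# oracle visits every partition of their node sets.

clique_edges <- function(ids, weight = 1) {
  p <- utils::combn(ids, 2L)
  data.frame(from = p[1L, ], to = p[2L, ], weight = weight,
             stringsAsFactors = FALSE)
}

fx_clique <- function(n, prefix = "v") {
  weighted_graph(edges = clique_edges(sprintf("%s%d", prefix, seq_len(n))))
}

# two K_k cliques joined by a single bridge edge
fx_barbell <- function(k = 4) {
  a <- sprintf("a%d", seq_len(k))
  b <- sprintf("b%d", seq_len(k))
  weighted_graph(edges = rbind(clique_edges(a), clique_edges(b),
                               data.frame(from = a[1], to = b[1], weight = 1)))
}

fx_two_triangles <- function() {
  weighted_graph(edges = rbind(clique_edges(c("a", "b", "c")),
                               clique_edges(c("x", "y", "z"))))
}

fx_ring <- function(n) {
  ids <- sprintf("r%02d", seq_len(n))
  weighted_graph(edges = data.frame(from = ids, to = ids[c(2:n, 1)],
                                    weight = 1, stringsAsFactors = FALSE))
}

fx_path3 <- function() {
  weighted_graph(edges = data.frame(from = c("a", "b"), to = c("b", "c"),
                                    weight = 1, stringsAsFactors = FALSE))
}

fx_star <- function(leaves = 3) {
  weighted_graph(edges = data.frame(from = "hub",
                                    to = sprintf("leaf%d", seq_len(leaves)),
                                    weight = 1, stringsAsFactors = FALSE))
}

# partition from a list of blocks
fx_partition <- function(blocks) {
  lab <- character()
  for (i in seq_along(blocks)) {
    lab[blocks[[i]]] <- paste0("blk", i)
  }
  partition(lab)
}

write_tmp_lines <- function(lines) {
  f <- withr::local_tempfile(fileext = ".tsv",
                             .local_envir = parent.frame())
  writeLines(lines, f)
  f
}
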