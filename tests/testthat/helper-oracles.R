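# Independent oracles used across the suite.

# Brute force: all non-empty node subsets of size <= k that induce a
# connected subgraph, via power-set enumeration + igraph connectivity.
brute_connected_subsets <- function(n_nodes, edges, k = 0) {
  g <- igraph::make_empty_graph(n_nodes, directed = FALSE)
  if (nrow(edges)) {
    g <- igraph::add_edges(g, rbind(edges$node_i, edges$node_j))
  }
  if (k <= 0 || k > n_nodes) k <- n_nodes
  out <- list()
  for (code in seq_len(2^n_nodes - 1)) {
    members <- which(bitwAnd(code, 2^(seq_len(n_nodes) - 1)) != 0)
    if (length(members) > k) next
    sub <- igraph::induced_subgraph(g, members)
    if (igraph::is_connected(sub)) out[[length(out) + 1]] <- members
  }
  key <- vapply(out, function(s) paste(sprintf("%06d", s), collapse = ","),
                character(1))
  out[order(lengths(out), key)]
}

# Number of distinct 6-bead binary necklaces (hexagon symmetry, rotations
# and reflections) with a marked-bead count in [min_marks, max_marks].
necklace_count_hexagon <- function(min_marks, max_marks) {
  perms <- list()
  for (r in 0:5) perms[[length(perms) + 1]] <- ((0:5 + r) %% 6) + 1
  for (r in 0:5) perms[[length(perms) + 1]] <- ((r - 0:5) %% 6) + 1
  seen <- character()
  for (code in 0:63) {
    bits <- as.integer(intToBits(code)[1:6])
    if (!(sum(bits) >= min_marks && sum(bits) <= max_marks)) next
    canon <- min(vapply(perms, function(p) paste(bits[p], collapse = ""),
                        character(1)))
    seen <- c(seen, canon)
  }
  length(unique(seen))
}

# closed-form connected-subset count for a path of p nodes with cap k
path_subset_count <- function(p, k) {
  if (k <= 0 || k > p) k <- p
  sum(vapply(seq_len(k), function(j) p - j + 1, numeric(1)))
}

subset_keys <- function(subsets) {
  vapply(subsets, function(s) paste(s, collapse = ","), character(1))
}

canonical_smiles <- function(smiles) {
  res <- molfrag:::chem_canonical(smiles)
  vapply(res, function(r) {
    if (isTRUE(r$ok)) r$canonical else NA_character_
  }, character(1))
}
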