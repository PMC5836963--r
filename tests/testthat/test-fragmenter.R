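# Fragment graphs, connected-subset enumeration, assembly, pipeline.

test_that("cutting yields a partition of the parent into base fragments", {
  # no cuts: one node holding every heavy atom
  g <- cut_to_base_fragments("c1ccccc1", ruleset = builtin_ruleset("RECAP"))
  expect_equal(length(g$nodes), 1)
  expect_equal(nrow(g$edges), 0)
  expect_equal(length(g$nodes[[1]]), 6)

  # chain with m matched bonds: m+1 nodes in a path, atoms partitioned
  for (m in c(2, 4)) {
    g <- cut_to_base_fragments(chain_molecule(m),
                               ruleset = builtin_ruleset("RECAP"))
    expect_equal(length(g$nodes), m + 1)
    expect_equal(nrow(g$edges), m)
    atoms <- sort(unlist(g$nodes))
    expect_equal(atoms, seq(0L, g$parent$heavy_atoms - 1L))  # disjoint cover
    # path topology: node degrees are 1,2,...,2,1
    deg <- table(factor(c(g$edges$node_i, g$edges$node_j),
                        levels = seq_along(g$nodes)))
    expect_equal(sort(as.integer(deg)), c(1L, 1L, rep(2L, m - 1)))
  }
})

test_that("connected-subset enumeration matches examples and brute force", {
  path3 <- list(n_nodes = 3, edges = tibble::tibble(node_i = c(1, 2),
                                                    node_j = c(2, 3)))
  got <- enumerate_connected_subsets(path3, k = 2)
  expect_equal(subset_keys(got), c("1", "2", "3", "1,2", "2,3"))

  single <- list(n_nodes = 1, edges = tibble::tibble(node_i = integer(),
                                                     node_j = integer()))
  expect_equal(length(enumerate_connected_subsets(single, k = 5)), 1)

  triangle <- list(n_nodes = 3, edges = tibble::tibble(node_i = c(1, 1, 2),
                                                       node_j = c(2, 3, 3)))
  expect_equal(length(enumerate_connected_subsets(triangle, k = 0)), 7)

  # oracle agreement on assorted small topologies (tree, star, cycle+tail)
  topologies <- list(
    list(n_nodes = 6, edges = tibble::tibble(node_i = c(1, 2, 2, 4, 4),
                                             node_j = c(2, 3, 4, 5, 6))),
    list(n_nodes = 5, edges = tibble::tibble(node_i = c(1, 1, 1, 1),
                                             node_j = c(2, 3, 4, 5))),
    list(n_nodes = 6, edges = tibble::tibble(node_i = c(1, 2, 3, 4, 4),
                                             node_j = c(2, 3, 4, 1, 5)))
  )
  for (g in topologies) {
    for (k in c(1, 2, 3, 0)) {
      got <- enumerate_connected_subsets(g, k)
      want <- brute_connected_subsets(g$n_nodes, g$edges, k)
      expect_equal(subset_keys(got), subset_keys(want))
    }
  }
})

test_that("enumeration guard aborts oversized expansions with a clear error", {
  star <- list(n_nodes = 12,
               edges = tibble::tibble(node_i = rep(1, 11), node_j = 2:12))
  expect_error(enumerate_connected_subsets(star, k = 0, guard = 50),
               class = "molfrag_guard_error")
  expect_error(enumerate_connected_subsets(star, k = 0, guard = 50), "50")
})

test_that("assembly restores internal bonds and caps boundaries", {
  g <- cut_to_base_fragments("O=C(c1ccccc1)Nc1ccccc1",
                             ruleset = builtin_ruleset("extendedRECAP"))
  expect_equal(length(g$nodes), 3)  # benzoyl | N | phenyl

  # the acyl+N pair: one boundary cut, amide bond restored
  pair <- assemble(g, 1:2, x = TRUE)
  expect_equal(pair$smiles, canonical_smiles("O=C(c1ccccc1)N*"))
  expect_equal(pair$n_cuts, 1)

  # full graph: no boundary, SMILES equals the parent canonical SMILES
  whole <- assemble(g, 1:3, x = TRUE)
  expect_equal(whole$n_cuts, 0)
  expect_false(grepl("*", whole$smiles, fixed = TRUE))
  expect_equal(whole$smiles, g$parent$canonical)

  # cap equivalence: H-capping the dummy form gives the x-off form
  with_x <- assemble(g, 2:3, x = TRUE)
  without_x <- assemble(g, 2:3, x = FALSE)
  expect_equal(canonical_smiles(gsub("\\*", "[H]", with_x$smiles)),
               without_x$smiles)
  # heavy atoms exclude caps either way; dummies are massless
  expect_equal(with_x$heavy_atoms, without_x$heavy_atoms)
  expect_lt(with_x$mol_weight, without_x$mol_weight)

  expect_error(assemble(g, c(1, 3), x = TRUE), "connected")
})

test_that("the pipeline reproduces the worked single-molecule cases", {
  # benzene: no cut bonds; the lone base fragment is the parent, dropped by s
  out <- fragment_molecules("c1ccccc1", builtin_ruleset("RECAP"),
                            k = 1, n_min = 5, s_rel = 0.99)
  expect_equal(nrow(out), 0)

  # 2-phenylethylamine + CCQ: the aminomethyl piece is below n_min
  out <- fragment_molecules("NCCc1ccccc1", builtin_ruleset("CCQ"),
                            k = 1, n_min = 5, s_rel = 0.99, x = TRUE)
  expect_equal(out$smiles, "*Cc1ccccc1")

  # two base fragments: the only size-2 subset is the parent, removed by s
  two <- "O=C(c1ccccc1)Nc1ccccc1"  # RECAP: single amide cut
  k1 <- fragment_molecules(two, builtin_ruleset("RECAP"), k = 1, n_min = 1)
  k8 <- fragment_molecules(two, builtin_ruleset("RECAP"), k = 8, n_min = 1)
  expect_equal(k1$smiles, k8$smiles)
})

test_that("pipeline filters respect heavy-atom and weight semantics", {
  mols <- tibble::tibble(compound_id = "chain", smiles = chain_molecule(2))
  rs <- builtin_ruleset("RECAP")
  # no filters: all 6 connected subsets of the 3-node path survive
  all6 <- fragment_molecules(mols, rs, k = 0, n_min = 1, s_rel = NULL)
  expect_equal(nrow(all6), 6)
  # s_rel < 1 excludes the intact parent only
  no_parent <- fragment_molecules(mols, rs, k = 0, n_min = 1, s_rel = 0.99)
  expect_equal(nrow(no_parent), 5)
  expect_false(canonical_smiles(chain_molecule(2)) %in% no_parent$smiles)
  # m_max in heavy atoms
  small <- fragment_molecules(mols, rs, k = 0, n_min = 1, s_rel = NULL,
                              m_max = 9)
  expect_true(all(small$heavy_atoms <= 9))
  expect_lt(nrow(small), 6)
  # w_max on the capped structure
  light <- fragment_molecules(mols, rs, k = 0, n_min = 1, s_rel = NULL,
                              w_max = 150)
  expect_true(all(light$mol_weight <= 150))
})

test_that("per-record failures do not abort a batch run", {
  mols <- tibble::tibble(
    compound_id = c("ok", "bad", "salt"),
    smiles = c("NCCc1ccccc1", "not_a_smiles", "CC.[Na+]")
  )
  expect_warning(
    out <- fragment_molecules(mols, builtin_ruleset("CCQ"), k = 1, x = TRUE),
    "skipped")
  expect_equal(unique(out$compound_id), "ok")
  probs <- fragmentation_problems(out)
  expect_setequal(probs$compound_id, c("bad", "salt"))
  expect_error(fragment_molecules(c(a = "CC", a = "CCC")), "duplicate")
})

test_that("fragment output is monotone in k and refined by x", {
  mols <- worked_examples()
  rs <- builtin_ruleset("extendedRECAP")
  prev <- character()
  for (k in 1:4) {
    out <- fragment_molecules(mols, rs, k = k, n_min = 5, s_rel = 0.99)
    keys <- paste(out$compound_id, out$smiles)
    expect_true(all(prev %in% keys))  # superset of the k-1 output
    prev <- keys
  }
  # dummy-capped forms refine hydrogen-capped forms per compound
  k8 <- fragment_molecules(mols, rs, k = 8, n_min = 5, s_rel = 0.99)
  k8x <- fragment_molecules(mols, rs, k = 8, n_min = 5, s_rel = 0.99, x = TRUE)
  n_off <- table(k8$compound_id)
  n_on <- table(k8x$compound_id)
  for (id in names(n_off)) {
    expect_gte(as.integer(n_on[id]), as.integer(n_off[id]))
  }
  # cut-point accounting: '*' count equals the boundary-cut count
  stars <- vapply(strsplit(k8x$smiles, ""), function(ch) sum(ch == "*"),
                  integer(1))
  expect_equal(stars, k8x$n_cuts)
})
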