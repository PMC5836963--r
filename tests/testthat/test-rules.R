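# Rule model: rule files, built-in sets, cut-bond detection.

test_that("rule files parse, auto-number, and reject bad patterns", {
  rs <- parse_rules("[C;$(C=O)]!@[#7]\tamide")
  expect_s3_class(rs, "molfrag_ruleset")
  expect_equal(nrow(rs), 1)
  expect_equal(rs$rule_id, "amide")
  expect_equal(ruleset_name(rs), "custom")

  expect_equal(nrow(parse_rules("")), 0)
  expect_equal(nrow(parse_rules("# only a comment\n\n")), 0)

  # missing ids are auto-numbered by rule position; comments/blanks skipped
  rs2 <- parse_rules("# header\n[C]!@[N]\n\n[c]!@[c]\tbiaryl")
  expect_equal(rs2$rule_id, c("rule1", "biaryl"))

  # three-atom pattern violates the two-atom invariant, reported by line
  expect_error(parse_rules("[C][N][O]"), "line 1")
  expect_error(parse_rules("[c]!@[c]\tok\nnot_a_smarts((("), "line 2")
})

test_that("rule sets round-trip through the rule-file format", {
  rs <- builtin_ruleset("RECAP")
  path <- withr::local_tempfile(fileext = ".smarts")
  write_rules(rs, path)
  back <- read_rules(path)
  expect_equal(back$rule_id, rs$rule_id)
  expect_equal(back$smarts, rs$smarts)
})

test_that("built-in rule sets have the documented shapes", {
  expect_equal(nrow(builtin_ruleset("RECAP")), 11)
  expect_equal(nrow(builtin_ruleset("CCQ")), 1)
  expect_equal(nrow(builtin_ruleset("extendedRECAP")),
               nrow(builtin_ruleset("RECAP")) + 16)
  expect_gt(nrow(builtin_ruleset("BRICS")), 0)
  expect_error(builtin_ruleset("FOO"), "RECAP, BRICS, CCQ, extendedRECAP")
})

test_that("cut-bond detection matches hand-derived cases", {
  # benzene: no rule matches anything
  expect_equal(nrow(find_cut_bonds("c1ccccc1", builtin_ruleset("RECAP"))), 0)

  # 2-phenylethylamine + CCQ: only the C-C bond whose carbon bears the N
  cuts <- find_cut_bonds("NCCc1ccccc1", builtin_ruleset("CCQ"))
  expect_equal(nrow(cuts), 1)
  expect_equal(c(cuts$atom_a, cuts$atom_b), c(1L, 2L))  # Calpha-Cbeta

  # N-phenylbenzamide + RECAP: the amide C-N bond is among the cuts
  cuts <- find_cut_bonds("O=C(c1ccccc1)Nc1ccccc1", builtin_ruleset("RECAP"))
  expect_true(any(purrr::map_lgl(cuts$rule_ids, ~ "amide" %in% .x)))
})

test_that("cut-bond detection is deterministic and direction-independent", {
  smi <- "CC(=O)Nc1ccc(OCC)cc1S(=O)(=O)NC"
  rs <- builtin_ruleset("extendedRECAP")
  a <- find_cut_bonds(smi, rs)
  b <- find_cut_bonds(smi, rs)
  expect_identical(a[c("bond_index", "atom_a", "atom_b")],
                   b[c("bond_index", "atom_a", "atom_b")])

  # reversing a rule's two-atom SMARTS yields the same bond set
  fwd <- parse_rules("[C;$(C=O)]!@[N;X3]\tamide")
  rev <- parse_rules("[N;X3]!@[C;$(C=O)]\tamide")
  for (s in c(smi, "O=C(c1ccccc1)Nc1ccccc1", chain_molecule(3))) {
    expect_equal(find_cut_bonds(s, fwd)[c("atom_a", "atom_b")],
                 find_cut_bonds(s, rev)[c("atom_a", "atom_b")])
  }
})

test_that("ring bonds are never cut, even when a SMARTS matches them", {
  # a deliberately greedy rule matching any C-N bond, including ring ones
  greedy <- parse_rules("[#6]~[#7]\tany_cn")

  # N-methyl lactam: the ring amide C-N bonds are matched but skipped;
  # only the exocyclic N-CH3 bond survives
  cuts <- find_cut_bonds("O=C1CCCCN1C", greedy)
  expect_equal(nrow(cuts), 1)

  # macrocyclic tetrapeptide: every C-N bond is in the ring -> nothing cut
  macro <- "O=C1CNC(=O)CNC(=O)CNC(=O)CN1"
  expect_equal(nrow(find_cut_bonds(macro, greedy)), 0)
  expect_equal(nrow(find_cut_bonds(macro, builtin_ruleset("extendedRECAP"))), 0)

  # naphthalene under the biaryl rule: the fusion bond is a ring bond
  expect_equal(nrow(find_cut_bonds("c1ccc2ccccc2c1",
                                   builtin_ruleset("RECAP"))), 0)

  # double bonds are not cleavable either (olefin pattern matches C=C)
  expect_equal(nrow(find_cut_bonds("CC=CC", parse_rules("[C]=!@[C]\tolefin"))), 0)
})
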