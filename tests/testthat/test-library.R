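# Library aggregation: frequencies, top-N, count distributions.

toy_fragments <- function(...) {
  rows <- list(...)
  tibble::tibble(
    compound_id = purrr::map_chr(rows, 1),
    smiles = purrr::map_chr(rows, 2)
  )
}

test_that("aggregation counts compounds per fragment", {
  lib <- fragment_library(toy_fragments(
    list("c1", "c1ccccc1"), list("c2", "c1ccccc1"), list("c2", "CCO")))
  expect_equal(lib$freq$n_compounds[lib$freq$smiles == "c1ccccc1"], 2L)
  expect_equal(nrow(lib$freq), 2)
  expect_equal(lib$n_fragmented, 2)
  # conservation: sum of frequencies == sum of per-compound counts
  expect_equal(sum(lib$freq$n_compounds), sum(lib$per_compound$n_fragments))

  empty <- fragment_library(toy_fragments())
  expect_equal(empty$n_fragmented, 0)
  expect_equal(nrow(tidy(empty)), 0)
  expect_error(count_distribution(empty), "empty")

  expect_error(
    fragment_library(toy_fragments(list("a", "CC"), list("a", "CC"))),
    "deduplicated")
})

test_that("aggregation is invariant under compound order", {
  rows <- fragment_molecules(worked_examples(), builtin_ruleset("RECAP"),
                             k = 8, n_min = 5, s_rel = 0.99, x = TRUE)
  a <- fragment_library(rows)
  b <- fragment_library(rows[rev(seq_len(nrow(rows))), ])
  expect_equal(a$freq, b$freq)
  expect_equal(dplyr::arrange(a$per_compound, compound_id),
               dplyr::arrange(b$per_compound, compound_id))
})

test_that("top fragments rank by frequency with SMILES tie-break", {
  lib <- fragment_library(toy_fragments(
    list("m1", "B"), list("m2", "B"), list("m3", "B"),
    list("m1", "A"), list("m2", "A"), list("m3", "A"),
    list("m1", "Z")))
  top <- top_fragments(lib, 2)
  expect_equal(top$smiles, c("A", "B"))  # tie at 3, A < B
  expect_equal(top$n_compounds, c(3L, 3L))
  expect_equal(nrow(top_fragments(lib, 10)), 3)  # n exceeds unique count
})

test_that("count distribution summarises fragmented compounds", {
  one <- fragment_library(toy_fragments(
    list("a", "F1"), list("a", "F2"), list("a", "F3"), list("a", "F4"),
    list("a", "F5"), list("a", "F6"), list("a", "F7")))
  expect_equal(unlist(count_distribution(one)),
               c(min = 7, q1 = 7, median = 7, q3 = 7, max = 7))

  five <- fragment_library(dplyr::bind_rows(purrr::map(1:5, function(i) {
    tibble::tibble(compound_id = paste0("c", i),
                   smiles = paste0("F", i, "_", seq_len(i)))
  })))
  d <- count_distribution(five)
  expect_equal(d$median, 3)
  expect_equal(d$min, 1)
  expect_equal(d$max, 5)

  outlier <- fragment_library(dplyr::bind_rows(
    tibble::tibble(compound_id = "a", smiles = "X1"),
    tibble::tibble(compound_id = "b", smiles = paste0("Y", 1:1000))))
  expect_equal(count_distribution(outlier)$max, 1000)
})

test_that("glance reports the library shape", {
  rows <- fragment_molecules(worked_examples(), builtin_ruleset("RECAP"),
                             k = 1, n_min = 5, s_rel = 0.99)
  g <- glance(fragment_library(rows))
  expect_equal(g$n_unique_fragments, length(unique(rows$smiles)))
  expect_equal(g$total_records, nrow(rows))
  expect_true(g$min <= g$median && g$median <= g$max)
})
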