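# Library-level aggregation: fragment frequencies over a compound set,
# per-compound fragment counts, top-N tables and count distributions.

#' Aggregate per-compound fragments into a library
#'
#' Builds a fragment library from the (already per-compound
#' deduplicated) output of [fragment_molecules()]. A fragment's
#' frequency is the number of compounds containing it, so the sum of
#' all frequencies equals the sum of per-compound fragment counts.
#'
#' @param fragments a data frame with columns `compound_id` and
#'   `smiles`, one row per compound/fragment pair.
#' @return A `fragment_library` object with elements `freq` (tibble
#'   `smiles`, `n_compounds`), `per_compound` (tibble `compound_id`,
#'   `n_fragments`; compounds with at least one fragment) and
#'   `n_fragmented`.
#' @export
fragment_library <- function(fragments) {
  stopifnot(is.data.frame(fragments),
            all(c("compound_id", "smiles") %in% names(fragments)))
  dup <- duplicated(fragments[c("compound_id", "smiles")])
  if (any(dup)) {
    stop("duplicate (compound_id, smiles) pair(s), e.g. compound ",
         fragments$compound_id[dup][1],
         "; fragment lists must be per-compound deduplicated")
  }
  freq <- fragments |>
    dplyr::count(.data$smiles, name = "n_compounds") |>
    dplyr::arrange(dplyr::desc(.data$n_compounds), .data$smiles)
  per_compound <- fragments |>
    dplyr::count(.data$compound_id, name = "n_fragments")
  structure(
    list(freq = freq, per_compound = per_compound,
         n_fragmented = nrow(per_compound)),
    class = "fragment_library"
  )
}

#' @export
print.fragment_library <- function(x, ...) {
  cat("<fragment_library: ", nrow(x$freq), " unique fragment(s) from ",
      x$n_fragmented, " fragmented compound(s)>\n", sep = "")
  invisible(x)
}

#' Most frequent fragments of a library
#'
#' @param lib a `fragment_library`.
#' @param n number of fragments to report; ranking is by frequency
#'   descending with ties broken by canonical SMILES ascending.
#' @return A tibble with columns `smiles`, `n_compounds`, of
#'   `min(n, unique fragment count)` rows.
#' @export
top_fragments <- function(lib, n = 5) {
  stopifnot(inherits(lib, "fragment_library"), n >= 1)
  utils::head(lib$freq, n)
}

#' Distribution of fragments per compound
#'
#' Five-number summary (min, lower quartile, median, upper quartile,
#' max) of the per-compound unique-fragment counts, over compounds with
#' at least one surviving fragment. Quartiles use linear interpolation
#' between order statistics ([stats::quantile()] type 7).
#'
#' @param lib a `fragment_library`.
#' @return A one-row tibble: `min`, `q1`, `median`, `q3`, `max`.
#' @export
count_distribution <- function(lib) {
  stopifnot(inherits(lib, "fragment_library"))
  counts <- lib$per_compound$n_fragments
  if (length(counts) == 0) stop("empty fragment library")
  q <- stats::quantile(counts, c(0, .25, .5, .75, 1), names = FALSE, type = 7)
  tibble::tibble(min = q[1], q1 = q[2], median = q[3], q3 = q[4], max = q[5])
}

#' Tidy a fragment library
#'
#' @param x a `fragment_library`.
#' @param ... unused.
#' @return The frequency table as a tibble (`smiles`, `n_compounds`),
#'   in top-fragment order.
#' @importFrom generics tidy
#' @export
tidy.fragment_library <- function(x, ...) x$freq

#' One-row summary of a fragment library
#'
#' @param x a `fragment_library`.
#' @param ... unused.
#' @return A one-row tibble: `n_fragmented`, `n_unique_fragments`,
#'   `total_records`, and the five-number per-compound count summary.
#' @importFrom generics glance
#' @export
glance.fragment_library <- function(x, ...) {
  base <- tibble::tibble(
    n_fragmented = x$n_fragmented,
    n_unique_fragments = nrow(x$freq),
    total_records = sum(x$freq$n_compounds)
  )
  if (x$n_fragmented > 0) {
    dplyr::bind_cols(base, count_distribution(x))
  } else {
    dplyr::bind_cols(base, tibble::tibble(min = NA_real_, q1 = NA_real_,
                                          median = NA_real_, q3 = NA_real_,
                                          max = NA_real_))
  }
}
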