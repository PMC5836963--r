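# Rule-of-three fragment-likeness panel: properties are computed on the
# capped representation exactly as emitted, so hydrogen caps on N/O
# inflate the donor count while dummy-atom caps are inert (massless, no
# H-bonding, and bonds to them are terminal).

ro3_filter_names <- c("weight", "xlogp", "hbd", "hba", "rotb")

#' Compute rule-of-three properties for fragments
#'
#' Adds five property columns computed on each fragment's capped SMILES:
#' `mol_weight` (Da; dummy atoms massless), `xlogp` (atom-contribution
#' logP estimate standing in for ClogP), `hbd` (N/O bearing at least one
#' hydrogen), `hba` (N/O excluding pyrrole-type and amide nitrogens) and
#' `rotb_nt` (rotatable non-terminal bonds: acyclic single bonds between
#' two non-terminal heavy atoms, amide C-N and bonds to dummy atoms
#' excluded).
#'
#' @param fragments a data frame with a `smiles` column (e.g. from
#'   [fragment_molecules()]), or a character vector of SMILES.
#' @return The input as a tibble with columns `mol_weight`, `xlogp`,
#'   `hbd`, `hba`, `rotb_nt` added (replacing any same-named columns).
#' @examples
#' \dontrun{
#' compute_ro3(c("c1ccccc1", "*N1CCOCC1", "C1COCCN1"))
#' }
#' @export
compute_ro3 <- function(fragments) {
  if (is.character(fragments)) {
    fragments <- tibble::tibble(smiles = fragments)
  }
  stopifnot("smiles" %in% names(fragments))
  fragments <- tibble::as_tibble(fragments)
  if (nrow(fragments) == 0) {
    for (col in c("mol_weight", "xlogp", "hbd", "hba", "rotb_nt")) {
      fragments[[col]] <- double()
    }
    return(fragments)
  }
  res <- chem_props(fragments$smiles)
  bad <- which(!purrr::map_lgl(res, function(x) isTRUE(x$ok)))
  if (length(bad)) {
    stop("fragment SMILES failed to parse: ",
         paste(fragments$smiles[utils::head(bad, 3)], collapse = ", "))
  }
  fragments$mol_weight <- purrr::map_dbl(res, "mol_weight")
  fragments$xlogp <- purrr::map_dbl(res, "xlogp")
  fragments$hbd <- purrr::map_int(res, "hbd")
  fragments$hba <- purrr::map_int(res, "hba")
  fragments$rotb_nt <- purrr::map_int(res, "rotb_nt")
  fragments
}

ro3_pass <- function(props, which) {
  switch(which,
    weight = props$mol_weight < 300,
    xlogp = props$xlogp <= 3,
    hbd = props$hbd <= 3,
    hba = props$hba <= 3,
    rotb = props$rotb_nt <= 3,
    stop("unknown rule-of-three filter: ", which,
         "; valid filters are: ", paste(ro3_filter_names, collapse = ", "))
  )
}

#' Apply rule-of-three filters to a fragment set
#'
#' Thresholds: molecular weight < 300 Da, xlogP <= 3, H-bond donors
#' <= 3, H-bond acceptors <= 3, rotatable non-terminal bonds <= 3. The
#' requested filters are applied jointly; survivor counts for each
#' filter applied separately, and for the conjunction, are attached and
#' readable with [ro3_counts()].
#'
#' @param fragments a data frame with a `smiles` column; property
#'   columns are computed on the fly when missing.
#' @param filters character subset of
#'   `c("weight", "xlogp", "hbd", "hba", "rotb")`, or `"all"`.
#' @return The surviving rows, with attribute `"ro3_counts"`.
#' @export
apply_ro3 <- function(fragments, filters = "all") {
  if (identical(filters, "all")) filters <- ro3_filter_names
  bad <- setdiff(filters, ro3_filter_names)
  if (length(bad)) {
    stop("unknown rule-of-three filter: ", paste(bad, collapse = ", "),
         "; valid filters are: ", paste(ro3_filter_names, collapse = ", "))
  }
  props <- if (all(c("mol_weight", "xlogp", "hbd", "hba", "rotb_nt") %in%
                   names(fragments)) && is.data.frame(fragments)) {
    tibble::as_tibble(fragments)
  } else {
    compute_ro3(fragments)
  }
  pass <- purrr::map(filters, function(f) ro3_pass(props, f))
  names(pass) <- filters
  keep <- Reduce(`&`, pass, rep(TRUE, nrow(props)))
  counts <- tibble::tibble(
    filter = c(filters, "combined"),
    survivors = unname(c(purrr::map_int(pass, sum), sum(keep)))
  )
  out <- props[keep, , drop = FALSE]
  attr(out, "ro3_counts") <- counts
  out
}

#' Survivor counts of a rule-of-three filtering
#' @param x the tibble returned by [apply_ro3()].
#' @return A tibble with columns `filter` and `survivors`; the
#'   `"combined"` row is the conjunction of all requested filters.
#' @export
ro3_counts <- function(x) {
  attr(x, "ro3_counts") %||%
    stop("no rule-of-three counts attached; run apply_ro3() first")
}
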