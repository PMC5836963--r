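# Built-in test substrates: deterministic molecules that exercise every
# stage of the pipeline without any external data set.

ring_digit <- function(d) if (d < 10) as.character(d) else paste0("%", d)

#' Synthetic chain molecule with a known number of cleavable bonds
#'
#' Builds a linear oligo(benzamide): phenyl units joined by `m` amide
#' bonds. Under the RECAP rules exactly the `m` amide C-N bonds are
#' cleavable, so the fragment-adjacency graph is a path of `m + 1`
#' nodes and every base fragment has at least five heavy atoms (the
#' default minimum-size filter never interferes). This makes the
#' closed-form subset count \eqn{\sum_{j=1}^{\min(k, m+1)} (m+2-j)}
#' (and \eqn{(m+1)(m+2)/2} when unlimited) directly testable.
#'
#' @param m number of cleavable (amide) bonds, `m >= 0`.
#' @return A SMILES string.
#' @examples
#' chain_molecule(0)  # benzene: nothing to cleave
#' chain_molecule(2)  # three base fragments in a path
#' @export
chain_molecule <- function(m) {
  stopifnot(m >= 0)
  if (m == 0) return("c1ccccc1")
  inner <- function(i) {
    d <- ring_digit(i)
    if (i == m + 1) {
      paste0("C(=O)Nc", d, "ccccc", d)
    } else {
      paste0("C(=O)Nc", d, "ccc(", inner(i + 1), ")cc", d)
    }
  }
  paste0("c1ccc(", inner(2), ")cc1")
}

#' Count distinct capped benzene representations
#'
#' Enumerates every subset of the six benzene ring positions with a
#' cut-point count in `[min_cuts, max_cuts]`, attaches a dummy atom at
#' each selected position, canonicalizes, and counts the distinct
#' SMILES. Because canonicalization identifies rotated and reflected
#' substitution patterns, the result equals the number of binary
#' necklaces of six beads under the dihedral symmetry of the hexagon
#' (e.g. three doubly-cut forms: ortho, meta, para; eleven forms with
#' one to five cut points in total).
#'
#' @param min_cuts,max_cuts cut-point count range, `0 <= min <= max <= 6`.
#' @return Number of distinct capped representations.
#' @export
benzene_pattern_count <- function(min_cuts, max_cuts) {
  stopifnot(min_cuts >= 0, max_cuts <= 6, min_cuts <= max_cuts)
  decorate <- function(sel) {
    tok <- character(6)
    tok[1] <- paste0("c1", if (1 %in% sel) "(*)" else "")
    for (i in 2:5) tok[i] <- paste0("c", if (i %in% sel) "(*)" else "")
    tok[6] <- paste0("c1", if (6 %in% sel) "*" else "")
    paste(tok, collapse = "")
  }
  smi <- character()
  for (size in min_cuts:max_cuts) {
    sets <- if (size == 0) list(integer()) else
      utils::combn(6, size, simplify = FALSE)
    smi <- c(smi, vapply(sets, decorate, character(1)))
  }
  res <- chem_canonical(smi)
  ok <- purrr::map_lgl(res, function(r) isTRUE(r$ok))
  if (!all(ok)) stop("internal error: decorated benzene SMILES failed to parse")
  length(unique(purrr::map_chr(res, "canonical")))
}

#' Worked-example molecules
#'
#' A curated fixture set covering the behaviours the fragmenter must
#' reproduce: benzene rings behind cleavable substituents (one to five),
#' N-linked and C-linked morpholines (cut points on or off the ring
#' nitrogen), sulphonamides, amide/ester/amine substrates for RECAP, a
#' heteroatom-flanked C-C bond for CCQ, and a macrocyclic peptide-like
#' ring that no rule can open.
#'
#' @return A tibble with columns `compound_id`, `smiles`, `motif`.
#' @export
worked_examples <- function() {
  tibble::tribble(
    ~compound_id, ~smiles, ~motif,
    "benzanilide",      "O=C(c1ccccc1)Nc1ccccc1",            "amide",
    "anisole",          "COc1ccccc1",                        "benzene_1cut",
    "dimethoxybenzene", "COc1ccc(OC)cc1",                    "benzene_2cut",
    "trimethoxybenzene","COc1cc(OC)cc(OC)c1",                "benzene_3cut",
    "pentamethoxybenzene", "c1c(OC)c(OC)c(OC)c(OC)c1OC",     "benzene_5cut",
    "benzylmorpholine", "C(N1CCOCC1)c1ccccc1",               "morpholine_N",
    "benzylmorpholine_C", "C(C1CNCCO1)c1ccccc1",             "morpholine_C",
    "tosylamide",       "Cc1ccc(cc1)S(=O)(=O)NC(C)C",        "sulfonamide",
    "ethylbenzoate",    "CCOC(=O)c1ccccc1",                  "ester",
    "benzyldimethylamine", "CN(C)Cc1ccccc1",                 "amine",
    "phenethylamine",   "NCCc1ccccc1",                       "ccq",
    "cyclotetraglycine","O=C1CNC(=O)CNC(=O)CNC(=O)CN1",      "macrocycle"
  )
}

# building blocks for the synthetic drug-like library; each left part
# ends, and each right part starts, at its attachment atom
syn_left <- c(
  "c1ccccc1", "COc1ccccc1", "c1ccncc1", "C1CCCCC1", "Cc1ccccc1",
  "c1ccc2ccccc2c1", "c1ccsc1", "FC(F)(F)c1ccccc1", "CC(C)", "c1cnccc1O"
)
syn_linker <- c(
  "C(=O)N", "C(=O)O", "S(=O)(=O)N", "NC(=O)N", "CN", "OC", "CSC",
  "C(=O)C", "CC(=O)N"
)
syn_right <- c(
  "c1ccccc1", "N1CCOCC1", "C1CCNCC1", "CC(C)C", "c1ccc(F)cc1",
  "C1CCOC1", "CCO", "Cc1ccco1"
)

#' Generate a synthetic drug-like compound library
#'
#' Assembles small molecules by combining aromatic/aliphatic scaffolds,
#' common linkers (amide, ester, sulphonamide, urea, amine, ether,
#' thioether, ketone) and capping groups. The set emulates the motif
#' composition of a drug library for distribution-level tests; it does
#' not attempt to reproduce any real compound collection.
#'
#' @param n number of molecules (at most the number of distinct
#'   combinations, 720).
#' @param seed optional integer; when given, the `n` molecules are
#'   sampled from the full combination grid under this seed, otherwise
#'   a fixed interleaved selection is used.
#' @return A tibble with columns `compound_id`, `smiles`.
#' @export
synthetic_library <- function(n = 50, seed = NULL) {
  grid <- expand.grid(left = syn_left, linker = syn_linker,
                      right = syn_right, stringsAsFactors = FALSE)
  stopifnot(n >= 1, n <= nrow(grid))
  idx <- if (is.null(seed)) {
    # fixed stride walks the grid so all three factors vary early
    (seq_len(n) * 97L) %% nrow(grid) + 1L
  } else {
    withr::with_seed(seed, sample.int(nrow(grid), n))
  }
  tibble::tibble(
    compound_id = sprintf("SYN%03d", seq_len(n)),
    smiles = paste0(grid$left[idx], grid$linker[idx], grid$right[idx])
  )
}
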