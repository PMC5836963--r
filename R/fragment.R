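# Exhaustive fragmentation: cut every rule-matched acyclic single bond
# to obtain the smallest (base) fragments, build the fragment-adjacency
# graph, enumerate all connected unions of up to k base fragments, and
# reassemble each union into a capped fragment structure.

#' Cut a molecule into its smallest fragments
#'
#' Removes the given cut bonds from the molecular graph and returns the
#' fragment-adjacency graph: nodes are the connected components that
#' remain (the smallest fragments, as 0-based atom-index sets), edges
#' are the cut bonds joining them. With no cuts the graph has a single
#' node holding every heavy atom.
#'
#' @param smiles a single SMILES string.
#' @param cuts a cut-bond tibble as returned by [find_cut_bonds()];
#'   defaults to applying `ruleset`.
#' @param ruleset rule set used when `cuts` is not supplied.
#' @return A `fragment_graph` object: list with `parent` (canonical
#'   SMILES, heavy-atom count, molecular weight, bond table), `nodes`
#'   (list of integer atom-index vectors) and `edges` (tibble with
#'   `node_i`, `node_j`, `bond_index`, `atom_a`, `atom_b`).
#' @export
cut_to_base_fragments <- function(smiles, cuts = NULL,
                                  ruleset = builtin_ruleset("RECAP")) {
  stopifnot(is.character(smiles), length(smiles) == 1)
  res <- chem_analyze(smiles, if (is.null(cuts)) ruleset$smarts else character())
  mol <- res$mols[[1]]
  if (!isTRUE(mol$ok)) stop("SMILES failed to parse: ", smiles)
  if (is.null(cuts)) {
    cuts <- cut_bonds_for_mol(mol, res$matches[[1]], ruleset$rule_id)
  }
  build_fragment_graph(mol, cuts, smiles)
}

# mol: analyzed molecule (backend list); cuts: cut-bond tibble
build_fragment_graph <- function(mol, cuts, input_smiles) {
  bonds <- bond_table(mol)
  n_atoms <- if (nrow(bonds)) max(bonds$a, bonds$b) + 1L else mol$heavy_atoms
  n_atoms <- max(n_atoms, mol$heavy_atoms)
  keep <- !(bonds$index %in% cuts$bond_index)
  # connected components of the bond-deleted graph (atoms are 0-based)
  g <- igraph::graph_from_edgelist(
    cbind(bonds$a[keep] + 1L, bonds$b[keep] + 1L), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n_atoms - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  # stable node order: by smallest atom index in each component
  comp_ids <- unique(comp[order(seq_along(comp))])
  node_of_atom <- match(comp, comp_ids)
  nodes <- lapply(seq_along(comp_ids), function(i) {
    sort(which(node_of_atom == i) - 1L)
  })
  edges <- tibble::tibble(
    node_i = node_of_atom[cuts$atom_a + 1L],
    node_j = node_of_atom[cuts$atom_b + 1L],
    bond_index = cuts$bond_index,
    atom_a = cuts$atom_a,
    atom_b = cuts$atom_b
  )
  structure(
    list(
      parent = list(
        smiles = input_smiles,
        canonical = mol$canonical,
        heavy_atoms = mol$heavy_atoms,
        mol_weight = mol$mol_weight
      ),
      nodes = nodes,
      edges = edges
    ),
    class = "fragment_graph"
  )
}

#' @export
print.fragment_graph <- function(x, ...) {
  cat("<fragment_graph: ", length(x$nodes), " base fragment(s), ",
      nrow(x$edges), " cut bond(s); parent ", x$parent$canonical, ">\n",
      sep = "")
  invisible(x)
}

# adjacency list (1-based) from a fragment graph or an edge matrix
adjacency_list <- function(n_nodes, edges) {
  adj <- rep(list(integer()), n_nodes)
  if (nrow(edges)) {
    for (r in seq_len(nrow(edges))) {
      i <- edges$node_i[r]; j <- edges$node_j[r]
      adj[[i]] <- c(adj[[i]], j)
      adj[[j]] <- c(adj[[j]], i)
    }
    adj <- lapply(adj, function(v) sort(unique(v)))
  }
  adj
}

#' Enumerate connected subsets of base fragments
#'
#' Lists every non-empty node set that induces a connected subgraph of
#' the fragment-adjacency graph and contains at most `k` nodes. `k <= 0`
#' (or `k` at least the node count) means unlimited: every connected
#' subset is produced, which is the exhaustive fragmentation regime.
#'
#' The enumeration grows subgraphs from each seed node over
#' exclusive-neighbourhood extension sets, so every connected subset is
#' visited exactly once (no duplicate canonicalization pass is needed);
#' a brute-force power-set oracle is used in the test suite to confirm
#' agreement on small graphs.
#'
#' @param graph a `fragment_graph`, or a plain list with elements
#'   `n_nodes` and `edges` (tibble with `node_i`, `node_j`) for direct
#'   topological use.
#' @param k maximum number of base fragments per subset; `<= 0` for
#'   unlimited.
#' @param guard maximum number of subsets before the enumeration aborts
#'   with an error (combinatorial guard).
#' @return A list of sorted integer vectors (1-based node indices),
#'   ordered by size then lexicographically.
#' @export
enumerate_connected_subsets <- function(graph, k, guard = 1e5) {
  if (inherits(graph, "fragment_graph")) {
    n <- length(graph$nodes)
    edges <- graph$edges
  } else {
    n <- graph$n_nodes
    edges <- graph$edges
  }
  adj <- adjacency_list(n, edges)
  if (k <= 0 || k > n) k <- n
  out <- vector("list", 64L)
  count <- 0L
  emit <- function(sub) {
    count <<- count + 1L
    if (count > guard) {
      stop(structure(
        class = c("molfrag_guard_error", "error", "condition"),
        list(message = paste0(
          "connected-subset enumeration exceeded the guard cap of ", guard,
          " subsets; raise `guard` to proceed"), call = NULL)))
    }
    if (count > length(out)) length(out) <<- 2L * count
    out[[count]] <<- sub
  }
  # grow from each seed v using only nodes > v; `blocked` marks nodes in
  # the subgraph or already reachable through its neighbourhood, so each
  # connected subset is generated exactly once
  extend <- function(sub, ext, blocked, v) {
    emit(sort(sub))
    if (length(sub) >= k) return()
    while (length(ext)) {
      w <- ext[1]
      ext <- ext[-1]
      fresh <- adj[[w]][adj[[w]] > v & !blocked[adj[[w]]]]
      blocked2 <- blocked
      blocked2[fresh] <- TRUE
      extend(c(sub, w), c(ext, fresh), blocked2, v)
    }
  }
  for (v in seq_len(n)) {
    blocked <- rep(FALSE, n)
    blocked[seq_len(v)] <- TRUE
    fresh <- adj[[v]][adj[[v]] > v]
    blocked[fresh] <- TRUE
    extend(v, fresh, blocked, v)
  }
  out <- out[seq_len(count)]
  key <- vapply(out, function(s) paste(sprintf("%06d", s), collapse = ","),
                character(1))
  out[order(lengths(out), key)]
}

# boundary cut bonds for a member set: edges with exactly one endpoint inside
boundary_cuts <- function(graph, members) {
  e <- graph$edges
  inside_i <- e$node_i %in% members
  inside_j <- e$node_j %in% members
  e[xor(inside_i, inside_j), , drop = FALSE]
}

#' Reassemble a connected set of base fragments
#'
#' Restores every parent bond internal to the member set (including cut
#' bonds between member fragments) and caps each boundary cut with a
#' dummy atom (`x = TRUE`, written `*` in SMILES) or an implicit
#' hydrogen (`x = FALSE`).
#'
#' @param graph a `fragment_graph`.
#' @param members integer vector of node indices (1-based), connected in
#'   the graph.
#' @param x logical; cap cut points with dummy atoms instead of hydrogens.
#' @return A one-row tibble: `smiles` (capped canonical SMILES),
#'   `heavy_atoms` (dummy atoms and hydrogens excluded), `mol_weight`
#'   (capped structure; dummy atoms are massless), `n_cuts` (boundary
#'   cut count), `n_base` (member count).
#' @export
assemble <- function(graph, members, x = FALSE) {
  assemble_batch(graph, list(sort(unique(members))), x)
}

# batch assembly of many member sets of one fragment graph
assemble_batch <- function(graph, member_sets, x) {
  check_connected_members(graph, member_sets)
  jobs <- purrr::map(member_sets, function(m) {
    cuts <- boundary_cuts(graph, m)
    list(
      parent = 0L,
      atoms = I(as.list(unlist(graph$nodes[m]))),
      cuts = purrr::map2(cuts$atom_a, cuts$atom_b, c),
      x = x
    )
  })
  res <- chem_assemble(graph$parent$smiles, jobs)
  tibble::tibble(
    members = member_sets,
    smiles = purrr::map_chr(res, "smiles"),
    heavy_atoms = purrr::map_int(res, "heavy_atoms"),
    mol_weight = purrr::map_dbl(res, "mol_weight"),
    n_cuts = purrr::map_int(jobs, function(j) length(j$cuts)),
    n_base = lengths(member_sets)
  )
}

check_connected_members <- function(graph, member_sets) {
  adj <- adjacency_list(length(graph$nodes), graph$edges)
  for (m in member_sets) {
    if (length(m) == 0) stop("empty member set")
    seen <- m[1]
    frontier <- m[1]
    while (length(frontier)) {
      nxt <- setdiff(intersect(unlist(adj[frontier]), m), seen)
      seen <- c(seen, nxt)
      frontier <- nxt
    }
    if (length(seen) != length(m)) {
      stop("member set {", paste(m, collapse = ","),
           "} does not induce a connected subgraph")
    }
  }
  invisible(TRUE)
}

#' Fragmentation parameters
#'
#' Bundles the tunable parameters of the fragmentation pipeline. Atom
#' counts (`n_min`, `m_max`, `s_rel`) refer to heavy atoms only; dummy
#' atoms and hydrogens never count, so the size filters are invariant
#' under the `x` flag.
#'
#' @param k maximum number of smallest fragments combined per output
#'   fragment; `<= 0` means unlimited (fully exhaustive). `k = 1`
#'   reproduces plain smallest-fragment output.
#' @param n_min minimal heavy-atom count of an output fragment.
#' @param m_max maximal heavy-atom count, or `NULL` for no limit.
#' @param s_rel maximal fragment size relative to the parent, a fraction
#'   in (0, 1], or `NULL`. A fragment passes iff
#'   `heavy_atoms <= s_rel * parent_heavy_atoms` (real-valued, no
#'   rounding), so any value below 1 excludes the intact parent.
#' @param w_max maximal molecular weight in Daltons of the capped
#'   structure, or `NULL`.
#' @param x logical; cap cut points with dummy atoms (`*`) rather than
#'   hydrogens.
#' @param guard maximal number of connected subsets enumerated per
#'   molecule before the record fails with a guard error.
#' @return A list of class `fragmentation_params`.
#' @export
fragmentation_params <- function(k = 1, n_min = 5, m_max = NULL, s_rel = 0.99,
                                 w_max = NULL, x = FALSE, guard = 1e5) {
  stopifnot(n_min >= 1)
  if (!is.null(s_rel)) stopifnot(s_rel > 0, s_rel <= 1)
  structure(
    list(k = k, n_min = n_min, m_max = m_max, s_rel = s_rel, w_max = w_max,
         x = isTRUE(x), guard = guard),
    class = "fragmentation_params"
  )
}

passes_filters <- function(frags, params, parent_heavy) {
  ok <- frags$heavy_atoms >= params$n_min
  if (!is.null(params$m_max)) ok <- ok & frags$heavy_atoms <= params$m_max
  if (!is.null(params$s_rel)) {
    ok <- ok & frags$heavy_atoms <= params$s_rel * parent_heavy
  }
  if (!is.null(params$w_max)) ok <- ok & frags$mol_weight <= params$w_max
  ok
}

#' Fragment a set of molecules exhaustively
#'
#' End-to-end pipeline: match the rule set against each molecule, cut
#' every matched acyclic single bond to obtain the smallest fragments,
#' enumerate all connected combinations of up to `k` of them, reassemble
#' each combination with capped cut points, apply the size/weight
#' filters, and deduplicate per compound by capped canonical SMILES.
#'
#' Unparsable or multi-component (salt-like) records are skipped with a
#' diagnostic rather than aborting the run; see [fragmentation_problems()].
#'
#' @param molecules a data frame with columns `compound_id` and
#'   `smiles`, or a character vector of SMILES (names used as ids,
#'   otherwise `MOL1`, `MOL2`, ...).
#' @param ruleset a ruleset tibble (default RECAP).
#' @param k,n_min,m_max,s_rel,w_max,x,guard see [fragmentation_params()];
#'   the defaults (`k = 1`, `n_min = 5`, `s_rel = 0.99`) correspond to a
#'   standard smallest-fragment run in which the intact parent is never
#'   returned.
#' @param params a ready-made [fragmentation_params()] object; overrides
#'   the individual arguments.
#' @return A tibble with one row per surviving fragment: `compound_id`,
#'   `smiles` (capped canonical SMILES), `heavy_atoms`, `mol_weight`,
#'   `n_cuts`, `n_base`; within each compound rows are sorted by
#'   (`heavy_atoms`, `smiles`). Per-record diagnostics are attached as
#'   attribute `"problems"`, the parameter bundle as attribute
#'   `"params"`.
#' @examples
#' \dontrun{
#' mols <- tibble::tibble(compound_id = "pea", smiles = "NCCc1ccccc1")
#' fragment_molecules(mols, builtin_ruleset("CCQ"), k = 1, x = TRUE)
#' }
#' @export
fragment_molecules <- function(molecules, ruleset = builtin_ruleset("RECAP"),
                               k = 1, n_min = 5, m_max = NULL, s_rel = 0.99,
                               w_max = NULL, x = FALSE, guard = 1e5,
                               params = NULL) {
  if (is.null(params)) {
    params <- fragmentation_params(k = k, n_min = n_min, m_max = m_max,
                                   s_rel = s_rel, w_max = w_max, x = x,
                                   guard = guard)
  }
  mols <- as_molecule_table(molecules)
  if (anyDuplicated(mols$compound_id)) {
    stop("duplicate compound_id: ",
         paste(unique(mols$compound_id[duplicated(mols$compound_id)]),
               collapse = ", "))
  }
  analysis <- chem_analyze(mols$smiles, ruleset$smarts)

  problems <- list()
  graphs <- vector("list", nrow(mols))
  subset_lists <- vector("list", nrow(mols))
  for (i in seq_len(nrow(mols))) {
    mol <- analysis$mols[[i]]
    if (!isTRUE(mol$ok)) {
      problems[[length(problems) + 1]] <- tibble::tibble(
        compound_id = mols$compound_id[i], message = "SMILES failed to parse")
      next
    }
    if (mol$n_components > 1) {
      problems[[length(problems) + 1]] <- tibble::tibble(
        compound_id = mols$compound_id[i],
        message = "multi-component SMILES (salt?); record skipped")
      next
    }
    cuts <- cut_bonds_for_mol(mol, analysis$matches[[i]], ruleset$rule_id)
    graphs[[i]] <- build_fragment_graph(mol, cuts, mols$smiles[i])
    subset_lists[[i]] <- tryCatch(
      enumerate_connected_subsets(graphs[[i]], params$k, params$guard),
      molfrag_guard_error = function(e) {
        problems[[length(problems) + 1]] <<- tibble::tibble(
          compound_id = mols$compound_id[i], message = conditionMessage(e))
        NULL
      }
    )
  }

  # one backend call assembles every subset of every molecule
  live <- which(!purrr::map_lgl(subset_lists, is.null))
  jobs <- list()
  job_owner <- integer()
  for (i in live) {
    g <- graphs[[i]]
    for (m in subset_lists[[i]]) {
      cuts <- boundary_cuts(g, m)
      jobs[[length(jobs) + 1]] <- list(
        parent = match(i, live) - 1L,
        atoms = I(as.list(unlist(g$nodes[m]))),
        cuts = purrr::map2(cuts$atom_a, cuts$atom_b, c),
        x = params$x
      )
      job_owner <- c(job_owner, i)
    }
  }
  empty <- tibble::tibble(
    compound_id = character(), smiles = character(), heavy_atoms = integer(),
    mol_weight = double(), n_cuts = integer(), n_base = integer()
  )
  if (length(jobs) == 0) {
    return(finish_fragments(empty, problems, params))
  }
  res <- chem_assemble(mols$smiles[live], jobs)
  frags <- tibble::tibble(
    compound_id = mols$compound_id[job_owner],
    smiles = purrr::map_chr(res, "smiles"),
    heavy_atoms = purrr::map_int(res, "heavy_atoms"),
    mol_weight = purrr::map_dbl(res, "mol_weight"),
    n_cuts = purrr::map_int(jobs, function(j) length(j$cuts)),
    n_base = purrr::map_int(jobs, function(j) {
      # member count is recoverable from the subset list, carried below
      NA_integer_
    })
  )
  frags$n_base <- unlist(purrr::map(live, function(i) {
    lengths(subset_lists[[i]])
  }))
  frags$parent_heavy <- purrr::map_int(
    graphs[job_owner], function(g) g$parent$heavy_atoms)
  frags <- frags[passes_filters(frags, params, frags$parent_heavy), ]
  frags$parent_heavy <- NULL
  out <- frags |>
    dplyr::group_by(.data$compound_id) |>
    dplyr::arrange(.data$heavy_atoms, .data$smiles, .by_group = TRUE) |>
    dplyr::distinct(.data$smiles, .keep_all = TRUE) |>
    dplyr::ungroup()
  out <- out[order(match(out$compound_id, mols$compound_id)), ]
  finish_fragments(out, problems, params)
}

finish_fragments <- function(out, problems, params) {
  probs <- if (length(problems)) dplyr::bind_rows(problems) else
    tibble::tibble(compound_id = character(), message = character())
  if (nrow(probs)) {
    warning(nrow(probs), " record(s) skipped during fragmentation; see ",
            "fragmentation_problems()", call. = FALSE)
  }
  attr(out, "problems") <- probs
  attr(out, "params") <- params
  out
}

#' Per-record diagnostics of a fragmentation run
#' @param fragments the tibble returned by [fragment_molecules()].
#' @return A tibble with columns `compound_id`, `message`.
#' @export
fragmentation_problems <- function(fragments) {
  attr(fragments, "problems") %||%
    tibble::tibble(compound_id = character(), message = character())
}

as_molecule_table <- function(molecules) {
  if (is.character(molecules)) {
    ids <- names(molecules)
    if (is.null(ids) || any(!nzchar(ids))) {
      auto <- paste0("MOL", seq_along(molecules))
      if (is.null(ids)) ids <- auto else ids[!nzchar(ids)] <- auto[!nzchar(ids)]
    }
    return(tibble::tibble(compound_id = ids, smiles = unname(molecules)))
  }
  stopifnot(is.data.frame(molecules),
            all(c("compound_id", "smiles") %in% names(molecules)))
  tibble::tibble(compound_id = as.character(molecules$compound_id),
                 smiles = as.character(molecules$smiles))
}
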