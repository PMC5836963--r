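---
title: "Exhaustive fragmentation: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exhaustive fragmentation: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The procedure

`molfrag` fragments a molecule in four stages.

**1. Cut-bond detection.** Every rule of the active rule set is a SMARTS
pattern spanning exactly two atoms joined by one bond; each match marks
that bond as a cleavage candidate. A candidate is cut only when the bond
is acyclic and of single order — matches on ring or multiple bonds are
silently skipped, so rings are always preserved and the published RECAP
"olefin" pattern (a C=C double bond) never produces a cut here. Each
physical bond is recorded once, with every rule that matched it;
matching is direction-independent because bonds are normalised to
ordered atom pairs.

**2. Smallest fragments and the fragment-adjacency graph.** Deleting all
cut bonds partitions the heavy atoms into connected components — the
smallest (base) fragments. The quotient graph with one node per base
fragment and one edge per cut bond is the substrate for everything that
follows. It is always connected (the parent is a single component), and
because cut bonds are acyclic it is in fact a tree for every real
molecule; the enumeration below does not rely on that and handles
arbitrary graphs.

**3. Connected-subset enumeration.** Exhaustive fragmentation emits
every node set that induces a connected subgraph and contains at most
`k` nodes (`k <= 0` means no cap). The enumerator grows subgraphs from
each seed node, extending only through the exclusive neighbourhood of
the current subgraph and only towards higher-numbered nodes, so each
connected subset is generated exactly once without a deduplication
pass. Output order is deterministic: by subset size, then
lexicographically by node indices. A configurable guard (default
100,000 subsets per molecule) aborts pathological cases with a
per-record error rather than stalling a library run; drug-sized
molecules stay far below it. The test suite checks the enumerator
against a power-set-plus-connectivity brute force on assorted small
topologies and against the closed form for path graphs,
$\sum_{j=1}^{\min(k,p)} (p - j + 1)$ for a path of $p$ nodes.

**4. Reassembly and capping.** For each subset, all parent bonds
internal to the member atoms — including cut bonds between member
fragments — are restored, and each boundary cut (an edge with exactly
one endpoint in the subset) becomes a cap: an implicit hydrogen by
default, or a dummy atom (`*`, no element, zero mass) when the `x` flag
is on. The capped structure is canonicalized; the dummy-atom count of a
fragment always equals its boundary-cut count. Dummy capping is the
finer representation: hydrogen capping is a many-to-one projection of
dummy-capped forms, so per compound the dummy-capped fragment set is
never smaller.

## Parameters

| parameter | meaning | unit | default |
|---|---|---|---|
| `k` | max base fragments combined; `<= 0` unlimited | count | 1 |
| `n_min` | minimal fragment size | heavy atoms | 5 |
| `m_max` | maximal fragment size | heavy atoms | off |
| `s_rel` | maximal size relative to parent | fraction (0, 1] | 0.99 |
| `w_max` | maximal weight of the capped structure | Da | off |
| `x` | dummy-atom caps | flag | off |
| `guard` | subset cap per molecule | count | 100,000 |

The defaults correspond to the standard run configuration of the study
this package operationalises: minimum five atoms, relative size 0.99
(any fragment missing at least one heavy atom passes, the intact parent
never does), with `k = 1` for classical smallest-fragment output and
`k = 8` for exhaustive runs — `k = 8` being an empirical sweet spot
beyond which additional combinations add little for drug-sized
molecules.

Three size-filter choices are deliberate and keep the filters invariant
under `x`:

* **Atom counting** uses heavy atoms only; hydrogens and dummy atoms
  never count. (Whether the original tooling counted hydrogens is
  unrecorded; heavy-atom counting is the only choice under which the
  same `n`/`s` settings behave identically with and without dummy
  caps.)
* **The `s` filter** is the real-valued comparison
  `heavy_atoms <= s_rel * parent_heavy_atoms`, no rounding.
* **Molecular weight** is computed on the capped structure; dummy atoms
  contribute zero mass, hydrogen caps contribute normally.

## Fragment identity and deduplication

Fragment identity is the capped canonical SMILES at constitution level:
stereochemistry is stripped before canonicalization, since cut-point
analysis concerns bonding patterns, not configuration. Within each
compound, fragments are deduplicated by this identity before any
aggregation; at the library level, a fragment's frequency is the number
of compounds containing it. This two-level convention is what makes
dummy capping informative: two benzene rings cut differently collapse
to one hydrogen-capped fragment but remain distinct dummy-capped
fragments. Output rows are ordered by (heavy atoms, SMILES) within a
compound for reproducibility; library-level rankings break frequency
ties by SMILES ascending.

## Rule sets

* **RECAP** — the 11 published retrosynthetic bond types (amide, ester,
  amine, urea, ether, olefin, quaternary nitrogen, aromatic N–aliphatic
  C, lactam N–aliphatic C, biaryl, sulphonamide), each recast as a
  two-atom cleavage SMARTS. Under this recast N-phenylbenzamide
  receives exactly one RECAP cut (the amide C–N); the N–aryl bond is
  not one of the 11 bond types.
* **BRICS** — the BRICS bond definitions folded into two-atom patterns.
  Link-atom environment labels are not emitted: this tool needs cut
  positions, not recombination typing.
* **CCQ** — one rule: cleave a C–C bond where at least one carbon has a
  heteroatom neighbour.
* **extendedRECAP** — RECAP plus 16 rules covering sulphur (sulfone,
  sulfoxide, thioether, disulfide, thioamide, thioester), phosphorus
  (P–O, P–C, P–N) and further carbon/nitrogen environments (carbamate
  flanks, benzylic and α-to-carbonyl C–C, aryl amines, amidines, acyl
  C–C). The literal SMARTS of the original extension are not published;
  this set reproduces the documented chemistry families and should be
  read as an extendedRECAP-*style* approximation — absolute fragment
  counts under it are not comparable with the original's.

User rule files (one `SMARTS<TAB>rule_id` per line) are validated at
load: every pattern must parse and span exactly two atoms joined by one
bond, with violations reported by line number. Symmetric patterns such
as `[c]!@[c]` are deduplicated by normalised atom pairs so a bond is
never counted twice.

## Rule-of-three panel

Thresholds: MW < 300 Da, xlogP ≤ 3, HBD ≤ 3, HBA ≤ 3, rotatable
non-terminal bonds ≤ 3; filters can be applied separately or jointly,
with survivor counts per filter and for the conjunction. Definitions
are deliberately simple and documented so counts are reproducible:

* **HBD**: N or O bearing at least one hydrogen. Hydrogen caps on N/O
  therefore inflate the count — the distortion that motivates dummy
  capping — while dummy caps do not.
* **HBA**: N or O, excluding pyrrole-type nitrogens (aromatic N with
  three sigma bonds) and amide nitrogens.
* **Rotatable non-terminal bonds**: acyclic single bonds whose two
  endpoints are each bonded to at least two real heavy atoms; amide C–N
  bonds and bonds to dummy atoms (terminal by construction) are
  excluded.
* **xlogP**: the Crippen atom-contribution logP estimator. Any
  atom-additive logP would do for a threshold filter; absolute
  xlogp-survivor counts are estimator-dependent and should not be
  compared across implementations.

## Synthetic data

Two generators make every stage testable without external data.
`chain_molecule(m)` builds an oligo(benzamide) whose fragment graph
under RECAP is a path of `m + 1` nodes, each base fragment ≥ 5 heavy
atoms, so combinatorial claims can be checked against closed forms
without filter interference. `synthetic_library(n, seed)` assembles up
to 720 small molecules from aromatic/aliphatic scaffolds, common
linkers (amide, ester, sulphonamide, urea, amine, ether, thioether,
ketone) and capping groups. It emulates the *motif composition* of a
drug library — enough for monotonicity and distribution-level tests —
but not its size distribution, scaffold diversity or decoration
density; absolute fragment counts from it say nothing about real drug
collections, and passing tests on it demonstrate algorithmic
correctness, not chemical coverage. The default test problem sizes
(50-molecule libraries, chains up to m = 8, subsets up to a few
thousand per molecule) were chosen as the smallest sets that exercise
every code path with headroom.

## Degenerate inputs and failure handling

Unparsable SMILES and multi-component records (salts; detected by
component count after parsing) are skipped with per-record diagnostics
rather than aborting a run — salt stripping is treated as upstream
preprocessing, not fragmentation. A molecule with no rule match yields
its single base fragment, which any `s_rel < 1` removes, so such
compounds simply contribute nothing. Guard-cap overruns are per-record
errors. The whole pipeline is deterministic: repeated runs on the same
input are byte-identical.

## Known limitations

* The extendedRECAP extension is a documented approximation (above).
* Ring bonds are never cut, so macrocycle-dominated structures may
  yield no fragments under any built-in rule set; opening rings
  requires purpose-built rules and is out of scope.
* Stereochemistry is discarded; enantiomeric fragments are identified.
* Fragment recombination chemistry (BRICS-style link typing,
  retrosynthesis-aware rebuilding) and downstream clustering/enrichment
  analysis of fragment libraries are out of scope.
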