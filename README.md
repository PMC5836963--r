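# molfrag

Exhaustive molecular fragmentation with cut-point capping, for
fragment-based drug discovery.

Deconstructing a hit molecule into "deletion analogues" is how medicinal
chemists locate the pharmacophore — the minimal arrangement of features
responsible for target recognition. Standard retrosynthetic fragmenters
(RECAP, BRICS) return only the *smallest* fragments, which often splits
a pharmacophore across pieces: an amide, for example, is reduced to an
amine and an acid, neither of which retains the amide's donor/acceptor
pattern. `molfrag` addresses this in two ways:

1. **Exhaustive fragmentation.** After cutting every rule-matched bond,
   the smallest fragments form a *fragment-adjacency graph* (nodes =
   smallest fragments, edges = cut bonds). The package enumerates every
   connected union of up to `k` smallest fragments and reassembles each
   into an intermediate fragment, so multi-group pharmacophores are
   recovered as single fragments. With `k = 1` the output reduces to the
   classical smallest-fragment set; with unlimited `k` every connected
   substructure reachable under the rules is produced. For a chain-like
   parent with `m` cut bonds this yields
   `sum_{j=1..min(k,m+1)} (m+2-j)` fragments, and `(m+1)(m+2)/2` when
   unlimited.
2. **Cut-point highlighting.** Broken bonds are capped either with
   hydrogens (classical) or, with the `x` flag, with dummy atoms (`*` in
   SMILES). Dummy caps preserve the original bonding pattern — a
   morpholine cut at nitrogen stays a non-donor instead of gaining a
   spurious N–H — and split fragments that hydrogen capping would
   collapse: a benzene ring carries 11 distinct dummy-capped
   representations with one to five cut points.

Cleavage rules are two-atom SMARTS patterns. Built-ins: the 11 published
RECAP bond types, a two-atom recast of BRICS, CCQ (C–C bonds where a
carbon bears a heteroatom), and an extendedRECAP-style set (RECAP + 16
rules covering sulphur, phosphorus and further carbon environments).
Only acyclic single bonds are ever cut, so rings are preserved. Fragment
sets can be filtered by heavy-atom count (`n`, `m`), size relative to
the parent (`s`), molecular weight (`w`) and the rule-of-three panel
(MW < 300, xlogP ≤ 3, HBD ≤ 3, HBA ≤ 3, rotatable non-terminal
bonds ≤ 3), then aggregated into fragment libraries with frequency
statistics.

## Installation and requirements

The package needs Python (≥ 3.8) with RDKit on the `PATH` as `python`
(override with the `MOLFRAG_PYTHON` environment variable); all
molecular perception runs through a bundled batch worker, so no R-level
chemistry toolkit is required.

```sh
R CMD INSTALL .
# test suite
Rscript -e 'testthat::test_dir("tests/testthat", package = "molfrag", load_package = "installed")'
```

## Worked example

```r
library(molfrag)

mols  <- worked_examples()[, c("compound_id", "smiles")]
frags <- fragment_molecules(mols, builtin_ruleset("extendedRECAP"),
                            k = 8, n_min = 5, s_rel = 0.99, x = TRUE)
frags
#> # A tibble: 156 × 6
#>   compound_id smiles          heavy_atoms mol_weight n_cuts n_base
#>   <chr>       <chr>                 <int>      <dbl>  <int>  <int>
#> 1 benzanilide *c1ccccc1                 6       77.1      1      1
#> 2 benzanilide *Nc1ccccc1                7       92.1      1      2
#> 3 benzanilide *C(=O)c1ccccc1            8      105.       1      1
#> 4 benzanilide *NC(=O)c1ccccc1           9      120.       1      2
#> 5 anisole     *c1ccccc1                 6       77.1      1      1
#> # ℹ 151 more rows
```

Each row is one surviving fragment of one compound: its dummy-capped
canonical SMILES, heavy-atom count (caps excluded), molecular weight
(dummy atoms are massless), number of cut points (`n_cuts`, equal to
the `*` count) and how many smallest fragments were combined
(`n_base`). Row 4 shows the point of exhaustive fragmentation: the
intact benzanilide amide `*NC(=O)c1ccccc1` is recovered as a single
fragment (`n_base = 2`), which a `k = 1` run cannot produce.

```r
lib <- fragment_library(frags)
glance(lib)
#> # A tibble: 1 × 8
#>   n_fragmented n_unique_fragments total_records   min    q1 median    q3   max
#>          <int>              <int>         <int> <dbl> <dbl>  <dbl> <dbl> <dbl>
#> 1           11                151           156     2     2      3   4.5   122

top_fragments(lib, 5)
#> # A tibble: 5 × 2
#>   smiles         n_compounds
#>   <chr>                <int>
#> 1 *Cc1ccccc1               4
#> 2 *C(=O)c1ccccc1           2
#> 3 *c1ccccc1                2
#> 4 *C1CNCCO1                1
#> 5 *CCc1ccccc1              1
```

Eleven of the twelve example compounds fragmented (the macrocyclic
peptide has no cleavable acyclic bond), giving 151 unique fragments;
frequency is the number of compounds containing a fragment. The
rule-of-three panel reports survivors per filter and for the
conjunction:

```r
ro3_counts(apply_ro3(tibble::tibble(smiles = unique(frags$smiles))))
#> # A tibble: 6 × 2
#>   filter   survivors
#>   <chr>        <int>
#> 1 weight         151
#> 2 xlogp          151
#> 3 hbd            151
#> 4 hba            102
#> 5 rotb           151
#> 6 combined       102
```

`autoplot(lib)` and `autoplot(lib, "distribution")` draw the
top-fragment bar chart and the per-compound count boxplot.

## Command line

An installed `molfrag` script mirrors the library API; flags follow the
fragmentation parameters (`-k` combine cap, `-n` minimal atoms, `-m`
maximal atoms, `-s` relative size, `-w` maximal weight, `-x` dummy
atoms, `-r` rule set or rule-file path, `-e` smallest-fragment mode):

```sh
molfrag -i molecules.smi -r extendedRECAP -k 8 -n 5 -s 0.99 -x --mode summary
```

Input is one `SMILES<TAB>ID` per line; outputs are per-compound
fragment lists, a frequency table, or a one-line run summary (all TSV).
Custom rule files contain one `SMARTS<TAB>rule_id` per line, each
pattern matching exactly two atoms joined by one bond.

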