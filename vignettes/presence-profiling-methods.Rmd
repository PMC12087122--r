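---
title: "Methods: from homology searches to presence-absence visualisations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from homology searches to presence-absence visualisations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taxoprofile)
```

## The model

`taxoprofile` treats *protein presence* as a thresholded property of
homology-search results: an organism possesses a protein when at least one
database hit for any of that protein's seed (query) sequences survives the
user's e-value and minimum-length cutoffs. This is deliberately the
weakest useful definition — no orthology inference, no reciprocal-best-hit
logic, no synteny. The assumptions that make it workable are:

* **seed quality carries the signal.** Each protein is represented by one
  or more well-annotated seed sequences, ideally spanning several
  kingdoms; hits inherit the seed's identity. Mislabelled or strongly
  paralogous seeds contaminate the profile, which is why the cross-hit
  check exists.
* **presence is organism-level.** Hits arrive with subject taxids at
  arbitrary rank (often strains). Organism identity is the
  species-collapsed taxid: `species_of()` walks the taxonomy to the
  nearest ancestor-or-self of rank `species`, falling back to the taxid
  itself when no species lies on the root path (e.g. a genus-level
  record). This prevents heavily sequenced strains from inflating counts.
  Collapsing can be disabled (`combine_protein(collapse_species = FALSE)`).
* **the tree of life is given, not inferred.** Tree topology is the NCBI
  taxonomy restricted to the union of lineages of organisms with at least
  one presence; hit alignments never influence topology.

## Filtering parameters

| parameter | unit | default | rationale |
|---|---|---|---|
| e-value cutoff | — | 1e-30 | strict enough to drop most low-quality alignments while keeping divergent homologs; per-protein overrides in `limits.txt` |
| minimum length | aa | 50 | removes fragment hits; should typically be raised to ~50% of the seed length per protein |
| score cap | score units | 200 | BLAST reports e-values far below the double-precision floor as 0; the cap makes `score(0)` well-defined and bounds the heatmap scale |
| slider default | exponent | 30 | mirrors the default e-value cutoff |

Both cutoffs are **inclusive** (`evalue <= cutoff`, `length >= min`): the
conservative reading, pinned by unit tests. The length cutoff applies to
the full subject sequence length, not the aligned span, because its
purpose is to discard hits that are short relative to the query protein.
Filtering counts are additive by construction: a record failing the
e-value cutoff counts there and nowhere else; `removed_by_length` counts
only records that passed the e-value test, so
`parsed = kept + removed_by_evalue + removed_by_length` holds exactly.

The coverage profile groups hits into **six e-value intervals of
increasing significance**. The interval count is fixed; the edges default
to log-uniform exponents between a working threshold of 1 and 1e-180
(`1e0, 1e-30, ..., 1e-180`), overridable per call. Two conventions close
the edge cases: e-values above the first edge land in the least
significant interval, and the most significant interval absorbs
everything below the last edge, including exact zeros. Within an
interval, spans sort by ascending e-value.

The cross-hit matrix entry for proteins $i, j$ is the minimum e-value over
every occurrence, in either protein's hit set, of accessions the two sets
share, and 0 when they share none. Because 0 is the sentinel for "no
cross-hit", a genuine e-value of 0.0 is floored to 1e-200 before entering
the matrix (the file header records this). The check runs on post-parse,
pre-final-filter data in the pipeline's combine stage, so the user can
tighten cutoffs in response and re-run only the affected stages.

## Scores and clustering

The heatmap cell for organism $o$ and protein $p$ is
$\min(200, \max(0, \lfloor -\log_{10} e^*_{op} \rfloor))$ with $e^*_{op}$
the best (minimum) e-value among $p$'s combined records attributed to $o$,
and 0 when there is no record. `floor` (rather than `round`) was chosen so
a score of $k$ certifies $e \le 10^{-k}$; the boundary is unit-tested.

Both axes are clustered agglomeratively on Euclidean distances between
integer score vectors (centroid linkage by default; `single`, `complete`,
`average`, `weighted`, `median` and `ward` are also supported — `centroid`
and `median` follow their geometric definitions, `ward` the
SSE-increase form). The implementation is in-package rather than a call
to `stats::hclust` because determinism across runs and platforms is part
of the contract and requires pinned tie-breaking: equal-distance merges
(compared with a relative tolerance of 1e-9) resolve in favour of the
earliest-created cluster pair, and every merge places the subtree
containing the smaller original index on the left, canonicalising the
leaf order. `stats::hclust` and a definition-based brute-force
agglomerator serve as independent cross-checks in the test suite.
Axes with fewer than two elements pass through unclustered. Note that the
leaf-rotation rule is defined on input indices, so the invariant preserved
under row permutation is the dendrogram topology (and heights), not the
index-dependent left-right orientation.

The rendered heatmap is one self-contained HTML file. The matrix, both
orders, the alphabetical column order, and the slider default are embedded
as a JSON payload (`read_heatmap_data()` recovers it), which makes the
document's semantics testable without a browser: the absolute view shows
exactly the cells with `score >= slider` (inclusive), the relative view
maps `score/200` onto the grayscale ramp, the e-value slider is enabled
only in the absolute view, and each cell's tooltip carries the best hit's
e-value — the tooltip is this package's reading of where a black/white
map should still expose the underlying e-value.

## Trees and combination codes

For up to three proteins, each organism's presence pattern is a bitmask
`combo_code()`: protein $k$ in the configured order (the `proteins =` line
of `tree_config.txt`) contributes bit $k$, giving $2^p - 1$ non-empty
categories — seven at three proteins, which is why three is the limit.
Node counts aggregate bottom-up: a node's count for a category is the
number of organisms with that category in its subtree, so at every
internal node the counts equal the sum over its children (organisms sit
at leaves; in the genus-fallback corner case an organism can occupy an
internal node, which then carries its own contribution). Pie slices are
`count/total` — exact on integer counts — and the pie radius is
`min(40, max(4, 4 * sqrt(total)))` display points, so pie *area* tracks
organism count, the perceptually honest choice; nodes below a configurable
organism minimum can suppress their pies. Pruning collapses named taxa
into terminal nodes that keep their aggregated counts, and an optional
partition restricts rendering to one subtree (typically a superkingdom).
Newick output labels nodes `name_taxid` and re-parses with standard
parsers; the per-node counts TSV is the machine-checkable surface.

## The synthetic-data generator

`presence_spec()` describes a miniature study: a clade layout (10 clades
over two superkingdoms, 5 species each, 20% of species carrying one
strain, by default) and per-protein presence rules — a presence fraction
per clade (defaults 0.6/0.5/0.5 for three proteins), a log-uniform
e-value range (`[1e-120, 1e-10]`, chosen to straddle the default 1e-30
cutoff so filtering is exercised), and normal subject-length components
(mean 400, sd 30; a two-component mixture reproduces a bimodal length
histogram). Two seeds per protein exercise the combine step, and one
crafted accession shared between the first two proteins exercises the
cross-hit path. All draws derive from the spec's seed in a fixed order,
so equal specs give byte-identical taxonomy dumps and XML documents; the
realisation (`realize_presence()`) is the planted ground truth, and
`planted_presence()` restates it under any e-value cutoff.

The generator emulates the *structure* of BLAST XML2 output — query/hit/
HSP nesting, accessions, taxids, e-values, coordinates, gapped aligned
segments — not its biology: sequences are random residues, e-values are
independent of the sequences, and there is no correlation between
relatedness and score. Passing the recovery tests therefore shows that
the pipeline's bookkeeping (parsing, filtering, pooling, collapsing,
counting) is exact, not that the thresholds are biologically optimal, and
says nothing about BLAST's own behaviour on real databases.

## Numerical and interface choices

* Coordinates are 1-based inclusive as delivered by BLAST XML2 and are
  converted nowhere.
* Parsed records sort by ascending e-value, ties by descending bitscore,
  then accession in C-locale order — a total order, so shuffled documents
  parse to identical tables.
* TSV tables carry three `#` metadata lines (protein, seed id, seed
  length), a mandatory header, `.` decimals and 17-significant-digit
  numbers, making round trips bit-exact; the aligned-sequence column is
  written only when non-empty.
* An e-value of exactly 0 is preserved through parsing and tables; it is
  capped only at scoring time and floored only inside the cross-hit
  matrix.
* Hits lacking a taxid are skipped with a warning and counted; hits with
  several taxids keep the first and log the rest. Unknown taxids are
  errors in the taxonomy store but soft-handled one layer up: kept
  uncollapsed in combine, listed as `unknown taxid <n>`, attached under
  the tree root, given all-zero heatmap rows.
* `run_blastp()` builds (and can execute) a local or remote BLASTp call
  writing XML2 — BLOSUM62, word size 6, gap open 11, gap extend 1,
  e-value 0.001, 20000 targets by default — but the analysis never
  depends on it and the test suite never executes it.
* The workspace keeps one FASTA per protein (protein names are unique in
  `proteinlist.txt`); each seed inside it maps to one
  `blastresults/<protein>__<seed>.xml` document.
* Configuration parsing collects *all* violations before failing, so a
  misconfigured workspace reports every problem at once.

## Problem sizes and limitations

The test suite and acceptance script run entirely on generated fixtures:
taxonomies of up to ~130 nodes, 35-hit result documents, 6×4 score
matrices for the clustering oracle, 100 randomised small trees for count
conservation, and the 10-clade/50-organism/3-protein reference spec for
end-to-end recovery — sizes chosen so every expected value can be
recomputed by brute force in the tests themselves.

Known limitations: only the BLAST XML2 dialect is parsed (no plain-text
or DIAMOND/MMseqs2 formats); merged/deleted taxid remapping is out of
scope, as is any orthology-aware notion of presence; the heatmap is
client-side only; and pie rendering aims for clarity, not for pixel
compatibility with any other tool.
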