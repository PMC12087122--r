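# taxoprofile

Phylogenetic profiling asks a simple question at scale: **which organisms
possess a protein, and which do not?** Presence-absence patterns of enzymes
across the tree of life point at the metabolic and regulatory pathways an
organism runs — and at the alternative routes it must use where an enzyme
is missing. `taxoprofile` turns raw protein homology-search results
(BLASTp, XML2 output) into such presence overviews for a user-chosen set
of query proteins, and renders them two ways:

* **taxonomy trees** whose topology follows the NCBI taxonomy (never the
  hit alignments), with a pie chart per node encoding which combination of
  up to three proteins the organisms below that node possess (7 categories
  at three proteins), pie area proportional to the number of organisms;
* an **interactive clustered heatmap** (self-contained HTML) of per-cell
  significance scores, with absolute/relative views, an e-value slider,
  and alphabetical/clustered column ordering.

The core statistic is the capped hit-significance score

```
score(e) = min(200, max(0, floor(-log10 e))),   score(0) = 200
```

so a cell holds an integer in [0, 200]: 0 means absent (or an e-value ≥ 1),
200 is the cap reached by e-values at or below 1e-200. Between search and
visualisation sit explicit, user-controlled filtering steps: per-protein
e-value and minimum hit-length cutoffs (defaults `1e-30` and `50` aa, both
inclusive), quality-check plots (hit length histogram, a six-interval
coverage profile over the query), and a cross-hit matrix that flags
subject accessions shared between two query proteins — the classic symptom
of paralog confusion.

The package is organised as a workspace-based workflow (`init_workspace()`,
five plain-text configuration files, `run_pipeline()` with re-entrant
stages `parse → qc → filter → combine → heatmap → tree`), plus standalone
building blocks: an NCBI-taxdump taxonomy store (`load_taxonomy()`,
`lineage()`, `species_of()`), BLAST XML2 parsing (`parse_blast_xml()`),
TSV result tables, FASTA extraction of hit sequences (`blast2fasta()`),
deterministic hierarchical clustering of both heatmap axes
(`cluster_axes()`, seven linkage methods), and a seeded synthetic-data
generator (`presence_spec()`, `make_workspace_fixture()`) that emulates
BLAST XML2 and taxonomy dumps with planted ground truth.

## Worked example

A complete run on a generated workspace (three proteins, 10 clades, 50
candidate organisms, two seeds per protein):

```r
library(taxoprofile)

fx <- make_workspace_fixture("demo_ws", presence_spec(seed = 42L))
writeLines("default 1e-40 100", file.path("demo_ws", "limits.txt"))
report <- run_pipeline(fx$ws)

report$parse[[1]]
#>    hits skipped
#>      35       0
report$filter[[1]]
#>            parsed              kept removed_by_evalue removed_by_length
#>                35                22                13                 0
str(report$combine)
#> List of 5
#>  $ protA            : Named int [1:2] 32 31   # records, organisms
#>  $ protB            : Named int [1:2] 27 26
#>  $ protC            : Named int [1:2] 25 25
#>  $ overall_organisms: int 43
#>  $ cross_hits       : int 1
significance_score(c(1e-30, 1e-250, 0.5))
#> [1]  30 200   0
```

Reading this: the first seed of `protA` returned 35 hits, of which 22
survive the tightened `1e-40`/100 aa cutoffs (13 fail the e-value cutoff,
none the length cutoff). After pooling seeds and deduplicating accessions,
`protA` is present in 31 distinct organisms (strain hits are collapsed
onto their species), 43 organisms have at least one protein, and exactly
one accession is shared between two proteins' hit sets — the cross-hit
matrix in `matrix.csv` shows its minimum e-value. The workspace root now
holds `heatmap.html`, `score_matrix.tsv`, per-protein and combined trees
(`tree_*.pdf`, `tree_*.nwk`, `tree_*_counts.tsv`), and the organism
listings under `combinedtables/`. The first rows of the combined tree's
count table:

```
taxid  name            rank          total_organisms  combo_protA  combo_protB  ...
1      root            no rank       43               5            2
2      Synthobacteria  superkingdom  22               2            2
11     Clade_01        phylum        5                0            0
```

so 43 organisms are mapped overall, 22 of them under the first
superkingdom, and each row splits its total over the seven
protein-combination categories that the pie charts draw.

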