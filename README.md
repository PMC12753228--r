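# papt — pooled analysis of protein truncations

Top-down proteomics (TDP) identifies intact proteoforms, and a large share of
the proteoforms reported by TDP studies are *truncated*: they lack canonical
N- and/or C-terminal residues relative to the database sequence. Truncations
arise both biologically (signal/transit-peptide removal, proteolytic
processing between domains, alternative translation initiation) and as
artifacts of the analytical workflow (hydrolysis of labile bonds such as
aspartate–proline during sample preparation, in-source fragmentation during
MS). `papt` implements a pooled meta-analysis of proteoform identification
lists from many independent TDP datasets that characterizes truncated
proteoforms, locates enriched truncation sites, and separates recurring
biological termini from likely artifacts.

The package is aimed at proteomics researchers who have per-dataset
proteoform identification tables (protein accession + proteoform sequence,
optionally ProForma strings, PrSM counts, and reported coordinates) and a
canonical sequence database (FASTA and/or UniProt-style XML with positional
features).

## What it computes

**Truncation state.** Each proteoform is mapped onto its canonical sequence
and assigned one of four states: full length, exclusively N-terminally
truncated, exclusively C-terminally truncated, or truncated at both termini.
Start-methionine excision is not a truncation: a proteoform starting at
position 2 of a Met-initiated protein has a canonical N terminus.

**Normalized truncation-site frequency.** Writing X | X′ for the residues
flanking a broken peptide bond, the enrichment of a site in a dataset is

```
value(X, X') = log2 [ (t(X,X') / T) / (b(X,X') / B) ]
```

where `t` counts truncation events at the pair (over `T` total events) and
`b` counts occurrences of the pair among the peptide bonds of all reported
proteoform sequences (over `B` total bonds). Zero means the bond is truncated
exactly as often as expected from its occurrence; positive values are
overrepresented sites. Cells with zero counts are missing, not pseudocounted.

**Cross-dataset clustering.** Terminus-specific site profiles (rows
`N:X|X'` and `C:X|X'`, columns datasets) are filtered to < 40 % missing
values, residual gaps are imputed with the neutral value 0, and the rows are
clustered with Ward's criterion ("ward.D2") on Euclidean distances; the
dendrogram is cut at k = 15 by default. Each cluster is summarized by its
per-slot residue frequencies and information content (bits), its median
enrichment, and its N/C terminus composition.

**Terminus consistency.** Noncanonical termini are collected per protein
and dataset (counted once per dataset), ranked by the number of independent
datasets reporting the identical position, matched against annotation
features (signal/transit peptides, propeptides, chains, peptides), and
categorized as `annotated_match`, `near_annotated`, `inter_domain`, or
`unrelated`.

**Diagnostics.** Per-dataset state proportions, protein-level summaries,
PrSM means for full-length vs truncated proteoforms, fractions of truncated
termini already described in the database, terminus-position histograms,
length-binned state proportions, abundance–truncation regression, and the
proline X′ ratio (N- vs C-terminal sites with proline C-terminal to the
break), an indicator of in-source fragmentation.

A seeded synthetic-data generator (`sim_config()`, `generate_proteome()`,
`generate_dataset()`) emulates these processes with known ground truth, and
`analytic_expected_enrichment()` computes the exact expected enrichment of
any residue pair under the generative model by brute-force summation — the
oracle used throughout the test suite.

## Worked example

```r
library(papt)

cfg <- sim_config(seed = 7, n_proteins = 150, n_proteoforms = 2000)
db  <- generate_proteome(cfg)
datasets <- setNames(lapply(1:6, function(i)
  generate_dataset(db, cfg, paste0("DS-", i), seed = 100 + i)$records),
  paste0("DS-", 1:6))

res <- run_papt(datasets, db, k = 8, min_datasets = 3)

round(res$summaries[["DS-1"]]$state$state_proportions, 3)
#> FULL_LENGTH     N_TRUNC     C_TRUNC    NC_TRUNC
#>       0.280       0.382       0.338       0.000

round(res$nfm[["DS-1"]]$N["D", "P"], 2)   # D|P enrichment, N-terminal sites
#> [1] 2.43

round(res$summaries[["DS-1"]]$proline_ratio, 2)
#> [1] 1.17

head(res$terminus_calls[, c("accession", "terminus", "position",
                            "n_datasets", "category")], 5)
#>   accession terminus position n_datasets        category
#> 1  SYN00006        N       79          6       unrelated
#> 2  SYN00010        C       48          6       unrelated
#> 3  SYN00055        N       29          6 annotated_match
#> 4  SYN00057        N       28          6 annotated_match
#> 5  SYN00057        N       62          6       unrelated
```

About 72 % of the synthetic proteoforms are truncated and 28 % full length,
matching the generator's configuration. The D|P cell sits near +2.4 log2
units because the generator plants an 8-fold cleavage-rate multiplier on the
aspartate–proline bond (the chemically labile bond). The proline ratio near 1
indicates no in-source fragmentation component (the default in-source
fraction is small). The top consistent termini are found in all six
datasets; those at signal-peptide cleavage sites are flagged
`annotated_match`.

With real data, replace the generator calls with `read_proteoform_table()`
(one call per study, with a per-study column-mapping dialect) and
`read_canonical_db()`; attach a PaxDb-style abundance table with
`set_abundance()`. Passing `out_dir =` to `run_papt()` writes every
intermediate artifact as TSV/JSON together with an md5 manifest;
`write_report()` assembles a JSON + text summary.

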