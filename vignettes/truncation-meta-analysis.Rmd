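---
title: "Methods: pooled analysis of truncated proteoforms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pooled analysis of truncated proteoforms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(papt)
```

## The analysis

`papt` pools proteoform identification lists from many independent top-down
proteomics (TDP) datasets and asks three questions about truncated
proteoforms: what fraction of reported proteoforms are truncated and where,
which peptide bonds break more often than their abundance predicts, and
which noncanonical termini recur across independent studies.

The pipeline is a fixed sequence of steps, each exposed as a function:

1. **Ingest** (`read_proteoform_table()`, `read_canonical_db()`,
   `link_and_filter()`): each study's table is mapped onto canonical record
   fields via a per-study column dialect; ProForma strings are stripped to
   bare sequences when no plain sequence is given. Records without an active
   accession in the canonical database, or whose sequence does not occur in
   their protein's canonical sequence, are removed and counted — filtering is
   reported, never silent.
2. **Placement and state** (`annotate_proteoforms()`): each proteoform is
   placed on its canonical sequence and given one of four truncation states.
3. **Site statistics** (`extract_truncation_sites()`,
   `count_peptide_bonds()`, `normalized_frequency()`, and the per-dataset
   summaries): 20×20 matrices of truncation events and peptide-bond
   background, and their log2 ratio of shares.
4. **Cross-dataset clustering** (`assemble_feature_matrix()`,
   `filter_by_missingness()`, `cluster_truncation_sites()`,
   `cut_clusters()`, `cluster_motif_summary()`).
5. **Terminus consistency** (`build_termini_profiles()`,
   `consistency_counts()`, `match_uniprot_annotation()`,
   `categorize_terminus()`).

`run_papt()` chains the steps and optionally writes every artifact with an
md5 manifest, so a rerun on identical inputs is verifiably identical.

## Truncation states and the start-methionine convention

A proteoform's N terminus is canonical if it starts at position 1, *or* at
position 2 of a methionine-initiated protein — cotranslational Met excision
is part of normal maturation, not a truncation. The C terminus is canonical
if the proteoform ends at the last canonical residue. The four states
(`FULL_LENGTH`, `N_TRUNC`, `C_TRUNC`, `NC_TRUNC`) follow from the two
booleans. Two corner cases deserve note:

* The Met exception requires the canonical first residue to actually be
  methionine; position-2 starts on non-Met-initiated proteins are genuine
  N-terminal truncations.
* Because a record's state depends only on (start, end, length, first
  residue), the classifier is tested against a brute-force re-statement of
  the rule over thousands of random placements.

**Placement.** Reported start/end coordinates are trusted only after
verification against the canonical sequence (`canonical[start..end] ==
sequence`); source tables use inconsistent coordinate conventions, and an
off-by-one would silently shift every downstream site. Unverifiable
coordinates fall back to the leftmost occurrence with a logged
coordinate-conflict count. Sequences occurring at several (possibly
overlapping) offsets are placed leftmost and flagged `ambiguous`, so
downstream analyses can exclude them; this keeps placement deterministic.

## Normalized truncation-site frequency

For the residue pair X | X′ flanking a broken bond, the dataset-level
enrichment is

$$v(X, X') = \log_2 \frac{t(X,X')/T}{\,b(X,X')/B\,}$$

with \(t\) the truncation-event counts (over \(T\) events in the requested
terminus scope) and \(b\) the peptide-bond counts of all reported proteoform
sequences (over \(B\) bonds). Numerical choices:

* **Log base 2**, recorded in the output metadata. The scale is symmetric
  around 0 and conventional for enrichment displays.
* **Missing, not pseudocounted.** Cells with zero truncation or bond counts
  are `NA`. A pseudocount would shift the zero line, which carries the
  meaning "truncated exactly as often as expected".
* **Bond background over reported records, redundantly.** "Bonds identified
  in the dataset" is read plainly: every record contributes its n−1 bonds,
  unweighted by PrSMs, even when records of the same protein overlap. The
  alternative (deduplicating overlapping records) would make the background
  depend on an arbitrary notion of record identity; the redundant count is
  reproducible from the table alone.
* **Non-standard residues** (B, J, O, U, X, Z) are excluded from both
  matrices symmetrically and tallied, preserving the 20×20 frame.

## Cross-dataset clustering

Rows are terminus-specific site keys (`N:X|X'`, `C:X|X'`; at most 800),
columns are datasets. Filtering removes rows with ≥ 40 % missing values,
then columns with ≥ 40 % missing among the surviving rows, then re-checks
rows once; the order is recorded in the matrix metadata. Row-first was
chosen because rows (sites) outnumber columns (datasets) and their
missingness is the dominant obstacle to a distance computation; the
alternative order can differ on engineered fixtures, which is why the order
is an explicit, recorded parameter rather than an implementation accident.

Residual missing cells are imputed with 0 before Euclidean distances are
computed — on the enrichment scale, 0 is the semantically neutral
"as expected" value, so an imputed cell pulls no profile toward either
over- or underrepresentation. The imputation mask is carried into the
result. Agglomeration uses Ward's criterion in the "ward.D2" convention
(squared-distance Lance–Williams update, square-root merge heights) via
`stats::hclust`, which is deterministic for a fixed input matrix; a small
hand-computed Lance–Williams example guards the convention in the tests.
The cut at `k` (default 15) relabels clusters 1..k in order of first row
appearance so that labels are stable across runs.

Cluster motifs are plain per-slot residue frequencies with information
content \( \log_2 20 - H \) in bits and no small-sample correction — the
summaries describe the cluster membership itself, not an estimate of an
underlying motif distribution.

## Terminus consistency and annotation matching

A noncanonical terminus counts **once per dataset** regardless of how many
proteoforms share it, because the unit of evidence is the independent study.
An N terminus at position p matches the database when p is the begin of a
chain/peptide feature starting after position 1, or one past the end of a
signal peptide, transit peptide, or propeptide; C termini symmetrically
(chain/peptide ends before the last residue, or one before a propeptide
begin). Chain features spanning the entire sequence describe the unprocessed
molecule and never imply a cleavage.

Unmatched termini within `near_window` residues of an implied cleavage are
`near_annotated`. The default window of 15 is a compromise: wide enough to
capture mispredicted signal-peptide cleavage sites (which are typically
displaced by around a dozen residues), narrow enough to stay local on a
protein of typical length; it is a configurable parameter, not a constant.
A terminus whose cut bond lies strictly between two annotated domains — both
domains entirely on opposite sides, none spanning the cut — is
`inter_domain`; everything else is `unrelated`.

## The synthetic-data generator

The generator is first-class, tested code. It emulates the processes the
analysis is designed to detect:

* a canonical proteome (default 300 proteins, truncated log-normal lengths
  60–500 residues) with methionine initiators, planted signal peptides
  (default 25 % of proteins, lengths 18–29 — producing the band of truncated
  starts in the twenties that real datasets show) and non-overlapping
  domains;
* log-normal protein abundances, with proteins sampled proportionally to
  abundance;
* a full-length fraction (default 0.29) with start-Met excision (default
  probability 0.5);
* bond hydrolysis with residue-pair-specific rate multipliers. Defaults
  plant an 8-fold multiplier on D|P (the chemically labile bond) and 3-fold
  on all bonds C-terminal to R or K (basic-residue protease specificity);
  wildcard keys (`"R|*"`) multiply onto the baseline, exact keys override.
  A cut yields the N-side, C-side, or both fragments (default probabilities
  0.4/0.4/0.2);
* signal-peptide cleavage for signal-bearing proteins (default 20 % of
  their truncated records);
* an in-source fragmentation process (default 5 % of truncated records)
  that emits only C-side fragments (y-ions, hence N-terminal truncations)
  with a 4-fold bond-choice bias toward proline at X′;
* geometric-like PrSM counts whose mean grows with abundance rank and is
  scaled down (default ×0.25) for truncated records.

Two observability conventions shape the emitted records. Fragments shorter
than 5 residues are never emitted (cut choices are renormalized), mimicking
the lower mass bound of proteoform detection. And a C-side fragment starting
at position 2 of a Met-initiated protein is indistinguishable from the
Met-excised full-length form, so such cuts are not emitted as truncated
records; a consequence is that first-bond (M|X′) truncation events are
structurally depleted relative to their bonds, leaving a small negative
expectation for M|X′ cells even under uniform cleavage rates.

`analytic_expected_enrichment()` computes the exact expected normalized
frequency for any pair by summing over every bond of every protein, weighted
by abundance-proportional sampling, the process mixture, fragment-side
probabilities, length rejection, and the Met convention — an independent
brute-force expectation, not a call into the analysis code. It agrees with a
hand-computed three-bond toy exactly and with Monte-Carlo runs of the
pipeline at 10^5 events to within the sampling noise.

**What the generator does not emulate**, and hence what passing tests do not
certify about real data: proteoforms truncated at *both* termini (every
synthetic cut retains one canonical terminus, so the `NC_TRUNC` state is
exercised only by hand-built fixtures); PTMs beyond the notation-stripping
path; sequence-dependent protein abundance; search-engine effects (FDR,
precursor-tolerance artifacts); exopeptidase ladders; and inter-study
heterogeneity of composition or instrumentation. The uniform-null and
recovery tests validate the estimator under the generative model, not the
biological fidelity of any particular dataset.

## Problem sizes and determinism

The test suite validates the classification oracle on 1,000 random
placements; the flat-matrix null on one dataset of ≈ 64,000 truncation
events (bound: mean |v| ≤ 0.15 over cells with ≥ 50 events, plus a sign
test); D|P recovery against the analytic oracle at ≈ 10^5 events (±0.3)
with sign recovery in 100 replicates of ≥ 10^4 events; and clustering
recovery on planted two-family matrices (adjusted Rand index 1 at 4×
separation-to-spread). These sizes keep each check's sampling noise well
inside its tolerance. All simulations are seeded; rerunning any test or the
acceptance script with the same seed reproduces identical numbers, and the
pipeline manifest makes end-to-end reruns hash-identical.

## Known limitations

* Records must carry a sequence or ProForma string; studies reporting only
  coordinates are not reconstructed from the canonical sequence (the
  coordinate conventions of such tables are exactly what the verification
  step exists to distrust).
* Isoform accessions are distinct keys; a proteoform is only compared to
  the sequence of its reported accession, never remapped across isoforms.
* Consistency counting is exact-position; ±1 jitter between studies is not
  merged. The terminus-position histograms make such ladders visible
  instead.
* The abundance regression defaults to log10 abundance (PaxDb-style values
  span orders of magnitude); a linear-scale switch is provided.
* Obsolete/merged accession resolution is out of scope; such records are
  filtered and counted.
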