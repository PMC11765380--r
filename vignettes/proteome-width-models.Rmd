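---
title: "Estimating proteome width from Swiss-Prot annotations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating proteome width from Swiss-Prot annotations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proteowidth)
```

## The problem

A genome encodes far more distinct protein molecules than it has
protein-coding genes. One gene can give rise to many *proteoforms*:
splice isoforms, sequence variants caused by single-nucleotide
substitutions (single-amino-acid polymorphisms, SAPs), and chemically
modified forms carrying post-translational modifications (PTMs). No
current analytical technology can measure the size of this proteoform
space directly, but the expert-reviewed annotations accumulated in
UniProtKB/Swiss-Prot make a *theoretical* estimate possible: count, per
gene, how many splice variants, SAP-bearing sequences and PTM-bearing
sequences have been documented, and combine the counts under an explicit
information model of how these events interact.

Because the counts reflect what has been annotated rather than what
exists, the resulting proteome width is as much a measure of how deeply
an organism has been studied as of its biology. That makes it a useful
comparative index across model organisms: it rises with curation depth,
and species whose reviewed annotation is thin (few reviewed genes, no
recorded isoforms) get small widths regardless of their true proteome
complexity. `proteowidth` implements this estimation pipeline end to
end, together with two companion measures of exploration degree: genome
annotation coverage, and the overlap between a human aging-gene list and
the orthogroups of model-organism proteomes.

## The 13-parameter vector

For one species, the pipeline reduces reviewed Swiss-Prot entries to a
vector of thirteen parameters:

| symbol  | meaning                                                          |
|---------|------------------------------------------------------------------|
| `N`     | number of protein-coding genes                                   |
| `ASg`   | genes with at least one alternative-splicing isoform             |
| `ASd`   | fraction of spliced genes, `ASg / N`                             |
| `AS`    | splice-variant sequences in total                                |
| `ASav`  | splice variants per spliced gene, `AS / ASg`                     |
| `SAPg`  | genes with at least one SAP                                      |
| `SAPd`  | `SAPg / N`                                                       |
| `SAP`   | SAP-bearing sequences in total                                   |
| `SAPav` | `SAP / SAPg`                                                     |
| `PTMg`  | genes whose proteins carry PTMs                                  |
| `PTMd`  | `PTMg / N`                                                       |
| `PTM`   | PTM-bearing sequences in total                                   |
| `PTMav` | `PTM / PTMg`                                                     |

An average with a zero denominator (for example `SAPav` in a species
with no recorded SAPs) is defined as 0. This convention is forced by
real data: the naked mole-rat's reviewed proteome has 6 genes, PTMs on
4 of them, and no splicing or variant annotation at all, and its width
must still be well defined.

`N` defaults to the number of distinct genes observed among the reviewed
entries; `n_override` substitutes an external protein-coding-gene count.
Both are legitimate choices — published comparative tables themselves mix
the two conventions (the mouse appears with 17,228 genes in one table and
17,775 in another) — so the package makes the source explicit rather
than hiding it.

## The three information models

Given a parameter vector, the proteome width `Nps(H)` under model
`H = 1, 2, 3` is:

$$N_{ps1} = N \,(1 + AS_d AS_{av} + SAP_d SAP_{av} + PTM_d PTM_{av})$$
$$N_{ps2} = N_{ps1} + AS \,(SAP_{av} + PTM_{av})$$
$$N_{ps3} = N_{ps2} + N \, SAP_{av} PTM_{av} + AS \, SAP_{av} PTM_{av}$$

Model 1 assumes SAPs and PTMs arise only on the canonical sequence of
each gene; model 2 lets them also arise on splice variants; model 3
additionally lets SAPs and PTMs co-occur on any sequence. The models are
nested, so `nps3 >= nps2 >= nps1 >= N` for any nonnegative counts, with
two exact collapse cases: `AS = 0` forces `nps2 = nps1`, and
`SAP = 0` or `PTM = 0` forces `nps3 = nps2`. Both collapses occur in
real species (the naked mole-rat and *Podospora anserina* rows of the
published comparative table have all three columns equal).

**Numerical evaluation.** The densities and averages are ratios of
integers, and evaluating model 1 as written — dividing first, then
multiplying by `N` — would lose the exact identity

$$N_{ps1} = N + AS + SAP + PTM,$$

which follows algebraically because `N \cdot ASd \cdot ASav = AS`
cancels exactly. `proteome_width()` therefore evaluates the formulas on
the raw integer counts (`AS * SAP / SAPg` instead of
`AS * (SAP/SAPg)` computed separately, and model 1 directly as the sum
identity). All intermediate products of realistic annotation counts are
far below 2^53, so they are exact in double precision. The identity and
the monotone nesting are property-tested on 1,000 random parameter
vectors.

```{r}
p <- parameter_vector(N = 10, ASg = 2, AS = 4, SAPg = 5, SAP = 10,
                      PTMg = 10, PTM = 20)
w <- proteome_width(p)
w$nps
```

## Counting conventions

The flat-file annotation does not dictate a unique counting rule, so the
package fixes defaults and exposes each choice as an argument:

* **Splice variants** come from the `Named isoforms=k` declaration of
  the `CC -!- ALTERNATIVE PRODUCTS` block, and count only when the
  block's event includes alternative splicing. The default convention
  `all_named` counts all `k` named isoforms, so a spliced gene
  contributes at least 2 splice-variant sequences — consistent with
  describing a spliced yeast gene as encoding "2 to 15" variants. The
  alternative `non_canonical` convention (`k - 1`) is available. Counting
  `VAR_SEQ` feature lines instead of named isoforms would be a third
  option; the parser retains `VAR_SEQ` features so users can compare,
  but they do not enter the default counts.
* **SAPs** are `FT VARIANT` features, one sequence variant per site.
* **PTMs** are `FT MOD_RES`, `CARBOHYD`, `LIPID` and `CROSSLNK`
  features by default, again one counted sequence per annotated site.
  Per-site counting is the only reading consistent with per-gene PTM
  averages well above 1 in curated proteomes; counting at most one
  PTM-bearing sequence per protein could never produce them. `DISULFID`
  features are recognised but excluded by default, since disulfide
  bonds are structural rather than chemical proteoform-generating
  events in most treatments; `ptm_keys` opts them in.
* **Genes** are keyed by (NCBI taxon, upper-cased gene name), with the
  GN-line precedence Name > OrderedLocusNames > ORFNames. An entry with
  no GN line becomes a singleton gene keyed by its primary accession —
  deflating the gene count silently would bias every density upward.
* **Coordinates** are 1-based inclusive, as in the flat file, and are
  never rescaled.

## Report rounding

Published comparative tables in this area print percentages in tiers:
integers at or above 10%, one decimal between 1 and 10%, one significant
figure below 1%. `annotation_coverage()` reproduces these tiers with
half-up rounding (`round_half_up()`), not banker's rounding, and always
returns the raw percentage alongside. A minority of published rows are
*truncated* instead of rounded (a raw 164.7% printed as 164); the
package does not reverse-engineer that inconsistency — it documents it
and reports the rounded value, so a one-unit discrepancy against such
rows is expected and visible. Coverage above 100% is legitimate and
preserved: it occurs when the reviewed set is annotated redundantly
relative to the Ensembl gene models.

Per-gene width ratios (`per_pcg_ratio()`) use one decimal, half-up; at
that precision all ninety published ratio cells of the comparative width
table reproduce exactly from the printed totals.

## The orthogroup-overlap statistic

To measure how well a model organism covers human aging biology, the
package counts, per species, the orthogroups that contain **at least one
mapped human aging protein and at least one protein of that species**.
Orthogroup tables are consumed in the OrthoFinder `Orthogroups.tsv`
dialect. Aging genes arrive as symbols and are joined to protein
accessions through an explicit symbol-to-accession mapping table,
case-insensitively; unmapped symbols are reported, never silently
dropped. The statistic is deliberately simple — set intersection per
group — and is verified against brute-force enumeration on hundreds of
random tables.

For self-contained use the package ships a reciprocal-best-hit (RBH)
orthogroup inferrer: per ordered species pair, each query's best hit by
global alignment score (Needleman–Wunsch, BLOSUM62, affine gaps with
open 10 / extend 1, a gap of length L costing `10 + L`); reciprocal
pairs form edges; orthogroups are connected components with at least two
proteins. Ties between equal best-hit scores break to the
lexicographically smallest target identifier, which makes inference
deterministic and permutation-invariant. RBH plus connected components
is a classical desk-scale heuristic: it does **not** reproduce
graph-clustering orthology pipelines (no MCL, no paralog
disambiguation), and whole-proteome overlap counts are out of scope
here — they require complete proteome downloads and a full orthology
run. The package validates the statistic at desk scale, on planted
families where the expected counts are enumerable.

## Synthetic data with planted truth

Both generators plant their ground truth deterministically rather than
sampling it, so recovery tests are exact rather than statistical:

* `simulate_proteome()` affects exactly `round(fraction * n_genes)`
  genes per event class and gives every affected gene exactly the stated
  number of events. Which genes are affected, the feature positions and
  the residues vary with the seed; the parameter vector does not. The
  generator emits its planted vector computed from this arithmetic
  directly — independent of the parser and aggregator it is used to
  test — and identical seeds give byte-identical DAT text. Defaults
  (100 genes; 40% / 50% / 60% of genes with splicing / SAPs / PTMs;
  3 / 4 / 5 events per affected gene) sit in the regime of well-annotated
  mammalian proteomes, where roughly half the genes have recorded
  splicing or variants and a majority carry modification sites.
* `simulate_ortholog_families()` builds each family from its own random
  ancestor, substituting a fraction `1 - within_family_identity`
  (default 0.9) of residues per member, so any two family members share
  roughly 80% identity or more while unrelated random sequences sit near
  the ~5% background — far below the declared `between_family_identity`
  ceiling of 0.3. The aging subset has deterministic size
  `round(aging_fraction * n_families)`.

What the synthetic records do **not** emulate: realistic PTM-type
frequencies, sequence composition, evidence tags, multi-entry genes
(the generator writes one entry per gene; multi-entry aggregation is
covered by hand-written fixtures), or database growth across releases.
Passing recovery tests therefore demonstrate that the counting pipeline
is exact on well-formed flat files, not that any particular biological
density is correct.

## Degenerate inputs and error policy

* An empty DAT stream parses to an empty record collection; an entry
  missing ID, AC or SQ is skipped with a warning naming its starting
  line, and the skip count travels on the result.
* `N = 0` (no genes and no override) is an error: every density is
  undefined.
* Header-only orthogroup tables are valid (zero groups); duplicate
  orthogroup ids, duplicate protein ids within a species cell, and rows
  with excess fields are errors with row context. A row with *fewer*
  fields than the header is indistinguishable from empty trailing cells
  in tab-separated text and is padded, not rejected.
* Alignment sequences are restricted to the 20 standard amino-acid
  letters; anything else is an error naming the offending position.
* `run_pipeline()` aborts on the first stage error with a stage-tagged
  message and removes partial report files.

## Validation scale

The shipped test suite and the acceptance script size their problems for
exactness, not coverage of scale: 1,000 random parameter vectors for the
model identities, 100 seeded synthetic proteomes of 10–60 genes for
exact recovery, 200 random toy tables for the overlap oracle, and
planted RBH scenarios of 2–3 species × 3–5 families × ~60–80 residues.
These sizes keep every expected value enumerable by brute force; the
pipeline itself has no intrinsic size limit beyond memory and the
quadratic cost of the alignment-based RBH stand-in.

## Known limitations

* Proteome width measures annotation depth as much as biology; it is a
  comparative exploration index, not an abundance-aware proteome size
  (proteoform copy numbers are out of scope).
* The absolute width totals of a given database release are
  reproducible only from that release's full parameter appendix; the
  package reproduces the published per-gene ratios and coverage
  percentages from the printed tables it ships, and everything else
  from synthetic truth.
* The RBH inferrer is a stand-in for testing and small studies, not an
  OrthoFinder replacement.
* TrEMBL (unreviewed) entries, UniProt XML, live REST fetching and
  isoform sequence reconstruction from `VAR_SEQ` coordinates are out of
  scope.
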