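---
title: "Uncertainty-aware synthesis of biomarker and bioactivity tables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Uncertainty-aware synthesis of biomarker and bioactivity tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dtsynth)
```

## The problem

Two kinds of curated oncology resources describe drug-target relations from
different angles. Treatment-biomarker tables record that a tumor mutation
confers *responsiveness* or *resistance* to a drug, graded by a clinical
evidence level. Bioactivity tables record *measured* interaction strengths
(Kd, Ki, IC50, in nanomolar) between a drug and a target, which amounts to
pre-clinical evidence. Kept apart, the two views are hard to reconcile: a
clinician cannot easily see that a drug curated as resistant against a
mutation is, according to assay data, potently active against the very same
mutation -- or that no assay data exist at all.

dtsynth links both tables onto canonical (drug, target) keys and makes three
uncertainties explicit:

1. **missing data** -- every cell of the drug-by-target matrix carries a
   state, so absence is a first-class observation;
2. **cross-source consistency** -- each both-source cell is classified as
   consistent, conflicting or ambiguous;
3. **credibility** -- biomarker evidence levels are ordinal (1-5) and every
   record keeps its publication provenance (title, DOI).

A *target* is either a point mutation, written `GENE(MUTATION)` (e.g.
`ABL1(T315I)`), or a wild-type gene, written `GENE`. Drug combinations such
as `"DRUG001 + DRUG002"` are atomic drug entities.

## Harmonization

Matching across tables is purely lexical: names are trimmed,
whitespace-collapsed and case-folded; the display form of the first
occurrence is kept. No ontology or synonym dictionary is consulted -- two
spellings of one compound that differ beyond case and spacing stay distinct
entities. This is deliberate: the package measures what the *tables* say,
and silent synonym merging would itself be a source of untracked
uncertainty.

Target tokens must parse as `GENE` or `GENE(MUT)`; anything else
(unbalanced parentheses, nesting) is a row-level validation error. Ingest
never drops rows silently: every input row becomes either a record or one
row in an error table `(row, column, message)`, so records + errors always
equals the input row count.

## Potency classes and median aggregation

Activity values are binned into four ordinal potency classes:

| class          | value (nM)        |
|----------------|-------------------|
| highly potent  | (0, 10]           |
| potent         | (10, 1000]        |
| weakly potent  | (1000, 10000]     |
| inactive       | (10000, Inf)      |

The published thresholds do not state boundary membership; dtsynth uses
left-open/right-closed intervals uniformly, so a value exactly on a boundary
falls in the *more* potent class (10 nM is highly potent). This is the
conservative-toward-potency completion and keeps classification a total,
antitone step function of the value (property-tested).

When a pair has replicate measurements, the activity value is the **median**
of all values, pooled across measurement types, which damps outliers: the
values `{1, 10, 100000}` summarize to 10 nM, highly potent, despite the
extreme replicate. For an even number of values the median is the arithmetic
mean of the two central values (the standard convention; the sources are
silent on this). A per-measurement-type median would also be defensible
where types disagree systematically; pooling matches the single
activity-value-per-pair model used downstream, and the raw per-type values
remain available through `provenance_lookup()`.

Unit handling: the ingest dialect accepts nM, uM/µM, mM and M and converts
to nM on entry; a missing unit column means values are already nM (all
thresholds above are quoted in nM).

## Consistency states

The curated effect and the median-derived potency class of one cell combine
into a consistency state:

| effect \\ potency | highly potent / potent | weakly potent | inactive    |
|-------------------|------------------------|---------------|-------------|
| responsive        | consistent             | ambiguous     | conflicting |
| resistant         | **conflicting**        | ambiguous     | consistent  |

Cells present in one source only are `cgi_only` / `dtc_only`; cells in
neither are `missing`. Two completions in this table were design decisions:
`(responsive, inactive)` is conflicting by symmetry with the canonical
`(resistant, potent)` conflict, and weak potency maps to `ambiguous` because
it neither reinforces nor contradicts a curated effect; whether weak potency
should count as potent for conflict purposes is genuinely unclear, so it is
flagged rather than guessed. Conflicts are always evaluated against the
median-derived class, not against individual replicates, consistent with
the aggregation model.

When several biomarker records occupy one cell (same drug and target,
different studies), the record with the highest evidence level represents
the cell; an evidence tie with disagreeing effects resolves to *resistant*,
the cautious reading for treatment selection. The full record list is never
discarded and is returned by `provenance_lookup()`.

`conflict_report()` lists all conflicting and ambiguous cells,
conflicting-first, then by descending evidence rank, then alphabetically by
drug -- highest-credibility contradictions matter most. The ordering within
the report is invented plumbing, not a claim from the sources.

## The matrix model and sorting

`assemble_matrix(store, mutations)` builds columns from the selected
mutations plus, once per gene, the wild-type gene column when that gene
exists in the data (greater potency toward the wild type than toward the
mutant anticipates off-target side effects). Rows are exactly the drugs
related to at least one column; tumor-type rows are the tumor types linked
to at least one selected mutation. The base row order is alphabetical by
canonical key -- some deterministic order is needed for reproducible output,
and alphabetical is the least surprising.

Three sorting procedures reorder the rows:

- `sort_by_target()`: drugs related to one column first, grouped both-source
  < biomarker-only < bioactivity-only, the both-source and bioactivity-only
  groups ordered most-potent-first. "Descending potency" is read as
  ascending nM: the purpose of the sort is surfacing effective drugs, and
  in nM space smaller is stronger. Unrelated drugs keep their previous
  order (the sort is stable).
- `sort_by_potency_sum()`: score = sum of pActivity
  (`-log10` molar; 10 nM = 8) of the median over selected mutation columns
  with data; descending. Summing raw nM would *penalize* potency, so the
  log scale is the default; a `raw_nM` mode exists for sensitivity checks.
- `sort_by_responsive_count()`: number of selected mutation columns whose
  curated effect is responsive; descending.

Ties everywhere break alphabetically by canonical drug key. All three sorts
are verified against independent brute-force comparators on randomized
fixtures, and each output is checked to be a permutation of the row set.

## Rendering

`render_matrix()` emits a plain-text SVG. Per cell, layered bottom to top:
a colored bar for the curated effect (green responsive / red resistant)
whose *length and saturation both increase with evidence rank* (defaults:
bar height rank/5 of the cell, saturation ramp 20/40/60/80/100% toward the
full hue); a black overlay bar for the bioactivity layer whose width shrinks
with lower potency (defaults 1.0/0.6/0.3); a diagonal slash instead of a bar
for inactive pairs; and a horizontal line in tumor rows marking a
(tumor, mutation) link. Exact hues and ramps are configuration
(`render_config()`), not contract -- the contract is *determinism*: the same
matrix and configuration produce a byte-identical document (fixed `%.2f`
coordinate formatting, no timestamps, stable per-cell `id` attributes so a
front end can attach interactivity). Interactive behaviour itself is out of
scope; `highlight_sets()` computes the hover sets a front end would light
up.

## The fixture generator

`generate_fixture(fixture_spec(...))` builds both source tables plus a
ground-truth manifest. It emulates the *relational* statistics of the real
resources -- per-source and shared counts of mutations, wild-type genes,
drugs, pairs and tumor types, replicate counts per pair, and a controlled
fraction of shared pairs planted as conflicts (resistant effect with
activity values whose median lands in (0, 1000] nM; the planted count is
`round(conflict_fraction * n_pairs_both)`, stated in the manifest to avoid
off-by-one ambiguity in tests). All remaining shared pairs are planted
consistent, so conflict recall and precision against the manifest are exact.
`table2_spec()` carries the published cardinalities of the two real
resources (350/217/31 mutations, 166/116/24 drugs, 546/1859/42 pairs with
665 wild-type pairs, 16 wild-type genes, 52 tumor types); its
`conflict_fraction` defaults to 0.25, a modest rate chosen once as
plausible for curated resources of this size.

What the generator does **not** emulate: real-world name variants and
synonyms, ontology structure in tumor names, realistic (e.g. log-normal)
activity-value distributions beyond class-correct ranges, or correlations
between evidence level and effect. Passing tests therefore demonstrate the
correctness of the linkage, accounting, classification, sorting and
rendering machinery -- not robustness to the messiness of live exports.

A note on pair accounting: with the published marginals, distinct pairs
union to 546 + 1859 − 42 = 2363, while summing per-source pairs gives 2405
(shared pairs counted twice). Both readings are reported
(`merge_statistics()` and `pair_rows_sum()`), since published summaries use
both.

## Numerical and scale choices

- Even-n median: mean of the two central values.
- Potency bins: right-closed, as above; boundary behaviour is sweep-tested
  at `{10, 1000, 10000}` and ±1e-4 offsets.
- Degenerate inputs: empty stores and empty matrices are valid except where
  meaningless (rendering requires ≥ 1 column; aggregation requires ≥ 1
  measurement).
- Test problem sizes: property suites run on fixtures of ~10 drugs and ≤ 4
  selected targets over 100 seeds (sorting) and 20 seeds (conflict
  discovery); merge accounting runs once at the full published scale
  (2405 pair rows, ~5400 bioactivity rows). These sizes exercise every code
  path while keeping the default suite fast.

## Known limitations

- Lexical-only harmonization (no ChEMBL/HGNC resolution) undercounts true
  overlap between sources whenever naming conventions differ.
- The consistency mapping treats evidence levels as credibility only; it
  does not weight conflicts by tumor-type context.
- Causes of conflicts (measurement-type differences, patient history) are
  out of scope: the report exposes *that* sources disagree and hands the
  user the provenance to investigate *why*.
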