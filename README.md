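# dtsynth

Links two kinds of curated oncology tables — **cancer treatment biomarkers**
(drug, mutation, responsive/resistant effect, clinical evidence level) and
**drug–target bioactivities** (Kd/Ki/IC50 in nanomolar) — into one store
keyed by canonical (drug, target) pairs, and exposes the three data
uncertainties that matter when the two views are compared: missing data,
cross-source consistency, and evidence credibility. It is aimed at
bioinformaticians and tool builders triaging drug–mutation evidence, e.g.
for repurposing candidates against resistance mutations.

## The model

A *target* is a point mutation `GENE(MUTATION)` or a wild-type gene `GENE`.
Replicate bioactivities of a pair are summarized by their median (pooled
across measurement types) and binned into ordinal potency classes:

- highly potent: value ∈ (0, 10] nM
- potent: (10, 1000] nM
- weakly potent: (1000, 10000] nM
- inactive: > 10000 nM

with pActivity = −log10(value in molar) as the quantitative scale (10 nM → 8).
Biomarker evidence is ordinal: pre-clinical (1) < case report (2) <
early trials (3) < late trials (4) < guidelines (5).

Each (drug, target) cell gets a consistency state from the pair
(effect, potency class):

| effect \ potency | highly potent / potent | weakly potent | inactive    |
|------------------|------------------------|---------------|-------------|
| responsive       | consistent             | ambiguous     | conflicting |
| resistant        | conflicting            | ambiguous     | consistent  |

plus `cgi_only` / `dtc_only` / `missing` for single-source and empty cells.
A drug-by-target matrix model (with tumor-type rows and auto-added wild-type
columns) supports three drug-sorting procedures and deterministic SVG
rendering with layered encodings: effect as hue, evidence as bar length +
saturation, potency as black overlay width, inactive as a slash.

## Worked example

```r
library(dtsynth)

fix   <- generate_fixture(fixture_spec(seed = 42))  # synthetic source tables
store <- fixture_store(fix)                         # parse + link
merge_statistics(store)
#>               class count_cgi count_dtc count_both count_union
#> 1         mutations        12         9          4          17
#> 2   wild_type_genes         0         3          0           3
#> 3             drugs         8         7          3          12
#> 4 drug_target_pairs        20        24          5          39
#> 5       tumor_types         5         0          0           5
```

Per class, the counts are distinct entities seen in the biomarker source,
the bioactivity source, both, and the union (inclusion–exclusion holds by
construction). The conflict report lists cells where the sources disagree,
highest-credibility contradictions first:

```r
conflict_report(store)[, 1:7]
#>      drug         target       state cgi_effect cgi_evidence dtc_median_nM   dtc_potency
#> 1 DRUG002 GENE002(Q117P) conflicting  resistant   guidelines         1.921 highly_potent
#> 2 DRUG002 GENE003(I109L) conflicting  resistant  late_trials       907.782        potent
```

Row 1 reads: the biomarker source curates DRUG002 as *resistant* against
GENE002(Q117P) at guidelines-level evidence, yet the measured activities
have a median of 1.9 nM — highly potent — so the sources conflict.
Assembling a matrix around a mutation adds its wild-type column (if the gene
has data), pulls in the related drugs and tumor types, and can be sorted and
rendered:

```r
m <- assemble_matrix(store, "GENE002(Q117P)")
m
#> <matrix_model> 3 drugs x 2 targets (1 selected), 4 tumor rows
#>   cell states: consistent=1, conflicting=1, ambiguous=0, cgi_only=0, dtc_only=2, missing=2
sort_by_target(m, "GENE002(Q117P)")
#> [1] "drug002" "drug003" "drug007"
render_matrix(m, path = "matrix.svg")   # byte-deterministic SVG
```

See `vignettes/uncertainty-aware-synthesis.Rmd` for the full account of the
model, its defaults and its limitations.

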