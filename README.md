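# mmint

Integrated miRNA–mRNA differential expression and network analysis for
two-condition RNA-seq experiments.

When a treatment (for example, a sublethal metformin dose in colorectal
cancer cells) shifts both the miRNA repertoire and the coding
transcriptome, the regulatory signal of interest is the set of
miRNA::target pairs in which a differentially expressed miRNA represses a
differentially expressed mRNA. `mmint` implements that integrative
analysis end to end:

1. **Differential expression** — median-of-ratios size factors, moderated
   method-of-moments NB dispersions, a Wald test on
   log₂((q̄_T + c)/(q̄_C + c)), BH adjustment, and the study filters
   (total raw count ≥ 50, padj ≤ 0.05, |log₂FC| ≥ 1, RPM floors of 6/12).
2. **Target integration** — per-resource score thresholds for seven
   prediction/curation resources (TargetScan ≤ −0.15, microT-CDS ≥ 0.85,
   miRDB ≥ 80, miRanda ≤ −1.2, miRmap ≥ 90, miRTarBase/miRecords by
   strong-evidence flag), a ≥ 2-distinct-resource consensus rule, and the
   anti-correlation requirement sign(log₂FC_miRNA) = −sign(log₂FC_gene).
3. **Network** — zero-order PPI subnetwork on DE genes merged with
   miRNA-target edges; degree, betweenness and component metrics.
4. **Enrichment** — one-sided hypergeometric over-representation with
   Bonferroni step-down (Holm) correction, term selection at overlap ≥ 3 /
   attribution ≥ 4% / padj ≤ 0.05, and kappa-score grouping (κ ≥ 0.04)
   with leading-term labelling.

A seeded synthetic-data module generates every input — count matrices,
prediction tables, a random interactome, gene-set collections — with
planted miRNA→target repressions, so the pipeline's precision and recall
against known truth are measurable at any time.

## Worked example

```r
library(mmint)

run <- run_pipeline(pipeline_config(seed = 42))
run
#> <mmint_run>
#>   DE: 24/20 miRNA up/down, 20/28 gene up/down
#>   pairs: 50 consensus -> 42 anti-correlated -> 42 refined
#>   network: 84 nodes, 44 edges
#>   enrichment: 1 terms in 1 groups
#>   recovery: precision 1.000, recall 0.840

run$recovery
#> # A tibble: 1 x 6
#>   n_true_pairs n_reported_pairs true_positive_count precision recall    f1
#>          <int>            <int>               <int>     <dbl>  <dbl> <dbl>
#> 1           50               42                  42         1   0.84 0.913
```

The default configuration simulates 150 miRNAs and 2000 genes with 50
planted repressions at |log₂FC| = 1.5 and three prediction resources at
sensitivity 0.9. Of the 50 planted pairs, 42 survive the full filter
chain (every reported pair is a planted one — precision 1.0; the misses
are pairs whose miRNA or gene fell just short of the |log₂FC| ≥ 1 filter
under sampling noise). The single enriched term is the one seeded with
the planted target genes. Individual stages are available as ordinary
functions on data frames:

```r
de <- de_analysis(counts, conditions)   # counts: feature_id + sample cols
glance(de)
#> # A tibble: 1 x 6
#>   n_features  n_up n_down min_total_count max_padj min_abs_lfc
#>        <int> <int>  <int>           <dbl>    <dbl>       <dbl>
#> 1       2000    20     28              50     0.05           1
autoplot(de)                            # volcano plot

pairs <- predictions |>
  apply_source_thresholds() |>
  consensus_pairs() |>
  anticorrelation_filter(de_mirna, de_mrna)
```

A thin command-line interface over the same functions ships in
`inst/scripts/mmint` (subcommands `simulate`, `de`, `integrate`,
`network`, `enrich`, `run`, `evaluate`), reading and writing plain TSV,
SIF and GMT files; `inst/config/paper_defaults.yaml` carries every default
threshold.

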