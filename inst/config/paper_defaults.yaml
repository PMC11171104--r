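# Default thresholds for the integrated miRNA-mRNA pipeline.
# Values are inclusive boundaries.
seed: 1
de:
  min_total_count: 50      # total raw count over all samples
  max_padj: 0.05           # Benjamini-Hochberg adjusted p
  min_abs_lfc: 1.0         # |log2 fold change|
  pseudo_count: 0.5
  prior_df: 20
rpm_floor_gene: 6          # reads-per-million floor, both condition means
rpm_floor_mirna: 12        # stricter miRNA floor used at refinement
integration:
  min_sources: 2           # distinct supporting resources
  validated_bypass_consensus: false
network:
  min_degree: 1            # genes entering the enrichment query
enrichment:
  min_genes: 3             # minimum overlap per term
  min_attribution: 0.04    # minimum overlap / term-size fraction
  alpha: 0.05              # term adjusted-p cut-off
  kappa_threshold: 0.04    # kappa connectivity for term grouping
  kappa_reference: overlap_union
# Source score thresholds (directional, inclusive) used by
# apply_source_thresholds(); validated resources require the
# strong-evidence flag instead of a score.
sources:
  TargetScan: {kind: predicted, direction: le, threshold: -0.15}
  DIANA-microT-CDS: {kind: predicted, direction: ge, threshold: 0.85}
  miRDB: {kind: predicted, direction: ge, threshold: 80}
  miRanda: {kind: predicted, direction: le, threshold: -1.2}
  miRmap: {kind: predicted, direction: ge, threshold: 90}
  miRTarBase: {kind: validated}
  miRecords: {kind: validated}
sim:
  n_mirna: 150
  n_gene: 2000
  n_pairs: 50
  lfc_magnitude: 1.5
  dispersion: 0.05
  n_rep: 3
  mean_libsize: 1.0e6
  sensitivity: 0.9
  fp_rate: 0.002
  validated_fraction: 0.1
  ppi_mean_degree: 4
  n_terms: 50
  planted_fraction: 0.8
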