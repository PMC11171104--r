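#' Pipeline configuration with the study's default thresholds
#'
#' Collects every tunable of the pipeline in one list. The filtering
#' defaults are the study values: total raw count >= 50, adjusted
#' p <= 0.05, |log2FC| >= 1, RPM floors of 6 (genes) and 12 (miRNAs),
#' consensus across >= 2 resources, enrichment selection at >= 3 overlap
#' genes / >= 4% attribution / adjusted p <= 0.05, and kappa connectivity
#' 0.04. The simulation block defines the default synthetic scenario: 150
#' miRNAs and 2000 genes, 50 planted repressions at |log2FC| 1.5,
#' dispersion 0.05, 3 replicates per condition, three score-based
#' prediction resources at sensitivity 0.9 and false-pair rate 0.002, a
#' random interactome of mean degree 4, and 50 gene sets with one term
#' seeded from the planted targets.
#'
#' @param ... Named overrides of any default (unknown names are an error).
#' @return A list of class `mmint_config`.
#' @examples
#' cfg <- pipeline_config(seed = 7, sim = list(n_pairs = 20))
#' cfg$sim$n_pairs
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    seed = 1L,
    sim = list(
      n_mirna = 150, n_gene = 2000, n_pairs = 50, lfc_magnitude = 1.5,
      dispersion = 0.05, n_rep = 3, mean_libsize = 1e6,
      libsize_range = c(0.5, 2),
      sources = c("TargetScan", "miRDB", "miRmap"),
      sensitivity = 0.9, fp_rate = 0.002, validated_fraction = 0.1,
      ppi_mean_degree = 4, n_terms = 50, term_size_range = c(10, 200),
      planted_fraction = 0.8
    ),
    de = list(min_total_count = 50, max_padj = 0.05, min_abs_lfc = 1,
              pseudo_count = 0.5, prior_df = 20),
    rpm_floor_gene = 6,
    rpm_floor_mirna = 12,
    integration = list(min_sources = 2, validated_bypass_consensus = FALSE),
    network = list(min_degree = 1),
    enrichment = list(min_genes = 3, min_attribution = 0.04, alpha = 0.05,
                      kappa_threshold = 0.04,
                      kappa_reference = "overlap_union"),
    role_table = NULL,
    out_dir = NULL
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown) > 0) {
    abort(paste0("Unknown configuration field(s): ",
                 paste(unknown, collapse = ", ")))
  }
  for (nm in names(overrides)) {
    if (is.list(defaults[[nm]]) && is.list(overrides[[nm]])) {
      bad <- setdiff(names(overrides[[nm]]), names(defaults[[nm]]))
      if (length(bad) > 0) {
        abort(paste0("Unknown field(s) in `", nm, "`: ",
                     paste(bad, collapse = ", ")))
      }
      defaults[[nm]] <- modifyList(defaults[[nm]], overrides[[nm]])
    } else {
      defaults[[nm]] <- overrides[[nm]]
    }
  }
  structure(defaults, class = "mmint_config")
}

#' Run the integrated miRNA-mRNA pipeline
#'
#' Executes simulate (optional) -> differential expression -> target
#' integration -> network assembly -> enrichment as one seeded run, and
#' scores recovery against the planted truth when available.
#'
#' When `inputs` is `NULL` every input is generated by the synthetic-data
#' module from `config$sim` (stage seeds are derived from `config$seed`).
#' Alternatively pass a named list with `mirna_counts`, `mrna_counts`,
#' `conditions`, `predictions`, `ppi`, `genesets` and optionally `truth`.
#'
#' @param config A [pipeline_config()] list.
#' @param inputs Optional named list of pre-loaded inputs (see Details).
#' @return An object of class `mmint_run`: list with the stage outputs
#'   (`truth`, `de_mirna`, `de_mrna`, `pairs_consensus`, `pairs`,
#'   `pairs_refined`, `network`, `topology`, `enrichment`), the filter
#'   funnel `summary` (named list of counts), and `recovery` (one-row
#'   tibble, or NULL without truth). With `config$out_dir` set, every stage
#'   output plus `summary.json` is written there.
#' @export
run_pipeline <- function(config = pipeline_config(), inputs = NULL) {
  stopifnot(inherits(config, "mmint_config") || is.list(config))
  seed <- .check_seed(config$seed)

  truth <- NULL
  if (is.null(inputs)) {
    sim <- config$sim
    truth <- simulate_ground_truth(
      sim$n_mirna, sim$n_gene, sim$n_pairs, sim$lfc_magnitude,
      dispersion = sim$dispersion, seed = seed)
    counts <- simulate_counts(truth, n_rep = sim$n_rep,
                              mean_libsize = sim$mean_libsize,
                              libsize_range = sim$libsize_range,
                              seed = seed + 1L)
    predictions <- simulate_predictions(
      truth, sources = sim$sources, sensitivity = sim$sensitivity,
      fp_rate = sim$fp_rate, validated_fraction = sim$validated_fraction,
      seed = seed + 2L)
    gene_ids <- truth$features$feature_id[truth$features$type == "gene"]
    ppi <- simulate_ppi(gene_ids, mean_degree = sim$ppi_mean_degree,
                        seed = seed + 3L)
    genesets <- simulate_genesets(
      gene_ids, n_terms = sim$n_terms,
      term_size_range = pmin(sim$term_size_range, length(gene_ids)),
      planted_genes = unique(truth$pairs$gene_id),
      planted_fraction = sim$planted_fraction, seed = seed + 4L)
    inputs <- list(mirna_counts = counts$mirna, mrna_counts = counts$mrna,
                   conditions = counts$conditions,
                   predictions = predictions, ppi = ppi,
                   genesets = genesets, truth = truth,
                   lib_factors = counts$lib_factors)
  } else {
    need <- c("mirna_counts", "mrna_counts", "conditions", "predictions",
              "ppi", "genesets")
    missing <- setdiff(need, names(inputs))
    if (length(missing) > 0) {
      abort(paste0("Missing pipeline input(s): ",
                   paste(missing, collapse = ", ")))
    }
    truth <- inputs$truth
  }

  de_args <- config$de
  # --- differential expression ---
  de_mirna <- de_analysis(inputs$mirna_counts, inputs$conditions,
                          min_total_count = de_args$min_total_count,
                          max_padj = de_args$max_padj,
                          min_abs_lfc = de_args$min_abs_lfc,
                          pseudo_count = de_args$pseudo_count,
                          prior_df = de_args$prior_df)
  de_mrna <- de_analysis(inputs$mrna_counts, inputs$conditions,
                         min_total_count = de_args$min_total_count,
                         max_padj = de_args$max_padj,
                         min_abs_lfc = de_args$min_abs_lfc,
                         pseudo_count = de_args$pseudo_count,
                         prior_df = de_args$prior_df)

  # --- gene RPM floor: genes below the floor leave the analysis ---
  gene_rpm_kept <- rpm_filter(inputs$mrna_counts, inputs$conditions,
                              config$rpm_floor_gene)
  de_mrna_kept <- de_mrna[de_mrna$feature_id %in% gene_rpm_kept, ,
                          drop = FALSE]

  # --- target integration ---
  thresholded <- apply_source_thresholds(inputs$predictions)
  consensus <- consensus_pairs(
    thresholded, min_sources = config$integration$min_sources,
    validated_bypass_consensus = config$integration$validated_bypass_consensus)
  pairs <- anticorrelation_filter(consensus, de_mirna, de_mrna_kept)

  # --- refinement (miRNA RPM floor + optional cancer-role orientation) ---
  mirna_rpm_kept <- rpm_filter(inputs$mirna_counts, inputs$conditions,
                               config$rpm_floor_mirna)
  pairs_refined <- refine_pairs(pairs, mirna_rpm_kept,
                                role_table = config$role_table)

  # --- network ---
  de_gene_ids <- c(filter_de(de_mrna_kept)$up$feature_id,
                   filter_de(de_mrna_kept)$down$feature_id)
  ppi_sub <- zero_order_subnetwork(inputs$ppi, de_gene_ids)
  network <- assemble_network(pairs, ppi_sub, de_mirna, de_mrna_kept)
  topology <- network_topology(network)

  # --- enrichment on network genes with degree >= min_degree ---
  query <- degree_filter(network, config$network$min_degree)
  enr <- config$enrichment
  enrichment <- run_enrichment(query, inputs$genesets,
                               min_genes = enr$min_genes,
                               min_attribution = enr$min_attribution,
                               alpha = enr$alpha,
                               kappa_threshold = enr$kappa_threshold,
                               kappa_reference = enr$kappa_reference)

  recovery <- if (!is.null(truth)) evaluate_recovery(pairs, truth) else NULL

  summary <- list(
    seed = seed,
    mirna_features = nrow(inputs$mirna_counts),
    mirna_de_up = sum(de_mirna$direction == "up"),
    mirna_de_down = sum(de_mirna$direction == "down"),
    gene_features = nrow(inputs$mrna_counts),
    gene_de_up = sum(de_mrna$direction == "up"),
    gene_de_down = sum(de_mrna$direction == "down"),
    gene_de_rpm_kept = length(de_gene_ids),
    prediction_records = nrow(inputs$predictions),
    records_pass_threshold = nrow(thresholded),
    pairs_consensus = nrow(consensus),
    pairs_anticorrelated = nrow(pairs),
    pairs_refined = nrow(pairs_refined),
    network_nodes = nrow(network$nodes),
    network_mirna_nodes = sum(network$nodes$type == "miRNA"),
    network_gene_nodes = sum(network$nodes$type == "gene"),
    network_edges = nrow(network$edges),
    network_mirna_gene_edges =
      sum(network$edges$edge_type == "mirna_gene"),
    network_gene_gene_edges =
      sum(network$edges$edge_type == "gene_gene"),
    enrichment_terms_tested = attr(enrichment, "n_tested"),
    enrichment_terms_selected = nrow(enrichment),
    enrichment_groups = nrow(attr(enrichment, "groups"))
  )
  if (!is.null(recovery)) {
    summary <- c(summary, list(
      n_true_pairs = recovery$n_true_pairs,
      true_positive_count = recovery$true_positive_count,
      precision = recovery$precision,
      recall = recovery$recall,
      f1 = recovery$f1
    ))
  }

  run <- structure(
    list(truth = truth, inputs = inputs, config = config,
         de_mirna = de_mirna, de_mrna = de_mrna,
         de_mrna_kept = de_mrna_kept,
         pairs_consensus = consensus, pairs = pairs,
         pairs_refined = pairs_refined,
         network = network, topology = topology, enrichment = enrichment,
         summary = summary, recovery = recovery),
    class = "mmint_run"
  )
  if (!is.null(config$out_dir)) .write_run(run, config$out_dir)
  run
}

.write_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(out_dir, ...)
  write_counts_tsv(run$inputs$mirna_counts, p("mirna_counts.tsv"))
  write_counts_tsv(run$inputs$mrna_counts, p("mrna_counts.tsv"))
  write_conditions_tsv(run$inputs$conditions, p("conditions.tsv"))
  write_predictions_tsv(run$inputs$predictions, p("predictions.tsv"))
  write_ppi_tsv(run$inputs$ppi, p("ppi.tsv"))
  write_gmt(run$inputs$genesets, p("genesets.gmt"))
  write_de_tsv(run$de_mirna, p("de_mirna.tsv"))
  write_de_tsv(run$de_mrna, p("de_mrna.tsv"))
  write_pairs_tsv(run$pairs, p("pairs.tsv"))
  write_pairs_tsv(run$pairs_refined, p("pairs_refined.tsv"))
  write_sif(run$network, p("network.sif"))
  write_node_attributes(run$topology, p("network_nodes.tsv"))
  .write_tsv(dplyr::select(tidy(run$enrichment), -"overlap_genes"),
             p("enriched_terms.tsv"))
  jsonlite::write_json(run$summary, p("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.mmint_run <- function(x, ...) {
  cat("<mmint_run>\n")
  s <- x$summary
  cat(sprintf("  DE: %d/%d miRNA up/down, %d/%d gene up/down\n",
              s$mirna_de_up, s$mirna_de_down, s$gene_de_up, s$gene_de_down))
  cat(sprintf("  pairs: %d consensus -> %d anti-correlated -> %d refined\n",
              s$pairs_consensus, s$pairs_anticorrelated, s$pairs_refined))
  cat(sprintf("  network: %d nodes, %d edges\n",
              s$network_nodes, s$network_edges))
  cat(sprintf("  enrichment: %d terms in %d groups\n",
              s$enrichment_terms_selected, s$enrichment_groups))
  if (!is.null(x$recovery)) {
    cat(sprintf("  recovery: precision %.3f, recall %.3f\n",
                x$recovery$precision, x$recovery$recall))
  }
  invisible(x)
}

#' @method glance mmint_run
#' @export
glance.mmint_run <- function(x, ...) {
  as_tibble(x$summary)
}

#' Score reported pairs against the planted truth
#'
#' Set comparison of reported (miRNA, gene) tuples with the planted
#' regulated pairs: precision, recall and F1. With zero reported pairs the
#' precision is undefined (NA); with zero planted pairs the recall is NA.
#'
#' @param pairs Pair tibble with `mirna_id`, `gene_id`.
#' @param truth A [simulate_ground_truth()] object.
#' @return One-row tibble: `n_true_pairs`, `n_reported_pairs`,
#'   `true_positive_count`, `precision`, `recall`, `f1`.
#' @export
evaluate_recovery <- function(pairs, truth) {
  stopifnot(inherits(truth, "mmint_truth"))
  reported <- unique(paste(pairs$mirna_id, pairs$gene_id, sep = "::"))
  planted <- unique(paste(truth$pairs$mirna_id, truth$pairs$gene_id,
                          sep = "::"))
  tp <- length(intersect(reported, planted))
  precision <- if (length(reported) > 0) tp / length(reported) else NA_real_
  recall <- if (length(planted) > 0) tp / length(planted) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else NA_real_
  tibble(n_true_pairs = length(planted),
         n_reported_pairs = length(reported),
         true_positive_count = tp,
         precision = precision, recall = recall, f1 = f1)
}

#' Filter-funnel plot of a pipeline run
#'
#' Bar chart of the pair-selection funnel: raw prediction records, records
#' passing per-resource thresholds, consensus pairs, anti-correlated DE
#' pairs, refined pairs.
#'
#' @param run An [run_pipeline()] result.
#' @return A ggplot.
#' @export
plot_filter_funnel <- function(run) {
  stopifnot(inherits(run, "mmint_run"))
  s <- run$summary
  df <- tibble(
    stage = factor(c("records", "pass threshold", "consensus",
                     "anti-correlated", "refined"),
                   levels = c("records", "pass threshold", "consensus",
                              "anti-correlated", "refined")),
    count = c(s$prediction_records, s$records_pass_threshold,
              s$pairs_consensus, s$pairs_anticorrelated, s$pairs_refined)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$stage, .data$count)) +
    ggplot2::geom_col(fill = "#4477aa") +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), vjust = -0.4,
                       size = 3) +
    ggplot2::labs(x = NULL, y = "pairs / records") +
    ggplot2::theme_minimal()
}
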