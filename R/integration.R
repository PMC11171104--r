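#' Registry of target-prediction resources and their score thresholds
#'
#' The seven resources with the score cut-offs used throughout the package:
#' TargetScan context score <= -0.15, DIANA-microT-CDS miTG score >= 0.85,
#' miRDB score >= 80, miRanda miRSV score <= -1.2, miRmap score >= 90, and
#' the two curation resources miRTarBase and miRecords, for which a record
#' passes when it carries a strong-evidence (reporter assay) validation
#' flag rather than a score. All score thresholds are inclusive.
#'
#' The `score_lo`/`score_hi` and `pass_lo`/`pass_hi` columns describe each
#' resource's plausible and passing score ranges; they drive the
#' synthetic-prediction generator and have no effect on filtering.
#'
#' @return A tibble with columns `source`, `kind` (predicted/validated),
#'   `direction` (`"le"`/`"ge"`), `threshold`, `score_lo`, `score_hi`,
#'   `pass_lo`, `pass_hi`.
#' @export
source_registry <- function() {
  tibble(
    source = c("TargetScan", "DIANA-microT-CDS", "miRDB", "miRanda",
               "miRmap", "miRTarBase", "miRecords"),
    kind = c(rep("predicted", 5), rep("validated", 2)),
    direction = c("le", "ge", "ge", "le", "ge", NA, NA),
    threshold = c(-0.15, 0.85, 80, -1.2, 90, NA, NA),
    score_lo = c(-1.5, 0.4, 50, -2.5, 60, NA, NA),
    score_hi = c(0.1, 1.0, 100, -0.3, 100, NA, NA),
    pass_lo = c(-1.2, 0.85, 80, -2.4, 90, NA, NA),
    pass_hi = c(-0.15, 1.0, 100, -1.2, 100, NA, NA)
  )
}

#' Apply per-resource score thresholds to a prediction table
#'
#' Score-based records are kept iff the score passes the resource's
#' directional threshold (inclusive in both directions, e.g. a TargetScan
#' context score of exactly -0.15 passes). Records from curation resources
#' are kept iff their validated flag is set. Records with a missing score
#' from a score-based resource are dropped.
#'
#' @param predictions Tibble with `source`, `mirna_id`, `gene_id`, `score`,
#'   `validated`.
#' @param config Source configuration tibble; defaults to
#'   [source_registry()].
#' @return The filtered prediction tibble.
#' @export
apply_source_thresholds <- function(predictions, config = source_registry()) {
  req <- c("source", "mirna_id", "gene_id", "score", "validated")
  stopifnot(all(req %in% names(predictions)))
  unknown <- setdiff(unique(predictions$source), config$source)
  if (length(unknown) > 0) {
    abort(paste0("Prediction source(s) without a configuration: ",
                 paste(sort(unknown), collapse = ", ")))
  }
  joined <- predictions %>%
    left_join(dplyr::select(config, "source", "kind", "direction",
                            "threshold"),
              by = "source")
  keep <- ifelse(
    joined$kind == "validated",
    joined$validated,
    !is.na(joined$score) & ifelse(joined$direction == "le",
                                  joined$score <= joined$threshold,
                                  joined$score >= joined$threshold)
  )
  predictions[keep, , drop = FALSE]
}

#' Consensus pairs supported by at least `min_sources` distinct resources
#'
#' Groups threshold-passing records by (miRNA, gene) and keeps pairs
#' supported by at least `min_sources` *distinct* resources — duplicate
#' records from one resource count once. A pair is marked validated when
#' any supporting record carries the validated flag.
#'
#' @param records Threshold-filtered prediction tibble.
#' @param min_sources Minimum number of distinct supporting resources.
#' @param validated_bypass_consensus If `TRUE`, experimentally validated
#'   pairs are retained even when supported by fewer than `min_sources`
#'   resources (default `FALSE`: validated and predicted resources count on
#'   equal footing).
#' @return Tibble with `mirna_id`, `gene_id`, `n_sources`, `sources`
#'   (comma-separated, sorted), `validated`.
#' @export
consensus_pairs <- function(records, min_sources = 2,
                            validated_bypass_consensus = FALSE) {
  .check_scalar_number(min_sources, "min_sources", lower = 1)
  records %>%
    group_by(.data$mirna_id, .data$gene_id) %>%
    summarise(
      n_sources = n_distinct(.data$source),
      sources = paste(sort(unique(.data$source)), collapse = ","),
      validated = any(.data$validated),
      .groups = "drop"
    ) %>%
    filter(.data$n_sources >= min_sources |
             (validated_bypass_consensus & .data$validated)) %>%
    arrange(.data$mirna_id, .data$gene_id)
}

#' Keep pairs whose members are differentially expressed in opposite directions
#'
#' Implements the repression-consistency rule: a pair survives only when
#' the miRNA is up and the gene down, or the miRNA down and the gene up,
#' according to the supplied DE tables. Pairs with either member not
#' differentially expressed are dropped. Both log2 fold changes are
#' attached to the surviving pairs.
#'
#' @param pairs Consensus-pair tibble (`mirna_id`, `gene_id`, ...).
#' @param de_mirna,de_mrna DE tibbles with `feature_id`, `log2fc`,
#'   `direction` (from [de_analysis()]).
#' @return The pair tibble restricted to anti-correlated DE pairs, with
#'   `mirna_log2fc` and `gene_log2fc` columns added.
#' @export
anticorrelation_filter <- function(pairs, de_mirna, de_mrna) {
  for (x in list(de_mirna, de_mrna)) {
    stopifnot(all(c("feature_id", "log2fc", "direction") %in% names(x)))
  }
  out <- pairs %>%
    inner_join(dplyr::select(de_mirna, mirna_id = "feature_id",
                             mirna_log2fc = "log2fc",
                             mirna_dir = "direction"),
               by = "mirna_id") %>%
    inner_join(dplyr::select(de_mrna, gene_id = "feature_id",
                             gene_log2fc = "log2fc",
                             gene_dir = "direction"),
               by = "gene_id") %>%
    filter((.data$mirna_dir == "up" & .data$gene_dir == "down") |
             (.data$mirna_dir == "down" & .data$gene_dir == "up")) %>%
    dplyr::select(-"mirna_dir", -"gene_dir") %>%
    arrange(.data$mirna_id, .data$gene_id)
  out
}

#' Refine pairs by the miRNA expression floor and cancer-role orientation
#'
#' Drops pairs whose miRNA did not reach the reads-per-million floor
#' (computed upstream with [rpm_filter()], conventionally at RPM >= 12).
#' When a role table is supplied, pairs are additionally required to be
#' role-consistent: a downregulated miRNA annotated as an oncogenic miRNA
#' paired with an upregulated tumour-suppressor gene, or — symmetrically —
#' an upregulated tumour-suppressor miRNA paired with a downregulated
#' oncogene. Without a role table the role filter is skipped with a notice.
#'
#' @param pairs Pair tibble with `mirna_id`, `gene_id`, `mirna_log2fc`,
#'   `gene_log2fc`.
#' @param mirna_rpm_kept Character vector of miRNAs passing the RPM floor.
#' @param role_table Optional tibble with `id` and `role`
#'   (`"oncogene"`, `"tumour_suppressor"` or `"unknown"`).
#' @return The refined pair tibble.
#' @export
refine_pairs <- function(pairs, mirna_rpm_kept, role_table = NULL) {
  stopifnot(all(c("mirna_id", "gene_id", "mirna_log2fc", "gene_log2fc")
                %in% names(pairs)))
  out <- pairs[pairs$mirna_id %in% mirna_rpm_kept, , drop = FALSE]
  if (is.null(role_table)) {
    inform("No role table supplied; skipping oncogene/tumour-suppressor orientation filter.")
    return(out)
  }
  stopifnot(all(c("id", "role") %in% names(role_table)))
  role <- setNames(role_table$role, role_table$id)
  get_role <- function(ids) {
    r <- role[ids]
    r[is.na(r)] <- "unknown"
    unname(r)
  }
  mr <- get_role(out$mirna_id)
  gr <- get_role(out$gene_id)
  keep <- (out$mirna_log2fc < 0 & mr == "oncogene" &
             out$gene_log2fc > 0 & gr == "tumour_suppressor") |
    (out$mirna_log2fc > 0 & mr == "tumour_suppressor" &
       out$gene_log2fc < 0 & gr == "oncogene")
  out[keep, , drop = FALSE]
}

#' Run the full target-integration stage
#'
#' Convenience wrapper chaining [apply_source_thresholds()],
#' [consensus_pairs()] and [anticorrelation_filter()].
#'
#' @inheritParams apply_source_thresholds
#' @inheritParams consensus_pairs
#' @inheritParams anticorrelation_filter
#' @return A pair tibble as returned by [anticorrelation_filter()].
#' @export
integrate_targets <- function(predictions, de_mirna, de_mrna,
                              config = source_registry(), min_sources = 2) {
  predictions %>%
    apply_source_thresholds(config) %>%
    consensus_pairs(min_sources) %>%
    anticorrelation_filter(de_mirna, de_mrna)
}
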