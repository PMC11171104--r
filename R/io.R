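# Plain-text readers/writers for the pipeline's interchange formats.
# All tables are tab-separated with a header row and no quoting, so outputs
# are byte-stable across runs and diffable.

.write_tsv <- function(df, path) {
  df <- as.data.frame(df)
  list_cols <- vapply(df, is.list, logical(1))
  for (col in names(df)[list_cols]) {
    df[[col]] <- vapply(df[[col]], paste, character(1), collapse = ",")
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.read_tsv <- function(path) {
  as_tibble(utils::read.delim(path, sep = "\t", header = TRUE,
                              stringsAsFactors = FALSE, check.names = FALSE))
}

#' Read and write count matrices as TSV
#'
#' The layout is one `feature_id` column followed by one column per sample;
#' the header row carries the sample ids.
#'
#' @param counts Count tibble.
#' @param path File path.
#' @return `read_counts_tsv()` returns the count tibble;
#'   `write_counts_tsv()` returns `path` invisibly.
#' @export
write_counts_tsv <- function(counts, path) .write_tsv(counts, path)

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path) .read_tsv(path)

#' Read and write sample-condition maps as two-column TSV
#'
#' @param conditions Tibble with `sample_id`, `condition`.
#' @param path File path.
#' @return `read_conditions_tsv()` returns the tibble.
#' @export
write_conditions_tsv <- function(conditions, path) {
  stopifnot(all(c("sample_id", "condition") %in% names(conditions)))
  .write_tsv(conditions[, c("sample_id", "condition")], path)
}

#' @rdname write_conditions_tsv
#' @export
read_conditions_tsv <- function(path) .read_tsv(path)

#' Read and write prediction tables as five-column TSV
#'
#' Columns: `source`, `mirna_id`, `gene_id`, `score` (NA allowed),
#' `validated` (TRUE/FALSE).
#'
#' @param predictions Prediction tibble.
#' @param path File path.
#' @return `read_predictions_tsv()` returns the tibble with `validated`
#'   as logical.
#' @export
write_predictions_tsv <- function(predictions, path) {
  .write_tsv(predictions[, c("source", "mirna_id", "gene_id", "score",
                             "validated")], path)
}

#' @rdname write_predictions_tsv
#' @export
read_predictions_tsv <- function(path) {
  out <- .read_tsv(path)
  out$validated <- as.logical(out$validated)
  out$score <- as.numeric(out$score)
  out
}

#' Read and write PPI edge lists
#'
#' Two-column TSV (`gene_a`, `gene_b`) or, with `format = "sif"`, the SIF
#' dialect `A pp B`.
#'
#' @param ppi Edge tibble with `gene_a`, `gene_b`.
#' @param path File path.
#' @param format `"tsv"` (default) or `"sif"`.
#' @return `read_ppi_tsv()` returns the edge tibble.
#' @export
write_ppi_tsv <- function(ppi, path, format = c("tsv", "sif")) {
  format <- match.arg(format)
  if (format == "tsv") {
    .write_tsv(ppi[, c("gene_a", "gene_b")], path)
  } else {
    writeLines(paste(ppi$gene_a, "pp", ppi$gene_b), path)
    invisible(path)
  }
}

#' @rdname write_ppi_tsv
#' @export
read_ppi_tsv <- function(path, format = c("tsv", "sif")) {
  format <- match.arg(format)
  if (format == "tsv") {
    .read_tsv(path)
  } else {
    parts <- strsplit(readLines(path), "[ \t]+")
    tibble(gene_a = vapply(parts, `[`, character(1), 1),
           gene_b = vapply(parts, `[`, character(1), 3))
  }
}

#' Read and write gene-set collections in GMT format
#'
#' One term per line: term id, term name, then tab-separated member genes.
#' `read_gmt()` takes the universe as the union of all members unless given.
#'
#' @param genesets A [simulate_genesets()] object or named list of gene
#'   vectors.
#' @param path File path.
#' @param universe Optional universe for `read_gmt()`.
#' @return `read_gmt()` returns an `mmint_genesets` object.
#' @export
write_gmt <- function(genesets, path) {
  if (inherits(genesets, "mmint_genesets")) {
    ids <- names(genesets$sets)
    names_ <- genesets$info$term_name[match(ids, genesets$info$term_id)]
    sets <- genesets$sets
  } else {
    ids <- names(genesets)
    names_ <- ids
    sets <- genesets
  }
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(ids[i], names_[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- readLines(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(parts, `[`, character(1), 1)
  names_ <- vapply(parts, `[`, character(1), 2)
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- ids
  if (is.null(universe)) universe <- sort(unique(unlist(sets)))
  structure(
    list(sets = sets, info = tibble(term_id = ids, term_name = names_),
         universe = universe, planted_term_id = NA_character_),
    class = "mmint_genesets"
  )
}

#' Write an integrated network as SIF plus node attributes
#'
#' Edges are written in the SIF dialect with interaction type `pp` for
#' gene-gene edges and `mg` for miRNA-gene edges. The companion node table
#' (`id`, `type`, `regulation`, `degree`, `betweenness`) is what standard
#' graph viewers import as node attributes.
#'
#' @param network An [assemble_network()] object.
#' @param path SIF file path.
#' @return `path`, invisibly.
#' @export
write_sif <- function(network, path) {
  stopifnot(inherits(network, "mmint_network"))
  rel <- ifelse(network$edges$edge_type == "gene_gene", "pp", "mg")
  writeLines(paste(network$edges$from, rel, network$edges$to), path)
  invisible(path)
}

#' @rdname write_sif
#' @param topology A [network_topology()] result.
#' @export
write_node_attributes <- function(topology, path) {
  stopifnot(inherits(topology, "mmint_topology"))
  .write_tsv(topology$nodes[, c("id", "type", "regulation", "degree",
                                "betweenness")], path)
}

#' Write a pair table as TSV
#'
#' @param pairs Pair tibble.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_pairs_tsv <- function(pairs, path) .write_tsv(pairs, path)

#' @rdname write_pairs_tsv
#' @export
read_pairs_tsv <- function(path) .read_tsv(path)

#' Write a differential-expression table as TSV
#'
#' @param de A [de_analysis()] result or plain DE tibble.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_de_tsv <- function(de, path) {
  cols <- intersect(c("feature_id", "base_mean", "log2fc", "stat", "pvalue",
                      "padj", "total_raw_count", "rpm_control",
                      "rpm_treated", "direction"), names(de))
  .write_tsv(as_tibble(de)[, cols], path)
}

#' @rdname write_de_tsv
#' @export
read_de_tsv <- function(path) .read_tsv(path)
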