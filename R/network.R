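#' Zero-order subnetwork of a reference interactome
#'
#' Restricts a protein-protein interaction edge list to the edges whose
#' *both* endpoints belong to the seed genes (the induced subgraph), then
#' drops seed genes left without any edge — the usual zero-order network
#' convention of interactome browsers.
#'
#' @param ppi Tibble with `gene_a`, `gene_b` (undirected simple graph).
#' @param seed_genes Character vector of seed gene ids.
#' @return A list with `edges` (tibble `gene_a`, `gene_b`, canonical
#'   `gene_a < gene_b` ordering) and `genes` (endpoints of kept edges).
#' @export
zero_order_subnetwork <- function(ppi, seed_genes) {
  stopifnot(all(c("gene_a", "gene_b") %in% names(ppi)))
  keep <- ppi$gene_a %in% seed_genes & ppi$gene_b %in% seed_genes
  edges <- ppi[keep, c("gene_a", "gene_b"), drop = FALSE]
  edges <- tibble(gene_a = pmin(edges$gene_a, edges$gene_b),
                  gene_b = pmax(edges$gene_a, edges$gene_b)) %>%
    filter(.data$gene_a != .data$gene_b) %>%
    distinct() %>%
    arrange(.data$gene_a, .data$gene_b)
  list(edges = edges,
       genes = sort(unique(c(edges$gene_a, edges$gene_b))))
}

#' Assemble the integrated miRNA-gene network
#'
#' Merges miRNA-target pairs and the zero-order PPI subnetwork into one
#' undirected network with typed nodes (miRNA / gene) and typed edges
#' (`mirna_gene` / `gene_gene`). Node regulation (up / down) is annotated
#' from the DE tables; regulatory direction is node metadata, not edge
#' direction. Edges are deduplicated and stored in a canonical order so
#' assembly is invariant to input ordering.
#'
#' @param pairs Pair tibble (`mirna_id`, `gene_id`).
#' @param ppi_sub Zero-order result from [zero_order_subnetwork()], or a
#'   tibble of `gene_a`, `gene_b` edges.
#' @param de_mirna,de_mrna DE tibbles carrying `feature_id` and `direction`.
#' @return An object of class `mmint_network`: list with `nodes` (tibble
#'   `id`, `type`, `regulation`) and `edges` (tibble `from`, `to`,
#'   `edge_type`).
#' @export
assemble_network <- function(pairs, ppi_sub, de_mirna = NULL,
                             de_mrna = NULL) {
  ppi_edges <- if (is.list(ppi_sub) && !is.data.frame(ppi_sub)) {
    ppi_sub$edges
  } else {
    ppi_sub
  }
  mirna_ids <- unique(pairs$mirna_id)
  gene_ids <- unique(c(pairs$gene_id, ppi_edges$gene_a, ppi_edges$gene_b))
  clash <- intersect(mirna_ids, gene_ids)
  if (length(clash) > 0) {
    abort(paste0("Id(s) typed both as miRNA and as gene: ",
                 paste(sort(clash), collapse = ", ")))
  }

  direction_of <- function(ids, de_a, de_b) {
    dirs <- rep(NA_character_, length(ids))
    for (de in list(de_a, de_b)) {
      if (!is.null(de)) {
        hit <- match(ids, de$feature_id)
        found <- !is.na(hit)
        dirs[found] <- de$direction[hit[found]]
      }
    }
    dirs
  }

  nodes <- bind_rows(
    tibble(id = mirna_ids, type = "miRNA"),
    tibble(id = gene_ids, type = "gene")
  ) %>%
    mutate(regulation = direction_of(.data$id, de_mirna, de_mrna)) %>%
    arrange(.data$type, .data$id)

  mg <- tibble(from = pairs$mirna_id, to = pairs$gene_id,
               edge_type = "mirna_gene")
  gg <- tibble(from = pmin(ppi_edges$gene_a, ppi_edges$gene_b),
               to = pmax(ppi_edges$gene_a, ppi_edges$gene_b),
               edge_type = "gene_gene")
  edges <- bind_rows(mg, gg) %>%
    filter(.data$from != .data$to) %>%
    distinct() %>%
    arrange(.data$edge_type, .data$from, .data$to)

  structure(list(nodes = nodes, edges = edges), class = "mmint_network")
}

#' @export
print.mmint_network <- function(x, ...) {
  cat("<mmint_network>\n")
  cat(sprintf("  nodes: %d (%d miRNA, %d gene)\n", nrow(x$nodes),
              sum(x$nodes$type == "miRNA"), sum(x$nodes$type == "gene")))
  cat(sprintf("  edges: %d (%d miRNA-gene, %d gene-gene)\n", nrow(x$edges),
              sum(x$edges$edge_type == "mirna_gene"),
              sum(x$edges$edge_type == "gene_gene")))
  invisible(x)
}

.as_igraph <- function(network) {
  igraph::graph_from_data_frame(
    network$edges[, c("from", "to")],
    directed = FALSE,
    vertices = network$nodes$id
  )
}

#' Topology metrics of an integrated network
#'
#' Degree, betweenness centrality (shortest-path definition, undirected,
#' unweighted; unnormalised by default) and connected components.
#'
#' @param network An [assemble_network()] object.
#' @param normalized Normalise betweenness by `(n-1)(n-2)/2`?
#' @return A list of class `mmint_topology` with `nodes` (tibble `id`,
#'   `type`, `regulation`, `degree`, `betweenness`, `component`),
#'   `components` (tibble `component`, `size`) and `summary` (node/edge
#'   counts by type).
#' @export
network_topology <- function(network, normalized = FALSE) {
  stopifnot(inherits(network, "mmint_network"))
  g <- .as_igraph(network)
  deg <- igraph::degree(g)
  btw <- igraph::betweenness(g, directed = FALSE, normalized = normalized)
  comp <- igraph::components(g)
  nodes <- network$nodes %>%
    mutate(degree = as.numeric(deg[.data$id]),
           betweenness = as.numeric(btw[.data$id]),
           component = as.integer(comp$membership[.data$id]))
  structure(
    list(
      nodes = nodes,
      components = tibble(component = seq_along(comp$csize),
                          size = as.integer(comp$csize)),
      summary = tibble(
        n_nodes = nrow(network$nodes),
        n_mirna = sum(network$nodes$type == "miRNA"),
        n_gene = sum(network$nodes$type == "gene"),
        n_edges = nrow(network$edges),
        n_mirna_gene = sum(network$edges$edge_type == "mirna_gene"),
        n_gene_gene = sum(network$edges$edge_type == "gene_gene")
      )
    ),
    class = "mmint_topology"
  )
}

#' @export
print.mmint_topology <- function(x, ...) {
  cat("<mmint_topology>\n")
  print(x$summary)
  invisible(x)
}

#' @method tidy mmint_topology
#' @export
tidy.mmint_topology <- function(x, ...) x$nodes

#' @method glance mmint_topology
#' @export
glance.mmint_topology <- function(x, ...) {
  dplyr::mutate(x$summary, n_components = nrow(x$components))
}

#' Gene nodes reaching a minimum degree
#'
#' Returns gene-type nodes with at least `min_degree` incident edges of any
#' type (a gene connected only to a miRNA counts).
#'
#' @param network An [assemble_network()] object.
#' @param min_degree Inclusive degree floor (default 1).
#' @return Character vector of gene ids, sorted.
#' @export
degree_filter <- function(network, min_degree = 1) {
  stopifnot(inherits(network, "mmint_network"))
  deg <- igraph::degree(.as_igraph(network))
  genes <- network$nodes$id[network$nodes$type == "gene"]
  sort(genes[deg[genes] >= min_degree])
}
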