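#' One-sided hypergeometric over-representation test
#'
#' Probability of observing at least the actual overlap between a query
#' gene set and a term under random sampling from the universe:
#' `P(X >= k)` with `X ~ Hypergeometric(N = |universe|, K = |term|,
#' n = |query|)` and `k = |query intersect term|`.
#'
#' @param query,term,universe Character vectors of gene ids; `query` and
#'   `term` are intersected with `universe` before testing.
#' @return The one-sided p-value.
#' @examples
#' hypergeom_test(letters[1:5], letters[1:5], letters[1:10])  # 1 / choose(10, 5)
#' @export
hypergeom_test <- function(query, term, universe) {
  if (length(universe) == 0) abort("`universe` must be non-empty.")
  universe <- unique(universe)
  query <- intersect(unique(query), universe)
  term <- intersect(unique(term), universe)
  k <- length(intersect(query, term))
  phyper(k - 1, length(term), length(universe) - length(term),
         length(query), lower.tail = FALSE)
}

#' Bonferroni step-down (Holm) adjustment
#'
#' Sequentially rejective family-wise error correction: with p-values
#' sorted ascending, `adj_i = max_{j <= i} min(1, (m - j + 1) * p_(j))`.
#' Implemented via [stats::p.adjust()].
#'
#' @param pvalues Numeric vector in \[0, 1\].
#' @return Adjusted p-values in the original order.
#' @export
bonferroni_step_down <- function(pvalues) {
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1)) {
    abort("All p-values must lie in [0, 1].")
  }
  p.adjust(pvalues, method = "holm")
}

#' Over-representation analysis of a query against a gene-set collection
#'
#' Computes, per term, the overlap with the query, the attribution
#' (overlap / term size), the one-sided hypergeometric p-value and its
#' Bonferroni step-down adjustment.
#'
#' @param query Character vector of query gene ids.
#' @param genesets A [simulate_genesets()] object or a named list of
#'   member-gene vectors.
#' @param universe Universe gene ids; defaults to the collection's universe
#'   (or the union of all term members for a bare list).
#' @return Tibble with `term_id`, `term_name`, `term_size`, `overlap`,
#'   `overlap_genes` (list column), `attribution`, `pvalue`, `padj`,
#'   ordered by `pvalue` then `term_id`.
#' @export
enrich_terms <- function(query, genesets, universe = NULL) {
  if (inherits(genesets, "mmint_genesets")) {
    sets <- genesets$sets
    info <- genesets$info
    if (is.null(universe)) universe <- genesets$universe
  } else {
    sets <- genesets
    if (is.null(names(sets))) abort("`genesets` must be named.")
    info <- tibble(term_id = names(sets), term_name = names(sets))
    if (is.null(universe)) universe <- unique(unlist(sets))
  }
  if (length(sets) == 0) {
    return(tibble(term_id = character(), term_name = character(),
                  term_size = integer(), overlap = integer(),
                  overlap_genes = list(), attribution = double(),
                  pvalue = double(), padj = double()))
  }
  universe <- unique(universe)
  query <- intersect(unique(query), universe)

  rows <- purrr::map2(names(sets), sets, function(id, members) {
    members <- intersect(unique(members), universe)
    ov <- intersect(query, members)
    tibble(
      term_id = id,
      term_size = length(members),
      overlap = length(ov),
      overlap_genes = list(sort(ov)),
      attribution = if (length(members) > 0) length(ov) / length(members)
                    else 0,
      pvalue = hypergeom_test(query, members, universe)
    )
  })
  bind_rows(rows) %>%
    mutate(padj = bonferroni_step_down(.data$pvalue)) %>%
    left_join(info, by = "term_id") %>%
    dplyr::select("term_id", "term_name", "term_size", "overlap",
                  "overlap_genes", "attribution", "pvalue", "padj") %>%
    arrange(.data$pvalue, .data$term_id)
}

#' Select enriched terms by overlap, attribution and adjusted p
#'
#' Keeps terms with at least `min_genes` query genes, attribution of at
#' least `min_attribution`, and adjusted p-value at most `alpha` — all
#' boundaries inclusive.
#'
#' @param terms An [enrich_terms()] tibble.
#' @param min_genes Minimum overlap (default 3).
#' @param min_attribution Minimum overlap / term-size fraction (default
#'   0.04).
#' @param alpha Maximum adjusted p-value (default 0.05).
#' @return The filtered tibble.
#' @export
select_terms <- function(terms, min_genes = 3, min_attribution = 0.04,
                         alpha = 0.05) {
  terms %>%
    filter(.data$overlap >= min_genes,
           .data$attribution >= min_attribution,
           .data$padj <= alpha)
}

#' Cohen's kappa similarity between enriched terms
#'
#' For every pair of terms, binary membership vectors are formed over a
#' reference gene set (by default the union of the selected terms' overlap
#' genes) and Cohen's kappa is computed from the 2x2 contingency table:
#' `kappa = (p_o - p_e) / (1 - p_e)` with observed agreement `p_o` and
#' chance agreement `p_e` from the margins. The diagonal is 1. When
#' `p_e = 1` (both margins degenerate) kappa is defined as 1 for identical
#' memberships and 0 otherwise.
#'
#' @param terms An [enrich_terms()]/[select_terms()] tibble with an
#'   `overlap_genes` list column.
#' @param reference_genes Reference gene set; defaults to the union of
#'   `overlap_genes`.
#' @return A symmetric matrix with term ids as dimnames.
#' @export
kappa_matrix <- function(terms, reference_genes = NULL) {
  if (nrow(terms) < 2) {
    k <- diag(nrow(terms))
    dimnames(k) <- list(terms$term_id, terms$term_id)
    return(k)
  }
  if (is.null(reference_genes)) {
    reference_genes <- sort(unique(unlist(terms$overlap_genes)))
  }
  n_ref <- length(reference_genes)
  memb <- vapply(terms$overlap_genes,
                 function(g) reference_genes %in% g,
                 logical(n_ref))
  if (n_ref == 1) memb <- matrix(memb, nrow = 1)
  m <- nrow(terms)
  k <- diag(1, m)
  for (i in seq_len(m - 1)) {
    for (j in seq(i + 1, m)) {
      k[i, j] <- k[j, i] <- .cohen_kappa(memb[, i], memb[, j])
    }
  }
  dimnames(k) <- list(terms$term_id, terms$term_id)
  k
}

.cohen_kappa <- function(x, y) {
  n <- length(x)
  if (n == 0) return(0)
  a <- sum(x & y)
  b <- sum(x & !y)
  c_ <- sum(!x & y)
  d <- sum(!x & !y)
  p_o <- (a + d) / n
  p_e <- ((a + b) * (a + c_) + (c_ + d) * (b + d)) / n^2
  if (1 - p_e < .Machine$double.eps) {
    return(if (all(x == y)) 1 else 0)
  }
  (p_o - p_e) / (1 - p_e)
}

#' Group enriched terms by kappa connectivity
#'
#' Builds a term graph with an edge wherever off-diagonal kappa reaches the
#' threshold and takes connected components as groups. Each group's leading
#' term is its minimum-p member (ties broken by lexicographic term id).
#'
#' @param terms A selected-terms tibble (needs `term_id`, `pvalue`).
#' @param kappa Symmetric kappa matrix over the same terms.
#' @param threshold Minimum kappa for an edge (default 0.04, inclusive).
#' @return A list with `membership` (tibble `term_id`, `group_id`,
#'   `is_leading`) and `groups` (tibble `group_id`, `n_terms`,
#'   `leading_term_id`, `leading_pvalue`).
#' @export
group_terms <- function(terms, kappa, threshold = 0.04) {
  stopifnot(nrow(terms) == nrow(kappa))
  if (nrow(terms) == 0) {
    return(list(
      membership = tibble(term_id = character(), group_id = integer(),
                          is_leading = logical()),
      groups = tibble(group_id = integer(), n_terms = integer(),
                      leading_term_id = character(),
                      leading_pvalue = double())
    ))
  }
  adj <- kappa >= threshold
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  membership <- tibble(term_id = terms$term_id,
                       pvalue = terms$pvalue,
                       group_id = as.integer(comp)) %>%
    group_by(.data$group_id) %>%
    mutate(is_leading = dplyr::row_number() ==
             order(.data$pvalue, .data$term_id)[1]) %>%
    ungroup()
  groups <- membership %>%
    group_by(.data$group_id) %>%
    summarise(n_terms = n(),
              leading_term_id = .data$term_id[.data$is_leading],
              leading_pvalue = .data$pvalue[.data$is_leading],
              .groups = "drop")
  list(membership = dplyr::select(membership, "term_id", "group_id",
                                  "is_leading"),
       groups = groups)
}

#' Full enrichment stage
#'
#' Chains [enrich_terms()], [select_terms()], [kappa_matrix()] and
#' [group_terms()] into one call.
#'
#' @inheritParams enrich_terms
#' @inheritParams select_terms
#' @param kappa_threshold Kappa connectivity threshold (default 0.04).
#' @param kappa_reference `"overlap_union"` (default) builds kappa
#'   membership vectors over the union of selected terms' overlap genes;
#'   `"universe"` uses the whole universe.
#' @return An object of class `mmint_enrichment`: the selected-terms tibble
#'   with `group_id` and `is_leading` columns; the kappa matrix and group
#'   table are attached as attributes `kappa` and `groups`.
#' @export
run_enrichment <- function(query, genesets, universe = NULL, min_genes = 3,
                           min_attribution = 0.04, alpha = 0.05,
                           kappa_threshold = 0.04,
                           kappa_reference = c("overlap_union", "universe")) {
  kappa_reference <- match.arg(kappa_reference)
  all_terms <- enrich_terms(query, genesets, universe)
  sel <- select_terms(all_terms, min_genes, min_attribution, alpha)
  ref <- if (kappa_reference == "universe") {
    if (inherits(genesets, "mmint_genesets")) genesets$universe else universe
  } else NULL
  kap <- kappa_matrix(sel, reference_genes = ref)
  grouping <- group_terms(sel, kap, kappa_threshold)
  out <- sel %>%
    left_join(grouping$membership, by = "term_id") %>%
    arrange(.data$group_id, .data$pvalue, .data$term_id)
  structure(out,
            class = c("mmint_enrichment", class(out)),
            kappa = kap,
            groups = grouping$groups,
            n_tested = nrow(all_terms))
}

#' @method tidy mmint_enrichment
#' @export
tidy.mmint_enrichment <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "mmint_enrichment")
  attr(out, "kappa") <- NULL
  attr(out, "groups") <- NULL
  attr(out, "n_tested") <- NULL
  as_tibble(out)
}

#' @method glance mmint_enrichment
#' @export
glance.mmint_enrichment <- function(x, ...) {
  tibble(n_tested = attr(x, "n_tested"),
         n_selected = nrow(x),
         n_groups = nrow(attr(x, "groups")))
}

#' Dot plot of enriched terms by group
#'
#' @param object A [run_enrichment()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot mmint_enrichment
#' @export
autoplot.mmint_enrichment <- function(object, ...) {
  df <- tidy(object)
  if (nrow(df) == 0) {
    return(ggplot2::ggplot() + ggplot2::theme_void() +
             ggplot2::labs(title = "No enriched terms"))
  }
  df$term_name <- factor(df$term_name,
                         levels = rev(df$term_name[order(df$pvalue)]))
  ggplot2::ggplot(df, ggplot2::aes(-log10(.data$padj), .data$term_name,
                                   size = .data$overlap,
                                   colour = factor(.data$group_id),
                                   shape = .data$is_leading)) +
    ggplot2::geom_point() +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 17, `FALSE` = 16)) +
    ggplot2::labs(x = expression(-log[10] ~ "adjusted p"), y = NULL,
                  colour = "group", shape = "leading term",
                  size = "overlap") +
    ggplot2::theme_minimal()
}
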