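#' Plant a ground-truth regulatory structure
#'
#' Creates the ground truth for a two-condition (control vs metformin-like
#' treatment) simulation: a set of miRNA -> target-gene repressions with
#' anti-correlated planted log2 fold changes, plus per-feature baseline
#' means and negative binomial dispersions.
#'
#' Regulated miRNAs receive a planted log2 fold change of
#' `+lfc_magnitude` or `-lfc_magnitude` (sign chosen at random per miRNA);
#' each of their target genes receives the opposite sign, so every planted
#' pair is anti-correlated by construction. Every regulated gene is assigned
#' to exactly one regulating miRNA (a miRNA may target several genes); this
#' guarantees a single consistent planted direction per gene. All other
#' features have a log2 fold change of zero.
#'
#' @param n_mirna,n_gene Number of miRNA and mRNA features.
#' @param n_pairs Number of planted miRNA -> gene repressions. Must not
#'   exceed `n_gene` (one regulator per target gene) nor `n_mirna * n_gene`.
#' @param lfc_magnitude Absolute planted log2 fold change (default 1.5).
#' @param mirna_base_range,gene_base_range Ranges for the log-uniform draw
#'   of expected control-condition counts.
#' @param dispersion Negative binomial dispersion alpha (variance =
#'   mu + alpha * mu^2). Either a single value applied to every feature or a
#'   length-2 range for a per-feature log-uniform draw.
#' @param seed Integer seed; the same seed reproduces the truth exactly.
#'
#' @return An object of class `mmint_truth`: a list with
#'   \describe{
#'     \item{features}{tibble with `feature_id`, `type` ("miRNA"/"gene"),
#'       `base_mean`, `dispersion`, `lfc`.}
#'     \item{pairs}{tibble of planted pairs with `mirna_id`, `gene_id`.}
#'     \item{seed}{the seed used.}
#'   }
#' @examples
#' truth <- simulate_ground_truth(20, 100, n_pairs = 5, seed = 1)
#' truth$pairs
#' @export
simulate_ground_truth <- function(n_mirna, n_gene, n_pairs,
                                  lfc_magnitude = 1.5,
                                  mirna_base_range = c(100, 5000),
                                  gene_base_range = c(50, 2000),
                                  dispersion = 0.05,
                                  seed = 1L) {
  .check_scalar_number(n_mirna, "n_mirna", lower = 1)
  .check_scalar_number(n_gene, "n_gene", lower = 1)
  .check_scalar_number(n_pairs, "n_pairs", lower = 0)
  .check_scalar_number(lfc_magnitude, "lfc_magnitude")
  if (lfc_magnitude <= 0) abort("`lfc_magnitude` must be positive.")
  if (n_pairs > n_mirna * n_gene || n_pairs > n_gene) {
    abort(paste0("Impossible pair count: `n_pairs` must be <= n_gene (one ",
                 "regulator per target gene) and <= n_mirna * n_gene."))
  }
  if (!length(dispersion) %in% c(1, 2) || any(dispersion <= 0)) {
    abort("`dispersion` must be a positive scalar or a length-2 positive range.")
  }

  mirna_ids <- sprintf("miR-%04d", seq_len(n_mirna))
  gene_ids <- sprintf("GENE%05d", seq_len(n_gene))

  .with_seed(seed, {
    draw_log_unif <- function(n, range) {
      exp(runif(n, log(range[1]), log(range[2])))
    }
    base_mean <- c(draw_log_unif(n_mirna, mirna_base_range),
                   draw_log_unif(n_gene, gene_base_range))
    disp <- if (length(dispersion) == 1) {
      rep(dispersion, n_mirna + n_gene)
    } else {
      draw_log_unif(n_mirna + n_gene, sort(dispersion))
    }

    lfc <- setNames(rep(0, n_mirna + n_gene), c(mirna_ids, gene_ids))
    pairs <- tibble(mirna_id = character(), gene_id = character())
    if (n_pairs > 0) {
      target_genes <- sample(gene_ids, n_pairs)
      regulators <- sample(mirna_ids, n_pairs, replace = n_pairs > n_mirna)
      reg_mirnas <- unique(regulators)
      signs <- setNames(sample(c(-1, 1), length(reg_mirnas), replace = TRUE),
                        reg_mirnas)
      lfc[reg_mirnas] <- signs[reg_mirnas] * lfc_magnitude
      lfc[target_genes] <- -signs[regulators] * lfc_magnitude
      pairs <- tibble(mirna_id = regulators, gene_id = target_genes) %>%
        arrange(.data$mirna_id, .data$gene_id)
    }

    structure(
      list(
        features = tibble(
          feature_id = c(mirna_ids, gene_ids),
          type = rep(c("miRNA", "gene"), c(n_mirna, n_gene)),
          base_mean = base_mean,
          dispersion = disp,
          lfc = unname(lfc)
        ),
        pairs = pairs,
        seed = .check_seed(seed)
      ),
      class = "mmint_truth"
    )
  })
}

#' @export
print.mmint_truth <- function(x, ...) {
  n_reg <- sum(x$features$lfc != 0)
  cat("<mmint_truth>\n")
  cat("  features:", nrow(x$features),
      sprintf("(%d miRNA, %d gene)", sum(x$features$type == "miRNA"),
              sum(x$features$type == "gene")), "\n")
  cat("  planted pairs:", nrow(x$pairs),
      sprintf("(%d regulated features)", n_reg), "\n")
  cat("  seed:", x$seed, "\n")
  invisible(x)
}

#' Simulate paired miRNA and mRNA count matrices
#'
#' Draws negative binomial counts for both molecule classes under a
#' two-condition design. For feature i in sample j the mean is
#' `s_j * q_i * 2^(lfc_i * [j treated])` with `q_i` the planted baseline
#' mean and `s_j` a per-sample library scaling composed of a log-uniform
#' library factor (exercising normalisation) and a global scale that sets
#' the expected library size. Variance is `mu + alpha * mu^2`.
#'
#' @param truth A [simulate_ground_truth()] object.
#' @param n_rep Replicates per condition (>= 2).
#' @param mean_libsize Expected total counts per sample in each matrix.
#' @param libsize_range Range of the per-sample log-uniform library factor.
#' @param seed Integer seed.
#'
#' @return A list of class `mmint_sim_counts` with `mirna` and `mrna` count
#'   tibbles (`feature_id` + one column per sample), a `conditions` tibble
#'   (`sample_id`, `condition`), and `lib_factors`, the planted per-sample
#'   factors (tibble: `matrix`, `sample_id`, `factor`) rescaled to geometric
#'   mean 1 for comparison with estimated size factors.
#' @export
simulate_counts <- function(truth, n_rep = 3, mean_libsize = 1e6,
                            libsize_range = c(0.5, 2), seed = 1L) {
  stopifnot(inherits(truth, "mmint_truth"))
  .check_scalar_number(n_rep, "n_rep", lower = 2)
  .check_scalar_number(mean_libsize, "mean_libsize", lower = 1)

  sample_ids <- c(sprintf("control_%d", seq_len(n_rep)),
                  sprintf("treated_%d", seq_len(n_rep)))
  treated <- rep(c(0, 1), each = n_rep)

  .with_seed(seed, {
    sim_one <- function(feat) {
      q <- feat$base_mean
      alpha <- feat$dispersion
      lfc <- feat$lfc
      f <- exp(runif(2 * n_rep, log(libsize_range[1]), log(libsize_range[2])))
      f <- f / exp(mean(log(f)))  # geometric mean 1
      scale <- mean_libsize / sum(q)
      mu <- outer(q, f * scale) * 2^(outer(lfc, treated))
      counts <- matrix(
        rnbinom(length(mu), mu = as.vector(mu),
                size = 1 / pmax(rep(alpha, 2 * n_rep), 1e-12)),
        nrow = nrow(mu), dimnames = list(feat$feature_id, sample_ids)
      )
      list(counts = as_tibble(counts, rownames = "feature_id"), factors = f)
    }
    mi <- sim_one(truth$features[truth$features$type == "miRNA", ])
    mr <- sim_one(truth$features[truth$features$type == "gene", ])
    structure(
      list(
        mirna = mi$counts,
        mrna = mr$counts,
        conditions = tibble(
          sample_id = sample_ids,
          condition = rep(c("control", "treated"), each = n_rep)
        ),
        lib_factors = tibble(
          matrix = rep(c("mirna", "mrna"), each = 2 * n_rep),
          sample_id = rep(sample_ids, 2),
          factor = c(mi$factors, mr$factors)
        )
      ),
      class = "mmint_sim_counts"
    )
  })
}

#' Simulate a multi-resource target-prediction table
#'
#' Emits prediction records for a set of resources. Each planted pair is
#' reported by each resource with probability `sensitivity` and, for
#' score-based resources, receives a score drawn inside that resource's
#' passing range. False (unplanted) pairs are emitted independently at rate
#' `fp_rate` per (resource, possible pair) with scores drawn over the
#' resource's full plausible range, so they straddle the threshold and only
#' some survive threshold filtering. A fraction of true-pair records is
#' flagged as experimentally validated.
#'
#' @param truth A [simulate_ground_truth()] object.
#' @param sources Character vector of resource names; must appear in
#'   [source_registry()]. Defaults to three score-based resources.
#' @param sensitivity Per-resource probability of reporting a true pair.
#' @param fp_rate Per-(resource, possible-pair) false-positive rate.
#' @param validated_fraction Fraction of true-pair records flagged validated.
#' @param seed Integer seed.
#'
#' @return A tibble with columns `source`, `mirna_id`, `gene_id`, `score`
#'   (NA for validation-only resources), `validated`.
#' @export
simulate_predictions <- function(truth,
                                 sources = c("TargetScan", "miRDB", "miRmap"),
                                 sensitivity = 0.9, fp_rate = 0.002,
                                 validated_fraction = 0.1, seed = 1L) {
  stopifnot(inherits(truth, "mmint_truth"))
  .check_scalar_number(sensitivity, "sensitivity", 0, 1)
  .check_scalar_number(fp_rate, "fp_rate", 0, 1)
  .check_scalar_number(validated_fraction, "validated_fraction", 0, 1)
  registry <- source_registry()
  unknown <- setdiff(sources, registry$source)
  if (length(unknown) > 0) {
    abort(paste0("Unknown prediction source(s): ",
                 paste(unknown, collapse = ", ")))
  }

  mirna_ids <- truth$features$feature_id[truth$features$type == "miRNA"]
  gene_ids <- truth$features$feature_id[truth$features$type == "gene"]
  n_m <- length(mirna_ids)
  n_g <- length(gene_ids)
  true_idx <- (match(truth$pairs$mirna_id, mirna_ids) - 1) * n_g +
    match(truth$pairs$gene_id, gene_ids)

  .with_seed(seed, {
    out <- lapply(sources, function(src) {
      cfg <- registry[registry$source == src, ]
      # true pairs
      keep <- runif(nrow(truth$pairs)) < sensitivity
      tp <- truth$pairs[keep, , drop = FALSE]
      tp_score <- if (cfg$kind == "predicted") {
        runif(nrow(tp), cfg$pass_lo, cfg$pass_hi)
      } else {
        rep(NA_real_, nrow(tp))
      }
      # false pairs: binomial count over the non-planted grid
      n_false_possible <- n_m * n_g - length(true_idx)
      n_fp <- rbinom(1, n_false_possible, fp_rate)
      fp_idx <- integer(0)
      if (n_fp > 0) {
        cand <- sample.int(n_m * n_g, min(n_m * n_g, n_fp + length(true_idx)))
        fp_idx <- setdiff(cand, true_idx)[seq_len(n_fp)]
      }
      fp_score <- if (cfg$kind == "predicted") {
        runif(length(fp_idx), cfg$score_lo, cfg$score_hi)
      } else {
        rep(NA_real_, length(fp_idx))
      }
      tibble(
        source = src,
        mirna_id = c(tp$mirna_id, mirna_ids[(fp_idx - 1) %/% n_g + 1]),
        gene_id = c(tp$gene_id, gene_ids[(fp_idx - 1) %% n_g + 1]),
        score = c(tp_score, fp_score),
        validated = c(runif(nrow(tp)) < validated_fraction,
                      rep(FALSE, length(fp_idx)))
      )
    })
    bind_rows(out) %>% arrange(.data$source, .data$mirna_id, .data$gene_id)
  })
}

#' Simulate a random protein-protein interaction network
#'
#' Erdos-Renyi graph over the given genes with edge probability
#' `mean_degree / (n - 1)`, i.e. expected degree `mean_degree`. The result
#' is a simple undirected graph: no self-loops, no duplicate edges, each
#' edge stored once with `gene_a < gene_b` lexicographically.
#'
#' @param gene_ids Character vector of node ids.
#' @param mean_degree Expected node degree; must be < `length(gene_ids) - 1`.
#' @param seed Integer seed.
#' @return A tibble with columns `gene_a`, `gene_b`.
#' @export
simulate_ppi <- function(gene_ids, mean_degree = 4, seed = 1L) {
  n <- length(gene_ids)
  if (n < 2) abort("Need at least 2 genes for a PPI graph.")
  .check_scalar_number(mean_degree, "mean_degree", lower = 0)
  if (mean_degree >= n - 1) abort("`mean_degree` must be < n_genes - 1.")

  .with_seed(seed, {
    m_possible <- n * (n - 1) / 2
    p <- mean_degree / (n - 1)
    n_edges <- rbinom(1, m_possible, p)
    if (n_edges == 0) {
      return(tibble(gene_a = character(), gene_b = character()))
    }
    idx <- sort(sample.int(m_possible, n_edges))
    # map linear index over the upper triangle (row-major, i < j) to (i, j)
    i <- ceiling((2 * n - 1 - sqrt((2 * n - 1)^2 - 8 * idx)) / 2)
    j <- idx - (i - 1) * n + i * (i - 1) / 2 + i
    a <- gene_ids[i]
    b <- gene_ids[j]
    tibble(gene_a = pmin(a, b), gene_b = pmax(a, b)) %>%
      arrange(.data$gene_a, .data$gene_b)
  })
}

#' Simulate a gene-set collection, optionally with one planted enriched term
#'
#' Random terms are drawn by sampling member genes without replacement from
#' the universe. If `planted_genes` is supplied, the first term is seeded
#' with `planted_fraction` of those genes (plus random fillers), so a query
#' containing `planted_genes` is detectably over-represented in that term.
#'
#' @param gene_ids Universe of gene ids.
#' @param n_terms Number of terms.
#' @param term_size_range Inclusive range of term sizes.
#' @param planted_genes Optional character vector of genes to plant.
#' @param planted_fraction Fraction of `planted_genes` placed in the planted
#'   term (default 0.8).
#' @param seed Integer seed.
#'
#' @return An object of class `mmint_genesets`: list with `sets` (named list
#'   term_id -> member genes), `info` (tibble `term_id`, `term_name`),
#'   `universe`, and `planted_term_id` (NA if nothing planted).
#' @export
simulate_genesets <- function(gene_ids, n_terms = 50,
                              term_size_range = c(10, 200),
                              planted_genes = NULL, planted_fraction = 0.8,
                              seed = 1L) {
  .check_scalar_number(n_terms, "n_terms", lower = 0)
  if (max(term_size_range) > length(gene_ids)) {
    abort("Term sizes cannot exceed the universe size.")
  }
  if (!is.null(planted_genes) && !all(planted_genes %in% gene_ids)) {
    abort("All `planted_genes` must be in `gene_ids`.")
  }

  .with_seed(seed, {
    term_ids <- sprintf("T%04d", seq_len(n_terms))
    sizes <- if (n_terms > 0) {
      sample(seq(term_size_range[1], term_size_range[2]), n_terms,
             replace = TRUE)
    } else integer(0)
    sets <- lapply(sizes, function(k) sample(gene_ids, k))
    names(sets) <- term_ids
    planted_id <- NA_character_
    if (!is.null(planted_genes) && n_terms > 0) {
      planted_id <- term_ids[1]
      core <- sample(planted_genes,
                     ceiling(planted_fraction * length(planted_genes)))
      fill_n <- max(0, sizes[1] - length(core))
      fill <- sample(setdiff(gene_ids, core), fill_n)
      sets[[1]] <- c(core, fill)
    }
    structure(
      list(
        sets = sets,
        info = tibble(term_id = term_ids,
                      term_name = sprintf("Pathway %02d", seq_len(n_terms))),
        universe = gene_ids,
        planted_term_id = planted_id
      ),
      class = "mmint_genesets"
    )
  })
}

#' @export
print.mmint_genesets <- function(x, ...) {
  cat("<mmint_genesets>\n")
  cat("  terms:", length(x$sets), " universe:", length(x$universe), "genes\n")
  if (!is.na(x$planted_term_id)) cat("  planted term:", x$planted_term_id, "\n")
  invisible(x)
}
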