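#' Median-of-ratios size factors
#'
#' Per-sample normalisation factors computed by the median-of-ratios method:
#' for each feature with no zero count, a pseudo-reference is formed as the
#' geometric mean across samples; each sample's factor is the median over
#' those features of count / pseudo-reference. Factors are rescaled so their
#' geometric mean is exactly 1, making normalised counts comparable across
#' re-analyses that add or drop samples.
#'
#' @param counts Count tibble: `feature_id` column plus one numeric column
#'   per sample.
#' @return A tibble with `sample_id` and `size_factor`.
#' @examples
#' counts <- tibble::tibble(feature_id = paste0("g", 1:5),
#'                          s1 = c(10, 20, 30, 40, 50),
#'                          s2 = c(20, 40, 60, 80, 100))
#' size_factors(counts)
#' @export
size_factors <- function(counts) {
  m <- .count_matrix(counts)
  sf <- .size_factor_vector(m)
  tibble(sample_id = names(sf), size_factor = unname(sf))
}

.size_factor_vector <- function(m) {
  usable <- rowSums(m > 0) == ncol(m)
  if (!any(usable)) {
    abort(paste0(
      "Size-factor estimation needs at least one feature with positive ",
      "counts in every sample. Consider filtering samples with empty ",
      "libraries or supplying deeper data."))
  }
  log_geo <- rowMeans(log(m[usable, , drop = FALSE]))
  sf <- apply(m[usable, , drop = FALSE], 2, function(col) {
    exp(median(log(col) - log_geo))
  })
  sf <- sf / exp(mean(log(sf)))
  sf
}

#' Moderated moment estimates of negative binomial dispersion
#'
#' Per feature, the raw estimate is the method-of-moments value
#' `max(alpha_floor, (v - m) / m^2)` where `m` and `v` are the mean and the
#' pooled within-condition variance of size-factor-normalised counts. With
#' few replicates this raw estimate is extremely noisy (roughly 4 residual
#' degrees of freedom in a 3 vs 3 design), which makes a downstream Wald
#' test with a normal reference anti-conservative. The default therefore
#' moderates each raw estimate toward a bias-corrected central dispersion
#' shared across features, weighting the feature's own residual degrees of
#' freedom against `prior_df` pseudo-observations, in the spirit of the
#' empirical-Bayes shrinkage used by mainstream RNA-seq engines.
#'
#' The central dispersion solves the moment identities
#' `E[v - m] = alpha * mu^2` and `E[m^2 - v * (1/n_c + 1/n_t) / 4] = mu^2`
#' summed over features, which removes the upward ratio bias of the naive
#' per-feature plug-in.
#'
#' @param counts Count tibble (`feature_id` + sample columns).
#' @param conditions Tibble with `sample_id`, `condition` (control/treated),
#'   each condition with >= 2 samples.
#' @param sf Optional size-factor tibble from [size_factors()]; computed if
#'   omitted.
#' @param alpha_floor Lower bound for every estimate (default 1e-8).
#' @param prior_df Pseudo-observations for moderation (default 20). Set
#'   `moderate = FALSE` for the raw per-feature estimator.
#' @param moderate Apply moderation toward the central dispersion?
#' @return Tibble with `feature_id`, `dispersion_raw`, `dispersion`.
#' @export
estimate_dispersion <- function(counts, conditions, sf = NULL,
                                alpha_floor = 1e-8, prior_df = 20,
                                moderate = TRUE) {
  m <- .count_matrix(counts)
  cond <- .condition_vector(conditions, colnames(m))
  if (is.null(sf)) sf <- size_factors(counts)
  sfv <- setNames(sf$size_factor, sf$sample_id)[colnames(m)]
  norm <- sweep(m, 2, sfv, "/")

  grp <- split(seq_len(ncol(norm)), cond)
  n_c <- length(grp$control)
  n_t <- length(grp$treated)
  mean_c <- rowMeans(norm[, grp$control, drop = FALSE])
  mean_t <- rowMeans(norm[, grp$treated, drop = FALSE])
  var_c <- apply(norm[, grp$control, drop = FALSE], 1, var)
  var_t <- apply(norm[, grp$treated, drop = FALSE], 1, var)
  # pooled within-condition variance (weighted by residual df)
  v <- ((n_c - 1) * var_c + (n_t - 1) * var_t) / (n_c + n_t - 2)
  mu <- (mean_c + mean_t) / 2

  raw <- pmax(alpha_floor, ifelse(mu > 0, (v - mu) / mu^2, alpha_floor))

  if (moderate && nrow(m) >= 2) {
    num <- v - mu
    den <- mu^2 - v * (1 / n_c + 1 / n_t) / 4
    ok <- is.finite(num) & is.finite(den) & mu > 0
    central <- max(alpha_floor, sum(num[ok]) / max(sum(pmax(den[ok], 0)), 1))
    d <- n_c + n_t - 2
    alpha <- pmax(alpha_floor,
                  (d * raw + prior_df * central) / (d + prior_df))
  } else {
    alpha <- raw
  }

  tibble(feature_id = rownames(m), dispersion_raw = unname(raw),
         dispersion = unname(alpha))
}

#' Negative binomial Wald test for a two-condition design
#'
#' For each feature the treated/control log2 fold change is
#' `log2((q_t + c) / (q_c + c))` with pseudo-count `c` on the normalised
#' condition means. The Wald statistic divides the natural-log ratio by the
#' delta-method standard error of the log difference of negative binomial
#' means, `Var(q_g) = (1/n_g^2) * sum_j (q_g / s_j + alpha * q_g^2)`, and
#' the two-sided p-value is taken from the standard normal reference.
#' All-zero features are reported with `log2fc = 0`, `pvalue = 1`.
#'
#' Also reports, per feature, the total raw count over all samples and the
#' condition-mean reads-per-million in each condition (computed on raw
#' library sizes), which downstream filters consume.
#'
#' @inheritParams estimate_dispersion
#' @param dispersions Optional dispersion tibble from
#'   [estimate_dispersion()]; computed if omitted.
#' @param pseudo_count Pseudo-count added to normalised condition means in
#'   the fold-change ratio (default 0.5).
#' @return Tibble with `feature_id`, `base_mean`, `log2fc`, `stat`,
#'   `pvalue`, `total_raw_count`, `rpm_control`, `rpm_treated`.
#' @export
nb_wald_test <- function(counts, conditions, sf = NULL, dispersions = NULL,
                         pseudo_count = 0.5) {
  m <- .count_matrix(counts)
  cond <- .condition_vector(conditions, colnames(m))
  if (is.null(sf)) sf <- size_factors(counts)
  sfv <- setNames(sf$size_factor, sf$sample_id)[colnames(m)]
  if (is.null(dispersions)) {
    dispersions <- estimate_dispersion(counts, conditions, sf)
  }
  alpha <- setNames(dispersions$dispersion,
                    dispersions$feature_id)[rownames(m)]
  norm <- sweep(m, 2, sfv, "/")

  grp <- split(seq_len(ncol(norm)), cond)
  q_c <- rowMeans(norm[, grp$control, drop = FALSE])
  q_t <- rowMeans(norm[, grp$treated, drop = FALSE])
  n_c <- length(grp$control)
  n_t <- length(grp$treated)

  var_group <- function(q, idx) {
    shot <- outer(q, 1 / sfv[idx])  # q / s_j per sample
    (rowSums(shot) + length(idx) * alpha * q^2) / length(idx)^2
  }
  v_c <- var_group(q_c, grp$control)
  v_t <- var_group(q_t, grp$treated)

  log2fc <- log2((q_t + pseudo_count) / (q_c + pseudo_count))
  se2 <- v_c / (q_c + pseudo_count)^2 + v_t / (q_t + pseudo_count)^2
  stat <- ifelse(se2 > 0,
                 log((q_t + pseudo_count) / (q_c + pseudo_count)) / sqrt(se2),
                 0)
  pvalue <- 2 * pnorm(-abs(stat))

  all_zero <- rowSums(m) == 0
  log2fc[all_zero] <- 0
  stat[all_zero] <- 0
  pvalue[all_zero] <- 1

  libsize <- colSums(m)
  if (any(libsize == 0)) {
    abort("Sample(s) with zero library size; RPM is undefined.")
  }
  rpm <- sweep(m, 2, libsize / 1e6, "/")
  rpm_c <- rowMeans(rpm[, grp$control, drop = FALSE])
  rpm_t <- rowMeans(rpm[, grp$treated, drop = FALSE])

  tibble(
    feature_id = rownames(m),
    base_mean = unname(rowMeans(norm)),
    log2fc = unname(log2fc),
    stat = unname(stat),
    pvalue = unname(pvalue),
    total_raw_count = unname(rowSums(m)),
    rpm_control = unname(rpm_c),
    rpm_treated = unname(rpm_t)
  )
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement, as
#' implemented by [stats::p.adjust()]. Input p-values are validated to lie
#' in \[0, 1\].
#'
#' @param pvalues Numeric vector of p-values.
#' @param method Only `"BH"` is supported.
#' @return Numeric vector of adjusted p-values.
#' @export
adjust_pvalues <- function(pvalues, method = "BH") {
  method <- match.arg(method, "BH")
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1)) {
    abort("All p-values must lie in [0, 1].")
  }
  p.adjust(pvalues, method = method)
}

#' Full differential-expression analysis
#'
#' Runs [size_factors()], [estimate_dispersion()], [nb_wald_test()] and
#' [adjust_pvalues()] and annotates each feature with its direction under
#' the study filters: `up` / `down` when the feature passes
#' `total_raw_count >= min_total_count`, `padj <= max_padj` and
#' `|log2fc| >= min_abs_lfc` (all boundaries inclusive), otherwise `ns`.
#' Rows are ordered by `feature_id` for deterministic output.
#'
#' @inheritParams nb_wald_test
#' @param min_total_count Minimum total raw count over all samples.
#' @param max_padj Maximum BH-adjusted p-value.
#' @param min_abs_lfc Minimum absolute log2 fold change.
#' @param prior_df,moderate Passed to [estimate_dispersion()].
#' @return A tibble of class `mmint_de` with the [nb_wald_test()] columns
#'   plus `padj` and `direction`. The thresholds and size factors used are
#'   attached as attributes (`thresholds`, `size_factors`).
#' @examples
#' truth <- simulate_ground_truth(10, 50, 5, seed = 1)
#' sim <- simulate_counts(truth, n_rep = 3, seed = 2)
#' de <- de_analysis(sim$mrna, sim$conditions)
#' glance(de)
#' @export
de_analysis <- function(counts, conditions, min_total_count = 50,
                        max_padj = 0.05, min_abs_lfc = 1,
                        pseudo_count = 0.5, prior_df = 20, moderate = TRUE) {
  sf <- size_factors(counts)
  disp <- estimate_dispersion(counts, conditions, sf,
                              prior_df = prior_df, moderate = moderate)
  res <- nb_wald_test(counts, conditions, sf, disp,
                      pseudo_count = pseudo_count)
  res$padj <- adjust_pvalues(res$pvalue)
  res <- res %>%
    mutate(direction = dplyr::case_when(
      .data$total_raw_count >= min_total_count &
        .data$padj <= max_padj & .data$log2fc >= min_abs_lfc ~ "up",
      .data$total_raw_count >= min_total_count &
        .data$padj <= max_padj & .data$log2fc <= -min_abs_lfc ~ "down",
      TRUE ~ "ns"
    )) %>%
    arrange(.data$feature_id)
  structure(res,
            class = c("mmint_de", class(res)),
            thresholds = list(min_total_count = min_total_count,
                              max_padj = max_padj,
                              min_abs_lfc = min_abs_lfc),
            size_factors = sf)
}

#' Split a DE table by the study filters
#'
#' Applies the three inclusive predicates — total raw count, adjusted p and
#' absolute log2 fold change — and splits survivors by fold-change sign.
#'
#' @param records A DE tibble with `total_raw_count`, `padj`, `log2fc`.
#' @param min_total_count,max_padj,min_abs_lfc Filter thresholds.
#' @return A list with tibbles `up` and `down`.
#' @export
filter_de <- function(records, min_total_count = 50, max_padj = 0.05,
                      min_abs_lfc = 1) {
  stopifnot(all(c("total_raw_count", "padj", "log2fc") %in% names(records)))
  pass <- records$total_raw_count >= min_total_count &
    records$padj <= max_padj & abs(records$log2fc) >= min_abs_lfc
  kept <- as_tibble(records[pass, , drop = FALSE])
  list(up = kept[kept$log2fc > 0, , drop = FALSE],
       down = kept[kept$log2fc < 0, , drop = FALSE])
}

#' Reads-per-million floor
#'
#' RPM per sample is `count * 1e6 / library size` (raw column sum). A
#' feature is kept iff its condition-mean RPM reaches `threshold` in *both*
#' conditions; falling below the floor in either condition excludes it.
#'
#' @param counts Count tibble.
#' @param conditions Condition tibble.
#' @param threshold RPM floor (inclusive).
#' @return Character vector of kept feature ids.
#' @export
rpm_filter <- function(counts, conditions, threshold) {
  m <- .count_matrix(counts)
  cond <- .condition_vector(conditions, colnames(m))
  .check_scalar_number(threshold, "threshold", lower = 0)
  libsize <- colSums(m)
  if (any(libsize == 0)) {
    abort("Sample(s) with zero library size; RPM is undefined.")
  }
  rpm <- sweep(m, 2, libsize / 1e6, "/")
  rpm_c <- rowMeans(rpm[, cond == "control", drop = FALSE])
  rpm_t <- rowMeans(rpm[, cond == "treated", drop = FALSE])
  rownames(m)[rpm_c >= threshold & rpm_t >= threshold]
}

#' Cross-platform log2 fold-change concordance
#'
#' Pearson correlation of two log2 fold-change tables over their shared
#' features, as used to compare fold changes measured by two sequencing
#' platforms on the same contrast.
#'
#' @param lfc_a,lfc_b Data frames with `feature_id` and `log2fc`.
#' @return Pearson r (single number).
#' @export
concordance <- function(lfc_a, lfc_b) {
  for (x in list(lfc_a, lfc_b)) {
    stopifnot(is.data.frame(x), all(c("feature_id", "log2fc") %in% names(x)))
  }
  shared <- inner_join(
    dplyr::select(lfc_a, "feature_id", a = "log2fc"),
    dplyr::select(lfc_b, "feature_id", b = "log2fc"),
    by = "feature_id"
  ) %>%
    filter(is.finite(.data$a), is.finite(.data$b))
  if (nrow(shared) < 3) {
    abort("Concordance needs at least 3 shared features with finite values.")
  }
  cor(shared$a, shared$b)
}

#' @method tidy mmint_de
#' @export
tidy.mmint_de <- function(x, ...) {
  as_tibble(unclass_keep_tbl(x))
}

#' @method glance mmint_de
#' @export
glance.mmint_de <- function(x, ...) {
  thr <- attr(x, "thresholds")
  tibble(
    n_features = nrow(x),
    n_up = sum(x$direction == "up"),
    n_down = sum(x$direction == "down"),
    min_total_count = thr$min_total_count,
    max_padj = thr$max_padj,
    min_abs_lfc = thr$min_abs_lfc
  )
}

unclass_keep_tbl <- function(x) {
  class(x) <- setdiff(class(x), "mmint_de")
  attr(x, "thresholds") <- NULL
  attr(x, "size_factors") <- NULL
  x
}

#' Volcano plot of a DE result
#'
#' @param object A [de_analysis()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot mmint_de
#' @export
autoplot.mmint_de <- function(object, ...) {
  df <- tidy(object)
  df$direction <- factor(df$direction, levels = c("down", "ns", "up"))
  ggplot2::ggplot(df, ggplot2::aes(.data$log2fc, -log10(.data$padj),
                                   colour = .data$direction)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::scale_colour_manual(
      values = c(down = "#3366aa", ns = "grey70", up = "#aa3333"),
      drop = FALSE) +
    ggplot2::labs(x = "log2 fold change (treated vs control)",
                  y = expression(-log[10] ~ "adjusted p"),
                  colour = NULL) +
    ggplot2::theme_minimal()
}
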