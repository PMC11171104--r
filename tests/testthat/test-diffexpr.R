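test_that("size factors: symmetry, hand-computed doubling, permutation invariance", {
  same <- tibble::tibble(feature_id = paste0("g", 1:4),
                         a = c(5, 10, 20, 40), b = c(5, 10, 20, 40))
  expect_equal(size_factors(same)$size_factor, c(1, 1))

  # column B = 2 x column A: per-feature geometric mean is a * sqrt(2), so
  # every ratio is 1/sqrt(2) in A and sqrt(2) in B; the rescaled factors
  # are exactly (1/sqrt(2), sqrt(2)).
  doubled <- tibble::tibble(feature_id = paste0("g", 1:5),
                            a = c(10, 20, 30, 40, 50),
                            b = c(20, 40, 60, 80, 100))
  expect_equal(size_factors(doubled)$size_factor,
               c(1 / sqrt(2), sqrt(2)))

  perm <- doubled[c(3, 1, 5, 2, 4), ]
  expect_equal(size_factors(perm)$size_factor,
               size_factors(doubled)$size_factor)

  all_zero_rows <- tibble::tibble(feature_id = c("g1", "g2"),
                                  a = c(0, 5), b = c(3, 0))
  expect_error(size_factors(all_zero_rows), "positive counts")
})

test_that("size factors agree with DESeq2's median-of-ratios on random data", {
  skip_if_not_installed("DESeq2")
  set.seed(10)
  m <- matrix(rnbinom(200 * 6, mu = 200, size = 5), nrow = 200,
              dimnames = list(paste0("g", 1:200), paste0("s", 1:6)))
  counts <- tibble::as_tibble(m, rownames = "feature_id")
  ours <- size_factors(counts)$size_factor
  ref <- DESeq2::estimateSizeFactorsForMatrix(m)
  ref <- ref / exp(mean(log(ref)))
  expect_equal(ours, unname(ref), tolerance = 1e-8)
})

test_that("dispersion: zero-variance features hit the floor; estimates never fall below it", {
  const <- tibble::tibble(feature_id = paste0("g", 1:3),
                          c1 = c(10, 20, 30), c2 = c(10, 20, 30),
                          t1 = c(10, 20, 30), t2 = c(10, 20, 30))
  cond <- toy_conditions()
  raw <- estimate_dispersion(const, cond, moderate = FALSE)
  expect_equal(raw$dispersion, rep(1e-8, 3))
  mod <- estimate_dispersion(const, cond)
  expect_equal(mod$dispersion, rep(1e-8, 3))
  # on noisy data the floor still holds
  disp <- estimate_dispersion(toy_counts(), cond)
  expect_true(all(disp$dispersion >= 1e-8))
})

test_that("dispersion recovery: median estimate near the simulated truth", {
  truth <- simulate_ground_truth(5, 2000, 0, 1.5, dispersion = 0.1, seed = 61)
  sim <- simulate_counts(truth, n_rep = 10, seed = 62)
  disp <- estimate_dispersion(sim$mrna, sim$conditions)
  expect_gt(median(disp$dispersion), 0.05)
  expect_lt(median(disp$dispersion), 0.2)
  raw <- estimate_dispersion(sim$mrna, sim$conditions, moderate = FALSE)
  expect_gt(median(raw$dispersion_raw), 0.05)
  expect_lt(median(raw$dispersion_raw), 0.2)
})

test_that("Wald test: all-zero features are reported as null results", {
  counts <- tibble::tibble(feature_id = c("g1", "g2"),
                           c1 = c(0, 100), c2 = c(0, 110),
                           t1 = c(0, 95), t2 = c(0, 105))
  res <- nb_wald_test(counts, toy_conditions())
  expect_equal(res$log2fc[res$feature_id == "g1"], 0)
  expect_equal(res$pvalue[res$feature_id == "g1"], 1)
})

test_that("Wald test recovers a planted log2 fold change of 2", {
  set.seed(71)
  n_feat <- 200
  m <- cbind(
    matrix(rnbinom(n_feat * 3, mu = 500, size = 1 / 0.05), ncol = 3),
    matrix(rnbinom(n_feat * 3, mu = 2000, size = 1 / 0.05), ncol = 3)
  )
  counts <- tibble::as_tibble(
    `colnames<-`(m, c("c1", "c2", "c3", "t1", "t2", "t3"))) |>
    dplyr::mutate(feature_id = paste0("g", 1:n_feat), .before = 1)
  cond <- tibble::tibble(sample_id = c("c1", "c2", "c3", "t1", "t2", "t3"),
                         condition = rep(c("control", "treated"), each = 3))
  # libraries are equal by construction; with every feature shifted, the
  # median-of-ratios factors would absorb the planted change, so supply
  # the known unit factors
  sf <- tibble::tibble(sample_id = cond$sample_id, size_factor = 1)
  res <- nb_wald_test(counts, cond, sf = sf)
  expect_lt(abs(median(res$log2fc) - 2), 0.3)
})

test_that("BH adjustment matches hand computation and preserves order", {
  expect_equal(adjust_pvalues(0.04), 0.04)
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03, 0.04)),
               rep(0.04, 4))
  expect_error(adjust_pvalues(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(81)
  for (i in 1:20) {
    p <- runif(sample(2:20, 1))
    adj <- adjust_pvalues(p)
    expect_equal(adj, bh_oracle(p))
    expect_true(all(diff(adj[order(p)]) >= -1e-12))
  }
})

test_that("DE filter applies the three inclusive predicates and splits by sign", {
  rec <- function(count, padj, lfc) {
    tibble::tibble(feature_id = "x", total_raw_count = count, padj = padj,
                   log2fc = lfc)
  }
  expect_equal(nrow(filter_de(rec(49, 0.001, 3))$up), 0)   # count boundary
  expect_equal(nrow(filter_de(rec(50, 0.05, 1.0))$up), 1)  # all inclusive
  expect_equal(nrow(filter_de(rec(50, 0.051, 1.0))$up), 0)
  expect_equal(nrow(filter_de(rec(50, 0.05, -1.0))$down), 1)

  # 10 records, 3 designed survivors (f1 up, f6 up, f8 down)
  toy <- tibble::tibble(
    feature_id = paste0("f", 1:10),
    total_raw_count = c(500, 49, 500, 500, 500, 50, 10, 400, 500, 500),
    padj = c(0.01, 0.01, 0.06, 0.05, 0.01, 0.05, 0.01, 0.001, 0.2, 0.01),
    log2fc = c(2, 2, 2, 0.9, 0.99, 1, 3, -1.5, -3, -0.5)
  )
  got <- filter_de(toy)
  expect_equal(got$up$feature_id, c("f1", "f6"))
  expect_equal(got$down$feature_id, "f8")
})

test_that("RPM floor keeps a feature only when both condition means reach it", {
  # library sizes: 1e6 per sample by construction, so counts are RPM
  counts <- tibble::tibble(
    feature_id = c("keep_boundary", "fail_treated", "high", "filler"),
    c1 = c(6, 100, 5000, 994894), c2 = c(6, 100, 5000, 994894),
    t1 = c(6, 6, 5000, 994988), t2 = c(6, 5.8, 5000, 994988.2)
  )
  kept <- rpm_filter(counts, toy_conditions(), 6)
  expect_true("keep_boundary" %in% kept)   # exactly 6.0 in both: inclusive
  expect_false("fail_treated" %in% kept)   # 100 control but 5.9 treated
  expect_true("high" %in% kept)
  zero_lib <- tibble::tibble(feature_id = "g", c1 = 0, c2 = 1, t1 = 1, t2 = 1)
  expect_error(rpm_filter(zero_lib, toy_conditions(), 6), "library size")
})

test_that("RPM floor matches hand-computed condition means on a toy matrix", {
  counts <- tibble::tibble(
    feature_id = c("a", "b", "c", "d"),
    c1 = c(10, 40, 30, 20), c2 = c(30, 20, 30, 20),
    t1 = c(50, 10, 20, 20), t2 = c(50, 10, 20, 20)
  )
  # library sizes 100 everywhere, so RPM = count * 1e4.
  # condition means (control, treated) x 1e4: a (2e5, 5e5), b (3e5, 1e5),
  # c (3e5, 2e5), d (2e5, 2e5)
  expect_setequal(rpm_filter(counts, toy_conditions(), 2e5),
                  c("a", "c", "d"))
  # at 2.5e5 every feature fails in at least one condition
  expect_equal(rpm_filter(counts, toy_conditions(), 2.5e5), character(0))
})

test_that("concordance reproduces the textbook Pearson formula and its limits", {
  a <- tibble::tibble(feature_id = paste0("g", 1:5),
                      log2fc = c(-2, -0.5, 0.1, 1.3, 2.2))
  expect_equal(concordance(a, a), 1)
  neg <- a
  neg$log2fc <- -neg$log2fc
  expect_equal(concordance(a, neg), -1)

  b <- tibble::tibble(feature_id = paste0("g", 1:5),
                      log2fc = c(-1.4, 0.2, -0.3, 1.9, 1.1))
  x <- a$log2fc
  y <- b$log2fc
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(concordance(a, b), r_hand)
  expect_error(concordance(a[1:2, ], b[1:2, ]), "at least 3")
})

test_that("scaling a sample's column rescales its size factor and leaves fold changes stable", {
  counts <- toy_counts()
  cond <- toy_conditions()
  base_sf <- size_factors(counts)$size_factor
  scaled <- counts
  scaled$t1 <- scaled$t1 * 2
  sf2 <- size_factors(scaled)$size_factor
  # ratio of factors doubles for the scaled sample, up to global rescale
  rel <- (sf2 / base_sf)
  expect_equal(rel[3] / rel[1], 2, tolerance = 1e-9)
  res_a <- nb_wald_test(counts, cond)
  res_b <- nb_wald_test(scaled, cond)
  expect_equal(res_a$log2fc, res_b$log2fc, tolerance = 0.02)
})

test_that("swapping condition labels negates fold changes and keeps p-values", {
  counts <- toy_counts()
  cond <- toy_conditions()
  swapped <- cond
  swapped$condition <- ifelse(cond$condition == "control", "treated",
                              "control")
  a <- nb_wald_test(counts, cond)
  b <- nb_wald_test(counts, swapped)
  expect_equal(a$log2fc, -b$log2fc)
  expect_equal(a$pvalue, b$pvalue)
})

test_that("the full filter chain controls empirical FDR under the null", {
  truth <- simulate_ground_truth(5, 2000, 0, 1.5, dispersion = 0.1, seed = 91)
  sim <- simulate_counts(truth, n_rep = 3, seed = 92)
  de <- de_analysis(sim$mrna, sim$conditions)
  hits <- filter_de(de)
  n_disc <- nrow(hits$up) + nrow(hits$down)
  # every discovery is false here; the chain should make almost none
  expect_lte(n_disc / max(1, nrow(de)), 0.10)
  expect_lte(n_disc, 5)
})
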