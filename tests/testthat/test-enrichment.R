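test_that("hypergeometric test matches closed forms and is monotone in overlap", {
  uni <- sprintf("g%02d", 1:10)
  expect_equal(hypergeom_test(uni, uni[1:4], uni), 1)
  # all 5 query genes inside a 5-gene term: p = 1 / C(10, 5)
  expect_equal(hypergeom_test(uni[1:5], uni[1:5], uni), 1 / 252)
  expect_error(hypergeom_test("a", "a", character(0)), "non-empty")

  # monotone decreasing in k at fixed N, K, n
  N <- 30; K <- 10; n <- 8
  p <- vapply(0:8, function(k) {
    phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  }, numeric(1))
  expect_true(all(diff(p) < 0))
  uni2 <- sprintf("u%02d", 1:30)
  for (k in c(2, 5, 8)) {
    expect_equal(hypergeom_test(uni2[1:8],
                                c(uni2[1:k], uni2[20:(29 - k)]), uni2),
                 p[k + 1])
  }
})

test_that("hypergeometric p equals exhaustive enumeration on a small universe", {
  # enumerate every C(12, 5) draw and count overlaps directly
  N <- 12; n <- 5
  draws <- utils::combn(N, n)
  uni <- sprintf("g%02d", 1:N)
  for (K in c(3, 7, 12)) {
    ov <- colSums(draws <= K)
    term <- uni[seq_len(K)]
    for (k in max(0, n - (N - K)):min(K, n)) {
      query <- c(uni[seq_len(k)], uni[K + seq_len(n - k)])
      p_enum <- mean(ov >= k)
      expect_equal(hypergeom_test(query, term, uni), p_enum,
                   tolerance = 1e-12)
    }
  }
})

test_that("Bonferroni step-down matches hand computation and the definition", {
  expect_equal(bonferroni_step_down(0.2), 0.2)
  expect_equal(bonferroni_step_down(c(0.01, 0.04)), c(0.02, 0.04))
  set.seed(17)
  for (i in 1:20) {
    p <- runif(sample(2:20, 1))
    adj <- bonferroni_step_down(p)
    expect_equal(adj, holm_oracle(p))
    expect_true(all(adj <= 1))
    expect_true(all(diff(adj[order(p)]) >= -1e-12))
    # Holm dominates BH on the same vector
    expect_true(all(adj >= adjust_pvalues(p) - 1e-12))
  }
})

test_that("term selection applies the inclusive overlap/attribution/padj boundaries", {
  terms <- tibble::tibble(
    term_id = paste0("T", 1:5),
    term_name = paste0("T", 1:5),
    term_size = c(4, 75, 60, 100, 10),
    overlap = c(2, 3, 10, 4, 3),
    overlap_genes = replicate(5, character(0), simplify = FALSE),
    attribution = c(0.5, 0.04, 1 / 6, 0.039, 0.3),
    pvalue = c(1e-4, 1e-3, 1e-3, 1e-5, 0.02),
    padj = c(1e-3, 0.05, 1e-2, 1e-4, 0.051)
  )
  got <- select_terms(terms)
  # T1 fails overlap (2 < 3); T4 fails attribution; T5 fails padj
  expect_setequal(got$term_id, c("T2", "T3"))
})

test_that("kappa matches the direct 2x2 formula, including degenerate margins", {
  t2 <- tibble::tibble(
    term_id = c("A", "B"), pvalue = c(0.01, 0.02),
    overlap_genes = list(c("g1", "g2"), c("g1", "g2"))
  )
  expect_equal(kappa_matrix(t2)["A", "B"], 1)

  # two disjoint 1-gene terms over a 2-gene reference: p_o = 0, p_e = 0.5
  disj <- tibble::tibble(
    term_id = c("A", "B"), pvalue = c(0.01, 0.02),
    overlap_genes = list("g1", "g2")
  )
  expect_equal(kappa_matrix(disj)["A", "B"], -1)

  set.seed(23)
  genes <- sprintf("g%02d", 1:50)
  terms <- tibble::tibble(
    term_id = sprintf("T%02d", 1:20),
    pvalue = runif(20),
    overlap_genes = replicate(20, sample(genes, sample(3:25, 1)),
                              simplify = FALSE)
  )
  kap <- kappa_matrix(terms)
  expect_equal(kap, t(kap))
  ref <- sort(unique(unlist(terms$overlap_genes)))
  for (i in 1:19) for (j in (i + 1):20) {
    x <- ref %in% terms$overlap_genes[[i]]
    y <- ref %in% terms$overlap_genes[[j]]
    expect_equal(kap[i, j], kappa_oracle(x, y))
  }
})

test_that("kappa grouping forms connected components with min-p leading terms", {
  terms <- tibble::tibble(term_id = paste0("T", 1:5),
                          pvalue = c(0.03, 0.01, 0.02, 0.005, 0.04))
  kap <- diag(1, 5)
  rownames(kap) <- colnames(kap) <- terms$term_id
  # component {T1, T2, T3} via T1-T2 and T2-T3; component {T4, T5}
  kap["T1", "T2"] <- kap["T2", "T1"] <- 0.5
  kap["T2", "T3"] <- kap["T3", "T2"] <- 0.04  # boundary: inclusive
  kap["T4", "T5"] <- kap["T5", "T4"] <- 0.9
  got <- group_terms(terms, kap, threshold = 0.04)
  memb <- setNames(got$membership$group_id, got$membership$term_id)
  expect_equal(length(unique(memb[c("T1", "T2", "T3")])), 1)
  expect_equal(length(unique(memb[c("T4", "T5")])), 1)
  expect_true(memb["T1"] != memb["T4"])
  expect_setequal(got$groups$leading_term_id, c("T2", "T4"))

  # below threshold everywhere: singletons
  solo <- group_terms(terms, diag(1, 5) + 0, threshold = 0.04)
  expect_equal(nrow(solo$groups), 5)
  # threshold 0 with all-positive kappas: one group
  allpos <- matrix(0.2, 5, 5)
  diag(allpos) <- 1
  one <- group_terms(terms, allpos, threshold = 0)
  expect_equal(nrow(one$groups), 1)
})

test_that("leading-term ties break lexicographically", {
  terms <- tibble::tibble(term_id = c("TB", "TA"), pvalue = c(0.01, 0.01))
  kap <- matrix(1, 2, 2, dimnames = list(terms$term_id, terms$term_id))
  got <- group_terms(terms, kap, threshold = 0.04)
  expect_equal(got$groups$leading_term_id, "TA")
})

test_that("raising the kappa threshold only refines the grouping", {
  set.seed(29)
  genes <- sprintf("g%02d", 1:40)
  terms <- tibble::tibble(
    term_id = sprintf("T%02d", 1:12),
    pvalue = runif(12),
    overlap_genes = replicate(12, sample(genes, 10), simplify = FALSE)
  )
  kap <- kappa_matrix(terms)
  prev <- group_terms(terms, kap, threshold = -1)$membership$group_id
  for (thr in c(0.04, 0.2, 0.5, 1.1)) {
    cur <- group_terms(terms, kap, threshold = thr)$membership$group_id
    # same current group implies same previous group (refinement)
    for (g in unique(cur)) {
      expect_equal(length(unique(prev[cur == g])), 1)
    }
    prev <- cur
  }
})

test_that("a planted term is selected and leads its group", {
  set.seed(31)
  universe <- sprintf("G%04d", 1:2000)
  query <- sample(universe, 30)
  gs <- simulate_genesets(universe, n_terms = 40, term_size_range = c(20, 60),
                          planted_genes = query, planted_fraction = 0.8,
                          seed = 33)
  enr <- run_enrichment(query, gs)
  expect_true(gs$planted_term_id %in% enr$term_id)
  row <- enr[enr$term_id == gs$planted_term_id, ]
  expect_lte(row$padj, 0.05)
  expect_gte(row$overlap, 3)
  expect_gte(row$attribution, 0.04)
  expect_true(row$is_leading)
})
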