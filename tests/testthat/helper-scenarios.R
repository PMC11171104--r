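# Shared fixtures, built in code at test time.

# A small two-condition count table with hand-chosen values.
toy_counts <- function() {
  tibble::tibble(
    feature_id = paste0("g", 1:5),
    c1 = c(100, 50, 10, 200, 5),
    c2 = c(110, 55, 12, 180, 6),
    t1 = c(400, 48, 11, 50, 5),
    t2 = c(380, 52, 9, 60, 7)
  )
}

toy_conditions <- function() {
  tibble::tibble(
    sample_id = c("c1", "c2", "t1", "t2"),
    condition = c("control", "control", "treated", "treated")
  )
}

# Small default-style scenario, cheap enough for repeated use.
small_run <- function(seed = 42, ...) {
  cfg <- pipeline_config(
    seed = seed,
    sim = utils::modifyList(
      list(n_mirna = 40, n_gene = 400, n_pairs = 15), list(...))
  )
  suppressMessages(run_pipeline(cfg))
}

# Independent Holm implementation straight from the definition.
holm_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- 0
  for (i in seq_len(m)) {
    running <- max(running, min(1, (m - i + 1) * p[o[i]]))
    adj[o[i]] <- running
  }
  adj
}

# Independent BH implementation straight from the step-up definition.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (i in rev(seq_len(m))) {
    prev <- min(prev, m * p[o[i]] / i)
    adj[o[i]] <- prev
  }
  adj
}

# Cohen's kappa for two logical vectors, written independently of the
# package internals (explicit 2x2 cell counts and margin products).
kappa_oracle <- function(x, y) {
  tab <- table(factor(x, c(FALSE, TRUE)), factor(y, c(FALSE, TRUE)))
  n <- sum(tab)
  p_o <- (tab[1, 1] + tab[2, 2]) / n
  p_e <- (sum(tab[1, ]) * sum(tab[, 1]) + sum(tab[2, ]) * sum(tab[, 2])) / n^2
  if (1 - p_e < 1e-15) return(if (all(x == y)) 1 else 0)
  (p_o - p_e) / (1 - p_e)
}
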