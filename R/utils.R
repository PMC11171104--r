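# Internal validation helpers shared across modules.

# counts: data frame, first column feature_id, remaining columns numeric
# per-sample counts. Returns an integer-ish numeric matrix with rownames.
.count_matrix <- function(counts) {
  if (!is.data.frame(counts)) {
    abort("`counts` must be a data frame with a `feature_id` column followed by one numeric column per sample.")
  }
  if (!"feature_id" %in% names(counts)) {
    abort("`counts` must contain a `feature_id` column.")
  }
  samp_cols <- setdiff(names(counts), "feature_id")
  if (length(samp_cols) == 0) abort("`counts` has no sample columns.")
  m <- as.matrix(counts[samp_cols])
  if (!is.numeric(m)) abort("Sample columns of `counts` must be numeric.")
  if (anyNA(m)) abort("`counts` contains missing values.")
  if (any(m < 0)) abort("`counts` contains negative values.")
  rownames(m) <- counts$feature_id
  m
}

# conditions: data frame with sample_id, condition in {control, treated}.
# Returns a named character vector aligned to `sample_ids` if given.
.condition_vector <- function(conditions, sample_ids = NULL) {
  if (!is.data.frame(conditions) ||
      !all(c("sample_id", "condition") %in% names(conditions))) {
    abort("`conditions` must be a data frame with columns `sample_id` and `condition`.")
  }
  bad <- setdiff(unique(conditions$condition), c("control", "treated"))
  if (length(bad) > 0) {
    abort(paste0("`condition` must be 'control' or 'treated'; found: ",
                 paste(bad, collapse = ", ")))
  }
  cond <- setNames(conditions$condition, conditions$sample_id)
  if (!is.null(sample_ids)) {
    missing <- setdiff(sample_ids, names(cond))
    if (length(missing) > 0) {
      abort(paste0("No condition given for sample(s): ",
                   paste(missing, collapse = ", ")))
    }
    cond <- cond[sample_ids]
  }
  for (lev in c("control", "treated")) {
    if (sum(cond == lev) < 2) {
      abort(paste0("Each condition needs at least 2 samples; '", lev,
                   "' has ", sum(cond == lev), "."))
    }
  }
  cond
}

.check_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single finite number in [%s, %s].",
                  name, format(lower), format(upper)))
  }
  invisible(x)
}

.check_seed <- function(seed) {
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed) ||
      seed != round(seed)) {
    abort("`seed` must be a single integer.")
  }
  as.integer(seed)
}

# Run code under a local RNG state so generators never disturb the caller's
# stream and are reproducible from their explicit seed alone.
.with_seed <- function(seed, code) {
  seed <- .check_seed(seed)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
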