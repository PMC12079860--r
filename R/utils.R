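# Internal validation helpers. Kept deliberately small: user-facing errors
# come from rlang::abort() with a class so tests can assert on them.

stop_medseqr <- function(msg, class = "medseqr_error") {
  abort(msg, class = class)
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop_medseqr(sprintf("`%s` must be a single non-missing number.", name))
  }
  if (x < lower || x > upper) {
    stop_medseqr(sprintf("`%s` must be in [%s, %s], got %s.", name, lower, upper, x))
  }
  invisible(x)
}

assert_columns <- function(df, cols, name = deparse(substitute(df))) {
  if (!is.data.frame(df)) {
    stop_medseqr(sprintf("`%s` must be a data frame.", name))
  }
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    stop_medseqr(sprintf(
      "`%s` is missing required column(s): %s.",
      name, paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}

# Seed handling: every stochastic function takes a mandatory seed and uses a
# local RNG scope, so callers' global RNG state is never touched.
with_seed <- function(seed, code) {
  assert_scalar_number(seed, "seed")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Rank-based AUC (Mann-Whitney formulation), ties handled by midranks.
# Positive class = labels == case.
rank_auc <- function(scores, labels, case) {
  pos <- labels == case
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) {
    stop_medseqr("AUC needs at least one sample in each class.")
  }
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
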