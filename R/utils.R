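# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
# A NULL seed runs the code against the current stream unchanged.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Deterministically derive `k` independent substream seeds from one master
# seed. Kept below 2^31 - 1 so they remain valid R integer seeds.
spawn_seeds <- function(seed, k) {
  if (is.null(seed)) return(rep(list(NULL), k))
  with_seed(seed, sample.int(.Machine$integer.max - 1L, k))
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         integer = FALSE, open_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stopf("`%s` must be a single non-missing number", name)
  if (integer && x != round(x))
    stopf("`%s` must be an integer, got %s", name, format(x))
  if (x < lower || (open_lower && x <= lower) || x > upper)
    stopf("`%s` must be in %s%s, %s], got %s", name,
          if (open_lower) "(" else "[", format(lower), format(upper),
          format(x))
  invisible(x)
}

# Coerce a square nonnegative matrix-like object to dgCMatrix and validate
# the strength-matrix contract (square, nonnegative, zero diagonal).
as_strength_matrix <- function(A, name = "strengths") {
  A <- as(as(as(A, "dMatrix"), "generalMatrix"), "CsparseMatrix")
  if (nrow(A) != ncol(A)) stopf("`%s` must be square", name)
  if (length(A@x) && min(A@x) < 0) stopf("`%s` must be nonnegative", name)
  if (any(Matrix::diag(A) != 0)) stopf("`%s` must have a zero diagonal", name)
  A
}

# Rank threshold used by percentile-style rules throughout: the k-th order
# statistic with k = ceiling(p * length(x)); ties share rank.
bottom_threshold <- function(x, pct) {
  x <- x[is.finite(x)]
  if (!length(x)) return(NA_real_)
  sort(x)[ceiling(pct / 100 * length(x))]
}

top_threshold <- function(x, pct) {
  x <- x[is.finite(x)]
  if (!length(x)) return(NA_real_)
  sort(x, decreasing = TRUE)[ceiling(pct / 100 * length(x))]
}
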