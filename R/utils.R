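# Internal helpers shared across modules.

# Multiplicative lognormal noise with unit mean and a given coefficient of
# variation. cv = 0 returns exact ones so noise-free runs are bit-exact.
ln_noise <- function(n, cv) {
  if (cv < 0) abort("`cv` must be non-negative.")
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log1p(cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

with_seed <- function(seed, code) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  code
}

check_count <- function(x, name, positive = TRUE) {
  ok <- is.numeric(x) && length(x) == 1 && !is.na(x) && x == floor(x) &&
    (if (positive) x > 0 else x >= 0)
  if (!ok) {
    abort(sprintf("`%s` must be a single %s integer.",
                  name, if (positive) "positive" else "non-negative"))
  }
  as.integer(x)
}

check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must be a single value in [0, 1].", name))
  }
  x
}

check_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing required column(s): %s.",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

# All permutations of 1..n as an n!-row integer matrix (n <= 9 kept sane by
# callers). Used by the exact Spearman null.
all_permutations <- function(n) {
  n <- as.integer(n)
  if (n == 1L) return(matrix(1L, 1L, 1L))
  p <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(p + (p >= i), i, deparse.level = 0)
  }))
}
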