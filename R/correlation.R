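# Shared Spearman rank-correlation core.
#
# rho uses average ranks for ties. The two-sided p-value comes from an exact
# enumeration of the permutation null when n <= exact_limit and there are no
# ties (the null of S = sum d^2 over all n! rank permutations), and from the
# t approximation t = rho sqrt((n-2)/(1-rho^2)) on n - 2 df otherwise.
spearman_cor <- function(x, y, exact_limit = 9) {
  ok <- complete.cases(x, y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 3) abort("Spearman correlation needs at least 3 complete pairs.")
  rx <- rank(x)
  ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    abort("Spearman correlation is undefined for a constant variable.")
  }
  rho <- cor(rx, ry)
  ties <- anyDuplicated(rx) > 0 || anyDuplicated(ry) > 0

  if (n <= exact_limit && !ties) {
    s_obs <- sum((rx - ry)^2)
    perms <- all_permutations(n)
    s_all <- rowSums(sweep(perms, 2, seq_len(n))^2)
    mu <- n * (n^2 - 1) / 6  # S at rho = 0
    p <- mean(abs(s_all - mu) >= abs(s_obs - mu) - 1e-9)
    method <- "exact permutation"
  } else {
    if (abs(rho) >= 1) {
      p <- 0
    } else {
      tstat <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * pt(-abs(tstat), df = n - 2)
    }
    method <- "t approximation"
  }
  list(rho = rho, p_value = p, n = n, method = method)
}
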