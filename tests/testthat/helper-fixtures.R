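# Shared fixture builders and independent oracles for the test suite.

# A tiny well table built by hand (one plate, one replicate).
make_wells <- function(fib = c(10, 20, 40), cancer = fib,
                       entity = sprintf("ent-%d", seq_along(fib)),
                       plate = "P1", replicate = 1) {
  tibble::tibble(plate_id = plate,
                 well = sprintf("A%02d", seq_along(fib)),
                 entity_id = entity,
                 screen_replicate = replicate,
                 fib_count = fib, cancer_count = cancer, n_fields = 4L)
}

# Brute-force Jaccard index by explicit set arithmetic.
jaccard_oracle <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0) return(0)
  length(intersect(a, b)) / u
}

# Naive O(n^3) average-linkage agglomeration over a distance matrix.
# Ties broken by the lexicographically smallest cluster-index pair.
# Returns one row per merge: the two leaf sets (as sorted index strings)
# and the merge height.
average_linkage_oracle <- function(D) {
  n <- nrow(D)
  members <- lapply(seq_len(n), identity)
  active <- seq_len(n)
  steps <- list()
  for (s in seq_len(n - 1)) {
    best <- NULL
    for (ii in seq_along(active)) {
      for (jj in seq_len(ii - 1)) {
        A <- members[[active[jj]]]
        B <- members[[active[ii]]]
        d <- mean(D[A, B])
        if (is.null(best) || d < best$d - 1e-15) {
          best <- list(i = active[jj], j = active[ii], d = d)
        }
      }
    }
    A <- sort(members[[best$i]])
    B <- sort(members[[best$j]])
    steps[[s]] <- list(
      sets = sort(c(paste(A, collapse = ","), paste(B, collapse = ","))),
      height = best$d)
    members[[best$i]] <- c(members[[best$i]], members[[best$j]])
    active <- setdiff(active, best$j)
  }
  steps
}

# Leaf-set view of an hclust merge matrix, comparable with the oracle above.
hclust_steps <- function(hc) {
  sets <- vector("list", nrow(hc$merge))
  leafset <- function(j, s) {
    if (j < 0) -j else sets[[j]]
  }
  out <- vector("list", nrow(hc$merge))
  for (s in seq_len(nrow(hc$merge))) {
    a <- leafset(hc$merge[s, 1], s)
    b <- leafset(hc$merge[s, 2], s)
    sets[[s]] <- c(a, b)
    out[[s]] <- list(
      sets = sort(c(paste(sort(a), collapse = ","),
                    paste(sort(b), collapse = ","))),
      height = hc$height[s])
  }
  out
}

# Exhaustive two-sided Wilcoxon rank-sum p-value over all label assignments
# (no ties assumed), using the 2*min(tail) convention.
wilcoxon_oracle <- function(v1, v2) {
  v <- c(v1, v2)
  n1 <- length(v1)
  r <- rank(v)
  w_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(length(v), n1)
  w_all <- apply(combos, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  p <- 2 * min(mean(w_all <= w_obs), mean(w_all >= w_obs))
  min(1, p)
}

# Exhaustive two-sided Spearman permutation p-value: proportion of
# permutations of y with |rho| at least the observed |rho|.
spearman_perm_oracle <- function(x, y) {
  rho_obs <- cor(x, y, method = "spearman")
  perm_recurse <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      rest <- perm_recurse(v[-i])
      out <- c(out, lapply(rest, function(r) c(v[i], r)))
    }
    out
  }
  perms <- perm_recurse(seq_along(y))
  rhos <- vapply(perms, function(p) cor(x, y[p], method = "spearman"),
                 numeric(1))
  mean(abs(rhos) >= abs(rho_obs) - 1e-9)
}

# Closed-form two-variable OLS: slope, its SE, intercept, R^2.
ols_oracle <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  resid <- y - intercept - slope * x
  s2 <- sum(resid^2) / (n - 2)
  syy <- sum((y - mean(y))^2)
  list(slope = slope, slope_se = sqrt(s2 / sxx), intercept = intercept,
       r_squared = if (syy > 0) 1 - sum(resid^2) / syy else 0)
}

# Adjusted Rand index between two labelings (closed form from the
# contingency table); mclust::adjustedRandIndex is used as a cross-check
# where available.
ari <- function(a, b) {
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  n <- sum(tab)
  expected <- sum_a * sum_b / ch2(n)
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# Run the installed command-line interface in a child R process.
run_cli <- function(args) {
  script <- system.file("exec", "mirstroma", package = "mirstroma")
  if (!nzchar(script)) {
    script <- file.path(find.package("mirstroma"), "exec", "mirstroma")
  }
  rscript <- file.path(R.home("bin"), "Rscript")
  out <- system2(rscript, c(shQuote(script), args),
                 stdout = TRUE, stderr = TRUE,
                 env = paste0("R_LIBS=",
                              paste(.libPaths(),
                                    collapse = .Platform$path.sep)))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0) {
    stop("CLI failed: ", paste(out, collapse = "\n"))
  }
  invisible(out)
}
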