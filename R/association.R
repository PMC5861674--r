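#' Read a cohort table
#'
#' CSV of subject-level records, e.g. `subject_id, tissue, sex, age, smoking,
#' copd, histology, stage, grade, pack_years, analyte`. Only `subject_id`
#' and `analyte` are required; grouping and stratification columns are
#' chosen at analysis time.
#'
#' @param path Path to a CSV file.
#' @return A tibble of cohort records.
#' @export
read_cohort <- function(path) {
  cohort <- readr::read_csv(path, show_col_types = FALSE)
  check_columns(cohort, c("subject_id", "analyte"), "Cohort table")
  if (any(cohort$analyte <= 0, na.rm = TRUE)) {
    abort("Analyte levels must be positive.")
  }
  tibble::as_tibble(cohort)
}

quartiles <- function(x) {
  # linear interpolation between order statistics (quantile type 7)
  quantile(x, probs = c(0.25, 0.5, 0.75), type = 7, names = FALSE)
}

#' Median/IQR subgroup summaries with two-group comparisons
#'
#' Summarises an analyte by a categorical covariate as `median [IQR]`
#' (linear-interpolation quantile convention), overall and within each level
#' of an optional stratum (e.g. fibroblast tissue of origin, CAF vs NF).
#' When the grouping variable has exactly two levels, a two-sided Wilcoxon
#' rank-sum p-value is attached to each stratum's comparison.
#'
#' @param cohort A cohort tibble.
#' @param by Unquoted categorical grouping column.
#' @param value Unquoted analyte column (default `analyte`).
#' @param strata Optional unquoted stratification column.
#' @return A tibble `stratum, group, n, median, q25, q75, p_value`
#'   (`stratum = "All"` for the unstratified rows; the p-value is repeated
#'   across the rows of its comparison).
#' @export
subgroup_summary <- function(cohort, by, value = analyte, strata = NULL) {
  by_q <- enquo(by)
  value_q <- enquo(value)
  strata_q <- enquo(strata)
  df <- tibble::tibble(group = as.character(dplyr::pull(cohort, !!by_q)),
                       value = dplyr::pull(cohort, !!value_q))
  has_strata <- !rlang::quo_is_null(strata_q)
  df$stratum <- if (has_strata) {
    as.character(dplyr::pull(cohort, !!strata_q))
  } else {
    NA_character_
  }
  df <- df[complete.cases(df$group, df$value), , drop = FALSE]

  strata_levels <- c(list(c(stratum = "All", keep = NA)),
                     if (has_strata)
                       lapply(sort(unique(df$stratum)),
                              function(s) c(stratum = s, keep = s)))
  purrr::map_dfr(strata_levels, function(sl) {
    sub <- if (is.na(sl[["keep"]])) df else df[df$stratum == sl[["keep"]], ]
    groups <- sort(unique(sub$group))
    p <- if (length(groups) == 2) {
      wilcoxon_two_group(sub, value, group)$p_value
    } else {
      NA_real_
    }
    purrr::map_dfr(groups, function(g) {
      v <- sub$value[sub$group == g]
      q <- quartiles(v)
      tibble::tibble(stratum = sl[["stratum"]], group = g,
                     n = length(v), median = q[2], q25 = q[1], q75 = q[3],
                     p_value = p)
    })
  })
}

#' Two-group Wilcoxon rank-sum comparison
#'
#' Rank-sum test with average ranks for ties. The two-sided p-value is exact
#' (full enumeration of the null) when both groups have at most `exact_limit`
#' observations and there are no ties; otherwise the normal approximation
#' with tie and continuity corrections is used. The mode actually used is
#' recorded in the output.
#'
#' @param data A data frame.
#' @param value Unquoted numeric column.
#' @param group Unquoted two-level grouping column.
#' @param exact_limit Largest per-group size for the exact null
#'   (default 8).
#' @return A one-row tibble `n1, n2, statistic, p_value, method`.
#' @export
wilcoxon_two_group <- function(data, value, group, exact_limit = 8) {
  v <- dplyr::pull(data, {{ value }})
  g <- as.character(dplyr::pull(data, {{ group }}))
  ok <- complete.cases(v, g)
  v <- v[ok]
  g <- g[ok]
  levels <- sort(unique(g))
  if (length(levels) != 2) {
    abort(sprintf("Grouping must have exactly 2 levels, found %d.",
                  length(levels)))
  }
  v1 <- v[g == levels[1]]
  v2 <- v[g == levels[2]]
  if (length(v1) == 0 || length(v2) == 0) {
    abort("Both groups must be non-empty.")
  }
  ties <- anyDuplicated(v) > 0
  exact <- !ties && length(v1) <= exact_limit && length(v2) <= exact_limit
  res <- suppressWarnings(
    wilcox.test(v1, v2, exact = exact, correct = TRUE))
  tibble::tibble(n1 = length(v1), n2 = length(v2),
                 statistic = unname(res$statistic),
                 p_value = res$p.value,
                 method = if (exact) "exact" else
                   "normal approximation (tie/continuity corrected)")
}

#' Spearman correlation between an exposure and an analyte
#'
#' Rank correlation with average-rank ties; two-sided p-value by exact
#' permutation for small n and the t approximation otherwise. Flags
#' significance at the two-sided 0.05 level.
#'
#' @param data A data frame.
#' @param x,y Unquoted columns (e.g. pack-years exposure and analyte level).
#' @param exact_limit Largest n for the exact permutation null (default 9).
#' @return A one-row tibble `rho, p_value, n, method, significant`.
#' @export
spearman_assoc <- function(data, x, y, exact_limit = 9) {
  res <- spearman_cor(dplyr::pull(data, {{ x }}),
                      dplyr::pull(data, {{ y }}),
                      exact_limit = exact_limit)
  tibble::tibble(rho = res$rho, p_value = res$p_value, n = res$n,
                 method = res$method, significant = res$p_value < 0.05)
}
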