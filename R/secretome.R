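#' Read a multiplex secretome panel table
#'
#' CSV with columns `factor_id, condition, replicate, concentration_pg_ml`
#' (or `concentration`); optional `below_lod` (logical) and `lod` columns for
#' values under the limit of detection.
#'
#' @param path Path to a CSV file.
#' @return A tibble with a `concentration` column.
#' @export
read_secretome <- function(path) {
  panel <- readr::read_csv(path, show_col_types = FALSE)
  if ("concentration_pg_ml" %in% names(panel) &&
      !"concentration" %in% names(panel)) {
    panel <- dplyr::rename(panel, concentration = "concentration_pg_ml")
  }
  check_columns(panel, c("factor_id", "condition", "replicate",
                         "concentration"), "Secretome panel")
  tibble::as_tibble(panel)
}

#' @rdname read_secretome
#' @param panel A secretome panel table.
#' @export
write_secretome <- function(panel, path) {
  readr::write_csv(panel, path)
  invisible(path)
}

#' Percent-of-control secretome profile
#'
#' For each secreted factor computes the treated concentration as a
#' percentage of control: `100 x mean(treated) / mean(control)`, means over
#' replicates. Factors whose control mean is not positive are reported with
#' `percent = NA` (indeterminate) rather than failing the run; factors
#' present only in the treated arm are listed in an exceptions attribute and
#' excluded with a warning. Values below the limit of detection (rows with
#' `below_lod = TRUE`) are handled by `lod_policy`: substitute `lod / 2`
#' (default, requires an `lod` column), drop the replicate, or set it to
#' zero.
#'
#' @param panel A secretome panel (see [read_secretome()]).
#' @param lod_policy `"half"`, `"drop"` or `"zero"`.
#' @param control,treated Condition labels of the two arms.
#' @return A tibble `factor_id, n_control, n_treated, mean_control,
#'   mean_treated, percent` with an `"exceptions"` attribute.
#' @export
percent_of_control <- function(panel, lod_policy = c("half", "drop", "zero"),
                               control = "control", treated = "treated") {
  lod_policy <- match.arg(lod_policy)
  check_columns(panel, c("factor_id", "condition", "replicate",
                         "concentration"), "Secretome panel")
  if (any(panel$concentration < 0, na.rm = TRUE)) {
    abort("Concentrations must be non-negative.")
  }
  if ("below_lod" %in% names(panel) && any(panel$below_lod, na.rm = TRUE)) {
    sub <- which(panel$below_lod %in% TRUE)
    panel$concentration[sub] <- switch(lod_policy,
      half = {
        if (!"lod" %in% names(panel)) {
          abort("lod_policy = \"half\" requires an `lod` column.")
        }
        panel$lod[sub] / 2
      },
      zero = 0,
      drop = NA_real_)
    if (lod_policy == "drop") panel <- panel[-sub, , drop = FALSE]
  }
  panel <- dplyr::filter(panel, !is.na(.data$concentration))

  wide <- panel |>
    dplyr::filter(.data$condition %in% c(control, treated)) |>
    dplyr::group_by(.data$factor_id, .data$condition) |>
    dplyr::summarise(n = dplyr::n(), mean = mean(.data$concentration),
                     .groups = "drop") |>
    tidyr::pivot_wider(names_from = "condition",
                       values_from = c("n", "mean"),
                       names_sep = "_")
  for (col in c(paste0("n_", control), paste0("mean_", control),
                paste0("n_", treated), paste0("mean_", treated))) {
    if (!col %in% names(wide)) wide[[col]] <- NA
  }
  exceptions <- wide$factor_id[is.na(wide[[paste0("n_", control)]])]
  if (length(exceptions) > 0) {
    warn(sprintf("%d factor(s) with no control arm excluded: %s.",
                 length(exceptions),
                 paste(head(exceptions, 5), collapse = ", ")))
    wide <- wide[!wide$factor_id %in% exceptions, , drop = FALSE]
  }
  out <- tibble::tibble(
    factor_id = wide$factor_id,
    n_control = as.integer(wide[[paste0("n_", control)]]),
    n_treated = as.integer(tidyr::replace_na(wide[[paste0("n_", treated)]],
                                             0L)),
    mean_control = wide[[paste0("mean_", control)]],
    mean_treated = wide[[paste0("mean_", treated)]])
  out$percent <- ifelse(
    !is.na(out$mean_control) & out$mean_control > 0 &
      !is.na(out$mean_treated),
    100 * out$mean_treated / out$mean_control, NA_real_)
  attr(out, "exceptions") <- exceptions
  out
}

#' Flag perturbed secretome factors by the percent-of-control rule
#'
#' A factor is flagged `down` when its percent of control is strictly below
#' `low` and `up` when strictly above `high`; boundary values are unchanged.
#'
#' @param percents Output of [percent_of_control()].
#' @param low,high Strict thresholds in percent (defaults 75 and 125).
#' @return `percents` with a `flag` factor
#'   (`down`/`up`/`unchanged`/`indeterminate`).
#' @seealso [perturbation_summary()]
#' @export
flag_perturbed <- function(percents, low = 75, high = 125) {
  check_columns(percents, c("factor_id", "percent"), "Percent table")
  if (low >= high) abort("`low` must be below `high`.")
  percents |>
    dplyr::mutate(flag = factor(dplyr::case_when(
      is.na(.data$percent) ~ "indeterminate",
      .data$percent < low ~ "down",
      .data$percent > high ~ "up",
      TRUE ~ "unchanged"),
      levels = c("down", "up", "unchanged", "indeterminate")))
}

#' Count flagged secretome factors
#'
#' @param flagged Output of [flag_perturbed()].
#' @return A one-row tibble `n_down, n_up, n_unchanged, n_indeterminate,
#'   n_flagged, n_total`.
#' @export
perturbation_summary <- function(flagged) {
  check_columns(flagged, "flag", "Flagged percent table")
  tab <- table(flagged$flag)
  tibble::tibble(n_down = as.integer(tab[["down"]]),
                 n_up = as.integer(tab[["up"]]),
                 n_unchanged = as.integer(tab[["unchanged"]]),
                 n_indeterminate = as.integer(tab[["indeterminate"]]),
                 n_flagged = as.integer(tab[["down"]] + tab[["up"]]),
                 n_total = nrow(flagged))
}

#' Waterfall plot of a secretome percent-of-control profile
#'
#' Bars ordered by percent of control with the unchanged band marked, the
#' usual way a differential multiplex panel is displayed.
#'
#' @param flagged Output of [flag_perturbed()].
#' @param low,high Thresholds drawn as reference lines.
#' @return A ggplot object.
#' @export
plot_secretome <- function(flagged, low = 75, high = 125) {
  check_columns(flagged, c("factor_id", "percent", "flag"),
                "Flagged percent table")
  df <- flagged |>
    dplyr::filter(!is.na(.data$percent)) |>
    dplyr::mutate(factor_id = stats::reorder(.data$factor_id, .data$percent))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$factor_id, y = .data$percent,
                                   fill = .data$flag)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = c(low, high), linetype = "dashed") +
    ggplot2::scale_fill_manual(values = c(down = "#3366aa", up = "#aa3333",
                                          unchanged = "grey70",
                                          indeterminate = "grey40"),
                               drop = FALSE) +
    ggplot2::labs(x = NULL, y = "% of control", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       size = 6))
}
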