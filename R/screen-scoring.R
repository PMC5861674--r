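#' Default control entity labels
#'
#' Well records whose `entity_id` matches one of these labels are treated as
#' control wells (non-targeting mimic, mock transfection, untransfected) and
#' excluded from the plate median by default.
#' @export
default_control_ids <- function() c("miR-C", "mock", "untransfected")

#' Read a well-level screen table
#'
#' Reads and validates a tab-separated table of per-well two-channel nuclei
#' counts. Required columns: `plate_id, well, entity_id, screen_replicate,
#' fib_count, cancer_count` (`n_fields` optional, default 4). Duplicate
#' (plate, well, replicate) keys and negative counts are schema errors that
#' name the offending rows.
#'
#' @param path Path to a TSV file.
#' @return A validated tibble of well records.
#' @export
read_wells <- function(path) {
  wells <- readr::read_tsv(path, show_col_types = FALSE)
  validate_wells(wells)
}

validate_wells <- function(wells) {
  required <- c("plate_id", "well", "entity_id", "screen_replicate",
                "fib_count", "cancer_count")
  check_columns(wells, required, "Well table")
  if (!"n_fields" %in% names(wells)) wells$n_fields <- 4L
  key <- paste(wells$plate_id, wells$well, wells$screen_replicate, sep = "/")
  dup <- which(duplicated(key))
  if (length(dup) > 0) {
    abort(sprintf("Duplicate (plate, well, replicate) key at row(s) %s: %s.",
                  paste(head(dup, 5), collapse = ", "),
                  paste(unique(key[head(dup, 5)]), collapse = "; ")))
  }
  neg <- which(wells$fib_count < 0 | wells$cancer_count < 0)
  if (length(neg) > 0) {
    abort(sprintf("Negative counts at row(s) %s.",
                  paste(head(neg, 5), collapse = ", ")))
  }
  tibble::as_tibble(wells)
}

#' Write a well-level screen table
#' @param wells A well table.
#' @param path Output TSV path.
#' @export
write_wells <- function(wells, path) {
  readr::write_tsv(wells, path)
  invisible(path)
}

#' Plate-median normalization of well counts
#'
#' Normalizes each channel per plate and screen replicate relative to the
#' median of the sample wells on that plate: `normalized = count /
#' median(eligible counts)`. Control wells (matched by `control_ids`) are
#' excluded from the median when `exclude_controls` is set (the default) but
#' still receive normalized values. The median uses the midpoint convention
#' for even counts.
#'
#' @param wells A validated well table.
#' @param exclude_controls Exclude control wells from the plate median?
#' @param control_ids Entity labels treated as controls.
#' @return The input with `is_control`, `norm_fib` and `norm_cancer` columns.
#' @export
normalize_plate <- function(wells, exclude_controls = TRUE,
                            control_ids = default_control_ids()) {
  wells <- validate_wells(wells)
  wells$is_control <- wells$entity_id %in% control_ids
  out <- wells |>
    dplyr::group_by(.data$plate_id, .data$screen_replicate) |>
    dplyr::group_modify(function(df, key) {
      eligible <- if (exclude_controls) !df$is_control else rep(TRUE, nrow(df))
      if (!any(eligible)) {
        abort(sprintf("Plate %s (replicate %s) has no eligible wells.",
                      key$plate_id, key$screen_replicate))
      }
      for (ch in c("fib", "cancer")) {
        counts <- df[[paste0(ch, "_count")]]
        med <- median(counts[eligible])
        if (!is.finite(med) || med <= 0) {
          abort(sprintf(
            "Plate %s (replicate %s), channel %s: sample median is %s.",
            key$plate_id, key$screen_replicate, ch, format(med)))
        }
        df[[paste0("norm_", ch)]] <- counts / med
      }
      df
    }) |>
    dplyr::ungroup()
  out[, union(names(wells), c("norm_fib", "norm_cancer"))]
}

#' Aggregate normalized wells into per-miRNA screen scores
#'
#' Collapses normalized well values to one score per unique mature sequence
#' and channel. Library entries sharing a sequence, and wells across screen
#' replicates, are combined either as a flat arithmetic mean over all wells
#' (default: equal weight per measurement) or as a mean of per-replicate
#' means. Per-well values are retained as list columns.
#'
#' @param wells_norm Output of [normalize_plate()].
#' @param sequence_map Tibble mapping `entity_id` to `mirna_id` (unique
#'   mature sequence). Control wells need no mapping and are dropped.
#' @param method `"flat"` (mean over all wells) or `"replicate_mean"`.
#' @param control_ids Entity labels treated as controls.
#' @return A tibble with one row per miRNA: `mirna_id, norm_fib, norm_cancer,
#'   n_wells, fib_values, cancer_values`.
#' @export
aggregate_scores <- function(wells_norm, sequence_map,
                             method = c("flat", "replicate_mean"),
                             control_ids = default_control_ids()) {
  method <- match.arg(method)
  check_columns(wells_norm, c("entity_id", "screen_replicate",
                              "norm_fib", "norm_cancer"),
                "Normalized well table")
  check_columns(sequence_map, c("entity_id", "mirna_id"), "Sequence map")

  samples <- dplyr::filter(wells_norm, !.data$entity_id %in% control_ids)
  unmapped <- setdiff(unique(samples$entity_id), sequence_map$entity_id)
  if (length(unmapped) > 0) {
    abort(sprintf("Entities with no sequence mapping: %s%s.",
                  paste(head(unmapped, 5), collapse = ", "),
                  if (length(unmapped) > 5) ", ..." else ""))
  }
  joined <- dplyr::inner_join(samples, sequence_map, by = "entity_id")

  agg_one <- function(values, reps) {
    if (method == "flat") mean(values) else mean(tapply(values, reps, mean))
  }
  joined |>
    dplyr::group_by(.data$mirna_id) |>
    dplyr::summarise(
      norm_fib = agg_one(.data$norm_fib, .data$screen_replicate),
      norm_cancer = agg_one(.data$norm_cancer, .data$screen_replicate),
      n_wells = dplyr::n(),
      fib_values = list(.data$norm_fib),
      cancer_values = list(.data$norm_cancer),
      .groups = "drop")
}

#' Select top stimulatory and inhibitory candidate miRNAs
#'
#' Ranks miRNAs by their cancer-channel relative growth and returns the `k`
#' strongest inhibitory (smallest score) and `k` strongest stimulatory
#' (largest score) candidates. Ties are broken deterministically by effect
#' magnitude `|log(score)|` (descending) and then lexicographic miRNA id.
#' If fewer than `2k` miRNAs are scored the lists are truncated (with a
#' warning) and kept disjoint.
#'
#' @param scores Output of [aggregate_scores()].
#' @param k Candidate list size per direction (default 60).
#' @param thresholds Informational fold-change thresholds carried along for
#'   downstream classification (defaults `inhib = 0.9`, `stim = 1.3`).
#' @return A list of class `candidate_lists` with ranked `inhibitory` and
#'   `stimulatory` tibbles.
#' @export
select_candidates <- function(scores, k = 60,
                              thresholds = c(inhib = 0.9, stim = 1.3)) {
  check_columns(scores, c("mirna_id", "norm_cancer"), "Score table")
  k <- check_count(k, "k")
  n <- nrow(scores)
  if (n < 2 * k) {
    warn(sprintf("Only %d scored miRNAs for k = %d; candidate lists truncated.",
                 n, k))
  }
  magnitude <- abs(log(scores$norm_cancer))
  magnitude[!is.finite(magnitude)] <- Inf
  ranked <- scores |>
    dplyr::mutate(.mag = magnitude) |>
    dplyr::select("mirna_id", score = "norm_cancer", ".mag")

  inh <- ranked |>
    dplyr::arrange(.data$score, dplyr::desc(.data$.mag), .data$mirna_id) |>
    head(min(k, n))
  stim <- ranked |>
    dplyr::filter(!.data$mirna_id %in% inh$mirna_id) |>
    dplyr::arrange(dplyr::desc(.data$score), dplyr::desc(.data$.mag),
                   .data$mirna_id) |>
    head(k)
  strip <- function(df) {
    df |>
      dplyr::mutate(rank = dplyr::row_number()) |>
      dplyr::select("rank", "mirna_id", "score")
  }
  structure(list(inhibitory = strip(inh), stimulatory = strip(stim),
                 k = k, thresholds = thresholds),
            class = "candidate_lists")
}

#' @export
print.candidate_lists <- function(x, ...) {
  cat(sprintf("Candidate lists (k = %d): %d inhibitory, %d stimulatory\n",
              x$k, nrow(x$inhibitory), nrow(x$stimulatory)))
  cat("Top inhibitory:\n")
  print(head(x$inhibitory, 5))
  cat("Top stimulatory:\n")
  print(head(x$stimulatory, 5))
  invisible(x)
}

#' Classify miRNAs by their joint effect on both channels
#'
#' Labels each miRNA by comparing its fibroblast- and cancer-channel relative
#' growth against strict fold-change thresholds (`< inhib` is down,
#' `> stim` is up). miRNAs passing neither window on either channel are
#' labelled `"null"`; boundary values are non-hits.
#'
#' @param scores Output of [aggregate_scores()].
#' @param inhib Lower (inhibition) threshold, strict (default 0.9).
#' @param stim Upper (stimulation) threshold, strict (default 1.3).
#' @return `scores` with a `cross_label` factor in
#'   `concordant-down`, `concordant-up`, `fib-down/cancer-up`,
#'   `fib-up/cancer-down`, `null`.
#' @export
classify_cross_channel <- function(scores, inhib = 0.9, stim = 1.3) {
  check_columns(scores, c("mirna_id", "norm_fib", "norm_cancer"),
                "Score table")
  levels <- c("concordant-down", "concordant-up", "fib-down/cancer-up",
              "fib-up/cancer-down", "null")
  scores |>
    dplyr::mutate(cross_label = factor(dplyr::case_when(
      .data$norm_fib < inhib & .data$norm_cancer < inhib ~ "concordant-down",
      .data$norm_fib > stim & .data$norm_cancer > stim ~ "concordant-up",
      .data$norm_fib < inhib & .data$norm_cancer > stim ~ "fib-down/cancer-up",
      .data$norm_fib > stim & .data$norm_cancer < inhib ~ "fib-up/cancer-down",
      TRUE ~ "null"), levels = levels))
}

#' Cross-channel rank concordance of screen scores
#'
#' Spearman correlation between the fibroblast and cancer channel scores,
#' with average-rank tie handling; two-sided p-value by exact permutation for
#' small n and the t approximation otherwise (see [spearman_assoc()]).
#'
#' @param scores Output of [aggregate_scores()].
#' @return A one-row tibble: `rho, p_value, n, method`.
#' @export
channel_correlation <- function(scores) {
  check_columns(scores, c("norm_fib", "norm_cancer"), "Score table")
  res <- spearman_cor(scores$norm_fib, scores$norm_cancer)
  tibble::tibble(rho = res$rho, p_value = res$p_value, n = res$n,
                 method = res$method)
}
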