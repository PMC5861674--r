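#' Score a co-culture screen end to end
#'
#' Convenience wrapper chaining [normalize_plate()], [aggregate_scores()],
#' [select_candidates()], [classify_cross_channel()] and
#' [channel_correlation()].
#'
#' @param wells A validated well table.
#' @param sequence_map Tibble mapping `entity_id` to `mirna_id`.
#' @param k Candidate list size per direction.
#' @param inhib,stim Strict classification thresholds.
#' @param exclude_controls,control_ids Passed to [normalize_plate()].
#' @param method Replicate combination rule for [aggregate_scores()].
#' @return A list with `scores` (classified score table), `candidates`
#'   (a `candidate_lists` object) and `correlation` (one-row tibble).
#' @examples
#' sim <- sim_screen(screen_sim_config(n_mirnas = 30, n_duplicate_entries = 5,
#'                                     plate_capacity = 40, seed = 7))
#' res <- score_screen(sim$wells, sim$sequence_map, k = 5)
#' res$correlation
#' @export
score_screen <- function(wells, sequence_map, k = 60, inhib = 0.9,
                         stim = 1.3, exclude_controls = TRUE,
                         control_ids = default_control_ids(),
                         method = c("flat", "replicate_mean")) {
  scores <- wells |>
    normalize_plate(exclude_controls = exclude_controls,
                    control_ids = control_ids) |>
    aggregate_scores(sequence_map, method = method,
                     control_ids = control_ids) |>
    classify_cross_channel(inhib = inhib, stim = stim)
  list(scores = scores,
       candidates = select_candidates(scores, k = k,
                                      thresholds = c(inhib = inhib,
                                                     stim = stim)),
       correlation = channel_correlation(scores))
}

#' Cluster candidate miRNAs by consensus targets end to end
#'
#' Convenience wrapper chaining [consensus_targets()], [jaccard_matrix()],
#' [cluster_mirnas()] and [cut_clusters()]. By convention the input
#' prediction table is restricted to the candidate miRNAs of interest
#' (e.g. the top-k stimulatory and inhibitory lists from a screen) before
#' clustering; pass `mirnas` to subset, or leave `NULL` to use all.
#'
#' @param predictions Long prediction table.
#' @param k_min Consensus threshold (algorithms per target).
#' @param mirnas Optional miRNA ids to restrict to.
#' @param metric,linkage Passed to [cluster_mirnas()].
#' @param n_clusters,height Cut rule passed to [cut_clusters()]; when both
#'   are `NULL` no flat cut is made.
#' @return A list with `consensus`, `similarity`, `clusters` and (when cut)
#'   `labels`.
#' @export
cluster_targets <- function(predictions, k_min = 5, mirnas = NULL,
                            metric = c("euclidean-rows", "one-minus-jaccard"),
                            linkage = "average", n_clusters = NULL,
                            height = NULL) {
  if (!is.null(mirnas)) {
    predictions <- dplyr::filter(predictions, .data$mirna_id %in% mirnas)
  }
  consensus <- consensus_targets(predictions, k_min = k_min)
  similarity <- jaccard_matrix(consensus)
  clusters <- cluster_mirnas(similarity, metric = metric, linkage = linkage)
  labels <- if (!is.null(n_clusters) || !is.null(height)) {
    cut_clusters(clusters, n_clusters = n_clusters, height = height)
  }
  list(consensus = consensus, similarity = similarity, clusters = clusters,
       labels = labels)
}
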