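#' Read a long-format miRNA-target prediction table
#'
#' TSV with columns `algorithm_id, mirna_id, gene_id`; one row per predicted
#' interaction per algorithm. Duplicated triples are collapsed (set
#' semantics).
#'
#' @param path Path to a TSV file.
#' @return A tibble of unique (algorithm, miRNA, gene) triples.
#' @export
read_predictions <- function(path) {
  preds <- readr::read_tsv(path, show_col_types = FALSE)
  check_columns(preds, c("algorithm_id", "mirna_id", "gene_id"),
                "Prediction table")
  dplyr::distinct(tibble::as_tibble(preds))
}

#' @rdname read_predictions
#' @param predictions A prediction table.
#' @export
write_predictions <- function(predictions, path) {
  readr::write_tsv(predictions, path)
  invisible(path)
}

#' Consensus target sets across prediction algorithms
#'
#' Keeps, for each miRNA, the genes predicted by at least `k_min` distinct
#' algorithms (default 5 of 6). miRNAs whose consensus is empty are retained
#' with empty sets rather than dropped. Gene identifiers are opaque strings;
#' no symbol mapping is attempted.
#'
#' @param predictions Long prediction table
#'   (`algorithm_id, mirna_id, gene_id`).
#' @param k_min Minimum number of supporting algorithms.
#' @param algorithms Optional vector of allowed algorithm ids; unknown ids in
#'   the table raise an error. Defaults to the ids present in the table.
#' @return An object of class `consensus_sets`: a named list of gene-id
#'   vectors plus `k_min`/`m` metadata. Use [tidy()] for a long tibble.
#' @export
consensus_targets <- function(predictions, k_min = 5, algorithms = NULL) {
  check_columns(predictions, c("algorithm_id", "mirna_id", "gene_id"),
                "Prediction table")
  k_min <- check_count(k_min, "k_min")
  seen <- unique(predictions$algorithm_id)
  if (!is.null(algorithms)) {
    unknown <- setdiff(seen, algorithms)
    if (length(unknown) > 0) {
      abort(sprintf("Unknown algorithm id(s): %s.",
                    paste(unknown, collapse = ", ")))
    }
  } else {
    algorithms <- seen
  }
  m <- length(algorithms)
  if (m < k_min) {
    abort(sprintf("k_min = %d exceeds the number of algorithms (%d).",
                  k_min, m))
  }

  mirnas <- sort(unique(predictions$mirna_id))
  kept <- predictions |>
    dplyr::distinct(.data$algorithm_id, .data$mirna_id, .data$gene_id) |>
    dplyr::count(.data$mirna_id, .data$gene_id, name = "n_algorithms") |>
    dplyr::filter(.data$n_algorithms >= k_min)
  sets <- split(kept$gene_id, factor(kept$mirna_id, levels = mirnas))
  sets <- lapply(sets, function(g) sort(unique(g)))

  structure(list(sets = sets, k_min = k_min, m = m, algorithms = algorithms),
            class = "consensus_sets")
}

#' @export
print.consensus_sets <- function(x, ...) {
  sizes <- lengths(x$sets)
  cat(sprintf(
    "Consensus target sets (>= %d of %d algorithms): %d miRNAs, %d empty\n",
    x$k_min, x$m, length(x$sets), sum(sizes == 0)))
  cat(sprintf("Set sizes: min %d, median %s, max %d\n",
              min(sizes), format(median(sizes)), max(sizes)))
  invisible(x)
}

#' @export
tidy.consensus_sets <- function(x, ...) {
  tibble::tibble(
    mirna_id = rep(names(x$sets), lengths(x$sets)),
    gene_id = unlist(x$sets, use.names = FALSE))
}

#' Pairwise Jaccard similarity of target sets
#'
#' For each pair of miRNAs computes `J(A, B) = |A ∩ B| / |A ∪ B|`
#' over their consensus target sets. Two empty sets have `J = 0` off the
#' diagonal; the diagonal is 1 by convention (including empty sets).
#'
#' @param sets A [consensus_targets()] result or a named list of gene-id
#'   vectors.
#' @return A symmetric numeric matrix with miRNA ids as dimnames.
#' @export
jaccard_matrix <- function(sets) {
  if (inherits(sets, "consensus_sets")) sets <- sets$sets
  if (is.null(names(sets)) || anyDuplicated(names(sets))) {
    abort("`sets` must be a uniquely named list of gene-id vectors.")
  }
  n <- length(sets)
  genes <- unique(unlist(sets, use.names = FALSE))
  if (length(genes) == 0) {
    J <- matrix(0, n, n, dimnames = list(names(sets), names(sets)))
    diag(J) <- 1
    return(J)
  }
  M <- matrix(0, n, length(genes), dimnames = list(names(sets), genes))
  for (i in seq_len(n)) M[i, match(unique(sets[[i]]), genes)] <- 1
  inter <- tcrossprod(M)
  sizes <- rowSums(M)
  union <- outer(sizes, sizes, "+") - inter
  J <- ifelse(union > 0, inter / union, 0)
  diag(J) <- 1
  J
}

#' Hierarchically cluster miRNAs by target-set similarity
#'
#' Agglomerative (average-linkage by default) clustering of miRNAs from
#' their Jaccard similarity matrix. The default row metric follows the
#' convention of clustering the similarity matrix itself: Euclidean distance
#' between rows of the Jaccard matrix. The more conventional `1 - J`
#' dissimilarity is available as `"one-minus-jaccard"`.
#'
#' @param similarity A square symmetric Jaccard matrix from
#'   [jaccard_matrix()].
#' @param metric `"euclidean-rows"` (Euclidean distance between similarity
#'   rows) or `"one-minus-jaccard"`.
#' @param linkage Agglomeration rule passed to [stats::hclust()]
#'   (default `"average"`).
#' @return An object of class `mirna_clusters` wrapping the merge tree;
#'   see [tidy.mirna_clusters()], [cut_clusters()], [write_newick()].
#' @export
cluster_mirnas <- function(similarity,
                           metric = c("euclidean-rows", "one-minus-jaccard"),
                           linkage = "average") {
  metric <- match.arg(metric)
  if (!is.matrix(similarity) || nrow(similarity) != ncol(similarity)) {
    abort("`similarity` must be a square matrix.")
  }
  if (nrow(similarity) < 2) abort("Clustering needs at least 2 miRNAs.")
  if (max(abs(similarity - t(similarity))) > 1e-8) {
    abort("`similarity` must be symmetric.")
  }
  d <- switch(metric,
              "euclidean-rows" = dist(similarity),
              "one-minus-jaccard" = as.dist(1 - similarity))
  hc <- hclust(d, method = linkage)
  structure(list(hclust = hc, metric = metric, linkage = linkage,
                 labels = rownames(similarity)),
            class = "mirna_clusters")
}

#' @export
print.mirna_clusters <- function(x, ...) {
  cat(sprintf("miRNA cluster tree: %d leaves, %s linkage, metric %s\n",
              length(x$labels), x$linkage, x$metric))
  invisible(x)
}

#' @export
as.hclust.mirna_clusters <- function(x, ...) x$hclust

#' Tidy the merge tree of a miRNA clustering
#'
#' One row per agglomeration step, in [stats::hclust()] merge convention
#' (negative entries are leaves, positive entries earlier merges).
#'
#' @param x A `mirna_clusters` object.
#' @param ... Unused.
#' @return A tibble with `step, merge1, merge2, height`.
#' @export
tidy.mirna_clusters <- function(x, ...) {
  hc <- x$hclust
  tibble::tibble(step = seq_len(nrow(hc$merge)),
                 merge1 = hc$merge[, 1], merge2 = hc$merge[, 2],
                 height = hc$height)
}

#' @export
glance.mirna_clusters <- function(x, ...) {
  tibble::tibble(n_leaves = length(x$labels), metric = x$metric,
                 linkage = x$linkage, max_height = max(x$hclust$height))
}

#' Cut a miRNA cluster tree into flat groups
#'
#' @param clusters A [cluster_mirnas()] result.
#' @param n_clusters Desired number of flat clusters, or
#' @param height Cut height (give exactly one of the two).
#' @return A tibble `mirna_id, cluster` (integer labels; singletons allowed).
#' @export
cut_clusters <- function(clusters, n_clusters = NULL, height = NULL) {
  stopifnot(inherits(clusters, "mirna_clusters"))
  if (is.null(n_clusters) == is.null(height)) {
    abort("Give exactly one of `n_clusters` or `height`.")
  }
  labels <- if (!is.null(n_clusters)) {
    cutree(clusters$hclust, k = n_clusters)
  } else {
    cutree(clusters$hclust, h = height)
  }
  tibble::tibble(mirna_id = names(labels), cluster = unname(labels))
}

#' Annotate miRNAs with seed families
#'
#' The seed region (nucleotides 2-8 of the mature sequence) is the primary
#' determinant of target recognition; miRNAs sharing it form a family.
#' Accepts either sequences (a named character vector or a tibble with
#' `mirna_id, sequence`) or a precomputed family map (tibble with
#' `mirna_id, family`), which is validated and passed through.
#'
#' @param x Sequences or family map (see Details).
#' @return A tibble `mirna_id, seed, family` (seed `NA` when a map was
#'   supplied).
#' @export
annotate_seed_families <- function(x) {
  if (is.character(x)) {
    if (is.null(names(x))) abort("Sequence vector must be named by miRNA id.")
    x <- tibble::tibble(mirna_id = names(x), sequence = unname(x))
  }
  if (!is.data.frame(x)) abort("`x` must be sequences or a family map.")
  if ("family" %in% names(x)) {
    check_columns(x, c("mirna_id", "family"), "Family map")
    return(tibble::tibble(mirna_id = x$mirna_id, seed = NA_character_,
                          family = as.character(x$family)))
  }
  check_columns(x, c("mirna_id", "sequence"), "Sequence table")
  too_short <- which(nchar(x$sequence) < 8)
  if (length(too_short) > 0) {
    abort(sprintf("Sequence shorter than 8 nt for: %s.",
                  paste(head(x$mirna_id[too_short], 5), collapse = ", ")))
  }
  seed <- chartr("Uu", "Tt", toupper(substr(x$sequence, 2, 8)))
  tibble::tibble(mirna_id = x$mirna_id, seed = seed,
                 family = sprintf("family-%02d", match(seed, unique(seed))))
}

#' Read mature miRNA sequences from a FASTA file
#'
#' @param path FASTA of mature miRNA sequences (RNA or DNA alphabet).
#' @return A tibble `mirna_id, sequence` suitable for
#'   [annotate_seed_families()].
#' @export
read_mirna_fasta <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    abort("Reading FASTA requires the Biostrings package.")
  }
  seqs <- Biostrings::readBStringSet(path)
  tibble::tibble(mirna_id = sub("\\s.*$", "", names(seqs)),
                 sequence = as.character(seqs))
}

#' Export a cluster tree as a Newick string
#'
#' Merge heights become branch lengths via [ape::as.phylo()].
#'
#' @param clusters A [cluster_mirnas()] result.
#' @param path Optional output file; when `NULL` the Newick string is
#'   returned.
#' @return The Newick string (invisibly when written to `path`).
#' @export
write_newick <- function(clusters, path = NULL) {
  stopifnot(inherits(clusters, "mirna_clusters"))
  phy <- ape::as.phylo(clusters$hclust)
  if (is.null(path)) {
    ape::write.tree(phy)
  } else {
    ape::write.tree(phy, file = path)
    invisible(ape::write.tree(phy))
  }
}
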