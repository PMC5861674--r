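test_that("consensus filtering keeps genes with enough algorithm support", {
  algos <- sprintf("A%d", 1:6)
  preds <- dplyr::bind_rows(
    tibble::tibble(algorithm_id = algos[1:5], mirna_id = "m1",
                   gene_id = "g_keep"),
    tibble::tibble(algorithm_id = algos[1:4], mirna_id = "m1",
                   gene_id = "g_drop"))
  cons <- consensus_targets(preds, k_min = 5)
  expect_equal(cons$sets$m1, "g_keep")

  # k_min = 1 is the union over algorithms
  cons1 <- consensus_targets(preds, k_min = 1)
  expect_setequal(cons1$sets$m1, c("g_keep", "g_drop"))

  expect_error(consensus_targets(preds, k_min = 5, algorithms = algos[1:4]),
               "Unknown algorithm")
  expect_error(consensus_targets(preds[1:5, ], k_min = 6), "exceeds")
})

test_that("consensus equals a nested-loop count oracle on random tables", {
  set.seed(7)
  algos <- sprintf("A%d", 1:6)
  for (rep in 1:5) {
    preds <- tibble::tibble(
      algorithm_id = sample(algos, 300, replace = TRUE),
      mirna_id = sample(sprintf("m%d", 1:5), 300, replace = TRUE),
      gene_id = sample(sprintf("g%d", 1:20), 300, replace = TRUE)) |>
      dplyr::distinct()
    k_min <- sample(2:5, 1)
    cons <- consensus_targets(preds, k_min = k_min, algorithms = algos)
    for (m in unique(preds$mirna_id)) {
      expected <- character(0)
      for (g in unique(preds$gene_id)) {
        support <- sum(vapply(algos, function(a) {
          any(preds$algorithm_id == a & preds$mirna_id == m &
                preds$gene_id == g)
        }, logical(1)))
        if (support >= k_min) expected <- c(expected, g)
      }
      expect_setequal(cons$sets[[m]], expected)
    }
    # monotone: raising k_min never adds a gene
    tighter <- consensus_targets(preds, k_min = k_min + 1, algorithms = algos)
    for (m in names(cons$sets)) {
      expect_true(all(tighter$sets[[m]] %in% cons$sets[[m]]))
    }
  }
})

test_that("Jaccard matrix matches hand counts and conventions", {
  sets <- list(a = c("g1", "g2", "g3", "g4"),
               b = c("g1", "g2", "g5", "g6", "g7", "g8"),
               empty = character(0))
  J <- jaccard_matrix(sets)
  expect_equal(J["a", "b"], 2 / 8)            # |int| 2, |union| 8
  expect_equal(J["a", "a"], 1)
  expect_equal(J["a", "empty"], 0)
  expect_equal(J["empty", "empty"], 1)        # diagonal convention
  expect_true(isSymmetric(J))
})

test_that("Jaccard is label- and order-invariant, and 1-J is a metric", {
  set.seed(8)
  universe <- sprintf("g%02d", 1:30)
  rand_sets <- function() {
    lapply(setNames(1:4, c("w", "x", "y", "z")), function(i) {
      sample(universe, sample(0:12, 1))
    })
  }
  for (rep in 1:20) {
    sets <- rand_sets()
    J <- jaccard_matrix(sets)
    # gene relabeling
    relab <- lapply(sets, function(s) {
      if (length(s)) paste0("RE_", s) else s
    })
    expect_equal(jaccard_matrix(relab), J)
    # miRNA order permutation
    perm <- sample(names(sets))
    expect_equal(jaccard_matrix(sets[perm])[names(sets), names(sets)], J)
    # triangle inequality of the 1-J dissimilarity
    D <- 1 - J
    for (i in 1:4) for (j in 1:4) for (k in 1:4) {
      expect_lte(D[i, j], D[i, k] + D[k, j] + 1e-12)
    }
  }
})

test_that("average-linkage tree matches the naive agglomeration oracle", {
  set.seed(9)
  # two identical rows merge first at distance zero
  S <- diag(4)
  S[1, 2] <- S[2, 1] <- 0.5
  S[3, ] <- S[1, ]
  S[, 3] <- S[, 1]
  S[3, 3] <- 1
  S[1, 3] <- S[3, 1] <- 1
  dimnames(S) <- list(letters[1:4], letters[1:4])
  # rows 1 and 3 of the matrix are identical -> Euclidean distance 0
  cl <- cluster_mirnas(S)
  expect_equal(cl$hclust$height[1], 0)
  first <- sort(-cl$hclust$merge[1, ])
  expect_equal(first, c(1, 3))

  # 5-point random fixtures vs the O(n^3) oracle
  for (rep in 1:10) {
    M <- matrix(runif(25), 5, 5)
    S <- (M + t(M)) / 2
    diag(S) <- 1
    dimnames(S) <- list(letters[1:5], letters[1:5])
    cl <- cluster_mirnas(S, metric = "euclidean-rows")
    D <- as.matrix(dist(S))
    oracle <- average_linkage_oracle(D)
    got <- hclust_steps(cl$hclust)
    for (s in seq_along(oracle)) {
      expect_equal(got[[s]]$sets, oracle[[s]]$sets)
      expect_equal(got[[s]]$height, oracle[[s]]$height, tolerance = 1e-9)
    }
  }

  expect_error(cluster_mirnas(S[1, 1, drop = FALSE]), "at least 2")
})

test_that("planted family blocks are recovered by the default cut", {
  sim <- sim_predictions(n_mirnas = 12, n_genes = 200, n_families = 2,
                         core_targets_per_family = 15,
                         private_targets_per_mirna = 3,
                         per_algo_dropout = 0, per_algo_fp = 0, seed = 12)
  res <- cluster_targets(sim$predictions, k_min = 5, n_clusters = 2)
  truth <- sim$truth$families
  got <- res$labels$cluster[match(truth$mirna_id, res$labels$mirna_id)]
  expect_equal(ari(got, truth$family), 1)
})

test_that("cluster cuts and label partitions behave at the extremes", {
  set.seed(10)
  M <- matrix(runif(36), 6, 6)
  S <- (M + t(M)) / 2
  diag(S) <- 1
  dimnames(S) <- list(letters[1:6], letters[1:6])
  cl <- cluster_mirnas(S)
  expect_equal(dplyr::n_distinct(cut_clusters(cl, n_clusters = 6)$cluster), 6)
  expect_equal(dplyr::n_distinct(cut_clusters(cl, n_clusters = 1)$cluster), 1)
  expect_error(cut_clusters(cl), "exactly one")

  # permutation invariance up to relabeling
  perm <- sample(6)
  cl2 <- cluster_mirnas(S[perm, perm])
  l1 <- cut_clusters(cl, n_clusters = 3)
  l2 <- cut_clusters(cl2, n_clusters = 3)
  merged <- dplyr::inner_join(l1, l2, by = "mirna_id")
  expect_equal(ari(merged$cluster.x, merged$cluster.y), 1)
})

test_that("seed families come from nucleotides 2-8 of the mature sequence", {
  seqs <- c(m1 = "UAGCAGCACGUAAAUAUUGGCG",   # shares seed with m2, m3
            m2 = "UAGCAGCACAGAAAUAUUGGC",
            m3 = "UAGCAGCACAUAAUGGUUUGUG",
            m4 = "ACUGCAUUAUGAGCACUUAAAG")
  fam <- annotate_seed_families(seqs)
  expect_equal(fam$seed[1], "AGCAGCA")
  expect_equal(fam$family[1], fam$family[2])
  expect_equal(fam$family[2], fam$family[3])
  expect_false(fam$family[4] == fam$family[1])

  expect_error(annotate_seed_families(c(bad = "UAGCAG")), "shorter than 8")

  # precomputed map passes through
  map <- tibble::tibble(mirna_id = c("a", "b"), family = c("f1", "f1"))
  expect_equal(annotate_seed_families(map)$family, c("f1", "f1"))
})

test_that("cluster tree exports to Newick with merge heights", {
  sets <- list(a = c("g1", "g2"), b = c("g1", "g2"), c = c("g9", "g8"),
               d = c("g9", "g7"))
  cl <- cluster_mirnas(jaccard_matrix(sets))
  nwk <- write_newick(cl)
  expect_match(nwk, "^\\(")
  phy <- ape::read.tree(text = nwk)
  expect_setequal(phy$tip.label, names(sets))
})
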