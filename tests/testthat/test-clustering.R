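# two tight groups of near-identical sequences, for separation checks
two_group_set <- function() {
  seq_set(c("AAAAA", "AAAAA", "AAAAC", "SSSSS", "SSSSS", "SSSSG"),
          ids = paste0("g", 1:6), frame_length = 5)
}

test_that("k-medoids separates zero-distance groups and handles k = n", {
  ss <- seq_set(c("AAAA", "AAAA", "SSSS", "SSSS"), frame_length = 4)
  d <- pairwise_distances(ss)
  cl <- run_clustering(d, "k-medoids", k = 2)
  expect_equal(n_clusters(cl), 2)
  expect_equal(cl$labels[["s1"]], cl$labels[["s2"]])
  expect_equal(cl$labels[["s3"]], cl$labels[["s4"]])
  expect_false(cl$labels[["s1"]] == cl$labels[["s3"]])

  cln <- run_clustering(d, "k-medoids", k = 4)
  expect_equal(sort(unname(cln$labels)), 0:3)
  expect_setequal(unname(cln$medoids), sample_ids(ss))

  expect_error(run_clustering(d, "k-medoids", k = 0), "0 < k")
  expect_error(run_clustering(d, "k-medoids", k = 5), "0 < k")
})

test_that("agglomerative matches the exhaustive 2-partition oracle", {
  ss <- two_group_set()
  d <- pairwise_distances(ss)
  cl <- run_clustering(d, "agglomerative", k = 2, linkage = "complete")
  # brute force: all 2-partitions, minimize the complete-linkage objective
  # (largest within-cluster distance, then sum as tie-break)
  ids <- sample_ids(ss)
  best <- NULL; best_obj <- c(Inf, Inf)
  for (mask in 1:(2^5 - 1)) {   # s1 fixed in group 0 to kill symmetry
    grp <- c(0L, as.integer(intToBits(mask))[1:5])
    obj <- c(0, 0)
    for (g in 0:1) {
      m <- ids[grp == g]
      if (length(m) > 1) {
        dd <- d$d[m, m]
        obj <- obj + c(0, sum(dd) / 2)
        obj[1] <- max(obj[1], max(dd))
      }
    }
    if (obj[1] < best_obj[1] ||
        (obj[1] == best_obj[1] && obj[2] < best_obj[2])) {
      best_obj <- obj; best <- setNames(grp, ids)
    }
  }
  expect_equal(rand_index(cl$labels, best), 1)
})

test_that("compute_medoids minimizes total distance with declared ties", {
  d1 <- dist_matrix("x", matrix(0, 1, 1))
  expect_equal(compute_medoids(setNames(0L, "x"), d1), c("0" = "x"))

  dm <- matrix(c(0, 1, 1, 1, 0, 4, 1, 4, 0), 3,
               dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  d <- dist_matrix(c("x", "y", "z"), dm)
  labs <- setNames(rep(0L, 3), c("x", "y", "z"))
  expect_equal(compute_medoids(labs, d), c("0" = "x"))
  expect_equal(compute_medoids(labs, d)[["0"]], medoid_exhaustive(c("x", "y", "z"), dm))

  # all pairwise distances equal -> lexicographically smallest id
  eq <- matrix(1, 3, 3, dimnames = list(c("c", "a", "b"), c("c", "a", "b")))
  diag(eq) <- 0
  expect_equal(compute_medoids(setNames(rep(0L, 3), c("c", "a", "b")),
                               dist_matrix(c("c", "a", "b"), eq)),
               c("0" = "a"))

  expect_error(compute_medoids(setNames(c(0L, 2L), c("x", "y")),
                               d["x"]), "missing")
})

test_that("medoids match exhaustive search on random clusters", {
  set.seed(11)
  for (rep in 1:15) {
    n <- sample(3:12, 1)
    ss <- seq_set(replicate(n, paste(sample(aa_alphabet(), 6, TRUE),
                                     collapse = "")), frame_length = 6)
    d <- pairwise_distances(ss)
    labs <- setNames(rep(0L, n), sample_ids(ss))
    expect_equal(compute_medoids(labs, d)[["0"]],
                 medoid_exhaustive(sample_ids(ss), d$d))
  }
})

test_that("silhouette matches trivial cases, the hand oracle and cluster::silhouette", {
  # two clusters of two identical points, between-cluster distance 1
  dm <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  dm[c("a", "b"), c("c", "d")] <- 1
  dm[c("c", "d"), c("a", "b")] <- 1
  d <- dist_matrix(letters[1:4], dm)
  cl <- clustering(setNames(c(0L, 0L, 1L, 1L), letters[1:4]),
                   c("0" = "a", "1" = "c"), "fixture")
  expect_equal(evaluate_clustering(cl, d, "silhouette"), 1)

  set.seed(5)
  ss <- seq_set(replicate(8, paste(sample(aa_alphabet(), 6, TRUE),
                                   collapse = "")), frame_length = 6)
  d8 <- pairwise_distances(ss)
  cl8 <- run_clustering(d8, "k-medoids", k = 2)
  s_pkg <- evaluate_clustering(cl8, d8, "silhouette")
  expect_equal(s_pkg, silhouette_oracle(cl8$labels, d8$d))
  sil <- cluster::silhouette(cl8$labels + 1L, dmatrix = d8$d)
  expect_equal(s_pkg, mean(sil[, "sil_width"]))

  single <- clustering(setNames(rep(0L, 4), letters[1:4]), c("0" = "a"),
                       "fixture")
  expect_error(evaluate_clustering(single, d, "silhouette"),
               "fewer than two")
})

test_that("davies-bouldin works on features and rejects distances", {
  set.seed(2)
  x <- rbind(matrix(rnorm(20, 0), 10), matrix(rnorm(20, 6), 10))
  rownames(x) <- paste0("p", 1:20)
  labs <- setNames(rep(0:1, each = 10), rownames(x))
  cl <- clustering(labs, c("0" = "p1", "1" = "p11"), "fixture")
  db <- evaluate_clustering(cl, x, "davies-bouldin")
  expect_gte(db, 0)
  # manual check of the formula
  s0 <- mean(sqrt(rowSums(sweep(x[1:10, ], 2, colMeans(x[1:10, ]))^2)))
  s1 <- mean(sqrt(rowSums(sweep(x[11:20, ], 2, colMeans(x[11:20, ]))^2)))
  m01 <- sqrt(sum((colMeans(x[1:10, ]) - colMeans(x[11:20, ]))^2))
  expect_equal(db, (s0 + s1) / m01)
  d <- dist_matrix(rownames(x), as.matrix(dist(x)))
  expect_error(evaluate_clustering(cl, d, "davies-bouldin"),
               "vector features")
})

test_that("OPTICS labels dense groups and flags noise", {
  ss <- seq_set(c("AAAAAA", "AAAAAC", "AAAAAG", "SSSSSS", "SSSSSC",
                  "SSSSSG", "CDEFGH"),
                ids = paste0("o", 1:7), frame_length = 6)
  d <- pairwise_distances(ss)
  cl <- run_clustering(d, "optics", eps = 2.5, min_pts = 2)
  expect_equal(n_clusters(cl), 2)
  expect_equal(cl$labels[["o7"]], -1L)                   # isolated = noise
  expect_equal(length(unique(cl$labels[paste0("o", 1:3)])), 1)
  expect_equal(length(unique(cl$labels[paste0("o", 4:6)])), 1)
  expect_false("o7" %in% cl$medoids)                     # no noise medoid
})

test_that("birch clusters features and rejects precomputed distances", {
  set.seed(3)
  x <- rbind(matrix(rnorm(30, 0, 0.1), 15), matrix(rnorm(30, 5, 0.1), 15))
  rownames(x) <- paste0("b", 1:30)
  cl <- run_clustering(x, "birch", k = 2, threshold = 1)
  expect_equal(n_clusters(cl), 2)
  expect_equal(length(unique(cl$labels[paste0("b", 1:15)])), 1)
  d <- dist_matrix(rownames(x), as.matrix(dist(x)))
  expect_error(run_clustering(d, "birch", k = 2),
               "incompatible with a precomputed distance")
})

test_that("the hyperparameter sweep picks the best silhouette", {
  ss <- two_group_set()
  d <- pairwise_distances(ss)
  best <- sweep_clustering(d, "agglomerative", grid = 2:5)
  expect_equal(n_clusters(best), 2)   # true structure wins the sweep
  tab <- attr(best, "sweep")
  expect_equal(nrow(tab), 4)
  expect_equal(best$criterion_scores[["silhouette"]], max(tab$score))
})

test_that("consensus clustering is invariant to relabeling and matches the oracle", {
  ss <- two_group_set()
  d <- pairwise_distances(ss)
  ids <- sample_ids(ss)
  c1 <- clustering(setNames(c(0L, 0L, 0L, 1L, 1L, 1L), ids),
                   c("0" = "g1", "1" = "g4"), "fixture")
  c2 <- clustering(setNames(c(1L, 1L, 1L, 0L, 0L, 0L), ids),
                   c("1" = "g1", "0" = "g4"), "fixture")  # permuted labels
  cons <- consensus_clustering(list(c1, c2), d)
  expect_equal(rand_index(cons$labels, c1$labels), 1)

  c3 <- clustering(setNames(c(0L, 0L, 1L, 1L, 2L, 2L), ids),
                   c("0" = "g1", "1" = "g3", "2" = "g5"), "fixture")
  cons3 <- consensus_clustering(list(c1, c2, c3), d)
  # oracle: hand co-association + naive average linkage, k = floor(median(2,2,3))
  co <- matrix(0, 6, 6, dimnames = list(ids, ids))
  for (cl in list(c1, c2, c3)) {
    for (i in ids) for (j in ids) {
      if (cl$labels[[i]] == cl$labels[[j]]) co[i, j] <- co[i, j] + 1 / 3
    }
  }
  oracle <- average_linkage_oracle(1 - co, k = 2)
  expect_equal(rand_index(cons3$labels, oracle), 1)

  c_bad <- clustering(setNames(0L, "zz"), c("0" = "zz"), "fixture")
  expect_error(consensus_clustering(list(c1, c_bad)), "different id sets")
  expect_error(consensus_clustering(list(c1)), "at least two")
})

test_that("2-D projections are reproducible and separate far groups", {
  set.seed(8)
  base1 <- sample(aa_alphabet()[1:5], 10, TRUE)
  base2 <- sample(aa_alphabet()[15:20], 10, TRUE)
  mk <- function(base) paste(base, collapse = "")
  seqs <- c(replicate(6, mk(base1)), replicate(6, mk(base2)))
  ss <- seq_set(seqs, frame_length = 10)
  d <- pairwise_distances(ss)
  p1 <- project_2d(d, "tsne", seed = 4, perplexity = 3)
  p2 <- project_2d(d, "tsne", seed = 4, perplexity = 3)
  expect_identical(p1, p2)
  g1 <- p1[1:6, , drop = FALSE]; g2 <- p1[7:12, , drop = FALSE]
  spread <- function(g) mean(sqrt(rowSums(sweep(g, 2, colMeans(g))^2)))
  between <- sqrt(sum((colMeans(g1) - colMeans(g2))^2))
  expect_lt(spread(g1), between)
  expect_lt(spread(g2), between)

  one <- project_2d(pairwise_distances(seq_set("CASS", frame_length = 4)))
  expect_equal(nrow(one), 1)

  x <- matrix(rnorm(40), 20, 2, dimnames = list(paste0("p", 1:20), NULL))
  l1 <- project_2d(x, "lle", n_neighbors = 5)
  l2 <- project_2d(x, "lle", n_neighbors = 5)
  expect_identical(l1, l2)
  expect_error(project_2d(d, "lle"), "vector features")
})

test_that("clusterings round-trip through the stage table", {
  ss <- two_group_set()
  d <- pairwise_distances(ss)
  cl <- run_clustering(d, "agglomerative", k = 2, split = "binding")
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_clustering(cl, tf)
  back <- read_clustering(tf)
  expect_equal(back$labels, cl$labels)
  expect_equal(back$medoids, cl$medoids)
  expect_equal(back$split, "binding")
})
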