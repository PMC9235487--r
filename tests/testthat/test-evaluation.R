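# a hand-built 8-sample world: position 0 tags the cluster, position 1 the
# split (A*/C* binding clusters, F*/S* non-binding clusters)
eight_sample_world <- function() {
  seqs <- c("AAAA", "AAAC", "CCAA", "CCAC", "FFFF", "FFFC", "SSFF", "SSFC")
  ids <- paste0("w", 1:8)
  samples <- seq_set(seqs, ids = ids, frame_length = 4,
                     alphabet = c("A", "C", "F", "S"))
  labels <- rep(c("binding", "non-binding"), each = 4)
  split <- split_by_prediction(samples, labels)
  clusterings <- list(
    "binding" = clustering(
      setNames(c(0L, 0L, 1L, 1L), ids[1:4]),
      c("0" = "w1", "1" = "w3"), "fixture", split = "binding"),
    "non-binding" = clustering(
      setNames(c(0L, 0L, 1L, 1L), ids[5:8]),
      c("0" = "w5", "1" = "w7"), "fixture", split = "non-binding"))
  rules <- list(
    make_rule(0, "A", "binding", cluster = 0L, medoid_id = "w1"),
    make_rule(0, "C", "binding", cluster = 1L, medoid_id = "w3"),
    make_rule(0, "F", "non-binding", "non-binding", 0L, "w5"),
    make_rule(0, "S", "non-binding", "non-binding", 1L, "w7"))
  list(samples = samples, split = split, clusterings = clusterings,
       rules = rules)
}

test_that("a perfect rule set scores 1 everywhere at CL", {
  w <- eight_sample_world()
  m <- level_metrics(w$rules, w$samples, w$split, w$clusterings, "CL")
  expect_true(all(m$accuracy == 1))
  expect_true(all(m$precision == 1))
  expect_true(all(m$recall == 1))
})

test_that("CL 'only' semantics disqualifies doubly-covered samples", {
  w <- eight_sample_world()
  # duplicate the first rule under the other binding cluster: every A* sample
  # now satisfies two rules and is a CL true positive for neither
  rules <- w$rules
  rules[[5]] <- make_rule(0, "A", "binding", cluster = 1L, medoid_id = "w3")
  m <- suppressWarnings(
    level_metrics(rules, w$samples, w$split, w$clusterings, "CL"))
  expect_equal(m$tp[m$scope == "binding/c0"][1], 0)
  # inclusive variant keeps them
  mi <- level_metrics(rules, w$samples, w$split, w$clusterings, "CL",
                      cl_exclusive = FALSE)
  expect_equal(mi$tp[mi$scope == "binding/c0"][1], 2)
})

test_that("all levels match the brute-force enumerator on the 8-sample world", {
  w <- eight_sample_world()
  for (level in c("CL", "CS", "SP")) {
    m <- level_metrics(w$rules, w$samples, w$split, w$clusterings, level)
    oracle <- brute_level_metrics(w$rules, w$samples, w$split, w$clusterings,
                                  level)
    for (i in seq_len(nrow(m))) {
      expect_equal(unname(unlist(m[i, c("tp", "fp", "tn", "fn")])),
                   unname(oracle[[i]]), info = paste(level, i))
    }
  }
})

test_that("metric levels match the enumerator on random fixtures", {
  for (seed in 1:30) {
    f <- random_metric_fixture(seed)
    for (level in c("CL", "CS", "SP")) {
      m <- suppressWarnings(
        level_metrics(f$rules, f$samples, f$split, f$clusterings, level))
      oracle <- brute_level_metrics(f$rules, f$samples, f$split,
                                    f$clusterings, level)
      for (i in seq_len(nrow(m))) {
        expect_equal(unname(unlist(m[i, c("tp", "fp", "tn", "fn")])),
                     unname(oracle[[i]]),
                     info = paste("seed", seed, level, i))
      }
    }
  }
})

test_that("zero denominators give NA with a warning, never 0", {
  ss <- seq_set(c("AAAA", "CCCC"), frame_length = 4,
                alphabet = c("A", "C"))
  split <- split_by_prediction(ss, c("binding", "binding"))
  rules <- list(make_rule(0, "W", "non-binding", "non-binding", 0L))
  expect_warning(
    expect_warning(m <- level_metrics(rules, ss, split, NULL, "CS"),
                   "zero denominator"))
  expect_true(is.na(m$precision[1]))   # no sample satisfies the rule
})

test_that("predicate overlap counts matching sub-rules", {
  a <- make_rule(c(0, 2, 5), c("C", "A", "S"))
  expect_equal(predicate_overlap(a, a), 3)
  b <- make_rule(c(1, 3), c("C", "A"))
  expect_equal(predicate_overlap(a, b), 0)          # disjoint positions
  c_ <- make_rule(c(0, 2), c("C", "S"))
  expect_equal(predicate_overlap(a, c_), 1)         # same pos, one symbol off
  d <- make_rule(0, "F")
  expect_equal(predicate_overlap(a, d), 0)          # same position, != symbol
})

test_that("cofulfillment matches enumeration and orders non-binding first", {
  w <- eight_sample_world()
  om <- overlap_matrices(w$rules, w$samples)
  expect_equal(om$rule_ids,
               c("non-binding/c0", "non-binding/c1", "binding/c0",
                 "binding/c1"))
  reordered <- w$rules[c(3, 4, 1, 2)]
  expect_equal(unname(om$cofulfillment), brute_cofulfillment(reordered, w$samples))
  expect_equal(unname(om$predicate_overlap), brute_predicate_overlap(reordered))
  expect_equal(unname(diag(om$cofulfillment)), rep(2L, 4))  # fulfillment counts

  # rules conflicting at a shared position can never co-fire
  conflict <- list(make_rule(0, "A", cluster = 0L),
                   make_rule(0, "C", cluster = 1L))
  cm <- cofulfillment_matrix(conflict, w$samples)
  expect_equal(cm[1, 2], 0L)
})

test_that("completeness histogram counts applicable anchors per sample", {
  w <- eight_sample_world()
  h0 <- completeness_histogram(list(), w$samples)
  expect_equal(h0$n_samples[h0$n_anchors == 0], 8)

  h1 <- completeness_histogram(w$rules, w$samples)
  expect_equal(h1$n_samples[h1$n_anchors == 1], 8)  # exactly one rule each
  expect_equal(sum(h1$n_samples), 8)

  # weighted bin sum == trace of the cofulfillment matrix
  for (seed in 31:40) {
    f <- random_metric_fixture(seed)
    h <- completeness_histogram(f$rules, f$samples)
    cm <- cofulfillment_matrix(f$rules, f$samples)
    expect_equal(sum(h$n_anchors * h$n_samples), sum(diag(cm)))
    expect_equal(sum(h$n_samples), n_samples(f$samples))
  }
})

test_that("SP recall dominates every per-rule CS recall within a split", {
  for (seed in 41:55) {
    f <- random_metric_fixture(seed)
    cs <- suppressWarnings(
      level_metrics(f$rules, f$samples, f$split, f$clusterings, "CS"))
    sp <- suppressWarnings(
      level_metrics(f$rules, f$samples, f$split, f$clusterings, "SP"))
    for (s in c("binding", "non-binding")) {
      of_s <- vapply(f$rules, function(r) identical(r$source$split, s),
                     logical(1))
      if (!any(of_s)) next
      cs_rec <- cs$recall[of_s]
      sp_rec <- sp$recall[sp$scope == s]
      if (all(is.na(cs_rec)) || is.na(sp_rec)) next
      expect_gte(sp_rec, max(cs_rec, na.rm = TRUE))
    }
  }
})

test_that("rules referencing unknown clusters are rejected", {
  w <- eight_sample_world()
  bad <- list(make_rule(0, "A", "binding", cluster = 9L, medoid_id = "w1"))
  expect_error(level_metrics(bad, w$samples, w$split, w$clusterings, "CL"),
               "unknown cluster")
})

test_that("reports bundle metrics and write delimited tables", {
  w <- eight_sample_world()
  rep <- metrics_report(w$rules, w$samples, w$split, w$clusterings)
  expect_s3_class(rep, "metrics_report")
  expect_setequal(unique(rep$metrics$level), c("CL", "CS", "SP"))
  dir <- withr::local_tempdir()
  write_metrics_report(rep, dir)
  expect_true(all(file.exists(file.path(dir, c(
    "metrics.tsv", "overlap_predicates.tsv", "overlap_cofulfillment.tsv",
    "completeness.tsv")))))
  tab <- read.delim(file.path(dir, "metrics.tsv"))
  expect_equal(nrow(tab), 4 + 4 + 2)
})
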