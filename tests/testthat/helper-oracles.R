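# Independent oracles and fixture builders used across the suite.
# Everything here is deliberately naive (loops, enumeration) and shares no
# code path with the package implementation.

# full dynamic-programming edit-distance oracle
lev_dp <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  n <- length(ca); m <- length(cb)
  d <- matrix(0L, n + 1L, m + 1L)
  d[, 1L] <- 0:n
  d[1L, ] <- 0:m
  for (i in seq_len(n)) for (j in seq_len(m)) {
    d[i + 1L, j + 1L] <- min(d[i, j + 1L] + 1L, d[i + 1L, j] + 1L,
                             d[i, j] + (ca[i] != cb[j]))
  }
  d[n + 1L, m + 1L]
}

# exhaustive medoid: loops, no matrix algebra
medoid_exhaustive <- function(members, dm) {
  best <- NULL; best_sum <- Inf
  for (id in sort(members)) {
    s <- 0
    for (other in members) s <- s + dm[id, other]
    if (s < best_sum) { best <- id; best_sum <- s }
  }
  best
}

# per-sample silhouette oracle
silhouette_oracle <- function(labels, dm) {
  ids <- names(labels)
  s <- numeric(length(ids))
  for (i in seq_along(ids)) {
    own <- labels[[i]]
    mine <- ids[labels == own & ids != ids[i]]
    if (!length(mine)) { s[i] <- 0; next }
    a <- mean(sapply(mine, function(j) dm[ids[i], j]))
    b <- Inf
    for (k in setdiff(unique(labels), own)) {
      theirs <- ids[labels == k]
      b <- min(b, mean(sapply(theirs, function(j) dm[ids[i], j])))
    }
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# naive average-linkage agglomeration on a distance matrix, cut at k
average_linkage_oracle <- function(dm, k) {
  ids <- rownames(dm)
  groups <- as.list(ids)
  while (length(groups) > k) {
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_along(groups)) for (j in seq_along(groups)) {
      if (i >= j) next
      d <- mean(dm[groups[[i]], groups[[j]], drop = FALSE])
      if (d < best_d) { best_d <- d; best <- c(i, j) }
    }
    groups[[best[1]]] <- c(groups[[best[1]]], groups[[best[2]]])
    groups[[best[2]]] <- NULL
  }
  labels <- setNames(integer(length(ids)), ids)
  for (g in seq_along(groups)) labels[groups[[g]]] <- g - 1L
  labels
}

rand_index <- function(a, b) {
  ids <- names(a)
  agree <- 0L; total <- 0L
  for (i in seq_along(ids)) for (j in seq_along(ids)) {
    if (i >= j) next
    total <- total + 1L
    same_a <- a[[ids[i]]] == a[[ids[j]]]
    same_b <- b[[ids[i]]] == b[[ids[j]]]
    if (same_a == same_b) agree <- agree + 1L
  }
  agree / total
}

# literal per-(sample, rule) confusion-count enumerator for all three levels
brute_rule_sat <- function(rule, samples) {
  frame <- frame_matrix(samples)
  sapply(seq_len(nrow(frame)), function(i) {
    ok <- TRUE
    p <- rule$predicates
    for (q in seq_len(nrow(p))) {
      if (frame[i, p$position[q] + 1L] != p$symbol[q]) ok <- FALSE
    }
    ok
  })
}

brute_level_metrics <- function(rules, samples, split, clusterings, level,
                                cl_exclusive = TRUE) {
  ids <- sample_ids(samples)
  pred <- split$label_of[ids]
  sat <- sapply(rules, brute_rule_sat, samples = samples)
  if (length(ids) == 1L) sat <- matrix(sat, nrow = 1L)
  rows <- list()
  if (level == "SP") {
    for (s in c("binding", "non-binding")) {
      tp <- fp <- tn <- fn <- 0L
      for (i in seq_along(ids)) {
        any_s <- FALSE
        for (r in seq_along(rules)) {
          if (identical(rules[[r]]$source$split, s) && sat[i, r]) any_s <- TRUE
        }
        if (pred[i] == s && any_s) tp <- tp + 1L
        else if (pred[i] != s && any_s) fp <- fp + 1L
        else if (pred[i] == s && !any_s) fn <- fn + 1L
        else tn <- tn + 1L
      }
      rows[[s]] <- c(tp = tp, fp = fp, tn = tn, fn = fn)
    }
    return(rows)
  }
  for (r in seq_along(rules)) {
    s <- rules[[r]]$source$split
    tp <- fp <- tn <- fn <- 0L
    if (level == "CS") {
      for (i in seq_along(ids)) {
        if (sat[i, r] && pred[i] == s) tp <- tp + 1L
        else if (sat[i, r] && pred[i] != s) fp <- fp + 1L
        else if (!sat[i, r] && pred[i] == s) fn <- fn + 1L
        else tn <- tn + 1L
      }
    } else {
      cl <- clusterings[[s]]
      members <- names(cl$labels)[cl$labels == rules[[r]]$source$cluster]
      for (i in seq_along(ids)) {
        only_r <- sat[i, r]
        if (cl_exclusive && only_r) {
          for (o in setdiff(seq_along(rules), r)) {
            if (sat[i, o]) only_r <- FALSE
          }
        }
        in_c <- ids[i] %in% members
        if (in_c && only_r) tp <- tp + 1L
        else if (in_c) fn <- fn + 1L
        else if (sat[i, r]) fp <- fp + 1L
        else tn <- tn + 1L
      }
    }
    rows[[r]] <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  }
  rows
}

brute_cofulfillment <- function(rules, samples) {
  R <- length(rules)
  out <- matrix(0L, R, R)
  for (a in seq_len(R)) for (b in seq_len(R)) {
    sa <- brute_rule_sat(rules[[a]], samples)
    sb <- brute_rule_sat(rules[[b]], samples)
    out[a, b] <- sum(sa & sb)
  }
  out
}

brute_predicate_overlap <- function(rules) {
  R <- length(rules)
  out <- matrix(0L, R, R)
  for (a in seq_len(R)) for (b in seq_len(R)) {
    pa <- rules[[a]]$predicates; pb <- rules[[b]]$predicates
    cnt <- 0L
    for (i in seq_len(nrow(pa))) for (j in seq_len(nrow(pb))) {
      if (pa$position[i] == pb$position[j] && pa$symbol[i] == pb$symbol[j]) {
        cnt <- cnt + 1L
      }
    }
    out[a, b] <- cnt
  }
  out
}

brute_completeness <- function(rules, samples) {
  counts <- sapply(seq_len(n_samples(samples)), function(i) {
    k <- 0L
    for (r in rules) if (brute_rule_sat(r, samples)[i]) k <- k + 1L
    k
  })
  table(counts)
}

# random small world for the metric-oracle equivalence checks:
# <= 50 samples, <= 6 rules, frame 8, alphabet size 4, random clusterings
random_metric_fixture <- function(seed) {
  set.seed(seed)
  alpha <- c("A", "C", "G", "S")
  n <- sample(4:50, 1)
  seqs <- replicate(n, paste(sample(alpha, sample(4:8, 1), replace = TRUE),
                             collapse = ""))
  samples <- seq_set(seqs, frame_length = 8, alphabet = alpha)
  labels <- sample(c("binding", "non-binding"), n, replace = TRUE)
  # both splits non-empty
  labels[1] <- "binding"; labels[2] <- "non-binding"
  split <- split_by_prediction(samples, labels)
  clusterings <- list()
  for (s in c("binding", "non-binding")) {
    ids <- if (s == "binding") split$binding else split$non_binding
    k <- sample(1:min(3, length(ids)), 1)
    lab <- setNames(sample(0:(k - 1), length(ids), replace = TRUE), ids)
    lab[seq_len(k)] <- 0:(k - 1)   # every cluster non-empty
    meds <- sapply(0:(k - 1), function(kk) sort(names(lab)[lab == kk])[1])
    clusterings[[s]] <- clustering(lab, setNames(meds, 0:(k - 1)),
                                   algorithm = "fixture", split = s)
  }
  n_rules <- sample(1:6, 1)
  rules <- lapply(seq_len(n_rules), function(r) {
    s <- sample(c("binding", "non-binding"), 1)
    cl <- clusterings[[s]]
    kk <- sample(as.integer(names(cl$medoids)), 1)
    med <- cl$medoids[[as.character(kk)]]
    npred <- sample(0:3, 1)
    pos <- if (npred) sort(sample(0:7, npred)) else integer(0)
    sym <- frame_matrix(samples)[med, pos + 1L]
    structure(list(predicates = predicates(pos, sym),
                   prediction = s,
                   precision_estimate = 1, precision_lower_bound = 0.9,
                   coverage = 0,
                   source = list(split = s, cluster = kk, medoid_id = med),
                   n_samples_used = 0L, below_threshold = FALSE),
              class = "anchor_rule")
  })
  list(samples = samples, split = split, clusterings = clusterings,
       rules = rules)
}

# tiny deterministic anchor_rule constructor for evaluation tests
make_rule <- function(pos, sym, prediction = "binding", split = prediction,
                      cluster = 0L, medoid_id = NULL) {
  structure(list(predicates = predicates(pos, sym), prediction = prediction,
                 precision_estimate = 1, precision_lower_bound = 0.9,
                 coverage = 0,
                 source = list(split = split, cluster = as.integer(cluster),
                               medoid_id = medoid_id),
                 n_samples_used = 0L, below_threshold = FALSE),
            class = "anchor_rule")
}
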