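# Clustering of prediction splits --------------------------------------------
#
# Each prediction split is clustered under a sequence distance; the medoid of
# every cluster becomes the representative instance an anchor rule explains.
# k-medoids, agglomerative and t-SNE are delegated to cluster::pam,
# stats::hclust and Rtsne; OPTICS, LLE and a simplified BIRCH are implemented
# here because no installed package provides them.

#' Construct a clustering object
#'
#' @param labels Named integer vector id -> cluster index (0-based,
#'   contiguous; -1 marks noise points from density methods).
#' @param medoids Named character vector cluster index (as name) -> sample id.
#' @param algorithm Algorithm name.
#' @param params List of algorithm parameters.
#' @param split Which prediction split was clustered (optional).
#' @param criterion_scores Optional named numeric vector of criterion scores.
#' @return An object of class `clustering`.
#' @export
clustering <- function(labels, medoids, algorithm, params = list(),
                       split = NULL, criterion_scores = NULL) {
  labels <- stats::setNames(as.integer(labels), names(labels))
  ks <- sort(unique(labels[labels >= 0L]))
  if (length(ks) && !identical(ks, seq_along(ks) - 1L)) {
    stop("non-noise cluster indices must be contiguous from 0")
  }
  for (k in names(medoids)) {
    id <- medoids[[k]]
    if (is.na(labels[id]) || labels[id] != as.integer(k)) {
      stop("medoid ", id, " does not belong to cluster ", k)
    }
  }
  structure(list(labels = labels, medoids = medoids, algorithm = algorithm,
                 params = params, split = split,
                 criterion_scores = criterion_scores),
            class = "clustering")
}

#' @export
print.clustering <- function(x, ...) {
  k <- length(unique(x$labels[x$labels >= 0L]))
  noise <- sum(x$labels < 0L)
  cat("<clustering> ", x$algorithm, ": ", k, " clusters over ",
      length(x$labels), " samples", sep = "")
  if (noise) cat(" (", noise, " noise)", sep = "")
  if (!is.null(x$split)) cat(", split ", x$split, sep = "")
  cat("\n")
  if (!is.null(x$criterion_scores)) {
    cat("  scores: ",
        paste(names(x$criterion_scores),
              sprintf("%.3f", x$criterion_scores), collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Number of clusters (noise excluded)
#' @param x A `clustering`.
#' @export
n_clusters <- function(x) length(unique(x$labels[x$labels >= 0L]))

# relabel arbitrary labels to 0-based contiguous indices, keeping -1 noise,
# in order of first appearance (deterministic)
relabel_contiguous <- function(labels) {
  out <- stats::setNames(rep(-1L, length(labels)), names(labels))
  pos <- labels >= 0L
  u <- unique(labels[pos])
  out[pos] <- match(labels[pos], u) - 1L
  out
}

#' Compute cluster medoids
#'
#' For each non-noise cluster, returns the member minimizing the sum of
#' distances to all other members; ties are broken by the lexicographically
#' smallest sample id.
#'
#' @param labels Named integer vector id -> cluster index (-1 = noise).
#' @param d A `dist_matrix` covering all labelled ids.
#' @return Named character vector cluster index -> medoid id.
#' @export
compute_medoids <- function(labels, d) {
  stopifnot(inherits(d, "dist_matrix"))
  if (any(!names(labels) %in% d$ids)) {
    stop("labels reference ids missing from the distance matrix")
  }
  ks <- sort(unique(labels[labels >= 0L]))
  out <- character(0)
  for (k in ks) {
    members <- names(labels)[labels == k]
    if (!length(members)) stop("empty cluster ", k)
    sums <- colSums(d$d[members, members, drop = FALSE])
    cand <- members[sums == min(sums)]
    out[as.character(k)] <- sort(cand)[1L]
  }
  out
}

#' Run a clustering algorithm on a prediction split
#'
#' Supported algorithms on a precomputed [dist_matrix()]: `"k-medoids"`
#' (PAM, `cluster::pam`), `"agglomerative"` (`stats::hclust` + `cutree`,
#' linkage `complete` by default) and `"optics"` (reachability ordering with
#' a DBSCAN-style cut at `eps`; noise labelled -1).  `"birch"` is registered
#' for numeric feature matrices only and errors on precomputed distances.
#'
#' @param d A `dist_matrix`, or a numeric feature matrix (rownames = ids)
#'   for `"birch"`.
#' @param algorithm One of `"k-medoids"`, `"agglomerative"`, `"optics"`,
#'   `"birch"`.
#' @param k Number of clusters (partitioning/agglomerative/birch).
#' @param linkage Agglomerative linkage: `"complete"`, `"average"` or
#'   `"single"`.
#' @param eps OPTICS extraction radius.
#' @param min_pts OPTICS core-point threshold (default 5).
#' @param threshold BIRCH subcluster radius threshold.
#' @param seed Random seed (accepted for reproducibility of any stochastic
#'   initialization; PAM's BUILD+SWAP is deterministic and ignores it).
#' @param split Optional split name recorded in the result.
#' @return A `clustering` with medoids populated via [compute_medoids()]
#'   (feature-space algorithms use Euclidean distances for medoids).
#' @export
run_clustering <- function(d, algorithm = c("k-medoids", "agglomerative",
                                            "optics", "birch"),
                           k = NULL, linkage = "complete", eps = NULL,
                           min_pts = 5L, threshold = 0.5, seed = 0L,
                           split = NULL) {
  algorithm <- match.arg(algorithm)
  is_dist <- inherits(d, "dist_matrix")
  if (algorithm == "birch") {
    if (is_dist) {
      stop("algorithm 'birch' is incompatible with a precomputed distance ",
           "matrix; supply a numeric feature matrix")
    }
    return(birch_clustering(d, k = k, threshold = threshold, split = split))
  }
  if (!is_dist) stop("algorithm '", algorithm,
                     "' requires a precomputed dist_matrix")
  n <- length(d$ids)
  if (algorithm %in% c("k-medoids", "agglomerative")) {
    if (is.null(k)) stop("algorithm '", algorithm, "' needs k")
    if (k <= 0L || k > n) stop("k must satisfy 0 < k <= n (n = ", n, ")")
  }
  labels <- switch(algorithm,
    "k-medoids" = {
      if (k == n) {
        stats::setNames(seq_len(n) - 1L, d$ids)
      } else {
        fit <- with_seed(seed, cluster::pam(stats::as.dist(d$d), k = k,
                                            diss = TRUE, cluster.only = TRUE))
        stats::setNames(as.integer(fit) - 1L, d$ids)
      }
    },
    "agglomerative" = {
      if (n == 1L) {
        stats::setNames(0L, d$ids)
      } else {
        hc <- stats::hclust(stats::as.dist(d$d), method = linkage)
        stats::setNames(as.integer(stats::cutree(hc, k = k)) - 1L, d$ids)
      }
    },
    "optics" = {
      if (is.null(eps)) stop("algorithm 'optics' needs eps")
      optics_labels(d$d, eps = eps, min_pts = min_pts)
    })
  labels <- relabel_contiguous(labels)
  params <- list(k = k, linkage = linkage, eps = eps, min_pts = min_pts,
                 seed = seed)
  clustering(labels, compute_medoids(labels, d), algorithm = algorithm,
             params = params[!vapply(params, is.null, logical(1))],
             split = split)
}

# OPTICS on a precomputed distance matrix (Ankerst et al.): reachability
# ordering with unbounded generating radius, then a DBSCAN-equivalent cluster
# extraction at radius eps.  Quadratic, fine at desk scale.
optics_labels <- function(dm, eps, min_pts = 5L) {
  n <- nrow(dm)
  ids <- rownames(dm)
  if (n == 0L) return(stats::setNames(integer(0), character(0)))
  core <- apply(dm, 1L, function(row) sort(row)[min(min_pts, n)])
  processed <- rep(FALSE, n)
  reach <- rep(Inf, n)
  order_out <- integer(0)
  for (start in seq_len(n)) {
    if (processed[start]) next
    seeds <- start
    reach_seed <- Inf        # reachability of each seed, parallel to `seeds`
    while (length(seeds)) {
      j <- which.min(reach_seed)   # ties: first (lowest index), deterministic
      p <- seeds[j]
      reach[p] <- reach_seed[j]
      seeds <- seeds[-j]; reach_seed <- reach_seed[-j]
      processed[p] <- TRUE
      order_out <- c(order_out, p)
      newreach <- pmax(core[p], dm[p, ])
      for (q in which(!processed)) {
        pos <- match(q, seeds)
        if (is.na(pos)) {
          seeds <- c(seeds, q); reach_seed <- c(reach_seed, newreach[q])
        } else if (newreach[q] < reach_seed[pos]) {
          reach_seed[pos] <- newreach[q]
        }
      }
    }
  }
  labels <- rep(-1L, n)
  cl <- -1L
  for (p in order_out) {
    if (reach[p] > eps) {
      if (core[p] <= eps) { cl <- cl + 1L; labels[p] <- cl }
      # else: noise
    } else {
      labels[p] <- cl
    }
  }
  stats::setNames(labels, ids)
}

# simplified BIRCH: one sequential CF pass (assign to the nearest subcluster
# centroid within `threshold`, else open a new subcluster), then average-link
# agglomeration of subcluster centroids down to k; no CF tree.
birch_clustering <- function(x, k, threshold = 0.5, split = NULL) {
  x <- as.matrix(x)
  if (is.null(rownames(x))) rownames(x) <- paste0("s", seq_len(nrow(x)))
  n <- nrow(x)
  if (is.null(k)) stop("algorithm 'birch' needs k")
  if (k <= 0L || k > n) stop("k must satisfy 0 < k <= n (n = ", n, ")")
  centers <- x[1L, , drop = FALSE]
  counts <- 1L
  assign <- integer(n); assign[1L] <- 1L
  if (n > 1L) for (i in 2L:n) {
    dists <- sqrt(rowSums(sweep(centers, 2L, x[i, ])^2))
    j <- which.min(dists)
    if (dists[j] <= threshold) {
      centers[j, ] <- (centers[j, ] * counts[j] + x[i, ]) / (counts[j] + 1L)
      counts[j] <- counts[j] + 1L
      assign[i] <- j
    } else {
      centers <- rbind(centers, x[i, , drop = FALSE])
      counts <- c(counts, 1L)
      assign[i] <- nrow(centers)
    }
  }
  m <- nrow(centers)
  sub2cl <- if (m <= k) seq_len(m) else {
    hc <- stats::hclust(stats::dist(centers), method = "average")
    stats::cutree(hc, k = k)
  }
  labels <- relabel_contiguous(
    stats::setNames(as.integer(sub2cl[assign]) - 1L, rownames(x)))
  dmat <- dist_matrix(rownames(x), as.matrix(stats::dist(x)))
  clustering(labels, compute_medoids(labels, dmat), algorithm = "birch",
             params = list(k = k, threshold = threshold), split = split)
}

#' Evaluate a clustering with a quantitative criterion
#'
#' `silhouette` works on a precomputed [dist_matrix()] (mean per-sample
#' silhouette; samples in singleton clusters contribute 0; OPTICS noise
#' points are excluded).  `davies-bouldin` requires a numeric feature matrix.
#'
#' @param c A `clustering`.
#' @param d A `dist_matrix` (silhouette) or feature matrix (davies-bouldin).
#' @param criterion `"silhouette"` or `"davies-bouldin"`.
#' @return The score: silhouette in \[-1, 1\] (higher better),
#'   davies-bouldin >= 0 (lower better).
#' @export
evaluate_clustering <- function(c, d, criterion = c("silhouette",
                                                    "davies-bouldin")) {
  criterion <- match.arg(criterion)
  labels <- c$labels[c$labels >= 0L]
  if (length(unique(labels)) < 2L) {
    stop("criterion '", criterion,
         "' is undefined for fewer than two (non-noise) clusters")
  }
  if (criterion == "silhouette") {
    if (!inherits(d, "dist_matrix")) {
      stop("silhouette needs a precomputed dist_matrix")
    }
    return(silhouette_score(labels, d))
  }
  if (inherits(d, "dist_matrix")) {
    stop("davies-bouldin requires vector features, not a distance matrix")
  }
  davies_bouldin_score(labels, as.matrix(d))
}

silhouette_score <- function(labels, d) {
  ids <- names(labels)
  dm <- d$d[ids, ids, drop = FALSE]
  ks <- sort(unique(labels))
  s <- numeric(length(ids))
  for (i in seq_along(ids)) {
    own <- labels[i]
    members <- ids[labels == own]
    if (length(members) == 1L) { s[i] <- 0; next }   # singleton convention
    a <- sum(dm[ids[i], setdiff(members, ids[i])]) / (length(members) - 1L)
    b <- min(vapply(ks[ks != own], function(kk) {
      mean(dm[ids[i], ids[labels == kk]])
    }, numeric(1)))
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  mean(s)
}

davies_bouldin_score <- function(labels, x) {
  x <- x[names(labels), , drop = FALSE]
  ks <- sort(unique(labels))
  cent <- t(vapply(ks, function(kk) colMeans(x[labels == kk, , drop = FALSE]),
                   numeric(ncol(x))))
  scatter <- vapply(seq_along(ks), function(j) {
    pts <- x[labels == ks[j], , drop = FALSE]
    mean(sqrt(rowSums(sweep(pts, 2L, cent[j, ])^2)))
  }, numeric(1))
  m <- length(ks)
  r <- vapply(seq_len(m), function(i) {
    max(vapply(setdiff(seq_len(m), i), function(j) {
      (scatter[i] + scatter[j]) /
        sqrt(sum((cent[i, ] - cent[j, ])^2))
    }, numeric(1)))
  }, numeric(1))
  mean(r)
}

#' Sweep clustering hyperparameters and pick the best clustering
#'
#' Runs one algorithm over a parameter grid (`k` for k-medoids and
#' agglomerative, `eps` for OPTICS) and returns the clustering maximizing
#' silhouette (or minimizing davies-bouldin).  Settings whose criterion is
#' undefined (e.g. a single cluster) are skipped.
#'
#' @param d A `dist_matrix` (or feature matrix for birch).
#' @param algorithm Algorithm name as in [run_clustering()].
#' @param grid Numeric vector of `k` (or `eps`) values.
#' @param criterion Selection criterion, default `"silhouette"`.
#' @param ... Further arguments to [run_clustering()].
#' @return The best `clustering`, with `criterion_scores` recording its score
#'   and attribute `"sweep"` holding the full score table.
#' @export
sweep_clustering <- function(d, algorithm, grid,
                             criterion = "silhouette", ...) {
  if (!length(grid)) stop("empty parameter grid")
  rows <- list(); fits <- list()
  for (g in grid) {
    fit <- if (algorithm == "optics") {
      run_clustering(d, algorithm, eps = g, ...)
    } else {
      run_clustering(d, algorithm, k = as.integer(g), ...)
    }
    score <- tryCatch(evaluate_clustering(fit, d, criterion),
                      error = function(e) NA_real_)
    fits[[length(fits) + 1L]] <- fit
    rows[[length(rows) + 1L]] <- data.frame(param = g,
                                            n_clusters = n_clusters(fit),
                                            score = score)
  }
  tab <- do.call(rbind, rows)
  ok <- which(!is.na(tab$score))
  if (!length(ok)) stop("criterion '", criterion,
                        "' undefined for every setting in the grid")
  best <- if (criterion == "davies-bouldin") ok[which.min(tab$score[ok])]
          else ok[which.max(tab$score[ok])]
  out <- fits[[best]]
  out$criterion_scores <- stats::setNames(tab$score[best], criterion)
  attr(out, "sweep") <- tab
  out
}

#' Consensus clustering from a co-association matrix
#'
#' The co-association of two samples is the fraction of input clusterings
#' placing them in the same cluster (noise points co-associate with nothing).
#' The consensus is average-linkage agglomeration of `1 - co-association`,
#' cut at k = floor(median of the input cluster counts).  Invariant to
#' relabeling of the input partitions.
#'
#' @param clusterings List of >= 2 `clustering` objects over the same id set.
#' @param d Optional `dist_matrix` used to compute consensus medoids;
#'   defaults to `1 - co-association` itself.
#' @return A `clustering` with algorithm `"consensus"`.
#' @export
consensus_clustering <- function(clusterings, d = NULL) {
  if (length(clusterings) < 2L) stop("need at least two clusterings")
  ids <- sort(names(clusterings[[1L]]$labels))
  for (cl in clusterings[-1L]) {
    if (!identical(sort(names(cl$labels)), ids)) {
      stop("clusterings cover different id sets")
    }
  }
  n <- length(ids)
  co <- matrix(0, n, n, dimnames = list(ids, ids))
  for (cl in clusterings) {
    lab <- cl$labels[ids]
    same <- outer(lab, lab, "==") & outer(lab >= 0L, lab >= 0L, "&")
    co <- co + same
  }
  co <- co / length(clusterings)
  diag(co) <- 1
  k <- max(1L, floor(stats::median(
    vapply(clusterings, n_clusters, integer(1)))))
  labels <- if (n == 1L) stats::setNames(0L, ids) else {
    hc <- stats::hclust(stats::as.dist(1 - co), method = "average")
    stats::setNames(as.integer(stats::cutree(hc, k = min(k, n))) - 1L, ids)
  }
  labels <- relabel_contiguous(labels)
  dm <- if (is.null(d)) dist_matrix(ids, 1 - co) else d[ids]
  clustering(labels, compute_medoids(labels, dm), algorithm = "consensus",
             params = list(k = k, n_inputs = length(clusterings)),
             split = clusterings[[1L]]$split)
}

#' Project samples to 2-D for qualitative inspection
#'
#' `"tsne"` (exact t-SNE via \pkg{Rtsne}, `theta = 0`) accepts either a
#' precomputed [dist_matrix()] or a feature matrix; `"lle"` (locally linear
#' embedding, implemented here over \pkg{FNN} neighbours) requires features
#' and errors on a distance matrix.  A qualitative aid only: reproducible
#' for a fixed seed, no geometric guarantees.
#'
#' @param d A `dist_matrix` or numeric feature matrix (rownames = ids).
#' @param method `"tsne"` or `"lle"`.
#' @param seed Random seed (t-SNE).
#' @param perplexity t-SNE perplexity; capped at `(n - 1) / 3`.
#' @param n_neighbors LLE neighbourhood size.
#' @return Numeric matrix, one row per sample, columns `x`, `y`.
#' @export
project_2d <- function(d, method = c("tsne", "lle"), seed = 0L,
                       perplexity = 30, n_neighbors = 10L) {
  method <- match.arg(method)
  is_dist <- inherits(d, "dist_matrix")
  ids <- if (is_dist) d$ids else rownames(as.matrix(d))
  n <- length(ids)
  if (n == 0L) return(matrix(numeric(0), 0L, 2L,
                             dimnames = list(NULL, c("x", "y"))))
  if (method == "lle" && is_dist) {
    stop("lle requires vector features, not a precomputed distance matrix")
  }
  if (n <= 3L) {
    # too small for either method; lay out deterministically on a line
    out <- cbind(x = seq_len(n) - 1, y = rep(0, n))
    rownames(out) <- ids
    return(out)
  }
  out <- if (method == "tsne") {
    perp <- max(1, min(perplexity, floor((n - 1) / 3)))
    y <- with_seed(seed, {
      if (is_dist) {
        Rtsne::Rtsne(stats::as.dist(d$d), is_distance = TRUE, theta = 0,
                     perplexity = perp, check_duplicates = FALSE)$Y
      } else {
        Rtsne::Rtsne(as.matrix(d), theta = 0, perplexity = perp, pca = FALSE,
                     check_duplicates = FALSE)$Y
      }
    })
    y
  } else {
    lle_embed(as.matrix(d), k = min(n_neighbors, n - 1L))
  }
  dimnames(out) <- list(ids, c("x", "y"))
  out
}

# standard LLE (Roweis & Saul): reconstruction weights from the local Gram
# matrix (regularized), embedding = bottom non-constant eigenvectors of
# (I - W)'(I - W).  Deterministic.
lle_embed <- function(x, k) {
  n <- nrow(x)
  nn <- FNN::get.knn(x, k = k)$nn.index
  w <- matrix(0, n, n)
  for (i in seq_len(n)) {
    z <- sweep(x[nn[i, ], , drop = FALSE], 2L, x[i, ])
    g <- z %*% t(z)
    g <- g + diag(k) * (1e-3 * sum(diag(g)) / k + 1e-12)
    wi <- solve(g, rep(1, k))
    w[i, nn[i, ]] <- wi / sum(wi)
  }
  m <- t(diag(n) - w) %*% (diag(n) - w)
  e <- eigen((m + t(m)) / 2, symmetric = TRUE)
  take <- order(e$values)[2:3]          # skip the constant eigenvector
  y <- e$vectors[, take, drop = FALSE]
  # fix sign for determinism across LAPACK builds
  for (j in 1:2) if (y[which.max(abs(y[, j])), j] < 0) y[, j] <- -y[, j]
  y
}

#' Write a clustering as a delimited table
#'
#' Columns `id`, `split`, `cluster`, `is_medoid` (tab-delimited).
#'
#' @param x A `clustering`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clustering <- function(x, path) {
  ids <- names(x$labels)
  tab <- data.frame(id = ids,
                    split = if (is.null(x$split)) "" else x$split,
                    cluster = unname(x$labels),
                    is_medoid = ids %in% x$medoids,
                    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_clustering
#' @param algorithm,params Metadata restored onto the object.
#' @export
read_clustering <- function(path, algorithm = "unknown", params = list()) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  labels <- stats::setNames(as.integer(tab$cluster), tab$id)
  med <- tab[tab$is_medoid & tab$cluster >= 0L, , drop = FALSE]
  medoids <- stats::setNames(med$id, as.character(med$cluster))
  split <- if (nrow(tab) && nzchar(tab$split[1L])) tab$split[1L] else NULL
  clustering(labels, medoids, algorithm = algorithm, params = params,
             split = split)
}
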