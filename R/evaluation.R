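# Rule-set audit -------------------------------------------------------------
#
# Faithfulness, overlap and completeness of a set of anchors are measured
# over the full evaluation universe (both prediction splits) at three
# levels:
#   CL  - per rule, against the rule's own cluster (a true positive must,
#         under the default exclusive semantics, satisfy ONLY that rule);
#   CS  - per rule, against the rule's own split;
#   SP  - per split, against the union of the split's rules.

# n x R logical satisfaction matrix
satisfaction_matrix <- function(rules, samples) {
  sat <- vapply(rules, function(r) rule_applies(r, samples),
                logical(n_samples(samples)))
  if (n_samples(samples) == 1L) sat <- matrix(sat, nrow = 1L)
  if (!length(rules)) sat <- matrix(logical(0), n_samples(samples), 0L)
  rownames(sat) <- sample_ids(samples)
  colnames(sat) <- rule_ids(rules)
  sat
}

rule_ids <- function(rules) {
  vapply(seq_along(rules), function(i) {
    src <- rules[[i]]$source
    if (!is.null(src$split) && !is.null(src$cluster)) {
      paste0(src$split, "/c", src$cluster)
    } else paste0("rule", i)
  }, character(1))
}

metric_ratio <- function(num, den, what, scope) {
  if (den == 0L) {
    warning("undefined ", what, " (zero denominator) for ", scope,
            call. = FALSE)
    return(NA_real_)
  }
  num / den
}

confusion_row <- function(tp, fp, tn, fn, level, scope) {
  data.frame(scope = scope, level = level, tp = tp, fp = fp, tn = tn, fn = fn,
             accuracy = metric_ratio(tp + tn, tp + tn + fp + fn,
                                     "accuracy", scope),
             precision = metric_ratio(tp, tp + fp, "precision", scope),
             recall = metric_ratio(tp, tp + fn, "recall", scope),
             stringsAsFactors = FALSE)
}

#' Multi-level anchor metrics
#'
#' Computes accuracy, precision and recall of a rule set at one of three
#' levels.  The evaluation universe is always the full sample set (both
#' splits), so false positives can come from the opposite split.
#'
#' * `CL` (cluster level), per rule r from cluster c: TP = samples of c
#'   satisfying r and (under `cl_exclusive = TRUE`, the default) no other
#'   rule; FN = the remaining samples of c; FP = samples outside c
#'   satisfying r; TN = the rest.
#' * `CS` (cluster-split level), per rule r from split s: TP = samples
#'   satisfying r whose model prediction is s; FP = satisfiers predicted
#'   otherwise; FN = samples predicted s not satisfying r.
#' * `SP` (split level), per split s: TP = samples predicted s satisfying at
#'   least one of s's rules; FP = samples predicted otherwise satisfying one;
#'   FN = samples predicted s satisfying none.
#'
#' Zero-denominator ratios are reported as `NA` with a warning, never as 0.
#'
#' @param rules List of `anchor_rule` objects carrying `source` (split,
#'   cluster, medoid id).
#' @param samples The full evaluation `seq_set`.
#' @param split The `prediction_split` of `samples`.
#' @param clusterings Named list of `clustering` objects, names
#'   `"binding"` / `"non-binding"` (needed for CL).
#' @param level `"CL"`, `"CS"` or `"SP"`.
#' @param cl_exclusive CL "only" semantics: a CL true positive must satisfy
#'   no other rule (the default); `FALSE` gives the inclusive variant.
#' @param cl_scope Whether "no other rule" quantifies over `"all"` rules
#'   (default) or only the rule's `"split"`.
#' @return Data frame with columns `scope`, `level`, `tp`, `fp`, `tn`, `fn`,
#'   `accuracy`, `precision`, `recall`.
#' @export
level_metrics <- function(rules, samples, split, clusterings = NULL,
                          level = c("CL", "CS", "SP"), cl_exclusive = TRUE,
                          cl_scope = c("all", "split")) {
  level <- match.arg(level)
  cl_scope <- match.arg(cl_scope)
  sat <- satisfaction_matrix(rules, samples)
  ids <- sample_ids(samples)
  pred <- split$label_of[ids]
  rows <- list()

  if (level == "SP") {
    for (s in class_labels()) {
      of_split <- vapply(rules, function(r) identical(r$source$split, s),
                         logical(1))
      any_s <- if (any(of_split))
        rowSums(sat[, of_split, drop = FALSE]) > 0L else rep(FALSE, length(ids))
      in_s <- pred == s
      rows[[s]] <- confusion_row(sum(in_s & any_s), sum(!in_s & any_s),
                                 sum(!in_s & !any_s), sum(in_s & !any_s),
                                 "SP", s)
    }
    return(do.call(rbind, c(rows, list(make.row.names = FALSE))))
  }

  for (i in seq_along(rules)) {
    r <- rules[[i]]
    s <- r$source$split
    scope <- rule_ids(rules)[i]
    sat_r <- sat[, i]
    if (level == "CS") {
      if (is.null(s)) stop("rule ", scope, " lacks a source split")
      in_s <- pred == s
      rows[[i]] <- confusion_row(sum(sat_r & in_s), sum(sat_r & !in_s),
                                 sum(!sat_r & !in_s), sum(!sat_r & in_s),
                                 "CS", scope)
    } else {
      if (is.null(clusterings)) stop("CL metrics need the clusterings")
      cl <- clusterings[[s]]
      if (is.null(cl)) stop("no clustering for split ", s)
      if (!r$source$cluster %in% cl$labels) {
        stop("rule ", scope, " references unknown cluster ", r$source$cluster)
      }
      members <- names(cl$labels)[cl$labels == r$source$cluster]
      in_c <- ids %in% members
      only_r <- sat_r
      if (cl_exclusive) {
        others <- setdiff(seq_along(rules), i)
        if (cl_scope == "split") {
          others <- others[vapply(rules[others], function(q)
            identical(q$source$split, s), logical(1))]
        }
        if (length(others)) {
          only_r <- sat_r & rowSums(sat[, others, drop = FALSE]) == 0L
        }
      }
      tp <- sum(in_c & only_r)
      fn <- sum(in_c) - tp
      fp <- sum(!in_c & sat_r)
      tn <- length(ids) - tp - fn - fp
      rows[[i]] <- confusion_row(tp, fp, tn, fn, "CL", scope)
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Number of shared predicates between two rules
#'
#' A shared (sub-)rule requires the same amino acid in the same position;
#' identical positions with different symbols do not count.
#'
#' @param a,b `anchor_rule` objects (or predicate data frames).
#' @return Non-negative integer.
#' @export
predicate_overlap <- function(a, b) {
  pa <- if (inherits(a, "anchor_rule")) a$predicates else a
  pb <- if (inherits(b, "anchor_rule")) b$predicates else b
  sum(paste(pa$position, pa$symbol) %in% paste(pb$position, pb$symbol))
}

# order rules non-binding first, then binding (heatmap convention)
order_rules <- function(rules) {
  splits <- vapply(rules, function(r)
    if (is.null(r$source$split)) "" else r$source$split, character(1))
  order(match(splits, c("non-binding", "binding", "")))
}

#' Rule overlap matrices
#'
#' `predicate_overlap`: pairwise shared-predicate counts (diagonal = rule
#' length).  `cofulfillment`: number of evaluation samples satisfying both
#' rules (diagonal = per-rule fulfillment count).  Rules are ordered
#' non-binding first, then binding.
#'
#' @param rules List of `anchor_rule` objects.
#' @param samples The evaluation `seq_set`.
#' @return An object of class `overlap_matrix`: list with `rule_ids`,
#'   `predicate_overlap` and `cofulfillment` integer matrices.
#' @export
overlap_matrices <- function(rules, samples) {
  ord <- order_rules(rules)
  rules <- rules[ord]
  ids <- rule_ids(rules)
  R <- length(rules)
  po <- matrix(0L, R, R, dimnames = list(ids, ids))
  for (i in seq_len(R)) for (j in seq_len(R)) {
    po[i, j] <- predicate_overlap(rules[[i]], rules[[j]])
  }
  sat <- satisfaction_matrix(rules, samples)
  cf <- crossprod(sat)
  storage.mode(cf) <- "integer"
  dimnames(cf) <- list(ids, ids)
  structure(list(rule_ids = ids, predicate_overlap = po, cofulfillment = cf),
            class = "overlap_matrix")
}

#' @rdname overlap_matrices
#' @export
cofulfillment_matrix <- function(rules, samples) {
  overlap_matrices(rules, samples)$cofulfillment
}

#' Completeness histogram
#'
#' For each sample, counts the anchors applicable to it; returns the
#' histogram of those counts (bin 0 included).  An ideal global rule set
#' covers every sample exactly once.
#'
#' @param rules List of `anchor_rule` objects.
#' @param samples The evaluation `seq_set`.
#' @return Data frame with columns `n_anchors`, `n_samples`; the
#'   `n_samples` column sums to the universe size.
#' @export
completeness_histogram <- function(rules, samples) {
  sat <- satisfaction_matrix(rules, samples)
  counts <- if (ncol(sat)) rowSums(sat) else rep(0L, n_samples(samples))
  tab <- table(factor(counts, levels = 0:max(counts, 0L)))
  data.frame(n_anchors = as.integer(names(tab)),
             n_samples = as.integer(tab))
}

#' Full metrics report
#'
#' Bundles all three metric levels, the overlap matrices and the
#' completeness histogram.
#'
#' @inheritParams level_metrics
#' @return An object of class `metrics_report`: list with `metrics`
#'   (stacked CL/CS/SP table), `overlap` and `completeness`.
#' @export
metrics_report <- function(rules, samples, split, clusterings,
                           cl_exclusive = TRUE, cl_scope = "all") {
  metrics <- rbind(
    level_metrics(rules, samples, split, clusterings, "CL",
                  cl_exclusive = cl_exclusive, cl_scope = cl_scope),
    level_metrics(rules, samples, split, clusterings, "CS"),
    level_metrics(rules, samples, split, clusterings, "SP"))
  below <- vapply(rules, function(r) isTRUE(r$below_threshold), logical(1))
  structure(list(metrics = metrics,
                 overlap = overlap_matrices(rules, samples),
                 completeness = completeness_histogram(rules, samples),
                 below_threshold_rules = rule_ids(rules)[below]),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report>\n")
  print(x$metrics, digits = 3)
  if (length(x$below_threshold_rules)) {
    cat("below-threshold rules: ",
        paste(x$below_threshold_rules, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write a metrics report as delimited tables
#'
#' Writes `metrics.tsv` (scope, level, counts, accuracy/precision/recall),
#' `overlap_predicates.tsv`, `overlap_cofulfillment.tsv` and
#' `completeness.tsv` into `dir`.
#'
#' @param report A `metrics_report`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_metrics_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(x, f, rn = FALSE) {
    utils::write.table(x, file.path(dir, f), sep = "\t", quote = FALSE,
                       row.names = rn, col.names = if (rn) NA else TRUE)
  }
  w(report$metrics, "metrics.tsv")
  w(report$overlap$predicate_overlap, "overlap_predicates.tsv", rn = TRUE)
  w(report$overlap$cofulfillment, "overlap_cofulfillment.tsv", rn = TRUE)
  w(report$completeness, "completeness.tsv")
  invisible(dir)
}
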