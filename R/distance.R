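# Sequence distance layer ----------------------------------------------------
#
# Distances are computed on the raw residue strings: reserved tokens
# (<PAD>/<START>/<STOP>) are never part of the comparison, since edit
# distance on padding has no biological meaning.

.metric_registry <- new.env(parent = emptyenv())

#' Register a sequence distance metric
#'
#' A metric is a function taking a character vector of residue strings and
#' returning a symmetric non-negative matrix with zero diagonal.
#' `levenshtein` is built in.
#'
#' @param name Metric name.
#' @param fn Function `character vector -> numeric matrix`.
#' @return `name`, invisibly.
#' @export
register_metric <- function(name, fn) {
  stopifnot(is.character(name), length(name) == 1L, is.function(fn))
  assign(name, fn, envir = .metric_registry)
  invisible(name)
}

#' @rdname register_metric
#' @export
registered_metrics <- function() sort(ls(.metric_registry))

#' Levenshtein (edit) distance between two residue strings
#'
#' Minimal number of single-residue insertions, deletions and substitutions
#' turning `a` into `b`.  Reserved frame tokens must be stripped before the
#' call (raw residue strings never contain them).
#'
#' @param a,b Residue strings.
#' @param alphabet Residue alphabet used for validation.
#' @return Non-negative integer.
#' @examples
#' levenshtein_distance("CASS", "CASSL")  # 1
#' @export
levenshtein_distance <- function(a, b, alphabet = aa_alphabet()) {
  check_symbols(c(a, b), alphabet)
  as.integer(utils::adist(a, b))
}

check_symbols <- function(strings, alphabet) {
  toks <- unique(unlist(strsplit(strings, "", fixed = TRUE)))
  bad <- setdiff(toks, alphabet)
  if (length(bad)) {
    stop("symbols outside the alphabet: ", paste(bad, collapse = ", "))
  }
  invisible(TRUE)
}

#' Pairwise distance matrix over a sequence set
#'
#' @param samples A `seq_set`.
#' @param metric Name of a registered metric (see [registered_metrics()]).
#' @return An object of class `dist_matrix`: list with `ids` and the
#'   symmetric matrix `d` (dimnames = ids).
#' @export
pairwise_distances <- function(samples, metric = "levenshtein") {
  stopifnot(inherits(samples, "seq_set"))
  if (!exists(metric, envir = .metric_registry)) {
    stop("unknown metric '", metric, "'; registered metrics: ",
         paste(registered_metrics(), collapse = ", "))
  }
  fn <- get(metric, envir = .metric_registry)
  strings <- unname(raw_sequences(samples))
  d <- if (length(strings)) fn(strings) else
    matrix(numeric(0), 0L, 0L)
  d <- as.matrix(d)
  dimnames(d) <- list(samples$ids, samples$ids)
  dist_matrix(samples$ids, d)
}

#' Construct / validate a distance matrix object
#'
#' @param ids Ordered sample ids.
#' @param d Symmetric numeric matrix of non-negative distances, zero diagonal.
#' @return A `dist_matrix`.
#' @export
dist_matrix <- function(ids, d) {
  d <- as.matrix(d)
  ids <- as.character(ids)
  if (nrow(d) != length(ids) || ncol(d) != length(ids)) {
    stop("distance matrix dimensions do not match the id vector")
  }
  if (length(ids)) {
    if (any(d < 0)) stop("distances must be non-negative")
    if (any(abs(d - t(d)) > 1e-8)) stop("distance matrix must be symmetric")
    if (any(abs(diag(d)) > 1e-12)) stop("distance matrix diagonal must be zero")
  }
  dimnames(d) <- list(ids, ids)
  structure(list(ids = ids, d = d), class = "dist_matrix")
}

#' @export
print.dist_matrix <- function(x, ...) {
  cat("<dist_matrix> ", length(x$ids), " x ", length(x$ids), "\n", sep = "")
  invisible(x)
}

#' Subset a distance matrix by id
#' @param x A `dist_matrix`.
#' @param i Character ids (or indices).
#' @param ... Unused.
#' @export
`[.dist_matrix` <- function(x, i, ...) {
  ids <- if (is.character(i)) i else x$ids[i]
  dist_matrix(ids, x$d[ids, ids, drop = FALSE])
}

#' Read / write a distance matrix as a delimited square table
#'
#' Tab-delimited, first column `id`, remaining columns named by id.
#'
#' @param path File path.
#' @return `read_dist_matrix`: a `dist_matrix`.
#' @export
read_dist_matrix <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(tab[[1L]])
  d <- as.matrix(tab[, -1L, drop = FALSE])
  dist_matrix(ids, d)
}

#' @rdname read_dist_matrix
#' @param x A `dist_matrix`.
#' @export
write_dist_matrix <- function(x, path) {
  tab <- data.frame(id = x$ids, x$d, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# built-in metric: full-matrix Levenshtein via the C implementation in utils;
# symbols were already validated when the seq_set was built
register_metric("levenshtein", function(strings) utils::adist(strings))
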