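# Fixed-frame sequence sets -------------------------------------------------
#
# Every sample in a run lives in the same fixed-length coordinate frame:
# an optional <START> token, the raw residues, an optional <STOP> token, and
# <PAD> tokens up to the frame length.  Rule positions are 0-based indices
# into this frame.

#' Reserved frame tokens
#'
#' Tokens that may occupy frame positions but are not amino-acid residues.
#'
#' @return Character vector `c("<PAD>", "<START>", "<STOP>")`.
#' @export
reserved_tokens <- function() c(pad_token(), start_token(), stop_token())

#' @rdname reserved_tokens
#' @export
pad_token <- function() "<PAD>"

#' @rdname reserved_tokens
#' @export
start_token <- function() "<START>"

#' @rdname reserved_tokens
#' @export
stop_token <- function() "<STOP>"

#' The 20 canonical amino acids
#'
#' @return Character vector of the 20 one-letter amino-acid codes.
#' @export
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

#' Region label vocabulary
#'
#' Closed set of labels usable in region annotations: the four framework
#' regions, three complementarity-determining regions, plus `Other` for
#' unaligned residues and the reserved-token labels.
#'
#' @return Character vector of admissible region labels.
#' @export
region_labels <- function() {
  c("FR1", "CDR1", "FR2", "CDR2", "FR3", "CDR3", "FR4",
    "Other", "PAD", "Start", "Stop")
}

#' Construct a fixed-frame sequence set
#'
#' Builds the padded coordinate frame shared by all pipeline stages.  Each
#' input sequence is a string of residues over `alphabet`; it is placed into
#' a frame of `frame_length` symbols, optionally wrapped in `<START>`/`<STOP>`
#' tokens, and right-padded with `<PAD>`.
#'
#' @param sequences Character vector of residue strings.
#' @param ids Optional unique sample ids; defaults to `s1`, `s2`, ...
#' @param frame_length Total frame length; defaults to the smallest length
#'   that fits the longest sequence (plus start/stop tokens if requested).
#' @param alphabet Residue alphabet (default the 20 canonical amino acids).
#' @param start_stop Wrap each sequence in `<START>`/`<STOP>` tokens?
#' @param regions Optional region annotation: a data frame with columns
#'   `id`, `label`, `start`, `end` (0-based, half-open, frame coordinates),
#'   labels from [region_labels()].
#' @return An object of class `seq_set`: a list with elements `ids`, `frame`
#'   (character matrix, one row per sample, one column per frame position),
#'   `raw` (residue strings), `alphabet`, `frame_length`, `regions`.
#' @examples
#' ss <- seq_set(c("CASSL", "CASRL"), frame_length = 8)
#' frame_matrix(ss)[, 1:6]
#' @export
seq_set <- function(sequences, ids = NULL, frame_length = NULL,
                    alphabet = aa_alphabet(), start_stop = FALSE,
                    regions = NULL) {
  stopifnot(is.character(sequences))
  n <- length(sequences)
  if (is.null(ids)) ids <- sprintf("s%d", seq_len(n))
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("sample ids must be unique")
  if (length(ids) != n) stop("ids and sequences must have equal length")

  toks <- strsplit(sequences, "", fixed = TRUE)
  bad <- vapply(toks, function(t) any(!t %in% alphabet), logical(1))
  if (any(bad)) {
    stop("sequence ", ids[which(bad)[1]], " contains symbols outside the alphabet")
  }
  reserve <- if (start_stop) 2L else 0L
  raw_len <- nchar(sequences)
  if (is.null(frame_length)) frame_length <- max(raw_len, 0L) + reserve
  if (any(raw_len > frame_length - reserve)) {
    stop("sequence longer than frame length minus reserved tokens: ",
         ids[which(raw_len > frame_length - reserve)[1]])
  }

  frame <- matrix(pad_token(), nrow = n, ncol = frame_length,
                  dimnames = list(ids, NULL))
  for (i in seq_len(n)) {
    row <- toks[[i]]
    if (start_stop) row <- c(start_token(), row, stop_token())
    if (length(row)) frame[i, seq_along(row)] <- row
  }

  x <- structure(
    list(ids = ids, frame = frame, raw = stats::setNames(sequences, ids),
         alphabet = alphabet, frame_length = as.integer(frame_length),
         start_stop = start_stop, regions = NULL),
    class = "seq_set")
  if (!is.null(regions)) x$regions <- validate_regions(regions, x)
  x
}

validate_regions <- function(regions, x) {
  regions <- as.data.frame(regions)
  need <- c("id", "label", "start", "end")
  if (!all(need %in% names(regions))) {
    stop("region annotation needs columns ", paste(need, collapse = ", "))
  }
  regions$id <- as.character(regions$id)
  regions$label <- as.character(regions$label)
  regions$start <- as.integer(regions$start)
  regions$end <- as.integer(regions$end)
  if (any(!regions$label %in% region_labels())) {
    stop("unknown region label(s): ",
         paste(setdiff(regions$label, region_labels()), collapse = ", "))
  }
  if (any(!regions$id %in% x$ids)) {
    stop("region annotation references unknown sample id(s)")
  }
  if (any(regions$start < 0L | regions$end > x$frame_length |
          regions$start >= regions$end)) {
    stop("region intervals must be 0-based half-open and lie within the frame")
  }
  for (id in unique(regions$id)) {
    r <- regions[regions$id == id, , drop = FALSE]
    r <- r[order(r$start), , drop = FALSE]
    if (nrow(r) > 1L && any(r$start[-1L] < r$end[-nrow(r)])) {
      stop("overlapping region intervals for sample ", id)
    }
  }
  rownames(regions) <- NULL
  regions
}

#' @export
print.seq_set <- function(x, ...) {
  cat("<seq_set> ", length(x$ids), " samples, frame length ", x$frame_length,
      ", alphabet size ", length(x$alphabet), "\n", sep = "")
  if (!is.null(x$regions)) cat("  region annotation: present\n")
  show <- utils::head(x$ids, 3L)
  for (id in show) cat("  ", id, ": ", x$raw[[id]], "\n", sep = "")
  if (length(x$ids) > 3L) cat("  ...\n")
  invisible(x)
}

#' Number of samples in a sequence set
#' @param x A `seq_set`.
#' @return Integer count.
#' @export
n_samples <- function(x) length(x$ids)

#' Sample ids of a sequence set
#' @param x A `seq_set`.
#' @return Character vector of ids.
#' @export
sample_ids <- function(x) x$ids

#' Frame matrix of a sequence set
#' @param x A `seq_set`.
#' @return Character matrix (samples x frame positions) of frame symbols.
#' @export
frame_matrix <- function(x) x$frame

#' Raw residue strings of a sequence set
#' @param x A `seq_set`.
#' @return Named character vector (reserved tokens never appear).
#' @export
raw_sequences <- function(x) x$raw

#' Subset a sequence set by sample id
#'
#' @param x A `seq_set`.
#' @param i Character ids, integer indices or logical mask.
#' @param ... Unused.
#' @return A `seq_set` restricted to the selected samples (region annotation
#'   carried along).
#' @export
`[.seq_set` <- function(x, i, ...) {
  if (is.character(i)) {
    missing <- setdiff(i, x$ids)
    if (length(missing)) stop("unknown sample id(s): ", paste(missing, collapse = ", "))
    keep <- i
  } else {
    keep <- x$ids[i]
  }
  out <- x
  out$ids <- keep
  out$frame <- x$frame[keep, , drop = FALSE]
  out$raw <- x$raw[keep]
  if (!is.null(x$regions)) {
    out$regions <- x$regions[x$regions$id %in% keep, , drop = FALSE]
    rownames(out$regions) <- NULL
  }
  out
}

# I/O ------------------------------------------------------------------------

#' Read sequences from FASTA or a delimited table
#'
#' FASTA ids are the first whitespace-delimited header token.  Tables must be
#' tab-delimited with columns `id` and `sequence`; an optional `regions`
#' column holds per-sample annotations encoded `label:start-end;label:start-end`
#' (0-based half-open frame coordinates).
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"fasta"` or `"table"`.
#' @param ... Passed on to [seq_set()] (e.g. `frame_length`, `start_stop`).
#' @return A `seq_set`.
#' @export
read_sequences <- function(path, format = c("auto", "fasta", "table"), ...) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(fa|fasta|faa)$", path, ignore.case = TRUE))
      "fasta" else "table"
  }
  if (format == "fasta") {
    aa <- Biostrings::readAAStringSet(path)
    ids <- vapply(strsplit(names(aa), "\\s+"), `[[`, character(1), 1L)
    return(seq_set(as.character(aa), ids = ids, ...))
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("id", "sequence") %in% names(tab))) {
    stop("table input needs columns 'id' and 'sequence'")
  }
  regions <- NULL
  if ("regions" %in% names(tab) && any(nzchar(tab$regions))) {
    regions <- parse_region_strings(tab$id, tab$regions)
  }
  seq_set(tab$sequence, ids = tab$id, regions = regions, ...)
}

parse_region_strings <- function(ids, strings) {
  rows <- lapply(seq_along(ids), function(i) {
    s <- strings[i]
    if (!nzchar(s)) return(NULL)
    parts <- strsplit(s, ";", fixed = TRUE)[[1]]
    m <- regmatches(parts, regexec("^([^:]+):([0-9]+)-([0-9]+)$", parts))
    bad <- vapply(m, length, integer(1)) != 4L
    if (any(bad)) stop("malformed region string for sample ", ids[i], ": ", s)
    data.frame(id = ids[i],
               label = vapply(m, `[[`, character(1), 2L),
               start = as.integer(vapply(m, `[[`, character(1), 3L)),
               end = as.integer(vapply(m, `[[`, character(1), 4L)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Read / write a region map table
#'
#' Delimited table with columns `id`, `label`, `start`, `end` (0-based,
#' half-open frame coordinates).
#'
#' @param path File path.
#' @return `read_region_map`: a region data frame.
#' @export
read_region_map <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("id", "label", "start", "end")
  if (!all(need %in% names(tab))) {
    stop("region map needs columns ", paste(need, collapse = ", "))
  }
  tab
}

#' @rdname read_region_map
#' @param regions Region data frame.
#' @export
write_region_map <- function(regions, path) {
  utils::write.table(regions, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a sequence set
#'
#' Writes the tab-delimited table format accepted by [read_sequences()]
#' (columns `id`, `sequence`, and `regions` when annotated), or FASTA.
#'
#' @param x A `seq_set`.
#' @param path Output path.
#' @param format `"table"` or `"fasta"` (FASTA drops region annotations).
#' @return `path`, invisibly.
#' @export
write_sequences <- function(x, path, format = c("table", "fasta")) {
  format <- match.arg(format)
  if (format == "fasta") {
    writeLines(paste0(">", x$ids, "\n", x$raw), path)
    return(invisible(path))
  }
  tab <- data.frame(id = x$ids, sequence = unname(x$raw),
                    stringsAsFactors = FALSE)
  if (!is.null(x$regions)) {
    enc <- vapply(x$ids, function(id) {
      r <- x$regions[x$regions$id == id, , drop = FALSE]
      if (!nrow(r)) return("")
      r <- r[order(r$start), , drop = FALSE]
      paste(sprintf("%s:%d-%d", r$label, r$start, r$end), collapse = ";")
    }, character(1))
    tab$regions <- unname(enc)
  }
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# deterministic seeded evaluation: save/restore the global RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
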