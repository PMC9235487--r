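# Region analysis and motif rendering ---------------------------------------
#
# Rule predicates are mapped onto the biological regions (FR1-4, CDR1-3,
# Other, PAD, Start, Stop) of each rule's own medoid annotation, and rule
# sets are rendered against the sequence logo of their split.

region_at <- function(regions_for_id, position) {
  hit <- regions_for_id$label[regions_for_id$start <= position &
                                position < regions_for_id$end]
  if (length(hit)) hit[1L] else NA_character_
}

#' Length-normalized distribution of rule predicates over regions
#'
#' Each predicate of each rule of the split is assigned to the region
#' containing its position in the rule's own medoid annotation; counts are
#' divided by the summed length of that region across the split's medoids.
#' Predicate positions not covered by any interval fall into `Other` with a
#' warning.
#'
#' @param rules List of `anchor_rule` objects (their `source$medoid_id` must
#'   be annotated in `region_map`).
#' @param region_map Region data frame (`id`, `label`, `start`, `end`).
#' @param split Split name the rules belong to (stored on the result).
#' @param mode `"predicate"` (default): one count per predicate;
#'   `"rule"`: each rule contributes `1 / n_predicates` per predicate, so a
#'   whole rule counts once.
#' @return Data frame with columns `split`, `region`, `count`, `length`,
#'   `density` (= count / length; `NA` for regions absent from the medoids).
#' @export
region_rule_distribution <- function(rules, region_map, split = NULL,
                                     mode = c("predicate", "rule")) {
  mode <- match.arg(mode)
  labels <- region_labels()
  counts <- stats::setNames(numeric(length(labels)), labels)
  lengths <- stats::setNames(numeric(length(labels)), labels)
  medoid_ids <- unique(vapply(rules, function(r) {
    id <- r$source$medoid_id
    if (is.null(id)) stop("rule lacks a source medoid id")
    id
  }, character(1)))
  for (id in medoid_ids) {
    ann <- region_map[region_map$id == id, , drop = FALSE]
    if (!nrow(ann)) stop("no region annotation for medoid ", id)
    for (j in seq_len(nrow(ann))) {
      lengths[ann$label[j]] <- lengths[ann$label[j]] +
        (ann$end[j] - ann$start[j])
    }
  }
  for (r in rules) {
    ann <- region_map[region_map$id == r$source$medoid_id, , drop = FALSE]
    p <- r$predicates
    wt <- if (mode == "rule" && nrow(p)) 1 / nrow(p) else 1
    for (pos in p$position) {
      lab <- region_at(ann, pos)
      if (is.na(lab)) {
        warning("predicate position ", pos, " of medoid ",
                r$source$medoid_id,
                " not covered by any region interval; counted as Other",
                call. = FALSE)
        lab <- "Other"
      }
      counts[lab] <- counts[lab] + wt
    }
  }
  data.frame(split = if (is.null(split)) NA_character_ else split,
             region = labels, count = unname(counts),
             length = unname(lengths),
             density = ifelse(lengths > 0, counts / lengths,
                              ifelse(counts > 0, NA_real_, 0)),
             stringsAsFactors = FALSE)
}

#' Position-by-symbol frequency matrix of a split
#'
#' Column j holds the relative frequencies of the non-PAD symbols observed
#' at frame position j across the samples (each non-empty column sums to 1).
#' All-PAD columns are flagged empty via the `"empty"` attribute.
#'
#' @param samples Non-empty `seq_set`.
#' @param region Optional region label: restrict to that region's interval
#'   (requires all samples to carry identical intervals for the label).
#' @return Numeric matrix symbols x positions, column names = 0-based frame
#'   positions, with attribute `empty` (logical per column).
#' @export
split_frequency_matrix <- function(samples, region = NULL) {
  if (n_samples(samples) == 0L) stop("empty sample list")
  frame <- frame_matrix(samples)
  cols <- seq_len(ncol(frame))
  if (!is.null(region)) {
    rm <- samples$regions
    if (is.null(rm)) stop("samples carry no region annotation")
    iv <- unique(rm[rm$label == region, c("start", "end")])
    if (!nrow(iv)) stop("region label ", region, " absent from the annotation")
    if (nrow(iv) > 1L) {
      stop("samples carry differing intervals for region ", region)
    }
    cols <- (iv$start + 1L):iv$end
  }
  syms <- sort(setdiff(unique(as.vector(frame[, cols, drop = FALSE])),
                       pad_token()))
  if (!length(syms)) syms <- pad_token()  # degenerate all-PAD set
  freq <- matrix(0, length(syms), length(cols),
                 dimnames = list(syms, cols - 1L))
  empty <- logical(length(cols))
  for (j in seq_along(cols)) {
    col <- frame[, cols[j]]
    col <- col[col != pad_token()]
    if (!length(col)) { empty[j] <- TRUE; next }
    tab <- table(col) / length(col)
    freq[names(tab), j] <- as.numeric(tab)
  }
  attr(freq, "empty") <- empty
  freq
}

# stacked-letter logo column at frame position `pos` (plot x = pos + 0.5)
draw_logo_column <- function(pos, freqs, y0 = 0, height = 1) {
  freqs <- freqs[freqs > 0]
  if (!length(freqs)) return(invisible())
  freqs <- sort(freqs)   # largest on top
  y <- y0
  for (i in seq_along(freqs)) {
    h <- freqs[[i]] * height
    sym <- names(freqs)[i]
    lab <- if (sym %in% reserved_tokens())
      sub("[<>]", "", sub(">$", "", sym)) else sym
    graphics::text(pos + 0.5, y + h / 2, lab,
                   cex = min(2.5, max(0.2, 3 * h)),
                   col = if (sym %in% reserved_tokens()) "grey60" else "black")
    y <- y + h
  }
  invisible()
}

#' Render a rule against its split's sequence logo
#'
#' Two-row motif figure: the rule's predicates on top (one letter per fixed
#' position), the split's per-position frequency logo below.  Written as SVG
#' so that identical input produces byte-identical files.
#'
#' @param rule An `anchor_rule`.
#' @param region_map Region data frame (used to shade/label regions; may be
#'   `NULL`).
#' @param freq Frequency matrix from [split_frequency_matrix()] over the
#'   same frame (or region window).
#' @param file Output file path (`.svg`).
#' @param region Optional region label: restrict the plot to that region's
#'   interval of the rule's medoid.
#' @param title Plot title.
#' @return `file`, invisibly.
#' @export
render_rule_motif <- function(rule, region_map, freq, file, region = NULL,
                              title = NULL) {
  positions <- as.integer(colnames(freq))
  window <- range(positions)
  ann <- NULL
  if (!is.null(region_map) && !is.null(rule$source$medoid_id)) {
    ann <- region_map[region_map$id == rule$source$medoid_id, , drop = FALSE]
  }
  if (!is.null(region)) {
    if (is.null(ann) || !region %in% ann$label) {
      stop("region label ", region, " absent from the rule's annotation")
    }
    iv <- ann[ann$label == region, , drop = FALSE][1L, ]
    window <- c(iv$start, iv$end - 1L)
  }
  keep <- positions >= window[1L] & positions <= window[2L]
  grDevices::svg(file, width = max(4, sum(keep) * 0.35), height = 3.2)
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(2.5, 3, if (is.null(title)) 1 else 2, 0.5))
  graphics::plot(NULL, xlim = c(window[1L], window[2L] + 1L), ylim = c(0, 2.3),
                 xlab = "", ylab = "", axes = FALSE, main = title)
  graphics::axis(1, at = positions[keep] + 0.5, labels = positions[keep],
                 cex.axis = 0.7, tick = FALSE, line = -0.8)
  graphics::mtext(c("rule", "split"), side = 2, at = c(1.8, 0.5), las = 1,
                  cex = 0.8)
  graphics::abline(h = c(0, 1, 1.3, 2.3), col = "grey80")
  # bottom row: split logo
  for (j in which(keep)) {
    draw_logo_column(positions[j], freq[, j], y0 = 0, height = 1)
  }
  # top row: the rule itself
  p <- rule$predicates
  p <- p[p$position >= window[1L] & p$position <= window[2L], , drop = FALSE]
  for (i in seq_len(nrow(p))) {
    draw_logo_column(p$position[i],
                     stats::setNames(1, p$symbol[i]), y0 = 1.3, height = 1)
  }
  if (!is.null(ann) && nrow(ann)) {
    inside <- ann[ann$end - 1L >= window[1L] & ann$start <= window[2L], ,
                  drop = FALSE]
    graphics::segments(inside$start, 2.32, inside$end, 2.32, col = "grey40")
    graphics::text((pmax(inside$start, window[1L]) +
                      pmin(inside$end, window[2L] + 1L)) / 2, 2.42,
                   inside$label, cex = 0.6, col = "grey40", xpd = NA)
  }
  invisible(file)
}

#' Bar chart of region rule densities
#'
#' Renders the output of [region_rule_distribution()] for one or both splits
#' as an SVG bar chart.
#'
#' @param density Data frame from [region_rule_distribution()] (rows from
#'   several splits may be stacked).
#' @param file Output `.svg` path.
#' @return `file`, invisibly.
#' @export
render_region_density <- function(density, file) {
  splits <- unique(density$split)
  grDevices::svg(file, width = 7, height = 3.5)
  on.exit(grDevices::dev.off())
  graphics::par(mfrow = c(1, length(splits)), mar = c(6, 4, 2, 1))
  for (s in splits) {
    d <- density[density$split %in% s, , drop = FALSE]
    graphics::barplot(d$density, names.arg = d$region, las = 2,
                      ylab = "predicates / position",
                      main = if (is.na(s)) "rules" else paste(s, "rules"),
                      col = if (identical(s, "binding")) "orange" else "steelblue")
  }
  invisible(file)
}
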