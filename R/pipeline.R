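# Pipeline stages ------------------------------------------------------------
#
# Each stage consumes only the declared artifacts of the previous stages,
# so any stage can be rerun from disk:
#   split     -> splits.tsv
#   cluster   -> clustering_<split>.tsv (+ sweep tables)
#   explain   -> anchors.jsonl, anchors.txt
#   evaluate  -> metrics.tsv, overlap_*.tsv, completeness.tsv,
#                region_density.tsv
#   visualize -> figures/*.svg
# run_pipeline() chains them and writes a run log.

stage_fail <- function(stage, e) {
  stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
       call. = FALSE)
}

load_pipeline_inputs <- function(config) {
  samples <- read_sequences(config$data$path, format = config$data$format)
  if (!is.null(config$data$regions_path)) {
    samples$regions <- validate_regions(read_region_map(
      config$data$regions_path), samples)
  }
  samples
}

split_file <- function(config) file.path(config$output_dir, "splits.tsv")
clust_file <- function(config, side) {
  file.path(config$output_dir,
            paste0("clustering_", sub("-", "_", side), ".tsv"))
}
anchors_file <- function(config) file.path(config$output_dir, "anchors.jsonl")

#' Run one pipeline stage
#'
#' See [run_pipeline()] for the overall flow; each stage reads its inputs
#' from `config$output_dir` and writes its declared artifacts there.
#'
#' @param config A validated `pipeline_config` (see [load_config()]).
#' @return The stage's main in-memory result, invisibly.
#' @export
stage_split <- function(config) {
  tryCatch({
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    samples <- load_pipeline_inputs(config)
    model <- config_model(config, samples)
    labels <- predict_labels(model, samples)
    split <- split_by_prediction(samples, labels)
    write_split(split, split_file(config))
    invisible(split)
  }, error = function(e) stage_fail("split", e))
}

#' @rdname stage_split
#' @export
stage_cluster <- function(config) {
  tryCatch({
    samples <- load_pipeline_inputs(config)
    split <- read_split(split_file(config))
    cc <- config$clustering
    out <- list()
    for (side in class_labels()) {
      ids <- split_ids(split, side)
      if (length(ids) < 2L) {
        stop("split '", side, "' has fewer than 2 samples; cannot cluster")
      }
      sub <- samples[ids]
      d <- if (!is.null(config$preprocessing$precomputed_distance)) {
        read_dist_matrix(config$preprocessing$precomputed_distance)[ids]
      } else {
        pairwise_distances(sub, metric = config$preprocessing$distance_metric)
      }
      grid <- if (cc$algorithm == "optics") unlist(cc$eps_grid)
              else unlist(cc$k_grid)
      grid <- grid[if (cc$algorithm == "optics") rep(TRUE, length(grid))
                   else grid <= length(ids)]
      if (!length(grid)) stop("empty usable parameter grid for split ", side)
      fit <- if (length(grid) > 1L) {
        sweep_clustering(d, cc$algorithm, grid, criterion = cc$criterion,
                         linkage = cc$linkage, min_pts = cc$min_pts,
                         seed = config$seed, split = side)
      } else if (cc$algorithm == "optics") {
        run_clustering(d, cc$algorithm, eps = grid, min_pts = cc$min_pts,
                       seed = config$seed, split = side)
      } else {
        run_clustering(d, cc$algorithm, k = as.integer(grid),
                       linkage = cc$linkage, seed = config$seed, split = side)
      }
      write_clustering(fit, clust_file(config, side))
      sweep <- attr(fit, "sweep")
      if (!is.null(sweep)) {
        utils::write.table(sweep,
                           file.path(config$output_dir,
                                     paste0("sweep_", sub("-", "_", side),
                                            ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
      out[[side]] <- fit
    }
    invisible(out)
  }, error = function(e) stage_fail("cluster", e))
}

#' @rdname stage_split
#' @export
stage_explain <- function(config) {
  tryCatch({
    samples <- load_pipeline_inputs(config)
    split <- read_split(split_file(config))
    model <- config_model(config, samples)
    ac <- config$anchors
    rules <- list()
    for (side in class_labels()) {
      cl <- read_clustering(clust_file(config, side))
      pool <- if (ac$pool == "all") samples
              else samples[split_ids(split, side)]
      for (k in names(cl$medoids)) {
        mid <- cl$medoids[[k]]
        params <- anchor_params(
          precision_threshold = ac$precision_threshold, delta = ac$delta,
          tau = ac$tau, beam_width = ac$beam_width,
          batch_size = ac$batch_size, max_predicates = ac$max_predicates,
          max_pulls = ac$max_pulls,
          seed = (as.numeric(config$seed) * 1000 + as.integer(k) +
                    if (side == "binding") 0 else 500) %% 2147480009)
        rules[[length(rules) + 1L]] <- find_anchor(
          samples[mid], model, pool, params,
          source = list(split = side, cluster = as.integer(k),
                        medoid_id = mid))
      }
    }
    write_anchors_jsonl(rules, anchors_file(config))
    writeLines(vapply(rules, format_anchor, character(1)),
               file.path(config$output_dir, "anchors.txt"))
    invisible(rules)
  }, error = function(e) stage_fail("explain", e))
}

#' @rdname stage_split
#' @export
stage_evaluate <- function(config) {
  tryCatch({
    samples <- load_pipeline_inputs(config)
    split <- read_split(split_file(config))
    rules <- read_anchors_jsonl(anchors_file(config))
    clusterings <- stats::setNames(
      lapply(class_labels(), function(s) read_clustering(clust_file(config, s))),
      class_labels())
    report <- metrics_report(rules, samples, split, clusterings,
                             cl_exclusive = config$evaluation$cl_exclusive,
                             cl_scope = config$evaluation$cl_scope)
    write_metrics_report(report, config$output_dir)
    if (!is.null(samples$regions)) {
      dens <- do.call(rbind, lapply(class_labels(), function(s) {
        rs <- Filter(function(r) identical(r$source$split, s), rules)
        if (!length(rs)) return(NULL)
        region_rule_distribution(rs, samples$regions, split = s,
                                 mode = config$evaluation$region_count_mode)
      }))
      utils::write.table(dens,
                         file.path(config$output_dir, "region_density.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    invisible(report)
  }, error = function(e) stage_fail("evaluate", e))
}

#' @rdname stage_split
#' @export
stage_visualize <- function(config) {
  tryCatch({
    samples <- load_pipeline_inputs(config)
    split <- read_split(split_file(config))
    rules <- read_anchors_jsonl(anchors_file(config))
    figdir <- file.path(config$output_dir, "figures")
    dir.create(figdir, showWarnings = FALSE, recursive = TRUE)
    for (side in class_labels()) {
      ids <- split_ids(split, side)
      if (!length(ids)) next
      freq <- split_frequency_matrix(samples[ids])
      rs <- Filter(function(r) identical(r$source$split, side), rules)
      for (r in rs) {
        render_rule_motif(r, samples$regions, freq,
                          file.path(figdir,
                                    sprintf("motif_%s_c%d.svg",
                                            sub("-", "_", side),
                                            r$source$cluster)),
                          title = sprintf("%s cluster %d (%s)", side,
                                          r$source$cluster,
                                          r$source$medoid_id))
      }
    }
    dens_path <- file.path(config$output_dir, "region_density.tsv")
    if (file.exists(dens_path)) {
      render_region_density(utils::read.delim(dens_path),
                            file.path(figdir, "region_density.svg"))
    }
    invisible(figdir)
  }, error = function(e) stage_fail("visualize", e))
}

#' Run the full rule-extraction pipeline
#'
#' Executes split -> cluster (per split, with hyperparameter sweep and
#' criterion selection) -> anchor per medoid -> evaluation (all metric
#' levels, overlap matrices, completeness histogram, region densities)
#' -> optional figures, writing every artifact into `config$output_dir`
#' together with a run log (`run_log.json`: versions, seed, chosen
#' clusterings).  Idempotent for a fixed config and seed: rerunning
#' produces byte-identical rule files and metric tables.
#'
#' @param config A `pipeline_config` (from [load_config()]) or a path to a
#'   JSON configuration file.
#' @return An object of class `pipeline_result` with elements `split`,
#'   `clusterings`, `rules`, `report`, `output_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- load_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  split <- stage_split(config)
  clusterings <- stage_cluster(config)
  rules <- stage_explain(config)
  report <- stage_evaluate(config)
  if (isTRUE(config$figures)) stage_visualize(config)
  log <- list(
    package = "seqanchors",
    package_version = as.character(utils::packageVersion("seqanchors")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    clustering = lapply(clusterings, function(cl) {
      list(algorithm = cl$algorithm, params = cl$params,
           n_clusters = n_clusters(cl),
           criterion_scores = as.list(cl$criterion_scores))
    }),
    n_rules = length(rules))
  jsonlite::write_json(log, file.path(config$output_dir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  structure(list(split = split, clusterings = clusterings, rules = rules,
                 report = report, output_dir = config$output_dir),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result> in ", x$output_dir, "\n", sep = "")
  cat("  binding: ", length(x$split$binding), " samples, ",
      "non-binding: ", length(x$split$non_binding), "\n", sep = "")
  for (s in names(x$clusterings)) {
    cat("  ", s, ": ", n_clusters(x$clusterings[[s]]), " clusters (",
        x$clusterings[[s]]$algorithm, ")\n", sep = "")
  }
  cat("  rules:\n")
  for (r in x$rules) cat("    ", format_anchor(r), "\n", sep = "")
  invisible(x)
}
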