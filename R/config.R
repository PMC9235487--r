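# JSON pipeline configuration ------------------------------------------------
#
# One JSON file drives the whole pipeline.  Validation is total: every
# violation is collected and reported at once, unknown keys are rejected by
# name, and the published defaults (precision threshold 0.9, delta 0.3,
# tau 0.3) are filled in.

config_schema <- function() {
  list(
    data = list(
      path = NULL,                    # required
      format = "auto",
      regions_path = NULL),
    model = list(
      type = NULL,                    # required: planted|constant|registered
      rules = NULL,                   # planted: list of [[pos, sym], ...]
      label_noise = 0,
      seed = 0,
      label = "binding",              # constant
      name = NULL),                   # registered adapter name
    preprocessing = list(
      distance_metric = "levenshtein",
      precomputed_distance = NULL),
    clustering = list(
      algorithm = "agglomerative",
      k_grid = list(4),
      linkage = "complete",
      eps_grid = NULL,
      min_pts = 5,
      criterion = "silhouette",
      consensus = FALSE),
    anchors = list(
      precision_threshold = 0.9,
      delta = 0.3,
      tau = 0.3,
      beam_width = 1,
      batch_size = 100,
      max_predicates = NULL,
      max_pulls = 20000,
      pool = "split"),                # split|all
    evaluation = list(
      cl_exclusive = TRUE,
      cl_scope = "all",
      region_count_mode = "predicate"),
    output_dir = NULL,                # required
    figures = FALSE,
    seed = 0)
}

.model_registry <- new.env(parent = emptyenv())

#' Register a user model adapter for the configuration file
#'
#' Makes a model constructable from a config with
#' `model: {type: "registered", name: "<name>"}`.
#'
#' @param name Adapter name.
#' @param fn Function `(model_section, samples) -> bbox_model`.
#' @return `name`, invisibly.
#' @export
register_model_adapter <- function(name, fn) {
  stopifnot(is.character(name), length(name) == 1L, is.function(fn))
  assign(name, fn, envir = .model_registry)
  invisible(name)
}

check_enum <- function(value, allowed, key, errors) {
  if (!is.null(value) && !value %in% allowed) {
    errors <- c(errors, paste0(key, " must be one of ",
                               paste(allowed, collapse = ", "),
                               " (got '", value, "')"))
  }
  errors
}

check_range <- function(value, lo, hi, key, errors,
                        lo_open = FALSE, hi_open = FALSE) {
  if (is.null(value)) return(errors)
  bad <- !is.numeric(value) ||
    (if (lo_open) value <= lo else value < lo) ||
    (if (hi_open) value >= hi else value > hi)
  if (bad) {
    errors <- c(errors, paste0(key, " must lie in ",
                               if (lo_open) "(" else "[", lo, ", ", hi,
                               if (hi_open) ")" else "]",
                               " (got ", value, ")"))
  }
  errors
}

# recursive unknown-key check against the schema
unknown_keys <- function(cfg, schema, prefix = "") {
  bad <- character(0)
  for (key in names(cfg)) {
    full <- paste0(prefix, key)
    if (!key %in% names(schema)) {
      bad <- c(bad, full)
    } else if (is.list(schema[[key]]) && !is.null(names(schema[[key]])) &&
               is.list(cfg[[key]])) {
      bad <- c(bad, unknown_keys(cfg[[key]], schema[[key]],
                                 paste0(full, ".")))
    }
  }
  bad
}

fill_defaults <- function(cfg, schema) {
  for (key in names(schema)) {
    if (is.null(cfg[[key]])) {
      cfg[key] <- schema[key]
    } else if (is.list(schema[[key]]) && !is.null(names(schema[[key]])) &&
               is.list(cfg[[key]])) {
      cfg[[key]] <- fill_defaults(cfg[[key]], schema[[key]])
    }
  }
  cfg
}

#' Load and validate a pipeline configuration
#'
#' Reads the JSON file, fills published defaults (threshold 0.9, delta 0.3,
#' tau 0.3), rejects unknown keys by name and reports every schema violation
#' at once.
#'
#' @param path Path to a JSON configuration file.
#' @param check_paths Verify that referenced input paths exist (default
#'   `TRUE`).
#' @return A validated config list of class `pipeline_config`.
#' @export
load_config <- function(path, check_paths = TRUE) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE,
                            simplifyMatrix = FALSE)
  validate_config(cfg, check_paths = check_paths)
}

#' @rdname load_config
#' @param cfg A configuration list (as parsed from JSON).
#' @export
validate_config <- function(cfg, check_paths = TRUE) {
  schema <- config_schema()
  errors <- character(0)
  bad <- unknown_keys(cfg, schema)
  if (length(bad)) {
    errors <- c(errors, paste0("unknown configuration key(s): ",
                               paste(bad, collapse = ", ")))
  }
  cfg <- fill_defaults(cfg, schema)

  if (is.null(cfg$data$path)) errors <- c(errors, "data.path is required")
  if (is.null(cfg$output_dir)) errors <- c(errors, "output_dir is required")
  if (is.null(cfg$model$type)) {
    errors <- c(errors, "model.type is required")
  } else {
    errors <- check_enum(cfg$model$type,
                         c("planted", "constant", "registered"),
                         "model.type", errors)
  }
  errors <- check_enum(cfg$data$format, c("auto", "fasta", "table"),
                       "data.format", errors)
  errors <- check_enum(cfg$clustering$algorithm,
                       c("k-medoids", "agglomerative", "optics", "birch"),
                       "clustering.algorithm", errors)
  errors <- check_enum(cfg$clustering$linkage,
                       c("complete", "average", "single"),
                       "clustering.linkage", errors)
  errors <- check_enum(cfg$clustering$criterion,
                       c("silhouette", "davies-bouldin"),
                       "clustering.criterion", errors)
  errors <- check_enum(cfg$anchors$pool, c("split", "all"),
                       "anchors.pool", errors)
  errors <- check_enum(cfg$evaluation$cl_scope, c("all", "split"),
                       "evaluation.cl_scope", errors)
  errors <- check_enum(cfg$evaluation$region_count_mode,
                       c("predicate", "rule"),
                       "evaluation.region_count_mode", errors)
  errors <- check_range(cfg$anchors$precision_threshold, 0, 1,
                        "anchors.precision_threshold", errors, lo_open = TRUE)
  errors <- check_range(cfg$anchors$delta, 0, 1, "anchors.delta", errors,
                        lo_open = TRUE, hi_open = TRUE)
  errors <- check_range(cfg$anchors$tau, 0, 1, "anchors.tau", errors,
                        lo_open = TRUE, hi_open = TRUE)
  errors <- check_range(cfg$model$label_noise, 0, 0.5, "model.label_noise",
                        errors, hi_open = TRUE)
  if (identical(cfg$model$type, "constant")) {
    errors <- check_enum(cfg$model$label, class_labels(), "model.label",
                         errors)
  }
  if (identical(cfg$model$type, "planted") && is.null(cfg$model$rules)) {
    errors <- c(errors, "model.rules is required for a planted model")
  }
  if (identical(cfg$model$type, "registered")) {
    if (is.null(cfg$model$name)) {
      errors <- c(errors, "model.name is required for a registered model")
    } else if (!exists(cfg$model$name, envir = .model_registry)) {
      errors <- c(errors, paste0("no registered model adapter named '",
                                 cfg$model$name, "'"))
    }
  }
  if (check_paths) {
    for (p in c(cfg$data$path, cfg$data$regions_path,
                cfg$preprocessing$precomputed_distance)) {
      if (!is.null(p) && !file.exists(p)) {
        errors <- c(errors, paste0("referenced path does not exist: ", p))
      }
    }
  }
  if (length(errors)) {
    stop("invalid configuration:\n  - ",
         paste(errors, collapse = "\n  - "), call. = FALSE)
  }
  structure(cfg, class = "pipeline_config")
}

config_model <- function(cfg, samples) {
  switch(cfg$model$type,
    constant = constant_model(cfg$model$label),
    planted = {
      rules <- lapply(cfg$model$rules, function(r) {
        predicates(vapply(r, function(q) as.integer(q[[1]]), integer(1)),
                   vapply(r, function(q) as.character(q[[2]]), character(1)))
      })
      planted_model(rules, label_noise = cfg$model$label_noise,
                    seed = cfg$model$seed,
                    frame_length = samples$frame_length)
    },
    registered = get(cfg$model$name, envir = .model_registry)(cfg$model,
                                                              samples))
}
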