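# Black-box model contract --------------------------------------------------

#' Class labels used throughout the pipeline
#' @return `c("binding", "non-binding")`.
#' @export
class_labels <- function() c("binding", "non-binding")

#' Wrap a predict function as a black-box model
#'
#' The only thing the pipeline ever asks of a model is a batch `predict`:
#' a function taking a [seq_set()] and returning one label from
#' [class_labels()] per sample, in order.  Any encoding the model needs
#' (BLOSUM, SMILES, physico-chemical factors, ...) is the adapter's business
#' and stays behind this contract.
#'
#' @param predict Function `seq_set -> character vector` of class labels.
#' @param name Short model name used in reports.
#' @param frame_length Optional expected frame length; when set,
#'   [predict_labels()] enforces it.
#' @param metadata Free-form list stored with the model.
#' @return An object of class `bbox_model`.
#' @export
black_box_model <- function(predict, name = "black-box", frame_length = NULL,
                            metadata = list()) {
  stopifnot(is.function(predict))
  structure(list(predict = predict, name = name,
                 frame_length = if (is.null(frame_length)) NULL
                                else as.integer(frame_length),
                 metadata = metadata),
            class = "bbox_model")
}

#' @export
print.bbox_model <- function(x, ...) {
  cat("<bbox_model> ", x$name,
      if (!is.null(x$frame_length)) paste0(" (frame length ", x$frame_length, ")"),
      "\n", sep = "")
  invisible(x)
}

#' Constant-prediction model
#'
#' @param label The label returned for every sample.
#' @return A `bbox_model`.
#' @export
constant_model <- function(label = "binding") {
  label <- match.arg(label, class_labels())
  black_box_model(function(samples) rep(label, n_samples(samples)),
                  name = paste0("constant(", label, ")"))
}

#' Adapt a probabilistic scorer into a binding/non-binding model
#'
#' Scores `>= threshold` are called `binding`.  Ties sit exactly at the
#' threshold and are therefore called `binding`; adapters wanting a
#' different tie rule should pre-shift their scores.
#'
#' @param score Function `seq_set -> numeric vector` of binding scores.
#' @param threshold Decision threshold, default 0.5.
#' @param name Model name.
#' @return A `bbox_model`.
#' @export
probability_model <- function(score, threshold = 0.5, name = "probability") {
  black_box_model(function(samples) {
    p <- score(samples)
    ifelse(p >= threshold, "binding", "non-binding")
  }, name = name)
}

#' Predict class labels for a batch of samples
#'
#' Thin contract-enforcing wrapper around a model's `predict`: checks the
#' frame length, the output length and the label vocabulary.
#'
#' @param model A `bbox_model`.
#' @param samples A `seq_set`.
#' @return Character vector of labels, one per sample, order-preserving.
#' @export
predict_labels <- function(model, samples) {
  stopifnot(inherits(model, "bbox_model"), inherits(samples, "seq_set"))
  if (!is.null(model$frame_length) &&
      samples$frame_length != model$frame_length) {
    offender <- if (n_samples(samples)) samples$ids[1] else "<empty set>"
    stop("frame length ", samples$frame_length,
         " does not match the model's expected frame length ",
         model$frame_length, " (sample ", offender, ")")
  }
  if (n_samples(samples) == 0L) return(character(0))
  labels <- model$predict(samples)
  if (length(labels) != n_samples(samples)) {
    stop("model returned ", length(labels), " labels for ",
         n_samples(samples), " samples")
  }
  if (any(!labels %in% class_labels())) {
    stop("model returned labels outside {",
         paste(class_labels(), collapse = ", "), "}")
  }
  labels
}

#' Split samples by model prediction
#'
#' Partitions a labelled batch into the binding and non-binding splits; all
#' downstream clustering and rule extraction is run separately per split.
#'
#' @param samples A `seq_set`.
#' @param labels Labels aligned with `samples` (from [predict_labels()]).
#' @return An object of class `prediction_split`: list with `binding` and
#'   `non_binding` id vectors and `label_of`, a named label vector.
#' @export
split_by_prediction <- function(samples, labels) {
  stopifnot(inherits(samples, "seq_set"))
  if (length(labels) != n_samples(samples)) {
    stop("got ", length(labels), " labels for ", n_samples(samples), " samples")
  }
  if (length(labels) && any(!labels %in% class_labels())) {
    stop("labels outside {", paste(class_labels(), collapse = ", "), "}")
  }
  label_of <- stats::setNames(as.character(labels), samples$ids)
  structure(list(binding = samples$ids[labels == "binding"],
                 non_binding = samples$ids[labels == "non-binding"],
                 label_of = label_of),
            class = "prediction_split")
}

#' @export
print.prediction_split <- function(x, ...) {
  cat("<prediction_split> binding: ", length(x$binding),
      ", non-binding: ", length(x$non_binding), "\n", sep = "")
  invisible(x)
}

#' Ids belonging to one side of a prediction split
#'
#' @param split A `prediction_split`.
#' @param side `"binding"` or `"non-binding"`.
#' @return Character id vector.
#' @export
split_ids <- function(split, side = class_labels()) {
  side <- match.arg(side)
  if (side == "binding") split$binding else split$non_binding
}

#' Write a prediction split as a delimited table
#'
#' @param split A `prediction_split`.
#' @param path Output path (tab-delimited, columns `id`, `predicted_class`).
#' @return `path`, invisibly.
#' @export
write_split <- function(split, path) {
  tab <- data.frame(id = names(split$label_of),
                    predicted_class = unname(split$label_of),
                    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_split
#' @param samples The `seq_set` the split refers to (to restore id order).
#' @export
read_split <- function(path, samples = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  structure(list(binding = tab$id[tab$predicted_class == "binding"],
                 non_binding = tab$id[tab$predicted_class == "non-binding"],
                 label_of = stats::setNames(tab$predicted_class, tab$id)),
            class = "prediction_split")
}
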