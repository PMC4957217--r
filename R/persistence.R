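MODEL_FORMAT_VERSION <- 1L

#' Save a trained model to disk
#'
#' The archive (an RDS file) stores a format version, the gap size,
#' normalization convention, selected feature subset, hyperparameters and
#' the fitted SVM, so a prediction run can verify compatibility before use.
#'
#' @param model A `ggap_svm_model` from [train_svm()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "ggap_svm_model"))
  saveRDS(list(format_version = MODEL_FORMAT_VERSION,
               package_version = as.character(utils::packageVersion("ggapfs")),
               model = model),
          path)
  invisible(path)
}

#' Load a model saved by [save_model()]
#'
#' Refuses archives written under a different (incompatible) format
#' version.
#'
#' @param path Path to the archive.
#' @return A `ggap_svm_model`.
#' @export
load_model <- function(path) {
  if (!file.exists(path))
    stop("model file '", path, "' does not exist", call. = FALSE)
  obj <- readRDS(path)
  if (!is.list(obj) || is.null(obj$format_version))
    stop("'", path, "' is not a saved model archive", call. = FALSE)
  if (obj$format_version != MODEL_FORMAT_VERSION)
    stop("model archive format version ", obj$format_version,
         " is incompatible with this package (expects ",
         MODEL_FORMAT_VERSION, ")", call. = FALSE)
  obj$model
}

#' Write a metrics report as TSV or JSON
#'
#' @param report A `metrics_report`.
#' @param path Output path; format chosen by extension (`.json` vs TSV).
#' @return `path`, invisibly.
#' @export
write_metrics <- function(report, path) {
  stopifnot(inherits(report, "metrics_report"))
  fields <- report[c("n_pos_correct", "n_neg_correct", "N_pos", "N_neg",
                     "Sn", "Sp", "OA")]
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(fields, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    utils::write.table(as.data.frame(fields), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
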