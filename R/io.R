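#' Read and write cohort artifacts
#'
#' Tables (manifest, predictions, threshold sweeps) are plain CSV with
#' documented headers; probability columns are named by coarse class so a
#' class-order mismatch is impossible at the file boundary. Bags are stored
#' in a single RDS container keyed by patient_id (rows = cells, columns =
#' embedding dimensions). Evaluation and attention reports serialize to
#' JSON.
#'
#' @name hemomil_io
NULL

#' @rdname hemomil_io
#' @param manifest cohort manifest data frame.
#' @param path file path.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' @rdname hemomil_io
#' @export
read_manifest <- function(path) {
  m <- utils::read.csv(path, check.names = FALSE,
                       colClasses = c(patient_id = "character"))
  required <- c("patient_id", "coarse_class", "hemoglobin")
  missing_cols <- setdiff(required, names(m))
  if (length(missing_cols))
    stop("manifest lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  m
}

#' @rdname hemomil_io
#' @param bags named list of `cell_bag`.
#' @export
write_bags <- function(bags, path) {
  stopifnot(all(vapply(bags, inherits, logical(1L), "cell_bag")))
  saveRDS(bags, path)
  invisible(path)
}

#' @rdname hemomil_io
#' @export
read_bags <- function(path) {
  bags <- readRDS(path)
  if (!is.list(bags) || !all(vapply(bags, inherits, logical(1L), "cell_bag")))
    stop("not a bag container: ", path, call. = FALSE)
  bags
}

#' @rdname hemomil_io
#' @param predictions predictions table (see [predict.hemomil()]).
#' @export
write_predictions <- function(predictions, path) {
  utils::write.csv(predictions, path, row.names = FALSE)
  invisible(path)
}

#' @rdname hemomil_io
#' @param h a `label_hierarchy` used to validate the probability columns.
#' @export
read_predictions <- function(path, h = default_hierarchy()) {
  p <- utils::read.csv(path, check.names = FALSE,
                       colClasses = c(patient_id = "character"))
  required <- c("patient_id", h$coarse_classes, "hemoglobin_predicted")
  missing_cols <- setdiff(required, names(p))
  if (length(missing_cols))
    stop("predictions table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  p
}

#' Save a fitted ensemble checkpoint
#'
#' The checkpoint bundles parameters, the full model configuration, the
#' coarse-class name order and the hemoglobin standardization constants.
#'
#' @param fit a `hemomil` ensemble or a single `mil_model`.
#' @param path file path (RDS).
#' @export
save_checkpoint <- function(fit, path) {
  stopifnot(inherits(fit, "hemomil") || inherits(fit, "mil_model"))
  saveRDS(fit, path)
  invisible(path)
}

#' Load a checkpoint, validating its class order
#'
#' Refuses to load if the stored coarse-class order differs from the active
#' hierarchy, preventing silent index/label mismatch.
#'
#' @param path file path.
#' @param hierarchy the active `label_hierarchy`.
#' @return The stored `hemomil` or `mil_model` object.
#' @export
load_checkpoint <- function(path, hierarchy = default_hierarchy()) {
  obj <- readRDS(path)
  order_stored <- if (inherits(obj, "hemomil"))
    obj$hierarchy$coarse_classes
  else if (inherits(obj, "mil_model")) obj$class_order
  else stop("not a hemomil checkpoint: ", path, call. = FALSE)
  if (!identical(order_stored, hierarchy$coarse_classes))
    stop("checkpoint class order (", paste(order_stored, collapse = ", "),
         ") differs from the active hierarchy", call. = FALSE)
  obj
}

#' Write an evaluation or attention report as JSON
#'
#' @param report an `evaluation_report` or `attention_report`.
#' @param path file path.
#' @export
write_report <- function(report, path) {
  x <- unclass(report)
  for (nm in names(x))
    if (is.table(x[[nm]]))
      x[[nm]] <- as.data.frame.matrix(x[[nm]])
  if (!is.null(x$sweep)) x$sweep <- as.data.frame(x$sweep)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
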