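#' Diagnostic label hierarchy
#'
#' Hematological diagnoses are organised on three levels: raw diagnostic
#' labels (free-text laboratory diagnoses), detailed classes (e.g. AML, CLL,
#' ET), and eight coarse classes used for classification. Six coarse classes
#' are malignant (acute leukemia, MDS, MDS/MPN, MPN, lymphoma, plasma cell
#' neoplasm); the two non-malignant classes are reactive changes and healthy.
#' The order of `coarse_classes` is authoritative: it fixes the index order of
#' every probability vector produced downstream.
#'
#' @param raw_to_detailed named character vector or list mapping raw labels to
#'   detailed class names.
#' @param detailed_to_coarse named character vector or list mapping detailed
#'   class names to coarse class names.
#' @param coarse_classes character vector of exactly 8 distinct coarse class
#'   names, in the order used for probability vectors.
#' @param malignant_flags named logical vector over `coarse_classes`; exactly
#'   6 must be `TRUE`, and the two `FALSE` classes must be
#'   `"reactive changes"` and `"healthy"`.
#' @return An object of class `label_hierarchy`.
#' @seealso [default_hierarchy()], [load_hierarchy()], [map_label()]
#' @export
label_hierarchy <- function(raw_to_detailed, detailed_to_coarse,
                            coarse_classes, malignant_flags) {
  raw_to_detailed <- unlist(raw_to_detailed)
  detailed_to_coarse <- unlist(detailed_to_coarse)
  malignant_flags <- unlist(malignant_flags)
  coarse_classes <- as.character(coarse_classes)

  if (length(coarse_classes) != 8L || anyDuplicated(coarse_classes))
    stop("`coarse_classes` must contain exactly 8 distinct class names, got ",
         length(coarse_classes), call. = FALSE)
  missing_flags <- setdiff(coarse_classes, names(malignant_flags))
  if (length(missing_flags))
    stop("malignant flag missing for coarse class: ",
         paste(missing_flags, collapse = ", "), call. = FALSE)
  malignant_flags <- as.logical(malignant_flags[coarse_classes])
  names(malignant_flags) <- coarse_classes
  if (anyNA(malignant_flags))
    stop("malignant flags must be logical", call. = FALSE)
  if (sum(malignant_flags) != 6L)
    stop("exactly 6 coarse classes must be flagged malignant, got ",
         sum(malignant_flags), call. = FALSE)
  benign <- sort(coarse_classes[!malignant_flags])
  if (!identical(benign, sort(c("healthy", "reactive changes"))))
    stop("the two non-malignant coarse classes must be 'reactive changes' ",
         "and 'healthy', got: ", paste(benign, collapse = ", "),
         call. = FALSE)

  dangling_coarse <- setdiff(unname(detailed_to_coarse), coarse_classes)
  if (length(dangling_coarse))
    stop("detailed class mapped to unknown coarse class: ",
         paste(dangling_coarse, collapse = ", "), call. = FALSE)
  dangling_detailed <- setdiff(unname(raw_to_detailed),
                               names(detailed_to_coarse))
  if (length(dangling_detailed))
    stop("raw label mapped to detailed class with no coarse assignment: ",
         paste(dangling_detailed, collapse = ", "), call. = FALSE)

  structure(
    list(raw_to_detailed = raw_to_detailed,
         detailed_to_coarse = detailed_to_coarse,
         coarse_classes = coarse_classes,
         malignant_flags = malignant_flags),
    class = "label_hierarchy")
}

#' Default exemplar hierarchy
#'
#' Ships the eight coarse classes with the detailed classes that are
#' enumerable from standard hematological practice (AML, ALL, CLL, ET, PV,
#' CML, multiple myeloma, MGUS, ...). The full laboratory label table is
#' site-specific; users override it via [load_hierarchy()].
#'
#' @return A `label_hierarchy`.
#' @export
default_hierarchy <- function() {
  load_hierarchy(system.file("extdata", "hierarchy_default.yaml",
                             package = "hemomil", mustWork = TRUE))
}

#' Load a label hierarchy from a YAML configuration file
#'
#' The file declares four blocks: `coarse_classes` (ordered list of 8),
#' `malignant` (map class -> true/false), `detailed_to_coarse` and
#' `raw_to_detailed` (maps). See
#' `system.file("extdata", "hierarchy_default.yaml", package = "hemomil")`
#' for the schema.
#'
#' @param path path to a YAML file.
#' @return A validated `label_hierarchy`.
#' @export
load_hierarchy <- function(path) {
  cfg <- yaml::read_yaml(path)
  for (field in c("coarse_classes", "malignant", "detailed_to_coarse",
                  "raw_to_detailed")) {
    if (is.null(cfg[[field]]))
      stop("hierarchy config is missing block '", field, "'", call. = FALSE)
  }
  label_hierarchy(raw_to_detailed = cfg$raw_to_detailed,
                  detailed_to_coarse = cfg$detailed_to_coarse,
                  coarse_classes = cfg$coarse_classes,
                  malignant_flags = cfg$malignant)
}

#' Resolve a raw diagnostic label through the hierarchy
#'
#' Accepts a raw label, a detailed class name, or a coarse class name, and
#' returns the full resolution. Unknown labels raise an error listing the
#' nearest known labels (by edit distance).
#'
#' @param h a `label_hierarchy`.
#' @param raw a single label string.
#' @return A list with elements `detailed`, `coarse` and `malignant`.
#' @export
map_label <- function(h, raw) {
  stopifnot(inherits(h, "label_hierarchy"), is.character(raw),
            length(raw) == 1L)
  if (raw %in% names(h$raw_to_detailed)) {
    detailed <- unname(h$raw_to_detailed[[raw]])
  } else if (raw %in% names(h$detailed_to_coarse)) {
    detailed <- raw
  } else if (raw %in% h$coarse_classes) {
    # coarse name given directly: detailed level collapses onto it
    return(list(detailed = raw, coarse = raw,
                malignant = unname(h$malignant_flags[[raw]])))
  } else {
    known <- unique(c(names(h$raw_to_detailed), names(h$detailed_to_coarse),
                      h$coarse_classes))
    d <- utils::adist(raw, known, ignore.case = TRUE)
    nearest <- known[order(d)][seq_len(min(3L, length(known)))]
    stop("unknown label '", raw, "'; nearest known labels: ",
         paste(nearest, collapse = ", "), call. = FALSE)
  }
  coarse <- unname(h$detailed_to_coarse[[detailed]])
  list(detailed = detailed, coarse = coarse,
       malignant = unname(h$malignant_flags[[coarse]]))
}

#' Names of the malignant coarse classes
#' @param h a `label_hierarchy`.
#' @return Character vector of the 6 malignant coarse classes, in class order.
#' @export
malignant_classes <- function(h) {
  stopifnot(inherits(h, "label_hierarchy"))
  h$coarse_classes[h$malignant_flags]
}

#' @export
print.label_hierarchy <- function(x, ...) {
  cat("Diagnostic label hierarchy\n")
  cat("  coarse classes (probability order):\n")
  for (cc in x$coarse_classes) {
    n_det <- sum(x$detailed_to_coarse == cc)
    cat(sprintf("    %-22s %-12s %d detailed class(es)\n", cc,
                if (x$malignant_flags[[cc]]) "malignant" else "non-malignant",
                n_det))
  }
  cat("  ", length(x$raw_to_detailed), "raw label aliases,",
      length(x$detailed_to_coarse), "detailed classes\n")
  invisible(x)
}
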