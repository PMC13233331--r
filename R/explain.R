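#' Per-patient attention explanation
#'
#' Combines the ensemble's bag-level outputs (class probabilities, predicted
#' hemoglobin, malignancy probability, per-cell attention) with per-cell
#' class assignments obtained by passing each cell through the model as a
#' singleton bag — the programmatic counterpart of a cell-level dashboard
#' view. Attention entropy (in nats) summarizes how concentrated the model's
#' focus is; a uniform distribution over n cells has entropy log(n).
#'
#' @param fit a `hemomil` ensemble (or list of `mil_model`).
#' @param bag a `cell_bag` or embedding matrix.
#' @param h a `label_hierarchy`.
#' @return An `attention_report`: `patient_id`, `class_probabilities`,
#'   `malignancy_probability`, `hemoglobin_predicted`, `attention_entropy`,
#'   and `cells` — a data frame with one row per cell (index, attention
#'   weight, optional true tag, singleton argmax class, singleton
#'   probability per class).
#' @export
explain <- function(fit, bag, h = default_hierarchy()) {
  X <- bag_matrix(bag)
  n <- nrow(X)
  bagpred <- ensemble_predict(fit, bag)
  att <- bagpred$attention_weights

  cell_probs <- matrix(NA_real_, n, length(h$coarse_classes),
                       dimnames = list(NULL, h$coarse_classes))
  for (i in seq_len(n)) {
    sp <- ensemble_predict(fit, X[i, , drop = FALSE])
    cell_probs[i, ] <- sp$class_probabilities[h$coarse_classes]
  }
  cell_class <- h$coarse_classes[max.col(cell_probs, ties.method = "first")]

  cells <- data.frame(cell = seq_len(n), attention = att,
                      singleton_class = cell_class, check.names = FALSE)
  if (inherits(bag, "cell_bag") && !is.null(bag$cell_types))
    cells$cell_type <- bag$cell_types
  cells <- cbind(cells, as.data.frame(cell_probs, check.names = FALSE))

  structure(list(
    patient_id = if (inherits(bag, "cell_bag")) bag$patient_id else NA,
    class_probabilities = bagpred$class_probabilities,
    malignancy_probability =
      malignancy_probability(bagpred$class_probabilities, h),
    hemoglobin_predicted = bagpred$hemoglobin_predicted,
    attention_entropy = -sum(ifelse(att > 0, att * log(att), 0)),
    cells = cells), class = "attention_report")
}

#' Indices of the most-attended cells
#'
#' @param report an `attention_report` (or a numeric attention vector).
#' @param m number of cells to return (`1 <= m <= n_cells`).
#' @return Integer cell indices of the `m` largest attention weights, in
#'   descending weight order; ties broken by ascending index.
#' @export
top_cells <- function(report, m) {
  w <- if (inherits(report, "attention_report")) report$cells$attention
       else as.numeric(report)
  stopifnot(m >= 1L, m <= length(w))
  order(-w, seq_along(w))[seq_len(m)]
}

#' @export
print.attention_report <- function(x, ...) {
  cat("<attention_report> patient", x$patient_id, "\n")
  pr <- sort(x$class_probabilities, decreasing = TRUE)
  cat(sprintf("  top class: %s (%.3f); malignancy probability %.3f\n",
              names(pr)[1L], pr[1L], x$malignancy_probability))
  cat(sprintf("  predicted hemoglobin %.2f g/dL\n", x$hemoglobin_predicted))
  n <- nrow(x$cells)
  cat(sprintf("  %d cells; attention entropy %.2f nats (uniform = %.2f)\n",
              n, x$attention_entropy, log(n)))
  top <- top_cells(x, min(5L, n))
  cat("  most-attended cells:\n")
  for (i in top) {
    tag <- if (!is.null(x$cells$cell_type)) x$cells$cell_type[i] else ""
    cat(sprintf("    cell %4d  attention %.4f  %s -> %s\n", i,
                x$cells$attention[i], tag, x$cells$singleton_class[i]))
  }
  invisible(x)
}
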