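#' Malignancy probability of a class-probability vector
#'
#' The sum of predicted probabilities over the six malignant coarse classes;
#' algebraically equal to `1 - p(reactive changes) - p(healthy)`.
#'
#' @param p probability vector over the coarse classes, either named or in
#'   hierarchy order.
#' @param h a `label_hierarchy`.
#' @return A single number in `[0, 1]`.
#' @export
malignancy_probability <- function(p, h) {
  p <- align_probs(p, h)
  sum(p[h$malignant_flags])
}

align_probs <- function(p, h) {
  if (!is.null(names(p))) {
    missing <- setdiff(h$coarse_classes, names(p))
    if (length(missing))
      stop("probability vector lacks class(es): ",
           paste(missing, collapse = ", "), call. = FALSE)
    p <- p[h$coarse_classes]
  } else if (length(p) != length(h$coarse_classes)) {
    stop("probability vector has length ", length(p), ", expected ",
         length(h$coarse_classes), call. = FALSE)
  }
  if (abs(sum(p) - 1) > 1e-6)
    stop("probabilities sum to ", sum(p), ", not 1", call. = FALSE)
  as.numeric(p)
}

# probability matrix (patients x classes) in hierarchy column order
align_prob_matrix <- function(P, h) {
  P <- as.matrix(as.data.frame(P, check.names = FALSE)[, h$coarse_classes,
                                                       drop = FALSE])
  if (any(abs(rowSums(P) - 1) > 1e-6))
    stop("probability rows must sum to 1", call. = FALSE)
  P
}

#' Biopsy-recommendation triage decision
#'
#' A bone marrow biopsy is recommended when the malignancy probability
#' strictly exceeds the threshold (default 0.5).
#'
#' @param p probability vector over coarse classes (or a `bag_prediction`).
#' @param h a `label_hierarchy`.
#' @param threshold decision threshold in `[0, 1]`.
#' @return A `triage_decision`: `malignancy_probability`, `threshold`,
#'   `recommend_biopsy`.
#' @export
triage <- function(p, h, threshold = 0.5) {
  stopifnot(threshold >= 0, threshold <= 1)
  if (inherits(p, "bag_prediction")) p <- p$class_probabilities
  mp <- malignancy_probability(p, h)
  structure(list(malignancy_probability = mp, threshold = threshold,
                 recommend_biopsy = mp > threshold),
            class = "triage_decision")
}

#' Sweep the malignancy threshold over a grid
#'
#' For each threshold, counts biopsy recommendations (strict `>` comparison)
#' and computes malignancy sensitivity and specificity, the aspiration FDR
#' (fraction of biopsy-recommended patients whose true class is
#' non-malignant), and acute-leukemia sensitivity (fraction of true
#' acute-leukemia patients recommended). Also reports the largest threshold
#' that keeps acute-leukemia sensitivity at 1 and the FDR achieved there.
#'
#' @param predictions probability matrix/data frame (patients x coarse
#'   classes, columns named by class) or a predictions table from
#'   [predict.hemomil()].
#' @param truth character vector of true coarse classes, aligned with rows.
#' @param h a `label_hierarchy`.
#' @param thresholds ascending numeric grid in `[0, 1]`.
#' @return A data frame of class `threshold_sweep` with one row per
#'   threshold; attributes `al_safe_threshold` and `al_safe_fdr`.
#' @export
threshold_sweep <- function(predictions, truth, h,
                            thresholds = seq(0, 1, by = 0.01)) {
  stopifnot(!is.unsorted(thresholds), all(thresholds >= 0 & thresholds <= 1))
  P <- align_prob_matrix(predictions, h)
  stopifnot(nrow(P) == length(truth))
  mal_p <- rowSums(P[, malignant_classes(h), drop = FALSE])
  truth_mal <- truth %in% malignant_classes(h)
  is_al <- truth == "acute leukemia"
  n_mal <- sum(truth_mal)
  n_ben <- sum(!truth_mal)
  n_al <- sum(is_al)

  rows <- lapply(thresholds, function(th) {
    rec <- mal_p > th
    n_rec <- sum(rec)
    data.frame(
      threshold = th,
      n_recommended = n_rec,
      sensitivity = if (n_mal) sum(rec & truth_mal) / n_mal else NA_real_,
      specificity = if (n_ben) sum(!rec & !truth_mal) / n_ben else NA_real_,
      fdr = if (n_rec) sum(rec & !truth_mal) / n_rec else NA_real_,
      acute_leukemia_sensitivity =
        if (n_al) sum(rec & is_al) / n_al else NA_real_)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("threshold_sweep", "data.frame")
  if (n_al) {
    safe <- out$threshold[!is.na(out$acute_leukemia_sensitivity) &
                            out$acute_leukemia_sensitivity == 1]
    attr(out, "al_safe_threshold") <- if (length(safe)) max(safe) else NA_real_
    attr(out, "al_safe_fdr") <- if (length(safe))
      out$fdr[out$threshold == max(safe)] else NA_real_
  } else {
    attr(out, "al_safe_threshold") <- NA_real_
    attr(out, "al_safe_fdr") <- NA_real_
  }
  out
}

#' Clinical baseline rate of unnecessary aspirations
#'
#' In routine practice every patient with a suspected malignancy or reactive
#' changes receives a bone marrow aspiration (healthy stem-cell donors are
#' not aspirated for diagnosis), so the baseline "unnecessary biopsy" rate
#' is `reactive / (reactive + sum of malignant-class counts)`.
#'
#' @param class_counts named nonnegative counts per coarse class.
#' @param h a `label_hierarchy`.
#' @return The baseline aspiration FDR as a fraction in `[0, 1]`.
#' @export
clinical_baseline_fdr <- function(class_counts, h) {
  stopifnot(all(class_counts >= 0))
  unknown <- setdiff(names(class_counts), h$coarse_classes)
  if (length(unknown))
    stop("unknown class(es): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cnt <- function(cc) if (cc %in% names(class_counts))
    class_counts[[cc]] else 0
  reactive <- cnt("reactive changes")
  aspirated <- reactive + sum(vapply(malignant_classes(h), cnt, numeric(1L)))
  if (aspirated == 0) return(0)
  reactive / aspirated
}

#' Confusion matrix with per-class sensitivity and precision
#'
#' @param truth,predicted aligned class-label vectors.
#' @param class_order character vector fixing row/column order.
#' @return List with `confusion` (rows = truth, columns = prediction),
#'   `sensitivity` (TP / truth count), `precision` (TP / predicted count,
#'   `NA` where a class is never predicted), and `accuracy`.
#' @export
confusion_and_rates <- function(truth, predicted, class_order) {
  stopifnot(length(truth) == length(predicted))
  bad <- setdiff(unique(c(truth, predicted)), class_order)
  if (length(bad))
    stop("label(s) outside class order: ", paste(bad, collapse = ", "),
         call. = FALSE)
  tf <- factor(truth, levels = class_order)
  pf <- factor(predicted, levels = class_order)
  cm <- table(truth = tf, predicted = pf)
  tp <- diag(cm)
  row_n <- rowSums(cm)
  col_n <- colSums(cm)
  sens <- ifelse(row_n > 0, tp / row_n, NA_real_)
  prec <- ifelse(col_n > 0, tp / col_n, NA_real_)
  list(confusion = cm,
       sensitivity = stats::setNames(as.numeric(sens), class_order),
       precision = stats::setNames(as.numeric(prec), class_order),
       accuracy = sum(tp) / length(truth))
}

#' Top-k accuracy
#'
#' Fraction of cases whose true class is among the `k` highest-probability
#' classes; probability ties are broken by the fixed class order.
#'
#' @param P probability matrix/data frame (patients x classes, columns in
#'   class order or named by class).
#' @param truth true class labels.
#' @param k number of top classes considered.
#' @param class_order column order; defaults to `colnames(P)`.
#' @return A fraction in `[0, 1]`.
#' @export
topk_accuracy <- function(P, truth, k, class_order = colnames(P)) {
  stopifnot(k >= 1L)
  P <- as.matrix(as.data.frame(P, check.names = FALSE)[, class_order,
                                                       drop = FALSE])
  k <- min(k, ncol(P))
  hits <- vapply(seq_len(nrow(P)), function(i) {
    topk <- class_order[order(-P[i, ], seq_len(ncol(P)))[seq_len(k)]]
    truth[i] %in% topk
  }, logical(1L))
  mean(hits)
}

#' Top-label expected calibration error
#'
#' Patients are binned by their maximum predicted probability into
#' `n_bins` equal-width bins over (0, 1]; the ECE is the bin-weighted mean
#' absolute gap between bin accuracy and bin mean confidence. Empty bins
#' contribute 0.
#'
#' @inheritParams topk_accuracy
#' @param n_bins number of equal-width confidence bins.
#' @return ECE as a fraction in `[0, 1]`.
#' @export
expected_calibration_error <- function(P, truth, n_bins = 10L,
                                       class_order = colnames(P)) {
  stopifnot(n_bins >= 1L)
  P <- as.matrix(as.data.frame(P, check.names = FALSE)[, class_order,
                                                       drop = FALSE])
  pred_idx <- max.col(P, ties.method = "first")
  conf <- P[cbind(seq_len(nrow(P)), pred_idx)]
  correct <- class_order[pred_idx] == truth
  bin <- pmax(ceiling(conf * n_bins), 1L)
  n <- length(conf)
  ece <- 0
  for (b in unique(bin)) {
    in_b <- bin == b
    ece <- ece + sum(in_b) / n * abs(mean(correct[in_b]) - mean(conf[in_b]))
  }
  ece
}

#' Rank-based AUROC (Mann-Whitney, ties counted half)
#'
#' @param scores numeric scores (higher = more likely positive).
#' @param truth logical (or 0/1) vector of true positives.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, truth) {
  truth <- as.logical(truth)
  stopifnot(length(scores) == length(truth), !anyNA(truth))
  n1 <- sum(truth)
  n0 <- sum(!truth)
  if (n1 == 0L || n0 == 0L)
    stop("both classes must be present to compute AUROC", call. = FALSE)
  r <- rank(scores)  # average ranks: ties get half credit
  (sum(r[truth]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Agreement between predicted and measured values
#'
#' Product-moment and rank correlations plus the mean absolute error (in the
#' measurement's units, g/dL for hemoglobin).
#'
#' @param predicted,measured aligned numeric vectors; at least 3 finite
#'   pairs required.
#' @return List with `pearson`, `spearman`, `mae`, `n`.
#' @export
agreement_metrics <- function(predicted, measured) {
  ok <- is.finite(predicted) & is.finite(measured)
  if (sum(ok) < 3L)
    stop("need at least 3 finite pairs, got ", sum(ok), call. = FALSE)
  x <- predicted[ok]
  y <- measured[ok]
  list(pearson = stats::cor(x, y),
       spearman = stats::cor(x, y, method = "spearman"),
       mae = mean(abs(x - y)),
       n = sum(ok))
}

#' Full evaluation report
#'
#' Consumes a predictions table (patient_id, one probability column per
#' coarse class, `hemoglobin_predicted`) and the cohort manifest; computes
#' the coarse confusion matrix with per-class sensitivity/precision, overall
#' and top-k accuracy, malignant-vs-non-malignant AUROC, expected
#' calibration error, hemoglobin agreement, probability-vs-cell-ratio
#' correlations (acute-leukemia probability vs blast ratio, lymphoma
#' probability vs lymphocyte ratio, when the manifest carries the ratios),
#' and a malignancy-threshold sweep. When the manifest has a
#' `detailed_class` column, a detailed-truth x coarse-prediction confusion
#' matrix is included.
#'
#' @param predictions predictions table (see [predict.hemomil()]).
#' @param manifest cohort manifest with `patient_id`, `coarse_class`,
#'   `hemoglobin`, optionally `detailed_class`, `blast_ratio`,
#'   `lymphocyte_ratio`.
#' @param h a `label_hierarchy`.
#' @param top_k integer vector of k values for top-k accuracy.
#' @param n_bins ECE bins.
#' @param thresholds grid for [threshold_sweep()].
#' @return An `evaluation_report` list.
#' @export
evaluate_predictions <- function(predictions, manifest,
                                 h = default_hierarchy(), top_k = c(1L, 2L),
                                 n_bins = 10L,
                                 thresholds = seq(0, 1, by = 0.01)) {
  required <- c("patient_id", h$coarse_classes, "hemoglobin_predicted")
  missing_cols <- setdiff(required, names(predictions))
  if (length(missing_cols))
    stop("predictions table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  m <- manifest[match(predictions$patient_id, manifest$patient_id), ]
  if (anyNA(m$patient_id))
    stop("predictions contain patient_ids absent from the manifest",
         call. = FALSE)
  P <- align_prob_matrix(predictions, h)
  truth <- m$coarse_class
  pred_cls <- h$coarse_classes[max.col(P, ties.method = "first")]

  rates <- confusion_and_rates(truth, pred_cls, h$coarse_classes)
  mal_p <- rowSums(P[, malignant_classes(h), drop = FALSE])
  truth_mal <- truth %in% malignant_classes(h)

  report <- list(
    n = nrow(P),
    confusion = rates$confusion,
    sensitivity = rates$sensitivity,
    precision = rates$precision,
    accuracy = rates$accuracy,
    top_k = stats::setNames(
      vapply(top_k, function(k)
        topk_accuracy(P, truth, k, h$coarse_classes), numeric(1L)),
      paste0("top", top_k)),
    ece = expected_calibration_error(P, truth, n_bins, h$coarse_classes),
    malignancy_auroc = if (any(truth_mal) && any(!truth_mal))
      auroc(mal_p, truth_mal) else NA_real_,
    hemoglobin = if (!is.null(m$hemoglobin))
      agreement_metrics(predictions$hemoglobin_predicted, m$hemoglobin)
      else NULL,
    sweep = threshold_sweep(P, truth, h, thresholds))

  if (!is.null(m$blast_ratio))
    report$blast_correlation <- stats::cor(
      P[, "acute leukemia"], m$blast_ratio, method = "spearman")
  if (!is.null(m$lymphocyte_ratio))
    report$lymphocyte_correlation <- stats::cor(
      P[, "lymphoma"], m$lymphocyte_ratio, method = "spearman")
  if (!is.null(m$detailed_class)) {
    det_levels <- unique(c(names(h$detailed_to_coarse), m$detailed_class))
    report$detailed_confusion <- table(
      truth = factor(m$detailed_class,
                     levels = intersect(det_levels, m$detailed_class)),
      predicted = factor(pred_cls, levels = h$coarse_classes))
  }
  class(report) <- "evaluation_report"
  report
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("Evaluation report (", x$n, " patients)\n", sep = "")
  cat(sprintf("  accuracy %.3f", x$accuracy))
  for (nm in names(x$top_k)) cat(sprintf("  %s %.3f", nm, x$top_k[[nm]]))
  cat("\n")
  cat(sprintf("  malignancy AUROC %.3f   ECE %.3f\n",
              x$malignancy_auroc, x$ece))
  if (!is.null(x$hemoglobin))
    cat(sprintf("  hemoglobin: Pearson %.3f, MAE %.2f g/dL\n",
                x$hemoglobin$pearson, x$hemoglobin$mae))
  if (!is.null(x$blast_correlation))
    cat(sprintf("  Spearman(acute-leukemia prob, blast ratio) %.3f\n",
                x$blast_correlation))
  th <- attr(x$sweep, "al_safe_threshold")
  if (!is.na(th))
    cat(sprintf("  largest threshold with full acute-leukemia sensitivity: %.2f (FDR %.3f)\n",
                th, attr(x$sweep, "al_safe_fdr")))
  cat("  per-class sensitivity:\n")
  for (cc in names(x$sensitivity))
    cat(sprintf("    %-22s %.3f\n", cc, x$sensitivity[[cc]]))
  invisible(x)
}

#' @export
print.triage_decision <- function(x, ...) {
  cat(sprintf("<triage> malignancy probability %.3f vs threshold %.2f -> %s\n",
              x$malignancy_probability, x$threshold,
              if (x$recommend_biopsy) "recommend bone marrow biopsy"
              else "no biopsy recommended"))
  invisible(x)
}
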