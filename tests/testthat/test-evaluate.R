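h <- default_hierarchy()

test_that("malignancy probability sums the six malignant classes", {
  uniform <- stats::setNames(rep(1 / 8, 8L), h$coarse_classes)
  expect_equal(malignancy_probability(uniform, h), 0.75)

  onehot <- function(cc) stats::setNames(as.numeric(h$coarse_classes == cc),
                                         h$coarse_classes)
  expect_equal(malignancy_probability(onehot("healthy"), h), 0)
  expect_equal(malignancy_probability(onehot("MDS"), h), 1)

  # identity 1 - p(reactive) - p(healthy), random simplex points
  set.seed(1)
  for (i in 1:50) {
    p <- stats::setNames(random_simplex(8L), h$coarse_classes)
    expect_lt(abs(malignancy_probability(p, h) -
                    (1 - p[["reactive changes"]] - p[["healthy"]])), 1e-9)
  }
})

test_that("triage uses a strict threshold comparison", {
  p <- stats::setNames(rep(1 / 8, 8L), h$coarse_classes)  # malignancy 0.75
  expect_true(triage(p, h, threshold = 0.74)$recommend_biopsy)
  expect_false(triage(p, h, threshold = 0.75)$recommend_biopsy)
  expect_true(triage(p, h, threshold = 0)$recommend_biopsy)
  expect_error(triage(p, h, threshold = 1.2))
})

test_that("clinical baseline FDR reproduces the printed cohort arithmetic", {
  counts <- c("acute leukemia" = 46, "MDS" = 38, "MDS/MPN" = 22,
              "MPN" = 48, "lymphoma" = 57, "plasma cell neoplasm" = 57,
              "reactive changes" = 42, "healthy" = 99)
  expect_equal(clinical_baseline_fdr(counts, h), 42 / 310)
  expect_equal(round(100 * clinical_baseline_fdr(counts, h), 1), 13.5)
  counts0 <- counts; counts0["reactive changes"] <- 0
  expect_equal(clinical_baseline_fdr(counts0, h), 0)
  expect_equal(clinical_baseline_fdr(
    c("reactive changes" = 10), h), 1)
  expect_error(clinical_baseline_fdr(c(foo = 1), h), "unknown class")
})

test_that("confusion rates match hand counts", {
  truth <- c(rep("CLL-like", 0), rep("lymphoma", 15), rep("healthy", 5))
  pred <- c(rep("lymphoma", 12), rep("plasma cell neoplasm", 3),
            rep("healthy", 5))
  r <- confusion_and_rates(truth, pred, h$coarse_classes)
  expect_equal(r$sensitivity[["lymphoma"]], 0.80)  # 12 of 15 correct
  expect_equal(r$precision[["lymphoma"]], 1)
  expect_equal(unname(rowSums(r$confusion)[c("lymphoma", "healthy")]),
               c(15, 5))

  perfect <- confusion_and_rates(truth, truth, h$coarse_classes)
  expect_equal(perfect$accuracy, 1)
  expect_true(all(perfect$sensitivity[c("lymphoma", "healthy")] == 1))

  # everything predicted as one class: its precision equals its prior
  truth10 <- c("MDS", "MDS", "MDS", "MPN", "healthy", "healthy", "lymphoma",
               "MDS", "MPN", "healthy")
  all_mds <- rep("MDS", 10L)
  r2 <- confusion_and_rates(truth10, all_mds, h$coarse_classes)
  expect_equal(r2$precision[["MDS"]], 4 / 10)
  expect_true(is.na(r2$precision[["MPN"]]))  # never predicted
  expect_error(confusion_and_rates(c("X"), c("MDS"), h$coarse_classes),
               "outside class order")
})

test_that("top-k accuracy matches exhaustive enumeration", {
  set.seed(7)
  P <- random_prob_matrix(5L, h)
  truth <- sample(h$coarse_classes, 5L, replace = TRUE)
  for (k in c(1L, 2L, 3L, 8L)) {
    oracle <- mean(vapply(1:5, function(i) {
      ranked <- h$coarse_classes[order(-P[i, ], seq_len(8L))]
      truth[i] %in% ranked[seq_len(k)]
    }, logical(1L)))
    expect_equal(topk_accuracy(P, truth, k, h$coarse_classes), oracle)
  }
  expect_equal(topk_accuracy(P, truth, 8L, h$coarse_classes), 1)
  pred_top1 <- h$coarse_classes[max.col(P, ties.method = "first")]
  expect_equal(topk_accuracy(P, truth, 1L, h$coarse_classes),
               mean(pred_top1 == truth))
})

test_that("expected calibration error matches a brute-force binning oracle", {
  classes <- h$coarse_classes
  # perfectly calibrated one-hot predictions
  P1 <- matrix(0, 10L, 8L, dimnames = list(NULL, classes))
  P1[cbind(1:10, rep(c(1L, 3L), 5L))] <- 1
  truth1 <- classes[rep(c(1L, 3L), 5L)]
  expect_equal(expected_calibration_error(P1, truth1), 0)

  # constant 0.9 confidence, 90% accurate: single perfectly calibrated bin
  P2 <- matrix((1 - 0.9) / 7, 10L, 8L, dimnames = list(NULL, classes))
  P2[, 1L] <- 0.9
  truth2 <- c(rep(classes[1L], 9L), classes[2L])
  expect_equal(expected_calibration_error(P2, truth2), 0, tolerance = 1e-12)

  set.seed(11)
  P <- random_prob_matrix(50L, h)
  truth <- sample(classes, 50L, replace = TRUE)
  for (n_bins in c(5L, 10L, 15L)) {
    conf <- apply(P, 1L, max)
    pred <- classes[apply(P, 1L, which.max)]
    correct <- pred == truth
    oracle <- 0
    for (b in seq_len(n_bins)) {
      lo <- (b - 1) / n_bins
      hi <- b / n_bins
      in_b <- if (b == 1L) conf <= hi else conf > lo & conf <= hi
      if (any(in_b))
        oracle <- oracle + sum(in_b) / 50 *
          abs(mean(correct[in_b]) - mean(conf[in_b]))
    }
    expect_equal(expected_calibration_error(P, truth, n_bins), oracle,
                 tolerance = 1e-9)
  }
})

test_that("AUROC equals all-pairs counting with half credit for ties", {
  expect_equal(auroc(c(1, 2, 3, 11, 12), c(0, 0, 0, 1, 1)), 1)
  expect_equal(auroc(rep(0.4, 6L), c(1, 0, 1, 0, 1, 0)), 0.5)
  expect_error(auroc(1:3, c(1, 1, 1)), "both classes")

  set.seed(13)
  scores <- round(rnorm(20), 1)  # rounding forces ties
  truth <- rbinom(20, 1, 0.4) == 1
  pos <- scores[truth]
  neg <- scores[!truth]
  oracle <- 0
  for (a in pos) for (b in neg)
    oracle <- oracle + (a > b) + 0.5 * (a == b)
  oracle <- oracle / (length(pos) * length(neg))
  expect_equal(auroc(scores, truth), oracle, tolerance = 1e-9)
})

test_that("agreement metrics follow the closed forms", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(agreement_metrics(x, x)$pearson, 1)
  expect_equal(agreement_metrics(x, x)$mae, 0)
  expect_equal(agreement_metrics(x, -x)$pearson, -1)
  expect_error(agreement_metrics(c(1, 2), c(1, 2)), "3 finite pairs")

  set.seed(3)
  a <- rnorm(10L)
  b <- rnorm(10L)
  m <- agreement_metrics(a, b)
  expect_equal(m$pearson,
               sum((a - mean(a)) * (b - mean(b))) /
                 sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2)),
               tolerance = 1e-12)
  expect_equal(m$spearman, stats::cor(rank(a), rank(b)), tolerance = 1e-12)
  expect_equal(m$mae, mean(abs(a - b)))
})

test_that("threshold sweep matches a brute-force recount", {
  set.seed(17)
  n <- 200L
  P <- random_prob_matrix(n, h)
  truth <- sample(h$coarse_classes, n, replace = TRUE,
                  prob = c(3, 2, 1, 2, 2, 2, 2, 4))
  grid <- seq(0, 1, by = 0.05)
  sw <- threshold_sweep(P, truth, h, grid)
  mal_p <- rowSums(P[, malignant_classes(h)])
  truth_mal <- truth %in% malignant_classes(h)
  for (r in seq_len(nrow(sw))) {
    th <- sw$threshold[r]
    rec <- mal_p > th
    expect_equal(sw$n_recommended[r], sum(rec))
    expect_equal(sw$sensitivity[r], sum(rec & truth_mal) / sum(truth_mal),
                 tolerance = 1e-9)
    expect_equal(sw$specificity[r], sum(!rec & !truth_mal) / sum(!truth_mal),
                 tolerance = 1e-9)
    expect_equal(sw$fdr[r],
                 if (sum(rec)) sum(rec & !truth_mal) / sum(rec) else
                   NA_real_, tolerance = 1e-9)
    expect_equal(sw$acute_leukemia_sensitivity[r],
                 sum(rec & truth == "acute leukemia") /
                   sum(truth == "acute leukemia"), tolerance = 1e-9)
  }
  # monotonicity along the ascending grid
  expect_true(all(diff(sw$n_recommended) <= 0))
  expect_true(all(diff(sw$acute_leukemia_sensitivity) <= 1e-12))
})

test_that("sweep edge cases: separation, single threshold, missing classes", {
  # perfectly separating scores: zero FDR with full sensitivity somewhere
  P <- matrix(0, 6L, 8L, dimnames = list(NULL, h$coarse_classes))
  P[1:3, "acute leukemia"] <- 0.9; P[1:3, "healthy"] <- 0.1
  P[4:6, "healthy"] <- 0.95; P[4:6, "MDS"] <- 0.05
  truth <- c(rep("acute leukemia", 3L), rep("healthy", 3L))
  sw <- threshold_sweep(P, truth, h, seq(0, 1, 0.1))
  best <- sw[!is.na(sw$fdr) & sw$sensitivity == 1, ]
  expect_true(any(best$fdr == 0))
  expect_equal(attr(sw, "al_safe_threshold"), 0.8)

  # grid of length 1 equals pointwise triage counts
  sw1 <- threshold_sweep(P, truth, h, 0.5)
  rec <- vapply(1:6, function(i)
    triage(P[i, ], h, 0.5)$recommend_biopsy, logical(1L))
  expect_equal(sw1$n_recommended, sum(rec))

  # no acute-leukemia patients: sensitivity reported missing, not 1
  sw2 <- threshold_sweep(P[4:6, ], truth[4:6], h, c(0.2, 0.5))
  expect_true(all(is.na(sw2$acute_leukemia_sensitivity)))
})

test_that("evaluation report is internally consistent", {
  set.seed(23)
  coh <- tiny_cohort(n_patients = 30L, n_cells = 10L, seed = 29L)
  P <- random_prob_matrix(30L, h)
  preds <- cbind(data.frame(patient_id = coh$manifest$patient_id),
                 as.data.frame(P, check.names = FALSE),
                 data.frame(hemoglobin_predicted = rnorm(30L, 12, 2)))
  rep <- evaluate_predictions(preds, coh$manifest, h)
  expect_equal(as.vector(rowSums(rep$confusion)),
               as.vector(table(factor(coh$manifest$coarse_class,
                                      h$coarse_classes))))
  expect_equal(rep$accuracy, sum(diag(rep$confusion)) / 30)
  expect_equal(rep$top_k[["top1"]], rep$accuracy)
  expect_true(rep$ece >= 0 && rep$ece <= 1)
  expect_true(!is.null(rep$blast_correlation))
  # schema violation: a missing probability column is refused
  expect_error(evaluate_predictions(preds[, -3L], coh$manifest, h),
               "lacks column")
})
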