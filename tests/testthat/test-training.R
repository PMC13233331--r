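test_that("fold assignment is stratified, exhaustive and reproducible", {
  h <- default_hierarchy()
  manifest <- data.frame(
    patient_id = sprintf("P%02d", 1:40),
    coarse_class = rep(h$coarse_classes, each = 5L))
  plan <- make_folds(manifest, k = 5L, seed = 2L)
  expect_setequal(names(plan$fold_id), manifest$patient_id)
  expect_true(all(plan$fold_id %in% 0:4))
  # 8 classes x 5 patients, k = 5: every fold holds exactly 1 per class
  for (f in 0:4) {
    ids <- names(plan$fold_id)[plan$fold_id == f]
    cls <- manifest$coarse_class[match(ids, manifest$patient_id)]
    expect_equal(as.vector(table(factor(cls, h$coarse_classes))),
                 rep(1L, 8L))
  }
  expect_identical(make_folds(manifest, 5L, seed = 2L)$fold_id,
                   plan$fold_id)
  small <- manifest[c(1:3, 6:40), ]
  expect_error(make_folds(small, k = 5L), "acute leukemia")
})

test_that("proportionality holds within one patient per class", {
  coh <- tiny_cohort(n_patients = 83L, n_cells = 5L, seed = 9L)
  plan <- make_folds(coh$manifest, k = 3L, seed = 1L)
  for (cc in unique(coh$manifest$coarse_class)) {
    ids <- coh$manifest$patient_id[coh$manifest$coarse_class == cc]
    per_fold <- table(factor(plan$fold_id[ids], levels = 0:2))
    expect_lte(max(per_fold) - min(per_fold), 1L)
  }
})

test_that("a tiny ensemble trains, predicts on the simplex, and is deterministic", {
  coh <- tiny_cohort(n_patients = 32L, n_cells = 20L, seed = 13L)
  cfg <- tiny_config()
  pars <- train_params(epochs = 3L, batch_size = 8L, bag_size = 20L)
  fit <- hemomil(coh$manifest, coh$bags, cfg, k = 2L, params = pars,
                 seed = 5L)
  expect_s3_class(fit, "hemomil")
  expect_length(fit$members, 2L)
  h <- fit$hierarchy
  expect_equal(nrow(fit$oof), 32L)
  P <- as.matrix(fit$oof[, h$coarse_classes])
  expect_true(all(abs(rowSums(P) - 1) < 1e-6))

  fit2 <- hemomil(coh$manifest, coh$bags, cfg, k = 2L, params = pars,
                  seed = 5L)
  expect_identical(fit$oof, fit2$oof)

  # degenerate single-model mode
  fit1 <- hemomil(coh$manifest, coh$bags, cfg, k = 1L,
                  params = train_params(epochs = 2L, bag_size = 20L),
                  seed = 5L)
  expect_length(fit1$members, 1L)
})

test_that("ensemble prediction averages member probabilities", {
  coh <- tiny_cohort(n_patients = 32L, n_cells = 15L, seed = 9L)
  fit <- hemomil(coh$manifest, coh$bags, tiny_config(), k = 2L,
                 params = train_params(epochs = 2L, bag_size = 15L),
                 seed = 3L)
  bag <- coh$bags[[1L]]
  ens <- ensemble_predict(fit, bag)
  singles <- lapply(fit$members, predict_bag, bag = bag)
  manual <- Reduce(`+`, lapply(singles, `[[`, "class_probabilities")) / 2
  expect_equal(ens$class_probabilities, manual, tolerance = 1e-12)
  expect_lt(abs(sum(ens$class_probabilities) - 1), 1e-9)
  expect_equal(ens$hemoglobin_predicted,
               mean(vapply(singles, `[[`, numeric(1L),
                           "hemoglobin_predicted")))
  att_manual <- Reduce(`+`, lapply(singles, `[[`, "attention_weights")) / 2
  expect_equal(ens$attention_weights, att_manual / sum(att_manual))

  # an ensemble of identical members equals the single model
  twin <- fit
  twin$members <- list(fit$members[[1L]], fit$members[[1L]])
  p1 <- predict_bag(fit$members[[1L]], bag)
  pt <- ensemble_predict(twin, bag)
  expect_equal(pt$class_probabilities, p1$class_probabilities,
               tolerance = 1e-12)
})

test_that("held-out patients never enter a member's training data", {
  coh <- tiny_cohort(n_patients = 32L, n_cells = 10L, seed = 9L)
  fit <- hemomil(coh$manifest, coh$bags, tiny_config(), k = 3L,
                 params = train_params(epochs = 1L, bag_size = 10L),
                 seed = 7L)
  fold_of <- fit$fold_plan$fold_id[coh$manifest$patient_id]
  for (f in 0:2) {
    held <- names(fold_of)[fold_of == f]
    trained_on <- names(fold_of)[fold_of != f]
    expect_length(intersect(held, trained_on), 0L)
  }
})

test_that("ensembling does not fall behind its best member by over 2 points", {
  pc <- positive_control()
  h <- default_hierarchy()
  truth <- pc$test$manifest$coarse_class
  ens_preds <- predict(pc$fit, pc$test$bags)
  ens_cls <- h$coarse_classes[max.col(
    as.matrix(ens_preds[, h$coarse_classes]), ties.method = "first")]
  ens_acc <- mean(ens_cls == truth)
  member_acc <- vapply(pc$fit$members, function(m) {
    cls <- vapply(pc$test$bags, function(b) {
      p <- predict_bag(m, b)$class_probabilities
      h$coarse_classes[which.max(p)]
    }, character(1L))
    mean(cls == truth)
  }, numeric(1L))
  expect_gte(ens_acc, max(member_acc) - 0.02)
  # every member alone beats the majority-class rate by a wide margin
  prior_max <- max(table(truth)) / length(truth)
  expect_true(all(member_acc > prior_max))
})
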