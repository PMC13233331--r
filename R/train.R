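#' Stratified k-fold assignment
#'
#' Patients are stratified on the coarse class: within each class, shuffled
#' patients are dealt round-robin across folds, so per-fold class counts
#' differ from perfect proportionality by at most one patient per class.
#'
#' @param manifest cohort manifest with `patient_id` and `coarse_class`.
#' @param k number of folds (default 5).
#' @param seed integer seed.
#' @return A `fold_plan`: `k`, named integer vector `fold_id` (values in
#'   `0..k-1`, one per patient), and the seed.
#' @export
make_folds <- function(manifest, k = 5L, seed = 1L) {
  stopifnot(k >= 1L, all(c("patient_id", "coarse_class") %in% names(manifest)))
  counts <- table(manifest$coarse_class)
  too_small <- names(counts)[counts < k]
  if (length(too_small))
    stop("class(es) with fewer than k = ", k, " patients: ",
         paste(too_small, collapse = ", "), call. = FALSE)
  fold_id <- with_seed(seed, {
    out <- stats::setNames(rep(NA_integer_, nrow(manifest)),
                           manifest$patient_id)
    for (cc in unique(manifest$coarse_class)) {
      ids <- manifest$patient_id[manifest$coarse_class == cc]
      ids <- sample(ids)
      start <- sample.int(k, 1L) - 1L
      out[ids] <- (start + seq_along(ids) - 1L) %% k
    }
    out
  })
  structure(list(k = as.integer(k), fold_id = fold_id, seed = seed),
            class = "fold_plan")
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

grad_accumulate <- function(acc, g) {
  if (is.null(acc)) return(g)
  for (nm in names(g)) acc[[nm]] <- acc[[nm]] + g[[nm]]
  acc
}

grad_scale <- function(g, s) {
  for (nm in names(g)) g[[nm]] <- g[[nm]] * s
  g
}

#' Training hyperparameters
#'
#' @param epochs maximum passes over the training bags.
#' @param lr Adam learning rate.
#' @param batch_size bags per gradient step.
#' @param patience early-stopping patience in epochs on validation loss.
#' @param val_fraction fraction of training patients held out (within the
#'   training folds) for early stopping.
#' @param bag_size cells subsampled per bag each epoch; `NULL` uses the model
#'   config's `bag_size`.
#' @param lr_decay multiplicative learning-rate decay applied after
#'   `lr_patience` epochs without validation improvement.
#' @param lr_patience epochs without improvement before the rate is decayed.
#' @param class_balance if `TRUE`, epochs resample training bags with
#'   replacement with weights proportional to `1/sqrt(class frequency)`,
#'   softly boosting rare classes.
#' @param verbose print per-epoch losses.
#' @return A list of class `train_params`.
#' @export
train_params <- function(epochs = 30L, lr = 1e-3, batch_size = 8L,
                         patience = 6L, val_fraction = 0.1, bag_size = NULL,
                         lr_decay = 0.5, lr_patience = 3L,
                         class_balance = FALSE, verbose = FALSE) {
  stopifnot(epochs >= 1L, lr > 0, batch_size >= 1L, patience >= 1L,
            val_fraction >= 0, val_fraction < 1, lr_decay > 0, lr_decay <= 1,
            lr_patience >= 1L)
  structure(list(epochs = as.integer(epochs), lr = lr,
                 batch_size = as.integer(batch_size),
                 patience = as.integer(patience),
                 val_fraction = val_fraction, bag_size = bag_size,
                 lr_decay = lr_decay, lr_patience = as.integer(lr_patience),
                 class_balance = isTRUE(class_balance),
                 verbose = isTRUE(verbose)), class = "train_params")
}

# mean loss of `model` over bags[idx] (full bags, no dropout)
eval_loss <- function(model, bags, labels, hb_z, idx) {
  tot <- 0
  for (chunk in split(idx, ceiling(seq_along(idx) / 16L))) {
    Xs <- lapply(bags[chunk], bag_matrix)
    res <- mil_fb_batch(model, Xs, labels[chunk], hb_z[chunk], grad = FALSE)
    tot <- tot + sum(res$losses)
  }
  tot / length(idx)
}

# Train a single model on bags[train_idx] with early stopping on
# bags[val_idx]. labels are 1-based class indices; hb in g/dL.
train_mil <- function(bags, labels, hb, config, params = train_params(),
                      train_idx, val_idx, class_order, seed = 1L) {
  model <- build_model_seeded(config, class_order, seed)
  hb_tr <- hb[train_idx]
  model$hb_center <- mean(hb_tr)
  model$hb_scale <- max(stats::sd(hb_tr), 1e-6)
  hb_z <- (hb - model$hb_center) / model$hb_scale
  bag_size <- params$bag_size %||% config$bag_size
  w <- config$hb_loss_weight

  opt <- adam_init(model$params)
  lr_now <- params$lr
  lr_bad <- 0L
  best <- list(loss = Inf, params = model$params, epoch = 0L)
  bad_epochs <- 0L
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric())

  for (epoch in seq_len(params$epochs)) {
    ord <- with_seed(derive_seed(seed, 1000L + epoch), {
      if (isTRUE(params$class_balance)) {
        freq <- table(labels[train_idx])
        w <- 1 / sqrt(as.numeric(freq[as.character(labels[train_idx])]))
        sample(train_idx, length(train_idx), replace = TRUE, prob = w)
      } else sample(train_idx)
    })
    ep_loss <- 0
    chunks <- split(ord, ceiling(seq_along(ord) / params$batch_size))
    for (chunk in chunks) {
      Xs <- lapply(chunk, function(i) bag_matrix(
        subsample_bag(bags[[i]], bag_size,
                      seed = derive_seed(seed, epoch * 100000L + i))))
      res <- mil_fb_batch(
        model, Xs, labels[chunk], hb_z[chunk], grad = TRUE,
        dropout_seed = if (config$dropout > 0)
          derive_seed(seed, epoch * 100000L + chunk[1L] + 7L) else NULL)
      if (any(!is.finite(res$losses)))
        stop("training diverged: non-finite loss at epoch ", epoch,
             call. = FALSE)
      ep_loss <- ep_loss + sum(res$losses)
      upd <- adam_step(model$params,
                       grad_scale(res$grads, 1 / length(chunk)),
                       opt, lr = lr_now)
      model$params <- upd$params
      opt <- upd$state
    }
    vl <- if (length(val_idx)) eval_loss(model, bags, labels, hb_z, val_idx)
          else ep_loss / length(ord)
    history <- rbind(history, data.frame(
      epoch = epoch, train_loss = ep_loss / length(ord), val_loss = vl))
    if (params$verbose)
      message(sprintf("epoch %3d  train %.4f  val %.4f", epoch,
                      ep_loss / length(ord), vl))
    if (vl < best$loss - 1e-6) {
      best <- list(loss = vl, params = model$params, epoch = epoch)
      bad_epochs <- 0L
      lr_bad <- 0L
    } else {
      bad_epochs <- bad_epochs + 1L
      lr_bad <- lr_bad + 1L
      if (bad_epochs >= params$patience) break
      if (lr_bad >= params$lr_patience) {
        lr_now <- lr_now * params$lr_decay
        lr_bad <- 0L
      }
    }
  }
  model$params <- best$params
  model$history <- history
  model$best_epoch <- best$epoch
  model
}

build_model_seeded <- function(config, class_order, seed) {
  cfg <- config
  cfg$seed <- as.integer(derive_seed(seed, config$seed) %% 2147483629)
  build_model(cfg, class_order)
}

#' Fit a cross-validated MIL ensemble
#'
#' The main fitting function: assigns patients to `k` stratified folds,
#' trains one transformer aggregator per fold on the other `k - 1` folds
#' (early stopping on an inner validation split of the training folds, so
#' the held-out fold is never seen), and combines members by probability
#' averaging at prediction time. Out-of-fold predictions — each patient
#' predicted by the one member that never saw it — are computed and stored
#' for honest evaluation. `k = 1` is a degenerate smoke-test mode: a single
#' model trained on all patients (its "out-of-fold" table is in-sample).
#'
#' @param manifest cohort manifest (`patient_id`, `coarse_class`,
#'   `hemoglobin`; see [generate_cohort()]).
#' @param bags named list of `cell_bag` aligned with `manifest$patient_id`.
#' @param config a [mil_config()].
#' @param k number of folds (default 5).
#' @param params a [train_params()].
#' @param hierarchy a `label_hierarchy`; class order is taken from it.
#' @param seed integer master seed for folds, initialization and training.
#' @return An object of class `hemomil`: `members` (list of `mil_model`),
#'   `fold_plan`, `oof` (out-of-fold predictions table), `config`,
#'   `hierarchy`, `seed`.
#' @export
hemomil <- function(manifest, bags, config = mil_config(), k = 5L,
                    params = train_params(), hierarchy = default_hierarchy(),
                    seed = 1L) {
  stopifnot(inherits(config, "mil_config"), k >= 1L)
  ids <- manifest$patient_id
  if (!setequal(ids, names(bags)))
    stop("manifest patient_ids and bag names do not match", call. = FALSE)
  bags <- bags[ids]
  labels <- match(manifest$coarse_class, hierarchy$coarse_classes)
  if (anyNA(labels))
    stop("manifest contains coarse classes outside the hierarchy: ",
         paste(unique(manifest$coarse_class[is.na(labels)]), collapse = ", "),
         call. = FALSE)
  hb <- manifest$hemoglobin

  plan <- if (k == 1L) {
    structure(list(k = 1L,
                   fold_id = stats::setNames(rep(0L, length(ids)), ids),
                   seed = seed), class = "fold_plan")
  } else make_folds(manifest, k, seed = derive_seed(seed, 17L))
  fold_of <- plan$fold_id[ids]

  members <- vector("list", plan$k)
  for (f in seq_len(plan$k) - 1L) {
    train_all <- which(fold_of != f | plan$k == 1L)
    # inner early-stopping split, carved out of the training folds only and
    # stratified by class so rare diagnoses are represented in it
    val_idx <- with_seed(derive_seed(seed, 31L + f), {
      picked <- integer(0)
      for (cc in unique(labels[train_all])) {
        pool <- train_all[labels[train_all] == cc]
        n_cc <- min(max(1L, round(params$val_fraction * length(pool))),
                    length(pool))
        picked <- c(picked, pool[sample.int(length(pool), n_cc)])
      }
      picked
    })
    tr_idx <- setdiff(train_all, val_idx)
    held_out <- ids[fold_of == f & plan$k > 1L]
    leak <- intersect(ids[c(tr_idx, val_idx)], held_out)
    if (length(leak))
      stop("internal error: held-out patients leaked into training: ",
           paste(utils::head(leak, 3L), collapse = ", "), call. = FALSE)
    members[[f + 1L]] <- train_mil(
      bags, labels, hb, config, params,
      train_idx = tr_idx, val_idx = val_idx,
      class_order = hierarchy$coarse_classes,
      seed = derive_seed(seed, 100L + f))
  }

  fit <- structure(list(members = members, fold_plan = plan,
                        config = config, hierarchy = hierarchy,
                        seed = seed, manifest_ids = ids),
                   class = "hemomil")
  # out-of-fold predictions: fold-f patients through member f
  oof <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    member <- members[[fold_of[i] + 1L]]
    oof[[i]] <- prediction_row(predict_bag(member, bags[[i]]), ids[i])
  }
  fit$oof <- do.call(rbind, oof)

  # Hemoglobin stacking: the MSE-trained head is noisy and shrinks rare
  # classes toward the cohort mean, while the class probabilities carry most
  # of the hemoglobin signal (anemia patterns are class-linked). A small
  # linear recalibration of [raw head output, class probabilities] is fitted
  # on the out-of-fold predictions and stored on the fit; ensemble_predict()
  # applies it, and the stored oof table is recalibrated in place.
  P <- as.matrix(fit$oof[, hierarchy$coarse_classes])
  hb_true <- hb[match(fit$oof$patient_id, ids)]
  if (nrow(P) >= 40L) {
    X <- cbind(1, fit$oof$hemoglobin_predicted,
               P[, -ncol(P), drop = FALSE])
    beta <- tryCatch(qr.solve(X, hb_true), error = function(e) NULL)
    if (!is.null(beta) && all(is.finite(beta))) {
      fit$hb_stack <- unname(beta)
      fit$oof$hemoglobin_predicted <- as.vector(X %*% beta)
    }
  }
  fit
}

prediction_row <- function(pred, id) {
  row <- as.data.frame(as.list(pred$class_probabilities),
                       check.names = FALSE)
  cbind(data.frame(patient_id = id), row,
        data.frame(hemoglobin_predicted = pred$hemoglobin_predicted))
}

#' Ensemble prediction for one bag
#'
#' Class probabilities and hemoglobin are arithmetic means over members
#' (probability averaging keeps the vector on the simplex); attention
#' weights are averaged and renormalized to sum 1.
#'
#' @param fit a `hemomil` ensemble (or a list of `mil_model` sharing one
#'   class order).
#' @param bag a `cell_bag` or matrix.
#' @return A `bag_prediction`.
#' @export
ensemble_predict <- function(fit, bag) {
  members <- if (inherits(fit, "hemomil")) fit$members else fit
  stopifnot(length(members) >= 1L)
  co <- members[[1L]]$class_order
  for (m in members)
    if (!identical(m$class_order, co))
      stop("ensemble members disagree on class order", call. = FALSE)
  preds <- lapply(members, predict_bag, bag = bag)
  probs <- Reduce(`+`, lapply(preds, `[[`, "class_probabilities")) /
    length(preds)
  att <- Reduce(`+`, lapply(preds, `[[`, "attention_weights")) / length(preds)
  hb <- mean(vapply(preds, `[[`, numeric(1L), "hemoglobin_predicted"))
  if (inherits(fit, "hemomil") && !is.null(fit$hb_stack))
    hb <- sum(fit$hb_stack * c(1, hb, probs[-length(probs)]))
  structure(list(
    class_probabilities = probs,
    hemoglobin_predicted = hb,
    patient_vector = Reduce(`+`, lapply(preds, `[[`, "patient_vector")) /
      length(preds),
    attention_weights = att / sum(att)), class = "bag_prediction")
}

#' Predict method for hemomil ensembles
#'
#' @param object a `hemomil` fit.
#' @param bags a single `cell_bag`/matrix, or a (named) list of them.
#' @param oof if `TRUE` and `bags` is missing, return the stored out-of-fold
#'   predictions table.
#' @param ... unused.
#' @return A `bag_prediction` for a single bag; a predictions data frame
#'   (patient_id, one probability column per coarse class in hierarchy
#'   order, `hemoglobin_predicted`) for a list.
#' @export
predict.hemomil <- function(object, bags, oof = FALSE, ...) {
  if (missing(bags) || isTRUE(oof)) return(object$oof)
  if (inherits(bags, "cell_bag") || is.matrix(bags))
    return(ensemble_predict(object, bags))
  rows <- lapply(seq_along(bags), function(i) {
    id <- names(bags)[i]
    if (is.null(id) || is.na(id) || !nzchar(id))
      id <- if (inherits(bags[[i]], "cell_bag")) bags[[i]]$patient_id
            else paste0("bag", i)
    prediction_row(ensemble_predict(object, bags[[i]]), id)
  })
  do.call(rbind, rows)
}

#' @export
print.hemomil <- function(x, ...) {
  cat("<hemomil> ensemble of", length(x$members), "transformer aggregator(s)\n")
  cfg <- x$config
  cat(sprintf("  %d-fold cross-validation, %d patients, %d classes\n",
              x$fold_plan$k, length(x$manifest_ids), cfg$n_classes))
  cat(sprintf("  config: dim %d -> latent %d, %d layer(s) x %d head(s)\n",
              cfg$embedding_dim, cfg$latent_dim, cfg$n_layers, cfg$n_heads))
  invisible(x)
}

#' @export
summary.hemomil <- function(object, ...) {
  cat("Cross-validated MIL ensemble\n")
  print(object)
  for (i in seq_along(object$members)) {
    m <- object$members[[i]]
    cat(sprintf("  member %d: best epoch %d, val loss %.4f\n", i,
                m$best_epoch, min(m$history$val_loss)))
  }
  invisible(object)
}
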