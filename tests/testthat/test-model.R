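test_that("config validation enforces head divisibility", {
  expect_error(mil_config(latent_dim = 65L, n_heads = 4L), "divisible")
  expect_error(mil_config(dropout = 1), "dropout")
  cfg <- tiny_config()
  expect_s3_class(cfg, "mil_config")
})

test_that("initialization is deterministic in the seed", {
  m1 <- build_model(tiny_config())
  m2 <- build_model(tiny_config())
  expect_identical(m1$params, m2$params)
  m3 <- build_model(tiny_config(seed = 8L))
  expect_gt(max(abs(m1$params$W_in - m3$params$W_in)), 0)
  expect_error(build_model(tiny_config(n_classes = 3L)), "class_order")
})

test_that("predictions satisfy simplex constraints for variable bag sizes", {
  m <- build_model(tiny_config())
  set.seed(1)
  for (n in c(1L, 2L, 499L, 500L, 501L)) {
    X <- matrix(rnorm(n * 6L), n, 6L)
    p <- predict_bag(m, X)
    expect_lt(abs(sum(p$class_probabilities) - 1), 1e-6)
    expect_true(all(p$class_probabilities >= 0))
    expect_length(p$attention_weights, n)
    expect_lt(abs(sum(p$attention_weights) - 1), 1e-6)
    expect_true(all(is.finite(p$patient_vector)))
  }
  expect_equal(predict_bag(m, matrix(rnorm(6), 1L, 6L))$attention_weights,
               1)
})

test_that("outputs are permutation invariant, attention equivariant", {
  m <- build_model(tiny_config())
  set.seed(42)
  for (rep in 1:5) {
    X <- matrix(rnorm(20 * 6L), 20, 6L)
    perm <- sample(20)
    p1 <- predict_bag(m, X)
    p2 <- predict_bag(m, X[perm, ])
    expect_lt(max(abs(p1$class_probabilities - p2$class_probabilities)),
              1e-5)
    expect_lt(abs(p1$hemoglobin_predicted - p2$hemoglobin_predicted), 1e-5)
    expect_lt(max(abs(p1$attention_weights[perm] - p2$attention_weights)),
              1e-5)
  }
})

test_that("dimension mismatches and empty bags are rejected", {
  m <- build_model(tiny_config())
  expect_error(predict_bag(m, matrix(0, 3L, 5L)), "embedding dims")
  expect_error(predict_bag(m, matrix(numeric(0), 0L, 6L)), "empty")
  expect_error(predict_bag(m, matrix(c(1, NA, rep(0, 10)), 2L, 6L)),
               "non-finite")
})

test_that("loss terms follow the closed forms", {
  cfg <- tiny_config()
  classes <- default_hierarchy()$coarse_classes
  onehot <- structure(list(
    class_probabilities = stats::setNames(c(1, rep(0, 7L)), classes),
    hemoglobin_predicted = 12), class = "bag_prediction")
  l <- mil_loss(onehot, 1L, 12, cfg)
  expect_equal(l$total, 0)
  expect_equal(l$classification, 0)
  expect_equal(l$regression, 0)

  uniform <- structure(list(
    class_probabilities = stats::setNames(rep(1 / 8, 8L), classes),
    hemoglobin_predicted = 10), class = "bag_prediction")
  l2 <- mil_loss(uniform, "MDS", 10, cfg)
  expect_equal(l2$classification, log(8), tolerance = 1e-12)

  cfg0 <- tiny_config(hb_loss_weight = 0)
  l3 <- mil_loss(uniform, 3L, 99, cfg0)
  expect_equal(l3$total, l3$classification)
  # regression measured on the standardized scale
  l4 <- mil_loss(onehot, 1L, 14, cfg, hb_scale = 2)
  expect_equal(l4$regression, 1)
})

test_that("analytic gradients match finite differences", {
  cfg <- mil_config(embedding_dim = 5L, bag_size = 10L, latent_dim = 8L,
                    n_heads = 2L, n_layers = 2L, n_classes = 3L,
                    hb_loss_weight = 0.7, dropout = 0, seed = 3L)
  m <- build_model(cfg, class_order = c("a", "b", "c"))
  set.seed(42)
  m$params$Whc[] <- rnorm(3L, sd = 0.5)  # exercise the logit->hb path
  X <- matrix(rnorm(4L * 5L), 4L, 5L)
  y <- 2L
  hb_t <- 0.3
  loss_at <- function(model) {
    f <- hemomil:::mil_forward(model, X)
    -log(f$probs[y]) + cfg$hb_loss_weight * (f$hbz - hb_t)^2
  }
  f <- hemomil:::mil_forward(m, X, keep_cache = TRUE)
  dlogits <- f$probs
  dlogits[y] <- dlogits[y] - 1
  g <- hemomil:::mil_backward(m, f, dlogits,
                              2 * cfg$hb_loss_weight * (f$hbz - hb_t))
  eps <- 1e-6
  for (nm in names(m$params)) {
    pv <- m$params[[nm]]
    for (i in sample(length(pv), min(4L, length(pv)))) {
      mp <- m; mp$params[[nm]][i] <- pv[i] + eps
      mm <- m; mm$params[[nm]][i] <- pv[i] - eps
      num <- (loss_at(mp) - loss_at(mm)) / (2 * eps)
      expect_equal(g[[nm]][i], num, tolerance = 1e-4,
                   label = paste0("grad ", nm, "[", i, "]"))
    }
  }
})

test_that("batched training pass equals summed per-bag passes", {
  cfg <- mil_config(embedding_dim = 6L, bag_size = 50L, latent_dim = 8L,
                    n_heads = 2L, n_layers = 2L, n_classes = 4L,
                    hb_loss_weight = 0.3, dropout = 0, seed = 9L)
  m <- build_model(cfg, class_order = letters[1:4])
  set.seed(1)
  Xs <- lapply(c(3L, 5L, 4L), function(n) matrix(rnorm(n * 6L), n, 6L))
  labels <- c(1L, 3L, 2L)
  hbz <- c(0.1, -0.5, 1.2)
  res <- hemomil:::mil_fb_batch(m, Xs, labels, hbz, grad = TRUE)
  acc <- NULL
  for (b in 1:3) {
    f <- hemomil:::mil_forward(m, Xs[[b]], keep_cache = TRUE)
    expect_equal(unname(res$probs[b, ]), unname(f$probs), tolerance = 1e-12)
    dl <- f$probs
    dl[labels[b]] <- dl[labels[b]] - 1
    acc <- hemomil:::grad_accumulate(
      acc, hemomil:::mil_backward(m, f, dl,
                                  2 * cfg$hb_loss_weight * (f$hbz - hbz[b])))
  }
  for (nm in names(acc))
    expect_lt(max(abs(acc[[nm]] - res$grads[[nm]])), 1e-10)
})

test_that("one optimization step decreases the batch loss", {
  cfg <- tiny_config()
  m <- build_model(cfg)
  set.seed(5)
  Xs <- lapply(1:4, function(i) matrix(rnorm(10L * 6L), 10L, 6L))
  labels <- c(1L, 2L, 3L, 4L)
  hbz <- rnorm(4L)
  before <- hemomil:::mil_fb_batch(m, Xs, labels, hbz, grad = TRUE)
  opt <- hemomil:::adam_init(m$params)
  upd <- hemomil:::adam_step(m$params,
                             hemomil:::grad_scale(before$grads, 1 / 4),
                             opt, lr = 1e-3)
  m$params <- upd$params
  after <- hemomil:::mil_fb_batch(m, Xs, labels, hbz, grad = FALSE)
  expect_lt(sum(after$losses), sum(before$losses))
})

test_that("bag subsampling is uniform without replacement and stable", {
  set.seed(2)
  X <- matrix(rnorm(800L * 6L), 800L, 6L)
  s <- subsample_bag(X, 500L, seed = 4L)
  expect_equal(nrow(s), 500L)
  expect_equal(anyDuplicated(s), 0L)
  expect_true(all(s %in% X))

  X300 <- X[1:300, ]
  expect_identical(subsample_bag(X300, 500L, seed = 4L), X300)
  expect_identical(subsample_bag(X, 500L, seed = 4L),
                   subsample_bag(X, 500L, seed = 4L))
  bag <- structure(list(patient_id = "p", embeddings = X,
                        cell_types = rep(c("a", "b"), 400L)),
                   class = "cell_bag")
  sb <- subsample_bag(bag, 100L, seed = 1L)
  expect_equal(nrow(sb$embeddings), 100L)
  expect_length(sb$cell_types, 100L)
})
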