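#' Model configuration for the transformer bag aggregator
#'
#' The aggregator is a permutation-invariant set transformer: a learnable
#' aggregation token is prepended to the cell tokens, self-attention layers
#' (no positional encodings) mix information across cells, and the
#' aggregation token's final representation feeds a small MLP head that
#' outputs coarse-class logits and a hemoglobin value on a standardized
#' scale. The aggregation token's final-layer attention row, averaged over
#' heads, is the exported per-cell relevance.
#'
#' @param embedding_dim width of the input cell embeddings (default 768, the
#'   width of common single-cell image foundation encoders).
#' @param bag_size cells sampled per bag during training (default 500).
#' @param latent_dim transformer width (default 512); must be divisible by
#'   `n_heads`.
#' @param n_heads attention heads per layer.
#' @param n_layers transformer layers.
#' @param n_classes number of coarse classes (8).
#' @param hb_loss_weight nonnegative weight of the hemoglobin squared-error
#'   term in the training loss (hemoglobin is z-scored on training folds).
#' @param dropout dropout rate in `[0, 1)` applied to the feed-forward and
#'   head hidden activations during training.
#' @param seed integer seed for parameter initialization.
#' @return A validated list of class `mil_config`.
#' @export
mil_config <- function(embedding_dim = 768L, bag_size = 500L,
                       latent_dim = 512L, n_heads = 8L, n_layers = 2L,
                       n_classes = 8L, hb_loss_weight = 0.5, dropout = 0.1,
                       seed = 1L) {
  cfg <- list(embedding_dim = as.integer(embedding_dim),
              bag_size = as.integer(bag_size),
              latent_dim = as.integer(latent_dim),
              n_heads = as.integer(n_heads),
              n_layers = as.integer(n_layers),
              n_classes = as.integer(n_classes),
              hb_loss_weight = hb_loss_weight,
              dropout = dropout,
              seed = as.integer(seed))
  stopifnot(cfg$embedding_dim >= 1L, cfg$bag_size >= 1L, cfg$latent_dim >= 2L,
            cfg$n_heads >= 1L, cfg$n_layers >= 1L, cfg$n_classes >= 2L,
            cfg$hb_loss_weight >= 0, cfg$dropout >= 0, cfg$dropout < 1)
  if (cfg$latent_dim %% cfg$n_heads != 0L)
    stop("latent_dim (", cfg$latent_dim, ") must be divisible by n_heads (",
         cfg$n_heads, ")", call. = FALSE)
  class(cfg) <- "mil_config"
  cfg
}

#' Build an untrained model
#'
#' Initialization is deterministic given `config$seed`. The model accepts
#' bags of any size `n_cells >= 1` (set-transformer contract: no fixed
#' positional structure).
#'
#' @param config a [mil_config()].
#' @param class_order character vector naming the coarse classes in
#'   probability order; length must equal `config$n_classes`.
#' @return An object of class `mil_model`: parameters, config, class order,
#'   and hemoglobin standardization constants (set during training).
#' @export
build_model <- function(config, class_order = default_hierarchy()$coarse_classes) {
  stopifnot(inherits(config, "mil_config"))
  if (length(class_order) != config$n_classes)
    stop("class_order has ", length(class_order), " entries but config ",
         "declares n_classes = ", config$n_classes, call. = FALSE)
  L <- config$latent_dim
  Fd <- 2L * L
  d <- config$embedding_dim
  K <- config$n_classes

  params <- with_seed(config$seed, {
    gl <- function(nr, nc) matrix(
      stats::rnorm(nr * nc, sd = sqrt(2 / (nr + nc))), nr, nc)
    p <- list(W_in = gl(d, L), b_in = numeric(L),
              cls = stats::rnorm(L, sd = 0.02))
    resid_scale <- 1 / sqrt(2 * config$n_layers)
    for (l in seq_len(config$n_layers)) {
      p[[paste0("ln1_g_", l)]] <- rep(1, L)
      p[[paste0("ln1_b_", l)]] <- numeric(L)
      p[[paste0("Wq_", l)]] <- gl(L, L)
      p[[paste0("Wk_", l)]] <- gl(L, L)
      p[[paste0("Wv_", l)]] <- gl(L, L)
      p[[paste0("Wo_", l)]] <- gl(L, L) * resid_scale
      p[[paste0("bo_", l)]] <- numeric(L)
      p[[paste0("ln2_g_", l)]] <- rep(1, L)
      p[[paste0("ln2_b_", l)]] <- numeric(L)
      p[[paste0("W1_", l)]] <- gl(L, Fd)
      p[[paste0("b1_", l)]] <- numeric(Fd)
      p[[paste0("W2_", l)]] <- gl(Fd, L) * resid_scale
      p[[paste0("b2_", l)]] <- numeric(L)
    }
    p$lnf_g <- rep(1, L)
    p$lnf_b <- numeric(L)
    p$Wm <- gl(L, Fd)      # head hidden layer, width 2L
    p$bm <- numeric(Fd)
    p$Wc <- gl(Fd, K)
    p$bc <- numeric(K)
    p$Wh <- gl(Fd, 1L)
    # class logits feed the hemoglobin output as well (anemia patterns are
    # strongly class-linked); starts neutral at zero
    p$Whc <- matrix(0, K, 1L)
    p$bh <- numeric(1L)
    p
  })

  structure(list(params = params, config = config,
                 class_order = as.character(class_order),
                 hb_center = 0, hb_scale = 1),
            class = "mil_model")
}

LN_EPS <- 1e-5

ln_forward <- function(X, g, b) {
  mu <- rowMeans(X)
  xc <- X - mu
  sd <- sqrt(rowMeans(xc^2) + LN_EPS)
  xhat <- xc / sd
  list(out = sweep(xhat, 2L, g, `*`) + rep(b, each = nrow(X)),
       xhat = xhat, sd = sd)
}

ln_backward <- function(dY, cache, g) {
  dxhat <- sweep(dY, 2L, g, `*`)
  xhat <- cache$xhat
  dx <- (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) / cache$sd
  list(dx = dx, dg = colSums(dY * xhat), db = colSums(dY))
}

# Full forward pass over one bag. X is n_cells x embedding_dim. When
# `keep_cache = TRUE` all intermediates needed by mil_backward are retained.
# `dropout_seed` (non-NULL) enables dropout masks for training.
mil_forward <- function(model, X, keep_cache = FALSE, dropout_seed = NULL) {
  p <- model$params
  cfg <- model$config
  if (!is.matrix(X)) X <- rbind(X)
  if (ncol(X) != cfg$embedding_dim)
    stop("bag has ", ncol(X), " embedding dims; model expects ",
         cfg$embedding_dim, call. = FALSE)
  if (nrow(X) < 1L) stop("empty bag", call. = FALSE)
  if (any(!is.finite(X))) stop("bag contains non-finite values", call. = FALSE)
  n <- nrow(X)
  L <- cfg$latent_dim
  h <- cfg$n_heads
  dh <- L %/% h
  keep_p <- 1 - cfg$dropout
  use_drop <- !is.null(dropout_seed) && cfg$dropout > 0
  drop_rng <- if (use_drop) with_seed(dropout_seed, {
    out <- list()
    for (l in seq_len(cfg$n_layers))
      out[[l]] <- matrix(stats::rbinom((n + 1L) * 2L * L, 1L, keep_p),
                         n + 1L, 2L * L)
    out$head <- stats::rbinom(ncol(p$Wm), 1L, keep_p)
    out
  }) else NULL

  Tm <- rbind(p$cls, X %*% p$W_in + rep(p$b_in, each = n))
  N <- n + 1L
  cache <- if (keep_cache) list(X = X, layers = vector("list", cfg$n_layers))
           else NULL
  att_last <- NULL

  for (l in seq_len(cfg$n_layers)) {
    lc <- list(T_in = Tm)
    ln1 <- ln_forward(Tm, p[[paste0("ln1_g_", l)]], p[[paste0("ln1_b_", l)]])
    Y <- ln1$out
    Q <- Y %*% p[[paste0("Wq_", l)]]
    Km <- Y %*% p[[paste0("Wk_", l)]]
    V <- Y %*% p[[paste0("Wv_", l)]]
    H <- matrix(0, N, L)
    Ps <- vector("list", h)
    for (j in seq_len(h)) {
      idx <- ((j - 1L) * dh + 1L):(j * dh)
      S <- tcrossprod(Q[, idx, drop = FALSE], Km[, idx, drop = FALSE]) /
        sqrt(dh)
      P <- softmax_rows(S)
      Ps[[j]] <- P
      H[, idx] <- P %*% V[, idx, drop = FALSE]
    }
    if (l == cfg$n_layers) {
      a <- Reduce(`+`, lapply(Ps, function(P) P[1L, ])) / h
      a <- a[-1L]            # drop self-attention of the aggregation token
      att_last <- a / sum(a)
    }
    O <- H %*% p[[paste0("Wo_", l)]] + rep(p[[paste0("bo_", l)]], each = N)
    T1 <- Tm + O
    ln2 <- ln_forward(T1, p[[paste0("ln2_g_", l)]], p[[paste0("ln2_b_", l)]])
    A1 <- ln2$out %*% p[[paste0("W1_", l)]] +
      rep(p[[paste0("b1_", l)]], each = N)
    R <- pmax(A1, 0)
    Rd <- if (use_drop) R * drop_rng[[l]] / keep_p else R
    F2 <- Rd %*% p[[paste0("W2_", l)]] + rep(p[[paste0("b2_", l)]], each = N)
    Tm <- T1 + F2
    if (keep_cache) {
      lc$ln1 <- ln1; lc$Y <- Y; lc$Q <- Q; lc$K <- Km; lc$V <- V
      lc$Ps <- Ps; lc$H <- H; lc$T1 <- T1; lc$ln2 <- ln2
      lc$A1 <- A1; lc$Rd <- Rd
      lc$drop <- if (use_drop) drop_rng[[l]] else NULL
      cache$layers[[l]] <- lc
    }
  }

  t_cls <- Tm[1L, , drop = FALSE]
  lnf <- ln_forward(t_cls, p$lnf_g, p$lnf_b)
  z <- lnf$out[1L, ]
  m_pre <- drop(z %*% p$Wm) + p$bm
  m <- pmax(m_pre, 0)
  md <- if (use_drop) m * drop_rng$head / keep_p else m
  logits <- drop(md %*% p$Wc) + p$bc
  probs <- softmax_vec(logits)
  hbz <- drop(md %*% p$Wh) + drop(logits %*% p$Whc) + p$bh

  if (keep_cache) {
    cache$lnf <- lnf; cache$t_cls <- t_cls; cache$z <- z
    cache$m_pre <- m_pre; cache$md <- md; cache$logits <- logits
    cache$head_drop <- if (use_drop) drop_rng$head else NULL
    cache$n <- n
  }
  list(probs = probs, logits = logits, hbz = hbz, z = z,
       attention = att_last, cache = cache)
}

# Backward pass: given gradients of the loss w.r.t. logits and hbz, returns
# the gradient for every parameter (same names/shapes as model$params).
mil_backward <- function(model, fwd, dlogits, dhbz) {
  p <- model$params
  cfg <- model$config
  cache <- fwd$cache
  L <- cfg$latent_dim
  h <- cfg$n_heads
  dh <- L %/% h
  keep_p <- 1 - cfg$dropout
  use_drop <- !is.null(cache$head_drop)
  g <- list()

  md <- cache$md
  # hemoglobin also depends on the class logits: fold that path into dlogits
  g$Whc <- matrix(cache$logits * dhbz, ncol = 1L)
  dlogits <- dlogits + drop(p$Whc) * dhbz
  g$Wc <- outer(md, dlogits)
  g$bc <- dlogits
  g$Wh <- matrix(md * dhbz, ncol = 1L)
  g$bh <- dhbz
  dmd <- drop(p$Wc %*% dlogits) + drop(p$Wh) * dhbz
  dm <- if (use_drop) dmd * cache$head_drop / keep_p else dmd
  dm_pre <- dm * (cache$m_pre > 0)
  g$Wm <- outer(cache$z, dm_pre)
  g$bm <- dm_pre
  dz <- drop(p$Wm %*% dm_pre)

  lb <- ln_backward(rbind(dz), cache$lnf, p$lnf_g)
  g$lnf_g <- lb$dg
  g$lnf_b <- lb$db
  N <- cache$n + 1L
  dT <- matrix(0, N, L)
  dT[1L, ] <- lb$dx[1L, ]

  for (l in rev(seq_len(cfg$n_layers))) {
    lc <- cache$layers[[l]]
    # FFN block: Tm = T1 + F2(ln2(T1))
    dF2 <- dT
    g[[paste0("W2_", l)]] <- crossprod(lc$Rd, dF2)
    g[[paste0("b2_", l)]] <- colSums(dF2)
    dRd <- tcrossprod(dF2, p[[paste0("W2_", l)]])
    dR <- if (use_drop) dRd * lc$drop / keep_p else dRd
    dA1 <- dR * (lc$A1 > 0)
    g[[paste0("W1_", l)]] <- crossprod(lc$ln2$out, dA1)
    g[[paste0("b1_", l)]] <- colSums(dA1)
    dY2 <- tcrossprod(dA1, p[[paste0("W1_", l)]])
    lb2 <- ln_backward(dY2, lc$ln2, p[[paste0("ln2_g_", l)]])
    g[[paste0("ln2_g_", l)]] <- lb2$dg
    g[[paste0("ln2_b_", l)]] <- lb2$db
    dT1 <- dT + lb2$dx

    # attention block: T1 = T_in + O(ln1(T_in))
    dO <- dT1
    g[[paste0("Wo_", l)]] <- crossprod(lc$H, dO)
    g[[paste0("bo_", l)]] <- colSums(dO)
    dH <- tcrossprod(dO, p[[paste0("Wo_", l)]])
    dQ <- matrix(0, N, L)
    dK <- matrix(0, N, L)
    dV <- matrix(0, N, L)
    for (j in seq_len(h)) {
      idx <- ((j - 1L) * dh + 1L):(j * dh)
      P <- lc$Ps[[j]]
      dHj <- dH[, idx, drop = FALSE]
      dP <- tcrossprod(dHj, lc$V[, idx, drop = FALSE])
      dV[, idx] <- crossprod(P, dHj)
      dS <- P * (dP - rowSums(dP * P))
      dS <- dS / sqrt(dh)
      dQ[, idx] <- dS %*% lc$K[, idx, drop = FALSE]
      dK[, idx] <- crossprod(dS, lc$Q[, idx, drop = FALSE])
    }
    g[[paste0("Wq_", l)]] <- crossprod(lc$Y, dQ)
    g[[paste0("Wk_", l)]] <- crossprod(lc$Y, dK)
    g[[paste0("Wv_", l)]] <- crossprod(lc$Y, dV)
    dY <- tcrossprod(dQ, p[[paste0("Wq_", l)]]) +
      tcrossprod(dK, p[[paste0("Wk_", l)]]) +
      tcrossprod(dV, p[[paste0("Wv_", l)]])
    lb1 <- ln_backward(dY, lc$ln1, p[[paste0("ln1_g_", l)]])
    g[[paste0("ln1_g_", l)]] <- lb1$dg
    g[[paste0("ln1_b_", l)]] <- lb1$db
    dT <- dT1 + lb1$dx
  }

  g$cls <- dT[1L, ]
  dP_in <- dT[-1L, , drop = FALSE]
  g$W_in <- crossprod(cache$X, dP_in)
  g$b_in <- colSums(dP_in)
  g
}

#' Predict class probabilities, hemoglobin and attention for one bag
#'
#' Outputs are invariant to the order of the bag's rows; the attention
#' weights permute with the rows. The hemoglobin prediction is
#' de-standardized to g/dL using the constants stored in the model.
#'
#' @param model a `mil_model`.
#' @param bag a `cell_bag` or a numeric matrix (`n_cells` x embedding dim).
#' @return A `bag_prediction`: `class_probabilities` (named, sums to 1),
#'   `hemoglobin_predicted` (g/dL), `patient_vector` (latent representation),
#'   `attention_weights` (length `n_cells`, sums to 1).
#' @export
predict_bag <- function(model, bag) {
  stopifnot(inherits(model, "mil_model"))
  X <- bag_matrix(bag)
  fwd <- mil_forward(model, X)
  structure(list(
    class_probabilities = stats::setNames(fwd$probs, model$class_order),
    hemoglobin_predicted = unname(fwd$hbz * model$hb_scale + model$hb_center),
    patient_vector = fwd$z,
    attention_weights = fwd$attention), class = "bag_prediction")
}

bag_matrix <- function(bag) {
  if (inherits(bag, "cell_bag")) bag$embeddings
  else if (is.matrix(bag)) bag
  else stop("bag must be a cell_bag or a numeric matrix", call. = FALSE)
}

#' Multi-task training loss
#'
#' `total = cross-entropy(class) + hb_loss_weight * squared error` of the
#' hemoglobin prediction on the standardized scale (`hb_scale` in g/dL per
#' standardized unit).
#'
#' @param pred a `bag_prediction`.
#' @param true_class index of the true class in the model's class order (or
#'   a class name).
#' @param true_hb measured hemoglobin in g/dL.
#' @param config a `mil_config` (supplies `hb_loss_weight`).
#' @param hb_scale standardization scale (g/dL per standardized unit).
#' @return List with `total`, `classification`, `regression` terms (all >= 0).
#' @export
mil_loss <- function(pred, true_class, true_hb, config, hb_scale = 1) {
  probs <- pred$class_probabilities
  if (is.character(true_class)) {
    ti <- match(true_class, names(probs))
    if (is.na(ti)) stop("unknown class '", true_class, "'", call. = FALSE)
  } else ti <- as.integer(true_class)
  stopifnot(ti >= 1L, ti <= length(probs), is.finite(true_hb))
  ce <- -log(max(probs[[ti]], 1e-12))
  err_z <- (pred$hemoglobin_predicted - true_hb) / hb_scale
  reg <- err_z^2
  list(total = ce + config$hb_loss_weight * reg,
       classification = ce, regression = reg)
}

#' Subsample a bag to at most `bag_size` cells
#'
#' Uniform sampling without replacement; bags at or below `bag_size` pass
#' through unchanged (no padding — the aggregator accepts variable sizes).
#'
#' @param bag a `cell_bag` or matrix.
#' @param bag_size maximum number of cells to keep.
#' @param seed integer seed for a reproducible subsample.
#' @return Same type as the input.
#' @export
subsample_bag <- function(bag, bag_size, seed = 1L) {
  stopifnot(bag_size >= 1L)
  X <- bag_matrix(bag)
  n <- nrow(X)
  if (n <= bag_size) return(bag)
  keep <- with_seed(seed, sort(sample.int(n, bag_size)))
  if (inherits(bag, "cell_bag")) {
    bag$embeddings <- X[keep, , drop = FALSE]
    if (!is.null(bag$cell_types)) bag$cell_types <- bag$cell_types[keep]
    bag
  } else X[keep, , drop = FALSE]
}

#' @export
print.mil_model <- function(x, ...) {
  cfg <- x$config
  n_par <- sum(vapply(x$params, length, integer(1L)))
  cat("<mil_model> set-transformer bag aggregator\n")
  cat(sprintf("  %d -> %d latent, %d layer(s) x %d head(s), %d classes\n",
              cfg$embedding_dim, cfg$latent_dim, cfg$n_layers, cfg$n_heads,
              cfg$n_classes))
  cat(sprintf("  %s parameters; hb scale %.3g g/dL (center %.3g)\n",
              format(n_par, big.mark = ","), x$hb_scale, x$hb_center))
  invisible(x)
}

#' @export
print.bag_prediction <- function(x, ...) {
  cat("<bag_prediction>\n")
  pr <- sort(x$class_probabilities, decreasing = TRUE)
  for (i in seq_len(min(3L, length(pr))))
    cat(sprintf("  %-22s %.3f\n", names(pr)[i], pr[i]))
  cat(sprintf("  hemoglobin %.2f g/dL; %d cells\n",
              x$hemoglobin_predicted, length(x$attention_weights)))
  invisible(x)
}
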