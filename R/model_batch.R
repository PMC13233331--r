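# Batched forward/backward used by the training loop. A batch of bags is
# stacked into one tall matrix (one aggregation-token row per bag followed by
# its cell rows); all row-wise operations (projections, layer norm,
# feed-forward) run on the stack, and only the attention score/mixing step
# loops over bags. Gradients returned are the SUM over the batch; the caller
# rescales. The hot path is the compiled kernel (src/mil_kernel.cpp); the
# base-R implementation below is the reference both are tested against, and
# both are asserted numerically identical to per-bag mil_forward /
# mil_backward in the test suite.

mil_fb_batch <- function(model, Xs, labels, hb_z, grad = TRUE,
                         dropout_seed = NULL,
                         use_cpp = getOption("hemomil.use_cpp", TRUE)) {
  cfg <- model$config
  masks <- draw_dropout_masks(model, Xs, dropout_seed)
  if (isTRUE(use_cpp)) {
    res <- .cpp_fb_batch(model$params, Xs, as.integer(labels),
                         as.numeric(hb_z), cfg$n_layers, cfg$n_heads,
                         cfg$hb_loss_weight, grad, masks,
                         1 - cfg$dropout)
    res$losses <- as.vector(res$losses)
    res$ce <- as.vector(res$ce)
    res$reg <- as.vector(res$reg)
    res$hbz <- as.vector(res$hbz)
    if (grad) {
      for (nm in names(model$params))
        if (!is.matrix(model$params[[nm]]))
          res$grads[[nm]] <- as.vector(res$grads[[nm]])
    }
    res
  } else {
    mil_fb_batch_r(model, Xs, labels, hb_z, grad, masks)
  }
}

# Dropout masks are drawn R-side under a private seeded stream so the
# compiled and reference paths see identical masks: one (Ntot x 2L) matrix
# per layer, then a (B x head width) matrix, as one list.
draw_dropout_masks <- function(model, Xs, dropout_seed) {
  cfg <- model$config
  if (is.null(dropout_seed) || cfg$dropout <= 0) return(NULL)
  keep_p <- 1 - cfg$dropout
  Ntot <- sum(vapply(Xs, nrow, integer(1L))) + length(Xs)
  L <- cfg$latent_dim
  with_seed(dropout_seed, {
    out <- vector("list", cfg$n_layers + 1L)
    for (l in seq_len(cfg$n_layers))
      out[[l]] <- matrix(stats::rbinom(Ntot * 2L * L, 1L, keep_p),
                         Ntot, 2L * L)
    out[[cfg$n_layers + 1L]] <-
      matrix(stats::rbinom(length(Xs) * ncol(model$params$Wm), 1L, keep_p),
             length(Xs), ncol(model$params$Wm))
    out
  })
}

mil_fb_batch_r <- function(model, Xs, labels, hb_z, grad = TRUE,
                           masks = NULL) {
  p <- model$params
  cfg <- model$config
  B <- length(Xs)
  L <- cfg$latent_dim
  h <- cfg$n_heads
  dh <- L %/% h
  keep_p <- 1 - cfg$dropout
  use_drop <- grad && !is.null(masks)
  w <- cfg$hb_loss_weight

  ns <- vapply(Xs, nrow, integer(1L))
  sizes <- ns + 1L
  starts <- cumsum(c(1L, sizes[-B]))
  Ntot <- sum(sizes)
  ranges <- lapply(seq_len(B), function(b)
    starts[b]:(starts[b] + ns[b]))

  Xall <- do.call(rbind, Xs)
  Tm <- matrix(0, Ntot, L)
  Tm[-starts, ] <- Xall %*% p$W_in + rep(p$b_in, each = nrow(Xall))
  Tm[starts, ] <- matrix(p$cls, B, L, byrow = TRUE)

  drop_rng <- if (use_drop) {
    out <- masks[seq_len(cfg$n_layers)]
    out$head <- masks[[cfg$n_layers + 1L]]
    out
  } else NULL

  layers <- vector("list", cfg$n_layers)
  for (l in seq_len(cfg$n_layers)) {
    lc <- list()
    ln1 <- ln_forward(Tm, p[[paste0("ln1_g_", l)]], p[[paste0("ln1_b_", l)]])
    Y <- ln1$out
    Q <- Y %*% p[[paste0("Wq_", l)]]
    Km <- Y %*% p[[paste0("Wk_", l)]]
    V <- Y %*% p[[paste0("Wv_", l)]]
    H <- matrix(0, Ntot, L)
    Ps <- vector("list", B)
    for (b in seq_len(B)) {
      r <- ranges[[b]]
      Pb <- vector("list", h)
      for (j in seq_len(h)) {
        idx <- ((j - 1L) * dh + 1L):(j * dh)
        S <- tcrossprod(Q[r, idx, drop = FALSE],
                        Km[r, idx, drop = FALSE]) / sqrt(dh)
        P <- softmax_rows(S)
        Pb[[j]] <- P
        H[r, idx] <- P %*% V[r, idx, drop = FALSE]
      }
      Ps[[b]] <- Pb
    }
    O <- H %*% p[[paste0("Wo_", l)]] + rep(p[[paste0("bo_", l)]], each = Ntot)
    T1 <- Tm + O
    ln2 <- ln_forward(T1, p[[paste0("ln2_g_", l)]], p[[paste0("ln2_b_", l)]])
    A1 <- ln2$out %*% p[[paste0("W1_", l)]] +
      rep(p[[paste0("b1_", l)]], each = Ntot)
    R <- pmax(A1, 0)
    Rd <- if (use_drop) R * drop_rng[[l]] / keep_p else R
    Tm <- T1 + Rd %*% p[[paste0("W2_", l)]] +
      rep(p[[paste0("b2_", l)]], each = Ntot)
    if (grad) {
      lc$ln1 <- ln1; lc$Y <- Y; lc$Q <- Q; lc$K <- Km; lc$V <- V
      lc$Ps <- Ps; lc$H <- H; lc$T1 <- T1; lc$ln2 <- ln2
      lc$A1 <- A1; lc$Rd <- Rd
      lc$drop <- if (use_drop) drop_rng[[l]] else NULL
      layers[[l]] <- lc
    }
  }

  Tcls <- Tm[starts, , drop = FALSE]
  lnf <- ln_forward(Tcls, p$lnf_g, p$lnf_b)
  Z <- lnf$out
  Mpre <- Z %*% p$Wm + rep(p$bm, each = B)
  M <- pmax(Mpre, 0)
  Md <- if (use_drop) M * drop_rng$head / keep_p else M
  logits <- Md %*% p$Wc + rep(p$bc, each = B)
  probs <- softmax_rows(logits)
  hbz <- drop(Md %*% p$Wh) + drop(logits %*% p$Whc) + p$bh

  p_true <- probs[cbind(seq_len(B), labels)]
  ce <- -log(pmax(p_true, 1e-12))
  reg <- (hbz - hb_z)^2
  losses <- ce + w * reg

  out <- list(losses = losses, ce = ce, reg = reg, probs = probs, hbz = hbz)
  if (!grad) return(out)

  # ---- backward ----
  g <- list()
  dlogits <- probs
  dlogits[cbind(seq_len(B), labels)] <- dlogits[cbind(seq_len(B), labels)] - 1
  dhbz <- 2 * w * (hbz - hb_z)
  g$Whc <- crossprod(logits, matrix(dhbz, ncol = 1L))
  dlogits <- dlogits + outer(dhbz, drop(p$Whc))
  g$Wc <- crossprod(Md, dlogits)
  g$bc <- colSums(dlogits)
  g$Wh <- crossprod(Md, matrix(dhbz, ncol = 1L))
  g$bh <- sum(dhbz)
  dMd <- tcrossprod(dlogits, p$Wc) + outer(dhbz, drop(p$Wh))
  dM <- if (use_drop) dMd * drop_rng$head / keep_p else dMd
  dMpre <- dM * (Mpre > 0)
  g$Wm <- crossprod(Z, dMpre)
  g$bm <- colSums(dMpre)
  dZ <- tcrossprod(dMpre, p$Wm)
  lb <- ln_backward(dZ, lnf, p$lnf_g)
  g$lnf_g <- lb$dg
  g$lnf_b <- lb$db
  dT <- matrix(0, Ntot, L)
  dT[starts, ] <- lb$dx

  for (l in rev(seq_len(cfg$n_layers))) {
    lc <- layers[[l]]
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

    dO <- dT1
    g[[paste0("Wo_", l)]] <- crossprod(lc$H, dO)
    g[[paste0("bo_", l)]] <- colSums(dO)
    dH <- tcrossprod(dO, p[[paste0("Wo_", l)]])
    dQ <- matrix(0, Ntot, L)
    dK <- matrix(0, Ntot, L)
    dV <- matrix(0, Ntot, L)
    for (b in seq_len(B)) {
      r <- ranges[[b]]
      for (j in seq_len(h)) {
        idx <- ((j - 1L) * dh + 1L):(j * dh)
        P <- lc$Ps[[b]][[j]]
        dHj <- dH[r, idx, drop = FALSE]
        dP <- tcrossprod(dHj, lc$V[r, idx, drop = FALSE])
        dV[r, idx] <- crossprod(P, dHj)
        dS <- P * (dP - rowSums(dP * P)) / sqrt(dh)
        dQ[r, idx] <- dS %*% lc$K[r, idx, drop = FALSE]
        dK[r, idx] <- crossprod(dS, lc$Q[r, idx, drop = FALSE])
      }
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

  g$cls <- colSums(dT[starts, , drop = FALSE])
  dP_in <- dT[-starts, , drop = FALSE]
  g$W_in <- crossprod(Xall, dP_in)
  g$b_in <- colSums(dP_in)
  out$grads <- g
  out
}
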