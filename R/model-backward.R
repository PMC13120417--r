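# Reverse-mode gradients for the batched forward pass. Mirrors
# sst_forward_batch() step by step; gradient names match the flat parameter
# names of init_params(). Only the training path (batch-statistics batch
# norm, cached dropout mask) is differentiated.

sst_backward_batch <- function(dlogits, cache, model) {
  cfg <- model$cfg; p <- model$params
  n <- cfg$n_tokens; d <- cfg$d_emb
  k <- cfg$n_heads; dh <- cfg$d_head
  hd <- cache$head
  Nb <- hd$Nb
  cidx <- center_token(cfg)
  idx_c <- (cidx - 1L) * Nb + seq_len(Nb)
  tok_of_row <- rep(seq_len(n), each = Nb)
  coords <- token_coords(cfg$patch_size)
  use_rope <- cfg$pos_encoding == "rope2d_mixed"
  g <- list()

  # classifier head
  g[["cls.W2"]] <- crossprod(hd$cr, dlogits)
  g[["cls.b2"]] <- colSums(dlogits)
  dcr <- tcrossprod(dlogits, p[["cls.W2"]])
  drelu <- drelu_cpp(dcr, hd$cr)
  bnb <- bn_bwd(drelu, hd$bn, p[["cls.gamma"]])
  g[["cls.gamma"]] <- bnb$dgamma; g[["cls.beta"]] <- bnb$dbeta
  dc1 <- if (is.null(hd$dropout_mask)) bnb$dX else bnb$dX * hd$dropout_mask
  g[["cls.W1"]] <- crossprod(hd$zF, dc1)
  g[["cls.b1"]] <- colSums(dc1)
  dzF <- tcrossprod(dc1, p[["cls.W1"]])

  # aggregation weights
  w <- p[["agg.w"]]
  gw <- numeric(cfg$n_layers)
  for (l in seq_len(cfg$n_layers))
    gw[l] <- sum(dzF * hd$z_list[[l]])
  g[["agg.w"]] <- gw

  dX <- matrix(0, Nb * n, d)

  for (l in rev(seq_len(cfg$n_layers))) {
    pre_l <- paste0("l", l, ".")
    lc <- cache[[paste0("layer", l)]]
    pwq <- layer_proj(p, l, "q"); pwk <- layer_proj(p, l, "k")
    pwv <- layer_proj(p, l, "v"); pwo <- layer_proj(p, l, "out")
    add_proj <- function(nm, grads) {
      for (f in names(grads)) {
        key <- paste0(pre_l, nm, ".", f)
        g[[key]] <<- if (is.null(g[[key]])) grads[[f]] else g[[key]] + grads[[f]]
      }
    }

    if (cfg$attention_mode == "cfla") {
      dz <- dX[idx_c, , drop = FALSE] + w[l] * dzF
      # FFN on the center token
      g[[paste0(pre_l, "ffn.W2")]] <- crossprod(lc$hr, dz)
      g[[paste0(pre_l, "ffn.b2")]] <- colSums(dz)
      dh1 <- drelu_cpp(tcrossprod(dz, p[[paste0(pre_l, "ffn.W2")]]), lc$hr)
      g[[paste0(pre_l, "ffn.W1")]] <- crossprod(lc$ln2out, dh1)
      g[[paste0(pre_l, "ffn.b1")]] <- colSums(dh1)
      dln2out <- tcrossprod(dh1, p[[paste0(pre_l, "ffn.W1")]])
      lnb2 <- ln_bwd(dln2out, lc$ln2, p[[paste0(pre_l, "ln2.gamma")]])
      g[[paste0(pre_l, "ln2.gamma")]] <- lnb2$dgamma
      g[[paste0(pre_l, "ln2.beta")]] <- lnb2$dbeta
      dxc1 <- dz + lnb2$dX
      # output projection
      pb <- proj_bwd(dxc1, lc$o, lc$op, pwo)
      add_proj("out", pb$grads)
      do <- pb$dX
      # attention-value product and softmax
      vm <- value_mix_bwd_cpp(lc$Aflat, lc$Vout, do, Nb)
      dV <- vm$dV
      dscores <- token_softmax_bwd_cpp(vm$dA, lc$Aflat, Nb) / sqrt(dh)
      hs <- head_scores_bwd_cpp(dscores, lc$Krot, lc$qrot, Nb)
      dKrot <- hs$dK; dqrot <- hs$dQ
      if (use_rope) {
        phic <- lc$rope$Phi[cidx, ]
        Cq <- matrix(cos(phic), Nb, d %/% 2L, byrow = TRUE)
        Sq <- matrix(sin(phic), Nb, d %/% 2L, byrow = TRUE)
        dq <- rope_rot_cpp(dqrot, Cq, Sq, TRUE)
        dK <- rope_rot_cpp(dKrot, lc$rope$Ck, lc$rope$Sk, TRUE)
        dphi_q <- rope_phase_grad_cpp(dqrot, lc$qrot)     # Nb x d/2
        dphi_k <- rope_phase_grad_cpp(dKrot, lc$Krot)     # (Nb*n) x d/2
        xs <- coords[tok_of_row, 1L]; ys <- coords[tok_of_row, 2L]
        cx <- coords[cidx, 1L]; cy <- coords[cidx, 2L]
        g[[paste0(pre_l, "theta_x")]] <-
          colSums(dphi_q) * cx + colSums(dphi_k * xs)
        g[[paste0(pre_l, "theta_y")]] <-
          colSums(dphi_q) * cy + colSums(dphi_k * ys)
      } else { dq <- dqrot; dK <- dKrot }
      # q/k/v projections
      pbq <- proj_bwd(dq, lc$Xc, lc$qp, pwq); add_proj("q", pbq$grads)
      pbk <- proj_bwd(dK, lc$Xn, lc$Kp, pwk); add_proj("k", pbk$grads)
      pbv <- proj_bwd(dV, lc$Xn, lc$Vp, pwv); add_proj("v", pbv$grads)
      dXn <- pbk$dX + pbv$dX
      dXn[idx_c, ] <- dXn[idx_c, , drop = FALSE] + pbq$dX
      lnb1 <- ln_bwd(dXn, lc$ln1, p[[paste0(pre_l, "ln1.gamma")]])
      g[[paste0(pre_l, "ln1.gamma")]] <- lnb1$dgamma
      g[[paste0(pre_l, "ln1.beta")]] <- lnb1$dbeta
      dX_prev <- lnb1$dX
      dX_prev[idx_c, ] <- dX_prev[idx_c, , drop = FALSE] + dxc1
      dX[idx_c, ] <- 0                  # center of input was overwritten
      dX <- dX_prev + dX
    } else {  # full self-attention
      dXout <- dX
      dXout[idx_c, ] <- dXout[idx_c, , drop = FALSE] + w[l] * dzF
      # FFN over all tokens
      g[[paste0(pre_l, "ffn.W2")]] <- crossprod(lc$hr, dXout)
      g[[paste0(pre_l, "ffn.b2")]] <- colSums(dXout)
      dh1 <- drelu_cpp(tcrossprod(dXout, p[[paste0(pre_l, "ffn.W2")]]),
                       lc$hr)
      g[[paste0(pre_l, "ffn.W1")]] <- crossprod(lc$ln2out, dh1)
      g[[paste0(pre_l, "ffn.b1")]] <- colSums(dh1)
      dln2out <- tcrossprod(dh1, p[[paste0(pre_l, "ffn.W1")]])
      lnb2 <- ln_bwd(dln2out, lc$ln2, p[[paste0(pre_l, "ln2.gamma")]])
      g[[paste0(pre_l, "ln2.gamma")]] <- lnb2$dgamma
      g[[paste0(pre_l, "ln2.beta")]] <- lnb2$dbeta
      dX1 <- dXout + lnb2$dX
      pb <- proj_bwd(dX1, lc$O, lc$op, pwo)
      add_proj("out", pb$grads)
      dO <- pb$dX
      dQrot <- matrix(0, Nb * n, d); dKrot <- matrix(0, Nb * n, d)
      dV <- matrix(0, Nb * n, d)
      for (h in seq_len(k)) {
        cols <- (h - 1L) * dh + seq_len(dh)
        for (b in seq_len(Nb)) {
          rows <- b + (seq_len(n) - 1L) * Nb
          Ab <- lc$Aall[, , b, h]
          dOb <- dO[rows, cols, drop = FALSE]
          Vb <- lc$Vout[rows, cols, drop = FALSE]
          dAb <- tcrossprod(dOb, Vb)
          dV[rows, cols] <- dV[rows, cols, drop = FALSE] + crossprod(Ab, dOb)
          dSb <- Ab * (dAb - rowSums(Ab * dAb))
          dSb <- dSb / sqrt(dh)
          dQrot[rows, cols] <- dSb %*% lc$Krot[rows, cols, drop = FALSE]
          dKrot[rows, cols] <- crossprod(dSb, lc$Qrot[rows, cols, drop = FALSE])
        }
      }
      if (use_rope) {
        dQ <- rope_rot_cpp(dQrot, lc$rope$Ck, lc$rope$Sk, TRUE)
        dK <- rope_rot_cpp(dKrot, lc$rope$Ck, lc$rope$Sk, TRUE)
        dphi_q <- rope_phase_grad_cpp(dQrot, lc$Qrot)
        dphi_k <- rope_phase_grad_cpp(dKrot, lc$Krot)
        xs <- coords[tok_of_row, 1L]; ys <- coords[tok_of_row, 2L]
        g[[paste0(pre_l, "theta_x")]] <-
          colSums(dphi_q * xs) + colSums(dphi_k * xs)
        g[[paste0(pre_l, "theta_y")]] <-
          colSums(dphi_q * ys) + colSums(dphi_k * ys)
      } else { dQ <- dQrot; dK <- dKrot }
      pbq <- proj_bwd(dQ, lc$Xn, lc$Qp, pwq); add_proj("q", pbq$grads)
      pbk <- proj_bwd(dK, lc$Xn, lc$Kp, pwk); add_proj("k", pbk$grads)
      pbv <- proj_bwd(dV, lc$Xn, lc$Vp, pwv); add_proj("v", pbv$grads)
      dXn <- pbq$dX + pbk$dX + pbv$dX
      lnb1 <- ln_bwd(dXn, lc$ln1, p[[paste0(pre_l, "ln1.gamma")]])
      g[[paste0(pre_l, "ln1.gamma")]] <- lnb1$dgamma
      g[[paste0(pre_l, "ln1.beta")]] <- lnb1$dbeta
      dX <- lnb1$dX + dX1
    }
  }

  # embedding
  if (cfg$pos_encoding == "ape")
    g[["ape"]] <- rowsum(dX, tok_of_row)
  drelu <- drelu_cpp(dX, cache$emb$act)
  bnb <- bn_bwd(drelu, cache$emb$bn, p[["emb.gamma"]])
  g[["emb.gamma"]] <- bnb$dgamma; g[["emb.beta"]] <- bnb$dbeta
  g[["emb.W"]] <- crossprod(cache$emb$Pmat, bnb$dX)
  g[["emb.b"]] <- colSums(bnb$dX)
  g
}

# Mean cross-entropy over a batch and its gradient w.r.t. the logits.
ce_loss <- function(logits, labels) {
  Nb <- nrow(logits)
  pr <- softmax_rows(logits)
  picked <- pr[cbind(seq_len(Nb), labels)]
  onehot <- matrix(0, Nb, ncol(logits))
  onehot[cbind(seq_len(Nb), labels)] <- 1
  list(loss = -mean(log(pmax(picked, 1e-12))),
       dlogits = (pr - onehot) / Nb)
}

adam_init <- function(params) {
  list(m = lapply(params, function(x) x * 0),
       v = lapply(params, function(x) x * 0), t = 0L)
}

adam_step <- function(params, grads, opt, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t; bc2 <- 1 - beta2^opt$t
  for (nm in names(params)) {
    gr <- grads[[nm]]
    if (is.null(gr)) next
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * gr
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * gr * gr
    params[[nm]] <- params[[nm]] -
      lr * (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + eps)
  }
  list(params = params, opt = opt)
}
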