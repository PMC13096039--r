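# Reverse-mode pass through MEM-ViT, mirroring memvit_fwd exactly.
# Gradients come back as a flat named list aligned with state$params;
# finite-difference tests pin the correctness of every branch.

split_cols <- function(M, widths) {
  out <- vector("list", length(widths))
  at <- 0L
  for (i in seq_along(widths)) {
    out[[i]] <- M[, (at + 1L):(at + widths[i]), drop = FALSE]
    at <- at + widths[i]
  }
  out
}

memvit_bwd <- function(dprob, fwd, state, B) {
  cfg <- state$config
  p <- cfg$patch_size; k <- cfg$n_stages
  nh <- cfg$image_size[1] %/% p; nw <- cfg$image_size[2] %/% p
  np <- nh * nw
  assign0 <- skip_assignment(cfg)
  ctx <- fwd$dec$ctx
  grads <- list()

  # head
  dz <- nn_sigmoid_bw(dprob, ctx$caches$sig)
  hd <- nn_linear_bw(dz, ctx$caches$head)
  grads$head_W <- hd$dW; grads$head_b <- hd$db
  dx <- hd$dx

  dskip_feats <- vector("list", 4)   # grads wrt refined skip branches
  draw_feat <- NULL
  for (j in rev(seq_len(k))) {
    r <- conv_bn_relu_bw(dx, grads, state, sprintf("F%d", j), ctx)
    grads <- r$grads
    widths <- ctx[[sprintf("fuse%d_channels", j)]]
    parts <- split_cols(r$dx, widths)
    du <- parts[[1]]
    if (j == k) {
      draw_feat <- parts[[2]]
    } else {
      taps <- assign0[[j + 1]] %||% integer()
      for (i in seq_along(taps)) {
        t <- taps[i]
        dup <- nn_upnearest_bw(parts[[i + 1]],
                               ctx$caches[[sprintf("up_s%d_j%d", t, j)]])
        dskip_feats[[t]] <- if (is.null(dskip_feats[[t]])) dup else
          dskip_feats[[t]] + dup
      }
    }
    tc <- nn_tconv2_bw(du, ctx$caches[[sprintf("U%d", j)]])
    grads[[sprintf("U%d_W", j)]] <- tc$dW
    grads[[sprintf("U%d_b", j)]] <- tc$db
    dx <- tc$dx
  }

  # token-resolution fusion
  dx <- nn_dropout_bw(dx, ctx$caches$d0_drop)
  r <- conv_bn_relu_bw(dx, grads, state, "D0", ctx)
  grads <- r$grads
  parts <- split_cols(r$dx, ctx$d0_in_channels)
  dtokens <- parts[[1]]
  for (i in seq_along(assign0[[1]])) {
    t <- assign0[[1]][i]
    dskip_feats[[t]] <- if (is.null(dskip_feats[[t]])) parts[[i + 1]] else
      dskip_feats[[t]] + parts[[i + 1]]
  }

  # raw branch (input gradient is discarded)
  r <- conv_bn_relu_bw(draw_feat, grads, state, "R_c2", ctx)
  grads <- r$grads
  r <- conv_bn_relu_bw(r$dx, grads, state, "R_c1", ctx)
  grads <- r$grads

  # transformer skip branches -> gradients wrt the tapped layer outputs
  dskips <- vector("list", 4)
  for (j in 1:4) {
    r <- conv_bn_relu_bw(dskip_feats[[j]], grads, state,
                         sprintf("S%d_c2", j), ctx)
    grads <- r$grads
    r <- conv_bn_relu_bw(r$dx, grads, state, sprintf("S%d_c1", j), ctx)
    grads <- r$grads
    dskips[[j]] <- r$dx
  }

  # encoder
  enc <- fwd$enc$caches
  dX <- nn_dropout_bw(dtokens, enc$drop)
  lf <- nn_layernorm_bw(dX, enc$lnf)
  grads$encf_g <- lf$dg; grads$encf_b <- lf$db
  dX <- lf$dx
  for (l in rev(seq_len(cfg$depth))) {
    if (l %in% cfg$skip_layers) {
      dX <- dX + dskips[[match(l, cfg$skip_layers)]]
    }
    pre <- paste0("L", l, "_")
    ch <- enc$layers[[l]]
    # MLP sub-block: X_out = X_mid + m2(gelu(m1(ln2(X_mid))))
    m2 <- nn_linear_bw(dX, ch$m2)
    grads[[paste0(pre, "m_W2")]] <- m2$dW
    grads[[paste0(pre, "m_b2")]] <- m2$db
    dg <- nn_gelu_bw(m2$dx, ch$ge)
    m1 <- nn_linear_bw(dg, ch$m1)
    grads[[paste0(pre, "m_W1")]] <- m1$dW
    grads[[paste0(pre, "m_b1")]] <- m1$db
    l2 <- nn_layernorm_bw(m1$dx, ch$ln2)
    grads[[paste0(pre, "ln2_g")]] <- l2$dg
    grads[[paste0(pre, "ln2_b")]] <- l2$db
    dX <- dX + l2$dx
    # attention sub-block: X_mid = X_in + attn(ln1(X_in))
    datt <- matrix(0, nrow(dX), ncol(dX))
    zero <- function(M) matrix(0, nrow(M), ncol(M))
    acc <- list(dWq = NULL)
    for (b in seq_len(B)) {
      rows <- ((b - 1L) * np + 1L):(b * np)
      ab <- mhsa_bw(dX[rows, , drop = FALSE], ch$att[[b]])
      datt[rows, ] <- ab$dx
      for (nm in c("dWq", "dbq", "dWk", "dbk", "dWv", "dbv", "dWo", "dbo")) {
        acc[[nm]] <- if (is.null(acc[[nm]])) ab[[nm]] else acc[[nm]] + ab[[nm]]
      }
    }
    grads[[paste0(pre, "Wq")]] <- acc$dWq; grads[[paste0(pre, "bq")]] <- acc$dbq
    grads[[paste0(pre, "Wk")]] <- acc$dWk; grads[[paste0(pre, "bk")]] <- acc$dbk
    grads[[paste0(pre, "Wv")]] <- acc$dWv; grads[[paste0(pre, "bv")]] <- acc$dbv
    grads[[paste0(pre, "Wo")]] <- acc$dWo; grads[[paste0(pre, "bo")]] <- acc$dbo
    l1 <- nn_layernorm_bw(datt, ch$ln1)
    grads[[paste0(pre, "ln1_g")]] <- l1$dg
    grads[[paste0(pre, "ln1_b")]] <- l1$db
    dX <- dX + l1$dx
  }
  # positional embedding: sum gradient over the batch
  dpos <- matrix(0, np, ncol(dX))
  for (b in seq_len(B)) {
    rows <- ((b - 1L) * np + 1L):(b * np)
    dpos <- dpos + dX[rows, , drop = FALSE]
  }
  grads$pos <- dpos
  pe <- nn_linear_bw(dX, enc$emb$cache)
  grads$pe_W <- pe$dW
  grads$pe_b <- pe$db
  grads
}
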