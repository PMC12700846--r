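# Independent naive-loop oracles and a finite-difference gradient checker.
# Everything here is written for clarity, not speed, and stays independent of
# the package's vectorized/compiled code paths.

# plain triple-loop 2-d convolution, (b,c,h,w), weight (co, ci/groups, kh, kw)
naive_conv2d <- function(x, w, bias, stride = 1, pad = 0, dil = 1, groups = 1) {
  d <- dim(x); wd <- dim(w)
  B <- d[1]; C <- d[2]; H <- d[3]; W <- d[4]
  CO <- wd[1]; CIG <- wd[2]; KH <- wd[3]; KW <- wd[4]
  HO <- (H + 2 * pad - dil * (KH - 1) - 1) %/% stride + 1
  WO <- (W + 2 * pad - dil * (KW - 1) - 1) %/% stride + 1
  COG <- CO / groups
  y <- array(0, c(B, CO, HO, WO))
  for (bb in 1:B) for (o in 1:CO) {
    g <- (o - 1) %/% COG
    for (oh in 1:HO) for (ow in 1:WO) {
      s <- bias[o]
      for (ci in 1:CIG) for (kh in 1:KH) for (kw in 1:KW) {
        hi <- (oh - 1) * stride - pad + (kh - 1) * dil + 1
        wi <- (ow - 1) * stride - pad + (kw - 1) * dil + 1
        if (hi >= 1 && hi <= H && wi >= 1 && wi <= W) {
          s <- s + x[bb, g * CIG + ci, hi, wi] * w[o, ci, kh, kw]
        }
      }
      y[bb, o, oh, ow] <- s
    }
  }
  y
}

naive_softmax_rows <- function(m) {
  t(apply(m, 1L, function(r) { e <- exp(r - max(r)); e / sum(e) }))
}

# layer normalization of a (C, P) token matrix: each token (column)
# normalized across its channels
naive_ln_tokens <- function(tm, eps = 1e-5) {
  apply(tm, 2L, function(col) {
    (col - mean(col)) / sqrt(mean((col - mean(col))^2) + eps)
  })
}

# scaled dot-product attention, one head at a time, loops only
naive_sdpa <- function(Q, K, V, scale, heads = 1) {
  dq <- ncol(Q) / heads
  dv <- ncol(V) / heads
  out <- matrix(0, nrow(Q), ncol(V))
  wts <- array(0, c(heads, nrow(Q), nrow(K)))
  for (h in seq_len(heads)) {
    qc <- (h - 1) * dq + seq_len(dq)
    vc <- (h - 1) * dv + seq_len(dv)
    for (i in seq_len(nrow(Q))) {
      logits <- numeric(nrow(K))
      for (j in seq_len(nrow(K))) {
        logits[j] <- sum(Q[i, qc] * K[j, qc]) * scale
      }
      e <- exp(logits - max(logits))
      a <- e / sum(e)
      wts[h, i, ] <- a
      for (v in vc) out[i, v] <- sum(a * V[, v])
    }
  }
  list(output = out, weights = wts)
}

# GCA with identity projections: LN per stage, concat channels, fused
# queries/keys/values, channel-by-channel softmax map, context = A V
naive_gca <- function(tokens, eps = 1e-5) {
  b <- dim(tokens[[1]])[1]
  P <- dim(tokens[[1]])[3]
  C_c <- sum(vapply(tokens, function(t) dim(t)[2], numeric(1)))
  Ygc <- array(0, c(b, C_c, C_c))
  ctx <- array(0, c(b, C_c, P))
  for (bb in seq_len(b)) {
    tc <- do.call(rbind, lapply(tokens, function(t) {
      naive_ln_tokens(matrix(t[bb, , ], dim(t)[2], P), eps)
    }))
    A <- naive_softmax_rows(tc %*% t(tc) / sqrt(C_c))
    Ygc[bb, , ] <- A
    ctx[bb, , ] <- A %*% tc
  }
  list(Ygc = Ygc, context = ctx)
}

# GSA with identity projections: per-head (P x P) maps over positions,
# values mixed per channel block
naive_gsa <- function(tokens, heads, eps = 1e-5) {
  b <- dim(tokens[[1]])[1]
  P <- dim(tokens[[1]])[3]
  C_c <- sum(vapply(tokens, function(t) dim(t)[2], numeric(1)))
  dk <- C_c / heads
  Ygs <- array(0, c(b, heads, P, P))
  ctx <- array(0, c(b, C_c, P))
  for (bb in seq_len(b)) {
    tc <- do.call(rbind, lapply(tokens, function(t) {
      naive_ln_tokens(matrix(t[bb, , ], dim(t)[2], P), eps)
    }))
    for (h in seq_len(heads)) {
      ch <- (h - 1) * dk + seq_len(dk)
      Qh <- tc[ch, , drop = FALSE]
      A <- naive_softmax_rows(t(Qh) %*% Qh / sqrt(dk))
      Ygs[bb, h, , ] <- A
      ctx[bb, ch, ] <- tc[ch, , drop = FALSE] %*% t(A)
    }
  }
  list(Ygs = Ygs, context = ctx)
}

# LCA: global average pool, circular k-tap channel convolution, sigmoid gate
naive_lca <- function(F, taps, bias) {
  d <- dim(F)
  k <- length(taps)
  half <- (k - 1) / 2
  Ylc <- array(0, c(d[1], d[2], 1, 1))
  out <- array(0, d)
  for (bb in seq_len(d[1])) {
    pooled <- vapply(seq_len(d[2]), function(c) mean(F[bb, c, , ]), numeric(1))
    conv <- vapply(seq_len(d[2]), function(c) {
      s <- bias
      for (j in seq_len(k)) {
        idx <- ((c - 1 + j - 1 - half) %% d[2]) + 1
        s <- s + taps[j] * pooled[idx]
      }
      s
    }, numeric(1))
    gate <- 1 / (1 + exp(-conv))
    Ylc[bb, , 1, 1] <- gate
    for (c in seq_len(d[2])) out[bb, c, , ] <- F[bb, c, , ] * gate[c] + F[bb, c, , ]
  }
  list(Ylc = Ylc, F_c_l = out)
}

# LSA built entirely from the naive convolution
naive_lsa <- function(F, params) {
  cp <- dim(params$reduce$w)[1]
  red <- naive_conv2d(F, params$reduce$w, params$reduce$b)
  b3 <- naive_conv2d(red, params$d3$w, params$d3$b, pad = 1, dil = 1, groups = cp)
  b5 <- naive_conv2d(red, params$d5$w, params$d5$b, pad = 4, dil = 2, groups = cp)
  b7 <- naive_conv2d(red, params$d7$w, params$d7$b, pad = 9, dil = 3, groups = cp)
  cat4 <- array(0, c(dim(F)[1], 4 * cp, dim(F)[3], dim(F)[4]))
  cat4[, 1:cp, , ] <- red
  cat4[, cp + 1:cp, , ] <- b3
  cat4[, 2 * cp + 1:cp, , ] <- b5
  cat4[, 3 * cp + 1:cp, , ] <- b7
  logits <- naive_conv2d(cat4, params$final$w, params$final$b)
  Yls <- 1 / (1 + exp(-logits))
  F_s_l <- array(0, dim(F))
  for (c in seq_len(dim(F)[2])) F_s_l[, c, , ] <- F[, c, , ] * Yls[, 1, , ]
  list(Yls = Yls, F_s_l = F_s_l)
}

# explicit channel-mixing / position-mixing loops
naive_combine_glca <- function(F_c_l, Ygc) {
  d <- dim(F_c_l)
  out <- array(0, d)
  for (bb in seq_len(d[1])) for (i in seq_len(d[2])) {
    acc <- array(0, d[3:4])
    for (j in seq_len(d[2])) acc <- acc + Ygc[bb, i, j] * F_c_l[bb, j, , ]
    out[bb, i, , ] <- acc + F_c_l[bb, i, , ]
  }
  out
}

naive_combine_glsa <- function(F_s_l, Ygs) {
  d <- dim(F_s_l)
  P <- d[3] * d[4]
  out <- array(0, d)
  for (bb in seq_len(d[1])) for (c in seq_len(d[2])) {
    flat <- as.vector(F_s_l[bb, c, , ])
    mixed <- numeric(P)
    for (p in seq_len(P)) mixed[p] <- sum(Ygs[bb, p, ] * flat)
    out[bb, c, , ] <- array(mixed + flat, d[3:4])
  }
  out
}

# SIM with identity projections: per-position attention across slices
naive_sim <- function(F, heads) {
  d <- dim(F)
  b <- d[1]; c <- d[2]; P <- d[3] * d[4]
  dk <- c / heads
  flat <- array(0, c(b, c, P))
  for (bb in 1:b) for (cc in 1:c) flat[bb, cc, ] <- as.vector(F[bb, cc, , ])
  out <- array(0, c(b, c, P))
  for (p in seq_len(P)) {
    for (h in seq_len(heads)) {
      ch <- (h - 1) * dk + seq_len(dk)
      Q <- flat[, ch, p, drop = FALSE]
      dim(Q) <- c(b, dk)
      A <- naive_softmax_rows(Q %*% t(Q) / sqrt(dk))
      out[, ch, p] <- A %*% Q
    }
  }
  array(out, d)
}

# finite-difference gradient check: max abs error over (up to) the first
# `n_probe` entries of every tensor in `tensors`
gradcheck <- function(f, tensors, h = 1e-6, n_probe = 8) {
  ag_zero_grad(tensors)
  out <- f()
  ag_backward(out)
  maxerr <- 0
  for (t in tensors) {
    g <- t$grad
    for (i in seq_len(min(length(t$value), n_probe))) {
      v0 <- t$value[i]
      t$value[i] <- v0 + h
      fp <- sum(f()$value)
      t$value[i] <- v0 - h
      fm <- sum(f()$value)
      t$value[i] <- v0
      maxerr <- max(maxerr, abs((fp - fm) / (2 * h) - g[i]))
    }
  }
  maxerr
}

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

rand_params_lca <- function(k, seed) {
  with_seed(seed, list(w = ag_tensor(array(rnorm(k), k)),
                       b = ag_tensor(array(rnorm(1), 1))))
}

rand_params_lsa <- function(c_in, seed) {
  cp <- max(1L, c_in %/% 4L)
  with_seed(seed, {
    rc <- function(co, ci, k) list(w = ag_tensor(array(rnorm(co * ci * k * k) / 4,
                                                       c(co, ci, k, k))),
                                   b = ag_tensor(array(rnorm(co) / 4, co)))
    list(reduce = rc(cp, c_in, 1), d3 = rc(cp, 1, 3), d5 = rc(cp, 1, 5),
         d7 = rc(cp, 1, 7), final = rc(1, 4 * cp, 1))
  })
}

plain_lsa_params <- function(p) {
  lapply(p, function(cv) list(w = cv$w$value, b = as.vector(cv$b$value)))
}
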