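# Global-Local Channel Spatial Attention (GLCSA).
#
# The block takes the skip features of the first n encoder stages, embeds
# them into a shared token space (P tokens per stage), runs a channel path
# (GLCA = global channel attention + local channel gating + cross-slice
# interaction) and a spatial path (GLSA = global spatial attention + local
# spatial gating + cross-slice interaction), fuses the path outputs with the
# original tokens through softmax-normalized weights, and upsamples back to
# each stage's resolution for the decoder.
#
# Per-stage projections are realized as channel blocks of depthwise
# projections on the channel-concatenated token matrix T_c: because every
# projection is per-channel, the fused formulation is identical to applying
# per-stage projections and sharing keys/values, and the per-stage attention
# maps are the corresponding row blocks of the fused (C_c x C_c) map.

#' GLCSA configuration
#'
#' Every architectural knob of the attention block, including the ablation
#' switches (channel-only / spatial-only, attention order, path fusion mode,
#' patch vs global embedding, LA1 vs LA2 local attention).
#'
#' @param Ps base patch size at the finest stage (stage i uses
#'   `Ps / 2^(i-1)`); default 8 (4 for denser variants).
#' @param glca_heads heads of the global channel attention (default 1).
#' @param glsa_heads heads of the global spatial attention (default 4).
#' @param lca_kernel odd kernel of the channelwise 1-d convolution in local
#'   channel attention (default 3).
#' @param embedding_mode `"patch"` (average pooling with kernel = stride =
#'   per-stage patch size) or `"global"` (bilinear interpolation to the token
#'   grid).
#' @param fusion_mode weighting of the final map fusion; only
#'   `"weighted_avg"` (softmax over three learnable scalars).
#' @param attention_order `"glca_first"` (default) or `"glsa_first"`.
#' @param module_fusion `"sequential"` (second path consumes the first's
#'   output; default), `"parallel"` (both consume the input, outputs fused
#'   separately) or `"sum"` (both consume the input, outputs summed before
#'   fusion).
#' @param sim_enabled apply the slice interaction module inside both paths.
#' @param local_mode `"la1"` (cross-slice attention over the whole stack) or
#'   `"la2"` (each slice treated as pseudo-depth 1, so the slice interaction
#'   degenerates to a per-slice value projection).
#' @param enable_glca,enable_glsa ablation switches for the two paths.
#' @param lsa_residual add the `+ F` residual to the local spatial gating
#'   (the printed formula omits it; off by default).
#' @param lca_window `"global"` (one pooling window over the whole map,
#'   default) or `"grid"` (independent windows on the token grid).
#' @return validated `glcsa_config` list.
#' @export
glcsa_config <- function(Ps = 8L, glca_heads = 1L, glsa_heads = 4L,
                         lca_kernel = 3L,
                         embedding_mode = c("patch", "global"),
                         fusion_mode = "weighted_avg",
                         attention_order = c("glca_first", "glsa_first"),
                         module_fusion = c("sequential", "sum", "parallel"),
                         sim_enabled = TRUE,
                         local_mode = c("la1", "la2"),
                         enable_glca = TRUE, enable_glsa = TRUE,
                         lsa_residual = FALSE,
                         lca_window = c("global", "grid")) {
  cfg <- list(Ps = as.integer(Ps), glca_heads = as.integer(glca_heads),
              glsa_heads = as.integer(glsa_heads),
              lca_kernel = as.integer(lca_kernel),
              embedding_mode = match.arg(embedding_mode),
              fusion_mode = match.arg(fusion_mode, "weighted_avg"),
              attention_order = match.arg(attention_order),
              module_fusion = match.arg(module_fusion),
              sim_enabled = isTRUE(sim_enabled),
              local_mode = match.arg(local_mode),
              enable_glca = isTRUE(enable_glca),
              enable_glsa = isTRUE(enable_glsa),
              lsa_residual = isTRUE(lsa_residual),
              lca_window = match.arg(lca_window))
  if (cfg$lca_kernel %% 2L == 0L) stop("lca_kernel must be odd")
  if (cfg$Ps < 1L || cfg$glca_heads < 1L || cfg$glsa_heads < 1L) {
    stop("Ps and head counts must be >= 1")
  }
  class(cfg) <- "glcsa_config"
  cfg
}

#' Multiscale token set
#'
#' @param tokens list over stages of arrays `(b, C_i, P)` sharing `P`.
#' @param Ps base patch size used to build them.
#' @return `token_set` object; `P` and the square grid side are derived.
#' @export
token_set <- function(tokens, Ps) {
  Pn <- vapply(tokens, function(t) {
    dims_of(if (is_tensor(t)) t$value else t)[3L]
  }, numeric(1))
  if (length(unique(Pn)) != 1L) stop("all stages must share the token count P")
  P <- Pn[1L]
  grid <- as.integer(round(sqrt(P)))
  structure(list(tokens = tokens, Ps = as.integer(Ps), P = as.integer(P),
                 grid = grid, n = length(tokens)),
            class = "token_set")
}

# ---- default (identity) parameters so every operation is runnable and
# ---- testable standalone, without a trained block --------------------------

dw_identity <- function(c) list(w = ag_tensor(array(1, c)), b = ag_tensor(array(0, c)))
ln_identity <- function(c) list(gamma = ag_tensor(array(1, c)), beta = ag_tensor(array(0, c)))
lca_identity <- function(k) {
  w <- array(0, k)
  w[(k + 1L) %/% 2L] <- 1
  list(w = ag_tensor(w), b = ag_tensor(array(0, 1L)))
}

as_ag <- function(x) if (is_tensor(x)) x else ag_tensor(x)

# ---- scaled dot-product attention ------------------------------------------

#' Scaled dot-product attention
#'
#' `weights = softmax(Q K' * scale)` row-wise, `output = weights V`.  With
#' `heads > 1` the feature columns of Q, K, V are split into `heads` groups,
#' attention runs per head, and the outputs are re-concatenated.
#'
#' @param Q,K,V numeric matrices `(len_q, d)`, `(len_k, d)`, `(len_k, dv)`.
#' @param scale positive scaling of the logits (e.g. `1/sqrt(d_k)`).
#' @param heads number of heads; must divide the feature columns.
#' @return list with `output` `(len_q, dv)` and `weights`
#'   `(heads, len_q, len_k)`.
#' @export
scaled_dot_attention <- function(Q, K, V, scale, heads = 1L) {
  Q <- as.matrix(Q); K <- as.matrix(K); V <- as.matrix(V)
  if (ncol(Q) != ncol(K) || nrow(K) != nrow(V)) {
    stop("scaled_dot_attention: non-conformable Q/K/V shapes")
  }
  if (scale <= 0) stop("scale must be > 0")
  if (ncol(Q) %% heads != 0L || ncol(V) %% heads != 0L) {
    stop("heads must divide the feature dimensions of Q and V")
  }
  dq <- ncol(Q) %/% heads
  dv <- ncol(V) %/% heads
  out <- matrix(0, nrow(Q), ncol(V))
  wts <- array(0, c(heads, nrow(Q), nrow(K)))
  for (h in seq_len(heads)) {
    qc <- (h - 1L) * dq + seq_len(dq)
    vc <- (h - 1L) * dv + seq_len(dv)
    logits <- (Q[, qc, drop = FALSE] %*% t(K[, qc, drop = FALSE])) * scale
    logits <- logits - apply(logits, 1L, max)
    e <- exp(logits)
    A <- e / rowSums(e)
    wts[h, , ] <- A
    out[, vc] <- A %*% V[, vc, drop = FALSE]
  }
  list(output = out, weights = wts)
}

# ---- multiscale embedding ---------------------------------------------------

#' Embed multiscale encoder features into a shared token space
#'
#' Stage `i` with extent `(H/2^(i-1), W/2^(i-1))` uses patch size
#' `P_si = Ps / 2^(i-1)`.  Patch mode: 2-d average pooling with kernel =
#' stride = `P_si`, flattening to `(C_i, P)`, then a depthwise 1x1
#' projection.  Global mode: bilinear interpolation of the whole stage to the
#' common token grid before flattening.  `P = (H/Ps)^2` at every stage.
#'
#' @param encoder_feats list over stages of arrays/tensors `(b, C_i, H_i, W_i)`.
#' @param cfg [glcsa_config].
#' @param params optional list of per-stage depthwise projection parameters;
#'   identity by default.
#' @return [token_set] (tokens as plain arrays when inputs were plain).
#' @export
embed_multiscale <- function(encoder_feats, cfg = glcsa_config(),
                             params = NULL) {
  plain <- !any(vapply(encoder_feats, is_tensor, logical(1)))
  toks <- embed_multiscale_ag(lapply(encoder_feats, as_ag), cfg, params)
  if (plain) toks$tokens <- lapply(toks$tokens, function(t) t$value)
  toks
}

embed_multiscale_ag <- function(feats, cfg, params = NULL) {
  n <- length(feats)
  H <- dims_of(feats[[1L]]$value)[3L]
  if (H %% cfg$Ps != 0L) stop("H must be divisible by the base patch size Ps")
  grid <- H %/% cfg$Ps
  toks <- vector("list", n)
  for (i in seq_len(n)) {
    d <- dims_of(feats[[i]]$value)
    psi <- cfg$Ps / 2^(i - 1)
    if (cfg$embedding_mode == "patch") {
      if (psi < 1 || psi != round(psi)) {
        stop("non-integer per-stage patch size P_s", i, " = Ps/2^(i-1) = ", psi)
      }
      if (d[3L] %% psi != 0L) {
        stop("stage ", i, " extent not divisible by its patch size")
      }
      g <- ag_avgpool(feats[[i]], as.integer(psi))
    } else {
      g <- ag_resize_bilinear(feats[[i]], grid, grid)
    }
    t_i <- ag_reshape(g, c(d[1L], d[2L], grid * grid))
    pp <- if (is.null(params)) dw_identity(d[2L]) else params[[i]]
    toks[[i]] <- dw_project(t_i, pp, 2L)
  }
  token_set(toks, cfg$Ps)
}

# Layer-normalize each stage's tokens and concatenate along channels.
ln_concat_tokens <- function(toks, ln_params = NULL) {
  normed <- lapply(seq_along(toks), function(i) {
    c_i <- dims_of(toks[[i]]$value)[2L]
    lp <- if (is.null(ln_params)) ln_identity(c_i) else ln_params[[i]]
    ag_layernorm(toks[[i]], lp$gamma, lp$beta, 2L)
  })
  if (length(normed) == 1L) normed[[1L]] else ag_concat(normed, 2L)
}

# ---- global channel attention ----------------------------------------------

#' Global channel attention over a token set
#'
#' Tokens are layer-normalized per stage, concatenated along channels to form
#' the fused matrix `T_c` that provides keys and values; queries are the
#' (concatenated) per-stage tokens.  All projections are depthwise 1x1.  The
#' channel-similarity map `softmax(Q K' / sqrt(C_c))` is row-stochastic of
#' size `(C_c, C_c)` per pseudo-depth slice; rows belonging to stage i's
#' channel block are exactly the per-stage map for query `T_i`.
#'
#' @param tok [token_set] (tokens may be plain arrays or tensors).
#' @param cfg [glcsa_config].
#' @param params optional parameter list (`ln`, `q`, `k`, `v`, `out`);
#'   identity by default.
#' @return list with `Ygc` (`(b, C_c, C_c)` for one head, otherwise
#'   `(b, heads, C_c, C_c)`) and `context` (refined tokens `(b, C_c, P)`).
#' @export
global_channel_attention <- function(tok, cfg = glcsa_config(), params = NULL) {
  plain <- !any(vapply(tok$tokens, is_tensor, logical(1)))
  r <- gca_forward(lapply(tok$tokens, as_ag), cfg, params)
  if (plain) list(Ygc = r$Ygc$value, context = r$context$value) else r
}

gca_forward <- function(toks, cfg, params = NULL) {
  tc <- ln_concat_tokens(toks, params$ln)
  d <- dims_of(tc$value) # (b, C_c, P)
  C_c <- d[2L]; P <- d[3L]; H <- cfg$glca_heads
  if (P %% H != 0L) stop("glca_heads must divide the token count P")
  dq <- P %/% H
  q <- dw_project(tc, params$q %||% dw_identity(C_c), 2L)
  k <- dw_project(tc, params$k %||% dw_identity(C_c), 2L)
  v <- dw_project(tc, params$v %||% dw_identity(C_c), 2L)
  # per head: logits (C_c x C_c) from the head's block of token positions
  maps <- vector("list", H)
  outs <- vector("list", H)
  for (h in seq_len(H)) {
    cols <- (h - 1L) * dq + seq_len(dq)
    qh <- ag_slice(q, 3L, cols)
    kh <- ag_slice(k, 3L, cols)
    logits <- ag_scale(ag_bmm(qh, ag_permute(kh, c(1L, 3L, 2L))), 1 / sqrt(C_c))
    A <- ag_softmax(logits, 3L)
    maps[[h]] <- A
    outs[[h]] <- ag_bmm(A, ag_slice(v, 3L, cols))
  }
  ctx <- if (H == 1L) outs[[1L]] else ag_concat(outs, 3L)
  ctx <- dw_project(ctx, params$out %||% dw_identity(C_c), 2L)
  Ygc <- if (H == 1L) maps[[1L]] else {
    ag_concat(lapply(maps, function(m) ag_reshape(m, c(d[1L], 1L, C_c, C_c))), 2L)
  }
  list(Ygc = Ygc, context = ctx)
}

# ---- global spatial attention ----------------------------------------------

#' Global spatial attention over a token set
#'
#' The normalized tokens concatenated along channels provide queries and
#' keys; each stage's tokens are the values.  Multi-head (default 4) scaled
#' dot-product attention over token positions with
#' `d_k = C_c / heads`; the `(P, P)` maps are row-stochastic per head.
#'
#' @inheritParams global_channel_attention
#' @return list with `Ygs` (`(b, P, P)` for one head, otherwise
#'   `(b, heads, P, P)`) and `context` `(b, C_c, P)`.
#' @export
global_spatial_attention <- function(tok, cfg = glcsa_config(), params = NULL) {
  plain <- !any(vapply(tok$tokens, is_tensor, logical(1)))
  r <- gsa_forward(lapply(tok$tokens, as_ag), cfg, params)
  if (plain) list(Ygs = r$Ygs$value, context = r$context$value) else r
}

gsa_forward <- function(toks, cfg, params = NULL) {
  tc <- ln_concat_tokens(toks, params$ln)
  d <- dims_of(tc$value)
  C_c <- d[2L]; P <- d[3L]; H <- cfg$glsa_heads
  if (C_c %% H != 0L) stop("glsa_heads must divide the concatenated channel ",
                           "count C_c = ", C_c)
  dk <- C_c %/% H
  q <- dw_project(tc, params$q %||% dw_identity(C_c), 2L)
  k <- dw_project(tc, params$k %||% dw_identity(C_c), 2L)
  v <- dw_project(tc, params$v %||% dw_identity(C_c), 2L)
  maps <- vector("list", H)
  outs <- vector("list", H)
  for (h in seq_len(H)) {
    ch <- (h - 1L) * dk + seq_len(dk)
    qh <- ag_permute(ag_slice(q, 2L, ch), c(1L, 3L, 2L)) # (b, P, dk)
    kh <- ag_permute(ag_slice(k, 2L, ch), c(1L, 3L, 2L))
    logits <- ag_scale(ag_bmm(qh, ag_permute(kh, c(1L, 3L, 2L))), 1 / sqrt(dk))
    A <- ag_softmax(logits, 3L) # (b, P, P)
    maps[[h]] <- A
    # positions mix: out[, c, p] = sum_q A[p, q] v[, c, q]
    outs[[h]] <- ag_bmm(ag_slice(v, 2L, ch), ag_permute(A, c(1L, 3L, 2L)))
  }
  ctx <- if (H == 1L) outs[[1L]] else ag_concat(outs, 2L)
  ctx <- dw_project(ctx, params$out %||% dw_identity(C_c), 2L)
  Ygs <- if (H == 1L) maps[[1L]] else {
    ag_concat(lapply(maps, function(m) ag_reshape(m, c(d[1L], 1L, P, P))), 2L)
  }
  list(Ygs = Ygs, context = ctx)
}

# ---- local channel attention ------------------------------------------------

#' Local channel attention (efficient-channel-attention style gating)
#'
#' Spatial average pooling to a `(b, c, 1, 1)` descriptor, a shared k-tap
#' depthwise 1-d convolution along channels (circular padding), and a sigmoid
#' produce the gate `Ylc`; the gated feature is `F_c_l = F * Ylc + F`.  With
#' `lca_window = "grid"` the map is split into non-overlapping windows that
#' are pooled and gated independently.
#'
#' @param F feature array/tensor `(b, c, h, w)`.
#' @param cfg [glcsa_config] (uses `lca_kernel`, `lca_window`, `Ps`).
#' @param params optional list with `w` (k taps) and `b` (scalar bias);
#'   default puts a unit tap at the center.
#' @return list with `Ylc` `(b, c, 1, 1)` and `F_c_l` `(b, c, h, w)`.
#' @export
local_channel_attention <- function(F, cfg = glcsa_config(), params = NULL) {
  plain <- !is_tensor(F)
  r <- lca_forward(as_ag(F), cfg, params)
  if (plain) list(Ylc = r$Ylc$value, F_c_l = r$F_c_l$value) else r
}

lca_forward <- function(F, cfg, params = NULL) {
  if (cfg$lca_kernel %% 2L == 0L) stop("lca_kernel must be odd")
  pp <- params %||% lca_identity(cfg$lca_kernel)
  d <- dims_of(F$value)
  windows <- if (cfg$lca_window == "grid") {
    side <- max(1L, d[3L] %/% cfg$Ps)
    list(h = side, w = side)
  } else {
    list(h = d[3L], w = d[4L])
  }
  if (windows$h == d[3L] && windows$w == d[4L]) {
    pooled <- ag_reshape(ag_avgpool_full(F), c(d[1L], d[2L]))
    gate <- ag_sigmoid(ag_conv1d_channels(pooled, pp$w, pp$b))
    Ylc <- ag_reshape(gate, c(d[1L], d[2L], 1L, 1L))
    F_c_l <- ag_add(ag_mul(F, Ylc), F)
    return(list(Ylc = Ylc, F_c_l = F_c_l))
  }
  # grid mode: gate each window independently; Ylc reported for the whole map
  kh <- d[3L] %/% windows$h
  gated <- vector("list", 0L)
  pooled_all <- ag_reshape(ag_avgpool_full(F), c(d[1L], d[2L]))
  Ylc <- ag_reshape(ag_sigmoid(ag_conv1d_channels(pooled_all, pp$w, pp$b)),
                    c(d[1L], d[2L], 1L, 1L))
  pieces_h <- vector("list", kh)
  for (ih in seq_len(kh)) {
    rows <- (ih - 1L) * windows$h + seq_len(windows$h)
    strip <- ag_slice(F, 3L, rows)
    kw <- d[4L] %/% windows$w
    pieces_w <- vector("list", kw)
    for (iw in seq_len(kw)) {
      cols <- (iw - 1L) * windows$w + seq_len(windows$w)
      win <- ag_slice(strip, 4L, cols)
      pw <- ag_reshape(ag_avgpool_full(win), c(d[1L], d[2L]))
      gw <- ag_reshape(ag_sigmoid(ag_conv1d_channels(pw, pp$w, pp$b)),
                       c(d[1L], d[2L], 1L, 1L))
      pieces_w[[iw]] <- ag_add(ag_mul(win, gw), win)
    }
    pieces_h[[ih]] <- if (kw == 1L) pieces_w[[1L]] else ag_concat(pieces_w, 4L)
  }
  F_c_l <- if (kh == 1L) pieces_h[[1L]] else ag_concat(pieces_h, 3L)
  list(Ylc = Ylc, F_c_l = F_c_l)
}

ag_avgpool_full <- function(x) {
  d <- dims_of(x$value)
  stopifnot(length(d) == 4L)
  if (d[3L] == d[4L]) return(ag_avgpool(x, d[3L]))
  m <- ag_reshape(x, c(d[1L], d[2L], d[3L] * d[4L], 1L))
  ag_scale(ag_reshape(ag_bmm_sum(m), c(d[1L], d[2L], 1L, 1L)), 1 / (d[3L] * d[4L]))
}

# sum over third dim of (b, c, m, 1)
ag_bmm_sum <- function(x) {
  d <- dims_of(x$value)
  v <- apply(x$value, c(1L, 2L), sum)
  ag_node(array(v, c(d[1L], d[2L])), list(x), function(g) {
    list(array(rep(as.vector(g), d[3L]), d))
  })
}

#' Weigh a channel-refined feature with a global channel map
#'
#' `Fl = Ygc (x)_c F_c_l + F_c_l`: per slice, channel `i` of the output mixes
#' all channels of `F_c_l` with row `i` of the square row-map `Ygc`, plus the
#' residual.  `Ygc = 0` returns `F_c_l`; identity mixing doubles it.
#'
#' @param F_c_l array/tensor `(b, c, h, w)`.
#' @param Ygc array/tensor `(b, c, c)`.
#' @return `Fl`, same shape as `F_c_l`.
#' @export
combine_glca <- function(F_c_l, Ygc) {
  plain <- !is_tensor(F_c_l)
  r <- combine_glca_ag(as_ag(F_c_l), as_ag(Ygc))
  if (plain) r$value else r
}

combine_glca_ag <- function(F_c_l, Ygc) {
  d <- dims_of(F_c_l$value)
  dy <- dims_of(Ygc$value)
  if (length(dy) != 3L || dy[1L] != d[1L] || dy[2L] != d[2L] || dy[3L] != d[2L]) {
    stop("Ygc must have shape (b, c, c) matching the feature channels")
  }
  flat <- ag_reshape(F_c_l, c(d[1L], d[2L], d[3L] * d[4L]))
  mixed <- ag_bmm(Ygc, flat)
  ag_add(ag_reshape(mixed, d), F_c_l)
}

# ---- local spatial attention ------------------------------------------------

lsa_param_new <- function(c_in) {
  cp <- max(1L, c_in %/% 4L)
  list(reduce = conv_param(cp, c_in, 1L, 1L),
       d3 = conv_param(cp, 1L, 3L, 3L), # depthwise: groups = cp
       d5 = conv_param(cp, 1L, 5L, 5L),
       d7 = conv_param(cp, 1L, 7L, 7L),
       final = conv_param(1L, 4L * cp, 1L, 1L))
}

lsa_zero_params <- function(c_in) {
  p <- lsa_param_new(c_in)
  for (nm in names(p)) {
    p[[nm]]$w <- ag_tensor(array(0, dims_of(p[[nm]]$w$value)))
    p[[nm]]$b <- ag_tensor(array(0, dims_of(p[[nm]]$b$value)))
  }
  p
}

#' Local spatial attention (inception-style dilated gating)
#'
#' A 1x1 convolution reduces channels to `c' = max(1, c/4)`; three depthwise
#' dilated branches (3x3/d1, 5x5/d2, 7x7/d3, "same" padding) plus the 1x1
#' branch concatenate to `(b, 4c', h, w)`; a final 1x1 convolution and a
#' sigmoid give the `(b, 1, h, w)` gate `Yls`.  The gated feature is
#' `F_s_l = F * Yls` (no residual, unless `cfg$lsa_residual`).
#'
#' @param F array/tensor `(b, c, h, w)`.
#' @param cfg [glcsa_config].
#' @param params optional convolution parameters (see `lsa_param_new`);
#'   zero-initialized weights give the closed form `Yls = 0.5`.
#' @return list with `Yls` `(b, 1, h, w)` and `F_s_l` `(b, c, h, w)`.
#' @export
local_spatial_attention <- function(F, cfg = glcsa_config(), params = NULL) {
  plain <- !is_tensor(F)
  r <- lsa_forward(as_ag(F), cfg, params)
  if (plain) list(Yls = r$Yls$value, F_s_l = r$F_s_l$value) else r
}

lsa_forward <- function(F, cfg, params = NULL) {
  d <- dims_of(F$value)
  pp <- params %||% lsa_zero_params(d[2L])
  cp <- dims_of(pp$reduce$w$value)[1L]
  red <- ag_conv2d(F, pp$reduce$w, pp$reduce$b)
  b3 <- ag_conv2d(red, pp$d3$w, pp$d3$b, pad = 1L, dilation = 1L, groups = cp)
  b5 <- ag_conv2d(red, pp$d5$w, pp$d5$b, pad = 4L, dilation = 2L, groups = cp)
  b7 <- ag_conv2d(red, pp$d7$w, pp$d7$b, pad = 9L, dilation = 3L, groups = cp)
  cat4 <- ag_concat(list(red, b3, b5, b7), 2L)
  Yls <- ag_sigmoid(ag_conv2d(cat4, pp$final$w, pp$final$b))
  F_s_l <- ag_mul(F, Yls)
  if (cfg$lsa_residual) F_s_l <- ag_add(F_s_l, F)
  list(Yls = Yls, F_s_l = F_s_l)
}

#' Weigh a spatially gated feature with a global spatial map
#'
#' `Fg = F_s_l (x)_p Ygs + F_s_l`: flattened spatial positions mix through
#' the row-stochastic `(P, P)` map (per head when `Ygs` carries a head axis,
#' each head mixing its channel block), plus the residual.
#'
#' @param F_s_l array/tensor `(b, c, h, w)` with `h * w = P`.
#' @param Ygs array/tensor `(b, P, P)` or `(b, heads, P, P)`.
#' @return `Fg`, same shape as `F_s_l`.
#' @export
combine_glsa <- function(F_s_l, Ygs) {
  plain <- !is_tensor(F_s_l)
  r <- combine_glsa_ag(as_ag(F_s_l), as_ag(Ygs))
  if (plain) r$value else r
}

combine_glsa_ag <- function(F_s_l, Ygs) {
  d <- dims_of(F_s_l$value)
  P <- d[3L] * d[4L]
  dy <- dims_of(Ygs$value)
  flat <- ag_reshape(F_s_l, c(d[1L], d[2L], P))
  if (length(dy) == 3L) {
    if (dy[2L] != P || dy[3L] != P) stop("Ygs must be (b, P, P) with P = h*w")
    mixed <- ag_bmm(flat, ag_permute(Ygs, c(1L, 3L, 2L)))
  } else if (length(dy) == 4L) {
    Hh <- dy[2L]
    if (d[2L] %% Hh != 0L) stop("head count must divide the channels")
    dk <- d[2L] %/% Hh
    parts <- vector("list", Hh)
    for (h in seq_len(Hh)) {
      ch <- (h - 1L) * dk + seq_len(dk)
      Ah <- ag_reshape(ag_slice(Ygs, 2L, h), c(dy[1L], P, P))
      parts[[h]] <- ag_bmm(ag_slice(flat, 2L, ch), ag_permute(Ah, c(1L, 3L, 2L)))
    }
    mixed <- if (Hh == 1L) parts[[1L]] else ag_concat(parts, 2L)
  } else stop("Ygs must be (b, P, P) or (b, heads, P, P)")
  ag_add(ag_reshape(mixed, d), F_s_l)
}

# ---- slice interaction module ----------------------------------------------

sim_param_new <- function(c) {
  list(q = dw_param(c), k = dw_param(c), v = dw_param(c), out = dw_param(c))
}

#' Slice interaction module (pseudo-3D cross-slice attention)
#'
#' The batch axis is repurposed as depth: at every spatial position,
#' multi-head dot-product attention runs across the `b` slices of the stack
#' (queries/keys/values from per-channel linear projections; no positional
#' encoding, so the module is permutation-equivariant along `b`).  In
#' `"la2"` mode each slice is treated as pseudo-depth 1 and the module
#' degenerates to the per-slice value/output projection.
#'
#' @param F array/tensor `(b, c, h, w)`.
#' @param cfg [glcsa_config] (`glsa_heads` heads; must divide `c`).
#' @param params optional projection parameters; identity by default.
#' @return refined feature, same shape as `F`.
#' @export
slice_interaction <- function(F, cfg = glcsa_config(), params = NULL) {
  plain <- !is_tensor(F)
  r <- sim_forward(as_ag(F), cfg, params)
  if (plain) r$value else r
}

sim_forward <- function(F, cfg, params = NULL) {
  d <- dims_of(F$value)
  b <- d[1L]; c <- d[2L]; P <- d[3L] * d[4L]
  H <- cfg$glsa_heads
  if (c %% H != 0L) stop("SIM head count must divide the channels")
  dk <- c %/% H
  pp <- params %||% list(q = dw_identity(c), k = dw_identity(c),
                         v = dw_identity(c), out = dw_identity(c))
  q <- dw_project(F, pp$q, 2L); k <- dw_project(F, pp$k, 2L)
  v <- dw_project(F, pp$v, 2L)
  if (cfg$local_mode == "la2" || b == 1L) {
    # pseudo-depth 1: softmax over a single slice is identically 1
    return(dw_project(v, pp$out, 2L))
  }
  # (b, c, hw) -> (hw, b, c): attention across b at every position
  to_pbc <- function(t) ag_permute(ag_reshape(t, c(b, c, P)), c(3L, 1L, 2L))
  qp <- to_pbc(q); kp <- to_pbc(k); vp <- to_pbc(v)
  parts <- vector("list", H)
  for (h in seq_len(H)) {
    ch <- (h - 1L) * dk + seq_len(dk)
    qh <- ag_slice(qp, 3L, ch) # (P, b, dk)
    kh <- ag_slice(kp, 3L, ch)
    A <- ag_softmax(ag_scale(ag_bmm(qh, ag_permute(kh, c(1L, 3L, 2L))),
                             1 / sqrt(dk)), 3L) # (P, b, b)
    parts[[h]] <- ag_bmm(A, ag_slice(vp, 3L, ch))
  }
  op <- if (H == 1L) parts[[1L]] else ag_concat(parts, 3L)
  out <- ag_reshape(ag_permute(op, c(2L, 3L, 1L)), d)
  dw_project(out, pp$out, 2L)
}

# ---- fusion -----------------------------------------------------------------

#' Softmax-normalized fusion weights
#' @param raw 3 learnable reals (order: local, global, original).
#' @return list with `raw` and `normalized` `(wlo, wgo, wt)` on the simplex.
#' @export
fusion_weights <- function(raw = c(0, 0, 0)) {
  rv <- if (is_tensor(raw)) as.vector(raw$value) else as.vector(raw)
  e <- exp(rv - max(rv))
  list(raw = rv, normalized = e / sum(e))
}

#' Fuse local, global and original feature maps
#'
#' `Fgl = wlo*Fl + wgo*Fg + wt*F` with `(wlo, wgo, wt)` the softmax of three
#' learnable parameters, so the output is a convex combination.
#'
#' @param Fl,Fg,F arrays/tensors of identical shape.
#' @param w raw weights (length 3) or a `fusion_weights()` result.
#' @return fused map, same shape as the inputs.
#' @export
fuse_maps <- function(Fl, Fg, F, w = c(0, 0, 0)) {
  plain <- !is_tensor(Fl)
  raw <- if (is.list(w)) w$raw else w
  r <- fuse_maps_ag(as_ag(Fl), as_ag(Fg), as_ag(F), as_ag(raw))
  if (plain) r$value else r
}

fuse_maps_ag <- function(Fl, Fg, F, raw) {
  stopifnot(identical(dims_of(Fl$value), dims_of(F$value)),
            identical(dims_of(Fg$value), dims_of(F$value)))
  w <- ag_softmax(ag_reshape(raw, c(1L, 3L)), 2L)
  shp <- rep(1L, length(dims_of(F$value)))
  pick <- function(i) ag_reshape(ag_slice(w, 2L, i), shp)
  ag_add(ag_add(ag_mul(Fl, pick(1L)), ag_mul(Fg, pick(2L))),
         ag_mul(F, pick(3L)))
}

# ---- assembled block --------------------------------------------------------

#' Create parameters for a GLCSA block
#'
#' @param stage_channels channel counts `C_1..C_n` of the skip stages.
#' @param cfg [glcsa_config].
#' @return nested parameter list (all `ag_tensor`s with gradients enabled).
#' @export
glcsa_block_new <- function(stage_channels, cfg = glcsa_config()) {
  n <- length(stage_channels)
  C_c <- sum(stage_channels)
  dw_p <- function(c) list(w = new_param(kaiming_uniform(c, 1L)),
                           b = new_param(array(0, c)))
  ln_p <- function(c) list(gamma = new_param(array(1, c)),
                           beta = new_param(array(0, c)))
  sim_p <- function() list(q = dw_p(C_c), k = dw_p(C_c), v = dw_p(C_c),
                           out = dw_p(C_c))
  lsa_p <- lsa_param_new(C_c)
  list(
    stage_channels = as.integer(stage_channels),
    embed = lapply(stage_channels, dw_p),
    ln_c = lapply(stage_channels, ln_p),
    ln_s = lapply(stage_channels, ln_p),
    gca = list(q = dw_p(C_c), k = dw_p(C_c), v = dw_p(C_c), out = dw_p(C_c)),
    gsa = list(q = dw_p(C_c), k = dw_p(C_c), v = dw_p(C_c), out = dw_p(C_c)),
    lca = list(w = new_param(kaiming_uniform(cfg$lca_kernel, cfg$lca_kernel)),
               b = new_param(array(0, 1L))),
    lsa = lsa_p,
    sim_c = sim_p(),
    sim_s = sim_p(),
    fusion_raw = new_param(array(0, 3L)),
    final_ln = ln_p(C_c),
    up = lapply(stage_channels, function(c) conv_param(c, c, 1L, 1L))
  )
}

split_stages <- function(F, stage_channels) {
  off <- 0L
  lapply(stage_channels, function(c_i) {
    s <- ag_slice(F, 2L, off + seq_len(c_i))
    off <<- off + c_i
    s
  })
}

# channel path: GCA -> LCA gate -> channel mixing -> SIM
glca_path <- function(F, pb, cfg) {
  d <- dims_of(F$value)
  toks <- split_stages(ag_reshape(F, c(d[1L], d[2L], d[3L] * d[4L])),
                       pb$stage_channels)
  g <- gca_forward(toks, cfg, list(ln = pb$ln_c, q = pb$gca$q, k = pb$gca$k,
                                   v = pb$gca$v, out = pb$gca$out))
  ctx <- ag_reshape(g$context, d)
  l <- lca_forward(ctx, cfg, pb$lca)
  Ygc <- if (cfg$glca_heads == 1L) g$Ygc else ag_mean_heads(g$Ygc)
  out <- combine_glca_ag(l$F_c_l, Ygc)
  if (cfg$sim_enabled) out <- sim_forward(out, cfg, pb$sim_c)
  out
}

# spatial path: GSA -> LSA gate -> position mixing -> SIM
glsa_path <- function(F, pb, cfg) {
  d <- dims_of(F$value)
  toks <- split_stages(ag_reshape(F, c(d[1L], d[2L], d[3L] * d[4L])),
                       pb$stage_channels)
  g <- gsa_forward(toks, cfg, list(ln = pb$ln_s, q = pb$gsa$q, k = pb$gsa$k,
                                   v = pb$gsa$v, out = pb$gsa$out))
  ctx <- ag_reshape(g$context, d)
  l <- lsa_forward(ctx, cfg, pb$lsa)
  out <- combine_glsa_ag(l$F_s_l, g$Ygs)
  if (cfg$sim_enabled) out <- sim_forward(out, cfg, pb$sim_s)
  out
}

ag_mean_heads <- function(Y) {
  d <- dims_of(Y$value)
  acc <- ag_reshape(ag_slice(Y, 2L, 1L), d[-2L])
  if (d[2L] > 1L) {
    for (h in 2:d[2L]) acc <- ag_add(acc, ag_reshape(ag_slice(Y, 2L, h), d[-2L]))
  }
  ag_scale(acc, 1 / d[2L])
}

#' Forward pass of the assembled GLCSA block
#'
#' Embedding, the configured channel/spatial attention paths with slice
#' interaction, weighted fusion with the original tokens, layer
#' normalization, GeLU, and per-stage upsampling back to each skip's
#' resolution.
#'
#' @param encoder_feats list over stages of arrays/tensors
#'   `(b, C_i, H/2^(i-1), W/2^(i-1))`.
#' @param cfg [glcsa_config].
#' @param params block parameters from [glcsa_block_new()]; identity-like
#'   defaults when `NULL`.
#' @return list of refined features, one per stage, with the input shapes.
#' @export
glcsa_block_forward <- function(encoder_feats, cfg = glcsa_config(),
                                params = NULL) {
  plain <- !any(vapply(encoder_feats, is_tensor, logical(1)))
  feats <- lapply(encoder_feats, as_ag)
  stage_channels <- vapply(feats, function(f) dims_of(f$value)[2L], numeric(1))
  C_c <- sum(stage_channels)
  if (cfg$enable_glsa && C_c %% cfg$glsa_heads != 0L) {
    stop("config error: glsa_heads (", cfg$glsa_heads,
         ") must divide C_c = ", C_c)
  }
  pb <- params %||% glcsa_block_identity(stage_channels, cfg)
  toks <- embed_multiscale_ag(feats, cfg, pb$embed)
  b <- dims_of(feats[[1L]]$value)[1L]
  grid <- toks$grid
  F0 <- ag_reshape(if (toks$n == 1L) toks$tokens[[1L]] else
    ag_concat(toks$tokens, 2L), c(b, C_c, grid, grid))

  paths <- list()
  if (cfg$enable_glca && cfg$enable_glsa) {
    first_c <- cfg$attention_order == "glca_first"
    if (cfg$module_fusion == "sequential") {
      if (first_c) {
        Fl <- glca_path(F0, pb, cfg)
        Fg <- glsa_path(Fl, pb, cfg)
      } else {
        Fg <- glsa_path(F0, pb, cfg)
        Fl <- glca_path(Fg, pb, cfg)
      }
      paths <- list(Fl = Fl, Fg = Fg)
    } else if (cfg$module_fusion == "parallel") {
      paths <- list(Fl = glca_path(F0, pb, cfg), Fg = glsa_path(F0, pb, cfg))
    } else { # sum
      s <- ag_add(glca_path(F0, pb, cfg), glsa_path(F0, pb, cfg))
      paths <- list(Fl = s, Fg = s)
    }
  } else if (cfg$enable_glca) {
    paths <- list(Fl = glca_path(F0, pb, cfg))
  } else if (cfg$enable_glsa) {
    paths <- list(Fg = glsa_path(F0, pb, cfg))
  }

  Fgl <- if (length(paths) == 2L) {
    fuse_maps_ag(paths$Fl, paths$Fg, F0, pb$fusion_raw)
  } else if (length(paths) == 1L) {
    raw_idx <- if (!is.null(paths$Fl)) c(1L, 3L) else c(2L, 3L)
    w <- ag_softmax(ag_reshape(ag_slice(pb$fusion_raw, 1L, raw_idx),
                               c(1L, 2L)), 2L)
    shp <- c(1L, 1L, 1L, 1L)
    ag_add(ag_mul(paths[[1L]], ag_reshape(ag_slice(w, 2L, 1L), shp)),
           ag_mul(F0, ag_reshape(ag_slice(w, 2L, 2L), shp)))
  } else {
    F0
  }

  z <- ag_gelu(ag_layernorm(Fgl, pb$final_ln$gamma, pb$final_ln$beta, 2L))
  outs <- split_stages(z, pb$stage_channels)
  res <- lapply(seq_along(outs), function(i) {
    di <- dims_of(feats[[i]]$value)
    u <- ag_resize_bilinear(outs[[i]], di[3L], di[4L])
    ag_conv2d(u, pb$up[[i]]$w, pb$up[[i]]$b)
  })
  if (plain) lapply(res, function(t) t$value) else res
}

# identity-like parameter set (no randomness): depthwise projections are
# unit scale / zero bias, LCA is a center tap, LSA weights zero (gate 0.5),
# fusion raws zero, upsample projections identity.
glcsa_block_identity <- function(stage_channels, cfg) {
  n <- length(stage_channels)
  C_c <- sum(stage_channels)
  eye_conv <- function(c) {
    w <- array(0, c(c, c, 1L, 1L))
    for (i in seq_len(c)) w[i, i, 1L, 1L] <- 1
    list(w = ag_tensor(w), b = ag_tensor(array(0, c)))
  }
  list(stage_channels = as.integer(stage_channels),
       embed = lapply(stage_channels, dw_identity),
       ln_c = lapply(stage_channels, ln_identity),
       ln_s = lapply(stage_channels, ln_identity),
       gca = list(q = dw_identity(C_c), k = dw_identity(C_c),
                  v = dw_identity(C_c), out = dw_identity(C_c)),
       gsa = list(q = dw_identity(C_c), k = dw_identity(C_c),
                  v = dw_identity(C_c), out = dw_identity(C_c)),
       lca = lca_identity(cfg$lca_kernel),
       lsa = lsa_zero_params(C_c),
       sim_c = list(q = dw_identity(C_c), k = dw_identity(C_c),
                    v = dw_identity(C_c), out = dw_identity(C_c)),
       sim_s = list(q = dw_identity(C_c), k = dw_identity(C_c),
                    v = dw_identity(C_c), out = dw_identity(C_c)),
       fusion_raw = ag_tensor(array(0, 3L)),
       final_ln = ln_identity(C_c),
       up = lapply(stage_channels, eye_conv))
}
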