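# Reverse-mode automatic differentiation over base R arrays.
#
# A tensor is an environment holding a numeric array (`value`), an optional
# accumulated gradient (`grad`), and - when it participates in a tracked
# computation - its parents plus a backward closure mapping the output
# gradient to per-parent gradients.  The graph is taped implicitly through
# parent links; `ag_backward()` topologically sorts it and runs the chain
# rule once.  Heavy spatial primitives (convolution, pooling, resizing) call
# the compiled kernels in src/.

.ag <- new.env(parent = emptyenv())
.ag$id <- 0L

`%||%` <- function(a, b) if (is.null(a)) b else a

dims_of <- function(x) dim(x) %||% length(x)

#' Create an autograd tensor
#'
#' Wraps a numeric array in a node of the automatic-differentiation graph.
#' Tensors with `requires_grad = TRUE` act as trainable parameters: after
#' [ag_backward()] their `grad` field holds d(output)/d(tensor).
#'
#' @param value numeric array (any dimensionality) or scalar.
#' @param requires_grad logical; track gradients into this tensor.
#' @return an object of class `ag_tensor`.
#' @export
ag_tensor <- function(value, requires_grad = FALSE) {
  e <- new.env(parent = emptyenv())
  if (is.null(dim(value))) value <- array(as.double(value), length(value))
  e$value <- value
  e$grad <- NULL
  e$requires_grad <- requires_grad
  e$track <- requires_grad
  e$parents <- NULL
  e$bwd <- NULL
  .ag$id <- .ag$id + 1L
  e$id <- .ag$id
  class(e) <- "ag_tensor"
  e
}

#' @export
print.ag_tensor <- function(x, ...) {
  cat("<ag_tensor dim=[", paste(dims_of(x$value), collapse = ","),
      "] requires_grad=", x$requires_grad, ">\n", sep = "")
  invisible(x)
}

is_tensor <- function(x) inherits(x, "ag_tensor")
ag_wrap <- function(x) if (is_tensor(x)) x else ag_tensor(x)

# Internal node constructor: drops the tape when no parent is tracked, so
# inference-only forward passes carry no graph.
ag_node <- function(value, parents, bwd) {
  t <- ag_tensor(value)
  if (any(vapply(parents, function(p) p$track, logical(1)))) {
    t$track <- TRUE
    t$parents <- parents
    t$bwd <- bwd
  }
  t
}

accumulate_grad <- function(p, g) {
  if (is.null(g) || !p$track) return(invisible(NULL))
  if (is.null(dim(g))) dim(g) <- dims_of(p$value)
  p$grad <- if (is.null(p$grad)) g else p$grad + g
  invisible(NULL)
}

#' Run backpropagation from a tensor
#'
#' @param t output tensor (typically a scalar loss).
#' @param grad seed gradient; defaults to an array of ones shaped like `t`.
#' @export
ag_backward <- function(t, grad = NULL) {
  stopifnot(is_tensor(t))
  if (is.null(grad)) grad <- array(1, dim = dims_of(t$value))
  # iterative post-order DFS over parent links
  topo <- vector("list", 256L)
  ntopo <- 0L
  seen <- new.env(parent = emptyenv())
  stack <- list(list(node = t, i = 0L))
  assign(as.character(t$id), TRUE, envir = seen)
  while (length(stack) > 0L) {
    fr <- stack[[length(stack)]]
    node <- fr$node
    kids <- node$parents
    if (fr$i < length(kids)) {
      stack[[length(stack)]]$i <- fr$i + 1L
      child <- kids[[fr$i + 1L]]
      key <- as.character(child$id)
      if (child$track && !exists(key, envir = seen, inherits = FALSE)) {
        assign(key, TRUE, envir = seen)
        stack[[length(stack) + 1L]] <- list(node = child, i = 0L)
      }
    } else {
      ntopo <- ntopo + 1L
      if (ntopo > length(topo)) topo <- c(topo, vector("list", length(topo)))
      topo[[ntopo]] <- node
      stack[[length(stack)]] <- NULL
    }
  }
  accumulate_grad(t, grad)
  for (i in rev(seq_len(ntopo))) {
    node <- topo[[i]]
    if (is.null(node$bwd)) next
    g <- node$grad
    if (is.null(g)) next
    pgrads <- node$bwd(g)
    for (j in seq_along(node$parents)) accumulate_grad(node$parents[[j]], pgrads[[j]])
    if (!node$requires_grad) node$grad <- NULL # free intermediate grads
  }
  invisible(t)
}

#' Clear gradients on a list of parameter tensors
#' @param params list of `ag_tensor`s.
#' @export
ag_zero_grad <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

# ---- broadcasting helpers ---------------------------------------------------

bc_expand <- function(x, td) {
  d <- as.integer(dims_of(x))
  td <- as.integer(td)
  if (identical(d, td)) return(x)
  if (length(x) == 1L) return(array(as.vector(x), td))
  stopifnot(length(d) == length(td))
  exp_dims <- which(d == 1L & td > 1L)
  keep <- setdiff(seq_along(td), exp_dims)
  v <- as.vector(x)
  if (length(exp_dims) > 0L && min(exp_dims) > max(c(0L, keep))) {
    # all expanded dims trail the kept ones: replicate the whole vector
    return(array(rep(v, prod(td[exp_dims])), td))
  }
  if (length(exp_dims) == 1L) {
    e <- exp_dims
    pre <- prod(td[seq_len(e - 1L)])
    m <- matrix(v, pre)
    return(array(m[rep(seq_len(pre), td[e]), , drop = FALSE], td))
  }
  idx <- lapply(seq_along(td), function(i) {
    if (d[i] == td[i]) seq_len(td[i]) else rep(1L, td[i])
  })
  do.call(`[`, c(list(array(x, d)), idx, list(drop = FALSE)))
}

bc_reduce <- function(g, d0) {
  d0 <- as.integer(d0)
  dg <- as.integer(dims_of(g))
  if (identical(dg, d0)) return(g)
  if (prod(d0) == 1L) return(array(sum(g), d0))
  red <- which(d0 == 1L & dg > 1L)
  keep <- setdiff(seq_along(d0), red)
  v <- as.vector(g)
  if (min(red) > max(keep)) {
    return(array(rowSums(matrix(v, prod(dg[keep]))), d0))
  }
  if (length(red) == 1L) {
    e <- red
    pre <- prod(dg[seq_len(e - 1L)])
    post <- prod(dg[seq_along(dg) > e])
    a <- aperm(array(v, c(pre, dg[e], post)), c(1L, 3L, 2L))
    return(array(rowSums(matrix(a, pre * post)), d0))
  }
  array(apply(g, keep, sum), d0)
}

bc_out_dim <- function(dx, dy) {
  if (length(dx) == 1L && prod(dx) == 1L) return(dy)
  if (length(dy) == 1L && prod(dy) == 1L) return(dx)
  stopifnot(length(dx) == length(dy))
  ok <- dx == dy | dx == 1L | dy == 1L
  if (!all(ok)) stop("non-broadcastable shapes: [", paste(dx, collapse = ","),
                     "] vs [", paste(dy, collapse = ","), "]")
  pmax(dx, dy)
}

# ---- elementwise ops --------------------------------------------------------

#' @rdname ag_ops
#' @export
ag_add <- function(x, y) {
  x <- ag_wrap(x); y <- ag_wrap(y)
  td <- bc_out_dim(dims_of(x$value), dims_of(y$value))
  v <- bc_expand(x$value, td) + bc_expand(y$value, td)
  ag_node(v, list(x, y), function(g) {
    list(bc_reduce(g, dims_of(x$value)), bc_reduce(g, dims_of(y$value)))
  })
}

#' @rdname ag_ops
#' @export
ag_sub <- function(x, y) ag_add(x, ag_scale(y, -1))

#' Elementwise tensor arithmetic with broadcasting
#'
#' `ag_add`, `ag_sub` and `ag_mul` broadcast singleton dimensions the way
#' array frameworks do; `ag_scale` multiplies by a fixed scalar.
#'
#' @param x,y tensors or numeric arrays.
#' @param s plain numeric scalar (not differentiated through).
#' @name ag_ops
#' @export
ag_mul <- function(x, y) {
  x <- ag_wrap(x); y <- ag_wrap(y)
  td <- bc_out_dim(dims_of(x$value), dims_of(y$value))
  xv <- bc_expand(x$value, td); yv <- bc_expand(y$value, td)
  ag_node(xv * yv, list(x, y), function(g) {
    list(bc_reduce(g * yv, dims_of(x$value)),
         bc_reduce(g * xv, dims_of(y$value)))
  })
}

#' @rdname ag_ops
#' @export
ag_scale <- function(x, s) {
  x <- ag_wrap(x)
  ag_node(x$value * s, list(x), function(g) list(g * s))
}

#' @rdname ag_ops
#' @export
ag_div <- function(x, y) {
  x <- ag_wrap(x); y <- ag_wrap(y)
  td <- bc_out_dim(dims_of(x$value), dims_of(y$value))
  xv <- bc_expand(x$value, td); yv <- bc_expand(y$value, td)
  ag_node(xv / yv, list(x, y), function(g) {
    list(bc_reduce(g / yv, dims_of(x$value)),
         bc_reduce(-g * xv / (yv * yv), dims_of(y$value)))
  })
}

#' @rdname ag_activations
#' @export
ag_sigmoid <- function(x) {
  x <- ag_wrap(x)
  v <- 1 / (1 + exp(-x$value))
  ag_node(v, list(x), function(g) list(g * v * (1 - v)))
}

#' @rdname ag_activations
#' @export
ag_relu <- function(x) {
  x <- ag_wrap(x)
  m <- x$value > 0
  ag_node(x$value * m, list(x), function(g) list(g * m))
}

#' Differentiable activations
#'
#' `ag_gelu` is the exact Gaussian-error-linear unit `x * pnorm(x)`.
#'
#' @param x tensor.
#' @name ag_activations
#' @export
ag_gelu <- function(x) {
  x <- ag_wrap(x)
  ph <- stats::pnorm(x$value)
  v <- x$value * ph
  dim(v) <- dims_of(x$value)
  ag_node(v, list(x), function(g) {
    d <- ph + x$value * stats::dnorm(x$value)
    list(g * d)
  })
}

# ---- shape ops --------------------------------------------------------------

#' @rdname ag_shape
#' @export
ag_reshape <- function(x, newdim) {
  x <- ag_wrap(x)
  d0 <- dims_of(x$value)
  v <- x$value
  dim(v) <- newdim
  ag_node(v, list(x), function(g) { dim(g) <- d0; list(g) })
}

#' @rdname ag_shape
#' @export
ag_permute <- function(x, perm) {
  x <- ag_wrap(x)
  inv <- order(perm)
  ag_node(aperm(x$value, perm), list(x), function(g) list(aperm(g, inv)))
}

#' Shape manipulation ops
#'
#' @param x tensor; `xs` a list of tensors.
#' @param newdim,perm,d,idx integer shape/permutation/index arguments.
#' @name ag_shape
#' @export
ag_concat <- function(xs, d) {
  xs <- lapply(xs, ag_wrap)
  vals <- lapply(xs, function(t) t$value)
  dms <- lapply(vals, function(v) as.integer(dims_of(v)))
  sizes <- vapply(dms, function(dd) dd[d], integer(1))
  outd <- dms[[1L]]
  outd[d] <- sum(sizes)
  pre <- prod(outd[seq_len(d - 1L)])
  post <- prod(outd[seq_along(outd) > d])
  # column-major 3-d view (pre, dim d, post): blocks along dim d are row
  # blocks of the (pre * nd, post) matrix
  out <- array(0, c(pre * outd[d], post))
  off <- 0L
  for (i in seq_along(vals)) {
    rows <- pre * off + seq_len(pre * sizes[i])
    out[rows, ] <- vals[[i]]
    off <- off + sizes[i]
  }
  dim(out) <- outd
  ag_node(out, xs, function(g) {
    dim(g) <- c(pre * outd[d], post)
    off <- 0L
    lapply(seq_along(vals), function(i) {
      rows <- pre * off + seq_len(pre * sizes[i])
      gi <- g[rows, , drop = FALSE]
      dim(gi) <- dms[[i]]
      off <<- off + sizes[i]
      gi
    })
  })
}

#' @rdname ag_shape
#' @export
ag_slice <- function(x, d, idx) {
  x <- ag_wrap(x)
  d0 <- as.integer(dims_of(x$value))
  idx <- as.integer(idx)
  pre <- prod(d0[seq_len(d - 1L)])
  post <- prod(d0[seq_along(d0) > d])
  contiguous <- length(idx) >= 1L && all(diff(idx) == 1L)
  outd <- d0
  outd[d] <- length(idx)
  if (contiguous) {
    rows <- pre * (idx[1L] - 1L) + seq_len(pre * length(idx))
    m <- x$value
    dim(m) <- c(pre * d0[d], post)
    v <- m[rows, , drop = FALSE]
    dim(v) <- outd
    ag_node(v, list(x), function(g) {
      gx <- array(0, c(pre * d0[d], post))
      dim(g) <- c(pre * length(idx), post)
      gx[rows, ] <- g
      dim(gx) <- d0
      list(gx)
    })
  } else {
    sel <- lapply(d0, seq_len)
    sel[[d]] <- idx
    v <- do.call(`[`, c(list(x$value), sel, list(drop = FALSE)))
    ag_node(v, list(x), function(g) {
      gx <- array(0, d0)
      gx <- do.call(`[<-`, c(list(gx), sel, list(value = g)))
      list(gx)
    })
  }
}

# ---- reductions -------------------------------------------------------------

#' @rdname ag_reduce
#' @export
ag_sum <- function(x) {
  x <- ag_wrap(x)
  d0 <- dims_of(x$value)
  ag_node(array(sum(x$value), 1L), list(x),
          function(g) list(array(as.vector(g), d0)))
}

#' Scalar reductions
#' @param x tensor.
#' @name ag_reduce
#' @export
ag_mean <- function(x) ag_scale(ag_sum(x), 1 / length(x$value))

# ---- linear algebra ---------------------------------------------------------

#' @rdname ag_linalg
#' @export
ag_matmul <- function(x, y) {
  x <- ag_wrap(x); y <- ag_wrap(y)
  xv <- x$value; yv <- y$value
  ag_node(xv %*% yv, list(x, y), function(g) {
    list(g %*% t(yv), t(xv) %*% g)
  })
}

#' Matrix products
#'
#' `ag_matmul` multiplies two matrices; `ag_bmm` multiplies two stacks of
#' matrices stored as 3-d arrays `(n, r, k)` sharing the leading index.
#'
#' @param x,y tensors.
#' @name ag_linalg
#' @export
ag_bmm <- function(x, y) {
  x <- ag_wrap(x); y <- ag_wrap(y)
  dx <- dims_of(x$value); dy <- dims_of(y$value)
  stopifnot(length(dx) == 3L, length(dy) == 3L, dx[1L] == dy[1L], dx[3L] == dy[2L])
  out <- cpp_bmm(x$value, y$value, FALSE, FALSE)
  ag_node(out, list(x, y), function(g) {
    if (is.null(dim(g))) dim(g) <- c(dx[1L], dx[2L], dy[3L])
    list(cpp_bmm(g, y$value, FALSE, TRUE), cpp_bmm(x$value, g, TRUE, FALSE))
  })
}

# ---- softmax / normalization ------------------------------------------------

#' Softmax along one dimension
#' @param x tensor.
#' @param d dimension index along which the values normalize to 1.
#' @export
ag_softmax <- function(x, d) {
  x <- ag_wrap(x)
  d0 <- dims_of(x$value)
  nd <- length(d0)
  perm <- c(setdiff(seq_len(nd), d), d)
  xp <- aperm(array(x$value, d0), perm)
  m <- prod(d0[-d])
  k <- d0[d]
  xm <- matrix(xp, m, k)
  xm <- xm - xm[cbind(seq_len(m), max.col(xm, ties.method = "first"))]
  e <- exp(xm)
  sm <- e / rowSums(e)
  y <- aperm(array(sm, c(d0[-d], k)), order(perm))
  ag_node(y, list(x), function(g) {
    gp <- matrix(aperm(array(g, d0), perm), m, k)
    dot <- rowSums(gp * sm)
    gx <- sm * (gp - dot)
    list(aperm(array(gx, c(d0[-d], k)), order(perm)))
  })
}

#' Layer normalization across the channel dimension
#'
#' Normalizes `x` to zero mean / unit variance along dimension `d` for every
#' other index combination, then applies a learnable per-channel affine map.
#'
#' @param x tensor.
#' @param gamma,beta parameter tensors of length `dim(x)[d]`.
#' @param d channel dimension index.
#' @param eps variance floor (default `1e-5`).
#' @export
ag_layernorm <- function(x, gamma, beta, d, eps = 1e-5) {
  x <- ag_wrap(x)
  d0 <- dims_of(x$value)
  nd <- length(d0)
  k <- d0[d]
  perm <- c(d, setdiff(seq_len(nd), d))
  xm <- matrix(aperm(array(x$value, d0), perm), k) # (k, m)
  mu <- colMeans(xm)
  xc <- sweep(xm, 2L, mu)
  v <- colMeans(xc^2)
  istd <- 1 / sqrt(v + eps)
  xhat <- sweep(xc, 2L, istd, `*`)
  gv <- as.vector(gamma$value); bv <- as.vector(beta$value)
  ym <- xhat * gv + bv
  y <- aperm(array(ym, c(k, d0[-d])), order(perm))
  ag_node(y, list(x, gamma, beta), function(g) {
    gm <- matrix(aperm(array(g, d0), perm), k)
    ggamma <- rowSums(gm * xhat)
    gbeta <- rowSums(gm)
    dxhat <- gm * gv
    t1 <- sweep(dxhat, 2L, colMeans(dxhat))
    t2 <- sweep(xhat, 2L, colMeans(dxhat * xhat), `*`)
    gxm <- sweep(t1 - t2, 2L, istd, `*`)
    gx <- aperm(array(gxm, c(k, d0[-d])), order(perm))
    list(gx, array(ggamma, dims_of(gamma$value)), array(gbeta, dims_of(beta$value)))
  })
}

# ---- spatial primitives (compiled kernels) ----------------------------------

#' 2-d convolution
#'
#' Standard cross-correlation over `(b, c, h, w)` tensors with stride,
#' zero-padding, dilation and channel groups (`groups = c` gives a depthwise
#' convolution).  Weight layout is `(c_out, c_in/groups, kh, kw)`.
#'
#' @param x input tensor `(b, c, h, w)`.
#' @param w weight tensor.
#' @param b bias tensor of length `c_out`.
#' @param stride,pad,dilation,groups integers.
#' @export
ag_conv2d <- function(x, w, b, stride = 1L, pad = 0L, dilation = 1L,
                      groups = 1L) {
  x <- ag_wrap(x); w <- ag_wrap(w); b <- ag_wrap(b)
  v <- cpp_conv2d_fwd(x$value, w$value, as.vector(b$value),
                      as.integer(stride), as.integer(pad),
                      as.integer(dilation), as.integer(groups))
  ag_node(v, list(x, w, b), function(g) {
    if (is.null(dim(g))) dim(g) <- dims_of(v)
    r <- cpp_conv2d_bwd(x$value, w$value, g, as.integer(stride),
                        as.integer(pad), as.integer(dilation),
                        as.integer(groups))
    list(r$gx, r$gw, array(r$gb, dims_of(b$value)))
  })
}

#' @rdname ag_pool
#' @export
ag_maxpool2 <- function(x) {
  x <- ag_wrap(x)
  r <- cpp_maxpool2_fwd(x$value)
  ind <- dims_of(x$value)
  ag_node(r$y, list(x), function(g) {
    if (is.null(dim(g))) dim(g) <- dims_of(r$y)
    list(cpp_maxpool2_bwd(r$idx, g, as.integer(ind)))
  })
}

#' Pooling and resampling
#'
#' `ag_maxpool2` is 2x2/stride-2 max pooling; `ag_avgpool` averages
#' non-overlapping `k` x `k` windows (kernel = stride = `k`);
#' `ag_resize_bilinear` resamples to `(ho, wo)` with half-pixel centers.
#'
#' @param x tensor `(b, c, h, w)`.
#' @param k,ho,wo integers.
#' @name ag_pool
#' @export
ag_avgpool <- function(x, k) {
  x <- ag_wrap(x)
  ind <- dims_of(x$value)
  v <- cpp_avgpool_fwd(x$value, as.integer(k))
  ag_node(v, list(x), function(g) {
    if (is.null(dim(g))) dim(g) <- dims_of(v)
    list(cpp_avgpool_bwd(g, as.integer(k), as.integer(ind)))
  })
}

#' @rdname ag_pool
#' @export
ag_resize_bilinear <- function(x, ho, wo) {
  x <- ag_wrap(x)
  ind <- dims_of(x$value)
  if (ind[3L] == ho && ind[4L] == wo) return(x)
  v <- cpp_resize_bilinear_fwd(x$value, as.integer(ho), as.integer(wo))
  ag_node(v, list(x), function(g) {
    if (is.null(dim(g))) dim(g) <- dims_of(v)
    list(cpp_resize_bilinear_bwd(g, as.integer(ind[3L]), as.integer(ind[4L])))
  })
}

#' Depthwise 1-d convolution along the channel axis
#'
#' The efficient-channel-attention primitive: one shared `k`-tap filter slid
#' along the channel dimension of a `(b, c)` descriptor with circular
#' padding, so every channel mixes with its `k - 1` nearest neighbours.
#'
#' @param x tensor `(b, c)`.
#' @param w parameter tensor of length `k` (odd).
#' @param b scalar bias parameter tensor.
#' @export
ag_conv1d_channels <- function(x, w, b) {
  x <- ag_wrap(x); w <- ag_wrap(w); b <- ag_wrap(b)
  d0 <- dims_of(x$value)
  nb <- d0[1L]; nc <- d0[2L]
  k <- length(w$value)
  stopifnot(k %% 2L == 1L)
  half <- (k - 1L) %/% 2L
  idx <- lapply(seq_len(k), function(j) ((seq_len(nc) - 1L + j - 1L - half) %% nc) + 1L)
  xm <- array(x$value, d0)
  out <- matrix(as.vector(b$value), nb, nc)
  for (j in seq_len(k)) out <- out + w$value[j] * xm[, idx[[j]], drop = FALSE]
  ag_node(out, list(x, w, b), function(g) {
    g <- matrix(g, nb, nc)
    gw <- numeric(k)
    gx <- matrix(0, nb, nc)
    for (j in seq_len(k)) {
      gw[j] <- sum(g * xm[, idx[[j]], drop = FALSE])
      gx[, idx[[j]]] <- gx[, idx[[j]]] + w$value[j] * g
    }
    list(gx, array(gw, k), array(sum(g), 1L))
  })
}
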