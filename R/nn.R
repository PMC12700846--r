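# Parameter containers, initialization, and the Adam optimizer.
#
# A "module" is a plain list with a named `params` list of ag_tensors (possibly
# nested) and closures that run its forward pass.  `collect_params()` walks any
# nesting depth so optimizers and parameter accounting see a flat list.

new_param <- function(value) ag_tensor(value, requires_grad = TRUE)

# Torch-style default conv/linear init: U(-1/sqrt(fan_in), 1/sqrt(fan_in)).
kaiming_uniform <- function(dim, fan_in) {
  bound <- 1 / sqrt(fan_in)
  array(stats::runif(prod(dim), -bound, bound), dim)
}

conv_param <- function(c_out, c_in_g, kh, kw) {
  fan_in <- c_in_g * kh * kw
  list(w = new_param(kaiming_uniform(c(c_out, c_in_g, kh, kw), fan_in)),
       b = new_param(kaiming_uniform(c_out, fan_in)))
}

# Depthwise 1x1 projection: per-channel scale + bias (the depthwise
# convolution degenerate with unit spatial support), initialized near
# identity for attention-path stability.
dw_param <- function(c) {
  list(w = new_param(array(1, c)), b = new_param(array(0, c)))
}

ln_param <- function(c) {
  list(gamma = new_param(array(1, c)), beta = new_param(array(0, c)))
}

# Apply a depthwise (per-channel affine) projection along dimension `d`.
dw_project <- function(x, p, d) {
  dx <- dims_of(x$value)
  shp <- rep(1L, length(dx))
  shp[d] <- dx[d]
  ag_add(ag_mul(x, ag_reshape(p$w, shp)), ag_reshape(p$b, shp))
}

#' Collect all parameter tensors of a module
#'
#' Recursively walks nested lists and returns every `ag_tensor` with
#' `requires_grad = TRUE`, named by its path.
#'
#' @param x module (nested list of parameter tensors).
#' @return flat named list of tensors.
#' @export
collect_params <- function(x) {
  out <- list()
  walk <- function(v, path) {
    if (is_tensor(v)) {
      if (v$requires_grad) out[[path]] <<- v
    } else if (is.list(v) && !is.function(v)) {
      nms <- names(v) %||% as.character(seq_along(v))
      for (i in seq_along(v)) {
        if (is.function(v[[i]])) next
        walk(v[[i]], paste0(path, ".", nms[i]))
      }
    }
  }
  walk(x, "p")
  out
}

#' Count trainable parameters
#' @param net a module (e.g. from [build_unet()]).
#' @return integer scalar: number of trainable values.
#' @export
count_parameters <- function(net) {
  ps <- if (is.list(net) && !is.null(net$params)) net$params else net
  sum(vapply(collect_params(ps), function(p) length(p$value), numeric(1)))
}

#' Relative parameter overhead between two networks
#' @param base,augmented networks or parameter counts.
#' @return percentage `100 * (p1 - p0) / p0`.
#' @export
param_overhead <- function(base, augmented) {
  p0 <- if (is.numeric(base)) base else count_parameters(base)
  p1 <- if (is.numeric(augmented)) augmented else count_parameters(augmented)
  100 * (p1 - p0) / p0
}

#' Adam optimizer
#'
#' @param params flat list of parameter tensors (see [collect_params()]).
#' @param lr learning rate (paper setting: `1e-4`).
#' @param beta1,beta2,eps standard Adam moment/stabilization constants.
#' @return optimizer state; advance with [adam_step()].
#' @export
adam_new <- function(params, lr = 1e-4, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  st <- new.env(parent = emptyenv())
  st$params <- params
  st$lr <- lr; st$beta1 <- beta1; st$beta2 <- beta2; st$eps <- eps
  st$t <- 0L
  st$m <- lapply(params, function(p) array(0, dims_of(p$value)))
  st$v <- lapply(params, function(p) array(0, dims_of(p$value)))
  st
}

#' @rdname adam_new
#' @export
adam_step <- function(st) {
  st$t <- st$t + 1L
  bc1 <- 1 - st$beta1^st$t
  bc2 <- 1 - st$beta2^st$t
  for (i in seq_along(st$params)) {
    p <- st$params[[i]]
    g <- p$grad
    if (is.null(g)) next
    st$m[[i]] <- st$beta1 * st$m[[i]] + (1 - st$beta1) * g
    st$v[[i]] <- st$beta2 * st$v[[i]] + (1 - st$beta2) * g * g
    mhat <- st$m[[i]] / bc1
    vhat <- st$v[[i]] / bc2
    p$value <- p$value - st$lr * mhat / (sqrt(vhat) + st$eps)
  }
  invisible(st)
}
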