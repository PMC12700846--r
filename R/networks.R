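# Vanilla U-Net backbone and the GLCSA attachment point.
#
# The encoder is the classic double-3x3-conv + ReLU ladder with 2x2 max
# pooling, channels doubling per stage from `base_channels`; the decoder
# mirrors it with bilinear upsampling, skip concatenation and double convs;
# a final 1x1 convolution emits the 3 class scores (background/TZ/PZ).
# GLCSA attaches as a bridge: the first n skip tensors are routed through
# one block whose per-stage outputs replace the raw skips.

#' Network specification
#'
#' @param stages number of encoder stages `n + 1` (default 5; the first `n`
#'   provide skip connections).
#' @param base_channels channels of the first stage, doubling per stage
#'   (default 64).
#' @param in_channels input channels (1 for grayscale MRI).
#' @param out_classes output classes (3: background, TZ, PZ).
#' @param input_hw spatial extent `(h, w)` the network will see; must be
#'   divisible by `2^n`.
#' @param glcsa optional [glcsa_config].
#' @param placement `"none"`, `"bridge"` (one block over all skips) or
#'   `"per_skip"` (an independent single-stage block per skip).
#' @return validated `network_spec`.
#' @export
network_spec <- function(stages = 5L, base_channels = 64L, in_channels = 1L,
                         out_classes = 3L, input_hw = c(128L, 128L),
                         glcsa = NULL, placement = c("none", "bridge", "per_skip")) {
  placement <- match.arg(placement)
  spec <- list(stages = as.integer(stages),
               base_channels = as.integer(base_channels),
               in_channels = as.integer(in_channels),
               out_classes = as.integer(out_classes),
               input_hw = as.integer(input_hw),
               glcsa = glcsa, placement = placement)
  n <- spec$stages - 1L
  if (any(spec$input_hw %% 2L^n != 0L)) {
    stop("spatial extent [", paste(input_hw, collapse = "x"),
         "] must be divisible by 2^n = ", 2L^n)
  }
  if (!is.null(glcsa) && placement == "none") spec$placement <- "bridge"
  class(spec) <- "network_spec"
  spec
}

stage_channels_of <- function(spec) {
  spec$base_channels * 2L^(seq_len(spec$stages) - 1L)
}

double_conv_new <- function(c_in, c_out) {
  list(c1 = conv_param(c_out, c_in, 3L, 3L), c2 = conv_param(c_out, c_out, 3L, 3L))
}

double_conv_fwd <- function(x, p) {
  x <- ag_relu(ag_conv2d(x, p$c1$w, p$c1$b, pad = 1L))
  ag_relu(ag_conv2d(x, p$c2$w, p$c2$b, pad = 1L))
}

#' Build a vanilla U-Net
#'
#' @param spec [network_spec].
#' @return a network object: list with `spec`, `params`, and a `forward`
#'   closure mapping `(b, in_channels, h, w)` tensors to class logits
#'   `(b, out_classes, h, w)`.
#' @export
build_unet <- function(spec = network_spec()) {
  stopifnot(inherits(spec, "network_spec"))
  ch <- stage_channels_of(spec)
  n <- spec$stages - 1L
  params <- list(
    enc = lapply(seq_len(spec$stages), function(i) {
      double_conv_new(if (i == 1L) spec$in_channels else ch[i - 1L], ch[i])
    }),
    dec = lapply(seq_len(n), function(i) {
      double_conv_new(ch[i] + ch[i + 1L], ch[i])
    }),
    head = conv_param(spec$out_classes, ch[1L], 1L, 1L)
  )
  if (spec$placement == "bridge" && !is.null(spec$glcsa)) {
    params$glcsa <- glcsa_block_new(ch[seq_len(n)], spec$glcsa)
  } else if (spec$placement == "per_skip" && !is.null(spec$glcsa)) {
    params$glcsa <- lapply(seq_len(n), function(i) {
      glcsa_block_new(ch[i], spec$glcsa)
    })
  }
  net <- list(spec = spec, params = params)
  net$forward <- function(x) unet_forward(net, x)
  class(net) <- "glcsa_network"
  net
}

unet_forward <- function(net, x) {
  spec <- net$spec
  p <- net$params
  n <- spec$stages - 1L
  x <- as_ag(x)
  skips <- vector("list", n)
  h <- x
  for (i in seq_len(spec$stages)) {
    h <- double_conv_fwd(h, p$enc[[i]])
    if (i <= n) {
      skips[[i]] <- h
      h <- ag_maxpool2(h)
    }
  }
  if (!is.null(p$glcsa)) {
    cfg <- spec$glcsa
    if (spec$placement == "bridge") {
      skips <- glcsa_block_forward(skips, cfg, p$glcsa)
    } else {
      skips <- lapply(seq_len(n), function(i) {
        glcsa_block_forward(list(skips[[i]]), cfg, p$glcsa[[i]])[[1L]]
      })
    }
  }
  for (i in rev(seq_len(n))) {
    di <- dims_of(skips[[i]]$value)
    h <- ag_resize_bilinear(h, di[3L], di[4L])
    h <- ag_concat(list(skips[[i]], h), 2L)
    h <- double_conv_fwd(h, p$dec[[i]])
  }
  ag_conv2d(h, p$head$w, p$head$b)
}

#' @export
print.glcsa_network <- function(x, ...) {
  cat("<", if (is.null(x$params$glcsa)) "U-Net" else "GLCSA-UNet",
      ": stages=", x$spec$stages, " base=", x$spec$base_channels,
      " params=", count_parameters(x), ">\n", sep = "")
  invisible(x)
}

#' Attach a GLCSA block to an existing network
#'
#' Routes the skip features of the first n encoder stages through a GLCSA
#' block whose per-stage outputs replace the raw skips.  The output shape and
#' class count are unchanged.  Backbone weights are kept; only the block's
#' parameters are new.
#'
#' @param net network from [build_unet()].
#' @param cfg [glcsa_config].
#' @param placement `"bridge"` (default, one block across all skips) or
#'   `"per_skip"`.
#' @return a new network with the block attached.
#' @export
attach_glcsa <- function(net, cfg = glcsa_config(),
                         placement = c("bridge", "per_skip")) {
  placement <- match.arg(placement)
  spec <- net$spec
  spec$glcsa <- cfg
  spec$placement <- placement
  ch <- stage_channels_of(spec)
  n <- spec$stages - 1L
  if (placement == "bridge") {
    C_c <- sum(ch[seq_len(n)])
    if (C_c %% cfg$glsa_heads != 0L) {
      stop("glsa_heads (", cfg$glsa_heads, ") must divide C_c = ", C_c)
    }
  }
  out <- net
  out$spec <- spec
  out$params$glcsa <- if (placement == "bridge") {
    glcsa_block_new(ch[seq_len(n)], cfg)
  } else {
    lapply(seq_len(n), function(i) glcsa_block_new(ch[i], cfg))
  }
  out$forward <- function(x) unet_forward(out, x)
  out
}

#' Save / load network checkpoints
#'
#' Checkpoints store the full parameter values plus the network and
#' attention configurations, and reload byte-exactly.
#'
#' @param net network object.
#' @param path checkpoint file path (`.rds`).
#' @param extra optional named list stored alongside (e.g. training history).
#' @export
save_checkpoint <- function(net, path, extra = NULL) {
  flat <- collect_params(net$params)
  vals <- lapply(flat, function(p) p$value)
  saveRDS(list(spec = net$spec, values = vals, extra = extra), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  net <- build_unet(ck$spec)
  flat <- collect_params(net$params)
  stopifnot(identical(sort(names(flat)), sort(names(ck$values))))
  for (nm in names(flat)) flat[[nm]]$value <- ck$values[[nm]]
  net$extra <- ck$extra
  net
}
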