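# Loss, segmentation metrics, the training loop, evaluation tables, and the
# paired Wilcoxon signed-rank comparison.

CLASS_NAMES <- c(TZ = 1L, PZ = 2L)

resolve_class <- function(cls) {
  if (is.character(cls)) {
    if (!cls %in% names(CLASS_NAMES)) stop("unknown class: ", cls)
    return(CLASS_NAMES[[cls]])
  }
  cls <- as.integer(cls)
  if (!cls %in% 0:2) stop("unknown class: ", cls)
  cls
}

one_hot <- function(labels, n_classes = 3L) {
  d <- dims_of(labels)
  oh <- array(0, c(d[1L], n_classes, d[2L], d[3L]))
  for (k in seq_len(n_classes)) oh[, k, , ] <- (labels == (k - 1L))
  oh
}

#' Multiclass soft Dice loss
#'
#' `L = 1 - mean_c (2 sum(p_c g_c) + eps) / (sum(p_c) + sum(g_c) + eps)`
#' over the whole volume.  Background is included in the class average by
#' default.
#'
#' @param scores class probabilities `(b, 3, h, w)` (array or tensor);
#'   must be nonnegative and sum to 1 per voxel.
#' @param target [zone_mask], label array `(b, h, w)`, or one-hot array.
#' @param eps smoothing constant (default `1e-6`).
#' @param include_background include class 0 in the average (default TRUE).
#' @return scalar loss in `[0, 1]` (tensor when `scores` is a tensor).
#' @export
dice_loss <- function(scores, target, eps = 1e-6, include_background = TRUE) {
  plain <- !is_tensor(scores)
  s <- as_ag(scores)
  d <- dims_of(s$value)
  if (length(d) != 4L) stop("scores must be (b, classes, h, w)")
  g <- if (inherits(target, "zone_mask")) one_hot(target$labels, d[2L])
       else if (length(dims_of(target)) == 3L) one_hot(target, d[2L])
       else target
  if (!identical(as.integer(dims_of(g)), as.integer(d))) {
    stop("scores and target shapes differ")
  }
  cls <- if (include_background) seq_len(d[2L]) else 2:d[2L]
  total <- NULL
  for (k in cls) {
    pk <- ag_slice(s, 2L, k)
    gk <- g[, k, , , drop = FALSE]
    num <- ag_add(ag_scale(ag_sum(ag_mul(pk, gk)), 2), eps)
    den <- ag_add(ag_add(ag_sum(pk), sum(gk)), eps)
    dk <- ag_div(num, den)
    total <- if (is.null(total)) dk else ag_add(total, dk)
  }
  loss <- ag_add(ag_scale(total, -1 / length(cls)), 1)
  if (plain) as.vector(loss$value) else loss
}

hard_counts <- function(pred, truth, k) {
  a <- pred == k
  b <- truth == k
  c(inter = sum(a & b), na = sum(a), nb = sum(b))
}

#' Dice similarity coefficient (hard, per class, whole volume)
#'
#' `DSC = 2|A n B| / (|A| + |B|)`; when both masks are empty for the class
#' the value is defined as 1.
#'
#' @param pred,truth [zone_mask] objects or integer arrays of equal shape.
#' @param cls class: `"TZ"`, `"PZ"`, or an integer label.
#' @return numeric scalar in `[0, 1]`.
#' @export
dsc <- function(pred, truth, cls) {
  k <- resolve_class(cls)
  p <- if (inherits(pred, "zone_mask")) pred$labels else pred
  t <- if (inherits(truth, "zone_mask")) truth$labels else truth
  stopifnot(identical(dims_of(p), dims_of(t)))
  n <- hard_counts(p, t, k)
  if (n["na"] + n["nb"] == 0L) return(1)
  as.numeric(2 * n["inter"] / (n["na"] + n["nb"]))
}

#' Intersection over union (hard, per class)
#'
#' `IoU = |A n B| / |A u B|`; both-empty is defined as 1.  For hard masks
#' `IoU = DSC / (2 - DSC)` exactly.
#'
#' @inheritParams dsc
#' @return numeric scalar in `[0, 1]`.
#' @export
iou <- function(pred, truth, cls) {
  k <- resolve_class(cls)
  p <- if (inherits(pred, "zone_mask")) pred$labels else pred
  t <- if (inherits(truth, "zone_mask")) truth$labels else truth
  n <- hard_counts(p, t, k)
  uni <- n["na"] + n["nb"] - n["inter"]
  if (uni == 0L) return(1)
  as.numeric(n["inter"] / uni)
}

boundary_coords <- function(labels, k, spacing) {
  m <- labels == k
  if (!any(m)) return(matrix(numeric(0), 0L, 3L))
  d <- dim(m)
  inside <- m
  # a voxel is boundary if any of its 6 face neighbours (or the array edge)
  # lies outside the class
  shift_ok <- function(ax, by) {
    out <- array(FALSE, d)
    idx_src <- lapply(d, seq_len)
    idx_dst <- lapply(d, seq_len)
    if (by > 0) {
      idx_dst[[ax]] <- seq_len(d[ax] - 1L) + 1L
      idx_src[[ax]] <- seq_len(d[ax] - 1L)
    } else {
      idx_dst[[ax]] <- seq_len(d[ax] - 1L)
      idx_src[[ax]] <- seq_len(d[ax] - 1L) + 1L
    }
    out <- do.call(`[<-`, c(list(out), idx_dst,
                            list(value = do.call(`[`, c(list(m), idx_src)))))
    out
  }
  surrounded <- m
  for (ax in 1:3) for (by in c(1L, -1L)) {
    surrounded <- surrounded & shift_ok(ax, by)
  }
  bnd <- which(m & !surrounded, arr.ind = TRUE)
  sweep(bnd - 1, 2L, spacing, `*`)
}

#' Symmetric mean surface distance
#'
#' Mean of the two directed mean nearest-boundary distances between the
#' class boundaries of `pred` and `truth` (boundary voxel: a class voxel
#' with at least one face neighbour outside the class).  Distances are
#' scaled by `spacing`; an empty prediction or truth yields `NaN`.
#'
#' @inheritParams dsc
#' @param spacing voxel spacing `(dz, dy, dx)`; defaults to the masks' or
#'   unit spacing.
#' @return numeric scalar (>= 0) or `NaN` with attribute `flag`.
#' @export
msd <- function(pred, truth, cls, spacing = NULL) {
  k <- resolve_class(cls)
  p <- if (inherits(pred, "zone_mask")) pred$labels else pred
  t <- if (inherits(truth, "zone_mask")) truth$labels else truth
  stopifnot(identical(dims_of(p), dims_of(t)))
  if (is.null(spacing)) {
    spacing <- if (inherits(truth, "zone_mask")) truth$spacing else c(1, 1, 1)
  }
  bp <- boundary_coords(p, k, spacing)
  bt <- boundary_coords(t, k, spacing)
  if (nrow(bp) == 0L || nrow(bt) == 0L) {
    out <- NaN
    attr(out, "flag") <- if (nrow(bp) == 0L) "empty-prediction" else "empty-truth"
    return(out)
  }
  0.5 * (cpp_mean_nn_dist(bp, bt) + cpp_mean_nn_dist(bt, bp))
}

#' Training configuration
#'
#' @param lr Adam learning rate (paper setting `1e-4`).
#' @param epochs training epochs (paper setting 200; reduce for CPU runs).
#' @param eps Dice-loss smoothing.
#' @param seed integer seed governing shuffling (weight init is seeded at
#'   network construction).
#' @param include_background include background in the Dice loss average.
#' @param verbose print per-epoch progress.
#' @return `train_config` list.
#' @export
train_config <- function(lr = 1e-4, epochs = 200L, eps = 1e-6, seed = 1L,
                         include_background = TRUE, verbose = FALSE) {
  stopifnot(lr > 0, epochs >= 1L)
  structure(list(lr = lr, epochs = as.integer(epochs), eps = eps,
                 seed = as.integer(seed),
                 include_background = isTRUE(include_background),
                 verbose = isTRUE(verbose)),
            class = "train_config")
}

volume_to_batch <- function(vol) {
  v <- vol$voxels / 255 # network inputs live in [0, 1]
  d <- dim(v)
  x <- array(0, c(d[1L], 1L, d[2L], d[3L]))
  x[, 1L, , ] <- v
  x
}

argmax_classes <- function(scores) {
  d <- dims_of(scores)
  m <- matrix(aperm(array(scores, c(d[1L], d[2L], d[3L] * d[4L])),
                    c(1L, 3L, 2L)), ncol = d[2L])
  array(max.col(m, ties.method = "first") - 1L, c(d[1L], d[3L], d[4L]))
}

predict_mask <- function(net, vol) {
  logits <- net$forward(ag_tensor(volume_to_batch(vol)))
  lab <- argmax_classes(logits$value)
  zone_mask(lab, vol$spacing, vol$subject_id)
}

#' Train a segmentation network
#'
#' Epoch loop minimizing the multiclass Dice loss with Adam; one batch is
#' one subject volume (all slices of the stack together, so the pseudo-depth
#' axis of the slice-interaction module is anatomical depth).  Shuffling is
#' across subjects only and fully deterministic given `cfg$seed`.
#'
#' @param net network from [build_unet()] / [attach_glcsa()]; modified by
#'   reference (parameters are environments) and also returned.
#' @param dataset list of `list(image =, mask =)` pairs.
#' @param cfg [train_config].
#' @return list with `net` and `history` (data frame: epoch, loss, dsc, iou
#'   averaged over subjects and the two foreground classes).
#' @export
train_network <- function(net, dataset, cfg = train_config()) {
  stopifnot(length(dataset) >= 1L)
  params <- collect_params(net$params)
  opt <- adam_new(params, lr = cfg$lr)
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        dsc = numeric(0), iou = numeric(0))
  xs <- lapply(dataset, function(p) volume_to_batch(p$image))
  for (epoch in seq_len(cfg$epochs)) {
    order_i <- with_seed(cfg$seed * 10000L + epoch, sample(length(dataset)))
    losses <- numeric(0)
    dscs <- numeric(0)
    ious <- numeric(0)
    for (i in order_i) {
      x <- ag_tensor(xs[[i]])
      logits <- net$forward(x)
      probs <- ag_softmax(logits, 2L)
      loss <- dice_loss(probs, dataset[[i]]$mask$labels, eps = cfg$eps,
                        include_background = cfg$include_background)
      lv <- as.vector(loss$value)
      if (!is.finite(lv)) {
        stop("training diverged: non-finite loss at epoch ", epoch,
             " subject ", i)
      }
      ag_zero_grad(params)
      ag_backward(loss)
      adam_step(opt)
      losses <- c(losses, lv)
      lab <- argmax_classes(probs$value)
      truth <- dataset[[i]]$mask$labels
      dscs <- c(dscs, mean(c(dsc(lab, truth, "TZ"), dsc(lab, truth, "PZ"))))
      ious <- c(ious, mean(c(iou(lab, truth, "TZ"), iou(lab, truth, "PZ"))))
    }
    history <- rbind(history, data.frame(epoch = epoch, loss = mean(losses),
                                         dsc = mean(dscs), iou = mean(ious)))
    if (cfg$verbose) {
      message(sprintf("epoch %3d  loss %.4f  dsc %.4f  iou %.4f", epoch,
                      mean(losses), mean(dscs), mean(ious)))
    }
  }
  list(net = net, history = history)
}

#' Evaluate a network on a dataset
#'
#' Per-subject argmax prediction, per-class DSC/IoU/MSD, plus per-class
#' summaries (mean, population SD, worst case).
#'
#' @param net trained network.
#' @param dataset list of `list(image =, mask =)` pairs.
#' @return list with `records` (data frame: subject_id, class, dsc, iou,
#'   msd, flags) and `summary` (per class: mean/sd/worst of each metric).
#' @export
evaluate_network <- function(net, dataset) {
  rows <- list()
  for (p in dataset) {
    pred <- predict_mask(net, p$image)
    for (cls in names(CLASS_NAMES)) {
      m <- msd(pred, p$mask, cls)
      flag <- attr(m, "flag") %||% ""
      k <- resolve_class(cls)
      if (sum(pred$labels == k) == 0L && sum(p$mask$labels == k) == 0L) {
        flag <- paste0(flag, if (nzchar(flag)) ";" else "", "both-empty")
      }
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = p$image$subject_id, class = cls,
        dsc = dsc(pred, p$mask, cls), iou = iou(pred, p$mask, cls),
        msd = as.numeric(m), flags = flag, stringsAsFactors = FALSE)
    }
  }
  records <- do.call(rbind, rows)
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  summary <- lapply(split(records, records$class), function(g) {
    list(mean_dsc = mean(g$dsc), sd_dsc = pop_sd(g$dsc), worst_dsc = min(g$dsc),
         mean_iou = mean(g$iou), sd_iou = pop_sd(g$iou), worst_iou = min(g$iou),
         mean_msd = mean(g$msd, na.rm = TRUE),
         worst_msd = suppressWarnings(max(g$msd, na.rm = TRUE)))
  })
  list(records = records, summary = summary)
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided test on paired samples.  Zero differences are dropped (flagged);
#' ties get average ranks.  The null distribution is exact (computed by
#' dynamic programming over doubled ranks, valid with ties) for up to 25
#' effective pairs, and a normal approximation with tie correction and
#' continuity correction above that.
#'
#' @param a,b equal-length numeric vectors of paired metrics (length >= 5).
#' @return list: `statistic` (V = sum of positive ranks), `p_value`,
#'   `n_effective`, `degenerate` (all differences zero), `zeros_dropped`,
#'   `method`.
#' @export
wilcoxon_compare <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 5L)
  d <- a - b
  zeros <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    return(list(statistic = 0, p_value = 1, n_effective = 0L,
                degenerate = TRUE, zeros_dropped = zeros, method = "degenerate"))
  }
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  if (n <= 25L) {
    # exact distribution of 2*V via subset-sum convolution on doubled ranks
    dr <- as.integer(round(2 * r))
    total <- sum(dr)
    f <- numeric(total + 1L)
    f[1L] <- 1
    for (x in dr) {
      g <- f
      g[(x + 1L):(total + 1L)] <- g[(x + 1L):(total + 1L)] + f[1L:(total + 1L - x)]
      f <- g
    }
    f <- f / sum(f)
    v2 <- as.integer(round(2 * V))
    p_le <- sum(f[seq_len(v2 + 1L)])
    p_ge <- sum(f[(v2 + 1L):(total + 1L)])
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (V - mu - sign(V - mu) * 0.5) / sqrt(sig2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal-approximation"
  }
  list(statistic = V, p_value = p, n_effective = n,
       degenerate = FALSE, zeros_dropped = zeros, method = method)
}
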