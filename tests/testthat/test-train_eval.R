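# Loss, metrics, evaluation summaries, Wilcoxon signed-rank.

test_that("dice loss: perfect match, closed forms, bounds, gradient", {
  lab <- array(sample(0:2, 2 * 4 * 4, TRUE), c(2, 4, 4))
  onehot <- glcsa:::one_hot(lab)
  expect_lt(dice_loss(onehot, lab), 1e-5)
  # uniform 1/3 prediction vs all-background target, closed form:
  # class 0: (2N/3 + eps)/(N/3 + N + eps); classes 1,2: eps/(N/3 + eps)
  N <- 2 * 4 * 4
  unif <- array(1 / 3, c(2, 3, 4, 4))
  bg <- array(0L, c(2, 4, 4))
  eps <- 1e-6
  want <- 1 - mean(c((2 * N / 3 + eps) / (N / 3 + N + eps),
                     eps / (N / 3 + eps), eps / (N / 3 + eps)))
  expect_equal(dice_loss(unif, bg, eps = eps), want, tolerance = 1e-10)
  # any valid probability field keeps the loss in [0, 1]
  for (s in 1:5) {
    raw <- feature_fixture(2, 3, 4, 4, seed = s)
    pr <- ag_softmax(ag_tensor(raw), 2)$value
    l <- dice_loss(pr, lab)
    expect_gte(l, 0); expect_lte(l, 1)
  }
  # background exclusion changes the average as expected
  expect_false(isTRUE(all.equal(dice_loss(unif, lab),
                                dice_loss(unif, lab, include_background = FALSE))))
  # differentiable end to end
  tx <- ag_tensor(feature_fixture(1, 3, 4, 4, seed = 6), requires_grad = TRUE)
  tgt <- with_seed(7, array(sample(0:2, 16, TRUE), c(1, 4, 4)))
  err <- gradcheck(function() dice_loss(ag_softmax(tx, 2), tgt), list(tx))
  expect_lt(err, 1e-6)
})

test_that("hard DSC/IoU match hand arithmetic and the ratio identity", {
  a <- array(0L, c(1, 4, 4)); b <- array(0L, c(1, 4, 4))
  a[1, 1, 1:4] <- 1L          # |A| = 4
  b[1, 1, 3:4] <- 1L; b[1, 2, 1:2] <- 1L # |B| = 4, |A n B| = 2
  expect_equal(dsc(a, b, "TZ"), 0.5)
  expect_equal(iou(a, b, "TZ"), 1 / 3)
  expect_equal(dsc(a, a, "TZ"), 1)
  disj <- array(0L, c(1, 4, 4)); disj[1, 4, 1] <- 1L
  expect_equal(dsc(a, disj, "TZ"), 0)
  expect_equal(dsc(a, b, "PZ"), 1) # both empty, defined as 1
  expect_error(dsc(a, b, "WG"), "unknown class")
  # IoU = DSC / (2 - DSC) on random hard masks
  for (s in 1:6) {
    p <- with_seed(s, array(sample(0:2, 5 * 6 * 6, TRUE), c(5, 6, 6)))
    t <- with_seed(s + 50, array(sample(0:2, 5 * 6 * 6, TRUE), c(5, 6, 6)))
    for (cls in c("TZ", "PZ")) {
      d <- dsc(p, t, cls)
      expect_equal(iou(p, t, cls), d / (2 - d), tolerance = 1e-12)
    }
  }
})

test_that("metrics are symmetric and invariant under shared rotations", {
  ph <- generate_phantom(phantom_spec(shape = c(4, 32, 32), seed = 41))
  p <- with_seed(42, array(sample(0:2, 4 * 32 * 32, TRUE, prob = c(.8, .1, .1)),
                           c(4, 32, 32)))
  t <- ph$mask$labels
  for (cls in c("TZ", "PZ")) {
    expect_equal(dsc(p, t, cls), dsc(t, p, cls))
    expect_equal(as.numeric(msd(p, t, cls)), as.numeric(msd(t, p, cls)))
  }
  ap <- augment_pair(image_volume(p * 1.0), zone_mask(p), seed = 7)
  at <- augment_pair(image_volume(t * 1.0), zone_mask(t), seed = 7)
  expect_equal(dsc(ap$mask$labels, at$mask$labels, "TZ"), dsc(p, t, "TZ"))
})

test_that("MSD matches a brute-force boundary oracle and scales with spacing", {
  # 2x2 square vs the same square shifted by one voxel, unit spacing
  a <- array(0L, c(1, 6, 6)); a[1, 2:3, 2:3] <- 1L
  b <- array(0L, c(1, 6, 6)); b[1, 3:4, 2:3] <- 1L
  brute <- function(x, y, k) {
    bound <- function(m) {
      d <- dim(m); out <- NULL
      for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (l in seq_len(d[3])) {
        if (m[i, j, l] != k) next
        nb <- c(if (i > 1) m[i - 1, j, l] else -1, if (i < d[1]) m[i + 1, j, l] else -1,
                if (j > 1) m[i, j - 1, l] else -1, if (j < d[2]) m[i, j + 1, l] else -1,
                if (l > 1) m[i, j, l - 1] else -1, if (l < d[3]) m[i, j, l + 1] else -1)
        if (any(nb != k)) out <- rbind(out, c(i, j, l))
      }
      out
    }
    ba <- bound(x); bb <- bound(y)
    mnn <- function(p, q) mean(apply(p, 1, function(r) {
      min(sqrt(colSums((t(q) - r)^2)))
    }))
    (mnn(ba, bb) + mnn(bb, ba)) / 2
  }
  expect_equal(msd(a, b, "TZ"), brute(a, b, 1L), tolerance = 1e-12)
  expect_equal(msd(a, a, "TZ"), 0)
  # spacing scales distances linearly
  expect_equal(msd(a, b, "TZ", spacing = c(2, 2, 2)),
               2 * msd(a, b, "TZ"), tolerance = 1e-12)
  # empty prediction: NaN with flag
  e <- array(0L, c(1, 6, 6))
  m <- msd(e, b, "TZ")
  expect_true(is.nan(m))
  expect_equal(attr(m, "flag"), "empty-prediction")
})

test_that("training is deterministic given a seed and records history", {
  ds <- lapply(1:2, function(i) generate_phantom(phantom_spec(shape = c(4, 32, 32),
                                                              seed = i)))
  make <- function() with_seed(55, build_unet(network_spec(stages = 2,
                                                           base_channels = 8,
                                                           input_hw = c(32, 32))))
  f1 <- train_network(make(), ds, train_config(epochs = 2, seed = 9))
  f2 <- train_network(make(), ds, train_config(epochs = 2, seed = 9))
  expect_identical(f1$history, f2$history)
  expect_equal(nrow(f1$history), 2L)
  expect_named(f1$history, c("epoch", "loss", "dsc", "iou"))
  expect_equal(eval(formals(train_config)$lr), 1e-4)
  expect_equal(eval(formals(train_config)$epochs), 200L)
})

test_that("evaluation against the truth gives perfect rows and sane summaries", {
  ds <- lapply(1:3, function(i) generate_phantom(phantom_spec(shape = c(6, 32, 32),
                                                              seed = i + 60)))
  # truth evaluated against itself through the metric layer
  rows <- do.call(rbind, lapply(ds, function(p) {
    data.frame(subject_id = p$image$subject_id, class = c("TZ", "PZ"),
               dsc = c(dsc(p$mask, p$mask, "TZ"), dsc(p$mask, p$mask, "PZ")),
               iou = 1, msd = c(msd(p$mask, p$mask, "TZ"), msd(p$mask, p$mask, "PZ")),
               flags = "")
  }))
  expect_true(all(rows$dsc == 1))
  expect_true(all(rows$msd == 0))
  # summary arithmetic: mean/worst over an explicit triple
  recs <- data.frame(subject_id = c("a", "b", "c"), class = "TZ",
                     dsc = c(0.8, 0.9, 1.0), iou = c(0.7, 0.8, 1.0),
                     msd = c(1, 2, 3), flags = "")
  f <- tempfile(fileext = ".csv")
  out <- export_metrics(recs, f)
  expect_equal(out$dsc[out$subject_id == "mean"], 0.9)
  expect_equal(out$dsc[out$subject_id == "worst_case"], 0.8)
  expect_lte(out$dsc[out$subject_id == "worst_case"],
             out$dsc[out$subject_id == "mean"])
})

test_that("Wilcoxon signed-rank matches exhaustive enumeration at n = 6", {
  a <- c(0.80, 0.72, 0.91, 0.66, 0.84, 0.77)
  b <- c(0.74, 0.70, 0.95, 0.60, 0.79, 0.70)
  got <- wilcoxon_compare(a, b)
  d <- a - b
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  # enumerate all 2^6 sign assignments of the ranks
  Vs <- vapply(0:63, function(mask) {
    signs <- as.integer(intToBits(mask))[1:6]
    sum(r[signs == 1])
  }, numeric(1))
  p_exact <- min(1, 2 * min(mean(Vs <= V), mean(Vs >= V)))
  expect_equal(got$statistic, V)
  expect_equal(got$p_value, p_exact, tolerance = 1e-12)
  # agreement with R's reference implementation on tie-free data
  a3 <- c(0.81, 0.72, 0.91, 0.66, 0.84, 0.77, 0.59)
  b3 <- c(0.74, 0.705, 0.95, 0.60, 0.78, 0.702, 0.63)
  stopifnot(!anyDuplicated(abs(a3 - b3)))
  ref <- wilcox.test(a3, b3, paired = TRUE, exact = TRUE)
  expect_equal(wilcoxon_compare(a3, b3)$p_value, unname(ref$p.value),
               tolerance = 1e-12)
  # two-sided symmetry under swapping
  swapped <- wilcoxon_compare(b, a)
  expect_equal(swapped$p_value, got$p_value, tolerance = 1e-12)
  # identical lists: degenerate with p = 1
  deg <- wilcoxon_compare(a, a)
  expect_true(deg$degenerate)
  expect_equal(deg$p_value, 1)
  # zero differences dropped, ties handled, exact DP still valid
  a2 <- c(a, 0.5); b2 <- c(b, 0.5)
  got2 <- wilcoxon_compare(a2, b2)
  expect_equal(got2$zeros_dropped, 1L)
  expect_equal(got2$n_effective, 6L)
  expect_equal(got2$p_value, got$p_value, tolerance = 1e-12)
  # large-n normal approximation tracks wilcox.test with correction
  set.seed(77)
  x <- rnorm(40); y <- x + rnorm(40, 0.3, 0.5)
  gotn <- wilcoxon_compare(x, y)
  refn <- wilcox.test(x, y, paired = TRUE, exact = FALSE, correct = TRUE)
  expect_equal(gotn$p_value, unname(refn$p.value), tolerance = 1e-6)
})
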