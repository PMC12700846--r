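# Prostate-like phantom volumes and random tensor fixtures.
#
# The phantom stands in for T2-weighted prostate MRI: a bright inner
# ellipsoid plays the transition zone (TZ, label 1), the surrounding
# ellipsoidal shell - thicker posteriorly because the TZ sits anterior of the
# prostate center - plays the peripheral zone (PZ, label 2), over a darker
# background with additive Gaussian noise.  Geometry is axis-aligned, which
# keeps the zone volumes analytically checkable.

#' Phantom specification
#'
#' @param shape output shape `(d, h, w)`; default `c(20, 128, 128)`.
#' @param prostate_semiaxes ellipsoid semiaxes as fractions of `(d, h, w)`.
#' @param tz_semiaxes TZ ellipsoid semiaxes, fractions of `(d, h, w)`; the TZ
#'   must fit strictly inside the prostate after its anterior offset.
#' @param tz_offset_frac anterior (negative row) shift of the TZ center as a
#'   fraction of `h`; makes the PZ shell crescent-like (thicker posteriorly).
#' @param intensity_means mean intensities `(background, TZ, PZ)` in `[0, 255]`.
#' @param noise_sigma additive Gaussian noise SD (intensity units).
#' @param jitter relative per-subject jitter of center and semiaxes.
#' @param seed integer seed.
#' @return validated `phantom_spec` list.
#' @export
phantom_spec <- function(shape = c(20L, 128L, 128L),
                         prostate_semiaxes = c(0.35, 0.26, 0.30),
                         tz_semiaxes = c(0.20, 0.14, 0.17),
                         tz_offset_frac = 0.07,
                         intensity_means = c(50, 180, 110),
                         noise_sigma = 25,
                         jitter = 0.06,
                         seed = 1L) {
  spec <- list(shape = as.integer(shape),
               prostate_semiaxes = prostate_semiaxes,
               tz_semiaxes = tz_semiaxes,
               tz_offset_frac = tz_offset_frac,
               intensity_means = intensity_means,
               noise_sigma = noise_sigma,
               jitter = jitter,
               seed = as.integer(seed))
  stopifnot(length(shape) == 3L, all(shape >= 1L), noise_sigma >= 0,
            length(intensity_means) == 3L)
  # sufficient condition for strict containment of axis-aligned ellipsoids
  off <- c(0, tz_offset_frac, 0)
  if (!all(abs(off) + tz_semiaxes < prostate_semiaxes)) {
    stop("phantom_spec: TZ ellipsoid (offset + semiaxes) is not strictly ",
         "inside the prostate ellipsoid")
  }
  if (noise_sigma == 0 && anyDuplicated(intensity_means)) {
    stop("phantom_spec: intensity means must be pairwise distinct when ",
         "noise_sigma = 0")
  }
  class(spec) <- "phantom_spec"
  spec
}

ellipsoid_mask <- function(shape, center, semiaxes) {
  zq <- ((seq_len(shape[1L]) - 1 - center[1L]) / semiaxes[1L])^2
  yq <- ((seq_len(shape[2L]) - 1 - center[2L]) / semiaxes[2L])^2
  xq <- ((seq_len(shape[3L]) - 1 - center[3L]) / semiaxes[3L])^2
  outer(outer(zq, yq, `+`), xq, `+`) <= 1
}

#' Generate one phantom volume with its zone mask
#'
#' @param spec [phantom_spec]; `spec$seed` fully determines the output.
#' @return list with `image` ([image_volume]) and `mask` ([zone_mask]).
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  shp <- spec$shape
  with_seed(spec$seed, {
    jit <- spec$jitter
    center <- (shp - 1) / 2 + stats::runif(3L, -jit, jit) * shp
    pro_ax <- spec$prostate_semiaxes * shp *
      (1 + stats::runif(3L, -jit, jit))
    tz_ax <- spec$tz_semiaxes * shp * (1 + stats::runif(3L, -jit, jit))
    tz_center <- center + c(0, -spec$tz_offset_frac * shp[2L], 0)
    # keep the jittered TZ strictly inside the jittered prostate
    room <- pro_ax - abs(tz_center - center) - 1
    tz_ax <- pmin(tz_ax, 0.95 * room)
    prostate <- ellipsoid_mask(shp, center, pro_ax)
    tz <- ellipsoid_mask(shp, tz_center, tz_ax)
    tz <- tz & prostate
    if (!any(tz)) {
      # very shallow grids can voxelize the inner ellipsoid to nothing;
      # guarantee at least the in-prostate voxel nearest the TZ center
      idx <- which(prostate, arr.ind = TRUE)
      d2 <- colSums((t(idx) - 1 - tz_center)^2)
      tz[matrix(idx[which.min(d2), ], 1L)] <- TRUE
    }
    labels <- array(0L, shp)
    labels[prostate] <- 2L # PZ shell ...
    labels[tz] <- 1L       # ... minus the inner TZ
    img <- array(spec$intensity_means[labels + 1L], shp)
    if (spec$noise_sigma > 0) {
      img <- img + stats::rnorm(length(img), 0, spec$noise_sigma)
    }
    img <- pmin(pmax(img, 0), 255)
    dim(img) <- shp
    sid <- sprintf("phantom-%06d", spec$seed %% 1000000L)
    list(image = image_volume(img, c(1, 1, 1), sid),
         mask = zone_mask(labels, c(1, 1, 1), sid))
  })
}

#' Generate a phantom dataset on disk
#'
#' Writes `n` NIfTI image/mask pairs plus a `manifest.json` recording the
#' train/test split.  Fully deterministic given `spec$seed`.
#'
#' @param n number of subjects (>= 2).
#' @param out_dir output directory (created if absent).
#' @param spec base [phantom_spec]; per-subject seeds are derived from
#'   `spec$seed`.
#' @param split `(train_frac, test_frac)`, summing to 1.
#' @return the manifest as a list, invisibly; also written as JSON.
#' @export
generate_dataset <- function(n, out_dir, spec = phantom_spec(),
                             split = c(0.8, 0.2)) {
  stopifnot(n >= 2L, abs(sum(split) - 1) < 1e-8)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sub_seeds <- with_seed(spec$seed, sample.int(2^31 - 1, n))
  n_train <- round(split[1L] * n)
  assignment <- with_seed(spec$seed + 1L, sample(rep(c("train", "test"),
                                                     c(n_train, n - n_train))))
  subjects <- vector("list", n)
  for (i in seq_len(n)) {
    sp <- spec
    sp$seed <- sub_seeds[i]
    pair <- generate_phantom(sp)
    sid <- sprintf("sub-%03d", i)
    pair$image$subject_id <- sid
    pair$mask$subject_id <- sid
    img_path <- file.path(out_dir, paste0(sid, "_img.nii.gz"))
    msk_path <- file.path(out_dir, paste0(sid, "_mask.nii.gz"))
    save_volume(pair$image, img_path)
    save_volume(pair$mask, msk_path)
    subjects[[i]] <- list(id = sid, image = basename(img_path),
                          mask = basename(msk_path), split = assignment[i],
                          seed = sub_seeds[i])
  }
  manifest <- list(n = n, seed = spec$seed, split = split,
                   shape = spec$shape, noise_sigma = spec$noise_sigma,
                   subjects = subjects)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Load a generated dataset back into memory
#'
#' @param dir directory produced by [generate_dataset()].
#' @param split optional filter: `"train"` or `"test"`.
#' @return list of `list(image =, mask =)` pairs.
#' @export
load_dataset <- function(dir, split = NULL) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = FALSE)
  subs <- manifest$subjects
  if (!is.null(split)) {
    subs <- Filter(function(s) s$split == split, subs)
  }
  lapply(subs, function(s) {
    img <- load_volume(file.path(dir, s$image), "image")
    msk <- load_volume(file.path(dir, s$mask), "mask")
    img$subject_id <- s$id
    msk$subject_id <- s$id
    list(image = img, mask = msk)
  })
}

#' Reproducible random feature tensor
#'
#' @param b,c,h,w tensor extents.
#' @param seed integer seed.
#' @param dist `"normal"` (standard normal) or `"uniform"` (values in `[0,1)`).
#' @return numeric array `(b, c, h, w)`.
#' @export
feature_fixture <- function(b, c, h, w, seed = 1L,
                            dist = c("normal", "uniform")) {
  dist <- match.arg(dist)
  stopifnot(b >= 1L, c >= 1L, h >= 1L, w >= 1L)
  with_seed(seed, {
    v <- if (dist == "normal") stats::rnorm(b * c * h * w) else
      stats::runif(b * c * h * w)
    array(v, c(b, c, h, w))
  })
}
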