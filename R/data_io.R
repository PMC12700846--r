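# Volume/mask containers, NIfTI-backed loading, preprocessing and
# augmentation.
#
# Arrays follow the (slice, row, col) = (d, h, w) convention, 0-based in all
# coordinate arithmetic, with half-open crops [start, start + crop).  Zone
# labels: 0 background, 1 transition zone (TZ), 2 peripheral zone (PZ).

ZONE_LABELS <- 0:2

#' Image volume container
#'
#' @param voxels numeric array `(d, h, w)`.
#' @param spacing voxel spacing `(dz, dy, dx)` in mm.
#' @param subject_id identifier string.
#' @return object of class `image_volume`.
#' @export
image_volume <- function(voxels, spacing = c(1, 1, 1), subject_id = "subject") {
  stopifnot(length(dim(voxels)) == 3L, all(dim(voxels) >= 1L))
  structure(list(voxels = voxels, spacing = as.double(spacing),
                 subject_id = subject_id), class = "image_volume")
}

#' Zonal label mask container
#'
#' @param labels integer array `(d, h, w)` with values in `{0, 1, 2}`.
#' @inheritParams image_volume
#' @return object of class `zone_mask`.
#' @export
zone_mask <- function(labels, spacing = c(1, 1, 1), subject_id = "subject") {
  stopifnot(length(dim(labels)) == 3L)
  bad <- setdiff(unique(as.vector(labels)), ZONE_LABELS)
  if (length(bad) > 0L) {
    stop("mask contains labels outside {0,1,2}: {",
         paste(sort(bad), collapse = ","), "}")
  }
  storage.mode(labels) <- "integer"
  structure(list(labels = labels, spacing = as.double(spacing),
                 subject_id = subject_id), class = "zone_mask")
}

#' @export
print.image_volume <- function(x, ...) {
  cat("<image_volume ", x$subject_id, " [", paste(dim(x$voxels), collapse = "x"),
      "] range [", round(min(x$voxels), 2), ",", round(max(x$voxels), 2),
      "]>\n", sep = "")
  invisible(x)
}

#' @export
print.zone_mask <- function(x, ...) {
  cat("<zone_mask ", x$subject_id, " [", paste(dim(x$labels), collapse = "x"),
      "] labels {", paste(sort(unique(as.vector(x$labels))), collapse = ","),
      "}>\n", sep = "")
  invisible(x)
}

#' Load a volume or mask from disk
#'
#' Reads a NIfTI file and normalizes the axis order to `(d, h, w)` (NIfTI
#' stores x fastest; the slice axis z comes last on disk).  Masks are cast to
#' integer and validated against the zonal label set.
#'
#' @param path NIfTI file (`.nii` / `.nii.gz`).
#' @param kind `"image"` or `"mask"`.
#' @return [image_volume] or [zone_mask].
#' @export
load_volume <- function(path, kind = c("image", "mask")) {
  kind <- match.arg(kind)
  if (dir.exists(path)) {
    stop("DICOM series directories are not supported by this build; ",
         "convert to NIfTI first")
  }
  if (!file.exists(path)) stop("file not found: ", path)
  nii <- read_nifti(path)
  arr <- nii$data
  if (length(dim(arr)) == 2L) dim(arr) <- c(dim(arr), 1L)
  if (length(dim(arr)) > 3L) {
    extra <- dim(arr)[-(1:3)]
    if (any(extra != 1L)) stop("expected a 3-d volume, got dim [",
                               paste(dim(arr), collapse = ","), "] in ", path)
    dim(arr) <- dim(arr)[1:3]
  }
  vox <- aperm(arr, c(3L, 2L, 1L)) # (x,y,z) -> (d,h,w)
  spacing <- rev(nii$pixdim)
  sid <- sub("\\.nii(\\.gz)?$", "", basename(path))
  if (kind == "image") {
    image_volume(vox, spacing, sid)
  } else {
    r <- round(vox)
    if (max(abs(vox - r)) > 1e-6) stop("mask is not integer-valued: ", path)
    zone_mask(r, spacing, sid)
  }
}

#' Save a volume or mask to disk as NIfTI
#'
#' @param x [image_volume] or [zone_mask].
#' @param path output `.nii` / `.nii.gz` path.
#' @export
save_volume <- function(x, path) {
  if (inherits(x, "image_volume")) {
    arr <- aperm(x$voxels, c(3L, 2L, 1L))
    write_nifti(arr, path, pixdim = rev(x$spacing), datatype = 16L)
  } else if (inherits(x, "zone_mask")) {
    arr <- aperm(x$labels, c(3L, 2L, 1L))
    write_nifti(arr, path, pixdim = rev(x$spacing), datatype = 4L)
  } else {
    stop("x must be an image_volume or zone_mask")
  }
}

# 1-d resampling index/weight tables, half-pixel centers (matches the
# bilinear kernel used everywhere else in the package).
resample_coords <- function(n_in, n_out) {
  src <- (seq_len(n_out) - 0.5) * n_in / n_out - 0.5
  src <- pmin(pmax(src, 0), n_in - 1)
  i0 <- floor(src)
  list(i0 = as.integer(i0) + 1L, i1 = pmin(as.integer(i0) + 2L, n_in),
       w1 = src - i0, nearest = as.integer(round(src)) + 1L)
}

resample_depth_linear <- function(arr, d_out) {
  d_in <- dim(arr)[1L]
  if (d_in == d_out) return(arr)
  cc <- resample_coords(d_in, d_out)
  out <- array(0, c(d_out, dim(arr)[2L], dim(arr)[3L]))
  for (j in seq_len(d_out)) {
    out[j, , ] <- (1 - cc$w1[j]) * arr[cc$i0[j], , ] + cc$w1[j] * arr[cc$i1[j], , ]
  }
  out
}

resample_depth_nearest <- function(arr, d_out) {
  d_in <- dim(arr)[1L]
  if (d_in == d_out) return(arr)
  cc <- resample_coords(d_in, d_out)
  arr[cc$nearest, , , drop = FALSE]
}

resample_plane <- function(arr, h_out, w_out, nearest = FALSE) {
  h_in <- dim(arr)[2L]; w_in <- dim(arr)[3L]
  if (h_in == h_out && w_in == w_out) return(arr)
  if (nearest) {
    ch <- resample_coords(h_in, h_out)$nearest
    cw <- resample_coords(w_in, w_out)$nearest
    return(arr[, ch, cw, drop = FALSE])
  }
  x <- arr
  dim(x) <- c(1L, dim(arr))
  y <- cpp_resize_bilinear_fwd(x, as.integer(h_out), as.integer(w_out))
  dim(y) <- c(dim(arr)[1L], h_out, w_out)
  y
}

#' Preprocess an image/mask pair
#'
#' Applies the standard pipeline: spatial center crop of
#' `crop_hw` x `crop_hw` (crop start = image center minus half the crop
#' extent), resampling to `target` = `(d, h, w)` (linear for the image,
#' nearest-neighbour for the mask so the label set is untouched), and
#' per-volume min-max normalization of the image to `[0, 255]`.  A constant
#' image maps to all zeros.
#'
#' @param vol [image_volume].
#' @param mask [zone_mask] with the same shape.
#' @param crop_hw in-plane crop extent (default 128).
#' @param target output shape `(d, h, w)`, default `c(20, 128, 128)`.
#' @return list with elements `image` and `mask`.
#' @export
preprocess <- function(vol, mask, crop_hw = 128L, target = c(20L, 128L, 128L)) {
  stopifnot(inherits(vol, "image_volume"), inherits(mask, "zone_mask"))
  dm <- dim(vol$voxels)
  if (!identical(dm, dim(mask$labels))) stop("image and mask shapes differ")
  h <- dm[2L]; w <- dm[3L]
  if (crop_hw > h || crop_hw > w) {
    stop("crop_hw (", crop_hw, ") exceeds input extent (", h, "x", w, ")")
  }
  r0 <- floor(h / 2) - floor(crop_hw / 2) # 0-based, half-open [r0, r0+crop)
  c0 <- floor(w / 2) - floor(crop_hw / 2)
  rows <- (r0 + 1L):(r0 + crop_hw)
  cols <- (c0 + 1L):(c0 + crop_hw)
  img <- vol$voxels[, rows, cols, drop = FALSE]
  lab <- mask$labels[, rows, cols, drop = FALSE]
  img <- resample_plane(img, target[2L], target[3L], nearest = FALSE)
  lab <- resample_plane(lab, target[2L], target[3L], nearest = TRUE)
  img <- resample_depth_linear(img, target[1L])
  lab <- resample_depth_nearest(lab, target[1L])
  rng <- range(img)
  img <- if (rng[2L] > rng[1L]) (img - rng[1L]) / (rng[2L] - rng[1L]) * 255 else img * 0
  sp_scale <- c(dm[1L] / target[1L], crop_hw / target[2L], crop_hw / target[3L])
  spacing <- vol$spacing * sp_scale
  list(image = image_volume(img, spacing, vol$subject_id),
       mask = zone_mask(lab, spacing, mask$subject_id))
}

rot90_once <- function(m) t(m)[, nrow(m):1, drop = FALSE] # (r,c) -> (c, h-1-r)

apply_plane_op <- function(arr, flip, quarter_turns) {
  d <- dim(arr)[1L]
  slices <- lapply(seq_len(d), function(i) {
    m <- arr[i, , ]
    dim(m) <- dim(arr)[2:3]
    if (flip == "horizontal") m <- m[, ncol(m):1, drop = FALSE]
    if (flip == "vertical") m <- m[nrow(m):1, , drop = FALSE]
    if (quarter_turns > 0) for (k in seq_len(quarter_turns)) m <- rot90_once(m)
    m
  })
  out <- array(0, c(d, dim(slices[[1L]])))
  for (i in seq_len(d)) out[i, , ] <- slices[[i]]
  out
}

#' Randomly flip/rotate an image/mask pair
#'
#' Draws one in-plane flip (horizontal / vertical / none) and one right-angle
#' rotation (0/90/180/270 degrees) and applies both identically to image and
#' mask.  Right angles keep masks interpolation-free, so the per-label voxel
#' counts are preserved exactly.  Deterministic given `seed`.  Non-square
#' slices only draw 0/180 rotations.
#'
#' @inheritParams preprocess
#' @param seed integer seed controlling the draw.
#' @return list with elements `image` and `mask`.
#' @export
augment_pair <- function(vol, mask, seed) {
  stopifnot(identical(dim(vol$voxels), dim(mask$labels)))
  square <- dim(vol$voxels)[2L] == dim(vol$voxels)[3L]
  draw <- with_seed(seed, {
    list(flip = sample(c("none", "horizontal", "vertical"), 1L),
         turns = sample(if (square) 0:3 else c(0L, 2L), 1L))
  })
  img <- apply_plane_op(vol$voxels, draw$flip, draw$turns)
  lab <- apply_plane_op(mask$labels, draw$flip, draw$turns)
  list(image = image_volume(img, vol$spacing, vol$subject_id),
       mask = zone_mask(lab, mask$spacing, mask$subject_id))
}

#' Double a dataset by augmentation
#'
#' Emits one augmented copy per original pair, each with a per-sample seed
#' derived deterministically from `seed`.
#'
#' @param pairs list of `list(image =, mask =)` pairs.
#' @param seed global integer seed.
#' @return list of length `2 * length(pairs)` (originals first).
#' @export
augment_dataset <- function(pairs, seed) {
  sub_seeds <- with_seed(seed, sample.int(2^31 - 1, length(pairs)))
  aug <- lapply(seq_along(pairs), function(i) {
    p <- augment_pair(pairs[[i]]$image, pairs[[i]]$mask, sub_seeds[i])
    p$image$subject_id <- paste0(p$image$subject_id, "_aug")
    p$mask$subject_id <- paste0(p$mask$subject_id, "_aug")
    p
  })
  c(pairs, aug)
}

#' Write per-subject metrics and per-class summaries to CSV
#'
#' One row per (subject, class) with DSC, IoU and MSD, followed by summary
#' rows per class: `mean`, `sd` (population SD) and `worst_case` (minimum
#' DSC/IoU, maximum MSD).
#'
#' @param records data frame from [evaluate_network()] (columns `subject_id`,
#'   `class`, `dsc`, `iou`, `msd`, `flags`).
#' @param path output CSV path.
#' @return the full data frame (rows + summaries), invisibly.
#' @export
export_metrics <- function(records, path) {
  if (is.null(records) || NROW(records) == 0L) stop("no metrics records to export")
  records <- as.data.frame(records)
  need <- c("subject_id", "class", "dsc", "iou", "msd", "flags")
  stopifnot(all(need %in% names(records)))
  records <- records[, need]
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  summaries <- do.call(rbind, lapply(split(records, records$class), function(g) {
    data.frame(
      subject_id = c("mean", "sd", "worst_case"),
      class = g$class[1L],
      dsc = c(mean(g$dsc), pop_sd(g$dsc), min(g$dsc)),
      iou = c(mean(g$iou), pop_sd(g$iou), min(g$iou)),
      msd = c(mean(g$msd, na.rm = TRUE),
              pop_sd(g$msd[!is.na(g$msd)]),
              suppressWarnings(max(g$msd, na.rm = TRUE))),
      flags = "",
      stringsAsFactors = FALSE
    )
  }))
  out <- rbind(records, summaries)
  rownames(out) <- NULL
  utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Seeds the R RNG, evaluates `expr`, and restores the caller's stream, so
#' seeded construction (e.g. of network weights) never perturbs outer
#' randomness.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  expr
}
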