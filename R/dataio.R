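#' Cine slice container
#'
#' A short-axis cine slice of three-directional velocity-mapping CMR: a
#' 4-channel image time series with channel order (magnitude, v_x, v_y, v_z),
#' where `v_x` is the physical rightward and `v_y` the physical upward
#' in-plane velocity component and `v_z` the through-plane component, all in
#' cm/s.
#'
#' @param frames Numeric array `[H, W, T, 4]`.
#' @param pixel_spacing_mm Length-2 pixel spacing (x, y) in mm.
#' @param rr_ms Cardiac cycle duration in ms.
#' @param slice_id,subject_id Identifiers.
#' @return An object of class `mvm_cine_slice`.
#' @export
cine_slice <- function(frames, pixel_spacing_mm, rr_ms,
                       slice_id = "slice001", subject_id = "sub01") {
  d <- dim(frames)
  if (length(d) != 4L || d[4] != 4L) {
    data_error("frames must be an [H, W, T, 4] array (magnitude + 3 phase channels)")
  }
  if (d[1] < 16L || d[2] < 16L || d[3] < 1L) {
    data_error("frames must have H, W >= 16 and T >= 1")
  }
  if (!all(is.finite(frames))) data_error("frames contain non-finite values")
  if (length(pixel_spacing_mm) == 1L) pixel_spacing_mm <- rep(pixel_spacing_mm, 2)
  if (any(pixel_spacing_mm <= 0) || rr_ms <= 0) {
    data_error("pixel_spacing_mm and rr_ms must be positive")
  }
  structure(list(frames = frames, pixel_spacing_mm = pixel_spacing_mm,
                 rr_ms = rr_ms, slice_id = slice_id, subject_id = subject_id),
            class = "mvm_cine_slice")
}

#' @export
print.mvm_cine_slice <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<mvm_cine_slice %s/%s: %dx%d px, %d frames, 4 channels, RR %.0f ms>\n",
              x$subject_id, x$slice_id, d[1], d[2], d[3], x$rr_ms))
  invisible(x)
}

#' Myocardium mask container
#'
#' A per-frame binary left-ventricular myocardium ring mask.
#'
#' @param labels Integer array `[H, W, T]` with values 0/1.
#' @param provenance One of `"manual"`, `"model"`, `"postprocessed"`.
#' @return An object of class `mvm_myo_mask`.
#' @export
myo_mask <- function(labels, provenance = c("manual", "model", "postprocessed")) {
  provenance <- match.arg(provenance)
  if (length(dim(labels)) == 2L) labels <- array(labels, c(dim(labels), 1L))
  if (length(dim(labels)) != 3L) data_error("labels must be an [H, W, T] array")
  if (!all(labels %in% c(0L, 1L))) data_error("mask labels must be binary (0/1)")
  storage.mode(labels) <- "integer"
  structure(list(labels = labels, provenance = provenance),
            class = "mvm_myo_mask")
}

#' @export
print.mvm_myo_mask <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<mvm_myo_mask: %dx%d px, %d frames, provenance=%s>\n",
              d[1], d[2], d[3], x$provenance))
  invisible(x)
}

sidecar_path <- function(path) {
  sub("\\.nii(\\.gz)?$", ".json", path)
}

#' Read and write cine slices as NIfTI
#'
#' A cine slice is stored as one 4-D NIfTI file, shape `[H, W, T, 4]`, in
#' double precision so the round trip is lossless, with spacing in the NIfTI
#' header (`pixdim` 1--2 spatial, 3 the frame interval `rr_ms / T`).  The
#' identifiers and exact timing metadata live in a small JSON sidecar next to
#' the image (same name, `.json` extension).
#'
#' @param slice An [cine_slice()] object.
#' @param path Output `.nii.gz` path.
#' @return `write_cine_slice` returns `path` invisibly; `read_cine_slice`
#'   returns an `mvm_cine_slice`.
#' @export
write_cine_slice <- function(slice, path) {
  stopifnot(inherits(slice, "mvm_cine_slice"))
  d <- dim(slice$frames)
  img <- RNifti::asNifti(slice$frames,
                         pixdim = c(slice$pixel_spacing_mm[1],
                                    slice$pixel_spacing_mm[2],
                                    slice$rr_ms / d[3], 1))
  RNifti::writeNifti(img, path, datatype = "double")
  jsonlite::write_json(
    list(slice_id = slice$slice_id, subject_id = slice$subject_id,
         rr_ms = slice$rr_ms, pixel_spacing_mm = slice$pixel_spacing_mm,
         n_frames = d[3]),
    sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_cine_slice
#' @export
read_cine_slice <- function(path) {
  if (!file.exists(path)) data_error(paste0("no such file: ", path))
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L) {
    format_error("cine slice must be a 4-D NIfTI [H, W, T, channels]", "dim")
  }
  if (d[4] != 4L) {
    format_error(sprintf("expected 4 channels (magnitude + 3 phase), found %d", d[4]),
                 "channels")
  }
  pd <- RNifti::pixdim(img)
  if (length(pd) < 2L || any(!is.finite(pd[1:2])) || any(pd[1:2] <= 0)) {
    format_error("missing or invalid pixel spacing in NIfTI header", "pixdim")
  }
  sc <- sidecar_path(path)
  if (!file.exists(sc)) {
    format_error("missing JSON sidecar with slice metadata", "sidecar")
  }
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  if (is.null(meta$rr_ms)) format_error("sidecar lacks rr_ms", "rr_ms")
  cine_slice(array(as.numeric(img), d),
             pixel_spacing_mm = pd[1:2], rr_ms = meta$rr_ms,
             slice_id = meta$slice_id %||% basename(path),
             subject_id = meta$subject_id %||% "unknown")
}

#' Read and write myocardium masks as NIfTI
#'
#' Masks are stored as uint8 NIfTI `[H, W, T]` with the provenance recorded
#' in a JSON sidecar.
#'
#' @param mask An [myo_mask()] object.
#' @param path Output `.nii.gz` path.
#' @export
write_myo_mask <- function(mask, path) {
  stopifnot(inherits(mask, "mvm_myo_mask"))
  RNifti::writeNifti(RNifti::asNifti(mask$labels), path, datatype = "uint8")
  jsonlite::write_json(list(provenance = mask$provenance),
                       sidecar_path(path), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_myo_mask
#' @export
read_myo_mask <- function(path) {
  if (!file.exists(path)) data_error(paste0("no such file: ", path))
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (!length(d) %in% c(2L, 3L)) format_error("mask must be 2-D or 3-D", "dim")
  prov <- "model"
  sc <- sidecar_path(path)
  if (file.exists(sc)) {
    meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
    prov <- meta$provenance %||% "model"
  }
  myo_mask(array(as.integer(img), if (length(d) == 2L) c(d, 1L) else d),
           provenance = prov)
}

#' Apply a flip/rotation augmentation to a frame and its mask
#'
#' Applies the same geometric transform to an image frame and its mask: an
#' optional horizontal (left-right) flip followed by a counter-clockwise
#' rotation about the image centre with zero padding.  The image is resampled
#' bilinearly; the mask with nearest-neighbour interpolation so it stays
#' binary.
#'
#' @param frame Numeric array `[H, W, C]` (or matrix).
#' @param mask Binary matrix `[H, W]`.
#' @param flip Logical, apply horizontal flip.
#' @param angle_deg Rotation angle in degrees.
#' @return A list with elements `frame` and `mask`.
#' @export
apply_augmentation <- function(frame, mask, flip, angle_deg) {
  if (is.matrix(frame)) frame <- array(frame, c(dim(frame), 1L))
  if (!identical(dim(frame)[1:2], dim(mask))) {
    data_error("frame and mask shapes disagree")
  }
  if (flip) {
    frame <- frame[, rev(seq_len(dim(frame)[2])), , drop = FALSE]
    mask <- mask[, rev(seq_len(ncol(mask))), drop = FALSE]
  }
  if (angle_deg != 0) {
    frame <- rotate_stack(frame, angle_deg, TRUE)
    mask <- rotate_stack(array(as.numeric(mask), c(dim(mask), 1L)),
                         angle_deg, FALSE)[, , 1]
  }
  list(frame = frame, mask = as_mask_frame(round(mask)))
}

#' Randomly augment a frame/mask pair
#'
#' Draws a horizontal flip with probability 0.5 and a rotation angle
#' uniformly from `[0, 90]` degrees using the current R random number
#' stream, then applies both via [apply_augmentation()].
#'
#' @inheritParams apply_augmentation
#' @return A list with `frame`, `mask`, and the drawn `flip` and `angle_deg`.
#' @export
augment_frame <- function(frame, mask) {
  flip <- stats::runif(1) < 0.5
  angle <- stats::runif(1, 0, 90)
  out <- apply_augmentation(frame, mask, flip, angle)
  out$flip <- flip
  out$angle_deg <- angle
  out
}

#' Assemble the training pool of original and augmented frames
#'
#' Each cine slice is augmented `n_aug` times (one flip/rotation draw per
#' slice copy, shared by all frames of that copy) and the augmented copies
#' are stacked with the originals, giving `(n_aug + 1) * sum(T)` pooled
#' frames.  Frames are materialised lazily through [pool_frame()], so the
#' pool itself is only a manifest.
#'
#' @param slices One of: an `mvm_phantom`-style tibble with list columns
#'   `slice` and `mask`; a list of [cine_slice()] objects; or an index-only
#'   manifest tibble with columns `slice_id` and `n_frames` (counting only,
#'   frames cannot be materialised).
#' @param n_aug Number of augmented copies per slice (>= 0).
#' @param seed Integer seed for the augmentation draws.
#' @return An object of class `mvm_pool` with a `manifest` tibble
#'   (`idx`, `slice_id`, `frame`, `aug_id`, `flip`, `angle_deg`).
#' @export
build_training_pool <- function(slices, n_aug = 4L, seed = 1L) {
  if (n_aug < 0L) data_error("n_aug must be >= 0")
  slice_list <- NULL
  mask_list <- NULL
  if (is.data.frame(slices) && "slice" %in% names(slices)) {
    slice_list <- stats::setNames(slices$slice,
                                  purrr::map_chr(slices$slice, "slice_id"))
    if ("mask" %in% names(slices)) {
      mask_list <- stats::setNames(slices$mask, names(slice_list))
    }
    index <- tibble::tibble(
      slice_id = names(slice_list),
      n_frames = purrr::map_int(slice_list, ~ dim(.x$frames)[3])
    )
  } else if (is.data.frame(slices)) {
    if (!all(c("slice_id", "n_frames") %in% names(slices))) {
      data_error("index manifest needs columns slice_id and n_frames")
    }
    index <- tibble::as_tibble(slices[, c("slice_id", "n_frames")])
  } else if (is.list(slices) && length(slices) > 0 &&
             inherits(slices[[1]], "mvm_cine_slice")) {
    slice_list <- stats::setNames(slices, purrr::map_chr(slices, "slice_id"))
    index <- tibble::tibble(
      slice_id = names(slice_list),
      n_frames = purrr::map_int(slice_list, ~ dim(.x$frames)[3])
    )
  } else {
    data_error("empty or unrecognised slice input")
  }
  if (nrow(index) == 0L) data_error("no slices to pool")

  draws <- with_seed(seed, {
    tidyr::expand_grid(slice_id = index$slice_id, aug_id = seq_len(n_aug)) |>
      dplyr::mutate(flip = stats::runif(dplyr::n()) < 0.5,
                    angle_deg = stats::runif(dplyr::n(), 0, 90))
  })
  manifest <- index |>
    dplyr::mutate(aug_id = 0L, flip = FALSE, angle_deg = 0) |>
    dplyr::bind_rows(dplyr::left_join(draws, index, by = "slice_id")) |>
    tidyr::uncount(.data$n_frames, .id = "frame") |>
    dplyr::arrange(.data$aug_id, .data$slice_id, .data$frame) |>
    dplyr::mutate(idx = dplyr::row_number()) |>
    dplyr::select("idx", "slice_id", "frame", "aug_id", "flip", "angle_deg")

  mag_max <- if (!is.null(slice_list)) {
    purrr::map_dbl(slice_list, ~ max(abs(.x$frames[, , , 1]), 1e-12))
  }
  structure(list(manifest = manifest, slices = slice_list, masks = mask_list,
                 mag_max = mag_max, n_aug = as.integer(n_aug), seed = seed),
            class = "mvm_pool")
}

#' @export
print.mvm_pool <- function(x, ...) {
  cat(sprintf("<mvm_pool: %d frames (%d slices x (1 + %d augmentations))%s>\n",
              nrow(x$manifest), length(unique(x$manifest$slice_id)), x$n_aug,
              if (is.null(x$slices)) ", index only" else ""))
  invisible(x)
}

#' Number of frames in a training pool
#' @param pool An `mvm_pool`.
#' @return Integer frame count.
#' @export
pool_size <- function(pool) nrow(pool$manifest)

#' Materialise one pooled frame
#'
#' @param pool An `mvm_pool` built from actual slices.
#' @param i Frame index into the pool manifest.
#' @return A list with the 4-channel `frame` (`[H, W, 4]`), its binary
#'   `mask` (or `NULL` if the pool has no masks), and the manifest row.
#' @export
pool_frame <- function(pool, i) {
  if (is.null(pool$slices)) {
    data_error("index-only pool: frames cannot be materialised")
  }
  row <- pool$manifest[i, ]
  sl <- pool$slices[[row$slice_id]]
  fr <- sl$frames[, , row$frame, , drop = TRUE]
  mk <- if (!is.null(pool$masks)) {
    pool$masks[[row$slice_id]]$labels[, , row$frame]
  }
  if (row$aug_id > 0L) {
    if (is.null(mk)) mk <- matrix(0L, dim(fr)[1], dim(fr)[2])
    aug <- apply_augmentation(fr, mk, row$flip, row$angle_deg)
    fr <- aug$frame
    mk <- aug$mask
  }
  list(frame = fr, mask = mk, info = row)
}

#' Build a k-fold cross-validation split over cine slices
#'
#' Slices are shuffled deterministically and partitioned into `k` folds whose
#' sizes differ by at most one.  Validation always uses the original frames
#' of the held-out slices only; augmented copies never cross folds because
#' pools are built per fold from the training slices alone.
#'
#' @param slice_ids Character vector of slice identifiers.
#' @param k Number of folds (>= 2).
#' @param seed Integer seed.
#' @return A tibble (`slice_id`, `fold`) with folds numbered `1..k`.
#' @export
make_cv_folds <- function(slice_ids, k = 5L, seed = 1L) {
  n <- length(slice_ids)
  if (k < 2L) data_error("k must be >= 2")
  if (n < k) data_error("more folds than slices")
  sizes <- rep(n %/% k, k) + (seq_len(k) <= n %% k)
  with_seed(seed, {
    perm <- sample(slice_ids)
  })
  tibble::tibble(slice_id = perm,
                 fold = rep(seq_len(k), times = sizes)) |>
    dplyr::arrange(.data$slice_id)
}

#' Assert that a training pool excludes held-out slices
#'
#' Guards against data leakage: errors if any held-out slice identifier
#' appears in the pool manifest.
#'
#' @param pool An `mvm_pool`.
#' @param heldout_ids Slice identifiers of the validation set.
#' @return Invisibly `TRUE` if the pool is clean.
#' @export
audit_pool_leakage <- function(pool, heldout_ids) {
  bad <- intersect(unique(pool$manifest$slice_id), heldout_ids)
  if (length(bad) > 0) {
    data_error(paste0("data leakage: held-out slices present in training pool: ",
                      paste(bad, collapse = ", ")))
  }
  invisible(TRUE)
}
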