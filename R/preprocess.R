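# Intensity normalization, cropping/resizing, sliding-window patch
# extraction with overlap-averaged reassembly, stratified fold planning, and
# flip augmentation. Patch origins are 0-based voxel corners in (x, y, z)
# array order; the full grid along each axis is {0, stride, ..., edge - patch}.

#' Min-max intensity normalization to [0, 1]
#'
#' `(x - min) / (max - min)`; the minimum maps to 0 and the maximum to 1.
#' A constant volume has a degenerate range and raises an error rather than
#' silently returning zeros.
#' @param volume a `volume` or 3-D array.
#' @return same type as the input.
#' @export
minmax_normalize <- function(volume) {
  x <- volume_data(volume)
  rng <- range(x)
  if (rng[1] == rng[2]) stop("degenerate intensity range: volume is constant")
  y <- (x - rng[1]) / (rng[2] - rng[1])
  if (inherits(volume, "volume")) new_volume(y, volume$modality) else y
}

#' Crop away all-zero boundary slabs and resize to a target cube
#'
#' Removes all-zero slabs from each face of the volume, then trilinearly
#' resizes the remaining box to `target_edge^3`. When the cropped content is
#' already the target size no resampling occurs (exact crop).
#' @param volume a `volume` or 3-D array.
#' @param target_edge output edge length.
#' @export
crop_resize <- function(volume, target_edge) {
  x <- volume_data(volume)
  if (all(x == 0)) stop("cannot crop an all-zero volume")
  keep <- function(margin) {
    nz <- apply(x != 0, margin, any)
    seq.int(which(nz)[1L], rev(which(nz))[1L])
  }
  x <- x[keep(1L), keep(2L), keep(3L), drop = FALSE]
  y <- resize_trilinear(x, as.integer(target_edge))
  if (inherits(volume, "volume")) new_volume(y, volume$modality) else y
}

# Separable trilinear resize with align-corners coordinates (identity when
# input and output sizes agree).
resize_trilinear <- function(x, target) {
  along <- function(a, axis) {
    d <- dim(a)
    e <- d[axis]
    if (e == target) return(a)
    A <- interp_matrix(e, target)
    p <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
    b <- aperm(a, p)
    b <- array(A %*% matrix(b, nrow = e), c(target, dim(b)[2:3]))
    aperm(b, order(p))
  }
  along(along(along(x, 1L), 2L), 3L)
}

interp_matrix <- function(from, to) {
  A <- matrix(0, to, from)
  if (to == 1L) { A[1, ] <- 1 / from; return(A) }
  s <- if (from == 1L) rep(1, to) else 1 + (seq_len(to) - 1) * (from - 1) / (to - 1)
  lo <- pmin(floor(s), from - 1L); hi <- lo + 1L; w <- s - lo
  for (i in seq_len(to)) {
    A[i, lo[i]] <- A[i, lo[i]] + (1 - w[i])
    A[i, hi[i]] <- A[i, hi[i]] + w[i]
  }
  A
}

#' Extract the full sliding-window grid of cubic patches
#'
#' With edge `E`, patch `P` and stride `S`, requires `(E - P) %% S == 0` and
#' returns `((E - P)/S + 1)^3` patches; the reference geometry (128, 64, 32)
#' yields 27 per volume, 54 per MRI+PET pair. Indivisible geometry is an
#' error, not silent truncation, so reassembly stays exact.
#'
#' @param volume a `volume` or 3-D cubic array.
#' @param patch_size patch edge length.
#' @param stride window step.
#' @return object of class `patchset` with `patches`, 0-based `origins`,
#'   `patch_size`, `stride` and `source_shape`.
#' @export
extract_patches <- function(volume, patch_size, stride) {
  x <- volume_data(volume)
  e <- dim(x)[1L]
  stopifnot(length(unique(dim(x))) == 1L)
  patch_size <- as.integer(patch_size); stride <- as.integer(stride)
  if (patch_size > e) stop("patch size exceeds volume edge")
  if ((e - patch_size) %% stride != 0L) {
    stop(sprintf("indivisible patch geometry: (%d - %d) not a multiple of %d",
                 e, patch_size, stride))
  }
  offs <- seq.int(0L, e - patch_size, by = stride)
  origins <- as.matrix(expand.grid(x = offs, y = offs, z = offs))
  patches <- lapply(seq_len(nrow(origins)), function(i) {
    o <- origins[i, ]
    x[o[1] + seq_len(patch_size), o[2] + seq_len(patch_size),
      o[3] + seq_len(patch_size), drop = FALSE]
  })
  structure(list(patches = patches, origins = unname(origins),
                 patch_size = patch_size, stride = stride,
                 source_shape = e),
            class = "patchset")
}

#' Reassemble a volume from overlapping patches by overlap averaging
#'
#' Each voxel is the arithmetic mean of all patch values covering it, so
#' `reassemble(extract_patches(v, ...))` reproduces `v` exactly.
#' @param patchset a `patchset`.
#' @return 3-D array of edge `source_shape`.
#' @export
reassemble <- function(patchset) {
  stopifnot(inherits(patchset, "patchset"))
  e <- patchset$source_shape; p <- patchset$patch_size
  if (length(patchset$patches) != nrow(patchset$origins)) {
    stop("patches and origins lengths differ")
  }
  acc <- array(0, c(e, e, e)); cnt <- array(0, c(e, e, e))
  for (i in seq_along(patchset$patches)) {
    o <- patchset$origins[i, ]
    if (any(o < 0L) || any(o + p > e)) stop("patch origin outside source volume")
    pt <- patchset$patches[[i]]
    if (!all(dim(pt) == p)) stop("inconsistent patch shape")
    ix <- o[1] + seq_len(p); iy <- o[2] + seq_len(p); iz <- o[3] + seq_len(p)
    acc[ix, iy, iz] <- acc[ix, iy, iz] + pt
    cnt[ix, iy, iz] <- cnt[ix, iy, iz] + 1
  }
  if (any(cnt == 0)) stop("patch grid does not cover the volume")
  acc / cnt
}

#' Stratified fold plan over a cohort
#'
#' `protocol = "incomplete"`: paired subjects are split into `k` stratified
#' subsets (per-class sizes differing by at most 1) and every unpaired
#' subject is tagged as test. `protocol = "complete"`: paired and unpaired
#' subjects are pooled and stratified into `k` subsets; at
#' [apply_folds()] time the held-out subset contributes its paired members
#' to validation and its unpaired members to test.
#'
#' @param cohort a `cohort`.
#' @param k number of subsets.
#' @param protocol `"incomplete"` or `"complete"`.
#' @param seed RNG seed for the shuffle.
#' @return object of class `fold_plan`.
#' @export
make_folds <- function(cohort, k = 10L, protocol = c("incomplete", "complete"),
                       seed = 1L) {
  protocol <- match.arg(protocol)
  k <- as.integer(k)
  stopifnot(k >= 2L)
  labels <- cohort_labels(cohort)
  paired <- cohort_paired(cohort)
  ids <- vapply(cohort$subjects, function(s) s$subject_id, character(1))
  pool <- if (protocol == "incomplete") paired else rep(TRUE, length(ids))
  assignments <- stats::setNames(rep(NA_integer_, length(ids)), ids)
  with_seed(seed, {
    for (cl in c(0L, 1L)) {
      sel <- which(pool & labels == cl)
      if (length(sel) < k) {
        stop(sprintf("class %d has %d subjects in the partitioned pool; need >= k = %d",
                     cl, length(sel), k))
      }
      sel <- sample(sel)
      assignments[sel] <- rep(seq_len(k), length.out = length(sel))
    }
  })
  structure(list(k = k, assignments = assignments, protocol = protocol,
                 seed = as.integer(seed)),
            class = "fold_plan")
}

#' Apply a fold plan: tag each subject train / validation / test
#'
#' @param cohort a `cohort`.
#' @param plan a `fold_plan`.
#' @param val_fold index of the held-out subset.
#' @return the cohort with `split_tag` set on every subject.
#' @export
apply_folds <- function(cohort, plan, val_fold = plan$k) {
  stopifnot(inherits(plan, "fold_plan"), val_fold >= 1L, val_fold <= plan$k)
  paired <- cohort_paired(cohort)
  for (i in seq_along(cohort$subjects)) {
    s <- cohort$subjects[[i]]
    f <- plan$assignments[[s$subject_id]]
    tag <- if (plan$protocol == "incomplete") {
      if (!paired[i]) "test" else if (f == val_fold) "validation" else "train"
    } else {
      if (f != val_fold) "train" else if (paired[i]) "validation" else "test"
    }
    cohort$subjects[[i]]$split_tag <- tag
  }
  cohort
}

#' Serialize a fold plan to CSV (subject_id, fold, split_tag).
#' @export
write_fold_plan <- function(plan, cohort, path, val_fold = plan$k) {
  tagged <- apply_folds(cohort, plan, val_fold)
  df <- data.frame(subject_id = names(plan$assignments),
                   fold = unname(plan$assignments),
                   split_tag = cohort_tags(tagged),
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

flip_axis <- function(x, axis) {
  e <- dim(x)[axis]
  switch(axis,
         `1` = x[e:1, , , drop = FALSE],
         `2` = x[, e:1, , drop = FALSE],
         `3` = x[, , e:1, drop = FALSE])
}

#' Random flip augmentation
#'
#' Independently flips the volume along each listed axis with the given
#' probability. The first two array axes are the "horizontal" and "vertical"
#' flips; the third axis is never flipped by default. Use
#' [augment_flip_subject()] to apply one draw identically to both modalities
#' of a subject.
#' @param volume a `volume` or 3-D array.
#' @param axes axes eligible for flipping.
#' @param probability per-axis flip probability.
#' @param flips optional logical vector overriding the random draw.
#' @export
augment_flip <- function(volume, axes = c(1L, 2L), probability = 0.5, flips = NULL) {
  stopifnot(probability >= 0, probability <= 1)
  x <- volume_data(volume)
  if (is.null(flips)) flips <- stats::runif(length(axes)) < probability
  for (j in seq_along(axes)) if (flips[j]) x <- flip_axis(x, as.integer(axes[j]))
  if (inherits(volume, "volume")) new_volume(x, volume$modality) else x
}

#' @rdname augment_flip
#' @param subject a cohort subject (list with `mri` and optionally `pet`).
#' @export
augment_flip_subject <- function(subject, axes = c(1L, 2L), probability = 0.5) {
  flips <- stats::runif(length(axes)) < probability
  subject$mri <- augment_flip(subject$mri, axes, flips = flips)
  if (!is.null(subject$pet)) subject$pet <- augment_flip(subject$pet, axes, flips = flips)
  subject
}
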