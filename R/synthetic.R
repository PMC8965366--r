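# Synthetic two-class 3-D cohort generator. Emulates the statistical
# structure the pipeline assumes: a paired subset (MRI + PET) and a
# PET-missing unpaired subset, a smooth monotone voxelwise MRI->PET relation,
# class-dependent signal confined to designated lesion regions (stronger in
# PET, 25% strength in MRI), Gaussian-smoothed background texture on a fixed
# radial anatomy, and additive PET noise. The clean (noise-free) PET is kept
# on each paired/unpaired subject so oracle tests can measure a generator
# against ground truth.

#' Synthetic cohort configuration
#'
#' @param volume_size cubic edge length in voxels.
#' @param n_paired_per_class paired (MRI+PET) subjects per class.
#' @param n_unpaired_per_class MRI-only subjects per class (PET withheld);
#'   under the `"imbalanced"` policy this sets the total `2 * n` which is then
#'   split roughly 27:76 between classes.
#' @param smoothness Gaussian kernel width (voxels) of the background texture.
#' @param crossmodal_gain,crossmodal_offset parameters of the voxelwise map
#'   `PET_clean = gain * g(MRI) + offset`.
#' @param crossmodal_map `"squash"` (smooth monotone logistic curve) or
#'   `"identity"`.
#' @param effect_size mean intensity added to PET inside lesion regions for
#'   class 1; MRI receives 25% of it.
#' @param lesion_regions list of `list(center = c(x, y, z), radius = r)` in
#'   voxel units; `NULL` places two spheres at fixed fractional positions.
#' @param noise_sd standard deviation of additive Gaussian PET noise.
#' @param missing_label_policy `"balanced"` or `"imbalanced"` class ratio for
#'   the unpaired subset.
#' @param seed integer; identical (config, seed) gives a bit-identical cohort.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(volume_size = 16L,
                             n_paired_per_class = 8L,
                             n_unpaired_per_class = 4L,
                             smoothness = 2,
                             crossmodal_gain = 1,
                             crossmodal_offset = 0,
                             crossmodal_map = c("squash", "identity"),
                             effect_size = 0.15,
                             lesion_regions = NULL,
                             noise_sd = 0.02,
                             missing_label_policy = c("balanced", "imbalanced"),
                             seed = 1L) {
  crossmodal_map <- match.arg(crossmodal_map)
  missing_label_policy <- match.arg(missing_label_policy)
  volume_size <- as.integer(volume_size)
  stopifnot(volume_size >= 4L, n_paired_per_class >= 0L, n_unpaired_per_class >= 0L,
            effect_size >= 0, noise_sd >= 0, smoothness > 0)
  if (is.null(lesion_regions)) {
    e <- volume_size
    lesion_regions <- list(
      list(center = round(e * c(0.35, 0.35, 0.40)), radius = max(1.5, 0.16 * e)),
      list(center = round(e * c(0.62, 0.60, 0.55)), radius = max(1.2, 0.12 * e)))
  }
  for (lr in lesion_regions) {
    if (length(lr$center) != 3L || lr$radius <= 0) {
      stop("each lesion region needs a 3-vector center and a positive radius")
    }
    if (any(lr$center - lr$radius < 1) || any(lr$center + lr$radius > volume_size)) {
      stop("lesion region extends outside the volume")
    }
  }
  structure(list(volume_size = volume_size,
                 n_paired_per_class = as.integer(n_paired_per_class),
                 n_unpaired_per_class = as.integer(n_unpaired_per_class),
                 smoothness = smoothness,
                 crossmodal_gain = crossmodal_gain,
                 crossmodal_offset = crossmodal_offset,
                 crossmodal_map = crossmodal_map,
                 effect_size = effect_size,
                 lesion_regions = lesion_regions,
                 noise_sd = noise_sd,
                 missing_label_policy = missing_label_policy,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' A single-modality 3-D volume with metadata
#' @param data 3-D intensity array (cube).
#' @param modality `"MRI"` or `"PET"`.
#' @export
new_volume <- function(data, modality) {
  stopifnot(length(dim(data)) == 3L, length(unique(dim(data))) == 1L,
            modality %in% c("MRI", "PET"))
  structure(list(data = data, modality = modality,
                 intensity_range = range(data)),
            class = "volume")
}

#' @export
print.volume <- function(x, ...) {
  cat(sprintf("<volume> %s %dx%dx%d, range [%.4f, %.4f]\n", x$modality,
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3],
              x$intensity_range[1], x$intensity_range[2]))
  invisible(x)
}

volume_data <- function(v) if (inherits(v, "volume")) v$data else v

# Separable Gaussian smoothing of a cubic array (truncated, renormalized).
gauss_smooth3d <- function(x, sigma) {
  e <- dim(x)[1L]
  r <- max(1L, ceiling(3 * sigma))
  K <- outer(seq_len(e), seq_len(e), function(i, j) {
    w <- stats::dnorm(j - i, sd = sigma)
    w * (abs(j - i) <= r)
  })
  K <- K / rowSums(K)
  along <- function(a, axis) {
    p <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
    b <- aperm(a, p)
    b <- array(K %*% matrix(b, nrow = e), dim(b))
    aperm(b, order(p))
  }
  along(along(along(x, 1), 2), 3)
}

lesion_mask <- function(config) {
  e <- config$volume_size
  g <- expand.grid(x = seq_len(e), y = seq_len(e), z = seq_len(e))
  m <- rep(FALSE, nrow(g))
  for (lr in config$lesion_regions) {
    d2 <- (g$x - lr$center[1])^2 + (g$y - lr$center[2])^2 + (g$z - lr$center[3])^2
    m <- m | (d2 <= lr$radius^2)
  }
  array(as.numeric(m), c(e, e, e))
}

crossmodal_g <- function(v, map) {
  switch(map,
         identity = v,
         squash = 1 / (1 + exp(-6 * (v - 0.5))),
         stop("unknown cross-modal map"))
}

make_subject <- function(config, id, label, paired, mask) {
  e <- config$volume_size
  ax <- seq_len(e) - (e + 1) / 2
  r2 <- outer(outer(ax^2, ax^2, `+`), ax^2, `+`)
  anat <- exp(-(sqrt(r2) / (0.55 * e))^2)          # fixed radial "anatomy"
  tex <- gauss_smooth3d(array(stats::rnorm(e^3), c(e, e, e)), config$smoothness)
  tex <- tex / max(stats::sd(tex), 1e-12) * 0.12   # per-subject texture
  raw <- anat + tex
  mri <- 0.05 + 0.80 * (raw - min(raw)) / (max(raw) - min(raw))
  if (label == 1L) mri <- mri + 0.25 * config$effect_size * mask
  pet_clean <- config$crossmodal_gain * crossmodal_g(mri, config$crossmodal_map) +
    config$crossmodal_offset
  if (label == 1L) pet_clean <- pet_clean + config$effect_size * mask
  pet <- pet_clean + array(stats::rnorm(e^3, sd = config$noise_sd), c(e, e, e))
  list(subject_id = id, label = label,
       mri = new_volume(mri, "MRI"),
       pet = if (paired) new_volume(pet, "PET") else NULL,
       pet_clean = new_volume(pet_clean, "PET"),
       split_tag = NA_character_)
}

#' Generate a synthetic cohort
#'
#' Produces `2 * n_paired_per_class` paired subjects followed by the MRI-only
#' unpaired subjects. The clean PET (cross-modal map of the MRI plus class
#' signal, before noise) is retained on every subject as ground truth for
#' generator oracles; it is internal and not part of the on-disk manifest.
#'
#' @param config a [synthetic_config()].
#' @return object of class `cohort`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  mask <- lesion_mask(config)
  with_seed(config$seed, {
    subjects <- list()
    i <- 0L
    for (label in c(0L, 1L)) {
      for (j in seq_len(config$n_paired_per_class)) {
        i <- i + 1L
        subjects[[i]] <- make_subject(config, sprintf("S%03d", i), label, TRUE, mask)
      }
    }
    nu <- unpaired_counts(config)
    for (label in c(0L, 1L)) {
      for (j in seq_len(nu[label + 1L])) {
        i <- i + 1L
        subjects[[i]] <- make_subject(config, sprintf("S%03d", i), label, FALSE, mask)
      }
    }
    structure(list(subjects = subjects, config = config), class = "cohort")
  })
}

unpaired_counts <- function(config) {
  n <- config$n_unpaired_per_class
  if (n == 0L) return(c(0L, 0L))
  if (config$missing_label_policy == "balanced") return(c(n, n))
  total <- 2L * n                                   # 27:76 split of the total
  n0 <- max(1L, round(total * 27 / 103))
  c(as.integer(n0), as.integer(total - n0))
}

#' @export
print.cohort <- function(x, ...) {
  lab <- cohort_labels(x)
  paired <- vapply(x$subjects, function(s) !is.null(s$pet), logical(1))
  cat(sprintf("<cohort> %d subjects (%d paired, %d MRI-only); class 0/1: %d/%d; edge %d\n",
              length(x$subjects), sum(paired), sum(!paired),
              sum(lab == 0L), sum(lab == 1L), x$config$volume_size))
  invisible(x)
}

#' @export
cohort_labels <- function(cohort) {
  vapply(cohort$subjects, function(s) s$label, integer(1))
}

#' Subset a cohort by predicate or split tag.
#' @export
cohort_subset <- function(cohort, which) {
  out <- cohort
  out$subjects <- cohort$subjects[which]
  out
}

cohort_paired <- function(cohort) {
  vapply(cohort$subjects, function(s) !is.null(s$pet), logical(1))
}

cohort_tags <- function(cohort) {
  vapply(cohort$subjects, function(s) s$split_tag, character(1))
}

# ---- NIfTI persistence -----------------------------------------------------

#' Write a cohort to a directory of NIfTI volumes plus a CSV manifest
#'
#' One `.nii.gz` file per volume; the manifest has columns subject_id, label,
#' has_pet, mri_path, pet_path. Volumes are stored as float64, so a read
#' round-trip reproduces intensities exactly.
#' @param cohort a `cohort`.
#' @param directory output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
write_cohort <- function(cohort, directory) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(cohort$subjects, function(s) {
    mri_path <- paste0(s$subject_id, "_mri.nii.gz")
    RNifti::writeNifti(RNifti::asNifti(s$mri$data), file.path(directory, mri_path),
                       datatype = "double")
    pet_path <- ""
    if (!is.null(s$pet)) {
      pet_path <- paste0(s$subject_id, "_pet.nii.gz")
      RNifti::writeNifti(RNifti::asNifti(s$pet$data), file.path(directory, pet_path),
                         datatype = "double")
    }
    data.frame(subject_id = s$subject_id, label = s$label,
               has_pet = !is.null(s$pet), mri_path = mri_path,
               pet_path = pet_path, stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  mpath <- file.path(directory, "manifest.csv")
  utils::write.csv(manifest, mpath, row.names = FALSE)
  invisible(mpath)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param directory directory containing `manifest.csv`.
#' @return a `cohort` (without the internal clean-PET ground truth).
#' @export
read_cohort <- function(directory) {
  mpath <- file.path(directory, "manifest.csv")
  if (!file.exists(mpath)) stop("no manifest.csv in ", directory)
  manifest <- utils::read.csv(mpath, stringsAsFactors = FALSE)
  need <- c("subject_id", "label", "has_pet", "mri_path", "pet_path")
  if (!all(need %in% names(manifest))) stop("malformed manifest: missing columns")
  subjects <- lapply(seq_len(nrow(manifest)), function(i) {
    row <- manifest[i, ]
    mf <- file.path(directory, row$mri_path)
    if (!file.exists(mf)) {
      stop("missing MRI file for subject ", row$subject_id)
    }
    mri <- new_volume(as_cube(RNifti::readNifti(mf)), "MRI")
    pet <- NULL
    if (isTRUE(row$has_pet)) {
      pf <- file.path(directory, row$pet_path)
      if (!file.exists(pf)) {
        stop("missing PET file for subject ", row$subject_id)
      }
      pet <- new_volume(as_cube(RNifti::readNifti(pf)), "PET")
    }
    list(subject_id = row$subject_id, label = as.integer(row$label),
         mri = mri, pet = pet, pet_clean = NULL, split_tag = NA_character_)
  })
  structure(list(subjects = subjects, config = NULL), class = "cohort")
}

as_cube <- function(img) {
  a <- array(as.numeric(img), dim(img))
  stopifnot(length(dim(a)) == 3L)
  a
}
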