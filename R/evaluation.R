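# Classification metrics (ACC/SEN/SPE as percentages, AUC as a fraction),
# volumetric image-quality metrics (MSE, PSNR at peak 1, windowed SSIM), and
# Grad-CAM saliency volumes for the fusion classifier.
#
# Conventions fixed here because the source material leaves them open:
# the positive class for sensitivity is class 1 (the LMCI-like class); AUC
# uses the rank (Mann-Whitney) formulation with ties counted 1/2; PSNR uses
# peak 1 on [0,1]-normalized volumes; SSIM uses K1 = 0.01, K2 = 0.03 and a
# uniform 7^3 window over valid positions with unbiased covariance scaling.

#' Two-class classification metrics
#'
#' Accuracy, sensitivity and specificity (percentages, at the given
#' probability threshold; positive class = 1) and AUC (fraction in [0, 1],
#' rank formulation, ties counted one half).
#'
#' @param labels integer vector in \{0, 1\}; both classes must be present.
#' @param probabilities predicted probability of class 1.
#' @param threshold decision threshold (default 0.5).
#' @return object of class `metrics_report`.
#' @export
classification_metrics <- function(labels, probabilities, threshold = 0.5) {
  stopifnot(length(labels) == length(probabilities),
            all(labels %in% c(0L, 1L)),
            all(probabilities >= 0 & probabilities <= 1))
  if (length(unique(labels)) < 2L) {
    stop("AUC undefined: only one class present in labels")
  }
  pred <- as.integer(probabilities >= threshold)
  tp <- sum(pred == 1L & labels == 1L); tn <- sum(pred == 0L & labels == 0L)
  fp <- sum(pred == 1L & labels == 0L); fn <- sum(pred == 0L & labels == 1L)
  npos <- sum(labels == 1L); nneg <- sum(labels == 0L)
  r <- rank(probabilities)                       # midranks handle ties as 1/2
  auc <- (sum(r[labels == 1L]) - npos * (npos + 1) / 2) / (npos * nneg)
  structure(list(acc = 100 * (tp + tn) / length(labels),
                 sen = 100 * tp / (tp + fn),
                 spe = 100 * tn / (tn + fp),
                 auc = auc, n = length(labels), threshold = threshold),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("ACC %.2f%%  SEN %.2f%%  SPE %.2f%%  AUC %.4f  (n = %d, thr = %.2f)\n",
              x$acc, x$sen, x$spe, x$auc, x$n, x$threshold))
  invisible(x)
}

#' Volumetric image-quality metrics between a reference and a synthesis
#'
#' MSE is the mean squared voxel difference; PSNR is `10 log10(1 / MSE)` dB
#' (peak 1; `Inf` when MSE is 0); SSIM is the mean windowed structural
#' similarity (uniform window, valid positions only).
#'
#' @param reference,synthesized same-shape volumes or 3-D arrays with
#'   intensities in [0, 1].
#' @param ssim_window window edge length (default 7).
#' @return list with `mse`, `psnr`, `ssim`.
#' @export
image_metrics <- function(reference, synthesized, ssim_window = 7L) {
  x <- volume_data(reference); y <- volume_data(synthesized)
  if (!all(dim(x) == dim(y))) stop("image_metrics: shape mismatch")
  mse <- mean((x - y)^2)
  psnr <- if (mse == 0) Inf else 10 * log10(1 / mse)
  list(mse = mse, psnr = psnr, ssim = ssim3d(x, y, window = ssim_window))
}

# Uniform-window box sums over all valid window positions (separable cumsum).
box_sum3d <- function(x, w) {
  along <- function(a, axis) {
    p <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
    b <- aperm(a, p)
    d <- dim(b)
    m <- matrix(b, nrow = d[1L])
    cs <- rbind(0, apply(m, 2L, cumsum))
    s <- cs[(w + 1L):(d[1L] + 1L), , drop = FALSE] - cs[1:(d[1L] - w + 1L), , drop = FALSE]
    aperm(array(s, c(d[1L] - w + 1L, d[2L], d[3L])), order(p))
  }
  along(along(along(x, 1L), 2L), 3L)
}

#' Structural similarity of two 3-D volumes
#'
#' Mean SSIM over all valid `window^3` positions with constants
#' `C1 = (K1 * L)^2`, `C2 = (K2 * L)^2`, unbiased covariance normalization.
#' @param x,y 3-D arrays of equal cubic shape.
#' @param window window edge (odd, default 7).
#' @param data_range dynamic range L (default 1).
#' @param K1,K2 stability constants.
#' @export
ssim3d <- function(x, y, window = 7L, data_range = 1, K1 = 0.01, K2 = 0.03) {
  stopifnot(all(dim(x) == dim(y)), window <= min(dim(x)))
  np <- window^3
  ux <- box_sum3d(x, window) / np
  uy <- box_sum3d(y, window) / np
  uxx <- box_sum3d(x * x, window) / np
  uyy <- box_sum3d(y * y, window) / np
  uxy <- box_sum3d(x * y, window) / np
  cn <- np / (np - 1)                            # unbiased variance/covariance
  vx <- cn * (uxx - ux * ux)
  vy <- cn * (uyy - uy * uy)
  vxy <- cn * (uxy - ux * uy)
  C1 <- (K1 * data_range)^2; C2 <- (K2 * data_range)^2
  s <- ((2 * ux * uy + C1) * (2 * vxy + C2)) /
    ((ux^2 + uy^2 + C1) * (vx + vy + C2))
  mean(s)
}

#' Grad-CAM saliency volumes for the fusion classifier
#'
#' Computes, for each modality branch, the channel-weighted sum of the
#' branch's last convolutional activations, with channel weights equal to
#' the spatially averaged gradients of the target-class score; rectified at
#' zero, trilinearly upsampled to the input shape, and max-normalized to
#' [0, 1]. An all-zero gradient produces an all-zero map with attribute
#' `zero_gradient = TRUE`.
#'
#' @param params trained `fusion_params`, or a model function
#'   `(mri, pet) -> list(scores, branch_acts = list(mri, pet))` operating on
#'   tape nodes (useful for analytic stubs).
#' @param mri,pet input volumes (`volume` or 3-D arrays).
#' @param target_class class whose score is explained (0 or 1).
#' @return list with saliency `volume`s `mri` and `pet`.
#' @export
grad_cam <- function(params, mri, pet, target_class = 1L) {
  m <- as_input5d(mri); p <- as_input5d(pet)
  tape <- tape_new()
  mt <- tp_leaf(tape, m); pt <- tp_leaf(tape, p)
  out <- if (is.function(params)) {
    params(mt, pt)
  } else {
    fusion_forward(params, mt, pt, training = FALSE, capture = TRUE)
  }
  sel <- matrix(0, 1L, 2L); sel[1L, target_class + 1L] <- 1
  score <- tp_sum(tp_mul(out$scores, sel))
  tp_backward(score)
  cam_of <- function(act, edge, modality) {
    a <- vof(act)
    g <- tp_grad(act)
    wts <- apply(g, 4L, mean)
    cam <- array(0, dim(a)[1:3])
    for (c in seq_along(wts)) cam <- cam + wts[c] * a[, , , c, 1L]
    cam[cam < 0] <- 0
    cam <- resize_trilinear(cam, edge)
    cam[cam < 0] <- 0                            # interpolation guard
    zero <- max(cam) <= 0
    if (!zero) cam <- cam / max(cam) else warning("all-zero Grad-CAM gradients")
    v <- new_volume(cam, modality)
    attr(v, "zero_gradient") <- zero
    v
  }
  edge <- dim(m)[1L]
  list(mri = cam_of(out$branch_acts$mri, edge, "MRI"),
       pet = cam_of(out$branch_acts$pet, edge, "PET"))
}

# Coerce a volume / 3-D array to the (e, e, e, 1, 1) network input layout.
as_input5d <- function(v) {
  x <- volume_data(v)
  array(x, c(dim(x), 1L, 1L))
}

# Stack a list of volumes/arrays into (e, e, e, 1, N).
stack5d <- function(vols) {
  xs <- lapply(vols, volume_data)
  d <- dim(xs[[1L]])
  out <- array(0, c(d, 1L, length(xs)))
  for (i in seq_along(xs)) out[, , , 1L, i] <- xs[[i]]
  out
}
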