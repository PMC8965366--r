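# Loss algebra of the three-stage pipeline: the adversarial minimax value,
# the L1 estimation error, the feature-fusion loss computed through a frozen
# fusion model, the combined generator objective, and the regularized
# classification objective. All functions accept plain arrays or tape nodes,
# so they serve both reporting and gradient computation.

.PROB_EPS <- 1e-7

#' Loss weights of the combined generator objective
#'
#' `lambda1` weights the L1 estimation error, `lambda2` the feature-fusion
#' loss; the reference configuration sets both to 100.
#'
#' @param lambda1,lambda2 non-negative weights.
#' @export
loss_weights <- function(lambda1 = 100, lambda2 = 100) {
  stopifnot(lambda1 >= 0, lambda2 >= 0)
  structure(list(lambda1 = lambda1, lambda2 = lambda2), class = "loss_weights")
}

#' Adversarial losses of the GAN minimax game
#'
#' Given discriminator outputs on real PET patches and on generated patches,
#' returns the discriminator loss `-mean(log d_real) - mean(log(1 - d_fake))`
#' (the negated minimax value, which the discriminator minimizes) and the
#' generator loss. The generator term defaults to the non-saturating form
#' `-mean(log d_fake)`; `generator_form = "minimax"` gives the literal
#' `+mean(log(1 - d_fake))`. Probabilities are clamped away from 0 and 1, so
#' no input yields NaN.
#'
#' @param d_real,d_fake probabilities in (0, 1) (arrays or tape nodes).
#' @param generator_form `"non-saturating"` or `"minimax"`.
#' @return list with elements `loss_d` and `loss_g`.
#' @export
adversarial_loss <- function(d_real, d_fake,
                             generator_form = c("non-saturating", "minimax")) {
  generator_form <- match.arg(generator_form)
  dr <- tp_clamp(d_real, .PROB_EPS, 1 - .PROB_EPS)
  df <- tp_clamp(d_fake, .PROB_EPS, 1 - .PROB_EPS)
  one_m_df <- tp_sub(1, df)
  loss_d <- tp_sub(tp_scale(tp_mean(tp_log(dr)), -1), tp_mean(tp_log(one_m_df)))
  loss_g <- if (generator_form == "non-saturating") {
    tp_scale(tp_mean(tp_log(df)), -1)
  } else {
    tp_mean(tp_log(one_m_df))
  }
  list(loss_d = loss_d, loss_g = loss_g)
}

#' Mean absolute (L1) estimation error between a real and synthesized patch
#'
#' Computed as a per-voxel mean so the weight `lambda1 = 100` is meaningful
#' independent of patch size.
#' @param y,g_x same-shape arrays (or tape nodes).
#' @export
l1_loss <- function(y, g_x) {
  yv <- vof(y); gv <- vof(g_x)
  if (!isTRUE(all(dim_of(yv) == dim_of(gv)))) stop("l1_loss: shape mismatch")
  tp_mean(tp_abs(tp_sub(y, g_x)))
}

#' Feature-fusion loss through a frozen fusion model
#'
#' The mean absolute difference between the fused feature vectors of
#' (real MRI, real PET) and (real MRI, synthesized PET), both computed
#' through the frozen feature extractor `F`. Zero exactly when the two
#' feature vectors coincide; differentiable with respect to the synthesized
#' patch.
#'
#' @param F_fn feature extractor: either `fusion_params` (its head is
#'   ignored) or a function `(x, y) -> feature matrix`.
#' @param x real MRI input; `y` real PET; `g_x` synthesized PET.
#' @export
fusion_loss <- function(F_fn, x, y, g_x) {
  feat <- if (inherits(F_fn, "fusion_params")) {
    if (any(vapply(param_arrays(F_fn), is_tp, logical(1)))) {
      stop("fusion model must be frozen (plain parameters) in fusion_loss")
    }
    function(a, b) fusion_features(F_fn, a, b, training = FALSE)
  } else {
    F_fn
  }
  f_real <- feat(x, y)
  f_fake <- feat(x, g_x)
  tp_mean(tp_abs(tp_sub(f_real, f_fake)))
}

#' Combined generator objective
#'
#' `adv_g + lambda1 * l1 + lambda2 * fusion`.
#' @param adv_g,l1,fusion scalar loss components.
#' @param weights a [loss_weights()].
#' @export
generator_objective <- function(adv_g, l1, fusion, weights = loss_weights()) {
  tp_add(adv_g, tp_add(tp_scale(l1, weights$lambda1),
                       tp_scale(fusion, weights$lambda2)))
}

#' Regularized two-class classification objective
#'
#' Mean softmax cross-entropy of the class scores plus
#' `l2_coeff * sum(parameters^2)` over all trainable parameters.
#'
#' @param scores N x 2 score matrix (or tape node).
#' @param labels integer vector in \{0, 1\}.
#' @param parameters network parameters for the L2 penalty (may be NULL).
#' @param l2_coeff regularization coefficient (reference setting 0.001).
#' @export
classification_objective <- function(scores, labels, parameters = NULL,
                                     l2_coeff = 0.001) {
  stopifnot(all(labels %in% c(0L, 1L)))
  ce <- softmax_ce(scores, labels)
  if (is.null(parameters) || l2_coeff == 0) return(ce)
  pen <- NULL
  for (a in param_arrays(parameters)) {
    s <- tp_square_sum(a)
    pen <- if (is.null(pen)) s else tp_add(pen, s)
  }
  tp_add(ce, tp_scale(pen, l2_coeff))
}

# Numerically stable mean softmax cross-entropy with analytic backward.
softmax_ce <- function(scores, labels) {
  sv <- vof(scores)
  n <- nrow(sv)
  stopifnot(length(labels) == n)
  mx <- apply(sv, 1L, max)
  z <- sv - mx
  lse <- log(rowSums(exp(z))) + mx
  picked <- sv[cbind(seq_len(n), labels + 1L)]
  val <- mean(lse - picked)
  tp_op(val, list(scores), function(g) {
    p <- exp(sv - lse)                       # softmax rows
    onehot <- matrix(0, n, ncol(sv))
    onehot[cbind(seq_len(n), labels + 1L)] <- 1
    list(g * (p - onehot) / n)
  })
}

#' Class-1 probabilities from a two-class score matrix.
#' @export
score_probs <- function(scores) {
  sv <- vof(scores)
  1 / (1 + exp(sv[, 1L] - sv[, 2L]))
}
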