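# The hybrid pipeline: stage 1 once, then `cycles` repetitions of
# (stage 2 with the current fusion model frozen -> stage 3 fine-tuning),
# with model selection by validation accuracy (ties broken by validation
# AUC). Returns a classed fit object in the style of R modelling functions.

#' Fit the full three-stage hybrid pipeline
#'
#' Runs classifier pretraining, feature-fusion GAN training and classifier
#' fine-tuning, cycling the last two stages. Validation metrics are computed
#' on real MRI + real PET; test metrics on real MRI + synthesized PET
#' (unpaired subjects form the test set under the incomplete protocol).
#'
#' @param cohort a `cohort`; if subjects carry no split tags a fold plan is
#'   made with `k` subsets and the last subset held out for validation.
#' @param specs list with elements `generator`, `discriminator`, `fusion`
#'   (see [generator_spec()], [discriminator_spec()], [fusion_spec()]).
#' @param config a [stage_config()].
#' @param protocol `"incomplete"` or `"complete"` partitioning.
#' @param k number of fold subsets when the cohort is untagged.
#' @param val_fold held-out subset index (defaults to the last).
#' @return an object of class `hybrid_fit`.
#' @export
run_hybrid <- function(cohort, specs = NULL, config = stage_config(),
                       protocol = c("incomplete", "complete"),
                       k = 4L, val_fold = NULL) {
  protocol <- match.arg(protocol)
  specs <- utils::modifyList(
    list(generator = generator_spec(depth = 2L, width_scale = 1 / 16),
         discriminator = discriminator_spec(depth = 2L, width_scale = 1 / 16),
         fusion = fusion_spec()),
    specs %||% list())
  plan <- NULL
  if (all(is.na(cohort_tags(cohort)))) {
    plan <- make_folds(cohort, k = k, protocol = protocol, seed = config$seed)
    cohort <- apply_folds(cohort, plan, val_fold %||% plan$k)
  }
  tags <- cohort_tags(cohort)
  val_subs <- cohort$subjects[tags == "validation"]
  test_subs <- cohort$subjects[tags == "test"]
  geom <- patch_geometry(dim(cohort$subjects[[1L]]$mri$data)[1L], config$stage2)

  stage1 <- pretrain_classifier(cohort, specs$fusion, config)
  checkpoints <- list("stage1_cycle0" = stage1)
  current_f <- stage1$fusion
  gan_init <- NULL
  cycle_rows <- list()
  best <- NULL
  for (cy in seq_len(config$cycles)) {
    s2 <- train_ffgan(cohort, current_f, specs$generator, specs$discriminator,
                      config, init = gan_init)
    s2$cycle <- cy
    s3 <- finetune_classifier(cohort, s2$generator, new_artifacts(
      1L, cy, config$seed, fusion = current_f), config)
    s3$cycle <- cy
    checkpoints[[sprintf("stage2_cycle%d", cy)]] <- s2
    checkpoints[[sprintf("stage3_cycle%d", cy)]] <- s3
    val <- if (length(val_subs)) {
      evaluate_classifier(s3$fusion, val_subs, pet_source = "real")
    } else NULL
    test <- if (length(test_subs)) {
      evaluate_classifier(s3$fusion, test_subs, generator = s2$generator,
                          pet_source = "synth",
                          patch_size = geom$patch, stride = geom$stride)
    } else NULL
    cycle_rows[[cy]] <- data.frame(
      cycle = cy,
      val_acc = if (is.null(val)) NA_real_ else val$acc,
      val_auc = if (is.null(val)) NA_real_ else val$auc,
      test_acc = if (is.null(test)) NA_real_ else test$acc,
      test_auc = if (is.null(test)) NA_real_ else test$auc)
    score <- c(if (is.null(val)) -Inf else val$acc,
               if (is.null(val)) -Inf else val$auc)
    if (is.null(best) || score[1L] > best$score[1L] ||
        (score[1L] == best$score[1L] && score[2L] > best$score[2L])) {
      best <- list(cycle = cy, score = score, fusion = s3$fusion,
                   generator = s2$generator, val = val, test = test)
    }
    current_f <- s3$fusion
    if (isTRUE(config$stage2$resume)) {
      gan_init <- list(generator = s2$generator, discriminator = s2$discriminator)
    }
  }
  structure(list(fusion = best$fusion, generator = best$generator,
                 best_cycle = best$cycle,
                 val_metrics = best$val, test_metrics = best$test,
                 cycle_metrics = do.call(rbind, cycle_rows),
                 checkpoints = checkpoints, stage1 = stage1,
                 specs = specs, config = config, protocol = protocol,
                 fold_plan = plan, patch_geometry = geom,
                 seed = config$seed),
            class = "hybrid_fit")
}

#' Retrieve a per-cycle checkpoint by stage and cycle.
#' @param fit a `hybrid_fit`.
#' @param stage 1, 2 or 3.
#' @param cycle cycle index (0 for stage 1).
#' @export
get_checkpoint <- function(fit, stage, cycle = 0L) {
  key <- sprintf("stage%d_cycle%d", stage, cycle)
  ck <- fit$checkpoints[[key]]
  if (is.null(ck)) stop("no checkpoint for stage ", stage, ", cycle ", cycle)
  ck
}

#' @export
print.hybrid_fit <- function(x, ...) {
  cat("Hybrid MRI->PET synthesis + diagnosis fit\n")
  cat(sprintf("  protocol: %s; cycles: %d (best: %d); seed %d\n",
              x$protocol, x$config$cycles, x$best_cycle, x$seed))
  if (!is.null(x$val_metrics)) {
    cat("  validation (real MRI + real PET):  "); print(x$val_metrics)
  }
  if (!is.null(x$test_metrics)) {
    cat("  test (real MRI + synthesized PET): "); print(x$test_metrics)
  }
  invisible(x)
}

#' @export
summary.hybrid_fit <- function(object, ...) {
  cat("Per-cycle metrics:\n")
  print(object$cycle_metrics, row.names = FALSE)
  s1h <- object$stage1$metrics_history
  cat(sprintf("Stage-1 training loss: %.4f -> %.4f over %d epochs\n",
              s1h$loss[1L], s1h$loss[nrow(s1h)], nrow(s1h)))
  invisible(object)
}

#' Predict class probabilities (or labels) for cohort subjects
#'
#' Subjects lacking a real PET get one synthesized from their MRI by the
#' fitted generator.
#' @param object a `hybrid_fit`.
#' @param cohort a `cohort` (or list of subjects).
#' @param type `"prob"` for class-1 probabilities, `"class"` for hard labels.
#' @param pet_source `"auto"`, `"real"` or `"synth"`.
#' @param ... unused.
#' @export
predict.hybrid_fit <- function(object, cohort, type = c("prob", "class"),
                               pet_source = "auto", ...) {
  type <- match.arg(type)
  subjects <- if (inherits(cohort, "cohort")) cohort$subjects else cohort
  probs <- classifier_probs(object$fusion, subjects, object$generator,
                            pet_source,
                            object$patch_geometry$patch,
                            object$patch_geometry$stride)
  if (type == "prob") probs else as.integer(probs >= 0.5)
}

#' Plot stage training histories of a hybrid fit.
#' @param x a `hybrid_fit`.
#' @param ... unused.
#' @export
plot.hybrid_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(op))
  s1 <- x$stage1$metrics_history
  graphics::plot(s1$epoch, s1$loss, type = "l", xlab = "epoch",
                 ylab = "training loss", main = "Stage 1 pretraining")
  s2 <- get_checkpoint(x, 2L, x$best_cycle)$metrics_history
  graphics::plot(seq_len(nrow(s2)), s2$l1, type = "l", xlab = "generator step",
                 ylab = "loss", main = sprintf("Stage 2 (cycle %d)", x$best_cycle))
  graphics::lines(seq_len(nrow(s2)), s2$fusion, lty = 2)
  graphics::legend("topright", legend = c("L1", "fusion"), lty = 1:2, bty = "n")
  invisible(x)
}
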