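# The three-stage schedule: stage 1 pretrains the fusion classifier on
# paired whole volumes; stage 2 trains the MRI->PET generator adversarially
# with the L1 and feature-fusion losses, the fusion model frozen, alternating
# 5 discriminator steps with 1 generator step on the 54 patches of one
# subject pair; stage 3 fine-tunes the classifier on real MRI + synthesized
# PET. Stages 2 and 3 are cycled by run_hybrid().

#' Stage configuration
#'
#' Reference hyperparameters: stage 1 Adam lr 0.0005, batch 8, L2 0.001;
#' stage 2 Adam lr 0.00001, 5 discriminator steps per generator step,
#' lambda1 = lambda2 = 100; stage 3 Adam lr 0.0001 with the stage-1 batch
#' and L2 settings. Epoch counts are configuration-driven; the desk-scale
#' defaults are 30 / 200 / 20.
#'
#' @param stage1,stage2,stage3 named lists overriding individual fields.
#' @param cycles number of stage-2/stage-3 iterations in [run_hybrid()].
#' @param seed master seed for training randomness.
#' @export
stage_config <- function(stage1 = list(), stage2 = list(), stage3 = list(),
                         cycles = 3L, seed = 1L) {
  s1 <- utils::modifyList(list(lr = 5e-4, batch = 8L, l2 = 1e-3, epochs = 30L,
                               augment = FALSE), stage1)
  s2 <- utils::modifyList(list(lr = 1e-5, d_steps_per_g_step = 5L,
                               weights = loss_weights(100, 100),
                               generator_form = "non-saturating",
                               patch_size = NULL, stride = NULL,
                               epochs = 200L, resume = TRUE), stage2)
  s3 <- utils::modifyList(list(lr = 1e-4, batch = 8L, l2 = 1e-3, epochs = 20L), stage3)
  stopifnot(s1$lr > 0, s2$lr > 0, s3$lr > 0,
            s2$d_steps_per_g_step >= 1L, cycles >= 1L)
  structure(list(stage1 = s1, stage2 = s2, stage3 = s3,
                 cycles = as.integer(cycles), seed = as.integer(seed)),
            class = "stage_config")
}

# Patch geometry mirrors the reference 128/64/32 halving scheme by default.
patch_geometry <- function(edge, config2) {
  p <- config2$patch_size %||% (edge %/% 2L)
  s <- config2$stride %||% (p %/% 2L)
  list(patch = as.integer(p), stride = as.integer(s))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

new_artifacts <- function(stage, cycle, seed, ...) {
  structure(c(list(stage = stage, cycle = cycle, seed = seed), list(...)),
            class = "stage_artifacts")
}

#' @export
print.stage_artifacts <- function(x, ...) {
  cat(sprintf("<stage_artifacts> stage %d, cycle %d, seed %d\n",
              x$stage, x$cycle, x$seed))
  invisible(x)
}

train_subjects <- function(cohort, subjects = NULL) {
  if (!is.null(subjects)) return(cohort$subjects[subjects])
  tags <- cohort_tags(cohort)
  if (all(is.na(tags))) cohort$subjects else cohort$subjects[tags %in% "train"]
}

# One classifier training pass shared by stages 1 and 3 (they differ only in
# learning rate and PET source).
classifier_fit <- function(params, subjects, pets, lr, batch, l2, epochs,
                           augment = FALSE) {
  labels_all <- vapply(subjects, function(s) s$label, integer(1))
  n <- length(subjects)
  opt <- adam_init(lr)
  history <- data.frame(epoch = integer(), loss = numeric(), acc = numeric())
  for (ep in seq_len(epochs)) {
    ord <- sample(n)
    ep_loss <- 0; ep_correct <- 0; nb <- 0L
    for (start in seq.int(1L, n, by = batch)) {
      idx <- ord[start:min(start + batch - 1L, n)]
      mriv <- lapply(subjects[idx], function(s) s$mri)
      petv <- pets[idx]
      if (augment) {
        for (j in seq_along(idx)) {
          flips <- stats::runif(2L) < 0.5
          mriv[[j]] <- augment_flip(mriv[[j]], flips = flips)
          petv[[j]] <- augment_flip(petv[[j]], flips = flips)
        }
      }
      mri <- stack5d(mriv); pet <- stack5d(petv)
      labels <- labels_all[idx]
      tape <- tape_new()
      wp <- wrap_params(tape, params)
      collect <- new.env(parent = emptyenv())
      out <- fusion_forward(wp, mri, pet, training = TRUE, collect = collect)
      loss <- classification_objective(out$scores, labels, wp, l2_coeff = l2)
      tp_backward(loss)
      st <- adam_step(opt, params, grads_of(wp))
      opt <- st$state; params <- st$params
      params <- apply_bn_updates(params, collect)
      ep_loss <- ep_loss + vof(loss); nb <- nb + 1L
      ep_correct <- ep_correct + sum((score_probs(out$scores) >= 0.5) == (labels == 1L))
    }
    history <- rbind(history, data.frame(epoch = ep, loss = ep_loss / nb,
                                         acc = ep_correct / n))
  }
  list(params = params, history = history)
}

#' Stage 1: pretrain the fusion classifier on paired whole volumes
#'
#' Trains the dual-branch fusion network plus its affine head with Adam on
#' min-max-normalized whole volumes; softmax cross-entropy with L2 penalty.
#' Every training subject must have a real PET (stage 1 requires paired
#' data). Per-epoch training loss and accuracy are recorded.
#'
#' @param cohort a `cohort` (subjects tagged `train` are used; all subjects
#'   if no tags were applied).
#' @param fspec a [fusion_spec()].
#' @param config a [stage_config()].
#' @param subjects optional explicit subject index vector.
#' @return `stage_artifacts` with the trained fusion parameters.
#' @export
pretrain_classifier <- function(cohort, fspec, config = stage_config(),
                                subjects = NULL) {
  subs <- train_subjects(cohort, subjects)
  if (!length(subs)) stop("no training subjects")
  missing_pet <- vapply(subs, function(s) is.null(s$pet), logical(1))
  if (any(missing_pet)) {
    stop("stage 1 requires paired data; missing PET for ",
         paste(vapply(subs[missing_pet], function(s) s$subject_id, character(1)),
               collapse = ", "))
  }
  edge <- dim(subs[[1L]]$mri$data)[1L]
  with_seed(config$seed, {
    params <- build_fusion_classifier(fspec, edge, seed = config$seed)
    fit <- classifier_fit(params, subs, lapply(subs, function(s) s$pet),
                          lr = config$stage1$lr, batch = config$stage1$batch,
                          l2 = config$stage1$l2, epochs = config$stage1$epochs,
                          augment = isTRUE(config$stage1$augment))
    new_artifacts(1L, 0L, config$seed, fusion = fit$params,
                  metrics_history = fit$history,
                  f_checksum = param_checksum(fit$params))
  })
}

#' Stage 2: train the feature-fusion GAN with the fusion model frozen
#'
#' Alternates `d_steps_per_g_step` discriminator updates with one generator
#' update; every iteration draws the full patch grid (27 + 27 at the
#' reference geometry) of one training subject pair. The discriminator
#' minimizes the negated minimax value; the generator minimizes
#' `adv + lambda1 * L1 + lambda2 * fusion`, where the fusion term is the L1
#' distance between fused features of (MRI, PET) and (MRI, G(MRI)) computed
#' through the frozen feature extractor. The fusion parameters are verified
#' bit-identical before and after; mutation is a hard failure.
#'
#' @param cohort a `cohort`.
#' @param frozen_f `fusion_params` from stage 1 (frozen).
#' @param gspec,dspec generator / discriminator specs.
#' @param config a [stage_config()].
#' @param subjects optional explicit subject indices.
#' @param init optional list with `generator` / `discriminator` parameters to
#'   resume from (used when cycling).
#' @return `stage_artifacts` with generator, discriminator and loss history.
#' @export
train_ffgan <- function(cohort, frozen_f, gspec, dspec, config = stage_config(),
                        subjects = NULL, init = NULL) {
  subs <- train_subjects(cohort, subjects)
  subs <- subs[vapply(subs, function(s) !is.null(s$pet), logical(1))]
  if (!length(subs)) stop("stage 2 needs paired training subjects")
  stopifnot(inherits(frozen_f, "fusion_params"))
  f_before <- param_checksum(frozen_f)
  edge <- dim(subs[[1L]]$mri$data)[1L]
  geom <- patch_geometry(edge, config$stage2)
  lam <- config$stage2$weights
  use_fusion <- lam$lambda2 > 0
  fusion_calls <- 0L
  with_seed(config$seed + 1L, {
    gen <- init$generator %||% build_generator(gspec, seed = config$seed + 11L)
    dis <- init$discriminator %||% build_discriminator(dspec, seed = config$seed + 13L)
    dis <- disc_ensure_head(dis, geom$patch, seed = config$seed + 13L)
    gen_init <- gen                       # untrained snapshot for baselines
    opt_g <- adam_init(config$stage2$lr)
    opt_d <- adam_init(config$stage2$lr)
    # pre-extract the patch grids once per subject
    grids <- lapply(subs, function(s) {
      list(mri = stack5d(extract_patches(s$mri, geom$patch, geom$stride)$patches),
           pet = stack5d(extract_patches(s$pet, geom$patch, geom$stride)$patches))
    })
    hist <- list()
    d_steps <- 0L; g_steps <- 0L
    for (ep in seq_len(config$stage2$epochs)) {
      for (si in sample(length(subs))) {
        mri <- grids[[si]]$mri; pet <- grids[[si]]$pet
        # G is fixed during the D steps, so synthesize the fake batch once
        fake <- generator_forward(gen, mri)
        for (k in seq_len(config$stage2$d_steps_per_g_step)) {
          tape <- tape_new()
          wd <- wrap_params(tape, dis)
          adv <- adversarial_loss(discriminator_forward(wd, pet),
                                  discriminator_forward(wd, fake),
                                  config$stage2$generator_form)
          tp_backward(adv$loss_d)
          st <- adam_step(opt_d, dis, grads_of(wd))
          opt_d <- st$state; dis <- st$params
          d_steps <- d_steps + 1L
        }
        tape <- tape_new()
        wg <- wrap_params(tape, gen)
        fake <- generator_forward(wg, mri)
        d_fake <- discriminator_forward(dis, fake)
        d_real <- discriminator_forward(dis, pet)
        adv <- adversarial_loss(d_real, d_fake, config$stage2$generator_form)
        l1 <- l1_loss(pet, fake)
        fus <- if (use_fusion) {
          fusion_calls <- fusion_calls + 1L
          fusion_loss(frozen_f, mri, pet, fake)
        } else 0
        obj <- generator_objective(adv$loss_g, l1, fus, lam)
        tp_backward(obj)
        st <- adam_step(opt_g, gen, grads_of(wg))
        opt_g <- st$state; gen <- st$params
        g_steps <- g_steps + 1L
        hist[[length(hist) + 1L]] <- data.frame(
          epoch = ep, subject = subs[[si]]$subject_id,
          loss_d = vof(adv$loss_d), loss_g_adv = vof(adv$loss_g),
          l1 = vof(l1), fusion = vof(fus), objective = vof(obj))
      }
    }
    f_after <- param_checksum(frozen_f)
    if (!identical(f_before, f_after)) {
      stop("freeze contract violated: fusion model changed during stage 2")
    }
    new_artifacts(2L, 0L, config$seed, generator = gen, discriminator = dis,
                  generator_init = gen_init,
                  metrics_history = do.call(rbind, hist),
                  f_checksum = f_before, patch_geometry = geom,
                  d_steps = d_steps, g_steps = g_steps,
                  fusion_calls = fusion_calls)
  })
}

#' Synthesize a PET volume from an MRI volume with a trained generator
#'
#' Extracts the full patch grid, runs the generator on every patch, and
#' reassembles by overlap averaging. Output values stay in [0, 1] (sigmoid
#' output, averaging preserves the range).
#'
#' @param mri a `volume` or 3-D array (min-max normalized).
#' @param generator `generator_params`, or a function mapping a 5-D patch
#'   batch to a same-shape batch (useful as an identity stub).
#' @param patch_size,stride patch geometry; defaults to edge/2 and edge/4.
#' @return a PET `volume`.
#' @export
synthesize_pet <- function(mri, generator, patch_size = NULL, stride = NULL) {
  x <- volume_data(mri)
  edge <- dim(x)[1L]
  p <- as.integer(patch_size %||% (edge %/% 2L))
  s <- as.integer(stride %||% (p %/% 2L))
  ps <- extract_patches(x, p, s)
  batch <- stack5d(ps$patches)
  out <- if (inherits(generator, "generator_params")) {
    generator_forward(generator, batch)
  } else {
    generator(batch)
  }
  out <- vof(out)
  ps$patches <- lapply(seq_len(dim(out)[5L]), function(i) out[, , , 1L, i])
  new_volume(reassemble(ps), "PET")
}

#' Stage 3: fine-tune the classifier on real MRI + synthesized PET
#'
#' Replaces every training subject's PET with `synthesize_pet(MRI)` under the
#' frozen generator and resumes training of the stage-1 fusion network at the
#' stage-3 learning rate. Zero epochs returns the stage-1 parameters
#' unchanged. The generator is verified bit-identical before and after.
#'
#' @param cohort a `cohort`.
#' @param generator trained `generator_params` (frozen).
#' @param stage1_artifacts `stage_artifacts` holding the classifier to resume.
#' @param config a [stage_config()].
#' @param subjects optional explicit subject indices.
#' @return `stage_artifacts` with the fine-tuned fusion parameters.
#' @export
finetune_classifier <- function(cohort, generator, stage1_artifacts,
                                config = stage_config(), subjects = NULL) {
  if (is.null(stage1_artifacts$fusion)) stop("missing stage-1 checkpoint")
  subs <- train_subjects(cohort, subjects)
  if (!length(subs)) stop("no training subjects")
  g_before <- param_checksum(generator)
  geom <- patch_geometry(dim(subs[[1L]]$mri$data)[1L], config$stage2)
  with_seed(config$seed + 2L, {
    pets <- lapply(subs, function(s) {
      synthesize_pet(s$mri, generator, geom$patch, geom$stride)
    })
    params <- stage1_artifacts$fusion
    if (config$stage3$epochs > 0L) {
      fit <- classifier_fit(params, subs, pets,
                            lr = config$stage3$lr, batch = config$stage3$batch,
                            l2 = config$stage3$l2, epochs = config$stage3$epochs)
      params <- fit$params
      history <- fit$history
    } else {
      history <- data.frame(epoch = integer(), loss = numeric(), acc = numeric())
    }
    if (!identical(g_before, param_checksum(generator))) {
      stop("freeze contract violated: generator changed during stage 3")
    }
    new_artifacts(3L, 0L, config$seed, fusion = params,
                  metrics_history = history,
                  f_checksum = param_checksum(params),
                  g_checksum = g_before)
  })
}

#' Evaluate a fusion classifier on a subject set
#'
#' Validation inputs use real MRI + real PET; test inputs use real MRI +
#' synthesized PET (subjects without a real PET require a generator).
#'
#' @param params `fusion_params`.
#' @param subjects list of cohort subjects.
#' @param generator generator for subjects lacking real PET (or to force
#'   synthesis with `pet_source = "synth"`).
#' @param pet_source `"real"`, `"synth"`, or `"auto"` (real when present).
#' @param patch_size,stride geometry passed to [synthesize_pet()].
#' @return a `metrics_report`.
#' @export
evaluate_classifier <- function(params, subjects, generator = NULL,
                                pet_source = c("auto", "real", "synth"),
                                patch_size = NULL, stride = NULL) {
  pet_source <- match.arg(pet_source)
  labels <- vapply(subjects, function(s) s$label, integer(1))
  probs <- classifier_probs(params, subjects, generator, pet_source,
                            patch_size, stride)
  classification_metrics(labels, probs)
}

classifier_probs <- function(params, subjects, generator = NULL,
                             pet_source = "auto", patch_size = NULL,
                             stride = NULL) {
  pets <- lapply(subjects, function(s) {
    use_real <- switch(pet_source,
                       real = TRUE,
                       synth = FALSE,
                       auto = !is.null(s$pet))
    if (use_real) {
      if (is.null(s$pet)) stop("subject ", s$subject_id, " has no real PET")
      s$pet
    } else {
      if (is.null(generator)) stop("generator required to synthesize PET")
      synthesize_pet(s$mri, generator, patch_size, stride)
    }
  })
  mri <- stack5d(lapply(subjects, function(s) s$mri))
  pet <- stack5d(pets)
  out <- fusion_forward(params, mri, pet, training = FALSE)
  score_probs(out$scores)
}
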