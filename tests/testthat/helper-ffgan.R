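# Shared fixtures: all test data is generated in code at run time.

# A small tagged cohort at the desk-scale benchmark geometry.
tiny_cohort <- function(seed = 1, k = 4, ...) {
  co <- generate_cohort(synthetic_config(seed = seed, ...))
  apply_folds(co, make_folds(co, k = k, protocol = "incomplete", seed = seed))
}

tiny_specs <- function() {
  list(generator = generator_spec(depth = 2, width_scale = 1 / 16),
       discriminator = discriminator_spec(depth = 2, width_scale = 1 / 16),
       fusion = fusion_spec())
}

# Desk-scale stage configuration used throughout the training tests: paper
# learning rates for the classifier stages, scaled-up stage-2 rate (see the
# methods vignette for the rationale).
bench_config <- function(seed = 1, s1 = 30, s2 = 20, s3 = 20, lr2 = 3e-3,
                         lambda2 = 100, cycles = 1) {
  stage_config(stage1 = list(epochs = s1),
               stage2 = list(epochs = s2, lr = lr2,
                             weights = loss_weights(100, lambda2)),
               stage3 = list(epochs = s3),
               cycles = cycles, seed = seed)
}

# Area under the ROC curve of a score vector (independent re-implementation
# used as an oracle target in generator-level tests).
region_mean_auc <- function(cohort, what = c("pet", "mri")) {
  what <- match.arg(what)
  mask <- ffgan:::lesion_mask(cohort$config)
  score <- vapply(cohort$subjects, function(s) {
    v <- if (what == "pet") (s$pet %||% s$pet_clean) else s$mri
    mean(v$data[mask > 0])
  }, numeric(1))
  lab <- cohort_labels(cohort)
  r <- rank(score)
  n1 <- sum(lab == 1); n0 <- sum(lab == 0)
  (sum(r[lab == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Brute-force confusion-matrix / pairwise-rank oracle for the metric tests.
oracle_metrics <- function(labels, probs, threshold = 0.5) {
  pred <- ifelse(probs >= threshold, 1L, 0L)
  tp <- 0; tn <- 0; fp <- 0; fn <- 0
  for (i in seq_along(labels)) {
    if (labels[i] == 1 && pred[i] == 1) tp <- tp + 1
    if (labels[i] == 0 && pred[i] == 0) tn <- tn + 1
    if (labels[i] == 0 && pred[i] == 1) fp <- fp + 1
    if (labels[i] == 1 && pred[i] == 0) fn <- fn + 1
  }
  num <- 0; den <- 0
  for (i in which(labels == 1)) for (j in which(labels == 0)) {
    den <- den + 1
    if (probs[i] > probs[j]) num <- num + 1
    if (probs[i] == probs[j]) num <- num + 0.5
  }
  list(acc = 100 * (tp + tn) / length(labels),
       sen = 100 * tp / (tp + fn), spe = 100 * tn / (tn + fp),
       auc = num / den)
}
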