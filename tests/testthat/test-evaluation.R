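# Classification metrics, image-quality metrics, Grad-CAM.

test_that("classification metrics match hand counts and handle edge cases", {
  perfect <- classification_metrics(c(0L, 0L, 1L, 1L), c(0.1, 0.2, 0.8, 0.9))
  expect_equal(perfect$acc, 100); expect_equal(perfect$sen, 100)
  expect_equal(perfect$spe, 100); expect_equal(perfect$auc, 1)
  m <- classification_metrics(c(1L, 1L, 0L, 0L), c(1, 0, 0, 0))
  expect_equal(m$acc, 75); expect_equal(m$sen, 50); expect_equal(m$spe, 100)
  ties <- classification_metrics(c(0L, 1L, 0L, 1L), rep(0.4, 4))
  expect_equal(ties$auc, 0.5)                          # all-tie convention
  expect_error(classification_metrics(c(1L, 1L), c(0.2, 0.9)), "one class")
})

test_that("metrics agree with a brute-force confusion/rank oracle on random cases", {
  set.seed(55)
  for (case in 1:200) {
    n <- sample(4:20, 1)
    labels <- c(0L, 1L, sample(0:1, n - 2, replace = TRUE))  # both classes present
    probs <- round(runif(n), 2)                              # ties occur
    got <- classification_metrics(labels, probs)
    want <- oracle_metrics(labels, probs)
    expect_equal(got$acc, want$acc)
    expect_equal(got$sen, want$sen)
    expect_equal(got$spe, want$spe)
    expect_equal(got$auc, want$auc, tolerance = 1e-12)
  }
})

test_that("AUC is invariant under strictly monotone transforms", {
  set.seed(77)
  labels <- sample(0:1, 30, replace = TRUE); labels[1:2] <- 0:1
  probs <- runif(30)
  base <- classification_metrics(labels, probs)$auc
  expect_equal(classification_metrics(labels, probs^3)$auc, base)
  expect_equal(classification_metrics(labels, plogis(5 * probs - 2))$auc, base)
})

test_that("image metrics: analytic cases, brute-force MSE, reference SSIM", {
  v <- array(runif(8^3), c(8, 8, 8))
  same <- image_metrics(v, v)
  expect_equal(same$mse, 0); expect_equal(same$psnr, Inf); expect_equal(same$ssim, 1)
  opp <- image_metrics(array(1, c(8, 8, 8)), array(0, c(8, 8, 8)))
  expect_equal(opp$mse, 1); expect_equal(opp$psnr, 0)
  set.seed(20240817)
  x <- array(runif(512), c(8, 8, 8)); y <- array(runif(512), c(8, 8, 8))
  acc <- 0
  for (i in seq_along(x)) acc <- acc + (x[i] - y[i])^2
  m <- image_metrics(x, y)
  expect_equal(m$mse, acc / 512, tolerance = 1e-10)
  # frozen value from scikit-image structural_similarity (win_size = 7,
  # data_range = 1, uniform window) on this seeded pair
  expect_equal(m$ssim, 0.02859763908603219, tolerance = 1e-6)
  expect_error(image_metrics(x, array(0, c(4, 4, 4))), "shape")
})

test_that("Grad-CAM honors its contract and localizes an analytic stub's region", {
  fp <- build_fusion_classifier(fusion_spec(), 16, seed = 5)
  co <- tiny_cohort(seed = 5)
  s <- co$subjects[[1]]
  cams <- suppressWarnings(grad_cam(fp, s$mri, s$pet, target_class = 1L))
  for (cam in cams) {
    expect_equal(dim(cam$data), dim(s$mri$data))
    expect_true(all(cam$data >= 0 & cam$data <= 1))
  }
  # analytic stub whose class-1 score is the mean of one lesion region of the
  # PET "activation" (the input itself as the target layer): the gradient
  # weight is positive, so the saliency maximum must fall where the PET
  # peaks, i.e. inside the strongly planted lesion region
  co_big <- generate_cohort(synthetic_config(n_paired_per_class = 1,
                                             n_unpaired_per_class = 0,
                                             effect_size = 0.6, seed = 8))
  s1 <- co_big$subjects[[2]]                           # the class-1 subject
  expect_equal(s1$label, 1L)
  mask <- ffgan:::lesion_mask(co_big$config)
  sel <- array(mask, c(16, 16, 16, 1, 1))
  stub <- function(mt, pt) {
    score1 <- ffgan:::tp_scale(ffgan:::tp_sum(ffgan:::tp_mul(pt, sel)),
                               1 / sum(mask))
    scores <- ffgan:::tp_op(matrix(c(0, ffgan:::vof(score1)), 1, 2), list(score1),
                            function(g) list(g[1, 2]))
    list(scores = scores, branch_acts = list(mri = mt, pet = pt))
  }
  # the stub's score ignores the MRI branch, whose map is legitimately zero
  cams <- suppressWarnings(grad_cam(stub, s1$mri, s1$pet, target_class = 1L))
  peak <- which(cams$pet$data == max(cams$pet$data), arr.ind = TRUE)[1, ]
  expect_equal(mask[peak[1], peak[2], peak[3]], 1)
  expect_true(all(cams$pet$data >= 0))
})

test_that("Grad-CAM concentrates in planted lesion regions after training", {
  # desk-scale analogue of saliency localization: compare mean saliency in
  # the lesion mask vs random control regions of equal volume
  wins <- sapply(1:3, function(seed) {
    co <- tiny_cohort(seed = seed, effect_size = 0.4)
    art <- pretrain_classifier(co, fusion_spec(), bench_config(seed, s1 = 20))
    mask <- ffgan:::lesion_mask(co$config)
    subs <- co$subjects[ffgan:::cohort_tags(co) == "train"]
    subs <- subs[vapply(subs, function(s) s$label == 1L, logical(1))]
    in_mass <- 0; ctrl_mass <- 0
    set.seed(seed)
    for (s in subs[1:3]) {
      # an occasional all-zero map (dead rectifier) counts against localization
      cam <- suppressWarnings(grad_cam(art$fusion, s$mri, s$pet,
                                       target_class = 1L))$pet$data
      in_mass <- in_mass + mean(cam[mask > 0])
      ctrl <- sample(which(mask == 0), sum(mask > 0))
      ctrl_mass <- ctrl_mass + mean(cam[ctrl])
    }
    in_mass > ctrl_mass
  })
  expect_gte(sum(wins), 2)                             # majority of seeds
})
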