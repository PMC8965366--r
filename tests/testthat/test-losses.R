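# The loss algebra: adversarial, L1, feature-fusion, combined objective,
# regularized classification.

test_that("adversarial loss matches analytic values and a per-element oracle", {
  half <- rep(0.5, 4)
  al <- adversarial_loss(half, half)
  expect_equal(al$loss_d, -log(0.25), tolerance = 1e-12)   # minimax value log 1/4
  # perfect discriminator limit
  sharp <- adversarial_loss(rep(1 - 1e-9, 4), rep(1e-9, 4))
  expect_lt(abs(sharp$loss_d), 1e-5)
  # brute-force oracle on a random batch of 8
  set.seed(21)
  dr <- runif(8, 0.05, 0.95); df <- runif(8, 0.05, 0.95)
  al <- adversarial_loss(dr, df)
  expect_equal(al$loss_d, -sum(log(dr)) / 8 - sum(log(1 - df)) / 8, tolerance = 1e-6)
  expect_equal(al$loss_g, -sum(log(df)) / 8, tolerance = 1e-6)
  expect_equal(adversarial_loss(dr, df, "minimax")$loss_g,
               sum(log(1 - df)) / 8, tolerance = 1e-6)
  # clamping keeps everything finite at the boundary
  ext <- adversarial_loss(c(0, 1), c(0, 1))
  expect_true(is.finite(ext$loss_d) && is.finite(ext$loss_g))
})

test_that("L1 loss is the per-voxel mean absolute difference", {
  a <- array(runif(64), c(4, 4, 4))
  expect_equal(l1_loss(a, a), 0)
  expect_equal(l1_loss(array(1, c(4, 4, 4)), array(0, c(4, 4, 4))), 1)
  b <- array(runif(64), c(4, 4, 4))
  acc <- 0
  for (i in seq_along(a)) acc <- acc + abs(a[i] - b[i])
  expect_equal(l1_loss(a, b), acc / 64, tolerance = 1e-12)
  expect_error(l1_loss(a, array(0, c(2, 2, 2))), "shape")
})

test_that("fusion loss vanishes for an oracle generator and reduces to L1 under an identity stub", {
  fp <- build_fusion_classifier(fusion_spec(), input_edge = 16, seed = 4)
  x <- array(runif(16^3), c(16, 16, 16, 1, 1))
  y <- array(runif(16^3), c(16, 16, 16, 1, 1))
  expect_equal(fusion_loss(fp, x, y, y), 0)
  # identity stub F: features = concatenated inputs, so the fusion loss is
  # the L1 difference restricted to the PET slot (halved by the doubled mean)
  stub <- function(a, b) ffgan:::flatten5d(ffgan:::concat_ch(a, b))
  g_x <- array(runif(16^3), c(16, 16, 16, 1, 1))
  expect_equal(fusion_loss(stub, x, y, g_x), l1_loss(y, g_x) / 2, tolerance = 1e-12)
  # two-forward-pass oracle
  fr <- fusion_features(fp, x, y); ff <- fusion_features(fp, x, g_x)
  expect_equal(fusion_loss(fp, x, y, g_x), mean(abs(fr - ff)), tolerance = 1e-6)
  expect_gt(fusion_loss(fp, x, y, g_x), 0)
  # refusing a non-frozen fusion model
  tape <- ffgan:::tape_new()
  expect_error(fusion_loss(ffgan:::wrap_params(tape, fp), x, y, g_x), "frozen")
})

test_that("the combined generator objective is the stated weighted sum", {
  w <- loss_weights(100, 100)
  expect_equal(generator_objective(-0.7, 0.01, 0.002, w), 0.5, tolerance = 1e-12)
  expect_equal(generator_objective(1.5, 0.3, 0.7, loss_weights(0, 0)), 1.5)
  expect_equal(generator_objective(-0.3, 0, 0, w), -0.3)
  expect_error(loss_weights(-1, 0))
})

test_that("classification objective: analytic uniform case, limits, brute-force batch", {
  scores <- matrix(0, 4, 2)
  labels <- c(0L, 1L, 0L, 1L)
  expect_equal(classification_objective(scores, labels, NULL, 0), log(2),
               tolerance = 1e-12)
  hot <- matrix(c(50, -50, -50, 50), 2, 2, byrow = TRUE)
  expect_lt(classification_objective(hot, c(0L, 1L), NULL, 0), 1e-10)
  set.seed(8)
  s <- matrix(rnorm(16), 8, 2); lab <- rep(c(0L, 1L), 4)
  oracle <- mean(sapply(1:8, function(i) {
    p <- exp(s[i, ]) / sum(exp(s[i, ]))
    -log(p[lab[i] + 1])
  }))
  expect_equal(classification_objective(s, lab, NULL, 0), oracle, tolerance = 1e-6)
  # L2 term over all trainable parameters
  fp <- build_fusion_classifier(fusion_spec(base_channels = 1), 8, seed = 1)
  pen <- sum(sapply(ffgan:::param_arrays(fp), function(a) sum(a^2)))
  expect_equal(classification_objective(s, lab, fp, 0.001),
               oracle + 0.001 * pen, tolerance = 1e-6)
})

test_that("generator objective gradient passes a finite-difference check", {
  set.seed(31)
  co <- generate_cohort(synthetic_config(n_paired_per_class = 1,
                                         n_unpaired_per_class = 0, seed = 3))
  s <- co$subjects[[1]]
  mri <- ffgan:::stack5d(extract_patches(s$mri, 8, 8)$patches)
  pet <- ffgan:::stack5d(extract_patches(s$pet, 8, 8)$patches)
  gen <- build_generator(generator_spec(2, 1 / 16), seed = 6)
  dis <- ffgan:::disc_ensure_head(build_discriminator(discriminator_spec(2, 1 / 16), 7), 8)
  fp <- build_fusion_classifier(fusion_spec(), input_edge = 16, seed = 8)
  w <- loss_weights(100, 100)
  obj <- function(g) {
    fake <- generator_forward(g, mri)
    adv <- adversarial_loss(discriminator_forward(dis, pet),
                            discriminator_forward(dis, fake))
    ffgan:::vof(generator_objective(adv$loss_g, l1_loss(pet, fake),
                                    fusion_loss(fp, mri, pet, fake), w))
  }
  tape <- ffgan:::tape_new()
  wg <- ffgan:::wrap_params(tape, gen)
  fake <- generator_forward(wg, mri)
  adv <- adversarial_loss(discriminator_forward(dis, pet),
                          discriminator_forward(dis, fake))
  total <- generator_objective(adv$loss_g, l1_loss(pet, fake),
                               fusion_loss(fp, mri, pet, fake), w)
  ffgan:::tp_backward(total)
  gr <- ffgan:::grads_of(wg)
  for (trial in 1:5) {
    layer <- sample(2, 1); part <- sample(c("enc", "dec"), 1)
    arr <- gen[[part]][[layer]]$W
    i <- sample(length(arr), 1)
    eps <- 1e-5
    gp <- gen; gp[[part]][[layer]]$W[i] <- gp[[part]][[layer]]$W[i] + eps
    gm <- gen; gm[[part]][[layer]]$W[i] <- gm[[part]][[layer]]$W[i] - eps
    fd <- (obj(gp) - obj(gm)) / (2 * eps)
    an <- gr[[part]][[layer]]$W[i]
    expect_equal(an, fd, tolerance = 1e-3)
  }
})
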