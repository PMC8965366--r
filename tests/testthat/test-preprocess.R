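# Normalization, cropping, patch extraction/reassembly, folds and flips.

test_that("min-max normalization maps extremes to 0/1 and rejects constants", {
  v <- array(c(2, 4, 6, 4, 2, 6, 2, 4), c(2, 2, 2))
  n <- minmax_normalize(v)
  expect_setequal(unique(as.numeric(n)), c(0, 0.5, 1))
  already <- array(seq(0, 1, length.out = 8), c(2, 2, 2))
  expect_equal(minmax_normalize(already), already)
  expect_error(minmax_normalize(array(3, c(2, 2, 2))), "degenerate")
})

test_that("crop_resize removes zero slabs and honors the shape contract", {
  inner <- array(runif(4^3, min = 0.1), c(4, 4, 4))
  padded <- array(0, c(12, 12, 12))
  padded[5:8, 5:8, 5:8] <- inner
  expect_equal(crop_resize(padded, 4), inner)          # exact crop, no resample
  big <- array(runif(6^3, min = 0.1), c(6, 6, 6))
  expect_equal(dim(crop_resize(big, 4)), c(4, 4, 4))
  expect_equal(crop_resize(big, 6), big)               # identity at same size
  expect_error(crop_resize(array(0, c(4, 4, 4)), 4), "all-zero")
})

test_that("patch counts follow the closed form and match brute-force enumeration", {
  # closed form ((E - P)/S + 1)^3 against an explicit window scan
  cases <- list(c(16, 8, 4), c(12, 8, 4), c(8, 8, 4), c(32, 16, 8), c(20, 8, 6))
  for (cs in cases) {
    e <- cs[1]; p <- cs[2]; s <- cs[3]
    brute <- 0L
    for (ox in seq(0, e - p, by = s)) for (oy in seq(0, e - p, by = s)) {
      for (oz in seq(0, e - p, by = s)) brute <- brute + 1L
    }
    ps <- extract_patches(array(0, c(e, e, e)), p, s)
    expect_length(ps$patches, brute)
    expect_equal(length(ps$patches), ((e - p) / s + 1)^3)
  }
  one <- extract_patches(array(runif(8^3), c(8, 8, 8)), 8, 4)
  expect_length(one$patches, 1)
  expect_equal(one$origins[1, ], c(0, 0, 0))
  expect_error(extract_patches(array(0, c(10, 10, 10)), 8, 3), "indivisible")
})

test_that("extract -> reassemble is the identity and overlaps average", {
  set.seed(3)
  for (trial in 1:5) {
    e <- sample(c(8, 12, 16), 1)
    v <- array(runif(e^3), c(e, e, e))
    ps <- extract_patches(v, 8, 4)
    expect_equal(reassemble(ps), v)
  }
  # two half-overlapping patches with constant values a and b -> (a + b) / 2
  ps <- extract_patches(array(0, c(12, 12, 12)), 8, 4)
  ps$patches <- lapply(seq_along(ps$patches), function(i) {
    array(ifelse(all(ps$origins[i, ] == 0), 1, 3), c(8, 8, 8))
  })
  out <- reassemble(ps)
  expect_equal(out[1, 1, 1], 1)                        # covered only by patch a
  expect_equal(out[12, 12, 12], 3)
  expect_equal(out[6, 1, 1], 2)                        # overlap of 1 and 3
  # single patch returns itself
  single <- extract_patches(array(runif(8^3), c(8, 8, 8)), 8, 8)
  expect_equal(reassemble(single), single$patches[[1]])
})

test_that("fold plans stratify, tag unpaired subjects as test, and are reproducible", {
  co <- generate_cohort(synthetic_config(n_paired_per_class = 10,
                                         n_unpaired_per_class = 3, seed = 4))
  plan <- make_folds(co, k = 5, protocol = "incomplete", seed = 7)
  lab <- cohort_labels(co); paired <- ffgan:::cohort_paired(co)
  for (cl in 0:1) {
    sizes <- table(plan$assignments[paired & lab == cl])
    expect_true(max(sizes) - min(sizes) <= 1)
    expect_equal(sum(sizes), 10)
  }
  tagged <- apply_folds(co, plan, val_fold = 5)
  tags <- ffgan:::cohort_tags(tagged)
  expect_true(all(tags[!paired] == "test"))
  expect_true(all(tags[paired] %in% c("train", "validation")))
  expect_identical(make_folds(co, k = 5, protocol = "incomplete", seed = 7)$assignments,
                   plan$assignments)
  expect_error(make_folds(co, k = 11, protocol = "incomplete", seed = 1), "need")

  complete <- apply_folds(co, make_folds(co, k = 5, protocol = "complete", seed = 1))
  ctags <- ffgan:::cohort_tags(complete)
  expect_true(all(ctags[ctags != "train"] %in% c("validation", "test")))
  expect_true(all(ctags[!paired] %in% c("train", "test")))   # unpaired never validate
})

test_that("flip augmentation is an involution applied jointly to both modalities", {
  v <- array(runif(6^3), c(6, 6, 6))
  expect_equal(augment_flip(v, probability = 0), v)
  once <- augment_flip(v, flips = c(TRUE, TRUE))
  expect_equal(augment_flip(once, flips = c(TRUE, TRUE)), v)
  expect_false(isTRUE(all.equal(once, v)))
  co <- generate_cohort(synthetic_config(n_paired_per_class = 1,
                                         n_unpaired_per_class = 0, seed = 1))
  s <- co$subjects[[1]]
  set.seed(42); s1 <- augment_flip_subject(s, probability = 1)
  expect_equal(s1$mri$data, augment_flip(s$mri$data, flips = c(TRUE, TRUE)))
  expect_equal(s1$pet$data, augment_flip(s$pet$data, flips = c(TRUE, TRUE)))
  set.seed(9); a <- augment_flip(v)
  set.seed(9); b <- augment_flip(v)
  expect_identical(a, b)                               # reproducible stream
})
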