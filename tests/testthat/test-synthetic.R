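# The synthetic cohort generator and its NIfTI persistence.

test_that("cohort composition, determinism and degenerate cases", {
  cfg <- synthetic_config(n_paired_per_class = 3, n_unpaired_per_class = 2, seed = 5)
  co <- generate_cohort(cfg)
  paired <- vapply(co$subjects, function(s) !is.null(s$pet), logical(1))
  expect_length(co$subjects, 10)
  expect_equal(sum(paired), 6)
  expect_equal(sum(cohort_labels(co)), 5)              # 3 + 2 of class 1
  # MRI always present; PET absent exactly for unpaired
  expect_true(all(vapply(co$subjects, function(s) !is.null(s$mri), logical(1))))

  co2 <- generate_cohort(cfg)
  expect_identical(co, co2)                            # same (config, seed) -> identical

  empty <- generate_cohort(synthetic_config(n_paired_per_class = 0,
                                            n_unpaired_per_class = 0))
  expect_length(empty$subjects, 0)

  expect_error(synthetic_config(lesion_regions = list(
    list(center = c(1, 8, 8), radius = 3))), "outside the volume")

  imb <- generate_cohort(synthetic_config(n_paired_per_class = 0,
                                          n_unpaired_per_class = 10,
                                          missing_label_policy = "imbalanced"))
  lab <- cohort_labels(imb)
  expect_equal(sum(lab == 0), 5)                       # round(20 * 27/103)
  expect_equal(sum(lab == 1), 15)
})

test_that("identity cross-modal map with zero effect and noise gives PET == MRI", {
  cfg <- synthetic_config(n_paired_per_class = 2, n_unpaired_per_class = 0,
                          noise_sd = 0, effect_size = 0,
                          crossmodal_map = "identity",
                          crossmodal_gain = 1, crossmodal_offset = 0, seed = 2)
  co <- generate_cohort(cfg)
  for (s in co$subjects) {
    expect_identical(s$pet$data, s$mri$data)
  }
})

test_that("planted PET signal is monotone in effect size and absent when zero", {
  # region-mean discriminant as the oracle classifier
  aucs <- sapply(c(0, 0.1, 0.3), function(eff) {
    sapply(1:5, function(seed) {
      co <- generate_cohort(synthetic_config(n_paired_per_class = 20,
                                             n_unpaired_per_class = 0,
                                             effect_size = eff, seed = seed))
      region_mean_auc(co, "pet")
    })
  })
  med <- apply(aucs, 2, median)
  expect_true(med[2] >= med[1] && med[3] >= med[2])
  # no-signal null: with 40 subjects/class the oracle AUC sits in the 95%
  # binomial band around 0.5
  null_aucs <- sapply(1:5, function(seed) {
    co <- generate_cohort(synthetic_config(n_paired_per_class = 40,
                                           n_unpaired_per_class = 0,
                                           effect_size = 0, seed = 100 + seed))
    region_mean_auc(co, "pet")
  })
  sd_null <- sqrt((40 + 40 + 1) / (12 * 40 * 40))
  expect_true(all(abs(null_aucs - 0.5) <= 1.96 * sd_null))
})

test_that("NIfTI round-trip is lossless and errors name the missing subject", {
  dir <- withr::local_tempdir()
  co <- generate_cohort(synthetic_config(n_paired_per_class = 2,
                                         n_unpaired_per_class = 1, seed = 9))
  write_cohort(co, dir)
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"))
  expect_equal(nrow(manifest), length(co$subjects))

  back <- read_cohort(dir)
  for (i in seq_along(co$subjects)) {
    expect_equal(max(abs(back$subjects[[i]]$mri$data - co$subjects[[i]]$mri$data)), 0)
    if (!is.null(co$subjects[[i]]$pet)) {
      expect_equal(max(abs(back$subjects[[i]]$pet$data - co$subjects[[i]]$pet$data)), 0)
    }
  }
  unlink(file.path(dir, "S002_pet.nii.gz"))
  expect_error(read_cohort(dir), "S002")
})
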