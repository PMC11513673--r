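test_that("degenerate noise settings produce identical records", {
  p <- class_profile("CONTROL", mean_stride = 1.1, stride_cv = 0,
                     swing_fraction_mean = 0.38, swing_fraction_sd = 0,
                     lr_asymmetry = 0)
  s <- generate_subject(p, 6, seed = 1)
  r <- s$records
  expect_true(all(vapply(r[-1], function(col) length(unique(col)) == 1L,
                         logical(1))))
  expect_equal(unique(r$left_swing_pct), 38)
  expect_equal(unique(r$left_stride), 1.1)
})

test_that("generation is deterministic in (profile, n, seed) and seed-sensitive", {
  p <- default_profiles()$PD
  a <- generate_subject(p, 30, seed = 42)
  b <- generate_subject(p, 30, seed = 42)
  c <- generate_subject(p, 30, seed = 43)
  expect_identical(a$records, b$records)
  expect_false(isTRUE(all.equal(a$records, c$records)))
})

test_that("stride samples follow the stated lognormal mean/CV law", {
  p <- class_profile("CONTROL", mean_stride = 1.1, stride_cv = 0.05,
                     swing_fraction_mean = 0.38)
  s <- generate_subject(p, 500, seed = 7)
  x <- s$records$left_stride
  se <- 1.1 * 0.05 / sqrt(500)
  expect_lt(abs(mean(x) - 1.1), 3 * se)
  cv_hat <- stats::sd(x) / mean(x)
  expect_gt(cv_hat, 0.04)
  expect_lt(cv_hat, 0.06)
})

test_that("every generated record satisfies the timing identities exactly", {
  for (p in default_profiles()) {
    r <- generate_subject(p, 50, seed = 3)$records
    expect_true(all(abs(r$left_swing + r$left_stance - r$left_stride) < 1e-9))
    expect_true(all(abs(r$right_swing + r$right_stance - r$right_stride) < 1e-9))
    expect_true(all(abs(r$left_swing_pct - 100 * r$left_swing / r$left_stride) < 1e-9))
    expect_true(all(abs(r$right_stance_pct - 100 * r$right_stance / r$right_stride) < 1e-9))
    expect_true(all(abs(r$double_support_pct - 100 * r$double_support / r$left_stride) < 1e-9))
    expect_true(all(diff(r$elapsed_time) > 0))
    expect_true(all(as.matrix(r) > 0))
  }
})

test_that("default profiles are four distinct, valid classes", {
  profs <- default_profiles()
  expect_setequal(vapply(profs, `[[`, "", "label"), GAIT_CLASSES)
  mu <- vapply(profs, `[[`, 0, "mean_stride")
  cv <- vapply(profs, `[[`, 0, "stride_cv")
  expect_equal(anyDuplicated(paste(mu, cv)), 0L)
})

test_that("dataset generation honours counts, ids and the master seed", {
  cfg <- synthetic_config(subjects_per_class = 2, strides_per_subject = 10,
                          seed = 99)
  ds <- generate_dataset(cfg)
  expect_length(ds, 8L)
  expect_equal(sum(vapply(ds, function(s) nrow(s$records), 0L)), 80L)
  expect_setequal(vapply(ds, `[[`, "", "label"), GAIT_CLASSES)
  expect_true(all(grepl("^(als|hunt|park|control)[0-9]+$",
                        vapply(ds, `[[`, "", "subject_id"))))
  ds2 <- generate_dataset(cfg)
  expect_identical(lapply(ds, `[[`, "records"), lapply(ds2, `[[`, "records"))
  ds3 <- generate_dataset(synthetic_config(subjects_per_class = 2,
                                           strides_per_subject = 10, seed = 100))
  expect_false(identical(ds[[1]]$records, ds3[[1]]$records))
})

test_that("the writer emits the 13-column dialect and refuses empty series", {
  s <- generate_subject(default_profiles()$ALS, 3, seed = 2)
  f <- withr::local_tempfile(fileext = ".ts")
  write_subject_file(s, f)
  lines <- readLines(f)
  expect_length(lines, 3L)
  expect_true(all(lengths(strsplit(lines, "[ \t]+")) == 13L))
  s$records <- s$records[0, ]
  expect_error(write_subject_file(s, f), "empty")
})

test_that("write_dataset produces per-subject files plus a manifest", {
  dir <- withr::local_tempdir()
  cfg <- synthetic_config(subjects_per_class = 1, strides_per_subject = 5,
                          seed = 12)
  manifest <- write_dataset(cfg, dir)
  expect_equal(nrow(manifest), 4L)
  expect_true(all(file.exists(manifest$path)))
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  # files read back under the filename-prefix labeling convention
  s <- read_subject_file(manifest$path[manifest$label == "HD"])
  expect_equal(s$label, "HD")
  expect_equal(nrow(s$records), 5L)
})

test_that("optional AR(1) correlation induces autocorrelated strides", {
  p <- default_profiles()$HD
  s <- generate_subject(p, 400, seed = 31, ar1 = 0.8)
  x <- s$records$left_stride
  expect_gt(stats::cor(x[-1], x[-length(x)]), 0.5)
})
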