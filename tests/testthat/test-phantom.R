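test_that("phantom generation is deterministic in config+seed", {
  a <- generate_phantom(small_lesion_config(seed = 3))
  b <- generate_phantom(small_lesion_config(seed = 3))
  c <- generate_phantom(small_lesion_config(seed = 4))
  expect_identical(a$slice$pixels, b$slice$pixels)
  expect_identical(a$truth$tissue_map, b$truth$tissue_map)
  expect_false(identical(a$slice$pixels, c$slice$pixels))
})

test_that("control phantoms have no lesion; lesion phantoms have one connected lesion", {
  ctrl <- generate_phantom(small_control_config())
  expect_equal(sum(ctrl$truth$lesion_mask), 0)
  les <- generate_phantom(small_lesion_config())
  expect_gt(sum(les$truth$lesion_mask), 0)
  expect_equal(max(label_components(les$truth$lesion_mask, 8)), 1)
  # lesion lies inside the body
  body <- les$truth$tissue_map != 1L
  expect_true(all(body[les$truth$lesion_mask]))
})

test_that("fascia HU matches the configured group distributions", {
  les <- generate_phantom(phantom_config(group = "lesion", seed = 11))
  fs <- fascia_hu_stats(les)
  expect_gt(fs$n_pixels, 500)
  expect_lt(abs(fs$mean_hu - (-95.45)), 3 * 8.26 / sqrt(fs$n_pixels))
  ctl <- generate_phantom(phantom_config(group = "control", seed = 12))
  fc <- fascia_hu_stats(ctl)
  expect_lt(abs(fc$mean_hu - (-76.34)), 3 * 7.69 / sqrt(fc$n_pixels))
})

test_that("phantom HU values are finite and in the CT range", {
  for (seed in 1:3) {
    ph <- generate_phantom(small_lesion_config(seed = seed))
    expect_true(all(is.finite(ph$slice$pixels)))
    expect_gte(min(ph$slice$pixels), -1024)
    expect_lte(max(ph$slice$pixels), 3071)
  }
})

test_that("cohort generation respects sizes, groups and thickness ranges", {
  co <- generate_cohort(6, 5, small_lesion_config(), seed = 1)
  expect_length(co, 11)
  groups <- vapply(co, function(s) s$truth$group, "")
  expect_equal(sum(groups == "lesion"), 6)
  has_lesion <- vapply(co, function(s) any(s$truth$lesion_mask), TRUE)
  expect_equal(has_lesion, groups == "lesion")
  th <- vapply(co, function(s) s$truth$skin_thickness_mm, 0)
  expect_true(all(th[groups == "lesion"] >= 4.1 & th[groups == "lesion"] <= 4.9))
  expect_true(all(th[groups == "control"] >= 1.8 & th[groups == "control"] <= 3.6))
  # reproducible; empty cohort allowed
  co2 <- generate_cohort(6, 5, small_lesion_config(), seed = 1)
  expect_identical(co[[3]]$slice$pixels, co2[[3]]$slice$pixels)
  expect_length(generate_cohort(0, 0, small_lesion_config(), seed = 1), 0)
})

test_that("impossible geometry is rejected with a geometry error", {
  expect_error(phantom_config(image_size = 16), "geometry")
  expect_error(phantom_config(lesion_geometry = list(outer_radius_mm = 3,
                                                     core_radius_mm = 5)),
               "geometry")
  # lesion too large for the field of view
  cfg <- phantom_config(image_size = 32, pixel_spacing_mm = 0.5)
  expect_error(generate_phantom(cfg), "geometry")
})

test_that("fascia sample mean converges to the configured mean as n grows", {
  # Monte-Carlo convergence: absolute error shrinks with more pixels pooled
  errs <- vapply(c(1, 4), function(k) {
    means <- vapply(seq_len(k), function(i) {
      ph <- generate_phantom(phantom_config(group = "lesion", seed = 100 + i))
      fascia_hu_stats(ph)$mean_hu
    }, 0)
    abs(mean(means) - (-95.45))
  }, 0)
  expect_lt(errs[2], 1.0)
})
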