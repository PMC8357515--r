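test_that("iterative threshold solves the two-level and constant cases", {
  half <- matrix(c(rep(0, 50), rep(100, 50)), 10, 10)
  th <- iterative_threshold(half)
  expect_equal(th$threshold_hu, 50)
  expect_true(th$converged)

  const <- iterative_threshold(matrix(7, 5, 5))
  expect_equal(const$threshold_hu, 7)
  expect_equal(const$n_iterations, 1L)
  expect_true(const$degenerate)
})

test_that("iterative threshold reaches the two-class-mean fixed point on bimodal data", {
  set.seed(42)
  for (rep in 1:5) {
    px <- matrix(c(rnorm(800, -500, 30), rnorm(800, 50, 30)), 40, 40)
    th <- iterative_threshold(px, tolerance = 0.5)
    expect_true(th$converged)
    expect_lte(th$n_iterations, 100)
    expect_gt(th$threshold_hu, -500)
    expect_lt(th$threshold_hu, 50)
    # fixed-point property by direct recomputation of the class means
    m1 <- mean(px[px <= th$threshold_hu])
    m2 <- mean(px[px > th$threshold_hu])
    expect_lt(abs(th$threshold_hu - (m1 + m2) / 2), 0.5)
    # threshold within the image value range
    expect_gte(th$threshold_hu, min(px))
    expect_lte(th$threshold_hu, max(px))
  }
})

test_that("morphology chain fills holes and removes speckles", {
  # disk with an interior hole: hole is gone, per the flood-fill oracle
  m <- disk_mask(31, 16, 16, 10) & !disk_mask(31, 16, 16, 1.6)
  expect_gt(periseg:::count_holes(m), 0)
  out <- morphology_chain(m, 2)
  expect_equal(periseg:::count_holes(out), 0)
  expect_true(all(out[disk_mask(31, 16, 16, 8)]))

  expect_equal(sum(morphology_chain(matrix(FALSE, 9, 9), 2)), 0)

  # isolated pixel on a 7x7 grid dies in the opening step of the chain
  single <- matrix(FALSE, 7, 7); single[4, 4] <- TRUE
  expect_equal(sum(morphology_chain(single, 1)), 0)
  # hand-evaluated five-step chain on the same toy grid confirms it
  step <- binary_dilate(single, 1)
  step <- binary_erode(step, 1)
  step <- fill_holes(step)
  step <- binary_open(step, 1)
  step <- binary_close(step, 1)
  expect_identical(morphology_chain(single, 1), step)
})

test_that("morphology operators satisfy their lattice properties", {
  set.seed(9)
  for (rep in 1:5) {
    m <- random_mask(24, 0.4)
    op <- binary_open(m, 2)
    cl <- binary_close(m, 2)
    expect_identical(binary_open(op, 2), op)     # idempotent
    expect_identical(binary_close(cl, 2), cl)
    expect_true(all(!op | m))                    # opening anti-extensive
    expect_true(all(!m | cl))                    # closing extensive
    expect_true(all(!m | fill_holes(m)))         # filling never removes
  }
})

test_that("apply_mask selects per pixel and validates shape", {
  ramp <- matrix(as.numeric(seq_len(36)), 6, 6)
  expect_identical(apply_mask(ramp, matrix(TRUE, 6, 6), -5), ramp)
  expect_true(all(apply_mask(ramp, matrix(FALSE, 6, 6), -5) == -5))
  chk <- (row(ramp) + col(ramp)) %% 2 == 0
  out <- apply_mask(ramp, chk, -1024)
  oracle <- ifelse(chk, ramp, -1024)
  expect_equal(out, oracle)
  expect_error(apply_mask(ramp, matrix(TRUE, 3, 3)), "shape")
})

test_that("extract_roi produces one hole-free component covering the body", {
  ph <- generate_phantom(small_lesion_config(seed = 7))
  r <- extract_roi(ph$slice)
  expect_equal(max(label_components(r$roi_mask, 8)), 1)
  expect_equal(periseg:::count_holes(r$roi_mask), 0)
  # masked slice honours the ROI contract
  expect_equal(r$masked_slice$pixels[r$roi_mask], ph$slice$pixels[r$roi_mask])
  expect_true(all(r$masked_slice$pixels[!r$roi_mask] == -1024))

  # noiseless phantom: ROI covers >= 99% of true body pixels
  ph0 <- generate_phantom(noiseless_config(seed = 8))
  r0 <- extract_roi(ph0$slice)
  body <- ph0$truth$tissue_map != 1L
  expect_gte(sum(r0$roi_mask & body) / sum(body), 0.99)
})

test_that("an air-only image yields an empty ROI with a warning", {
  air <- ct_slice(matrix(-1000, 40, 40), 1)
  expect_warning(r <- extract_roi(air), "empty ROI")
  expect_equal(sum(r$roi_mask), 0)
})
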