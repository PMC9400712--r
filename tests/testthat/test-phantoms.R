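test_that("structural phantoms are seed-deterministic, diverse and multimodal", {
  a <- make_structural_phantom(7, 64)
  expect_identical(a, make_structural_phantom(7, 64))
  expect_true(all(a >= 0 & a <= 1))

  # different seeds must differ in at least 1% of pixels (20 seed pairs)
  for (s in 1:20) {
    x <- make_structural_phantom(s, 64)
    y <- make_structural_phantom(s + 1000, 64)
    expect_gt(mean(x != y), 0.01)
  }

  # piecewise-constant anatomy: at least 3 intensity modes (plateaus each
  # covering >= 1% of pixels) on every seed
  for (s in 1:10) {
    x <- make_structural_phantom(s, 64)
    tab <- table(round(as.vector(x), 6))
    expect_gte(sum(tab >= 0.01 * length(x)), 3)
  }
})

test_that("functional phantoms are registered, smooth and deterministic", {
  for (s in 1:10) {
    str <- make_structural_phantom(s, 64)
    fn <- make_functional_phantom(s + 50, 64, str)
    expect_true(all(fn >= 0 & fn <= 1))
    # hotspot centres fall inside the head (structural support)
    centres <- attr(fn, "hotspots")
    expect_true(all(str[centres] > 0.05))
    # low edge content relative to the structural partner
    expect_lt(mean_grad(fn), mean_grad(str))
  }
  str <- make_structural_phantom(1, 64)
  expect_identical(make_functional_phantom(2, 64, str),
                   make_functional_phantom(2, 64, str))
})

test_that("reference fusion is the pixelwise maximum", {
  x <- rand_img(32, 1); y <- rand_img(32, 2)
  expect_identical(make_reference_fusion(x, x), x)
  expect_identical(make_reference_fusion(matrix(0, 32, 32), y), y)
  f <- make_reference_fusion(x, y)
  expect_true(all(f >= x) && all(f >= y))
  expect_identical(f, pmax(x, y))
  expect_error(make_reference_fusion(x, rand_img(16, 3)), "shape")
})

test_that("degradation is identity at level 0 and degrades SSIM monotonically", {
  str <- make_structural_phantom(3, 64)
  fn <- make_functional_phantom(4, 64, str)
  ref <- make_reference_fusion(str, fn)
  expect_identical(degrade_fusion(ref, 0, 1), ref)

  levels <- c(0, 0.2, 0.4, 0.6, 0.8)
  mean_ssim <- vapply(levels, function(L) {
    mean(vapply(1:30, function(s) {
      ssim_index(ref, degrade_fusion(ref, L, s))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_ssim) <= 0))

  out <- degrade_fusion(ref, 0.8, 99)
  expect_true(all(out >= 0 & out <= 1))
})

test_that("phantom spec validates the degradation grid", {
  expect_error(phantom_spec(4, degradation_levels = c(0, 0.2, 0.2, 0.4, 0.6)),
               "strictly increasing")
  expect_error(phantom_spec(4, degradation_levels = c(0.1, 0.2, 0.3, 0.4, 0.5)),
               "first degradation level")
})

test_that("dataset generation is balanced, labelled on the MOS grid and reproducible", {
  dir1 <- withr::local_tempdir()
  spec <- phantom_spec(n_pairs = 4L, side = 48L, seed = 5L)
  man <- make_phantom_dataset(spec, dir1)
  expect_equal(nrow(man), 20L)
  expect_true(all(man$mos %in% c(0.2, 0.4, 0.6, 0.8, 1.0)))
  expect_true(all(table(man$mos) == 4L))   # balanced conditions
  expect_true(all(file.exists(man$fused)))
  reload <- load_manifest(file.path(dir1, "manifest.csv"))
  expect_equal(reload$mos, man$mos)

  dir2 <- withr::local_tempdir()
  man2 <- make_phantom_dataset(spec, dir2)
  expect_equal(man2$mos, man$mos)
  for (i in c(1L, 10L, 20L)) {   # bit-identical images
    expect_identical(load_image(man$fused[i]), load_image(man2$fused[i]))
  }
})

test_that("MOS labels rank-correlate strongly with fused-to-reference SSIM", {
  man <- get_study_dataset()
  keys <- paste(man$mi1, man$mi2)
  sims <- numeric(nrow(man))
  for (key in unique(keys)) {
    rows <- which(keys == key)
    ref <- load_image(man$fused[rows[man$mos[rows] == 1.0]])
    for (r in rows) sims[r] <- ssim_index(ref, load_image(man$fused[r]))
  }
  expect_gte(srcc(man$mos, sims), 0.8)
})
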