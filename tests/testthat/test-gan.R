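test_that("ablation wiring builds the structures each fusion mode describes", {
  w_h <- build_ablation(tiny_config())
  expect_equal(w_h$n_encoders, 2L)
  expect_setequal(names(w_h$safb),
                  c("down1", "down2", "down3", "up1", "up2", "up3"))

  w_e <- build_ablation(tiny_config(fusion_mode = "early"))
  expect_equal(w_e$n_encoders, 1L)        # exactly one encoder stack
  expect_equal(w_e$enc_in_ch, 3L)         # both modalities + MOS plane
  expect_length(w_e$safb, 0L)             # no SA-FBs instantiated
  expect_equal(w_e$dec_out_ch, 2L)        # one reconstruction per modality

  w_l <- build_ablation(tiny_config(fusion_mode = "late"))
  expect_equal(w_l$n_encoders, 2L)
  expect_equal(names(w_l$safb), "fuse3")  # level-3 fusion only
  expect_equal(w_l$safb$fuse3$level, 3L)
})

test_that("generator emits a clipped fused image at the configured side", {
  for (side in c(128L, 64L)) {
    st <- init_model(tiny_config(image_side = side))
    m1 <- rand_img(side, 1); m2 <- rand_img(side, 2)
    f <- generate_fused(m1, m2, 0.6, st)
    expect_equal(dim(f), c(side, side))
    expect_true(all(f >= 0 & f <= 1))
    expect_identical(f, generate_fused(m1, m2, 0.6, st))  # deterministic
  }
  st <- init_model(tiny_config())
  expect_error(generate_fused(rand_img(48, 1), rand_img(32, 2), 0.5, st),
               "shape")
  expect_error(generate_fused(rand_img(48, 1), rand_img(48, 2), 1.5, st),
               "mos")
  expect_error(init_model(tiny_config(image_side = 40L)), "divisible by 16")
})

test_that("each fusion mode and the log-loss variant produce a working generator", {
  for (mode in c("early", "late")) {
    st <- init_model(tiny_config(fusion_mode = mode))
    f <- generate_fused(rand_img(48, 3), rand_img(48, 4), 0.4, st)
    expect_equal(dim(f), c(48L, 48L))
    expect_true(all(is.finite(f)))
  }
})

test_that("discriminator map side follows the conv arithmetic side/16 - 2", {
  cases <- list(c(128L, 6L), c(96L, 4L), c(64L, 2L))
  for (cs in cases) {
    st <- init_model(tiny_config(image_side = cs[1]))
    sm <- discriminate(rand_img(cs[1], 5), 0.5, st)
    expect_equal(dim(sm), c(cs[2], cs[2]))
    expect_true(all(is.finite(sm)))
  }
  st <- init_model(tiny_config())
  expect_error(discriminate(rand_img(32, 1), 0.5, st), "must be 48")
})

test_that("every discriminator block quarters the feature-map area", {
  ns <- asNamespace("fuseqa")
  st <- init_model(tiny_config(image_side = 128L))
  tp <- ns$nn_tape()
  ctx <- ns$nn_pctx(tp, st$params, list2env(st$running), training = FALSE)
  h <- ns$nn_node(tp, array(rand_img(128, 6), c(128, 128, 1, 1)))
  mos <- ns$nn_node(tp, array(0.5, c(128, 128, 1, 1)))
  h <- ns$op_concat_c(tp, h, mos)
  side <- 128L
  for (k in 1:4) {
    h <- ns$op_conv2d(tp, h, ns$nn_pref(ctx, sprintf("d.b%d.W", k)),
                      ns$nn_pref(ctx, sprintf("d.b%d.b", k)), 2L, 1L)
    expect_equal(dim(h$value)[1] * dim(h$value)[2], (side / 2)^2)
    side <- side %/% 2L
  }
})

test_that("generator and discriminator compose", {
  st <- init_model(tiny_config(image_side = 64L))
  f <- generate_fused(rand_img(64, 7), rand_img(64, 8), 0.8, st)
  sm <- discriminate(f, 0.8, st)
  expect_equal(dim(sm), c(2L, 2L))
})

test_that("fusion loss is the mean absolute difference, symmetric, zero at equality", {
  x <- rand_img(16, 1)
  expect_identical(loss_fusion(x, x), 0)
  yt <- matrix(1, 2, 2); yh <- matrix(c(0, 1, 1, 1), 2, 2)
  expect_equal(loss_fusion(yt, yh), 0.25)
  for (s in 1:5) {
    a <- rand_img(8, s); b <- rand_img(8, s + 20)
    brute <- sum(abs(a - b)) / 64
    expect_equal(loss_fusion(a, b), brute, tolerance = 1e-12)
    expect_identical(loss_fusion(a, b), loss_fusion(b, a))
  }
  expect_error(loss_fusion(rand_img(8, 1), rand_img(16, 1)), "shape")
})

test_that("adversarial losses hit their optima and match brute-force values", {
  ones <- matrix(1, 6, 6); zeros <- matrix(0, 6, 6)
  expect_identical(loss_g(ones, 0), 0)
  expect_identical(loss_g(zeros, 0), 1)
  expect_equal(loss_g(ones, 0.01, alpha = 100), 1)
  expect_error(loss_g(ones, 0, alpha = -1), "alpha")
  # monotone in the fusion term at fixed scores
  expect_gt(loss_g(zeros, 0.2), loss_g(zeros, 0.1))

  expect_identical(loss_d(ones, zeros), 0)
  expect_identical(loss_d(zeros, ones), 1)
  expect_equal(loss_d(matrix(0.5, 6, 6), matrix(0.5, 6, 6)), 0.25)
  for (s in 1:5) {
    r <- rand_img(6, s); fk <- rand_img(6, s + 30)
    brute_d <- (mean((r - 1)^2) + mean(fk^2)) / 2
    expect_equal(loss_d(r, fk), brute_d, tolerance = 1e-12)
    brute_g <- mean((fk - 1)^2) + 100 * 0.05
    expect_equal(loss_g(fk, 0.05, 100), brute_g, tolerance = 1e-12)
  }
  expect_error(loss_d(ones, matrix(0, 4, 4)), "shape")
})

test_that("checkpoints round-trip the full model state under a magic string", {
  st <- init_model(tiny_config())
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(st, path)
  back <- load_checkpoint(path)
  expect_identical(back$params, st$params)
  expect_identical(back$running, st$running)
  expect_identical(back$config, st$config)

  junk <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(a = 1), junk)
  expect_error(load_checkpoint(junk), "magic")
})
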