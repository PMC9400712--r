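make_samples <- function(n, side = 48L, seed = 0L) {
  withr::with_seed(seed, {
    lapply(seq_len(n), function(i) {
      str <- make_structural_phantom(sample.int(1e6, 1), side)
      fn <- make_functional_phantom(sample.int(1e6, 1), side, str)
      ref <- make_reference_fusion(str, fn)
      lev <- c(0, 0.2, 0.4, 0.6, 0.8)[((i - 1) %% 5) + 1]
      list(m1 = str, m2 = fn,
           y = degrade_fusion(ref, lev, sample.int(1e6, 1)),
           mos = 1 - lev)
    })
  })
}

test_that("a zero-learning-rate step leaves every parameter bit-identical", {
  st <- init_model(tiny_config(learning_rate = 0))
  batch <- make_samples(2)
  out <- train_step(batch, st)
  expect_identical(out$state$params, st$params)
  expect_true(all(is.finite(out$losses)))
})

test_that("training steps are deterministic and reduce reconstruction loss", {
  cfg <- tiny_config(batch_size = 5L)
  batch <- make_samples(5)
  r1 <- train_step(batch, init_model(cfg))
  r2 <- train_step(batch, init_model(cfg))
  expect_identical(r1$losses, r2$losses)
  expect_identical(r1$state$params, r2$state$params)

  # 50 steps over a 10-sample set: loss_ED trends below its first value
  samples <- make_samples(10)
  st <- init_model(cfg)
  first <- NA
  for (step in 1:50) {
    sel <- ((step - 1) * 5) %% 10 + 1:5
    out <- train_step(samples[sel], st)
    st <- out$state
    if (step == 1) first <- out$losses[["loss_ed"]]
  }
  expect_lt(out$losses[["loss_ed"]], first)
})

test_that("doubling beta doubles the reconstruction contribution to the G-step gradient", {
  ns <- asNamespace("fuseqa")
  st <- init_model(tiny_config())
  batch <- make_samples(3)
  b <- ns$.stack_batch(batch, 48L)
  g_for_beta <- function(beta) {
    tp <- ns$nn_tape()
    ctx <- ns$nn_pctx(tp, st$params, list2env(st$running), training = TRUE)
    gen <- ns$fw_generator(ctx, b$X1, b$X2, b$mos, st$wiring)
    led <- ns$.fw_recon(ctx, gen, b, st$wiring, 48L)
    lfus <- ns$op_mean_abs(tp, gen$fused, array(b$Yt, c(48, 48, 3, 1)))
    total <- ns$op_wsum(tp, list(lfus, led), c(st$config$alpha, beta))
    ns$nn_backward(tp, total)
    ns$nn_grads(ctx)
  }
  g0 <- g_for_beta(0); g1 <- g_for_beta(20); g2 <- g_for_beta(40)
  # decoder parameters receive only the reconstruction gradient
  expect_equal(g2[["dec1.g2.W"]], 2 * g1[["dec1.g2.W"]], tolerance = 1e-10)
  expect_equal(max(abs(g0[["dec1.g2.W"]])), 0)
  # encoder parameters receive both terms, additively in beta
  d21 <- g2[["enc1.b3.c1.W"]] - g1[["enc1.b3.c1.W"]]
  d10 <- g1[["enc1.b3.c1.W"]] - g0[["enc1.b3.c1.W"]]
  expect_equal(d21, d10, tolerance = 1e-8)
})

test_that("train_model records one epoch per record, picks the best SRCC and reproduces", {
  dir <- withr::local_tempdir()
  man <- make_phantom_dataset(phantom_spec(4L, side = 48L, seed = 2L), dir)
  cfg <- tiny_config(epochs = 2L, batch_size = 5L, seed = 3L)
  fit <- suppressWarnings(train_model(man, cfg, quiet = TRUE))
  expect_equal(nrow(fit$history), 2L)
  expect_true(all(is.finite(unlist(fit$history[, c("loss_d", "loss_g", "loss_ed")]))))
  finite_srcc <- fit$history$srcc[is.finite(fit$history$srcc)]
  if (length(finite_srcc)) {
    expect_equal(fit$state$best$srcc, max(finite_srcc))
  }
  fit2 <- suppressWarnings(train_model(man, cfg, quiet = TRUE))
  expect_identical(fit$history, fit2$history)
  expect_identical(fit$state$params, fit2$state$params)
  expect_error(train_model(man[0, ], cfg), "empty manifest")
})

test_that("checkpoint round-trip preserves validation behaviour exactly", {
  dir <- withr::local_tempdir()
  man <- make_phantom_dataset(phantom_spec(2L, side = 48L, seed = 4L), dir)
  cfg <- tiny_config(epochs = 1L, batch_size = 5L, val_fraction = 0)
  fit <- suppressWarnings(train_model(man, cfg, quiet = TRUE))
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(fit$state, path)
  back <- load_checkpoint(path)
  r1 <- suppressWarnings(evaluate_model(man, fit$state))
  r2 <- suppressWarnings(evaluate_model(man, back))
  expect_identical(r1$predicted, r2$predicted)
  expect_identical(r1$rmse, r2$rmse)
})

test_that("the attention-free ablation equals the attention model at gamma = 0", {
  cfg_sa <- tiny_config(seed = 9L)
  cfg_no <- tiny_config(seed = 9L, use_sa = FALSE)
  st_sa <- init_model(cfg_sa)
  st_no <- init_model(cfg_no)
  expect_identical(st_sa$params, st_no$params)   # same draw order
  m1 <- rand_img(48, 1); m2 <- rand_img(48, 2)
  expect_identical(generate_fused(m1, m2, 0.6, st_sa),
                   generate_fused(m1, m2, 0.6, st_no))
  # once the gate opens the paths diverge
  st_sa$params[["safb.down1.sa.gamma"]] <- 0.5
  st_no$params[["safb.down1.sa.gamma"]] <- 0.5
  expect_false(identical(generate_fused(m1, m2, 0.6, st_sa),
                         generate_fused(m1, m2, 0.6, st_no)))
})
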