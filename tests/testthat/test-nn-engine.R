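# Finite-difference verification of the tape engine's analytic gradients.
# Each check perturbs a handful of entries of every input and compares the
# central difference against the backpropagated gradient.

fd_check <- function(make_loss, arrs, eps = 1e-6, tol = 1e-4) {
  r <- make_loss(arrs)
  fuseqa:::nn_backward(r$tape, r$out)
  for (i in seq_along(arrs)) {
    g_an <- r$leaves[[i]]$grad
    if (is.null(g_an)) g_an <- arrs[[i]] * 0
    a <- arrs[[i]]
    idx <- withr::with_seed(i, sample(length(a), min(5L, length(a))))
    for (j in idx) {
      arp <- arrs; arp[[i]][j] <- a[j] + eps
      arm <- arrs; arm[[i]][j] <- a[j] - eps
      g_fd <- (make_loss(arp)$out$value - make_loss(arm)$out$value) / (2 * eps)
      expect_equal(g_an[j], g_fd, tolerance = tol,
                   label = sprintf("analytic grad (input %d, entry %d)", i, j))
    }
  }
}

test_that("convolution gradients match finite differences (all stride/pad modes)", {
  ns <- asNamespace("fuseqa")
  X <- withr::with_seed(1, array(stats::rnorm(6 * 6 * 2 * 3), c(6, 6, 2, 3)))
  W <- withr::with_seed(2, array(stats::rnorm(3 * 3 * 3 * 4, sd = 0.3),
                                 c(3, 3, 3, 4)))
  b <- withr::with_seed(3, stats::rnorm(4))
  for (sp in list(c(1L, 1L), c(2L, 1L), c(1L, 0L))) {
    fd_check(function(a) {
      tp <- ns$nn_tape()
      x <- ns$nn_node(tp, a[[1]]); w <- ns$nn_node(tp, a[[2]])
      bb <- ns$nn_node(tp, a[[3]])
      y <- ns$op_conv2d(tp, x, w, bb, sp[1], sp[2])
      list(tape = tp, out = ns$op_mean_sq_target(tp, y, 0.3),
           leaves = list(x, w, bb))
    }, list(X, W, b))
  }
  Wt <- withr::with_seed(4, array(stats::rnorm(2 * 2 * 3 * 4, sd = 0.3),
                                  c(2, 2, 3, 4)))
  fd_check(function(a) {
    tp <- ns$nn_tape()
    x <- ns$nn_node(tp, a[[1]]); w <- ns$nn_node(tp, a[[2]])
    bb <- ns$nn_node(tp, a[[3]])
    y <- ns$op_convt2(tp, x, w, bb)
    list(tape = tp, out = ns$op_mean_sq_target(tp, y, 0.1),
         leaves = list(x, w, bb))
  }, list(X, Wt, b))
})

test_that("batch-norm, pooling, upsampling and clipping gradients match finite differences", {
  ns <- asNamespace("fuseqa")
  X <- withr::with_seed(5, array(stats::rnorm(6 * 6 * 2 * 3), c(6, 6, 2, 3)))
  gam <- withr::with_seed(6, stats::rnorm(3)); bet <- withr::with_seed(7, stats::rnorm(3))
  fd_check(function(a) {
    tp <- ns$nn_tape()
    run <- new.env()
    ns$bn_running_init(run, "t", 3L)
    ctx <- ns$nn_pctx(tp, list(t.gamma = a[[2]], t.beta = a[[3]]), run,
                      training = TRUE)
    x <- ns$nn_node(tp, a[[1]])
    y <- ns$op_lrelu(tp, ns$op_bn(ctx, x, "t"), 0.2)
    list(tape = tp, out = ns$op_mean_sq_target(tp, y, 0.2),
         leaves = list(x, ns$nn_pref(ctx, "t.gamma"), ns$nn_pref(ctx, "t.beta")))
  }, list(X, gam, bet), eps = 1e-5)

  fd_check(function(a) {
    tp <- ns$nn_tape()
    x <- ns$nn_node(tp, a[[1]])
    u <- ns$op_upnn(tp, ns$op_maxpool2(tp, x))
    cl <- ns$op_clip01(tp, ns$op_concat_c(tp, u, x))
    list(tape = tp, out = ns$op_mean_abs(tp, cl, 0.4), leaves = list(x))
  }, list(X))
})

test_that("self-attention gradients match finite differences", {
  ns <- asNamespace("fuseqa")
  C <- 8L
  Xs <- withr::with_seed(8, array(stats::rnorm(4 * 4 * 2 * C), c(4, 4, 2, C)))
  pr <- withr::with_seed(9, list(
    Wq = ns$init_mat(C, 2L), Wk = ns$init_mat(C, 2L), Wv = ns$init_mat(C, C),
    bq = stats::rnorm(2), bk = stats::rnorm(2), bv = stats::rnorm(C),
    gamma = 0.7))
  fd_check(function(a) {
    tp <- ns$nn_tape()
    nds <- lapply(a, function(v) ns$nn_node(tp, v))
    y <- ns$op_sa(tp, nds[[1]], nds[[2]], nds[[5]], nds[[3]], nds[[6]],
                  nds[[4]], nds[[7]], nds[[8]])
    list(tape = tp, out = ns$op_mean_sq_target(tp, y, 0.1), leaves = nds)
  }, list(Xs, pr$Wq, pr$Wk, pr$Wv, pr$bq, pr$bk, pr$bv, pr$gamma))
})
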