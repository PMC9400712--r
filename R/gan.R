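# Assembly of the conditional generator (dual conditioned encoders + SA-FB
# hierarchy + upsampling head) and the patch discriminator (four stride-2
# blocks + final valid conv), the adversarial losses, and model state
# initialisation / checkpointing.

#' Resolve the model wiring for a fusion mode
#'
#' Translates the configuration's `fusion_mode` / `use_sa` switches into the
#' concrete structure that gets built: how many encoders, which SA-FB blocks
#' exist at which pyramid levels, and the upsampling head. `"hierarchical"`
#' (the full model) fuses all three levels on a down path and re-consumes
#' them on an up path; `"early"` concatenates both modalities and the MOS
#' plane into a single shared encoder and generates from its deepest features
#' alone; `"late"` keeps dual encoders but fuses only the deepest features in
#' a single block.
#'
#' @param config A [run_config()].
#' @return A list describing the wiring (class `fq_wiring`).
#' @export
build_ablation <- function(config) {
  stopifnot(inherits(config, "fq_config"))
  w <- config$channel_widths
  mode <- config$fusion_mode
  safb_blocks <- switch(mode,
    hierarchical = list(
      down1 = list(in_ch = w[1], fsa_ch = 0L,   out_ch = w[1], down = TRUE,  level = 1L),
      down2 = list(in_ch = w[2], fsa_ch = w[1], out_ch = w[2], down = TRUE,  level = 2L),
      down3 = list(in_ch = w[3], fsa_ch = w[2], out_ch = w[3], down = TRUE,  level = 3L),
      up1   = list(in_ch = w[3], fsa_ch = w[3], out_ch = w[3], down = FALSE, level = 3L),
      up2   = list(in_ch = w[2], fsa_ch = w[3], out_ch = w[2], down = FALSE, level = 2L),
      up3   = list(in_ch = w[1], fsa_ch = w[2], out_ch = w[1], down = FALSE, level = 1L)
    ),
    late = list(
      fuse3 = list(in_ch = w[3], fsa_ch = 0L, out_ch = w[3], down = FALSE, level = 3L)
    ),
    early = list()
  )
  ghead <- if (mode == "hierarchical") list() else {
    list(g1 = list(cin = w[3], cout = w[2]),
         g2 = list(cin = w[2], cout = w[1]))
  }
  structure(list(
    mode = mode,
    use_sa = config$use_sa,
    n_encoders = if (mode == "early") 1L else 2L,
    enc_in_ch = if (mode == "early") 3L else 2L,
    widths = w,
    dec_out_ch = if (mode == "early") 2L else 1L,
    dec_plan = dec_plan(w, if (mode == "early") 2L else 1L),
    safb = safb_blocks,
    ghead = ghead,
    head_cin = w[1]
  ), class = "fq_wiring")
}

#' Initialise a model state
#'
#' Draws all generator and discriminator parameters (seeded by the config),
#' sets batch-norm running statistics to (0, 1), attention gates to 0, and
#' attaches empty Adam optimiser state. Requires `image_side` divisible
#' by 16 (three encoder poolings plus one fusion pooling) and at least 48
#' (so the discriminator's final valid convolution has a map to act on).
#'
#' @param config A [run_config()].
#' @return A list of class `fq_model`: `config`, `wiring`, flat named
#'   `params`, `running` statistics, optimiser state and epoch counter.
#' @export
init_model <- function(config) {
  stopifnot(inherits(config, "fq_config"))
  if (config$image_side %% 16 != 0 || config$image_side < 48) {
    stop("the generator/discriminator stack needs image_side divisible by 16 and >= 48")
  }
  wiring <- build_ablation(config)
  w <- wiring$widths
  params <- list()
  running <- list()
  add_bn <- function(prefix, ch) {
    params[[paste0(prefix, ".gamma")]] <<- rep(1, ch)
    params[[paste0(prefix, ".beta")]] <<- numeric(ch)
    running[[paste0(prefix, ".mean")]] <<- numeric(ch)
    running[[paste0(prefix, ".var")]] <<- rep(1, ch)
  }
  add_conv <- function(prefix, k, cin, cout, sd = NULL, bias = 0) {
    cv <- init_conv(k, cin, cout, sd = sd, bias = bias)
    params[[paste0(prefix, ".W")]] <<- cv$W
    params[[paste0(prefix, ".b")]] <<- cv$b
  }
  withr::with_seed(config$seed, {
    for (e in seq_len(wiring$n_encoders)) {
      cins <- c(wiring$enc_in_ch, w[1], w[2])
      for (j in 1:3) {
        pre <- sprintf("enc%d.b%d", e, j)
        add_conv(paste0(pre, ".c1"), 3L, cins[j], w[j])
        add_bn(paste0(pre, ".n1"), w[j])
        add_conv(paste0(pre, ".c2"), 3L, w[j], w[j])
        add_bn(paste0(pre, ".n2"), w[j])
      }
      dec <- sprintf("dec%d", e)
      for (k in seq_along(wiring$dec_plan)) {
        g <- wiring$dec_plan[[k]]
        add_conv(sprintf("%s.g%d", dec, k), if (g$type == "up") 2L else 3L,
                 g$cin, g$cout)
        add_bn(sprintf("%s.g%d.n", dec, k), g$cout)
      }
      add_conv(paste0(dec, ".out"), 3L,
               wiring$dec_plan[[length(wiring$dec_plan)]]$cout,
               wiring$dec_out_ch, sd = 0.01, bias = 0.5)
    }
    for (nm in names(wiring$safb)) {
      blk <- wiring$safb[[nm]]
      bp <- safb_params(blk$in_ch, blk$fsa_ch, blk$out_ch)
      for (pn in names(bp)) params[[sprintf("safb.%s.%s", nm, pn)]] <- bp[[pn]]
      add_bn(sprintf("safb.%s.n1", nm), 2L * blk$in_ch)
      add_bn(sprintf("safb.%s.n3", nm), blk$out_ch)
    }
    for (nm in names(wiring$ghead)) {
      g <- wiring$ghead[[nm]]
      add_conv(sprintf("ghead.%s", nm), 3L, g$cin, g$cout)
      add_bn(sprintf("ghead.%s.n", nm), g$cout)
    }
    add_conv("ghead.out", 3L, wiring$head_cin, 1L, sd = 0.01, bias = 0.5)
    dw <- config$disc_widths
    dcin <- c(2L, dw[1:3])
    for (k in 1:4) {
      add_conv(sprintf("d.b%d", k), 3L, dcin[k], dw[k])
      add_bn(sprintf("d.b%d.n", k), dw[k])
    }
    add_conv("d.out", 3L, dw[4], 1L)
  })
  structure(list(config = config, wiring = wiring, params = params,
                 running = running, opt_g = adam_init(), opt_d = adam_init(),
                 epoch = 0L, best = NULL),
            class = "fq_model")
}

# Generator forward on tape nodes. X1, X2: (H, W, N) arrays; mos: length-N
# vector. Returns fused node plus the per-modality deepest features (decoder
# inputs for the reconstruction loss).
fw_generator <- function(ctx, X1, X2, mos, wiring) {
  tp <- ctx$tape
  use_sa <- wiring$use_sa
  blk <- function(f1, f2, fsa, nm) {
    fw_safb(ctx, f1, f2, fsa, paste0("safb.", nm),
            down = wiring$safb[[nm]]$down, use_sa = use_sa)
  }
  head_conv <- function(u) {
    y <- op_conv2d(tp, u, nn_pref(ctx, "ghead.out.W"),
                   nn_pref(ctx, "ghead.out.b"), 1L, 1L)
    op_clip01(tp, y)
  }
  ghead_stack <- function(u) {
    for (nm in names(wiring$ghead)) {
      u <- op_upnn(tp, u)
      u <- op_conv2d(tp, u, nn_pref(ctx, sprintf("ghead.%s.W", nm)),
                     nn_pref(ctx, sprintf("ghead.%s.b", nm)), 1L, 1L)
      u <- op_relu(tp, op_bn(ctx, u, sprintf("ghead.%s.n", nm)))
    }
    head_conv(op_upnn(tp, u))
  }
  if (wiring$mode == "early") {
    d <- dim(X1)
    cond <- array(0, c(d[1], d[2], d[3], 3L))
    cond[, , , 1L] <- X1
    cond[, , , 2L] <- X2
    cond[, , , 3L] <- rep(mos, each = d[1] * d[2])
    p <- fw_encoder(ctx, nn_node(tp, cond), "enc1")
    return(list(fused = ghead_stack(p[[3]]), pyr = list(p)))
  }
  c1 <- nn_node(tp, .cond_array(X1, mos))
  c2 <- nn_node(tp, .cond_array(X2, mos))
  p1 <- fw_encoder(ctx, c1, "enc1")
  p2 <- fw_encoder(ctx, c2, "enc2")
  if (wiring$mode == "late") {
    u <- blk(p1[[3]], p2[[3]], NULL, "fuse3")
    return(list(fused = ghead_stack(u), pyr = list(p1, p2)))
  }
  s <- blk(p1[[1]], p2[[1]], NULL, "down1")
  s <- blk(p1[[2]], p2[[2]], s, "down2")
  s <- blk(p1[[3]], p2[[3]], s, "down3")
  u <- op_upnn(tp, s)
  u <- blk(p1[[3]], p2[[3]], u, "up1")
  u <- op_upnn(tp, u)
  u <- blk(p1[[2]], p2[[2]], u, "up2")
  u <- op_upnn(tp, u)
  u <- blk(p1[[1]], p2[[1]], u, "up3")
  list(fused = head_conv(op_upnn(tp, u)), pyr = list(p1, p2))
}

# Discriminator forward: candidate node (H, W, N, 1) + mos vector -> score
# map node of side image_side/16 - 2.
fw_discriminator <- function(ctx, cand, mos) {
  tp <- ctx$tape
  d <- dim(cand$value)
  mch <- array(rep(mos, each = d[1] * d[2]), c(d[1], d[2], d[3], 1L))
  h <- op_concat_c(tp, cand, nn_node(tp, mch))
  for (k in 1:4) {
    h <- op_conv2d(tp, h, nn_pref(ctx, sprintf("d.b%d.W", k)),
                   nn_pref(ctx, sprintf("d.b%d.b", k)), 2L, 1L)
    h <- op_lrelu(tp, op_bn(ctx, h, sprintf("d.b%d.n", k)))
  }
  op_conv2d(tp, h, nn_pref(ctx, "d.out.W"), nn_pref(ctx, "d.out.b"), 1L, 0L)
}

# Batched inference-mode generator pass on plain arrays.
gen_infer <- function(X1, X2, mos, state) {
  tp <- nn_tape()
  ctx <- nn_pctx(tp, state$params, list2env(state$running), training = FALSE)
  g <- fw_generator(ctx, X1, X2, mos, state$wiring)
  v <- g$fused$value
  array(v, dim(v)[1:3])
}

#' Generate a fused image at a requested quality level
#'
#' Runs the generator in inference mode: both source images are conditioned
#' with the same MOS value, encoded, hierarchically fused and decoded to a
#' fused image of the configured side, clipped to \[0, 1\]. Deterministic for
#' a fixed state.
#'
#' @param mi1,mi2 Registered source modality images (matrices of the model's
#'   `image_side`; use [resize_image()] first if needed).
#' @param mos Quality condition in \[0, 1\].
#' @param state Model state.
#' @return Fused image matrix in \[0, 1\].
#' @export
generate_fused <- function(mi1, mi2, mos, state) {
  stopifnot(inherits(state, "fq_model"))
  if (!identical(dim(mi1), dim(mi2))) stop("source images differ in shape")
  side <- state$config$image_side
  if (nrow(mi1) != side || ncol(mi1) != side) {
    stop("inputs must be ", side, "x", side, " (resize_image() first)")
  }
  if (mos < 0 || mos > 1) stop("mos must be in [0,1]")
  out <- gen_infer(array(mi1, c(side, side, 1L)),
                   array(mi2, c(side, side, 1L)), mos, state)
  matrix(out, side, side)
}

#' Discriminator score map for a candidate fused image
#'
#' The candidate is concatenated with a constant MOS plane and passed through
#' four stride-2 discriminator blocks (each quartering the feature-map area)
#' and a final valid 3x3 convolution, giving a 6x6 map for 128-side inputs.
#'
#' @param candidate Fused image matrix of the model's `image_side`.
#' @param mos Conditioning MOS in \[0, 1\].
#' @param state Model state.
#' @return Score map matrix of side `image_side/16 - 2`.
#' @export
discriminate <- function(candidate, mos, state) {
  stopifnot(inherits(state, "fq_model"))
  side <- state$config$image_side
  if (nrow(candidate) != side || ncol(candidate) != side) {
    stop("candidate must be ", side, "x", side)
  }
  tp <- nn_tape()
  ctx <- nn_pctx(tp, state$params, list2env(state$running), training = FALSE)
  cand <- nn_node(tp, array(candidate, c(side, side, 1L, 1L)))  # (H, W, N=1, C=1)
  sm <- fw_discriminator(ctx, cand, mos)
  matrix(sm$value, dim(sm$value)[1], dim(sm$value)[2])
}

#' L1 fusion loss
#'
#' Mean absolute pixel difference between the reference fused image and the
#' generated one, averaged over all pixels (and over the batch when given
#' batched arrays).
#'
#' @param y_true,y_hat Arrays of identical shape.
#' @return Non-negative scalar.
#' @export
loss_fusion <- function(y_true, y_hat) {
  if (!identical(dim(y_true), dim(y_hat))) stop("shape mismatch")
  mean(abs(y_true - y_hat))
}

#' Generator objective
#'
#' Least-squares adversarial term (generated scores pulled toward the "real"
#' target 1) plus `alpha` times the L1 fusion loss.
#'
#' @param fake_scores Discriminator score map(s) of generated images.
#' @param l_fusion Value of [loss_fusion()].
#' @param alpha Positive fusion weight.
#' @return Scalar loss.
#' @export
loss_g <- function(fake_scores, l_fusion, alpha = 100) {
  if (alpha <= 0) stop("alpha must be > 0")
  mean((fake_scores - 1)^2) + alpha * l_fusion
}

#' Discriminator objective
#'
#' Least-squares loss with target 1 for real fused images and 0 for
#' generated ones, halved: zero iff the discriminator separates both
#' perfectly with saturated scores.
#'
#' @param real_scores,fake_scores Score maps of identical shape.
#' @return Scalar loss.
#' @export
loss_d <- function(real_scores, fake_scores) {
  if (!identical(dim(real_scores), dim(fake_scores))) stop("shape mismatch")
  (mean((real_scores - 1)^2) + mean(fake_scores^2)) / 2
}

.CKPT_MAGIC <- "fuseqa-checkpoint-v1"

#' Save / load a model checkpoint
#'
#' The checkpoint bundles every parameter tensor, batch-norm running
#' statistic, optimiser moment, the configuration and the epoch/best-metric
#' record, under a versioned magic string.
#'
#' @param state Model state.
#' @param path Checkpoint file path.
#' @return `save_checkpoint`: `path` invisibly; `load_checkpoint`: the state.
#' @export
save_checkpoint <- function(state, path) {
  stopifnot(inherits(state, "fq_model"))
  saveRDS(list(magic = .CKPT_MAGIC, state = state), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path)
  obj <- readRDS(path)
  if (!identical(obj$magic, .CKPT_MAGIC)) {
    stop("not a fuseqa checkpoint (bad magic): ", path)
  }
  obj$state
}
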