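# Self-attention and the self-attention fusion block (SA-FB) that
# hierarchically merges the two modalities' pyramid features. No hand-crafted
# feature selection (no extreme-value picking) happens anywhere: the block is
# a composition of learned linear maps, normalisations and pointwise
# nonlinearities only.

#' Initialise self-attention parameters
#'
#' Query and key project to `channels / 8` dimensions (the cited attention
#' mechanism's standard reduction); the gate `gamma` starts at 0 so the block
#' is initially the identity and attention is blended in during training.
#' Draws from the current RNG state.
#'
#' @param channels Input channel count (>= 8).
#' @return Named list `Wq, bq, Wk, bk, Wv, bv, gamma`.
#' @export
sa_params <- function(channels) {
  stopifnot(channels >= 8)
  cq <- max(1L, channels %/% 8L)
  list(Wq = init_mat(channels, cq), bq = numeric(cq),
       Wk = init_mat(channels, cq), bk = numeric(cq),
       Wv = init_mat(channels, channels), bv = numeric(channels),
       gamma = 0)
}

#' Self-attention over a feature map
#'
#' Query, key and value come from 1x1 convolutions; attention is the
#' row-softmax (computed with max-subtraction, so finite for finite inputs)
#' of query-key inner products over all spatial position pairs; the output is
#' the gated residual `x + gamma * (attention %*% value)`. At `gamma = 0` the
#' operator is exactly the identity.
#'
#' @param f Feature array of dim `(H, W, C)` with `C >= 8`.
#' @param params Parameter list from [sa_params()].
#' @param return_attention If `TRUE`, attach the row-stochastic attention
#'   matrix (`(H*W) x (H*W)`) as attribute `"attention"`.
#' @return Array of the same shape as `f`.
#' @export
self_attention <- function(f, params, return_attention = FALSE) {
  d <- dim(f)
  stopifnot(length(d) == 3L)
  if (d[3] < 8) stop("self-attention requires at least 8 channels")
  tp <- nn_tape()
  nd <- function(v) nn_node(tp, v)
  # an (H, W, C) map and the internal (H, W, 1, C) layout share memory
  x4 <- array(f, c(d[1], d[2], 1L, d[3]))
  out <- op_sa(tp, nd(x4), nd(params$Wq), nd(params$bq), nd(params$Wk),
               nd(params$bk), nd(params$Wv), nd(params$bv), nd(params$gamma))
  val <- array(out$value, d)
  if (return_attention) {
    HW <- d[1] * d[2]
    Xm <- matrix(f, HW, d[3])
    Q <- Xm %*% params$Wq + rep(params$bq, each = HW)
    K <- Xm %*% params$Wk + rep(params$bk, each = HW)
    attr(val, "attention") <- row_softmax(tcrossprod(Q, K))
  }
  val
}

# SA-FB core on tape nodes. Structure: concat(F1j, F2j) -> self-attention
# (bypassed when use_sa is FALSE) -> conv 1x1 -> concat with the running
# fused feature F_sa (omitted when NULL) -> conv 3x3. Down-path blocks use
# BN + LeakyReLU after each conv and max-pool at the end; up-path blocks use
# BN + ReLU and no pooling.
fw_safb <- function(ctx, f1, f2, fsa, prefix, down, use_sa) {
  tp <- ctx$tape
  act <- if (down) function(x) op_lrelu(tp, x) else function(x) op_relu(tp, x)
  z <- op_concat_c(tp, f1, f2)
  if (use_sa) {
    z <- op_sa(tp, z,
               nn_pref(ctx, paste0(prefix, ".sa.Wq")),
               nn_pref(ctx, paste0(prefix, ".sa.bq")),
               nn_pref(ctx, paste0(prefix, ".sa.Wk")),
               nn_pref(ctx, paste0(prefix, ".sa.bk")),
               nn_pref(ctx, paste0(prefix, ".sa.Wv")),
               nn_pref(ctx, paste0(prefix, ".sa.bv")),
               nn_pref(ctx, paste0(prefix, ".sa.gamma")))
  }
  z <- op_conv2d(tp, z, nn_pref(ctx, paste0(prefix, ".c1.W")),
                 nn_pref(ctx, paste0(prefix, ".c1.b")), 1L, 0L)
  z <- act(op_bn(ctx, z, paste0(prefix, ".n1")))
  if (!is.null(fsa)) z <- op_concat_c(tp, z, fsa)
  z <- op_conv2d(tp, z, nn_pref(ctx, paste0(prefix, ".c3.W")),
                 nn_pref(ctx, paste0(prefix, ".c3.b")), 1L, 1L)
  z <- act(op_bn(ctx, z, paste0(prefix, ".n3")))
  if (down) z <- op_maxpool2(tp, z)
  z
}

# Parameters and running statistics for one SA-FB. in_ch is the per-modality
# channel count (the concat sees 2 * in_ch); fsa_ch is the running fused
# feature's channel count (0 for the first block).
safb_params <- function(in_ch, fsa_ch, out_ch) {
  cc <- 2L * in_ch
  p <- list()
  sa <- sa_params(cc)
  for (nm in names(sa)) p[[paste0("sa.", nm)]] <- sa[[nm]]
  c1 <- init_conv(1L, cc, cc)
  p[["c1.W"]] <- c1$W; p[["c1.b"]] <- c1$b
  c3 <- init_conv(3L, cc + fsa_ch, out_ch)
  p[["c3.W"]] <- c3$W; p[["c3.b"]] <- c3$b
  p[["n1.gamma"]] <- rep(1, cc); p[["n1.beta"]] <- numeric(cc)
  p[["n3.gamma"]] <- rep(1, out_ch); p[["n3.beta"]] <- numeric(out_ch)
  p
}

#' Self-attention fusion block
#'
#' Merges the two modalities' features at one pyramid level with the running
#' fused feature. See the package vignette for the wiring; this standalone
#' version runs in inference mode (batch-norm uses unit running statistics)
#' and is primarily useful for inspecting the block's contracts.
#'
#' @param f1,f2 Per-modality feature arrays `(H, W, C)` of identical shape.
#' @param f_sa Running fused feature `(H, W, C_sa)`, or `NULL` for the first
#'   block.
#' @param params Named parameter list from [init_safb_params()].
#' @param down Down-path block (BN + LeakyReLU + max-pool, halving the side)
#'   or up-path block (BN + ReLU, side-preserving)?
#' @param use_sa Bypass self-attention when `FALSE` (the "w/o SA" ablation).
#' @return Fused feature array; side `H/2` when `down`, else `H`.
#' @export
safb <- function(f1, f2, f_sa = NULL, params, down = TRUE, use_sa = TRUE) {
  if (!identical(dim(f1), dim(f2))) stop("f1 and f2 must have identical shape")
  tp <- nn_tape()
  pl <- params
  names(pl) <- paste0("blk.", names(pl))
  run <- new.env(parent = emptyenv())
  bn_running_init(run, "blk.n1", length(params[["n1.gamma"]]))
  bn_running_init(run, "blk.n3", length(params[["n3.gamma"]]))
  ctx <- nn_pctx(tp, pl, run, training = FALSE)
  as4 <- function(a) {
    da <- dim(a)
    nn_node(tp, array(a, c(da[1], da[2], 1L, da[3])))
  }
  z <- fw_safb(ctx, as4(f1), as4(f2),
               if (is.null(f_sa)) NULL else as4(f_sa),
               "blk", down = down, use_sa = use_sa)
  array(z$value, dim(z$value)[c(1L, 2L, 4L)])
}

#' Initialise the parameters of a standalone SA-FB
#'
#' @param in_ch Per-modality input channels (the concatenation has `2*in_ch`,
#'   which must be >= 8 for the attention projections).
#' @param fsa_ch Channels of the running fused feature (0 for none).
#' @param out_ch Output channels.
#' @param seed Seed for the draw.
#' @return Named parameter list for [safb()].
#' @export
init_safb_params <- function(in_ch, fsa_ch = 0L, out_ch = in_ch, seed = 0L) {
  withr::with_seed(seed, safb_params(in_ch, fsa_ch, out_ch))
}
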