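# MOS conditioning, the per-modality three-block encoder producing the
# feature pyramid, the seven-group deconvolutional decoder, and the
# reconstruction loss.

#' Attach a MOS condition plane to an image
#'
#' The scalar mean opinion score joins the image as a second, constant-valued
#' channel, so the conditioning is spatially uniform and survives every
#' convolution.
#'
#' @param img Numeric matrix in \[0, 1\].
#' @param mos Scalar in \[0, 1\].
#' @return An array of dim `c(side, side, 2)`: channel 1 the image, channel 2
#'   the constant MOS plane.
#' @export
condition_image <- function(img, mos) {
  stopifnot(is.matrix(img))
  if (!is.numeric(mos) || length(mos) != 1L || mos < 0 || mos > 1) {
    stop("mos must be a scalar in [0,1]")
  }
  array(c(img, matrix(mos, nrow(img), ncol(img))), c(nrow(img), ncol(img), 2L))
}

# Batched conditioned input: imgs (H, W, N) + mos vector -> (H, W, N, 2).
.cond_array <- function(imgs, mos) {
  d <- dim(imgs)
  out <- array(0, c(d[1], d[2], d[3], 2L))
  out[, , , 1L] <- imgs
  out[, , , 2L] <- rep(mos, each = d[1] * d[2])
  out
}

# One encoder block: [conv3x3 s1 p1 -> BN -> LeakyReLU] x2 -> maxpool 2x2.
fw_enc_block <- function(ctx, x, prefix) {
  tp <- ctx$tape
  h <- op_conv2d(tp, x, nn_pref(ctx, paste0(prefix, ".c1.W")),
                 nn_pref(ctx, paste0(prefix, ".c1.b")), 1L, 1L)
  h <- op_lrelu(tp, op_bn(ctx, h, paste0(prefix, ".n1")))
  h <- op_conv2d(tp, h, nn_pref(ctx, paste0(prefix, ".c2.W")),
                 nn_pref(ctx, paste0(prefix, ".c2.b")), 1L, 1L)
  h <- op_lrelu(tp, op_bn(ctx, h, paste0(prefix, ".n2")))
  op_maxpool2(tp, h)
}

# Full encoder: returns the three post-pooling pyramid levels (sides
# side/2, side/4, side/8).
fw_encoder <- function(ctx, x, enc) {
  lv <- vector("list", 3L)
  h <- x
  for (j in 1:3) {
    h <- fw_enc_block(ctx, h, sprintf("%s.b%d", enc, j))
    lv[[j]] <- h
  }
  lv
}

# Decoder: seven groups of (deconvolution -> BN -> ReLU) bridging side/8 to
# side -- three exact x2 transposed convolutions interleaved with four
# stride-1 refiners -- then a linear 3x3 output conv clipped to [0, 1].
fw_decoder <- function(ctx, top, dec, plan) {
  tp <- ctx$tape
  h <- top
  for (k in seq_along(plan)) {
    g <- plan[[k]]
    wn <- sprintf("%s.g%d.W", dec, k); bn <- sprintf("%s.g%d.b", dec, k)
    h <- if (g$type == "up") {
      op_convt2(tp, h, nn_pref(ctx, wn), nn_pref(ctx, bn))
    } else {
      op_conv2d(tp, h, nn_pref(ctx, wn), nn_pref(ctx, bn), 1L, 1L)
    }
    h <- op_relu(tp, op_bn(ctx, h, sprintf("%s.g%d.n", dec, k)))
  }
  h <- op_conv2d(tp, h, nn_pref(ctx, paste0(dec, ".out.W")),
                 nn_pref(ctx, paste0(dec, ".out.b")), 1L, 1L)
  op_clip01(tp, h)
}

# Decoder channel plan given encoder widths and output channel count.
dec_plan <- function(widths, out_ch = 1L) {
  w1 <- widths[1]; w2 <- widths[2]; w3 <- widths[3]
  h <- max(4L, w1 %/% 2L)
  list(
    list(type = "conv", cin = w3, cout = w3),
    list(type = "up",   cin = w3, cout = w2),
    list(type = "conv", cin = w2, cout = w2),
    list(type = "up",   cin = w2, cout = w1),
    list(type = "conv", cin = w1, cout = w1),
    list(type = "up",   cin = w1, cout = h),
    list(type = "conv", cin = h,  cout = h)
  )
}

#' Encode a conditioned image into its feature pyramid
#'
#' Runs one of the model's encoders in inference mode. Each of the three
#' blocks applies two (conv 3x3, stride 1, pad 1) + BN + LeakyReLU layers and
#' a 2x2 max-pool, so pyramid level j has side `side / 2^j`.
#'
#' @param cond Conditioned image from [condition_image()] (side divisible
#'   by 8), or a plain matrix for ablation modes with other input widths.
#' @param state A model state from [init_model()] or [train_model()].
#' @param modality Which encoder to use (1 or 2).
#' @return List of three feature arrays of dim `(side/2^j, side/2^j, width_j)`.
#' @export
encode_features <- function(cond, state, modality = 1L) {
  stopifnot(length(dim(cond)) == 3L)
  d <- dim(cond)
  if (d[1] %% 8 != 0) stop("input side must be divisible by 8")
  if (modality > state$wiring$n_encoders) stop("no such encoder: ", modality)
  # a single (H, W, C) map and the internal (H, W, 1, C) layout share memory
  x <- array(cond, c(d[1], d[2], 1L, d[3]))
  tp <- nn_tape()
  ctx <- nn_pctx(tp, state$params, list2env(state$running), training = FALSE)
  lv <- fw_encoder(ctx, nn_node(tp, x), sprintf("enc%d", modality))
  lapply(lv, function(nd) {
    dd <- dim(nd$value)
    array(nd$value, dd[c(1L, 2L, 4L)])
  })
}

#' Reconstruct an image from the deepest pyramid level
#'
#' Runs one of the model's decoders in inference mode on the third (deepest,
#' post-pooling) feature map; the output side is 8 times the input side,
#' i.e. the configured image side.
#'
#' @param top Feature array of dim `(side/8, side/8, width_3)`.
#' @param state Model state.
#' @param modality Which decoder to use.
#' @return Reconstructed image: a matrix in \[0, 1\] (or an array with one
#'   plane per reconstructed modality in early-fusion mode).
#' @export
decode_features <- function(top, state, modality = 1L) {
  stopifnot(length(dim(top)) == 3L)
  side <- state$config$image_side
  if (dim(top)[1] != side %/% 8L) {
    stop("decoder input side must be image_side/8 = ", side %/% 8L)
  }
  if (modality > state$wiring$n_encoders) stop("no such decoder: ", modality)
  tp <- nn_tape()
  ctx <- nn_pctx(tp, state$params, list2env(state$running), training = FALSE)
  dt <- dim(top)
  x <- nn_node(tp, array(top, c(dt[1], dt[2], 1L, dt[3])))
  y <- fw_decoder(ctx, x, sprintf("dec%d", modality), state$wiring$dec_plan)
  out <- y$value
  if (dim(out)[4] == 1L) matrix(out, dim(out)[1], dim(out)[2])
  else array(out, dim(out)[c(1L, 2L, 4L)])
}

#' Encoder-decoder reconstruction loss
#'
#' The unnormalised sum of absolute differences between each source modality
#' image and its reconstruction, summed over modalities. (The training loop
#' applies a per-pixel normalisation before weighting this term, so the
#' default weight is stable across image sides.)
#'
#' @param pairs List of `list(mi = original, rec = reconstruction)` pairs
#'   (one per modality), each a matrix or array of matching shape.
#' @return Non-negative scalar; zero iff every reconstruction is exact.
#' @export
loss_ed <- function(pairs) {
  total <- 0
  for (p in pairs) {
    if (!identical(dim(p$mi), dim(p$rec))) {
      stop("reconstruction shape does not match source image")
    }
    total <- total + sum(abs(p$mi - p$rec))
  }
  total
}
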