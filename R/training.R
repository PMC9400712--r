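# Alternating adversarial optimisation: one discriminator step (generator
# detached) then one generator + encoder-decoder step per batch, with the
# reconstruction term weighted by beta, per-epoch validation scoring, and
# best-SRCC checkpoint selection.

# Stack a list of samples (each list(m1, m2, y, mos)) into batch arrays.
.stack_batch <- function(batch, side) {
  N <- length(batch)
  X1 <- array(0, c(side, side, N)); X2 <- X1; Yt <- X1
  mos <- numeric(N)
  for (i in seq_len(N)) {
    X1[, , i] <- batch[[i]]$m1
    X2[, , i] <- batch[[i]]$m2
    Yt[, , i] <- batch[[i]]$y
    mos[i] <- batch[[i]]$mos
  }
  list(X1 = X1, X2 = X2, Yt = Yt, mos = mos)
}

.chk_finite <- function(value, term) {
  if (!is.finite(value)) stop("non-finite ", term, " (", value, "); aborting")
  value
}

# Reconstruction term (per-pixel mean absolute error over both modalities)
# on tape nodes; gradient reaches only encoder and decoder parameters plus
# the shared encoder activations.
.fw_recon <- function(ctx, gen, b, wiring, side) {
  tp <- ctx$tape
  N <- length(b$mos)
  if (wiring$mode == "early") {
    rec <- fw_decoder(ctx, gen$pyr[[1]][[3]], "dec1", wiring$dec_plan)
    target <- array(0, c(side, side, N, 2L))
    target[, , , 1L] <- b$X1
    target[, , , 2L] <- b$X2
    op_mean_abs(tp, rec, target)
  } else {
    r1 <- fw_decoder(ctx, gen$pyr[[1]][[3]], "dec1", wiring$dec_plan)
    r2 <- fw_decoder(ctx, gen$pyr[[2]][[3]], "dec2", wiring$dec_plan)
    t1 <- array(b$X1, c(side, side, N, 1L))
    t2 <- array(b$X2, c(side, side, N, 1L))
    op_wsum(tp, list(op_mean_abs(tp, r1, t1), op_mean_abs(tp, r2, t2)),
            c(0.5, 0.5))
  }
}

#' One adversarial training step
#'
#' Updates the discriminator on real versus generated fused images (with the
#' generator detached), then updates the generator and encoder-decoders on
#' the adversarial term plus `alpha` x L1 fusion loss plus `beta` x the
#' (per-pixel normalised) reconstruction loss, all conditioned on the batch's
#' true MOS values. Batch-norm runs in training mode; any non-finite loss
#' aborts with the offending term named.
#'
#' @param batch Nonempty list of samples, each a list with matrices `m1`,
#'   `m2`, `y` (pre-resized to `image_side`) and scalar `mos`.
#' @param state Model state from [init_model()].
#' @return List `state` (updated) and `losses` (named: `loss_d`, `loss_g`,
#'   `loss_ed`).
#' @export
train_step <- function(batch, state) {
  stopifnot(inherits(state, "fq_model"), length(batch) >= 1L)
  cfg <- state$config
  side <- cfg$image_side
  b <- .stack_batch(batch, side)
  N <- length(b$mos)
  runenv <- list2env(state$running)
  lsgan <- cfg$adv_loss == "lsgan"

  # generator forward (training mode), reused for both updates
  tpG <- nn_tape()
  ctxG <- nn_pctx(tpG, state$params, runenv, training = TRUE)
  gen <- fw_generator(ctxG, b$X1, b$X2, b$mos, state$wiring)
  Yt4 <- array(b$Yt, c(side, side, N, 1L))

  # discriminator update (generator detached)
  tpD <- nn_tape()
  ctxD <- nn_pctx(tpD, state$params, runenv, training = TRUE)
  sr <- fw_discriminator(ctxD, nn_node(tpD, Yt4), b$mos)
  sf <- fw_discriminator(ctxD, nn_node(tpD, gen$fused$value), b$mos)
  lD <- if (lsgan) {
    op_wsum(tpD, list(op_mean_sq_target(tpD, sr, 1),
                      op_mean_sq_target(tpD, sf, 0)), c(0.5, 0.5))
  } else {
    op_wsum(tpD, list(op_softplus_mean(tpD, sr, -1),
                      op_softplus_mean(tpD, sf, 1)), c(1, 1))
  }
  .chk_finite(lD$value, "discriminator loss")
  nn_backward(tpD, lD)
  up <- adam_step(state$params, state$opt_d, nn_grads(ctxD), cfg$learning_rate)
  state$params <- up$params; state$opt_d <- up$opt

  # generator + encoder-decoder update (against the updated discriminator)
  sf2 <- fw_discriminator(ctxG, gen$fused, b$mos)
  adv <- if (lsgan) op_mean_sq_target(tpG, sf2, 1)
         else op_softplus_mean(tpG, sf2, -1)
  lfus <- op_mean_abs(tpG, gen$fused, Yt4)
  led <- .fw_recon(ctxG, gen, b, state$wiring, side)
  .chk_finite(adv$value, "adversarial generator term")
  .chk_finite(lfus$value, "fusion loss")
  .chk_finite(led$value, "reconstruction loss")
  total <- op_wsum(tpG, list(adv, lfus, led), c(1, cfg$alpha, cfg$beta))
  nn_backward(tpG, total)
  gAll <- nn_grads(ctxG)
  gG <- gAll[!startsWith(names(gAll), "d.")]
  up <- adam_step(state$params, state$opt_g, gG, cfg$learning_rate)
  state$params <- up$params; state$opt_g <- up$opt
  state$running <- as.list(runenv)

  list(state = state,
       losses = c(loss_d = lD$value,
                  loss_g = adv$value + cfg$alpha * lfus$value,
                  loss_ed = led$value))
}

# Load and cache an image resized to the network side.
.img_cache_get <- function(cache, path, side) {
  img <- cache[[path]]
  if (is.null(img)) {
    img <- resize_image(load_image(path), side)
    cache[[path]] <- img
  }
  img
}

# Predicted quality for manifest records, generating each pair's five
# conditioned images once and reusing them across that pair's fused records.
.predict_q <- function(recs, state, cache) {
  side <- state$config$image_side
  mos_grid <- c(0.2, 0.4, 0.6, 0.8, 1.0)
  keys <- paste(recs$mi1, recs$mi2)
  preds <- numeric(nrow(recs))
  for (key in unique(keys)) {
    rows <- which(keys == key)
    m1 <- .img_cache_get(cache, recs$mi1[rows[1]], side)
    m2 <- .img_cache_get(cache, recs$mi2[rows[1]], side)
    fakes <- gen_infer(array(rep(m1, 5L), c(side, side, 5L)),
                       array(rep(m2, 5L), c(side, side, 5L)),
                       mos_grid, state)
    for (r in rows) {
      fused <- .img_cache_get(cache, recs$fused[r], side)
      sims <- vapply(1:5, function(k) {
        ssim_index(fused, matrix(fakes[, , k], side, side))
      }, numeric(1))
      preds[r] <- mos_grid[which.max(sims)]
    }
  }
  preds
}

#' Train the quality-assessment model
#'
#' Runs up to `config$epochs` epochs of alternating adversarial optimisation
#' on the manifest's samples. A validation split (default 20% of image
#' pairs, carved deterministically from the seed, with all five fused
#' variants of a pair kept on one side to prevent leakage) is scored after
#' every epoch via the five-condition SSIM scorer, and the returned model is
#' the checkpoint with the highest validation SRCC.
#'
#' @param manifest Manifest data.frame from [load_manifest()] or
#'   [make_phantom_dataset()].
#' @param config A [run_config()].
#' @param quiet Suppress per-epoch log lines?
#' @return List with `state` (the best checkpoint; `state$best` records its
#'   epoch and SRCC) and `history` (one row per epoch: losses and validation
#'   SRCC/KRCC/PLCC/RMSE).
#' @export
train_model <- function(manifest, config, quiet = FALSE) {
  stopifnot(inherits(config, "fq_config"))
  if (nrow(manifest) == 0L) stop("empty manifest")
  side <- config$image_side
  cache <- new.env(parent = emptyenv())
  keys <- paste(manifest$mi1, manifest$mi2)
  pairs <- unique(keys)
  n_val <- if (config$val_fraction > 0 && length(pairs) > 1L) {
    max(1L, round(config$val_fraction * length(pairs)))
  } else 0L
  state <- init_model(config)
  hist_rows <- vector("list", config$epochs)
  best <- list(epoch = NA_integer_, srcc = -Inf,
               params = state$params, running = state$running)
  withr::with_seed(config$seed, {
    val_pairs <- if (n_val > 0) sample(pairs, n_val) else character(0)
    val_idx <- which(keys %in% val_pairs)
    tr_idx <- setdiff(seq_len(nrow(manifest)), val_idx)
    if (length(tr_idx) == 0L) stop("validation split left no training samples")
    samples <- lapply(seq_len(nrow(manifest)), function(i) {
      list(m1 = .img_cache_get(cache, manifest$mi1[i], side),
           m2 = .img_cache_get(cache, manifest$mi2[i], side),
           y = .img_cache_get(cache, manifest$fused[i], side),
           mos = manifest$mos[i])
    })
    for (epoch in seq_len(config$epochs)) {
      ord <- sample(tr_idx)
      bs <- config$batch_size
      losses <- c(loss_d = 0, loss_g = 0, loss_ed = 0)
      nb <- 0L
      for (start in seq(1L, length(ord), by = bs)) {
        sel <- ord[start:min(start + bs - 1L, length(ord))]
        st <- train_step(samples[sel], state)
        state <- st$state
        losses <- losses + st$losses
        nb <- nb + 1L
      }
      losses <- losses / nb
      if (length(val_idx) > 0L) {
        preds <- .predict_q(manifest[val_idx, ], state, cache)
        labs <- manifest$mos[val_idx]
        met <- suppressWarnings(c(srcc = srcc(preds, labs),
                                  krcc = krcc(preds, labs),
                                  plcc = plcc(preds, labs),
                                  rmse = rmse(preds, labs)))
      } else {
        met <- c(srcc = NA_real_, krcc = NA_real_, plcc = NA_real_,
                 rmse = NA_real_)
      }
      state$epoch <- epoch
      hist_rows[[epoch]] <- data.frame(epoch = epoch, t(losses), t(met))
      if (is.finite(met[["srcc"]]) && met[["srcc"]] > best$srcc) {
        best <- list(epoch = epoch, srcc = met[["srcc"]],
                     params = state$params, running = state$running)
      }
      if (!quiet) {
        fq_log(sprintf(
          "epoch %d/%d  loss_D %.4f  loss_G %.4f  loss_ED %.4f  val SRCC %s",
          epoch, config$epochs, losses[["loss_d"]], losses[["loss_g"]],
          losses[["loss_ed"]],
          if (is.finite(met[["srcc"]])) sprintf("%.3f", met[["srcc"]]) else "NA"))
      }
    }
  })
  history <- do.call(rbind, hist_rows)
  if (!is.finite(best$srcc)) {
    warning("validation SRCC was never defined; returning the final epoch")
    best$epoch <- state$epoch
    best$srcc <- NA_real_
    best$params <- state$params
    best$running <- state$running
  }
  state$params <- best$params
  state$running <- best$running
  state$best <- list(epoch = best$epoch, srcc = best$srcc)
  list(state = state, history = history)
}
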