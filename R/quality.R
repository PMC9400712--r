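# SSIM, the five-condition quality scorer, and the SRCC/KRCC/PLCC/RMSE
# agreement metrics.

# 1-D Gaussian window, normalised.
.gauss_win <- function(window, sigma) {
  half <- (window - 1) / 2
  w <- exp(-((-half):half)^2 / (2 * sigma^2))
  w / sum(w)
}

# Separable valid-mode windowed filtering of a matrix.
.win_filter <- function(m, w) {
  k <- length(w)
  H <- nrow(m); W <- ncol(m)
  r <- matrix(0, H - k + 1L, W)
  for (i in seq_len(k)) r <- r + w[i] * m[i:(H - k + i), , drop = FALSE]
  out <- matrix(0, H - k + 1L, W - k + 1L)
  for (j in seq_len(k)) out <- out + w[j] * r[, j:(W - k + j), drop = FALSE]
  out
}

#' Structural similarity index
#'
#' Windowed SSIM with the standard settings: 11x11 Gaussian
#' weights (sigma 1.5), stabilisers K1 = 0.01 and K2 = 0.03, dynamic range
#' L = 1 (images live in \[0, 1\]), averaged over all valid windows.
#' Symmetric in its arguments; 1 exactly for identical images.
#'
#' @param a,b Matrices of identical dimension, side at least the window.
#' @param window Window side (odd).
#' @param sigma Gaussian window width.
#' @param k1,k2 Stabiliser constants.
#' @return Scalar mean SSIM in \[-1, 1\].
#' @export
ssim_index <- function(a, b, window = 11L, sigma = 1.5, k1 = 0.01, k2 = 0.03) {
  if (!identical(dim(a), dim(b))) stop("images differ in shape")
  if (nrow(a) < window || ncol(a) < window) {
    stop("images smaller than the ", window, "x", window, " SSIM window")
  }
  w <- .gauss_win(window, sigma)
  mu1 <- .win_filter(a, w); mu2 <- .win_filter(b, w)
  s11 <- .win_filter(a * a, w) - mu1^2
  s22 <- .win_filter(b * b, w) - mu2^2
  s12 <- .win_filter(a * b, w) - mu1 * mu2
  c1 <- k1^2; c2 <- k2^2
  mean(((2 * mu1 * mu2 + c1) * (2 * s12 + c2)) /
         ((mu1^2 + mu2^2 + c1) * (s11 + s22 + c2)))
}

#' Score the quality of a fused image
#'
#' Generates five candidate fusions of the two source images, one per MOS
#' condition on the grid 0.2k (k = 1..5), computes the SSIM between the
#' fused image under assessment and each candidate, and returns the MOS of
#' the most similar candidate. Ties break toward the smallest k (the
#' conservative quality call). Inputs not at the model's side are resized
#' with a warning.
#'
#' @param fi1,fi2 Registered source modality images (matrices).
#' @param fi12 The fused image to assess.
#' @param state Model state.
#' @param gen_fn Optional override for the generator: a function taking the
#'   MOS vector and returning a list of candidate matrices (used to probe
#'   the selection rule in isolation).
#' @return List of class `fq_quality`: `ssim_by_k` (five SSIM values), `q`
#'   (selected MOS on the five-point grid) and `argmax_k`.
#' @export
score_quality <- function(fi1, fi2, fi12, state, gen_fn = NULL) {
  side <- state$config$image_side
  fix <- function(img, nm) {
    if (nrow(img) != side || ncol(img) != side) {
      warning(nm, " resized to the model side ", side)
      resize_image(img, side)
    } else img
  }
  fi1 <- fix(fi1, "fi1"); fi2 <- fix(fi2, "fi2"); fi12 <- fix(fi12, "fi12")
  mos_k <- c(0.2, 0.4, 0.6, 0.8, 1.0)
  cands <- if (is.null(gen_fn)) {
    fakes <- gen_infer(array(rep(fi1, 5L), c(side, side, 5L)),
                       array(rep(fi2, 5L), c(side, side, 5L)), mos_k, state)
    lapply(1:5, function(k) matrix(fakes[, , k], side, side))
  } else {
    gen_fn(mos_k)
  }
  sims <- vapply(cands, function(cand) ssim_index(fi12, cand), numeric(1))
  k <- which.max(sims)   # first maximum: ties go to the smallest k
  structure(list(ssim_by_k = sims, q = mos_k[k], argmax_k = k),
            class = "fq_quality")
}

#' @export
print.fq_quality <- function(x, ...) {
  cat("Fused-image quality: Q =", x$q, "\n")
  cat("SSIM by MOS condition:",
      paste(sprintf("%.1f: %.4f", c(0.2, 0.4, 0.6, 0.8, 1.0), x$ssim_by_k),
            collapse = "  "),
      "\n")
  invisible(x)
}

.check_corr_input <- function(x, y) {
  if (length(x) != length(y)) stop("vectors differ in length")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance input: correlation undefined")
    return(FALSE)
  }
  TRUE
}

#' Agreement metrics between objective scores and MOS
#'
#' `srcc`: Spearman rank correlation (average ranks for ties); `krcc`:
#' Kendall's tau-b (tie-corrected -- grid-valued predictions guarantee
#' ties); `plcc`: Pearson correlation; `rmse`: root-mean-square error.
#' Correlations return `NA` with a warning when either input has zero
#' variance.
#'
#' @param x,y Numeric vectors of equal length (>= 3 for correlations).
#' @return Scalar metric value.
#' @export
srcc <- function(x, y) {
  if (!.check_corr_input(x, y)) return(NA_real_)
  stats::cor(x, y, method = "spearman")
}

#' @rdname srcc
#' @export
krcc <- function(x, y) {
  if (!.check_corr_input(x, y)) return(NA_real_)
  stats::cor(x, y, method = "kendall")
}

#' @rdname srcc
#' @export
plcc <- function(x, y) {
  if (!.check_corr_input(x, y)) return(NA_real_)
  stats::cor(x, y, method = "pearson")
}

#' @rdname srcc
#' @export
rmse <- function(x, y) {
  if (length(x) != length(y)) stop("vectors differ in length")
  if (length(x) < 1L) stop("need at least 1 observation")
  sqrt(mean((x - y)^2))
}

#' Evaluate a model against a labelled manifest
#'
#' Scores every fused record with [score_quality()] (generating each pair's
#' five candidates once) and reports the agreement between the predicted
#' quality and the manifest's MOS labels.
#'
#' @param manifest Manifest data.frame.
#' @param state Model state.
#' @return List of class `fq_agreement`: `srcc`, `krcc`, `plcc`, `rmse`,
#'   `n`, and the per-record `predicted` grid values.
#' @export
evaluate_model <- function(manifest, state) {
  if (nrow(manifest) == 0L) stop("empty manifest")
  cache <- new.env(parent = emptyenv())
  preds <- .predict_q(manifest, state, cache)
  labs <- manifest$mos
  structure(list(srcc = srcc(preds, labs), krcc = krcc(preds, labs),
                 plcc = plcc(preds, labs), rmse = rmse(preds, labs),
                 n = nrow(manifest), predicted = preds),
            class = "fq_agreement")
}

#' @export
print.fq_agreement <- function(x, ...) {
  cat(sprintf("Agreement over %d fused images:\n", x$n))
  cat(sprintf("  SRCC %.4f  KRCC %.4f  PLCC %.4f  RMSE %.4f\n",
              x$srcc, x$krcc, x$plcc, x$rmse))
  invisible(x)
}
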