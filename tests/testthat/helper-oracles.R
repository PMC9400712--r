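# Independent brute-force oracles: direct-from-definition implementations
# used to cross-check the package's vectorised/packaged routines. They share
# no code with the implementation paths they verify.

rand_img <- function(side, seed) {
  withr::with_seed(seed, matrix(stats::runif(side * side), side, side))
}

# SSIM by explicit per-window evaluation with Gaussian weights.
ssim_brute <- function(a, b, window = 11L, sigma = 1.5, k1 = 0.01, k2 = 0.03) {
  half <- (window - 1) / 2
  g <- exp(-((-half):half)^2 / (2 * sigma^2))
  W2 <- outer(g, g)
  W2 <- W2 / sum(W2)
  H <- nrow(a); W <- ncol(a)
  vals <- c()
  for (i in seq_len(H - window + 1L)) {
    for (j in seq_len(W - window + 1L)) {
      wa <- a[i:(i + window - 1L), j:(j + window - 1L)]
      wb <- b[i:(i + window - 1L), j:(j + window - 1L)]
      mu1 <- sum(W2 * wa); mu2 <- sum(W2 * wb)
      v1 <- sum(W2 * wa^2) - mu1^2
      v2 <- sum(W2 * wb^2) - mu2^2
      cv <- sum(W2 * wa * wb) - mu1 * mu2
      c1 <- k1^2; c2 <- k2^2
      vals <- c(vals, ((2 * mu1 * mu2 + c1) * (2 * cv + c2)) /
                        ((mu1^2 + mu2^2 + c1) * (v1 + v2 + c2)))
    }
  }
  mean(vals)
}

rank_avg_brute <- function(x) {
  vapply(seq_along(x), function(i) {
    sum(x < x[i]) + (sum(x == x[i]) + 1) / 2
  }, numeric(1))
}

pearson_brute <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- n * sum(x * y) - sx * sy
  den <- sqrt(n * sum(x^2) - sx^2) * sqrt(n * sum(y^2) - sy^2)
  num / den
}

spearman_brute <- function(x, y) pearson_brute(rank_avg_brute(x), rank_avg_brute(y))

# Kendall tau-b by explicit pair enumeration with tie correction.
kendall_brute <- function(x, y) {
  n <- length(x)
  conc <- 0; disc <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    s <- sign(x[i] - x[j]) * sign(y[i] - y[j])
    if (s > 0) conc <- conc + 1 else if (s < 0) disc <- disc + 1
  }
  n0 <- n * (n - 1) / 2
  tx <- table(x); ty <- table(y)
  n1 <- sum(tx * (tx - 1) / 2)
  n2 <- sum(ty * (ty - 1) / 2)
  (conc - disc) / sqrt((n0 - n1) * (n0 - n2))
}

rmse_brute <- function(x, y) {
  s <- 0
  for (i in seq_along(x)) s <- s + (x[i] - y[i])^2
  sqrt(s / length(x))
}

# Mean absolute gradient magnitude (forward differences).
mean_grad <- function(img) {
  gx <- img[-1, ] - img[-nrow(img), ]
  gy <- img[, -1] - img[, -ncol(img)]
  (sum(abs(gx)) + sum(abs(gy))) / (length(gx) + length(gy))
}

# Small network configuration used across tests (cheap but structurally
# identical to the default model).
tiny_config <- function(image_side = 48L, seed = 0L, ...) {
  run_config(image_side = image_side,
             channel_widths = c(8L, 16L, 32L),
             disc_widths = c(8L, 16L, 32L, 64L),
             seed = seed, ...)
}

# The seed-0 phantom study dataset (20 pairs, side 64) shared by several
# test files; generated once per session in a temporary directory.
.ds_cache <- new.env(parent = emptyenv())
get_study_dataset <- function() {
  if (is.null(.ds_cache$manifest)) {
    dir <- file.path(tempdir(), "fuseqa-study-ds")
    spec <- phantom_spec(n_pairs = 20L, side = 64L, seed = 0L)
    .ds_cache$manifest <- make_phantom_dataset(spec, dir)
  }
  .ds_cache$manifest
}

# The reduced-scale trained model shared by the learning-sanity checks;
# trained once per session (side 64, widths 16/32/64, 20 pairs, 15 epochs,
# seed 0).
get_study_fit <- function() {
  if (is.null(.ds_cache$fit)) {
    cfg <- run_config(image_side = 64L, channel_widths = c(16L, 32L, 64L),
                      disc_widths = c(16L, 32L, 64L, 128L), epochs = 15L,
                      seed = 0L)
    .ds_cache$fit <- train_model(get_study_dataset(), cfg, quiet = TRUE)
  }
  .ds_cache$fit
}
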