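# Synthetic brain phantoms: registered pseudo-modality pairs, a reference
# fusion, and graded-quality degraded fusions with known MOS labels. The
# module plays the role of a fusion-IQA database with radiologist scores: the
# five-level MOS grid {0.2, ..., 1.0} is tied one-to-one to degradation
# strength, so the quality ground truth is exactly recoverable.

# Squared-distance field from the image centre, in [-1, 1] coordinates.
.radial2 <- function(side) {
  ax <- seq(-1, 1, length.out = side)
  outer(ax^2, ax^2, "+")
}

#' Structural (CT/MRI-like) phantom
#'
#' A deterministic function of `seed`: a bright outer ring (skull analogue)
#' around a darker parenchyma disc containing 2-5 interior ellipses of
#' distinct intensities, all with sharp edges. Intensities lie in \[0, 1\].
#'
#' @param seed Integer seed; the image is a pure function of it.
#' @param side Image side, at least 32.
#' @return A `side` x `side` matrix in \[0, 1\].
#' @export
make_structural_phantom <- function(seed, side = 128L) {
  stopifnot(side >= 32)
  withr::with_seed(seed, {
    ax <- seq(-1, 1, length.out = side)
    X <- matrix(ax, side, side)         # row coordinate per pixel
    Y <- t(X)                           # column coordinate
    d2 <- X^2 + Y^2
    r_out <- stats::runif(1, 0.88, 0.94)
    r_in <- r_out - stats::runif(1, 0.05, 0.09)
    img <- matrix(0, side, side)
    img[d2 <= r_out^2] <- stats::runif(1, 0.85, 0.98)   # skull ring
    img[d2 <= r_in^2] <- stats::runif(1, 0.15, 0.30)    # parenchyma base
    n_ell <- sample(2:5, 1)
    levels_pool <- seq(0.35, 0.80, length.out = 8)
    ints <- sample(levels_pool, n_ell)
    for (e in seq_len(n_ell)) {
      cx <- stats::runif(1, -0.45, 0.45)
      cy <- stats::runif(1, -0.45, 0.45)
      a <- stats::runif(1, 0.08, 0.35)
      b <- stats::runif(1, 0.08, 0.35)
      th <- stats::runif(1, 0, pi)
      xr <- (X - cx) * cos(th) + (Y - cy) * sin(th)
      yr <- -(X - cx) * sin(th) + (Y - cy) * cos(th)
      img[(xr / a)^2 + (yr / b)^2 <= 1] <- ints[e]
    }
    img
  })
}

#' Functional (PET-like) phantom registered to a structural partner
#'
#' Smooth Gaussian hotspots placed strictly inside the skull ring of the
#' structural phantom (registration is by construction: both phantoms share
#' the same coordinate frame), on a broad low-intensity background that decays
#' to zero outside the head. The result is smooth, so its mean gradient
#' magnitude is well below the structural partner's. Hotspot centres (pixel
#' row/col) are attached as attribute `"hotspots"`.
#'
#' @param seed Integer seed.
#' @param side Image side, matching `structural`.
#' @param structural Output of [make_structural_phantom()] with the same side.
#' @return A `side` x `side` matrix in \[0, 1\].
#' @export
make_functional_phantom <- function(seed, side = 128L, structural) {
  stopifnot(is.matrix(structural), nrow(structural) == side,
            ncol(structural) == side)
  withr::with_seed(seed, {
    ax <- seq(-1, 1, length.out = side)
    X <- matrix(ax, side, side)
    Y <- t(X)
    d2 <- X^2 + Y^2
    img <- 0.18 * exp(-d2 / (2 * 0.55^2))
    n_hot <- sample(2:4, 1)
    centres <- matrix(0L, n_hot, 2L)
    for (h in seq_len(n_hot)) {
      # radius < 0.6 keeps centres strictly inside any generated skull ring
      r <- sqrt(stats::runif(1)) * 0.6
      ang <- stats::runif(1, 0, 2 * pi)
      cx <- r * cos(ang); cy <- r * sin(ang)
      amp <- stats::runif(1, 0.5, 0.9)
      sg <- stats::runif(1, 0.07, 0.14)
      img <- img + amp * exp(-((X - cx)^2 + (Y - cy)^2) / (2 * sg^2))
      centres[h, ] <- c(which.min(abs(ax - cx)), which.min(abs(ax - cy)))
    }
    img <- img / (1 + exp((sqrt(d2) - 0.80) / 0.03))  # soft head mask
    img <- pmin(pmax(img, 0), 1)
    attr(img, "hotspots") <- centres
    img
  })
}

#' Reference fusion of two registered phantoms
#'
#' Pixelwise maximum: monotone, idempotent, and preserves the salient content
#' of both modalities. Serves as the top-quality fused image (MOS 1.0).
#'
#' @param m1,m2 Matrices of identical dimension in \[0, 1\].
#' @return Pixelwise `pmax(m1, m2)`.
#' @export
make_reference_fusion <- function(m1, m2) {
  if (!identical(dim(m1), dim(m2))) stop("modality images differ in shape")
  img <- pmax(m1, m2)
  attributes(img) <- list(dim = dim(m1))
  img
}

# Separable Gaussian blur via EBImage (FFT, circular boundary).
.gauss_blur <- function(img, sigma) {
  out <- EBImage::imageData(EBImage::gblur(EBImage::as.Image(img),
                                           sigma = sigma))
  matrix(as.numeric(out), nrow(img), ncol(img))
}

#' Graded degradation of a fused image
#'
#' Emulates the quality spread that a bank of fusion algorithms of varying
#' fidelity would produce: Gaussian blur (sigma = 3 x level), additive
#' Gaussian noise (sd = 0.1 x level), and contrast compression toward the
#' mean (factor 0.5 x level), applied in that fixed order and clipped to
#' \[0, 1\]. Level 0 is exactly the identity.
#'
#' @param ref Reference fused image (matrix in \[0, 1\]).
#' @param level Degradation strength in \[0, 1).
#' @param seed Integer seed for the noise draw.
#' @return Degraded image, same dimension as `ref`.
#' @export
degrade_fusion <- function(ref, level, seed) {
  stopifnot(is.matrix(ref), level >= 0, level < 1)
  if (level == 0) return(ref)
  withr::with_seed(seed, {
    g <- .gauss_blur(ref, 3 * level)
    g <- g + matrix(stats::rnorm(length(ref), sd = 0.1 * level),
                    nrow(ref), ncol(ref))
    m <- mean(g)
    g <- m + (g - m) * (1 - 0.5 * level)
    pmin(pmax(g, 0), 1)
  })
}

#' Phantom dataset specification
#'
#' @param n_pairs Number of modality pairs.
#' @param side Image side.
#' @param seed Master seed; the dataset is a pure function of the spec.
#' @param degradation_levels Five strictly increasing levels in \[0, 1),
#'   mapped one-to-one onto the MOS grid `c(1.0, 0.8, 0.6, 0.4, 0.2)`; the
#'   first level must be 0 (MOS 1.0 is the undistorted reference).
#' @return A list of class `fq_phantom_spec`.
#' @export
phantom_spec <- function(n_pairs, side = 128L, seed = 0L,
                         degradation_levels = c(0, 0.2, 0.4, 0.6, 0.8)) {
  stopifnot(n_pairs >= 1, side >= 32, length(degradation_levels) == 5L)
  if (any(diff(degradation_levels) <= 0)) {
    stop("degradation_levels must be strictly increasing")
  }
  if (degradation_levels[1] != 0) stop("first degradation level must be 0")
  if (any(degradation_levels < 0 | degradation_levels >= 1)) {
    stop("degradation_levels must lie in [0,1)")
  }
  structure(list(n_pairs = as.integer(n_pairs), side = as.integer(side),
                 seed = as.integer(seed),
                 degradation_levels = degradation_levels,
                 mos_grid = c(1.0, 0.8, 0.6, 0.4, 0.2)),
            class = "fq_phantom_spec")
}

#' Generate a phantom dataset on disk
#'
#' For each pair writes the two modality images and the five fused images
#' (one per degradation level, with MOS labels 1.0 down to 0.2), plus
#' `manifest.csv`. Every image is an 8-bit PNG; the whole dataset is
#' bit-reproducible from the spec.
#'
#' @param spec A [phantom_spec()].
#' @param out_dir Output directory (created if missing).
#' @return The manifest data.frame (absolute paths), invisibly the same as
#'   written to `manifest.csv`.
#' @export
make_phantom_dataset <- function(spec, out_dir) {
  stopifnot(inherits(spec, "fq_phantom_spec"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  out_dir <- normalizePath(out_dir)
  seeds <- withr::with_seed(spec$seed,
    matrix(sample.int(.Machine$integer.max - 1L, spec$n_pairs * 7L),
           spec$n_pairs, 7L))
  rows <- vector("list", spec$n_pairs * 5L)
  for (i in seq_len(spec$n_pairs)) {
    m1 <- make_structural_phantom(seeds[i, 1], spec$side)
    m2 <- make_functional_phantom(seeds[i, 2], spec$side, m1)
    ref <- make_reference_fusion(m1, m2)
    p1 <- file.path(out_dir, sprintf("pair%03d_mi1.png", i))
    p2 <- file.path(out_dir, sprintf("pair%03d_mi2.png", i))
    save_image(m1, p1)
    save_image(m2, p2)
    for (k in seq_len(5L)) {
      fk <- degrade_fusion(ref, spec$degradation_levels[k], seeds[i, 2L + k])
      pf <- file.path(out_dir, sprintf("pair%03d_fused%d.png", i, k))
      save_image(fk, pf)
      rows[[(i - 1L) * 5L + k]] <- data.frame(
        mi1 = p1, mi2 = p2, fused = pf, mos = spec$mos_grid[k],
        stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  write_manifest(manifest, file.path(out_dir, "manifest.csv"))
  manifest
}
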