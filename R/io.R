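#' Load a grayscale image
#'
#' Reads an 8- or 16-bit PNG or TIFF as a matrix of intensities in \[0, 1\].
#' Colour inputs (e.g. PET pseudo-colour overlays) are converted to a single
#' intensity plane with ITU-R BT.601 luminance weights; an alpha channel, if
#' present, is dropped.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @return A numeric matrix with values in \[0, 1\] (rows are image rows).
#' @export
load_image <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- tryCatch(
    switch(ext,
      png = png::readPNG(path),
      tif = ,
      tiff = tiff::readTIFF(path),
      stop("unsupported image format '", ext, "': ", path)
    ),
    error = function(e) stop("failed to read image ", path, ": ",
                             conditionMessage(e))
  )
  if (length(dim(img)) == 3L) {
    nc <- dim(img)[3]
    img <- if (nc >= 3L) {
      0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
    } else img[, , 1]
  }
  img <- pmin(pmax(img, 0), 1)
  matrix(as.numeric(img), nrow(img), ncol(img))
}

#' Save a grayscale image as 8-bit PNG
#'
#' @param img Numeric matrix with values in \[0, 1\].
#' @param path Output path (`.png`).
#' @return `path`, invisibly.
#' @export
save_image <- function(img, path) {
  stopifnot(is.matrix(img))
  png::writePNG(pmin(pmax(img, 0), 1), path)
  invisible(path)
}

#' Resize a grayscale image
#'
#' Bilinear resampling to a `side` x `side` square (the network operates on
#' fixed power-of-two sides, 128 by default, while typical atlas slices are
#' 256 x 256). Values are clipped back to \[0, 1\]. Resizing to the current
#' side returns the input unchanged.
#'
#' @param img Numeric matrix in \[0, 1\].
#' @param side Target side length, at least 8.
#' @return A `side` x `side` numeric matrix in \[0, 1\].
#' @export
resize_image <- function(img, side) {
  stopifnot(is.matrix(img), side >= 1)
  if (nrow(img) == side && ncol(img) == side) return(img)
  if (side < 8) stop("side >= 8 required when resampling")
  out <- EBImage::imageData(EBImage::resize(EBImage::as.Image(img),
                                            w = side, h = side,
                                            filter = "bilinear"))
  pmin(pmax(matrix(as.numeric(out), side, side), 0), 1)
}

#' Load a dataset manifest
#'
#' The manifest is a CSV with header `mi1,mi2,fused,mos`: the two source
#' modality images, the fused image, and its mean opinion score in \[0, 1\].
#' Relative paths are resolved against the manifest's directory. Loading is
#' total: any bad row aborts with its row number.
#'
#' @param path Path to the CSV manifest.
#' @return A data.frame with columns `mi1`, `mi2`, `fused` (resolved paths)
#'   and `mos` (numeric).
#' @export
load_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("mi1", "mi2", "fused", "mos")
  if (!all(need %in% names(df))) {
    stop("manifest must have columns mi1,mi2,fused,mos: ", path)
  }
  df <- df[, need]
  if (nrow(df) == 0L) {
    warning("manifest has no records: ", path)
    df$mos <- numeric(0)
    return(df)
  }
  base <- dirname(normalizePath(path))
  resolve <- function(p) ifelse(grepl("^(/|[A-Za-z]:)", p), p,
                                file.path(base, p))
  for (col in c("mi1", "mi2", "fused")) df[[col]] <- resolve(df[[col]])
  df$mos <- suppressWarnings(as.numeric(df$mos))
  for (i in seq_len(nrow(df))) {
    if (is.na(df$mos[i]) || df$mos[i] < 0 || df$mos[i] > 1) {
      stop("manifest row ", i, ": mos must be in [0,1], got '", df$mos[i], "'")
    }
    for (col in c("mi1", "mi2", "fused")) {
      if (!file.exists(df[[col]][i])) {
        stop("manifest row ", i, ": missing file ", df[[col]][i])
      }
    }
  }
  if (anyDuplicated(df$fused)) stop("manifest has duplicate fused paths")
  df
}

#' Write a dataset manifest
#'
#' @param manifest Data.frame with columns `mi1`, `mi2`, `fused`, `mos`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(manifest[, c("mi1", "mi2", "fused", "mos")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Training/run configuration
#'
#' Collects every tunable of the model and training loop. `alpha` weights the
#' generator's L1 fusion term against its adversarial term; `beta` weights the
#' encoder-decoder reconstruction term in the total objective (defaults 100
#' and 20). `fusion_mode` and `use_sa` select the
#' ablation variants: `"hierarchical"` is the full model, `"early"`
#' concatenates the modalities before a single shared encoder, `"late"` fuses
#' only the deepest features, and `use_sa = FALSE` bypasses self-attention
#' inside the fusion blocks.
#'
#' @param image_side Network input side (divisible by 8; the generator and
#'   discriminator additionally require divisibility by 16).
#' @param channel_widths Encoder widths of the three convolutional blocks.
#' @param disc_widths Channel widths of the four discriminator blocks.
#' @param alpha Weight of the L1 fusion loss inside the generator objective.
#' @param beta Weight of the reconstruction loss in the total objective.
#' @param epochs Maximum training epochs; the returned model is the
#'   checkpoint with the best validation SRCC.
#' @param batch_size Samples per optimisation step.
#' @param learning_rate Adam step size (betas 0.5/0.999).
#' @param seed Integer seed controlling every random choice of a run.
#' @param fusion_mode One of `"hierarchical"`, `"early"`, `"late"`.
#' @param use_sa Keep the self-attention path inside the fusion blocks?
#' @param adv_loss `"lsgan"` (least-squares targets 1/0, the default) or
#'   `"log"` (the saturating log form, kept for fidelity experiments).
#' @param val_fraction Fraction of image pairs held out for validation.
#' @return A list of class `fq_config`.
#' @export
run_config <- function(image_side = 128L,
                       channel_widths = c(32L, 64L, 128L),
                       disc_widths = c(64L, 128L, 256L, 512L),
                       alpha = 100,
                       beta = 20,
                       epochs = 200L,
                       batch_size = 8L,
                       learning_rate = 2e-4,
                       seed = 0L,
                       fusion_mode = c("hierarchical", "early", "late"),
                       use_sa = TRUE,
                       adv_loss = c("lsgan", "log"),
                       val_fraction = 0.2) {
  fusion_mode <- match.arg(fusion_mode)
  adv_loss <- match.arg(adv_loss)
  if (alpha <= 0) stop("alpha must be > 0")
  if (beta <= 0) stop("beta must be > 0")
  if (image_side %% 8 != 0) stop("image_side must be divisible by 8")
  if (length(channel_widths) != 3L) stop("channel_widths must have length 3")
  if (length(disc_widths) != 4L) stop("disc_widths must have length 4")
  if (batch_size < 1L) stop("batch_size must be >= 1")
  if (val_fraction < 0 || val_fraction >= 1) stop("val_fraction must be in [0,1)")
  structure(list(
    image_side = as.integer(image_side),
    channel_widths = as.integer(channel_widths),
    disc_widths = as.integer(disc_widths),
    alpha = alpha, beta = beta,
    epochs = as.integer(epochs),
    batch_size = as.integer(batch_size),
    learning_rate = learning_rate,
    seed = as.integer(seed),
    fusion_mode = fusion_mode,
    use_sa = isTRUE(use_sa),
    adv_loss = adv_loss,
    val_fraction = val_fraction
  ), class = "fq_config")
}

#' Read a YAML run configuration
#'
#' Fields mirror [run_config()]; absent fields keep their defaults.
#'
#' @param path YAML file.
#' @param ... Overrides applied on top of the file values (CLI flags use this).
#' @return A `fq_config` list.
#' @export
load_run_config <- function(path = NULL, ...) {
  vals <- if (!is.null(path)) yaml::read_yaml(path) else list()
  over <- list(...)
  vals[names(over)] <- over
  known <- names(formals(run_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
  do.call(run_config, vals)
}

# Timestamped log line, optionally teed to a file.
fq_log <- function(..., file = NULL) {
  line <- paste0("[", format(Sys.time(), "%Y-%m-%d %H:%M:%S"), "] ", ...)
  message(line)
  if (!is.null(file)) cat(line, "\n", file = file, append = TRUE, sep = "")
  invisible(line)
}
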