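# Image and mask I/O. Masks are stored as human-viewable 8-bit grayscale
# PNGs with the canonical encoding 0 -> background, 128 -> optic disc,
# 255 -> optic cup, mapped bijectively to labels {0, 1, 2}.

MASK_ENCODING <- c(`0` = 0L, `128` = 1L, `255` = 2L)

#' Read / write fundus images
#'
#' Reads 8-bit RGB images (PNG always; JPEG/TIFF when the corresponding
#' reader package is available) into an `H x W x 3` array over `[0, 255]`.
#' Grayscale files are promoted to three channels; an alpha channel is
#' dropped.
#'
#' @param path File path; format follows the extension.
#' @param image `H x W x 3` array over `[0, 255]` (for `write_fundus`).
#' @return `read_fundus` returns the image array.
#' @export
read_fundus <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png = png::readPNG(path),
    tif = , tiff = {
      if (!requireNamespace("tiff", quietly = TRUE)) stop("package 'tiff' required for TIFF input")
      tiff::readTIFF(path)
    },
    stop("unsupported image format: ", ext)
  )
  if (is.matrix(raw)) raw <- array(rep(raw, 3), dim = c(dim(raw), 3))
  if (dim(raw)[3] > 3) raw <- raw[, , 1:3, drop = FALSE]
  raw * 255
}

#' @rdname read_fundus
#' @export
write_fundus <- function(image, path) {
  ext <- tolower(tools::file_ext(path))
  img01 <- pmin(pmax(image / 255, 0), 1)
  switch(ext,
    png = png::writePNG(img01, path),
    tif = , tiff = {
      if (!requireNamespace("tiff", quietly = TRUE)) stop("package 'tiff' required for TIFF output")
      tiff::writeTIFF(img01, path, bits.per.sample = 8)
    },
    stop("unsupported image format: ", ext)
  )
  invisible(path)
}

#' Read / write label masks
#'
#' On disk a mask is an 8-bit grayscale PNG with values 0 (background),
#' 128 (optic disc) and 255 (optic cup); in memory it is an integer matrix
#' over `{0, 1, 2}`. `write_mask(read_mask(x))` reproduces the file content
#' exactly; files containing any other pixel value are rejected with an
#' error naming the offending values.
#'
#' @param path PNG file path.
#' @param mask `H x W` integer matrix over `{0, 1, 2}` (for `write_mask`).
#' @return `read_mask` returns the label matrix.
#' @export
read_mask <- function(path) {
  raw <- png::readPNG(path)
  if (length(dim(raw)) == 3) raw <- raw[, , 1]
  vals <- round(raw * 255)
  bad <- setdiff(unique(as.vector(vals)), as.integer(names(MASK_ENCODING)))
  if (length(bad) > 0)
    stop("mask file contains unexpected pixel values: ", paste(sort(bad), collapse = ", "))
  out <- matrix(MASK_ENCODING[as.character(as.vector(vals))], nrow(vals), ncol(vals))
  storage.mode(out) <- "integer"
  out
}

#' @rdname read_mask
#' @export
write_mask <- function(mask, path) {
  check_mask(mask)
  disk <- matrix(c(0, 128, 255)[as.vector(mask) + 1] / 255, nrow(mask), ncol(mask))
  png::writePNG(disk, path)
  invisible(path)
}

# read a dataset directory: images/*.png(+tif) and masks/*.png with matching
# stems; optional split manifest (one stem per line) selects a subset
read_dataset <- function(data_dir, split_file = NULL) {
  img_dir <- file.path(data_dir, "images"); msk_dir <- file.path(data_dir, "masks")
  if (!dir.exists(img_dir) || !dir.exists(msk_dir))
    stop("data directory must contain images/ and masks/ subdirectories")
  imgs <- list.files(img_dir, pattern = "\\.(png|tif|tiff|PNG)$")
  stems <- tools::file_path_sans_ext(imgs)
  if (!is.null(split_file)) {
    keep <- readLines(split_file)
    sel <- stems %in% keep
    imgs <- imgs[sel]; stems <- stems[sel]
  }
  if (length(imgs) == 0) stop("no images found")
  lapply(seq_along(imgs), function(i) {
    mpath <- file.path(msk_dir, paste0(stems[i], ".png"))
    if (!file.exists(mpath)) stop("missing mask for image ", stems[i])
    mask <- read_mask(mpath)
    list(image = read_fundus(file.path(img_dir, imgs[i])), mask = mask,
         center = disc_centroid(mask), stem = stems[i])
  })
}
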