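# Image input/output and the three-level resolution pyramid. The scanners the
# method targets produce heterogeneous resolutions, so images are centre-
# cropped to the 2:1 sagittal aspect and then resampled (bilinear, up or
# down) to each pyramid level.

#' Load a grayscale image from PNG or TIFF
#'
#' RGB images are converted to luminance (Rec. 709 weights), alpha channels
#' are dropped, and values are scaled to [0, 1] (the PNG/TIFF readers already
#' scale 8- and 16-bit data).
#'
#' @param path file path; format inferred from the extension.
#' @return grayscale matrix with values in [0, 1].
#' @export
loadImage <- function(path) {
  if (!file.exists(path) || dir.exists(path))
    stop("cannot read image: no such file: ", path)
  if (file.size(path) == 0)
    stop("cannot read image: empty file: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- tryCatch(
    switch(ext,
           png = png::readPNG(path),
           tif = , tiff = tiff::readTIFF(path),
           stop("unsupported image format '", ext, "'")),
    error = function(e) stop("cannot read image ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  if (length(dim(img)) == 3L) {
    if (dim(img)[3] >= 3L)
      img <- 0.2126 * img[, , 1] + 0.7152 * img[, , 2] + 0.0722 * img[, , 3]
    else
      img <- img[, , 1]
  }
  clamp01(img)
}

centerCropAspect <- function(img, aspect = 2) {
  h <- nrow(img); w <- ncol(img)
  if (w > aspect * h) {
    tw <- floor(aspect * h)
    off <- (w - tw) %/% 2
    img[, off + seq_len(tw), drop = FALSE]
  } else if (w < aspect * h) {
    th <- floor(w / aspect)
    off <- (h - th) %/% 2
    img[off + seq_len(th), , drop = FALSE]
  } else img
}

#' Build the three-level resolution pyramid
#'
#' Centre-crops to the 2:1 aspect, then resamples to `baseSize`, 2x and 4x.
#' Sources below a level's resolution are upsampled, never rejected.
#'
#' @param image grayscale matrix in [0, 1].
#' @param baseSize integer `c(W, H)` of the low level, W = 2H.
#' @param caseId identifier stored in the result.
#' @return a [PyramidImage-class].
#' @export
buildPyramid <- function(image, baseSize = c(640L, 320L), caseId = "img") {
  if (length(baseSize) != 2L || baseSize[1] != 2L * baseSize[2])
    stop("baseSize must be c(W, H) with W = 2*H")
  if (length(image) == 0) stop("image is empty")
  img <- centerCropAspect(image, 2)
  W <- as.integer(baseSize[1]); H <- as.integer(baseSize[2])
  lev <- function(m) {
    if (nrow(img) == H * m && ncol(img) == W * m) img
    else resizeBilinear(img, H * m, W * m)
  }
  pyramidImage(lev(1L), lev(2L), lev(4L), caseId = caseId)
}

#' Load an image file straight into a pyramid
#'
#' @inheritParams buildPyramid
#' @param path image file path.
#' @return a [PyramidImage-class].
#' @export
loadPyramid <- function(path, baseSize = c(640L, 320L),
                        caseId = tools::file_path_sans_ext(basename(path))) {
  buildPyramid(loadImage(path), baseSize, caseId)
}

#' Read a dataset manifest written by [writeDataset()]
#'
#' @param path path to `manifest.csv`.
#' @return data frame with case ids, labels, horn tags and file paths.
#' @export
readManifest <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

# Rebuild PhantomCase-like records (pyramid + label + mask) from a manifest.
loadManifestCases <- function(manifest, dir = NULL) {
  lapply(seq_len(nrow(manifest)), function(i) {
    row <- manifest[i, ]
    pth <- function(p) if (is.null(dir)) p else file.path(dir, basename(p))
    pyr <- pyramidImage(loadImage(pth(row$low)), loadImage(pth(row$mid)),
                        loadImage(pth(row$high)), caseId = row$case_id)
    mask <- if (nzchar(row$mask)) (loadImage(pth(row$mask)) > 0.5) * 1L
            else matrix(0L, nrow(pyr@low), ncol(pyr@low))
    new("PhantomCase", pyramid = pyr, label = as.integer(row$label),
        lesionMask = mask, horn = row$horn)
  })
}
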