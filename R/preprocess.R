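# Slice loading, resizing and threshold-filter skull stripping.

#' Load 2D slices from an image file or a NIfTI volume
#'
#' 2D PNG/TIFF files pass through unchanged (single-channel; RGB inputs
#' are averaged to gray).  3D NIfTI volumes are cut into `n_slices`
#' central axial planes, each min--max scaled to \[0, 255\]; a slice with
#' no intensity range maps to all zeros.
#'
#' @param path path to a `.png`, `.tif(f)`, `.nii` or `.nii.gz` file.
#' @param plane slicing plane; only `"axial"` (third volume axis) is
#'   supported.
#' @param n_slices number of central axial slices to extract from volumes.
#' @return list of [gray_image()] objects.
#' @export
load_slices <- function(path, plane = "axial", n_slices = 30L) {
  plane <- match.arg(plane, "axial")
  if (!file.exists(path)) stop("cannot read file: ", path)
  low <- tolower(path)
  if (grepl("\\.(nii|nii\\.gz)$", low)) {
    vol <- RNifti::readNifti(path)
    vol <- as.array(vol)
    if (length(dim(vol)) != 3) {
      stop("axial slicing requires a 3D volume, got ",
           length(dim(vol)), "D")
    }
    d3 <- dim(vol)[3]
    n <- min(n_slices, d3)
    start <- floor((d3 - n) / 2) + 1L
    lapply(seq.int(start, start + n - 1L), function(k) {
      sl <- vol[, , k]
      rng <- range(sl)
      if (diff(rng) == 0) {
        sl[] <- 0
      } else {
        sl <- (sl - rng[1]) / diff(rng) * 255
      }
      gray_image(sl)
    })
  } else if (grepl("\\.png$", low)) {
    list(gray_image(flatten_gray(png::readPNG(path)) * 255))
  } else if (grepl("\\.(tif|tiff)$", low)) {
    list(gray_image(flatten_gray(tiff::readTIFF(path)) * 255))
  } else {
    stop("unsupported image format: ", path)
  }
}

# collapse an H x W x C array to gray by channel averaging
flatten_gray <- function(a) {
  if (length(dim(a)) == 3) {
    nc <- min(dim(a)[3], 3L)  # drop alpha if present
    apply(a[, , seq_len(nc), drop = FALSE], c(1, 2), mean)
  } else {
    a
  }
}

#' Write a grayscale image (and optionally its mask) as PNG
#' @param img a [gray_image()] or matrix in \[0, 255\].
#' @param path output PNG path.
#' @param what `"pixels"` or `"mask"` (mask written as 0/255).
#' @return invisibly, `path`.
#' @export
write_slice_png <- function(img, path, what = c("pixels", "mask")) {
  what <- match.arg(what)
  img <- as_gray_image(img)
  m <- if (what == "pixels") img$pixels / 255 else {
    if (is.null(img$brain_mask)) stop("image has no brain mask")
    img$brain_mask * 1
  }
  png::writePNG(m, path)
  invisible(path)
}

#' Bilinear resize of a grayscale image
#'
#' Samples output pixel centers in the input plane and interpolates
#' bilinearly; constant images are preserved exactly and results are
#' re-clipped to \[0, 255\].  An existing brain mask is resized by the
#' same map and re-binarized at 0.5.
#'
#' @param img a [gray_image()] or numeric matrix.
#' @param size integer (height, width) of the output.
#' @return resized [gray_image()].
#' @export
resize_image <- function(img, size = c(224L, 224L)) {
  img <- as_gray_image(img)
  size <- as.integer(rep(size, length.out = 2))
  if (any(size < 1)) stop("target size must be positive")
  p <- bilinear_resize(img$pixels, size[1], size[2])
  mask <- NULL
  if (!is.null(img$brain_mask)) {
    mask <- bilinear_resize(img$brain_mask * 1, size[1], size[2]) > 0.5
  }
  gray_image(clamp(p, 0, 255), mask)
}

bilinear_resize <- function(m, h2, w2) {
  h1 <- nrow(m); w1 <- ncol(m)
  axis_weights <- function(n_in, n_out) {
    u <- (seq_len(n_out) - 0.5) * n_in / n_out + 0.5
    u <- clamp(u, 1, n_in)
    lo <- pmin(floor(u), n_in)
    f <- u - lo
    hi <- pmin(lo + 1, n_in)
    f[hi == lo] <- 0
    list(lo = lo, hi = hi, f = f)
  }
  ry <- axis_weights(h1, h2)
  a <- m[ry$lo, , drop = FALSE] * (1 - ry$f) + m[ry$hi, , drop = FALSE] * ry$f
  rx <- axis_weights(w1, w2)
  t(t(a[, rx$lo, drop = FALSE]) * (1 - rx$f) +
      t(a[, rx$hi, drop = FALSE]) * rx$f)
}

# Exhaustive single-threshold Otsu on an integer-binned [0,255] image.
otsu_bilevel <- function(p) {
  counts <- tabulate(pmin(pmax(floor(p), 0), 255) + 1L, 256L)
  total <- sum(counts)
  lev <- 0:255
  w0 <- cumsum(counts) / total
  mu0 <- cumsum(counts * lev) / pmax(cumsum(counts), 1)
  muT <- sum(counts * lev) / total
  w1 <- 1 - w0
  mu1 <- (muT - w0 * mu0) / pmax(w1, .Machine$double.eps)
  bcv <- w0 * w1 * (mu0 - mu1)^2
  bcv[w0 == 0 | w1 == 0] <- -Inf
  which.max(bcv[1:255]) - 1L  # threshold level t: foreground is > t
}

#' Skull stripping by threshold filter and morphology
#'
#' Binarizes at Otsu's single threshold, detects a skull annulus among the
#' bright connected components (a component whose filled hull is much
#' larger than itself), and removes it by eroding the filled head mask
#' with a disc of radius `erosion_radius`; the largest remaining component
#' becomes the brain mask.  Inputs without an annulus keep the filled
#' largest bright component; if such an input also has a substantial
#' exact-zero background (the signature of prior stripping) the nonzero
#' support defines the foreground instead, so dark tissue at the rim is
#' not shed and the operation is idempotent up to the erosion tolerance.
#'
#' @param img a [gray_image()] or matrix.
#' @param erosion_radius disc radius in pixels for annulus removal.
#' @param hollow_ratio filled-area / area threshold above which a bright
#'   component is treated as an annulus.
#' @return [gray_image()] with `brain_mask` set and non-brain pixels
#'   zeroed.
#' @export
skull_strip <- function(img, erosion_radius = 6L, hollow_ratio = 1.5) {
  img <- as_gray_image(img)
  p <- img$pixels
  if (diff(range(p)) == 0) stop("no head found")
  thr <- otsu_bilevel(p)
  fg <- p > thr
  if (!any(fg)) stop("no head found")

  comp <- EBImage::bwlabel(fg)
  ncomp <- max(comp)
  areas <- tabulate(comp[comp > 0], ncomp)
  keep <- which(areas >= 50)
  if (!length(keep)) keep <- which.max(areas)
  hollow <- vapply(keep, function(k) {
    ck <- comp == k
    sum(EBImage::fillHull(ck)) / sum(ck)
  }, 0)
  has_ring <- any(hollow > hollow_ratio)

  if (has_ring) {
    head <- EBImage::fillHull(fg)
    brush <- EBImage::makeBrush(2L * as.integer(erosion_radius) + 1L, "disc")
    inner <- EBImage::erode(head, brush)
    if (!any(inner)) stop("no head found")
    lab <- EBImage::bwlabel(inner)
    mask <- lab == which.max(tabulate(lab[lab > 0], max(lab)))
  } else {
    if (mean(p == 0) > 0.2) {
      fg <- p > 0
      comp <- EBImage::bwlabel(fg)
      areas <- tabulate(comp[comp > 0], max(comp))
      mask <- EBImage::fillHull(comp == which.max(areas))
    } else {
      largest <- keep[which.max(areas[keep])]
      mask <- EBImage::fillHull(comp == largest)
    }
  }
  mask <- matrix(as.logical(mask), nrow(p), ncol(p))
  gray_image(p * mask, mask)
}
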