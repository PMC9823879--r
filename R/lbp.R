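# Weighted local binary patterns with the 59-bin uniform-pattern
# histogram (8 neighbors).
#
# The comparison threshold of each pixel blends a local reference -- the
# average local gray level ALGL, the mean of the 3x3 neighborhood (eight
# neighbors plus the center, divided by nine, so a constant image has
# ALGL equal to its gray level) -- with a global weighted gray level
# W * (mu + sigma) computed over the brain mask.  Raising the weight W raises the threshold, so codes grow
# progressively sparser.

# neighbor offsets in fixed circular bit order q = 0..7:
# E, NE, N, NW, W, SW, S, SE (rows grow downward)
lbp_offsets <- function() {
  list(c(0L, 1L), c(-1L, 1L), c(-1L, 0L), c(-1L, -1L),
       c(0L, -1L), c(1L, -1L), c(1L, 0L), c(1L, 1L))
}

#' 8-bit LBP code of one pixel
#'
#' Bit q is set iff the q-th neighbor is greater than or equal to the
#' effective threshold (ties count as 1).  The plain rule thresholds at
#' the center gray level; the weighted rule supplies its own threshold.
#'
#' @param center center gray level (the default threshold).
#' @param neighbors the 8 neighbor gray levels in circular order
#'   E, NE, N, NW, W, SW, S, SE.
#' @param threshold effective comparison value (defaults to `center`).
#' @return integer code in 0..255.
#' @export
lbp_code <- function(center, neighbors, threshold = center) {
  if (length(neighbors) != 8) stop("exactly 8 neighbors required")
  sum((neighbors >= threshold) * 2^(0:7))
}

# number of circular 0/1 transitions of an 8-bit code
lbp_transitions <- function(code) {
  bits <- as.integer(intToBits(code))[1:8]
  sum(bits != bits[c(2:8, 1)])
}

#' Map from 8-bit codes to the 59-bin uniform-pattern scheme
#'
#' The 58 uniform codes (at most two circular transitions) get their own
#' bins in ascending code order; all non-uniform codes pool into bin 59.
#'
#' @return integer vector of length 256 (bin index for codes 0..255).
#' @export
uniform_bin_map <- function() {
  tr <- vapply(0:255, lbp_transitions, 0L)
  uni <- which(tr <= 2L)                  # 58 codes, ascending
  map <- rep(59L, 256L)
  map[uni] <- seq_along(uni)
  map
}

#' Weighted-LBP coded image
#'
#' For every interior in-mask pixel: ALGL = (sum of the 8 neighbors +
#' center)/9; global weighted gray level `g_W = W * (mu + sigma)` with mu
#' and sigma over masked pixels; threshold `thr = (ALGL + g_W)/2`; bit q
#' of the code is `neighbor_q >= thr`.
#'
#' @param img a [gray_image()] with `brain_mask`.
#' @param w integer weight in 1..4.
#' @return integer matrix of codes (0..255), `NA` at border or
#'   off-mask pixels.
#' @export
lbp_weighted_image <- function(img, w) {
  if (!w %in% 1:4) stop("w must be one of 1, 2, 3, 4")
  img <- as_gray_image(img)
  if (is.null(img$brain_mask)) stop("image must carry a brain mask")
  p <- img$pixels
  mask <- img$brain_mask
  mu <- mean(p[mask])
  sigma <- stats::sd(p[mask])
  if (is.na(sigma)) sigma <- 0
  g_w <- w * (mu + sigma)

  offs <- lbp_offsets()
  nbr <- lapply(offs, function(o) shift_mat(p, o[1], o[2]))
  algl <- (Reduce(`+`, nbr) + p) / 9
  thr <- (algl + g_w) / 2
  code <- Reduce(`+`, lapply(seq_along(nbr), function(q)
    (nbr[[q]] >= thr) * 2^(q - 1)))

  interior <- matrix(FALSE, nrow(p), ncol(p))
  interior[2:(nrow(p) - 1), 2:(ncol(p) - 1)] <- TRUE
  code[!(interior & mask)] <- NA_integer_
  storage.mode(code) <- "integer"
  code
}

#' Plain (unweighted) LBP coded image
#'
#' Thresholds each pixel at its own center value; shift-invariant.
#'
#' @param img a [gray_image()] or matrix; mask optional (all pixels if
#'   absent).
#' @return integer code matrix, `NA` at borders / off-mask pixels.
#' @export
lbp_plain_image <- function(img) {
  img <- as_gray_image(img)
  p <- img$pixels
  mask <- if (is.null(img$brain_mask))
    matrix(TRUE, nrow(p), ncol(p)) else img$brain_mask
  offs <- lbp_offsets()
  nbr <- lapply(offs, function(o) shift_mat(p, o[1], o[2]))
  code <- Reduce(`+`, lapply(seq_along(nbr), function(q)
    (nbr[[q]] >= p) * 2^(q - 1)))
  interior <- matrix(FALSE, nrow(p), ncol(p))
  interior[2:(nrow(p) - 1), 2:(ncol(p) - 1)] <- TRUE
  code[!(interior & mask)] <- NA_integer_
  storage.mode(code) <- "integer"
  code
}

#' 59-bin uniform-pattern histogram of a coded image
#'
#' @param coded integer code matrix from [lbp_weighted_image()] (NA =
#'   not coded).
#' @param normalize if `TRUE`, L1-normalize the counts.
#' @return numeric vector of 59 bins; raw counts sum to the number of
#'   coded pixels.
#' @export
lbp_histogram <- function(coded, normalize = TRUE) {
  codes <- coded[!is.na(coded)]
  if (!length(codes)) stop("no coded pixels (empty mask)")
  map <- uniform_bin_map()
  h <- tabulate(map[codes + 1L], 59L)
  if (normalize) h <- h / sum(h)
  names(h) <- c(sprintf("u%02d", 1:58), "nonuniform")
  h
}

#' Names of the full 286-feature handcrafted block
#' @return character vector of length 286 (unique names).
#' @export
hf_feature_names <- function() {
  c(paste0("glcm_wm_", glcm_feature_names()),
    paste0("glcm_gm_", glcm_feature_names()),
    unlist(lapply(1:4, function(w)
      paste0("lbp_w", w, "_", c(sprintf("u%02d", 1:58), "nonuniform")))))
}

#' Assemble the 286-dim handcrafted feature block
#'
#' Fixed-order concatenation: GLCM on WM (25), GLCM on GM (25), then the
#' four weighted-LBP histograms (4 x 59).  Component names are checked so
#' a permuted call cannot silently produce a scrambled block.
#'
#' @param glcm_wm,glcm_gm named 25-vectors from [glcm_features()].
#' @param lbp_w1,lbp_w2,lbp_w3,lbp_w4 named 59-vectors from
#'   [lbp_histogram()].
#' @return named numeric vector of length 286.
#' @export
assemble_hf <- function(glcm_wm, glcm_gm, lbp_w1, lbp_w2, lbp_w3, lbp_w4) {
  comps <- list(glcm_wm, glcm_gm, lbp_w1, lbp_w2, lbp_w3, lbp_w4)
  lens <- c(25L, 25L, 59L, 59L, 59L, 59L)
  for (k in seq_along(comps)) {
    if (length(comps[[k]]) != lens[k]) {
      stop("component ", k, " has length ", length(comps[[k]]),
           ", expected ", lens[k])
    }
  }
  glcm_names <- glcm_feature_names()
  lbp_names <- c(sprintf("u%02d", 1:58), "nonuniform")
  for (k in 1:2) {
    if (!is.null(names(comps[[k]])) &&
        !identical(names(comps[[k]]), glcm_names)) {
      stop("component ", k, " is not a GLCM descriptor vector")
    }
  }
  for (k in 3:6) {
    if (!is.null(names(comps[[k]])) &&
        !identical(names(comps[[k]]), lbp_names)) {
      stop("component ", k, " is not an LBP histogram")
    }
  }
  out <- unlist(comps, use.names = FALSE)
  names(out) <- hf_feature_names()
  out
}

#' Full handcrafted block of one stripped slice
#'
#' Segments the slice (unless tissue maps are supplied), computes GLCM
#' descriptors on the WM and GM images and weighted-LBP histograms at
#' W = 1..4 on the whole stripped brain, and concatenates them.
#'
#' @param img a skull-stripped [gray_image()].
#' @param tissues optional precomputed [extract_tissues()] result.
#' @param moa_params,mrf_cfg forwarded to [segment_slice()] when
#'   `tissues` is missing.
#' @param normalize L1-normalize LBP histograms.
#' @return named numeric vector of length 286.
#' @export
extract_hf <- function(img, tissues = NULL, moa_params = NULL,
                       mrf_cfg = mrf_config(), normalize = TRUE) {
  if (is.null(tissues)) {
    tissues <- segment_slice(img, moa_params, mrf_cfg)$tissues
  }
  lbps <- lapply(1:4, function(w)
    lbp_histogram(lbp_weighted_image(img, w), normalize = normalize))
  assemble_hf(glcm_features(tissues$wm_image),
              glcm_features(tissues$gm_image),
              lbps[[1]], lbps[[2]], lbps[[3]], lbps[[4]])
}
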