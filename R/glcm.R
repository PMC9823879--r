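# Gray-level co-occurrence matrix texture descriptors.
#
# Co-occurrence is accumulated over pixel pairs with BOTH ends inside the
# tissue mask, quantized to a small number of gray levels, symmetrized and
# normalized per angle; the 25 descriptors are averaged over the four
# standard angles.

#' Names of the 25 GLCM descriptors, in output order
#' @return character vector of length 25.
#' @export
glcm_feature_names <- function() {
  c("contrast", "correlation", "energy", "homogeneity", "entropy",
    "dissimilarity", "max_probability", "sum_average", "sum_variance",
    "sum_entropy", "difference_variance", "difference_entropy",
    "autocorrelation", "cluster_shade", "cluster_prominence",
    "inverse_difference", "idmn", "idn", "imc1", "imc2",
    "variance", "mean", "max_row_mean", "trace", "marginal_uniformity")
}

# quantize masked intensities to 1..levels by min-max binning
quantize_levels <- function(p, mask, levels) {
  q <- matrix(NA_integer_, nrow(p), ncol(p))
  v <- p[mask]
  rng <- range(v)
  if (diff(rng) == 0) {
    q[mask] <- 1L
  } else {
    q[mask] <- pmin(floor((p[mask] - rng[1]) / diff(rng) * levels) + 1L,
                    levels)
  }
  q
}

# symmetrized, normalized co-occurrence matrix for one (dy, dx) offset
glcm_matrix <- function(q, mask, dy, dx, levels) {
  h <- nrow(q); w <- ncol(q)
  ys <- seq_len(h); xs <- seq_len(w)
  y2 <- ys + dy; x2 <- xs + dx
  oky <- y2 >= 1 & y2 <= h
  okx <- x2 >= 1 & x2 <= w
  a <- q[ys[oky], xs[okx], drop = FALSE]
  b <- q[y2[oky], x2[okx], drop = FALSE]
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) return(NULL)
  counts <- matrix(0, levels, levels)
  tab <- tabulate((a[ok] - 1L) * levels + b[ok], levels * levels)
  counts[] <- tab[matrix(seq_len(levels^2), levels, levels, byrow = TRUE)]
  counts <- counts + t(counts)
  counts / sum(counts)
}

# the 25 descriptors of one normalized symmetric co-occurrence matrix
glcm_descriptors <- function(P) {
  L <- nrow(P)
  i <- matrix(seq_len(L), L, L)
  j <- t(i)
  px <- rowSums(P)
  py <- colSums(P)
  lev <- seq_len(L)
  mux <- sum(lev * px); muy <- sum(lev * py)
  sdx <- sqrt(sum((lev - mux)^2 * px))
  sdy <- sqrt(sum((lev - muy)^2 * py))
  log2s <- function(x) ifelse(x > 0, log2(x), 0)
  # index-sum and index-difference distributions
  ks <- 2:(2 * L)
  pxy_sum <- vapply(ks, function(k) sum(P[(i + j) == k]), 0)
  kd <- 0:(L - 1)
  pxy_dif <- vapply(kd, function(k) sum(P[abs(i - j) == k]), 0)

  hxy <- -sum(P * log2s(P))
  pipj <- outer(px, py)
  hxy1 <- -sum(P * log2s(pipj))
  hxy2 <- -sum(pipj * log2s(pipj))
  hx <- -sum(px * log2s(px))
  hy <- -sum(py * log2s(py))

  sa <- sum(ks * pxy_sum)
  da <- sum(kd * pxy_dif)
  imc1 <- if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else 0
  imc2 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - hxy))))

  out <- c(
    contrast = sum((i - j)^2 * P),
    correlation = if (sdx * sdy > 0)
      (sum(i * j * P) - mux * muy) / (sdx * sdy) else 0,
    energy = sum(P^2),
    homogeneity = sum(P / (1 + (i - j)^2)),
    entropy = hxy,
    dissimilarity = sum(abs(i - j) * P),
    max_probability = max(P),
    sum_average = sa,
    sum_variance = sum((ks - sa)^2 * pxy_sum),
    sum_entropy = -sum(pxy_sum * log2s(pxy_sum)),
    difference_variance = sum((kd - da)^2 * pxy_dif),
    difference_entropy = -sum(pxy_dif * log2s(pxy_dif)),
    autocorrelation = sum(i * j * P),
    cluster_shade = sum((i + j - mux - muy)^3 * P),
    cluster_prominence = sum((i + j - mux - muy)^4 * P),
    inverse_difference = sum(P / (1 + abs(i - j))),
    idmn = sum(P / (1 + (i - j)^2 / L^2)),
    idn = sum(P / (1 + abs(i - j) / L)),
    imc1 = imc1,
    imc2 = imc2,
    variance = sum((i - mux)^2 * P),
    mean = mux,
    max_row_mean = mean(apply(P, 1, max)),
    trace = sum(diag(P)),
    marginal_uniformity = sum(px^2)
  )
  names(out) <- glcm_feature_names()
  out
}

#' GLCM texture descriptors of a masked tissue image
#'
#' @param tissue_image a [gray_image()] whose `brain_mask` marks the
#'   tissue (e.g. `gm_image` / `wm_image` from [extract_tissues()]).
#' @param levels gray-level quantization bins.
#' @param distance pixel-pair offset distance.
#' @param angles angles in degrees; the descriptor vector is the average
#'   over angles with at least one valid pair.
#' @return named numeric vector of 25 descriptors.
#' @export
glcm_features <- function(tissue_image, levels = 8L, distance = 1L,
                          angles = c(0, 45, 90, 135)) {
  img <- as_gray_image(tissue_image)
  if (is.null(img$brain_mask)) stop("tissue image must carry a mask")
  mask <- img$brain_mask
  if (sum(mask) < 2) stop("fewer than 2 in-mask pixels")
  q <- quantize_levels(img$pixels, mask, levels)
  d <- as.integer(distance)
  offsets <- list(`0` = c(0L, d), `45` = c(-d, d),
                  `90` = c(-d, 0L), `135` = c(-d, -d))
  acc <- NULL; n_used <- 0L
  for (a in as.character(angles)) {
    o <- offsets[[a]]
    if (is.null(o)) stop("unsupported angle: ", a)
    P <- glcm_matrix(q, mask, o[1], o[2], levels)
    if (is.null(P)) next
    f <- glcm_descriptors(P)
    acc <- if (is.null(acc)) f else acc + f
    n_used <- n_used + 1L
  }
  if (n_used == 0L) stop("no valid co-occurring pixel pairs in mask")
  acc / n_used
}
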