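# Shared fixtures and independent oracles, built in code at test time.

# small noiseless phantom configuration used across modules
tiny_phantom_cfg <- function(noise_sigma = 0, class_effect = 0,
                             size = 96, seed = 7, ...) {
  phantom_config(image_size = c(size, size), noise_sigma = noise_sigma,
                 class_effect = class_effect, seed = seed, ...)
}

# Brute-force GLCM oracle: enumerate in-mask pixel pairs with explicit
# loops, build the symmetric normalized matrix, and compute descriptors
# from first principles (kept independent of the package's vectorized
# path).
oracle_glcm_matrix <- function(q, mask, dy, dx, levels) {
  counts <- matrix(0, levels, levels)
  for (i in seq_len(nrow(q))) {
    for (j in seq_len(ncol(q))) {
      i2 <- i + dy; j2 <- j + dx
      if (i2 >= 1 && i2 <= nrow(q) && j2 >= 1 && j2 <= ncol(q) &&
          mask[i, j] && mask[i2, j2]) {
        counts[q[i, j], q[i2, j2]] <- counts[q[i, j], q[i2, j2]] + 1
      }
    }
  }
  counts <- counts + t(counts)
  counts / sum(counts)
}

oracle_glcm_descriptors <- function(P) {
  L <- nrow(P)
  v <- setNames(numeric(25), glcm_feature_names())
  px <- rowSums(P); py <- colSums(P)
  mux <- 0; muy <- 0
  for (i in 1:L) { mux <- mux + i * px[i]; muy <- muy + i * py[i] }
  sdx <- sqrt(sum(((1:L) - mux)^2 * px))
  sdy <- sqrt(sum(((1:L) - muy)^2 * py))
  psum <- rep(0, 2 * L); pdif <- rep(0, L)
  hxy <- 0; hxy1 <- 0; hxy2 <- 0
  for (i in 1:L) for (j in 1:L) {
    p <- P[i, j]
    psum[i + j] <- psum[i + j] + p
    pdif[abs(i - j) + 1] <- pdif[abs(i - j) + 1] + p
    if (p > 0) hxy <- hxy - p * log2(p)
    if (px[i] * py[j] > 0) {
      hxy1 <- hxy1 - p * log2(px[i] * py[j])
      hxy2 <- hxy2 - px[i] * py[j] * log2(px[i] * py[j])
    }
    v["contrast"] <- v["contrast"] + (i - j)^2 * p
    v["energy"] <- v["energy"] + p^2
    v["homogeneity"] <- v["homogeneity"] + p / (1 + (i - j)^2)
    v["dissimilarity"] <- v["dissimilarity"] + abs(i - j) * p
    v["autocorrelation"] <- v["autocorrelation"] + i * j * p
    v["cluster_shade"] <- v["cluster_shade"] + (i + j - mux - muy)^3 * p
    v["cluster_prominence"] <-
      v["cluster_prominence"] + (i + j - mux - muy)^4 * p
    v["inverse_difference"] <-
      v["inverse_difference"] + p / (1 + abs(i - j))
    v["idmn"] <- v["idmn"] + p / (1 + (i - j)^2 / L^2)
    v["idn"] <- v["idn"] + p / (1 + abs(i - j) / L)
    v["variance"] <- v["variance"] + (i - mux)^2 * p
  }
  v["correlation"] <- if (sdx * sdy > 0)
    (v["autocorrelation"] - mux * muy) / (sdx * sdy) else 0
  v["entropy"] <- hxy
  v["max_probability"] <- max(P)
  sa <- sum((2:(2 * L)) * psum[2:(2 * L)])
  v["sum_average"] <- sa
  v["sum_variance"] <- sum(((2:(2 * L)) - sa)^2 * psum[2:(2 * L)])
  v["sum_entropy"] <- -sum(ifelse(psum > 0, psum * log2(psum), 0))
  da <- sum((0:(L - 1)) * pdif)
  v["difference_variance"] <- sum(((0:(L - 1)) - da)^2 * pdif)
  v["difference_entropy"] <- -sum(ifelse(pdif > 0, pdif * log2(pdif), 0))
  hx <- -sum(ifelse(px > 0, px * log2(px), 0))
  hy <- -sum(ifelse(py > 0, py * log2(py), 0))
  v["imc1"] <- if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else 0
  v["imc2"] <- sqrt(max(0, 1 - exp(-2 * (hxy2 - hxy))))
  v["mean"] <- mux
  v["max_row_mean"] <- mean(apply(P, 1, max))
  v["trace"] <- sum(diag(P))
  v["marginal_uniformity"] <- sum(px^2)
  v
}

# two-loop brute-force fitness oracle for the selection objective
oracle_cd_fitness <- function(mask, x, labels) {
  z <- x
  for (j in seq_len(ncol(x))) {
    s <- stats::sd(x[, j])
    if (!is.finite(s) || s == 0) s <- 1
    z[, j] <- (x[, j] - mean(x[, j])) / s
  }
  idx <- which(mask)
  if (!length(idx)) return(-Inf)
  total <- 0
  for (j in idx) {
    gap <- mean(z[labels == "CON", j]) - mean(z[labels == "SCZ", j])
    total <- total + gap^2
  }
  sqrt(total) / sqrt(length(idx))
}

# reported fold-level confusion counts of the VGG16+SoftMax benchmark
# (five cross-validation trials)
softmax_fold_counts <- function() {
  list(c(TP = 155, FN = 25, TN = 148, FP = 32),
       c(TP = 159, FN = 21, TN = 152, FP = 28),
       c(TP = 154, FN = 26, TN = 161, FP = 19),
       c(TP = 168, FN = 12, TN = 161, FP = 19),
       c(TP = 156, FN = 24, TN = 160, FP = 20))
}

# the corresponding published metric cells (ACC, PRE, SEN, SPE, NPV, FS)
softmax_fold_metrics <- function() {
  rbind(
    c(84.1667, 82.8877, 86.1111, 82.2222, 85.5491, 84.4687),
    c(86.3889, 85.0267, 88.3333, 84.4444, 87.8613, 86.6485),
    c(87.5000, 89.0173, 85.5556, 89.4444, 86.0963, 87.2521),
    c(91.3889, 89.8396, 93.3333, 89.4444, 93.0636, 91.5531),
    c(87.7778, 88.6364, 86.6667, 88.8889, 86.9565, 87.6404))
}
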