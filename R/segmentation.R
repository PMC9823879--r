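# GM/WM separation: mayfly-optimized tri-level Otsu thresholding followed
# by Markov-random-field label refinement (iterated conditional modes).

#' 256-bin histogram over the brain mask
#' @param img a [gray_image()] with `brain_mask` (or a matrix, in which
#'   case all pixels count).
#' @return integer vector of 256 counts for levels 0..255.
#' @export
brain_histogram <- function(img) {
  img <- as_gray_image(img)
  p <- if (is.null(img$brain_mask)) img$pixels else img$pixels[img$brain_mask]
  if (!length(p)) stop("mask is empty")
  tabulate(pmin(pmax(floor(p), 0), 255) + 1L, 256L)
}

#' Between-class variance of a tri-level split
#'
#' Otsu's criterion for two cut points: classes `[0, t1]`, `(t1, t2]`,
#' `(t2, 255]`; returns `sum_k w_k (mu_k - mu_T)^2` with empty classes
#' contributing zero.  Maximized over (t1, t2) by the threshold search.
#'
#' @param counts 256-bin histogram (levels 0..255).
#' @param t1,t2 integer cut points, `0 < t1 < t2 < 255`.
#' @return the between-class variance (numeric scalar).
#' @export
otsu_trilevel_objective <- function(counts, t1, t2) {
  if (length(counts) != 256) stop("histogram must have exactly 256 bins")
  if (t1 >= t2) stop("thresholds must satisfy t1 < t2")
  if (t1 <= 0 || t2 >= 255) stop("thresholds must lie strictly inside (0, 255)")
  total <- sum(counts)
  if (total <= 0) stop("histogram is empty")
  lev <- 0:255
  cls <- findInterval(lev, c(t1 + 0.5, t2 + 0.5)) + 1L  # 1, 2, 3
  mu_t <- sum(counts * lev) / total
  obj <- 0
  for (k in 1:3) {
    nk <- sum(counts[cls == k])
    if (nk > 0) {
      wk <- nk / total
      muk <- sum((counts * lev)[cls == k]) / nk
      obj <- obj + wk * (muk - mu_t)^2
    }
  }
  obj
}

#' Exhaustive tri-level threshold search (reference)
#'
#' Scans all valid integer pairs; used as the oracle against which the
#' mayfly search is validated.
#'
#' @param counts 256-bin histogram.
#' @return list with `t1`, `t2`, `value`.
#' @export
otsu_trilevel_exhaustive <- function(counts) {
  best <- list(t1 = 1L, t2 = 2L, value = -Inf)
  for (t1 in 1:253) {
    for (t2 in (t1 + 1L):254) {
      v <- otsu_trilevel_objective(counts, t1, t2)
      if (v > best$value) best <- list(t1 = t1, t2 = t2, value = v)
    }
  }
  best
}

#' Mayfly-optimized tri-level Otsu thresholding
#'
#' Maximizes [otsu_trilevel_objective()] over continuous positions in
#' `[1, 254]^2`; positions are rounded and sorted at evaluation (equal
#' rounded thresholds are nudged apart by one level).  The histogram is
#' built over the brain mask only, so background zeros cannot dominate
#' the criterion.
#'
#' @param img a [gray_image()] with non-empty `brain_mask`.
#' @param params optional [mayfly_params()]; defaults to 30 flies and 60
#'   iterations, ample for this 2-D search space.
#' @return list with integer `t1 < t2`, the attained `value`, and the
#'   optimizer `trace`.
#' @export
moa_otsu_trilevel <- function(img, params = NULL) {
  counts <- brain_histogram(img)
  if (is.null(params)) {
    params <- mayfly_params(bounds = cbind(c(1, 1), c(254, 254)),
                            n_flies = 30L, max_iter = 60L)
  }
  decode <- function(x) {
    t <- sort(round(x))
    t <- clamp(t, 1, 254)
    if (t[1] == t[2]) {
      if (t[2] < 254) t[2] <- t[2] + 1 else t[1] <- t[1] - 1
    }
    t
  }
  obj <- function(x) {
    t <- decode(x)
    otsu_trilevel_objective(counts, t[1], t[2])
  }
  res <- mayfly_optimize(obj, params)
  t <- decode(res$gbest)
  list(t1 = as.integer(t[1]), t2 = as.integer(t[2]),
       value = res$value, trace = res$trace)
}

#' Initial label map from two thresholds
#'
#' Labels: 0 = darkest class (background/CSF), 1 = GM, 2 = WM,
#' 3 = excluded (outside the brain mask).
#'
#' @param img a [gray_image()] with `brain_mask`.
#' @param t1,t2 thresholds from [moa_otsu_trilevel()].
#' @return integer label matrix.
#' @export
threshold_labels <- function(img, t1, t2) {
  img <- as_gray_image(img)
  if (is.null(img$brain_mask)) stop("image must carry a brain mask")
  p <- img$pixels
  lab <- matrix(3L, nrow(p), ncol(p))
  m <- img$brain_mask
  lab[m] <- 0L
  lab[m & p > t1] <- 1L
  lab[m & p > t2] <- 2L
  lab
}

#' MRF refinement configuration
#' @param smoothness Potts penalty weight for unlike neighbor labels.
#' @param neighborhood 4 or 8 connectivity.
#' @param max_sweeps maximum ICM sweeps.
#' @param tol convergence: fraction of in-mask labels changed per sweep.
#' @return an `mrf_config` list.
#' @export
mrf_config <- function(smoothness = 1.0, neighborhood = 4L,
                       max_sweeps = 50L, tol = 1e-3) {
  if (smoothness < 0) stop("smoothness must be >= 0")
  if (!neighborhood %in% c(4L, 8L)) stop("neighborhood must be 4 or 8")
  if (max_sweeps < 1) stop("max_sweeps must be >= 1")
  structure(list(smoothness = smoothness,
                 neighborhood = as.integer(neighborhood),
                 max_sweeps = as.integer(max_sweeps), tol = tol),
            class = "mrf_config")
}

neighbor_offsets <- function(neighborhood) {
  off <- list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  if (neighborhood == 8L) {
    off <- c(off, list(c(-1L, -1L), c(-1L, 1L), c(1L, -1L), c(1L, 1L)))
  }
  off
}

# shift a matrix by (dy, dx), zero-filling vacated cells
shift_mat <- function(m, dy, dx) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(0, h, w)
  ys <- seq_len(h); xs <- seq_len(w)
  ysrc <- ys + dy; xsrc <- xs + dx
  ok_y <- ysrc >= 1 & ysrc <= h
  ok_x <- xsrc >= 1 & xsrc <= w
  out[ys[ok_y], xs[ok_x]] <- m[ysrc[ok_y], xsrc[ok_x]]
  out
}

mrf_energy <- function(p, lab, mask, mu, sigma, cfg) {
  data_e <- 0
  for (k in 0:2) {
    sel <- mask & lab == k
    if (any(sel)) {
      data_e <- data_e +
        sum((p[sel] - mu[k + 1])^2) / (2 * sigma[k + 1]^2) +
        sum(sel) * log(sigma[k + 1])
    }
  }
  pair_off <- list(c(0L, 1L), c(1L, 0L))
  if (cfg$neighborhood == 8L) {
    pair_off <- c(pair_off, list(c(1L, 1L), c(1L, -1L)))
  }
  pair_e <- 0
  for (o in pair_off) {
    ln <- shift_mat(lab, o[1], o[2])
    mn <- shift_mat(mask * 1, o[1], o[2]) > 0
    both <- mask & mn
    pair_e <- pair_e + sum(both & (lab != ln))
  }
  data_e + cfg$smoothness * pair_e
}

estimate_class_params <- function(p, lab, mask, prev = NULL) {
  mu <- numeric(3); sigma <- numeric(3); empty <- logical(3)
  for (k in 0:2) {
    sel <- mask & lab == k
    n <- sum(sel)
    if (n == 0) {
      empty[k + 1] <- TRUE
      mu[k + 1] <- if (is.null(prev)) NA_real_ else prev$mu[k + 1]
      sigma[k + 1] <- if (is.null(prev)) NA_real_ else prev$sigma[k + 1]
    } else {
      mu[k + 1] <- mean(p[sel])
      sigma[k + 1] <- max(sqrt(mean((p[sel] - mu[k + 1])^2)), 0.5)
    }
  }
  list(mu = mu, sigma = sigma, empty = empty)
}

#' MRF label refinement by iterated conditional modes
#'
#' Minimizes a Gaussian-likelihood + Potts energy -- per-pixel
#' `(I_p - mu_l)^2 / (2 sigma_l^2) + log sigma_l` plus `smoothness` per
#' unlike in-mask neighbor pair -- by chromatic ICM sweeps (the 2x2 pixel coloring makes each sub-sweep an
#' exact coordinate-descent step for both 4- and 8-neighborhoods).  Class
#' means and standard deviations are re-estimated after every sweep and a
#' candidate re-estimate is kept only if it does not increase the energy,
#' so the per-sweep energy trace is non-increasing by construction.  A
#' class that loses all pixels keeps its last non-empty parameters.
#'
#' @param img a [gray_image()] with `brain_mask`.
#' @param init initial label map from [threshold_labels()].
#' @param cfg an [mrf_config()].
#' @return list with `labels` (refined map), `energy` (per-sweep trace),
#'   and the final class `params`.
#' @export
mrf_refine <- function(img, init, cfg = mrf_config()) {
  img <- as_gray_image(img)
  if (is.null(img$brain_mask)) stop("image must carry a brain mask")
  p <- img$pixels
  mask <- img$brain_mask
  lab <- init
  n_mask <- sum(mask)
  if (n_mask == 0) stop("mask is empty")

  pars <- estimate_class_params(p, lab, mask)
  if (any(pars$empty)) stop("initial labeling leaves a class empty")
  offs <- neighbor_offsets(cfg$neighborhood)
  colors <- list(c(1L, 1L), c(1L, 0L), c(0L, 1L), c(0L, 0L))
  rowpar <- matrix((seq_len(nrow(p)) - 1L) %% 2L, nrow(p), ncol(p))
  colpar <- matrix((seq_len(ncol(p)) - 1L) %% 2L, nrow(p), ncol(p),
                   byrow = TRUE)
  maskn <- mask * 1

  energy <- numeric(0)
  e_cur <- mrf_energy(p, lab, mask, pars$mu, pars$sigma, cfg)
  for (sweep in seq_len(cfg$max_sweeps)) {
    old_lab <- lab
    data_cost <- lapply(0:2, function(k)
      (p - pars$mu[k + 1])^2 / (2 * pars$sigma[k + 1]^2) +
        log(pars$sigma[k + 1]))
    for (col in colors) {
      sel <- mask & rowpar == col[1] & colpar == col[2]
      if (!any(sel)) next
      valid_n <- Reduce(`+`, lapply(offs, function(o)
        shift_mat(maskn, o[1], o[2])))
      cost <- lapply(0:2, function(k) {
        same <- Reduce(`+`, lapply(offs, function(o)
          shift_mat((lab == k & mask) * 1, o[1], o[2])))
        data_cost[[k + 1]] + cfg$smoothness * (valid_n - same)
      })
      best <- matrix(0L, nrow(p), ncol(p))
      bestc <- cost[[1]]
      for (k in 1:2) {
        better <- cost[[k + 1]] < bestc
        best[better] <- k
        bestc[better] <- cost[[k + 1]][better]
      }
      lab[sel] <- best[sel]
    }
    # re-estimate class parameters; keep only if energy does not rise
    cand <- estimate_class_params(p, lab, mask, prev = pars)
    if (any(cand$empty)) {
      message("MRF: class ", paste(which(cand$empty) - 1, collapse = ","),
              " became empty; parameters frozen")
    }
    e_cand <- mrf_energy(p, lab, mask, cand$mu, cand$sigma, cfg)
    e_keep <- mrf_energy(p, lab, mask, pars$mu, pars$sigma, cfg)
    if (e_cand <= e_keep) {
      pars <- cand
      e_cur <- e_cand
    } else {
      e_cur <- e_keep
    }
    energy <- c(energy, e_cur)
    changed <- sum(lab != old_lab & mask) / n_mask
    if (changed < cfg$tol) break
  }
  list(labels = lab, energy = energy, params = pars)
}

#' Extract GM and WM tissue maps from a refined label map
#'
#' Classes are identified by the ordering of their mean intensities
#' (T1-weighted convention): darkest is background/CSF, middle is gray
#' matter, brightest is white matter.
#'
#' @param img a [gray_image()] with `brain_mask`.
#' @param labels refined label map (values 0..2 in-mask, 3 outside).
#' @return a `tissue_maps` list: `gm_mask`, `wm_mask` (disjoint logical
#'   rasters) and `gm_image`, `wm_image` (intensities masked to each
#'   tissue).
#' @export
extract_tissues <- function(img, labels) {
  img <- as_gray_image(img)
  if (is.null(img$brain_mask)) stop("image must carry a brain mask")
  p <- img$pixels
  mask <- img$brain_mask
  means <- sapply(0:2, function(k) {
    sel <- mask & labels == k
    if (any(sel)) mean(p[sel]) else NA_real_
  })
  if (any(is.na(means))) stop("degenerate segmentation: fewer than 3 classes")
  ord <- order(means)             # darkest, middle, brightest class ids
  gm_k <- ord[2] - 1L
  wm_k <- ord[3] - 1L
  gm_mask <- mask & labels == gm_k
  wm_mask <- mask & labels == wm_k
  structure(list(gm_mask = gm_mask, wm_mask = wm_mask,
                 gm_image = gray_image(p * gm_mask, gm_mask),
                 wm_image = gray_image(p * wm_mask, wm_mask)),
            class = "tissue_maps")
}

#' Threshold, refine and split one stripped slice into tissue maps
#'
#' Convenience wrapper chaining [moa_otsu_trilevel()],
#' [threshold_labels()], [mrf_refine()] and [extract_tissues()].
#'
#' @param img a skull-stripped [gray_image()].
#' @param moa_params optional [mayfly_params()] for the threshold search.
#' @param mrf_cfg an [mrf_config()].
#' @return list with `tissues`, `labels`, `thresholds`, `energy`.
#' @export
segment_slice <- function(img, moa_params = NULL, mrf_cfg = mrf_config()) {
  th <- moa_otsu_trilevel(img, moa_params)
  init <- threshold_labels(img, th$t1, th$t2)
  ref <- mrf_refine(img, init, mrf_cfg)
  list(tissues = extract_tissues(img, ref$labels),
       labels = ref$labels,
       thresholds = c(t1 = th$t1, t2 = th$t2),
       energy = ref$energy)
}
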