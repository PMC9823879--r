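# Mayfly wrapper selection of a fixed-size handcrafted feature subset.
#
# The selection fitness is the Cartesian (Euclidean) distance between the
# CON and SCZ class centroids of z-scored training features, restricted
# to the selected dimensions and normalized by sqrt(k) so that enlarging
# the subset with uninformative features never looks like progress.

#' Between-class centroid objective on z-scored training features
#'
#' @param features training feature matrix (rows = samples).
#' @param labels factor with levels CON, SCZ.
#' @return a `cd_objective` with per-class centroids, the per-feature
#'   standardized `gap`, the z-scoring `center`/`scale`, and a
#'   `zero_variance` flag vector (such features get scale 1).
#' @export
cd_objective <- function(features, labels) {
  y <- as.factor(labels)
  if (nlevels(y) != 2) stop("exactly two classes required")
  center <- colMeans(features)
  scale <- apply(features, 2, stats::sd)
  zero_var <- !is.finite(scale) | scale == 0
  scale[zero_var] <- 1
  z <- sweep(sweep(features, 2, center), 2, scale, "/")
  m1 <- colMeans(z[y == levels(y)[1], , drop = FALSE])
  m2 <- colMeans(z[y == levels(y)[2], , drop = FALSE])
  structure(list(m_con = m1, m_scz = m2, gap = m1 - m2,
                 center = center, scale = scale,
                 zero_variance = zero_var),
            class = "cd_objective")
}

#' Dimension-normalized Cartesian distance fitness of a feature mask
#'
#' `||gap restricted to selected dims||_2 / sqrt(k)`; an empty mask has
#' fitness `-Inf` and is never selected.
#'
#' @param mask logical vector over features.
#' @param obj a [cd_objective()].
#' @return numeric fitness (maximized).
#' @export
cd_fitness <- function(mask, obj) {
  k <- sum(mask)
  if (k == 0) return(-Inf)
  sqrt(sum(obj$gap[mask]^2)) / sqrt(k)
}

# deterministic coercion of a mask to exactly k bits by |gap| ranking
coerce_mask_k <- function(mask, gap, k) {
  agap <- abs(gap)
  n_sel <- sum(mask)
  if (n_sel > k) {
    sel <- which(mask)
    drop <- sel[order(agap[sel], -sel)][seq_len(n_sel - k)]
    mask[drop] <- FALSE
  } else if (n_sel < k) {
    un <- which(!mask)
    add <- un[order(-agap[un], un)][seq_len(k - n_sel)]
    mask[add] <- TRUE
  }
  mask
}

#' Mayfly wrapper feature selection
#'
#' Swarm positions live in `[0, 1]^D` and decode to masks by
#' `bit = (x > 0.5)`; fitness is [cd_fitness()] on the training data
#' (empty decodes score a large negative constant).  The optimizer's best
#' mask is then coerced to exactly `k` bits: oversized masks drop the
#' selected features with the smallest standardized |gap|, undersized
#' ones add the unselected features with the largest |gap| (ties toward
#' the lower index).
#'
#' @param features training-fold feature matrix (e.g. 286-dim handcrafted
#'   blocks).
#' @param labels factor CON/SCZ.
#' @param k target subset size (default 103).
#' @param params optional [mayfly_params()]; defaults to 20 flies and 150
#'   iterations over `[0, 1]^D`.
#' @param fit_fold leakage-guard identifier of the training fold.
#' @return a `selection_mask` with logical `bits` (popcount `k`), the
#'   `fitness` attained, feature `names`, the fitted `objective`, and
#'   `fit_fold`.
#' @export
moa_select <- function(features, labels, k = 103L, params = NULL,
                       fit_fold = NA) {
  d <- ncol(features)
  if (k < 1 || k > d) stop("k must lie in [1, ", d, "]")
  obj <- cd_objective(features, labels)
  if (is.null(params)) {
    params <- mayfly_params(bounds = cbind(rep(0, d), rep(1, d)),
                            n_flies = 20L, max_iter = 150L)
  }
  fit <- function(x) {
    m <- x > 0.5
    if (!any(m)) return(-1e300)
    cd_fitness(m, obj)
  }
  res <- mayfly_optimize(fit, params)
  bits <- coerce_mask_k(res$gbest > 0.5, obj$gap, k)
  structure(list(bits = bits, k = as.integer(k),
                 fitness = cd_fitness(bits, obj),
                 names = colnames(features),
                 objective = obj, trace = res$trace,
                 fit_fold = fit_fold),
            class = "selection_mask")
}

#' Apply a selection mask to a feature matrix
#' @param object a `selection_mask`.
#' @param newdata feature matrix with the same columns the mask was fit
#'   on.
#' @param ... unused.
#' @return matrix restricted to the selected features.
#' @export
predict.selection_mask <- function(object, newdata, ...) {
  newdata[, object$bits, drop = FALSE]
}

#' Persist a selection mask as JSON
#' @param mask a `selection_mask`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
selection_to_json <- function(mask, path) {
  jsonlite::write_json(
    list(k = mask$k,
         indices = which(mask$bits),
         names = if (is.null(mask$names)) NULL else mask$names[mask$bits]),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Selection report: per-feature standardized gap and selected flag
#' @param mask a `selection_mask`.
#' @return data frame (feature, abs_gap, selected).
#' @export
selection_report <- function(mask) {
  data.frame(
    feature = if (is.null(mask$names))
      sprintf("feat_%03d", seq_along(mask$bits)) else mask$names,
    abs_gap = abs(mask$objective$gap),
    selected = mask$bits)
}
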