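# Deep-feature backbone contract, a deterministic fixture backbone, and
# the supervised 1024 -> 512 rank reduction.
#
# Pretrained convolutional weights are deliberately not bundled: the
# backbone is a pluggable contract (image -> 1024 finite floats).  The
# fixture backbone is a fixed random projection of multi-scale image
# statistics -- deterministic, cheap, and Lipschitz in the pixel values --
# which is exactly what reproducible tests of everything downstream need.

df_cache <- new.env(parent = emptyenv())

# multi-scale image statistics: block means at 4x4 / 8x8 / 16x16 grids of
# the [0,1]-scaled image, plus 8x8 block means of the gradient magnitude.
# All terms vanish on an all-zero image.
df_stats <- function(p) {
  p <- p / 255
  block_means <- function(m, g) {
    ry <- ceiling(seq_len(nrow(m)) / (nrow(m) / g))
    rx <- ceiling(seq_len(ncol(m)) / (ncol(m) / g))
    as.vector(tapply(m, list(ry[row(m)], rx[col(m)]), mean))
  }
  gy <- abs(p - shift_mat(p, 1L, 0L))
  gx <- abs(p - shift_mat(p, 0L, 1L))
  c(block_means(p, 4), block_means(p, 8), block_means(p, 16),
    block_means(gy + gx, 8))
}

df_projection <- function() {
  if (is.null(df_cache$a)) {
    with_seed(8191L, {
      d_in <- 400L; d_out <- 1024L
      df_cache$a <- matrix(stats::rnorm(d_out * d_in) / sqrt(d_in),
                           d_out, d_in)
      df_cache$b <- stats::rnorm(d_out, sd = 0.1)
    })
  }
  list(a = df_cache$a, b = df_cache$b)
}

#' The deterministic fixture deep-feature backbone
#'
#' Maps a grayscale slice to 1024 floats via a fixed random projection of
#' 400 multi-scale block statistics plus a fixed bias.  An all-zero image
#' maps exactly to the bias vector ([df_fixture_bias()]).
#'
#' @return a `df_backbone` object.
#' @export
df_fixture_backbone <- function() {
  structure(list(
    id = "fixture-v1",
    n_out = 1024L,
    fun = function(p) {
      pr <- df_projection()
      as.numeric(pr$a %*% df_stats(p) + pr$b)
    }), class = "df_backbone")
}

#' Bias vector of the fixture backbone (its value on an all-zero image)
#' @return numeric vector of length 1024.
#' @export
df_fixture_bias <- function() df_projection()$b

#' Wrap an externally supplied pretrained network as a backbone
#'
#' The adapter contract: `fun` receives an H x W grayscale matrix in
#' \[0, 255\] (callers replicate to 3 channels if their network needs it)
#' and must return 1024 finite floats, deterministically given its
#' weights.  Recorded (not executed) training defaults for such
#' backbones: Adam, learning rate 1e-5, 4000 iterations, 50 epochs,
#' rotation augmentation +/-60 degrees in 10-degree steps.
#'
#' @param fun function(matrix) -> numeric(1024).
#' @param id identifier string (e.g. `"vgg16"`).
#' @return a `df_backbone` object.
#' @export
df_adapter_backbone <- function(fun, id = "adapter") {
  stopifnot(is.function(fun))
  structure(list(id = id, n_out = 1024L, fun = fun), class = "df_backbone")
}

#' Extract deep features for a list of slices
#'
#' @param slices list of [gray_image()] objects (or matrices).
#' @param backbone a `df_backbone` (default: the fixture).
#' @return numeric matrix, one 1024-dim row per slice.
#' @export
extract_df <- function(slices, backbone = df_fixture_backbone()) {
  stopifnot(inherits(backbone, "df_backbone"))
  out <- t(vapply(slices, function(s) {
    v <- backbone$fun(as_gray_image(s)$pixels)
    if (length(v) != backbone$n_out || any(!is.finite(v))) {
      stop("backbone '", backbone$id, "' returned an invalid feature vector")
    }
    v
  }, numeric(backbone$n_out)))
  colnames(out) <- sprintf("df_%04d", seq_len(backbone$n_out))
  out
}

#' Rotation augmentation variants of a slice
#'
#' Rotations at -60..-10 and +10..+60 degrees in 10-degree steps plus the
#' identity (13 variants).
#'
#' @param img a [gray_image()] or matrix.
#' @param angles rotation angles in degrees.
#' @return list of [gray_image()] objects, identity first.
#' @export
augment_rotations <- function(img, angles = c(seq(-60, -10, 10),
                                              seq(10, 60, 10))) {
  img <- as_gray_image(img)
  c(list(img), lapply(angles, function(a) {
    r <- EBImage::rotate(img$pixels, a, output.dim = dim(img$pixels))
    gray_image(clamp(as.matrix(r), 0, 255))
  }))
}

#' Fit the supervised 1024 -> 512 deep-feature reduction
#'
#' Ranks dimensions by the absolute pooled two-sample t-statistic between
#' classes on the training rows and keeps the top `k`.  A zero-variance
#' dimension ranks first when its class means still differ (infinite
#' separation) and last otherwise; ties break toward the lower index.
#' The fitted index set must be applied unchanged to validation folds;
#' `fit_fold` is recorded so the harness can assert that.
#'
#' @param train_df training deep-feature matrix (n x 1024).
#' @param train_labels factor with levels CON, SCZ (>= 2 samples per
#'   class).
#' @param k number of dimensions kept.
#' @param fit_fold identifier of the training fold this reducer was fit
#'   on (leakage guard).
#' @return a `df_reducer` with sorted `selected_idx`.
#' @export
rank_reduce_df <- function(train_df, train_labels, k = 512L, fit_fold = NA) {
  y <- as.factor(train_labels)
  if (nlevels(y) != 2 || any(table(y) < 2)) {
    stop("need two classes with >= 2 samples each")
  }
  g1 <- train_df[y == levels(y)[1], , drop = FALSE]
  g2 <- train_df[y == levels(y)[2], , drop = FALSE]
  n1 <- nrow(g1); n2 <- nrow(g2)
  m1 <- colMeans(g1); m2 <- colMeans(g2)
  v1 <- apply(g1, 2, stats::var); v2 <- apply(g2, 2, stats::var)
  sp <- sqrt(((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2))
  tt <- ifelse(sp > 0,
               (m1 - m2) / (sp * sqrt(1 / n1 + 1 / n2)),
               ifelse(m1 != m2, Inf, 0))
  ord <- order(-abs(tt), seq_along(tt))
  idx <- sort(ord[seq_len(min(k, length(tt)))])
  structure(list(selected_idx = idx, k = as.integer(k),
                 t_stats = tt, fit_fold = fit_fold),
            class = "df_reducer")
}

#' Apply a fitted deep-feature reducer
#' @param object a `df_reducer`.
#' @param newdata deep-feature matrix.
#' @param ... unused.
#' @return matrix restricted to the selected dimensions.
#' @export
predict.df_reducer <- function(object, newdata, ...) {
  newdata[, object$selected_idx, drop = FALSE]
}
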