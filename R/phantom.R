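# Synthetic head phantom and planted-signal feature tables.
#
# The phantom is a deliberately cartoonish 2D "axial slice": an elliptical
# skull annulus, a CSF gap, a gray-matter ribbon, a white-matter core and
# two CSF ventricles.  It is not anatomically realistic -- its purpose is
# to give every downstream stage (skull stripping, tri-level thresholding,
# MRF refinement, texture features, selection, classification) a ground
# truth with controllable tissue statistics.

#' Integer codes of the phantom ground-truth label maps
#' @return named integer vector (background, skull, csf, gm, wm).
#' @export
phantom_labels <- function() {
  c(background = 0L, skull = 1L, csf = 2L, gm = 3L, wm = 4L)
}

#' Configuration for the synthetic head phantom
#'
#' Tissue intensities follow the T1-weighted convention
#' (CSF dark < gray matter < white matter < skull rim bright).
#'
#' @param image_size integer vector (height, width) in pixels.
#' @param skull_intensity,csf_intensity,gm_intensity,wm_intensity tissue
#'   gray levels in \[0, 255\]; must satisfy csf < gm < wm.
#' @param noise_sigma standard deviation of additive Gaussian noise.
#' @param class_effect magnitude (gray levels) of the class-dependent
#'   texture perturbation applied to SCZ slices.
#' @param effect_mode how the SCZ perturbation is realized: `"texture"`
#'   adds spatially correlated noise of sd `class_effect` to the GM/WM
#'   compartments; `"gm_fraction"` shrinks the white-matter core, thickening
#'   the gray-matter ribbon.
#' @param n_per_class number of slices generated per class.
#' @param y_radius_frac,x_radius_frac head ellipse semi-axes as fractions
#'   of the image height/width; must be < 0.5 so the head fits.
#' @param seed integer master seed; every slice derives its own stream.
#' @return a `phantom_config` list.
#' @export
phantom_config <- function(image_size = c(224L, 224L),
                           skull_intensity = 240,
                           csf_intensity = 50,
                           gm_intensity = 120,
                           wm_intensity = 200,
                           noise_sigma = 6,
                           class_effect = 0,
                           effect_mode = c("texture", "gm_fraction"),
                           n_per_class = 20L,
                           y_radius_frac = 0.44,
                           x_radius_frac = 0.40,
                           seed = 1L) {
  effect_mode <- match.arg(effect_mode)
  image_size <- as.integer(rep(image_size, length.out = 2))
  ints <- c(skull_intensity, csf_intensity, gm_intensity, wm_intensity)
  if (any(ints < 0 | ints > 255)) stop("tissue intensities must lie in [0, 255]")
  if (!(csf_intensity < gm_intensity && gm_intensity < wm_intensity)) {
    stop("intensities must satisfy csf < gm < wm")
  }
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  if (class_effect < 0) stop("class_effect must be >= 0")
  if (n_per_class < 1) stop("n_per_class must be >= 1")
  if (y_radius_frac >= 0.5 || x_radius_frac >= 0.5) {
    stop("degenerate geometry: brain ellipse larger than image")
  }
  structure(list(image_size = image_size,
                 skull_intensity = skull_intensity,
                 csf_intensity = csf_intensity,
                 gm_intensity = gm_intensity,
                 wm_intensity = wm_intensity,
                 noise_sigma = noise_sigma,
                 class_effect = class_effect,
                 effect_mode = effect_mode,
                 n_per_class = as.integer(n_per_class),
                 y_radius_frac = y_radius_frac,
                 x_radius_frac = x_radius_frac,
                 seed = as.integer(seed)),
            class = "phantom_config")
}

# Normalized elliptical radius of every pixel w.r.t. the head ellipse.
phantom_rho <- function(h, w, ry, rx) {
  cy <- (h + 1) / 2
  cx <- (w + 1) / 2
  y <- matrix(seq_len(h), h, w)
  x <- matrix(seq_len(w), h, w, byrow = TRUE)
  sqrt(((y - cy) / ry)^2 + ((x - cx) / rx)^2)
}

#' Generate one phantom head slice with ground truth
#'
#' @param cfg a [phantom_config()].
#' @param class_label `"CON"` or `"SCZ"`; SCZ slices receive the
#'   `class_effect` perturbation.
#' @param index slice index (enters the per-slice random stream, so the
#'   same (cfg, class, index) triple is bit-reproducible).
#' @return list with `image` (a [gray_image()]), `labels` (integer matrix
#'   coded per [phantom_labels()]), `class_label` and `index`.
#' @export
generate_phantom <- function(cfg, class_label = c("CON", "SCZ"), index = 1L) {
  stopifnot(inherits(cfg, "phantom_config"))
  class_label <- match.arg(class_label)
  h <- cfg$image_size[1]; w <- cfg$image_size[2]
  ry <- cfg$y_radius_frac * h
  rx <- cfg$x_radius_frac * w
  rho <- phantom_rho(h, w, ry, rx)
  lab <- phantom_labels()

  # WM core shrinks under the gm_fraction effect mode for SCZ slices.
  wm_rho <- 0.70
  if (class_label == "SCZ" && cfg$effect_mode == "gm_fraction") {
    wm_rho <- wm_rho * max(0.2, 1 - 0.05 * cfg$class_effect)
  }

  labels <- matrix(lab["background"], h, w)
  labels[rho <= 1.00] <- lab["skull"]
  labels[rho <= 0.95] <- lab["csf"]
  labels[rho <= 0.915] <- lab["gm"]
  labels[rho <= wm_rho] <- lab["wm"]

  # lateral ventricles: two small CSF ellipses inside the WM core
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  y <- matrix(seq_len(h), h, w)
  x <- matrix(seq_len(w), h, w, byrow = TRUE)
  for (s in c(-1, 1)) {
    vc <- cx + s * 0.16 * rx
    vent <- (((y - cy) / (0.22 * ry))^2 + ((x - vc) / (0.07 * rx))^2) <= 1
    labels[vent & labels == lab["wm"]] <- lab["csf"]
  }

  intens <- c(0, cfg$skull_intensity, cfg$csf_intensity,
              cfg$gm_intensity, cfg$wm_intensity)
  img <- matrix(intens[labels + 1L], h, w)

  seed_i <- derive_seed(cfg$seed, as.integer(index),
                        as.integer(class_label == "SCZ"))
  img <- with_seed(seed_i, {
    if (class_label == "SCZ" && cfg$effect_mode == "texture" &&
        cfg$class_effect > 0) {
      field <- matrix(stats::rnorm(h * w), h, w)
      field <- EBImage::gblur(field, sigma = 2.5)
      field <- field / stats::sd(field)
      tissue <- labels == lab["gm"] | labels == lab["wm"]
      img[tissue] <- img[tissue] + cfg$class_effect * field[tissue]
    }
    if (cfg$noise_sigma > 0) {
      img <- img + matrix(stats::rnorm(h * w, sd = cfg$noise_sigma), h, w)
    }
    img
  })

  list(image = gray_image(clamp(img, 0, 255)),
       labels = labels, class_label = class_label, index = as.integer(index))
}

#' Generate a full phantom cohort (both classes)
#'
#' @param cfg a [phantom_config()].
#' @return list of [generate_phantom()] results, CON slices first.
#' @export
generate_phantom_set <- function(cfg) {
  out <- vector("list", 2L * cfg$n_per_class)
  k <- 0L
  for (cl in c("CON", "SCZ")) {
    for (i in seq_len(cfg$n_per_class)) {
      k <- k + 1L
      out[[k]] <- generate_phantom(cfg, cl, i)
    }
  }
  out
}

#' Write a phantom cohort as PNG slices plus a CSV manifest
#'
#' @param cfg a [phantom_config()].
#' @param dir output directory (created if missing).
#' @return invisibly, the manifest data frame (filename, class, index, seed).
#' @export
write_phantom_set <- function(cfg, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  phantoms <- generate_phantom_set(cfg)
  manifest <- data.frame(
    filename = vapply(phantoms, function(p)
      sprintf("%s_%03d.png", tolower(p$class_label), p$index), ""),
    class = vapply(phantoms, function(p) p$class_label, ""),
    index = vapply(phantoms, function(p) p$index, 0L),
    seed = cfg$seed)
  for (j in seq_along(phantoms)) {
    png::writePNG(phantoms[[j]]$image$pixels / 255,
                  file.path(dir, manifest$filename[j]))
  }
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

#' Configuration for planted-signal feature tables
#'
#' @param n_per_class samples per class.
#' @param n_features number of feature columns (default 286, the size of
#'   the handcrafted block).
#' @param informative_idx integer indices of columns carrying class signal.
#' @param effect_size standardized mean shift applied to informative
#'   columns in the SCZ class.
#' @param seed integer seed.
#' @return a `planted_table_config` list.
#' @export
planted_table_config <- function(n_per_class = 100L,
                                 n_features = 286L,
                                 informative_idx = integer(0),
                                 effect_size = 0,
                                 seed = 1L) {
  informative_idx <- as.integer(informative_idx)
  if (length(informative_idx) > n_features) {
    stop("more informative indices than features")
  }
  if (length(informative_idx) &&
      (min(informative_idx) < 1 || max(informative_idx) > n_features)) {
    stop("informative_idx out of range")
  }
  if (effect_size < 0) stop("effect_size must be >= 0")
  structure(list(n_per_class = as.integer(n_per_class),
                 n_features = as.integer(n_features),
                 informative_idx = informative_idx,
                 effect_size = effect_size,
                 seed = as.integer(seed)),
            class = "planted_table_config")
}

#' Generate a labeled feature table with planted class signal
#'
#' Features are standard normal; columns listed in `informative_idx` are
#' shifted by `effect_size` in the SCZ class.
#'
#' @param cfg a [planted_table_config()].
#' @return list with `x` (matrix, named columns), `labels` (factor
#'   CON/SCZ) and `informative_idx`.
#' @export
generate_feature_table <- function(cfg) {
  stopifnot(inherits(cfg, "planted_table_config"))
  n <- 2L * cfg$n_per_class
  x <- with_seed(cfg$seed,
                 matrix(stats::rnorm(n * cfg$n_features), n, cfg$n_features))
  labels <- factor(rep(c("CON", "SCZ"), each = cfg$n_per_class),
                   levels = c("CON", "SCZ"))
  if (length(cfg$informative_idx)) {
    x[labels == "SCZ", cfg$informative_idx] <-
      x[labels == "SCZ", cfg$informative_idx] + cfg$effect_size
  }
  colnames(x) <- sprintf("feat_%03d", seq_len(cfg$n_features))
  list(x = x, labels = labels, informative_idx = cfg$informative_idx)
}

#' Write a feature table as CSV with a final label column
#' @param table result of [generate_feature_table()] (or any list with
#'   `x` and `labels`).
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
write_feature_table <- function(table, path) {
  df <- as.data.frame(table$x)
  df$label <- as.character(table$labels)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
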