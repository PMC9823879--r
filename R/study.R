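# In-memory end-to-end phantom study: generate -> strip -> segment ->
# features -> fused cross-validated classification.  This is the
# programmatic counterpart of cmd_run_all without any file artifacts.

#' Run the full pipeline on a synthetic phantom cohort
#'
#' Generates `n_per_class` slices per class, skull-strips each, separates
#' GM/WM (mayfly Otsu + MRF), extracts the 286-dim handcrafted block and
#' the 1024-dim fixture deep block, and evaluates the fused 615-dim
#' vectors under stratified cross-validation with per-fold transformer
#' fitting.
#'
#' @param n_per_class slices per class.
#' @param image_size phantom geometry (pixels).
#' @param class_effect SCZ texture perturbation magnitude.
#' @param noise_sigma additive noise level.
#' @param seed master seed (phantoms, folds, optimizers).
#' @param classifier id from [classifier_registry()].
#' @param n_folds cross-validation folds.
#' @param moa_iter,select_iter iteration budgets of the threshold search
#'   and the selection wrapper.
#' @param effect_mode forwarded to [phantom_config()].
#' @return [evaluate_pipeline()] result plus `pooled_acc` (fraction of
#'   correct validation predictions pooled over folds) and `n` (total
#'   slices).
#' @export
phantom_study <- function(n_per_class = 10L,
                          image_size = c(96L, 96L),
                          class_effect = 0,
                          noise_sigma = 6,
                          seed = 1L,
                          classifier = "svm-linear",
                          n_folds = 5L,
                          moa_iter = 40L,
                          select_iter = 60L,
                          effect_mode = "texture") {
  cfg <- phantom_config(image_size = image_size,
                        noise_sigma = noise_sigma,
                        class_effect = class_effect,
                        effect_mode = effect_mode,
                        n_per_class = n_per_class,
                        seed = seed)
  phantoms <- generate_phantom_set(cfg)
  labels <- factor(vapply(phantoms, `[[`, "", "class_label"),
                   levels = c("CON", "SCZ"))
  moa_par <- mayfly_params(bounds = cbind(c(1, 1), c(254, 254)),
                           n_flies = 15L, max_iter = moa_iter, seed = seed)
  feats <- lapply(phantoms, function(ph) {
    st <- skull_strip(ph$image)
    seg <- segment_slice(st, moa_par)
    extract_hf(st, tissues = seg$tissues)
  })
  hf <- do.call(rbind, feats)
  df <- extract_df(lapply(phantoms, `[[`, "image"))
  plan <- cv_plan(labels, n_folds = n_folds, seed = seed)
  sel_par <- mayfly_params(bounds = cbind(rep(0, ncol(hf)), rep(1, ncol(hf))),
                           n_flies = 15L, max_iter = select_iter,
                           seed = seed)
  res <- evaluate_pipeline(df, hf, labels, plan, classifier = classifier,
                           select_params = sel_par)
  correct <- sum(vapply(res$counts, function(ct) ct[["TP"]] + ct[["TN"]], 0))
  res$n <- length(labels)
  res$pooled_acc <- correct / res$n
  res
}
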