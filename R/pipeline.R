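# Pipeline driver: staged commands over a single configuration, with a
# config hash embedded in every stage's metadata so stale artifacts are
# never silently mixed.  Stages: generate -> segment -> features ->
# select -> evaluate; run_all chains them.

#' Build a pipeline configuration
#'
#' One nested list drives every stage; any block can be overridden.  The
#' same structure can be loaded from YAML or JSON with
#' [read_pipeline_config()].
#'
#' @param out_dir output directory for all artifacts.
#' @param input_dir optional directory of existing PNG slices with a
#'   `manifest.csv` (filename, class); when `NULL` the phantom generator
#'   provides the slices.
#' @param phantom named list overriding [phantom_config()] arguments.
#' @param preprocess list: `size` (working geometry), `erosion_radius`.
#' @param moa list: mayfly settings for the threshold search
#'   (`n_flies`, `max_iter`).
#' @param mrf named list overriding [mrf_config()] arguments.
#' @param lbp_weights integer LBP weights.
#' @param glcm list: `levels`, `distance`.
#' @param selection list: `k`, `n_flies`, `max_iter`.
#' @param backbone `"fixture"` or a `df_backbone` object.
#' @param classifiers classifier ids to evaluate.
#' @param cv list: `n_folds`, `grouping`, `seed`.
#' @param seed master seed.
#' @param force overwrite artifacts produced under a different config.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir,
                            input_dir = NULL,
                            phantom = list(),
                            preprocess = list(size = c(224L, 224L),
                                              erosion_radius = 6L),
                            moa = list(n_flies = 15L, max_iter = 40L),
                            mrf = list(),
                            lbp_weights = 1:4,
                            glcm = list(levels = 8L, distance = 1L),
                            selection = list(k = 103L, n_flies = 15L,
                                             max_iter = 60L),
                            backbone = "fixture",
                            classifiers = "svm-linear",
                            cv = list(n_folds = 5L, grouping = "slice",
                                      seed = 1L),
                            seed = 1L,
                            force = FALSE) {
  cfg <- list(out_dir = out_dir, input_dir = input_dir, phantom = phantom,
              preprocess = preprocess, moa = moa, mrf = mrf,
              lbp_weights = lbp_weights, glcm = glcm,
              selection = selection, backbone = backbone,
              classifiers = classifiers, cv = cv,
              seed = as.integer(seed), force = isTRUE(force))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML or JSON
#' @param path config file; top-level keys as in [pipeline_config()].
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.json$", tolower(path))) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  do.call(pipeline_config, raw)
}

stage_dir <- function(cfg, stage) file.path(cfg$out_dir, stage)

stage_hash <- function(cfg) {
  h <- cfg
  h$force <- NULL
  config_hash(h)
}

check_stage_fresh <- function(cfg, stage) {
  meta <- file.path(stage_dir(cfg, stage), "stage.json")
  if (file.exists(meta)) {
    old <- jsonlite::read_json(meta)
    if (!identical(old$config_hash, stage_hash(cfg)) && !cfg$force) {
      stop("artifacts in ", stage_dir(cfg, stage),
           " were produced under a different config; re-run with force")
    }
  }
  dir.create(stage_dir(cfg, stage), recursive = TRUE, showWarnings = FALSE)
}

write_stage_meta <- function(cfg, stage, extra = list()) {
  jsonlite::write_json(
    c(list(stage = stage, config_hash = stage_hash(cfg),
           seed = cfg$seed, time = format(Sys.time())), extra),
    file.path(stage_dir(cfg, stage), "stage.json"),
    auto_unbox = TRUE, pretty = TRUE)
}

require_stage <- function(cfg, stage, producer) {
  if (!file.exists(file.path(stage_dir(cfg, stage), "stage.json"))) {
    stop("missing artifacts of stage '", stage,
         "'; run ", producer, " first")
  }
}

#' Generate phantom slices (stage: generate)
#' @param cfg a [pipeline_config()].
#' @return invisibly, the slice manifest.
#' @export
cmd_generate <- function(cfg) {
  check_stage_fresh(cfg, "generate")
  ph <- do.call(phantom_config, c(cfg$phantom, list(seed = cfg$seed)))
  manifest <- write_phantom_set(ph, stage_dir(cfg, "generate"))
  write_stage_meta(cfg, "generate", list(n_slices = nrow(manifest)))
  invisible(manifest)
}

read_cohort <- function(cfg) {
  src <- if (!is.null(cfg$input_dir)) cfg$input_dir else {
    require_stage(cfg, "generate", "cmd_generate")
    stage_dir(cfg, "generate")
  }
  manifest <- utils::read.csv(file.path(src, "manifest.csv"))
  slices <- lapply(manifest$filename, function(f)
    load_slices(file.path(src, f))[[1]])
  list(manifest = manifest, slices = slices)
}

#' Strip and segment every slice (stage: segment)
#' @param cfg a [pipeline_config()].
#' @return invisibly, `NULL`.
#' @export
cmd_segment <- function(cfg) {
  check_stage_fresh(cfg, "segment")
  cohort <- read_cohort(cfg)
  dir <- stage_dir(cfg, "segment")
  moa_par <- mayfly_params(bounds = cbind(c(1, 1), c(254, 254)),
                           n_flies = cfg$moa$n_flies,
                           max_iter = cfg$moa$max_iter,
                           seed = cfg$seed)
  mrf_cfg <- do.call(mrf_config, cfg$mrf)
  for (i in seq_along(cohort$slices)) {
    img <- resize_image(cohort$slices[[i]], cfg$preprocess$size)
    stripped <- skull_strip(img, cfg$preprocess$erosion_radius)
    seg <- segment_slice(stripped, moa_par, mrf_cfg)
    base <- sub("\\.png$", "", cohort$manifest$filename[i])
    write_slice_png(stripped, file.path(dir, paste0(base, "_brain.png")))
    write_slice_png(stripped, file.path(dir, paste0(base, "_mask.png")),
                    what = "mask")
    write_slice_png(gray_image(seg$tissues$gm_mask * 255),
                    file.path(dir, paste0(base, "_gm.png")))
    write_slice_png(gray_image(seg$tissues$wm_mask * 255),
                    file.path(dir, paste0(base, "_wm.png")))
    utils::write.csv(data.frame(sweep = seq_along(seg$energy),
                                energy = seg$energy),
                     file.path(dir, paste0(base, "_energy.csv")),
                     row.names = FALSE)
  }
  write_stage_meta(cfg, "segment")
  invisible(NULL)
}

read_segmented <- function(cfg) {
  require_stage(cfg, "segment", "cmd_segment")
  cohort <- read_cohort(cfg)
  dir <- stage_dir(cfg, "segment")
  slices <- lapply(cohort$manifest$filename, function(f) {
    base <- sub("\\.png$", "", f)
    p <- load_slices(file.path(dir, paste0(base, "_brain.png")))[[1]]
    mask <- load_slices(file.path(dir, paste0(base, "_mask.png")))[[1]]
    gm <- load_slices(file.path(dir, paste0(base, "_gm.png")))[[1]]
    wm <- load_slices(file.path(dir, paste0(base, "_wm.png")))[[1]]
    list(stripped = gray_image(p$pixels, mask$pixels > 127),
         gm_mask = gm$pixels > 127, wm_mask = wm$pixels > 127)
  })
  list(manifest = cohort$manifest, slices = slices)
}

#' Extract handcrafted and deep feature tables (stage: features)
#' @param cfg a [pipeline_config()].
#' @return invisibly, `NULL`.
#' @export
cmd_features <- function(cfg) {
  check_stage_fresh(cfg, "features")
  seg <- read_segmented(cfg)
  dir <- stage_dir(cfg, "features")
  backbone <- if (inherits(cfg$backbone, "df_backbone")) cfg$backbone
              else df_fixture_backbone()
  hf <- t(vapply(seg$slices, function(s) {
    tissues <- list(
      gm_image = gray_image(s$stripped$pixels * s$gm_mask, s$gm_mask),
      wm_image = gray_image(s$stripped$pixels * s$wm_mask, s$wm_mask))
    extract_hf(s$stripped, tissues = tissues)
  }, numeric(286)))
  df <- extract_df(lapply(seg$slices, `[[`, "stripped"), backbone)
  labels <- seg$manifest$class
  utils::write.csv(cbind(as.data.frame(hf), label = labels),
                   file.path(dir, "hf.csv"), row.names = FALSE)
  utils::write.csv(cbind(as.data.frame(df), label = labels),
                   file.path(dir, "df.csv"), row.names = FALSE)
  write_stage_meta(cfg, "features",
                   list(hf_width = ncol(hf), df_width = ncol(df)))
  invisible(NULL)
}

read_features <- function(cfg) {
  require_stage(cfg, "features", "cmd_features")
  dir <- stage_dir(cfg, "features")
  hf <- utils::read.csv(file.path(dir, "hf.csv"), check.names = FALSE)
  df <- utils::read.csv(file.path(dir, "df.csv"), check.names = FALSE)
  labels <- factor(hf$label, levels = c("CON", "SCZ"))
  list(hf = as.matrix(hf[, names(hf) != "label"]),
       df = as.matrix(df[, names(df) != "label"]),
       labels = labels)
}

select_mayfly_params <- function(cfg, d) {
  mayfly_params(bounds = cbind(rep(0, d), rep(1, d)),
                n_flies = cfg$selection$n_flies,
                max_iter = cfg$selection$max_iter,
                seed = cfg$seed)
}

#' Fit the handcrafted selection mask on the full table (stage: select)
#'
#' This reporting mask describes the whole cohort; cross-validated
#' evaluation refits it per training fold.
#'
#' @param cfg a [pipeline_config()].
#' @return invisibly, the `selection_mask`.
#' @export
cmd_select <- function(cfg) {
  check_stage_fresh(cfg, "select")
  feats <- read_features(cfg)
  mask <- moa_select(feats$hf, feats$labels, k = cfg$selection$k,
                     params = select_mayfly_params(cfg, ncol(feats$hf)),
                     fit_fold = "all")
  dir <- stage_dir(cfg, "select")
  selection_to_json(mask, file.path(dir, "mask.json"))
  utils::write.csv(selection_report(mask),
                   file.path(dir, "report.csv"), row.names = FALSE)
  write_stage_meta(cfg, "select", list(k = mask$k))
  invisible(mask)
}

#' Cross-validated evaluation of the fused pipeline (stage: evaluate)
#' @param cfg a [pipeline_config()].
#' @return invisibly, named list of [evaluate_pipeline()] results per
#'   classifier.
#' @export
cmd_evaluate <- function(cfg) {
  check_stage_fresh(cfg, "evaluate")
  feats <- read_features(cfg)
  subjects <- NULL
  if (identical(cfg$cv$grouping, "subject")) {
    manifest <- read_cohort(cfg)$manifest
    subjects <- paste(manifest$class, manifest$index)
  }
  plan <- cv_plan(feats$labels, n_folds = cfg$cv$n_folds,
                  grouping = cfg$cv$grouping, subjects = subjects,
                  seed = cfg$cv$seed)
  results <- lapply(cfg$classifiers, function(id)
    evaluate_pipeline(feats$df, feats$hf, feats$labels, plan,
                      classifier = id, k_hf = cfg$selection$k,
                      select_params = select_mayfly_params(cfg,
                                                           ncol(feats$hf))))
  names(results) <- cfg$classifiers
  dir <- stage_dir(cfg, "evaluate")
  for (id in cfg$classifiers) {
    utils::write.csv(results[[id]]$table,
                     file.path(dir, paste0("metrics_", id, ".csv")),
                     row.names = FALSE)
  }
  jsonlite::write_json(
    lapply(results, function(r)
      list(best_fold = r$best_fold,
           best_metrics = as.list(r$best_metrics),
           mean_acc = r$mean_acc,
           fused_width = r$fused_width,
           counts = lapply(r$counts, as.list))),
    file.path(dir, "metrics.json"), auto_unbox = TRUE, pretty = TRUE)
  jsonlite::write_json(
    list(config_hash = stage_hash(cfg), seed = cfg$seed,
         fold_of = plan$fold_of, grouping = plan$grouping),
    file.path(dir, "run_manifest.json"), auto_unbox = TRUE, pretty = TRUE)
  write_stage_meta(cfg, "evaluate")
  invisible(results)
}

#' Run every pipeline stage in order
#' @param cfg a [pipeline_config()].
#' @return invisibly, the [cmd_evaluate()] results.
#' @export
cmd_run_all <- function(cfg) {
  if (is.null(cfg$input_dir)) cmd_generate(cfg)
  cmd_segment(cfg)
  cmd_features(cfg)
  cmd_select(cfg)
  invisible(cmd_evaluate(cfg))
}
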