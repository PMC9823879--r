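test_that("serial fusion is a width-checked ordered concatenation", {
  df <- seq_len(512); hf <- seq_len(103) + 1000
  out <- fuse(df, hf)
  expect_length(out, 615)
  expect_equal(out[513], hf[1])
  expect_equal(fuse(rep(0, 512), rep(0, 103)), rep(0, 615))
  expect_error(fuse(seq_len(511), hf), "width 512")
  expect_error(fuse(df, seq_len(104)), "width 103")
  m <- fuse(matrix(0, 2, 512), matrix(1, 2, 103))
  expect_equal(dim(m), c(2, 615))
})

test_that("metric formulas reproduce the published fold table exactly", {
  counts <- softmax_fold_counts()
  printed <- softmax_fold_metrics()
  for (i in seq_along(counts)) {
    expect_equal(unname(compute_metrics(counts[[i]])), printed[i, ],
                 tolerance = 1e-9)
  }
  tab <- metrics_table(counts)
  expect_equal(as.matrix(tab[, c("ACC", "PRE", "SEN", "SPE", "NPV", "FS")]),
               printed, ignore_attr = TRUE)
  expect_equal(which(tab$best), 4)  # the reported best trial
})

test_that("perfect classifiers score 100 on every metric", {
  m <- compute_metrics(c(TP = 37, FN = 0, TN = 37, FP = 0))
  expect_true(all(m == 100))
})

test_that("metric identities hold on random counts before rounding", {
  for (seed in 1:10) {
    ct <- withr::with_seed(seed, c(TP = sample(1:200, 1), FN = sample(1:200, 1),
                                   TN = sample(1:200, 1), FP = sample(1:200, 1)))
    m <- compute_metrics(ct, digits = NULL)
    p <- ct[["TP"]] + ct[["FN"]]; n <- ct[["TN"]] + ct[["FP"]]
    expect_equal(m[["ACC"]], (m[["SEN"]] * p + m[["SPE"]] * n) / (p + n),
                 tolerance = 1e-9)
    expect_equal(m[["FS"]],
                 2 * m[["PRE"]] * m[["SEN"]] / (m[["PRE"]] + m[["SEN"]]),
                 tolerance = 1e-9)
  }
})

test_that("zero denominators warn and report NaN, never zero", {
  expect_warning(m <- compute_metrics(c(TP = 0, FN = 5, TN = 5, FP = 0)),
                 "PRE undefined")
  expect_true(is.nan(m[["PRE"]]))
  expect_equal(m[["SEN"]], 0)
  expect_error(compute_metrics(c(TP = 0, FN = 0, TN = 0, FP = 0)),
               "all counts are zero")
  expect_error(compute_metrics(c(TP = -1, FN = 0, TN = 5, FP = 0)),
               "non-negative")
})

test_that("rounding is half-up to four decimals", {
  expect_equal(round_half_up(91.38885, 4), 91.3889)
  expect_equal(round_half_up(0.00005, 4), 1e-4)
  expect_equal(round_half_up(-0.00005, 4), -1e-4)
})

test_that("fold tables track permutations and mark single folds best", {
  counts <- softmax_fold_counts()
  tab1 <- metrics_table(counts)
  perm <- c(3, 1, 4, 2, 5)
  tab2 <- metrics_table(counts[perm])
  expect_equal(tab2$ACC, tab1$ACC[perm])
  expect_equal(which(tab2$best), which(perm == 4))
  single <- metrics_table(counts[2])
  expect_true(single$best)
})

test_that("slice-level plans partition samples with stratified folds", {
  y <- factor(rep(c("CON", "SCZ"), each = 50))
  plan <- cv_plan(y, n_folds = 5, seed = 3)
  all_va <- sort(unlist(lapply(plan$folds, `[[`, "validation")))
  expect_equal(all_va, seq_along(y))
  for (f in plan$folds) {
    expect_setequal(c(f$train, f$validation), seq_along(y))
    expect_equal(sum(y[f$validation] == "SCZ"), 10)
  }
})

test_that("subject grouping never splits a subject across folds", {
  subjects <- rep(sprintf("s%02d", 1:10), each = 30)
  y <- factor(rep(rep(c("CON", "SCZ"), each = 5 * 30), length.out = 300))
  plan <- cv_plan(y, n_folds = 5, grouping = "subject",
                  subjects = subjects, seed = 2)
  for (f in plan$folds) {
    expect_length(intersect(unique(subjects[f$train]),
                            unique(subjects[f$validation])), 0)
  }
  expect_error(cv_plan(y, grouping = "subject"), "subject ids")
})

test_that("every registered classifier separates an easy synthetic task", {
  tab <- generate_feature_table(
    planted_table_config(n_per_class = 150, n_features = 10,
                         informative_idx = 1:5, effect_size = 4, seed = 6))
  plan <- cv_plan(tab$labels, n_folds = 5, seed = 6)
  for (id in classifier_registry()) {
    res <- run_cv(tab$x, tab$labels, id, plan)
    expect_gt(res$best_metrics[["ACC"]], 90)
  }
  expect_error(run_cv(tab$x, tab$labels, "kernel-ridge", plan),
               "unknown classifier")
})

test_that("null features stay near chance under cross-validation", {
  tab <- generate_feature_table(
    planted_table_config(n_per_class = 60, n_features = 10,
                         effect_size = 0, seed = 14))
  plan <- cv_plan(tab$labels, n_folds = 5, seed = 14)
  res <- run_cv(tab$x, tab$labels, "logistic", plan)
  correct <- sum(vapply(res$counts, function(ct) ct[["TP"]] + ct[["TN"]], 0))
  ci <- stats::binom.test(correct, 120, 0.5)$conf.int
  expect_true(ci[1] < 0.5 && 0.5 < ci[2] || correct / 120 <= 0.62)
})

test_that("the fused pipeline enforces widths and per-fold fitting", {
  n <- 24
  df <- withr::with_seed(5, matrix(stats::rnorm(n * 1024), n, 1024))
  hf <- withr::with_seed(6, matrix(stats::rnorm(n * 286), n, 286))
  colnames(hf) <- hf_feature_names()
  y <- factor(rep(c("CON", "SCZ"), each = n / 2))
  hf[y == "SCZ", 1:20] <- hf[y == "SCZ", 1:20] + 3
  plan <- cv_plan(y, n_folds = 3, seed = 5)
  res <- evaluate_pipeline(df, hf, y, plan, classifier = "svm-linear",
                           select_params = mayfly_params(
                             bounds = cbind(rep(0, 286), rep(1, 286)),
                             n_flies = 8, max_iter = 20, seed = 1))
  expect_equal(res$fused_width, 615)
  expect_length(res$counts, 3)
  for (f in seq_along(res$masks)) {
    expect_equal(res$masks[[f]]$fit_fold, f)
    expect_equal(sum(res$masks[[f]]$bits), 103)
  }
  expect_gt(res$best_metrics[["ACC"]], 80)
})
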