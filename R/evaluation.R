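# Serial feature fusion, binary classifiers, cross-validation and the
# confusion-matrix metric suite.  Positive class is SCZ throughout.

#' Serially fuse reduced deep features with selected handcrafted features
#'
#' Ordered concatenation DF-then-HF: 512 + 103 = 615 values.
#'
#' @param df reduced deep-feature vector (length 512) or matrix (512
#'   columns).
#' @param hf selected handcrafted vector (length 103) or matrix.
#' @return fused vector / matrix of width 615.
#' @export
fuse <- function(df, hf) {
  ncol_of <- function(x) if (is.matrix(x)) ncol(x) else length(x)
  if (ncol_of(df) != 512L) stop("deep block must have width 512")
  if (ncol_of(hf) != 103L) stop("handcrafted block must have width 103")
  if (is.matrix(df) || is.matrix(hf)) cbind(df, hf) else c(df, hf)
}

#' Confusion counts of a binary prediction
#' @param truth,pred factors/characters with values CON and SCZ.
#' @param positive the positive class (default SCZ).
#' @return named integer vector (TP, FN, TN, FP).
#' @export
confusion_counts <- function(truth, pred, positive = "SCZ") {
  truth <- as.character(truth); pred <- as.character(pred)
  c(TP = sum(truth == positive & pred == positive),
    FN = sum(truth == positive & pred != positive),
    TN = sum(truth != positive & pred != positive),
    FP = sum(truth != positive & pred == positive))
}

#' Confusion-matrix metric suite
#'
#' Accuracy, precision, sensitivity, specificity, negative predictive
#' value and F1 score, each as a percentage rounded half-up to `digits`
#' decimals (`digits = NULL` leaves them unrounded).  A zero denominator
#' yields `NaN` with a warning, never a silent 0.
#'
#' @param counts named vector with TP, FN, TN, FP.
#' @param digits decimal places of the reported percentages.
#' @return named numeric vector (ACC, PRE, SEN, SPE, NPV, FS).
#' @export
compute_metrics <- function(counts, digits = 4) {
  tp <- counts[["TP"]]; fn <- counts[["FN"]]
  tn <- counts[["TN"]]; fp <- counts[["FP"]]
  if (any(c(tp, fn, tn, fp) < 0)) stop("counts must be non-negative")
  total <- tp + fn + tn + fp
  if (total == 0) stop("all counts are zero")
  ratio <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined: zero denominator")
      return(NaN)
    }
    num / den
  }
  m <- c(ACC = ratio(tp + tn, total, "ACC"),
         PRE = ratio(tp, tp + fp, "PRE"),
         SEN = ratio(tp, tp + fn, "SEN"),
         SPE = ratio(tn, tn + fp, "SPE"),
         NPV = ratio(tn, tn + fn, "NPV"),
         FS  = ratio(2 * tp, 2 * tp + fn + fp, "FS")) * 100
  if (!is.null(digits)) m <- round_half_up(m, digits)
  m
}

#' Fold-level metrics table with a best-fold marker
#'
#' One row per fold: the four counts, the six metrics, and `best`
#' marking the highest-accuracy fold (ties broken by F1), the
#' best-trial reporting convention.
#'
#' @param counts_list list of confusion-count vectors (one per fold).
#' @param digits rounding of the percentage metrics.
#' @return data frame with `fold`, TP, FN, TN, FP, ACC..FS, `best`.
#' @export
metrics_table <- function(counts_list, digits = 4) {
  if (!length(counts_list)) stop("at least one fold required")
  rows <- lapply(seq_along(counts_list), function(i) {
    ct <- counts_list[[i]]
    data.frame(fold = i, TP = ct[["TP"]], FN = ct[["FN"]],
               TN = ct[["TN"]], FP = ct[["FP"]],
               t(compute_metrics(ct, digits)))
  })
  out <- do.call(rbind, rows)
  best <- order(-out$ACC, -out$FS, out$fold)[1]
  out$best <- seq_len(nrow(out)) == best
  out
}

#' Build a cross-validation plan
#'
#' Slice-level grouping stratifies folds by class; subject-level grouping
#' keeps all slices of one subject in a single fold (no subject spans
#' folds), which avoids the optimistic bias of letting a subject's slices
#' straddle train and validation.
#'
#' @param labels class factor (CON/SCZ), one entry per slice.
#' @param n_folds number of folds.
#' @param grouping `"slice"` or `"subject"`.
#' @param subjects subject identifier per slice (required for subject
#'   grouping).
#' @param seed integer seed for the fold shuffle.
#' @return a `cv_plan` with `folds` (per fold: `train`, `validation`
#'   index vectors).
#' @export
cv_plan <- function(labels, n_folds = 5L, grouping = c("slice", "subject"),
                    subjects = NULL, seed = 1L) {
  grouping <- match.arg(grouping)
  n <- length(labels)
  y <- as.factor(labels)
  fold_of <- integer(n)
  with_seed(seed, {
    if (grouping == "slice") {
      for (cl in levels(y)) {
        idx <- sample(which(y == cl))
        fold_of[idx] <- rep_len(seq_len(n_folds), length(idx))
      }
    } else {
      if (is.null(subjects)) stop("subject grouping requires subject ids")
      subj <- unique(subjects)
      subj_class <- vapply(subj, function(s)
        as.character(y[subjects == s][1]), "")
      sfold <- integer(length(subj))
      for (cl in unique(subj_class)) {
        si <- sample(which(subj_class == cl))
        sfold[si] <- rep_len(seq_len(n_folds), length(si))
      }
      fold_of <- sfold[match(subjects, subj)]
    }
  })
  folds <- lapply(seq_len(n_folds), function(f)
    list(train = which(fold_of != f), validation = which(fold_of == f)))
  structure(list(folds = folds, n_folds = as.integer(n_folds),
                 grouping = grouping, seed = as.integer(seed),
                 fold_of = fold_of),
            class = "cv_plan")
}

#' Names of the registered binary classifiers
#' @return character vector of classifier ids.
#' @export
classifier_registry <- function() {
  c("softmax", "dt-coarse", "dt-medium", "dt-fine", "logistic",
    "naive-bayes", "svm-linear", "boosted-trees",
    "knn-coarse", "knn-medium", "knn-fine")
}

# prune an rpart tree to at most `leaves` terminal nodes
prune_to_leaves <- function(fit, leaves) {
  cp <- fit$cptable
  ok <- which(cp[, "nsplit"] + 1 <= leaves)
  if (!length(ok)) return(fit)
  rpart::prune(fit, cp = cp[max(ok), "CP"] + 1e-12)
}

#' Fit a registered classifier on training data and predict validation
#'
#' Registry tiers: decision trees are pruned to at most 4 / 20 / 100
#' leaves (coarse / medium / fine); boosted trees are depth-3 gradient
#' boosting with 30 rounds; KNN uses k = 100 / 10 / 1 (Euclidean).
#' Zero-variance training columns are dropped before fitting.
#'
#' @param id a classifier id from [classifier_registry()].
#' @param xtr,ytr training matrix and class factor.
#' @param xva validation matrix.
#' @return factor of predicted classes for `xva`.
#' @export
fit_predict_classifier <- function(id, xtr, ytr, xva) {
  if (!id %in% classifier_registry()) stop("unknown classifier id: ", id)
  ytr <- droplevels(as.factor(ytr))
  if (nlevels(ytr) < 2) stop("training fold has a single class")
  keep <- apply(xtr, 2, stats::sd) > 1e-10
  if (!any(keep)) keep[1] <- TRUE
  xtr <- xtr[, keep, drop = FALSE]
  xva <- xva[, keep, drop = FALSE]
  lv <- levels(ytr)
  as_lv <- function(x) factor(x, levels = lv)

  if (id == "softmax") {
    d <- data.frame(xtr); d$.y <- ytr
    fit <- nnet::multinom(.y ~ ., d, trace = FALSE,
                          MaxNWts = 10000, maxit = 200)
    as_lv(predict(fit, data.frame(xva)))
  } else if (id == "logistic") {
    d <- data.frame(xtr); d$.y <- ytr
    fit <- suppressWarnings(stats::glm(.y ~ ., binomial(), d))
    p <- suppressWarnings(predict(fit, data.frame(xva), type = "response"))
    as_lv(lv[1 + (p > 0.5)])
  } else if (grepl("^dt-", id)) {
    leaves <- c(`dt-coarse` = 4, `dt-medium` = 20, `dt-fine` = 100)[[id]]
    d <- data.frame(xtr); d$.y <- ytr
    fit <- rpart::rpart(.y ~ ., d, method = "class",
                        control = rpart::rpart.control(
                          cp = 0, minsplit = 4, xval = 0))
    fit <- prune_to_leaves(fit, leaves)
    as_lv(predict(fit, data.frame(xva), type = "class"))
  } else if (id == "naive-bayes") {
    fit <- e1071::naiveBayes(xtr, ytr)
    as_lv(predict(fit, xva))
  } else if (id == "svm-linear") {
    fit <- e1071::svm(xtr, ytr, kernel = "linear", scale = FALSE)
    as_lv(predict(fit, xva))
  } else if (id == "boosted-trees") {
    dtr <- xgboost::xgb.DMatrix(xtr, label = as.numeric(ytr) - 1)
    fit <- xgboost::xgb.train(
      params = list(objective = "binary:logistic", max_depth = 3,
                    eta = 0.3, nthread = 1),
      data = dtr, nrounds = 30, verbose = 0)
    p <- predict(fit, xgboost::xgb.DMatrix(xva))
    as_lv(lv[1 + (p > 0.5)])
  } else {
    k <- c(`knn-coarse` = 100, `knn-medium` = 10, `knn-fine` = 1)[[id]]
    as_lv(class::knn(xtr, xva, ytr, k = min(k, nrow(xtr))))
  }
}

#' Cross-validated evaluation of a classifier on a feature matrix
#'
#' @param x feature matrix.
#' @param y class factor (CON/SCZ).
#' @param classifier id from [classifier_registry()].
#' @param plan a [cv_plan()].
#' @return list with per-fold `counts`, the metrics `table`
#'   ([metrics_table()]), `best_fold`, its `best_metrics`, and
#'   `mean_acc` across folds.
#' @export
run_cv <- function(x, y, classifier, plan) {
  y <- as.factor(y)
  counts <- lapply(seq_along(plan$folds), function(f) {
    fold <- plan$folds[[f]]
    if (length(unique(y[fold$train])) < 2 ||
        length(unique(y[fold$validation])) < 1) {
      stop("fold ", f, " lacks both classes")
    }
    pred <- with_seed(plan$seed + 7919L * f,
                      fit_predict_classifier(classifier,
                                             x[fold$train, , drop = FALSE],
                                             y[fold$train],
                                             x[fold$validation, , drop = FALSE]))
    confusion_counts(y[fold$validation], pred)
  })
  tab <- metrics_table(counts)
  best <- which(tab$best)
  list(counts = counts, table = tab, best_fold = best,
       best_metrics = compute_metrics(counts[[best]]),
       mean_acc = mean(tab$ACC))
}

assert_fit_fold <- function(transformer, fold) {
  if (!identical(transformer$fit_fold, fold)) {
    stop("leakage guard: transformer fit on fold '", transformer$fit_fold,
         "' applied to fold '", fold, "'")
  }
  invisible(TRUE)
}

#' Cross-validated evaluation of the fused DF+HF pipeline
#'
#' Per fold, every stage transformer is fit on the training rows only --
#' deep-feature rank reduction (1024 -> 512), handcrafted z-scoring and
#' mayfly selection (286 -> 103) -- then applied unchanged to the
#' validation rows; the two blocks are serially fused to width 615.
#' Each transformer records its fit fold and the harness asserts it
#' before use.
#'
#' @param df deep-feature matrix (n x 1024).
#' @param hf handcrafted matrix (n x 286).
#' @param y class factor CON/SCZ.
#' @param plan a [cv_plan()].
#' @param classifier id from [classifier_registry()].
#' @param select_params optional [mayfly_params()] for the selection
#'   wrapper.
#' @param k_df,k_hf reduced block widths.
#' @return as [run_cv()], plus `fused_width` and the per-fold `masks`.
#' @export
evaluate_pipeline <- function(df, hf, y, plan, classifier = "svm-linear",
                              select_params = NULL, k_df = 512L,
                              k_hf = 103L) {
  y <- as.factor(y)
  masks <- vector("list", length(plan$folds))
  counts <- vector("list", length(plan$folds))
  fused_width <- NA_integer_
  for (f in seq_along(plan$folds)) {
    fold <- plan$folds[[f]]
    tr <- fold$train; va <- fold$validation
    reducer <- rank_reduce_df(df[tr, , drop = FALSE], y[tr],
                              k = k_df, fit_fold = f)
    sel_par <- select_params
    if (!is.null(sel_par)) sel_par$seed <- sel_par$seed + f
    mask <- moa_select(hf[tr, , drop = FALSE], y[tr], k = k_hf,
                       params = sel_par, fit_fold = f)
    assert_fit_fold(reducer, f)
    assert_fit_fold(mask, f)
    zs <- function(m) sweep(sweep(m, 2, mask$objective$center), 2,
                            mask$objective$scale, "/")
    x_tr <- fuse(predict(reducer, df[tr, , drop = FALSE]),
                 predict(mask, zs(hf[tr, , drop = FALSE])))
    x_va <- fuse(predict(reducer, df[va, , drop = FALSE]),
                 predict(mask, zs(hf[va, , drop = FALSE])))
    fused_width <- ncol(x_tr)
    pred <- with_seed(plan$seed + 7919L * f,
                      fit_predict_classifier(classifier, x_tr, y[tr], x_va))
    counts[[f]] <- confusion_counts(y[va], pred)
    masks[[f]] <- mask
  }
  tab <- metrics_table(counts)
  best <- which(tab$best)
  list(counts = counts, table = tab, best_fold = best,
       best_metrics = compute_metrics(counts[[best]]),
       mean_acc = mean(tab$ACC),
       fused_width = fused_width, masks = masks)
}
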