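#' Gini impurity of a label multiset
#'
#' `1 - sum(p_class^2)`; 0 for a pure node, 0.5 for a balanced binary node.
#'
#' @param labels non-empty vector of class labels.
#' @return impurity in `[0, 1)`.
#' @export
gini_impurity <- function(labels) {
  stop_if_not(length(labels) > 0, "labels must be non-empty")
  p <- table(labels) / length(labels)
  1 - sum(p^2)
}

#' Assemble labelled panel features from log-CPM values
#'
#' For the diagnostic panel every sample of the cohort is used and positives
#' are the HA samples of severe-AMS subjects (their SL samples and all samples
#' of non-severe subjects are negative); the alternative `"subject"` rule
#' labels every sample of a severe subject positive. The predictive panel uses
#' SL samples only, labelled by the subject's eventual severity.
#'
#' @param log_cpm gene-by-sample log-CPM matrix for the cohort.
#' @param meta cohort sample metadata.
#' @param genes panel gene pool (typically a common biomarker set).
#' @param category `"diagnostic"` or `"predictive"`.
#' @param label_rule `"sample"` (default) or `"subject"`, see above; ignored
#'   for the predictive panel.
#' @return list with `x` (samples x genes), `y` (factor `neg`/`pos`) and
#'   `sample_id`.
#' @export
panel_features <- function(log_cpm, meta, genes,
                           category = c("diagnostic", "predictive"),
                           label_rule = c("sample", "subject")) {
  category <- match.arg(category)
  label_rule <- match.arg(label_rule)
  miss <- setdiff(genes, rownames(log_cpm))
  stop_if_not(length(miss) == 0,
              "panel genes absent from the expression matrix: ",
              paste(miss, collapse = ", "))
  meta <- meta[meta$sample_id %in% colnames(log_cpm), , drop = FALSE]
  if (category == "predictive") {
    meta <- meta[meta$timepoint == "SL", , drop = FALSE]
    pos <- meta$severe_ams
  } else if (label_rule == "subject") {
    pos <- meta$severe_ams
  } else {
    pos <- meta$severe_ams & meta$timepoint == "HA"
  }
  x <- t(log_cpm[genes, meta$sample_id, drop = FALSE])
  y <- factor(ifelse(pos, "pos", "neg"), levels = c("neg", "pos"))
  list(x = x, y = y, sample_id = meta$sample_id)
}

#' Rank genes by random-forest Gini importance
#'
#' Grows a classification forest (bootstrap sample per tree, sqrt(p) candidate
#' features per split, trees grown to purity) and ranks genes by mean total
#' decrease in Gini impurity. Ties are broken lexicographically by gene name
#' so the ranking is fully reproducible for a fixed seed.
#'
#' @param x samples-by-genes feature matrix.
#' @param y two-class factor of sample labels.
#' @param n_trees forest size (default 10000).
#' @param seed integer RNG seed.
#' @return `gene_ranking` data frame with `gene`, `importance`, `rank`.
#' @export
gini_rank <- function(x, y, n_trees = 10000, seed = 1L) {
  y <- droplevels(as.factor(y))
  stop_if_not(nlevels(y) == 2, "labels must contain both classes")
  stop_if_not(min(table(y)) >= 2, "need at least two samples per class")
  fit <- with_seed(seed,
                   randomForest::randomForest(x = x, y = y, ntree = n_trees))
  imp <- fit$importance[, "MeanDecreaseGini"]
  ord <- order(-imp, names(imp))
  out <- data.frame(gene = names(imp)[ord],
                    importance = unname(imp[ord]),
                    rank = seq_along(imp),
                    stringsAsFactors = FALSE)
  attr(out, "n_trees") <- n_trees
  attr(out, "seed") <- seed
  class(out) <- c("gene_ranking", "data.frame")
  out
}

#' Train a linear maximum-margin classifier on a gene panel
#'
#' Fits a linear support vector machine (L2-regularized hinge loss) on
#' training-standardized features with inverse-class-frequency weights, and
#' returns a scoring rule whose decision score increases with the positive
#' (AMS+) class.
#'
#' @param x samples-by-genes training matrix.
#' @param y two-class factor (`neg`/`pos`; the second level is positive).
#' @param panel character vector of panel genes (columns of `x`).
#' @param C regularization (SVM cost) parameter, default 1.
#' @return object of class `linear_scorer`; use [score_samples()] on new data.
#' @export
train_linear_classifier <- function(x, y, panel = colnames(x), C = 1) {
  y <- droplevels(as.factor(y))
  stop_if_not(nlevels(y) == 2, "training labels must contain both classes")
  x <- x[, panel, drop = FALSE]
  center <- colMeans(x)
  scale_ <- apply(x, 2, stats::sd)
  dead <- scale_ == 0
  if (any(dead)) {
    warning("dropping zero-variance feature(s): ",
            paste(panel[dead], collapse = ", "))
    stop_if_not(!all(dead), "all features have zero variance")
    x <- x[, !dead, drop = FALSE]
    panel <- panel[!dead]
    center <- center[!dead]
    scale_ <- scale_[!dead]
  }
  xs <- scale(x, center = center, scale = scale_)
  freq <- table(y)
  cw <- stats::setNames(as.numeric(sum(freq) / (2 * freq)), names(freq))
  fit <- e1071::svm(x = xs, y = y, kernel = "linear", cost = C,
                    class.weights = cw, scale = FALSE, tolerance = 1e-6)
  dv <- attr(stats::predict(fit, xs, decision.values = TRUE), "decision.values")
  pos_level <- levels(y)[2]
  flip <- !startsWith(colnames(dv), paste0(pos_level, "/"))
  structure(list(model = fit, panel = panel, center = center,
                 scale = scale_, flip = flip, positive = pos_level),
            class = "linear_scorer")
}

#' Decision scores of a trained linear classifier
#'
#' @param scorer a `linear_scorer` from [train_linear_classifier()].
#' @param x samples-by-genes matrix containing the panel columns.
#' @return numeric decision score per sample (higher = more positive-like).
#' @export
score_samples <- function(scorer, x) {
  stop_if_not(inherits(scorer, "linear_scorer"), "scorer must be a linear_scorer")
  xs <- scale(x[, scorer$panel, drop = FALSE],
              center = scorer$center, scale = scorer$scale)
  dv <- attr(stats::predict(scorer$model, xs, decision.values = TRUE),
             "decision.values")
  s <- as.numeric(dv)
  if (scorer$flip) s <- -s
  stats::setNames(s, rownames(x))
}

#' ROC curve and AUC of a real-valued score
#'
#' A sample is classified positive when its score is at least the threshold.
#' The AUC equals the Mann-Whitney pair statistic (ties count one half).
#'
#' @param scores numeric decision scores.
#' @param labels logical, or factor whose second level is positive.
#' @return `roc_curve` list: `thresholds`, `sensitivity`, `specificity`,
#'   `auc`, `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores, labels) {
  if (!is.logical(labels)) {
    labels <- droplevels(as.factor(labels))
    stop_if_not(nlevels(labels) == 2, "labels must have two classes")
    labels <- labels == levels(labels)[2]
  }
  stop_if_not(length(scores) == length(labels) && !anyNA(scores),
              "scores and labels must align and be complete")
  stop_if_not(any(labels) && any(!labels), "both classes must be present")
  n_pos <- sum(labels); n_neg <- sum(!labels)
  r <- rank(scores)
  auc <- (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  sens <- vapply(thr, function(t) mean(scores[labels] >= t), 0)
  spec <- vapply(thr, function(t) mean(scores[!labels] < t), 0)
  structure(list(thresholds = thr, sensitivity = sens, specificity = spec,
                 auc = auc, n_pos = n_pos, n_neg = n_neg),
            class = "roc_curve")
}

#' Youden-index operating point of a ROC curve
#'
#' Maximizes J = sensitivity + specificity - 1 over the curve's thresholds;
#' ties are broken toward higher sensitivity.
#'
#' @param roc a `roc_curve` from [roc_auc()].
#' @return list with `threshold`, `sensitivity`, `specificity`, `youden`.
#' @export
youden_threshold <- function(roc) {
  stop_if_not(inherits(roc, "roc_curve"), "roc must come from roc_auc()")
  j <- roc$sensitivity + roc$specificity - 1
  best <- which(j == max(j))
  best <- best[which.max(roc$sensitivity[best])]
  list(threshold = roc$thresholds[best],
       sensitivity = roc$sensitivity[best],
       specificity = roc$specificity[best],
       youden = j[best])
}

#' Forward panel-selection trajectory over a Gini ranking
#'
#' For each k = 1..`max_k`, trains a linear classifier on the top-k ranked
#' genes of the training cohort, scores the held-out test cohort, and records
#' the test AUC with its Youden operating point. The best panel attains the
#' maximum AUC, with ties resolved toward the smallest panel.
#'
#' @param ranking `gene_ranking` from [gini_rank()].
#' @param train,test lists with `x` and `y` as from [panel_features()]; the
#'   cohorts must be disjoint.
#' @param max_k largest panel size (default: all ranked genes).
#' @param C SVM cost parameter.
#' @return `panel_trajectory`: data frame of `k`, `genes`, `auc`,
#'   `threshold`, `sensitivity`, `specificity`; attributes `best_k`,
#'   `best_genes`, `rocs` (per-k `roc_curve`s).
#' @export
forward_trajectory <- function(ranking, train, test, max_k = nrow(ranking),
                               C = 1) {
  stop_if_not(inherits(ranking, "gene_ranking"), "ranking must come from gini_rank()")
  stop_if_not(max_k >= 1 && max_k <= nrow(ranking),
              "max_k must be between 1 and the pool size")
  stop_if_not(nlevels(droplevels(as.factor(test$y))) == 2,
              "test cohort must contain both classes")
  rows <- vector("list", max_k)
  rocs <- vector("list", max_k)
  for (k in seq_len(max_k)) {
    panel <- ranking$gene[seq_len(k)]
    scorer <- suppressWarnings(
      train_linear_classifier(train$x, train$y, panel = panel, C = C))
    sc <- score_samples(scorer, test$x)
    roc <- roc_auc(sc, test$y)
    yj <- youden_threshold(roc)
    rocs[[k]] <- roc
    rows[[k]] <- data.frame(k = k, genes = paste(panel, collapse = ","),
                            auc = roc$auc, threshold = yj$threshold,
                            sensitivity = yj$sensitivity,
                            specificity = yj$specificity,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  best_k <- which.max(out$auc)  # which.max takes the first (smallest k) tie
  attr(out, "best_k") <- best_k
  attr(out, "best_genes") <- ranking$gene[seq_len(best_k)]
  attr(out, "rocs") <- rocs
  class(out) <- c("panel_trajectory", "data.frame")
  out
}

#' Write a panel trajectory (and its ROC points) as TSV
#'
#' @param trajectory a `panel_trajectory`.
#' @param path output TSV; the best-k ROC points go to
#'   `<path>.roc.tsv` alongside.
#' @export
write_trajectory <- function(trajectory, path) {
  utils::write.table(as.data.frame(trajectory), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  roc <- attr(trajectory, "rocs")[[attr(trajectory, "best_k")]]
  utils::write.table(
    data.frame(threshold = roc$thresholds, sensitivity = roc$sensitivity,
               specificity = roc$specificity),
    paste0(path, ".roc.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
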