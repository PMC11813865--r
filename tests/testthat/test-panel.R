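gauss_features <- function(n_pos, n_neg, n_genes, informative = integer(0),
                           shift = 3, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm((n_pos + n_neg) * n_genes), n_pos + n_neg, n_genes,
              dimnames = list(paste0("s", seq_len(n_pos + n_neg)),
                              paste0("g", seq_len(n_genes))))
  x[seq_len(n_pos), informative] <- x[seq_len(n_pos), informative] + shift
  y <- factor(rep(c("pos", "neg"), c(n_pos, n_neg)), levels = c("neg", "pos"))
  list(x = x, y = y)
}

test_that("gini_impurity matches hand values", {
  expect_equal(gini_impurity(rep("a", 7)), 0)
  expect_equal(gini_impurity(c("a", "a", "b", "b")), 0.5)
  expect_equal(gini_impurity(c(1, 1, 1, 0)), 0.375)
  expect_error(gini_impurity(character(0)), "non-empty")
})

test_that("panel_features applies the sample and subject labeling rules", {
  st <- small_study()
  meta <- st$meta[st$meta$cohort == "A", ]
  pp <- quiet(preprocess_counts(st$counts$A))
  genes <- rownames(pp$log_cpm)[1:5]
  d <- panel_features(pp$log_cpm, meta, genes, "diagnostic")
  expect_equal(ncol(d$x), 5)
  expect_equal(nrow(d$x), nrow(meta))
  # sample rule: positives are exactly the HA samples of severe subjects
  pos_ids <- meta$sample_id[meta$severe_ams & meta$timepoint == "HA"]
  expect_setequal(d$sample_id[d$y == "pos"], pos_ids)
  # subject rule: both timepoints of severe subjects are positive
  ds <- panel_features(pp$log_cpm, meta, genes, "diagnostic",
                       label_rule = "subject")
  expect_equal(sum(ds$y == "pos"), 2 * length(pos_ids))
  # predictive: SL samples only, labeled by eventual severity
  pr <- panel_features(pp$log_cpm, meta, genes, "predictive")
  expect_true(all(endsWith(pr$sample_id, "_SL")))
  expect_equal(sum(pr$y == "pos"),
               length(unique(meta$subject_id[meta$severe_ams])))
  expect_error(panel_features(pp$log_cpm, meta, c(genes, "nope"), "diagnostic"),
               "absent")
})

test_that("gini_rank puts a perfect separator first and is reproducible", {
  hits <- 0
  for (seed in 1:15) {
    f <- gauss_features(15, 15, 11, informative = 4, shift = 4, seed = seed)
    rk <- gini_rank(f$x, f$y, n_trees = 1000, seed = seed)
    expect_s3_class(rk, "gene_ranking")
    expect_identical(rk$rank, seq_len(11L))
    expect_true(all(rk$importance >= 0))
    expect_true(all(diff(rk$importance) <= 0))
    hits <- hits + (rk$gene[1] == "g4")
  }
  expect_gte(hits, 14)
  # reproducibility for a fixed seed
  f <- gauss_features(15, 15, 11, informative = 4, seed = 1)
  expect_identical(gini_rank(f$x, f$y, n_trees = 500, seed = 9),
                   gini_rank(f$x, f$y, n_trees = 500, seed = 9))
  expect_error(gini_rank(f$x, factor(rep("pos", 30))), "both classes")
})

test_that("pure-noise features yield no stable top gene", {
  first <- character(0)
  for (seed in 1:20) {
    f <- gauss_features(10, 10, 8, informative = integer(0), seed = 100 + seed)
    rk <- gini_rank(f$x, f$y, n_trees = 300, seed = seed)
    first <- c(first, rk$gene[1])
  }
  expect_lte(max(table(first)), 12)  # no gene dominates rank 1
})

test_that("a duplicated informative gene occupies the top two ranks", {
  f <- gauss_features(15, 15, 10, informative = 3, shift = 4, seed = 2)
  f$x[, 7] <- f$x[, 3]
  rk <- gini_rank(f$x, f$y, n_trees = 2000, seed = 5)
  expect_setequal(rk$gene[1:2], c("g3", "g7"))
})

test_that("the linear classifier separates 1-D separable data", {
  x <- matrix(c(-3, -2.5, -2, 2, 2.5, 3), 6, 1,
              dimnames = list(paste0("s", 1:6), "g1"))
  y <- factor(c("neg", "neg", "neg", "pos", "pos", "pos"),
              levels = c("neg", "pos"))
  sc <- train_linear_classifier(x, y)
  s <- score_samples(sc, x)
  expect_true(all(s[y == "pos"] > 0))
  expect_true(all(s[y == "neg"] < 0))
  # flipped labels negate the decision scores (up to solver tolerance)
  yf <- factor(ifelse(y == "pos", "neg", "pos"), levels = c("neg", "pos"))
  sf <- score_samples(train_linear_classifier(x, yf), x)
  expect_equal(unname(sf), unname(-s), tolerance = 1e-4)
})

test_that("zero-variance panel features are dropped with a warning", {
  f <- gauss_features(8, 8, 3, informative = 1, seed = 3)
  f$x[, 2] <- 5
  expect_warning(sc <- train_linear_classifier(f$x, f$y), "zero-variance")
  expect_identical(sc$panel, c("g1", "g3"))
  expect_length(score_samples(sc, f$x), 16)
})

test_that("the SVM solution matches brute-force objective minimization", {
  x <- matrix(c(0, 1, 1, 2,
                0, -1, 1, 0), 4, 2,
              dimnames = list(paste0("s", 1:4), c("g1", "g2")))
  y <- factor(c("neg", "neg", "pos", "pos"), levels = c("neg", "pos"))
  C <- 1
  sc <- train_linear_classifier(x, y, C = C)
  s <- score_samples(sc, x)
  # recover (w, b) in the standardized feature space the SVM was fit in
  xs <- scale(x, center = sc$center, scale = sc$scale)
  coefs <- coef(lm(s ~ xs))
  w_fit <- coefs[-1]
  b_fit <- coefs[1]
  tlab <- ifelse(y == "pos", 1, -1)
  cw <- as.numeric(length(y) / (2 * table(y)[as.character(y)]))
  objective <- function(par) {
    w <- par[1:2]; b <- par[3]
    margins <- tlab * (xs %*% w + b)
    0.5 * sum(w^2) + C * sum(cw * pmax(0, 1 - margins))
  }
  best <- Inf
  for (i in 1:40) {
    set.seed(i)
    o <- optim(rnorm(3), objective, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-12))
    best <- min(best, o$value)
  }
  expect_equal(objective(c(w_fit, b_fit)), best, tolerance = 1e-3)
})

test_that("roc_auc matches hand values and the all-pairs oracle", {
  r <- roc_auc(c(1, 2, 10, 11), c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(r$auc, 1)
  expect_equal(roc_auc(rep(3, 6), rep(c(TRUE, FALSE), 3))$auc, 0.5)
  # 3 of 4 pairs concordant
  expect_equal(roc_auc(c(0.9, 0.2, 0.8, 0.1),
                       c(TRUE, TRUE, FALSE, FALSE))$auc, 0.75)
  expect_error(roc_auc(1:3, rep(TRUE, 3)), "both classes")
  set.seed(41)
  for (rep in 1:30) {
    n <- sample(4:25, 1)
    scores <- sample(round(rnorm(n), 1))  # coarse values force ties
    labels <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(labels) || all(labels)) next
    r <- roc_auc(scores, labels)
    expect_equal(r$auc, oracle_auc(scores, labels))
    # sensitivity non-increasing as the threshold rises
    expect_true(all(diff(r$sensitivity[order(r$thresholds)]) <= 0))
    # invariance under a strictly increasing transform
    expect_equal(roc_auc(exp(scores), labels)$auc, r$auc)
  }
})

test_that("roc_auc agrees with the reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(52)
  for (rep in 1:20) {
    scores <- rnorm(20)
    labels <- sample(c(TRUE, FALSE), 20, replace = TRUE)
    if (!any(labels) || all(labels)) next
    expect_equal(roc_auc(scores, labels)$auc,
                 as.numeric(pROC::auc(pROC::roc(labels, scores,
                                                quiet = TRUE,
                                                direction = "<"))))
  }
})

test_that("youden_threshold matches exhaustive search", {
  scores <- c(0.1, 0.4, 0.35, 0.8, 0.7, 0.2)
  labels <- c(FALSE, TRUE, FALSE, TRUE, TRUE, FALSE)
  r <- roc_auc(scores, labels)
  yj <- youden_threshold(r)
  ref <- oracle_youden(scores, labels)
  expect_equal(yj$threshold, ref$threshold)
  expect_equal(yj$sensitivity, ref$sensitivity)
  expect_equal(yj$specificity, ref$specificity)
  expect_equal(yj$youden, ref$youden)
  # perfect separation: J = 1 at full sensitivity and specificity
  perf <- youden_threshold(roc_auc(c(1, 2, 9, 10), c(FALSE, FALSE, TRUE, TRUE)))
  expect_equal(perf$youden, 1)
  expect_equal(perf$sensitivity, 1)
  expect_equal(perf$specificity, 1)
  # all ties: J = 0
  expect_equal(youden_threshold(roc_auc(rep(1, 4),
                                        c(TRUE, TRUE, FALSE, FALSE)))$youden, 0)
})

test_that("youden operating point is consistent with its confusion matrix", {
  set.seed(63)
  for (rep in 1:25) {
    scores <- round(rnorm(15), 1)
    labels <- sample(c(TRUE, FALSE), 15, replace = TRUE)
    if (!any(labels) || all(labels)) next
    yj <- youden_threshold(roc_auc(scores, labels))
    expect_equal(yj$sensitivity, mean(scores[labels] >= yj$threshold))
    expect_equal(yj$specificity, mean(scores[!labels] < yj$threshold))
    oracle <- oracle_youden(scores, labels)
    expect_equal(yj$youden, oracle$youden)
    expect_equal(yj$sensitivity, oracle$sensitivity)
  }
})

test_that("forward_trajectory finds a planted single informative gene", {
  tr <- gauss_features(12, 24, 10, informative = 5, shift = 4, seed = 31)
  te <- gauss_features(6, 12, 10, informative = 5, shift = 4, seed = 32)
  rk <- gini_rank(tr$x, tr$y, n_trees = 1000, seed = 1)
  traj <- forward_trajectory(rk, tr, te)
  expect_s3_class(traj, "panel_trajectory")
  expect_equal(nrow(traj), 10)          # max_k = pool size: one row per k
  expect_identical(traj$k, 1:10)
  expect_identical(rk$gene[1], "g5")
  expect_gte(traj$auc[1], 0.95)
  expect_true("g5" %in% attr(traj, "best_genes"))
  expect_gte(max(traj$auc), 0.95)
  bk <- attr(traj, "best_k")
  expect_equal(traj$auc[bk], max(traj$auc))
  expect_equal(bk, which.max(traj$auc))  # smallest k on ties
})

test_that("all-noise pools give chance-level test AUC", {
  aucs <- numeric(0)
  for (seed in 1:8) {
    tr <- gauss_features(8, 16, 6, seed = 200 + seed)
    te <- gauss_features(5, 10, 6, seed = 300 + seed)
    rk <- gini_rank(tr$x, tr$y, n_trees = 300, seed = seed)
    traj <- quiet(forward_trajectory(rk, tr, te))
    aucs <- c(aucs, traj$auc)
  }
  expect_gt(mean(aucs), 0.35)
  expect_lt(mean(aucs), 0.65)
})

test_that("trajectories serialize together with the best ROC curve", {
  tr <- gauss_features(10, 20, 5, informative = 2, shift = 3, seed = 77)
  te <- gauss_features(5, 10, 5, informative = 2, shift = 3, seed = 78)
  rk <- gini_rank(tr$x, tr$y, n_trees = 500, seed = 1)
  traj <- forward_trajectory(rk, tr, te, max_k = 3)
  expect_equal(nrow(traj), 3)
  f <- tempfile(fileext = ".tsv")
  write_trajectory(traj, f)
  back <- read.delim(f)
  expect_equal(back$auc, traj$auc)
  roc_back <- read.delim(paste0(f, ".roc.tsv"))
  roc <- attr(traj, "rocs")[[attr(traj, "best_k")]]
  expect_equal(nrow(roc_back), length(roc$thresholds))
  expect_error(forward_trajectory(rk, tr, te, max_k = 99), "pool size")
})
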