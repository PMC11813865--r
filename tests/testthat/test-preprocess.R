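make_counts <- function(values, n_genes, n_samples) {
  matrix(values, n_genes, n_samples,
         dimnames = list(paste0("g", seq_len(n_genes)),
                         paste0("s", seq_len(n_samples))))
}

test_that("filter_samples removes samples above the strict low-count limit", {
  m <- make_counts(50, 10, 3)
  m[1:3, 1] <- 0      # 30% low: removed
  m[1:2, 2] <- 0      # exactly 20% low: retained (strict 'more than')
  out <- quiet(filter_samples(m))
  expect_identical(colnames(out), c("s2", "s3"))
  expect_identical(rownames(out), rownames(m))
  rem <- attr(out, "removed_samples")
  expect_identical(rem$sample_id, "s1")
  expect_equal(rem$low_fraction, 0.3)
  # all counts >= 10: retained
  expect_identical(colnames(quiet(filter_samples(make_counts(10, 5, 2)))),
                   c("s1", "s2"))
})

test_that("filter_samples is idempotent and errors when nothing survives", {
  m <- make_counts(rpois(40, 60), 10, 4)
  m[1:3, 2] <- 1
  once <- quiet(filter_samples(m))
  twice <- quiet(filter_samples(once))
  expect_equal(once, twice, ignore_attr = TRUE)
  expect_identical(dimnames(once), dimnames(twice))
  expect_equal(nrow(attr(twice, "removed_samples")), 0)
  low <- make_counts(1, 10, 3)
  expect_error(filter_samples(low), "all samples")
})

test_that("mask_low_counts masks strictly below the threshold", {
  m <- make_counts(c(9, 10, 0, 25), 2, 2)
  out <- mask_low_counts(m)
  expect_true(is.na(out["g1", "s1"]))
  expect_equal(out["g2", "s1"], 10)
  expect_true(is.na(out["g1", "s2"]))
  expect_equal(out["g2", "s2"], 25)
  expect_identical(attr(out, "all_missing_genes"), "g1")
  # no entry below threshold: identity
  hi <- make_counts(100, 4, 3)
  expect_equal(unclass(mask_low_counts(hi)), unclass(hi),
               ignore_attr = TRUE)
})

test_that("knn_impute fills a constant neighborhood with that value", {
  m <- make_counts(40, 5, 6)
  m[2, 1] <- NA
  out <- knn_impute(m, k = 5)
  expect_equal(out[2, 1], 40)
  expect_false(anyNA(out))
})

test_that("knn_impute copies from an exact duplicate sample at k = 1", {
  set.seed(5)
  base <- make_counts(rpois(20, 80), 10, 2)
  base[, 2] <- base[, 1]
  m <- cbind(base, s3 = rpois(10, 400))
  m[4, 2] <- NA
  out <- knn_impute(m, k = 1)
  expect_equal(out[4, 2], base[4, 1])
})

test_that("knn_impute matches a hand-computed 4-sample oracle at k = 2", {
  m <- make_counts(c(20, 30, 40, 100,
                     22, 31, 42, 104,
                     80, 90, 70, 250,
                     NA, 33, 41, 102), 4, 4)
  # distances from s4 on log2(x+1) over co-observed genes (g2..g4)
  lg <- log2(m + 1)
  d <- sapply(1:3, function(j) mean((lg[2:4, 4] - lg[2:4, j])^2))
  nb <- order(d)[1:2]
  expected <- mean(m[1, nb])
  out <- knn_impute(m, k = 2)
  expect_equal(out[1, 4], expected)
  expect_identical(nb, c(2L, 1L))  # fixture really exercises a nontrivial order
})

test_that("knn_impute preserves observed entries and bounds imputed ones", {
  set.seed(8)
  for (rep in 1:5) {
    m <- random_counts(40, 8)
    mask <- matrix(runif(length(m)) < 0.08, nrow(m))
    mask[, 1] <- FALSE  # keep every gene observed somewhere
    m[mask] <- NA
    out <- quiet(knn_impute(m, k = 3))
    expect_identical(out[!is.na(m)], m[!is.na(m)])
    for (g in seq_len(nrow(m))) {
      miss <- is.na(m[g, ])
      if (!any(miss)) next
      obs <- m[g, !miss]
      expect_true(all(out[g, miss] >= min(obs) - 1e-12 &
                        out[g, miss] <= max(obs) + 1e-12))
    }
  }
})

test_that("knn_impute drops fully-missing genes and validates k", {
  m <- make_counts(50, 4, 3)
  m[2, ] <- NA
  expect_warning(out <- knn_impute(m, k = 2), "no observed value")
  expect_identical(rownames(out), c("g1", "g3", "g4"))
  expect_error(knn_impute(make_counts(5, 3, 3), k = 3), "k <")
  # samples sharing no observed genes is an error
  bad <- make_counts(c(10, NA, NA, 10), 2, 2)
  expect_error(knn_impute(bad, k = 1), "share no observed genes")
})

test_that("tmm_factors handles the trivial scaling cases", {
  m <- make_counts(c(10, 60, 200, 35, 500, 12), 6, 1)
  two <- cbind(m, s2 = m[, 1])
  colnames(two) <- c("s1", "s2")
  f <- tmm_factors(two)
  expect_equal(f$norm_factor, c(1, 1))
  # entrywise 3x scaling: pure library-size difference, factors stay 1
  three <- cbind(two[, 1, drop = FALSE], s2 = 3 * two[, 1])
  f3 <- tmm_factors(three)
  expect_equal(f3$norm_factor, c(1, 1))
  expect_equal(f3$eff_lib_size, f3$lib_size * f3$norm_factor)
  expect_equal(exp(mean(log(f3$norm_factor))), 1)
})

test_that("tmm_factors matches the brute-force trimming oracle", {
  set.seed(31)
  for (rep in 1:10) {
    m <- random_counts(sample(30:120, 1), sample(3:6, 1))
    expect_equal(tmm_factors(m)$norm_factor, oracle_tmm(m), tolerance = 1e-10)
  }
})

test_that("tmm_factors agrees with the reference implementation", {
  skip_if_not_installed("edgeR")
  set.seed(77)
  for (rep in 1:10) {
    m <- random_counts(sample(80:300, 1), sample(3:8, 1))
    expect_equal(tmm_factors(m)$norm_factor,
                 unname(edgeR::calcNormFactors(m, method = "TMM")),
                 tolerance = 1e-8)
  }
})

test_that("tmm_factors is stable under relabeling and sample scaling", {
  set.seed(13)
  m <- random_counts(100, 4)
  f <- tmm_factors(m)
  # permuting samples permutes the factors (deterministic reference rule)
  perm <- c(3, 1, 4, 2)
  fp <- tmm_factors(m[, perm])
  expect_equal(fp$norm_factor, f$norm_factor[perm], tolerance = 1e-12)
  expect_identical(fp$sample_id, f$sample_id[perm])
  # multiplying one sample by a constant only moves its library size; the
  # factors change only through the precision weights (near-invariance)
  m2 <- m
  m2[, 2] <- m2[, 2] * 5
  f2 <- tmm_factors(m2)
  expect_equal(f2$norm_factor, f$norm_factor, tolerance = 0.02)
})

test_that("log_cpm computes the documented transform and its invariances", {
  m <- make_counts(c(0, 10, 100, 5, 50, 500), 3, 2)
  f <- tmm_factors(m)
  lc <- log_cpm(m, f, prior_count = 0.5)
  expect_equal(lc[1, 1], log2(0.5 / (f$eff_lib_size[1] + 1) * 1e6))
  expect_equal(lc[3, 2], log2(500.5 / (f$eff_lib_size[2] + 1) * 1e6))
  # strictly increasing in the count
  expect_true(all(diff(lc[, 1]) > 0))
  # doubling counts and effective library sizes leaves values fixed
  f2 <- f
  f2$eff_lib_size <- 2 * f$eff_lib_size
  expect_equal(log_cpm(2 * m, f2, prior_count = 0), log_cpm(m, f, prior_count = 0))
})

test_that("pca_outlier_check flags a shifted sample and nothing else", {
  set.seed(21)
  lg <- matrix(rnorm(100 * 12, 6), 100, 12,
               dimnames = list(paste0("g", 1:100), paste0("s", 1:12)))
  rep1 <- pca_outlier_check(lg)
  expect_length(rep1$flagged, 0)
  lg[1:50, 1] <- lg[1:50, 1] + log2(10)
  rep2 <- pca_outlier_check(lg)
  expect_identical(rep2$flagged, "s1")
  expect_equal(sum(rep2$var_explained), 1)
  expect_error(pca_outlier_check(lg[, 1:2]), "three samples")
})

test_that("preprocess_counts composes the stages end to end", {
  st <- small_study()
  pp <- quiet(preprocess_counts(st$counts$A))
  expect_false(anyNA(pp$counts))
  expect_true(all(pp$counts == round(pp$counts)))
  expect_identical(colnames(pp$counts), pp$factors$sample_id)
  expect_equal(dim(pp$log_cpm), dim(pp$counts))
  expect_true(all(pp$dropped_genes %in% rownames(st$counts$A)))
  expect_equal(nrow(pp$counts) + length(pp$dropped_genes), nrow(st$counts$A))
})
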