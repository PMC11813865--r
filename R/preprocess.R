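#' Remove samples with an excessive fraction of low counts
#'
#' A sample is discarded when the fraction of its genes with raw count below
#' `low_threshold` strictly exceeds `max_low_fraction` ("more than 20% low read
#' counts"). The gene set is never changed.
#'
#' @param counts raw integer gene-by-sample count matrix.
#' @param low_threshold counts strictly below this are "low" (default 10).
#' @param max_low_fraction maximum tolerated low-count fraction (default 0.2,
#'   strict inequality).
#' @return the retained columns of `counts`; the attribute `"removed_samples"`
#'   holds a data frame of dropped samples and their low-count fractions.
#' @export
filter_samples <- function(counts, low_threshold = 10, max_low_fraction = 0.2) {
  check_count_matrix(counts)
  frac_low <- colMeans(counts < low_threshold)
  drop <- frac_low > max_low_fraction
  if (all(drop)) {
    stop("all samples exceed the low-count fraction limit: ",
         paste(sprintf("%s=%.3f", colnames(counts), frac_low), collapse = ", "),
         call. = FALSE)
  }
  if (any(drop)) {
    message("filter_samples: removed ", sum(drop), " sample(s): ",
            paste(sprintf("%s (%.1f%% low)", colnames(counts)[drop],
                          100 * frac_low[drop]), collapse = ", "))
  }
  out <- counts[, !drop, drop = FALSE]
  attr(out, "removed_samples") <- data.frame(
    sample_id = colnames(counts)[drop],
    low_fraction = unname(frac_low[drop]),
    stringsAsFactors = FALSE
  )
  out
}

#' Mask low counts as missing values
#'
#' Entries strictly below `low_threshold` become `NA`, to be restored by
#' [knn_impute()]. Genes left with no observed value are flagged in the
#' `"all_missing_genes"` attribute (and dropped during imputation).
#'
#' @inheritParams filter_samples
#' @return the matrix with low entries set to `NA`.
#' @export
mask_low_counts <- function(counts, low_threshold = 10) {
  check_count_matrix(counts)
  out <- counts
  out[out < low_threshold] <- NA_real_
  attr(out, "all_missing_genes") <- rownames(out)[rowSums(!is.na(out)) == 0]
  out
}

# Pairwise sample distances on log2(count + 1), restricted to mutually
# observed genes, scaled by the number of shared genes (mean squared
# difference) so attrition-shortened overlaps stay comparable.
sample_log_distances <- function(masked) {
  lg <- log2(masked + 1)
  n <- ncol(lg)
  d <- matrix(0, n, n, dimnames = list(colnames(lg), colnames(lg)))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      shared <- !is.na(lg[, i]) & !is.na(lg[, j])
      if (!any(shared)) {
        stop("samples ", colnames(lg)[i], " and ", colnames(lg)[j],
             " share no observed genes", call. = FALSE)
      }
      d[i, j] <- d[j, i] <- mean((lg[shared, i] - lg[shared, j])^2)
    }
  }
  d
}

#' K-nearest-neighbour imputation of masked counts
#'
#' Each missing entry is replaced by the average of the same gene's values in
#' the `k` nearest samples among those where the gene is observed. Sample
#' distance is the mean squared difference of log2(count + 1) over mutually
#' observed genes. Genes observed in no sample are dropped with a warning.
#'
#' @param masked count matrix with `NA` entries, as from [mask_low_counts()].
#' @param k number of neighbours (default 5); must be below the sample count.
#' @return a complete (real-valued) count matrix.
#' @export
knn_impute <- function(masked, k = 5) {
  check_count_matrix(masked, allow_na = TRUE)
  n <- ncol(masked)
  stop_if_not(k >= 1 && k < n, "need 1 <= k < number of samples")
  all_missing <- rowSums(!is.na(masked)) == 0
  if (any(all_missing)) {
    warning("dropping ", sum(all_missing), " gene(s) with no observed value: ",
            paste(utils::head(rownames(masked)[all_missing], 5), collapse = ", "),
            if (sum(all_missing) > 5) ", ...")
    masked <- masked[!all_missing, , drop = FALSE]
  }
  if (!anyNA(masked)) return(masked)
  d <- sample_log_distances(masked)
  # neighbour order per sample, nearest first, self excluded
  nb_order <- apply(d, 2, order)
  out <- masked
  for (g in which(rowSums(is.na(masked)) > 0)) {
    row <- masked[g, ]
    obs <- !is.na(row)
    for (s in which(!obs)) {
      nb <- nb_order[, s]
      nb <- nb[nb != s & obs[nb]]
      use <- nb[seq_len(min(k, length(nb)))]
      out[g, s] <- mean(row[use])
    }
  }
  out
}

.tmm_pair <- function(obs, ref, n_obs, n_ref, trim_M, trim_A) {
  pos <- obs > 0 & ref > 0
  if (!any(pos)) stop("sample shares no nonzero genes with the reference", call. = FALSE)
  obs <- obs[pos]; ref <- ref[pos]
  logR <- log2((obs / n_obs) / (ref / n_ref))
  absE <- (log2(obs / n_obs) + log2(ref / n_ref)) / 2
  # binomial delta-method precision weights
  v <- (n_obs - obs) / (n_obs * obs) + (n_ref - ref) / (n_ref * ref)
  fin <- is.finite(logR) & is.finite(absE)
  logR <- logR[fin]; absE <- absE[fin]; v <- v[fin]
  if (length(logR) == 0 || max(abs(logR)) < 1e-6) return(1)
  n <- length(logR)
  loM <- floor(n * trim_M) + 1; hiM <- n + 1 - loM
  loA <- floor(n * trim_A) + 1; hiA <- n + 1 - loA
  keep <- rank(logR) >= loM & rank(logR) <= hiM &
    rank(absE) >= loA & rank(absE) <= hiA
  if (!any(keep)) return(1)
  v <- pmax(v, 1e-12)
  2^(sum(logR[keep] / v[keep]) / sum(1 / v[keep]))
}

#' Trimmed-mean-of-M-values normalization factors
#'
#' For each sample, the scaling factor is the precision-weighted mean of
#' gene-wise log2 expression ratios (M-values) against a reference sample,
#' after symmetrically trimming the most extreme `trim_M` fraction by M and
#' `trim_A` fraction by average log expression (A). Genes with a zero count in
#' either sample are excluded. The reference is the sample whose
#' 75th-percentile count fraction is closest to the mean of those fractions.
#' Factors are rescaled to have geometric mean 1.
#'
#' @param counts complete nonnegative matrix with at least two samples.
#' @param trim_M,trim_A two-sided trim fractions on M and A (defaults 0.30
#'   and 0.05).
#' @return data frame with columns `sample_id`, `lib_size`, `norm_factor`,
#'   `eff_lib_size`; the reference sample is stored in the `"ref_sample"`
#'   attribute.
#' @export
tmm_factors <- function(counts, trim_M = 0.30, trim_A = 0.05) {
  check_count_matrix(counts)
  stop_if_not(ncol(counts) >= 2, "TMM needs at least two samples")
  lib <- colSums(counts)
  stop_if_not(all(lib > 0), "every sample needs a positive library size")
  f75 <- apply(counts, 2, stats::quantile, probs = 0.75) / lib
  ref <- which.min(abs(f75 - mean(f75)))
  f <- vapply(seq_len(ncol(counts)), function(j) {
    if (j == ref) return(1)
    .tmm_pair(counts[, j], counts[, ref], lib[j], lib[ref], trim_M, trim_A)
  }, 0)
  f <- f / exp(mean(log(f)))
  out <- data.frame(sample_id = colnames(counts),
                    lib_size = unname(lib),
                    norm_factor = unname(f),
                    eff_lib_size = unname(lib * f),
                    stringsAsFactors = FALSE)
  attr(out, "ref_sample") <- colnames(counts)[ref]
  out
}

#' Log2 counts per million with a prior count
#'
#' `log2((count + prior) / (effective library size + 2 * prior) * 1e6)`, using
#' TMM effective library sizes. Strictly increasing in the count for a fixed
#' sample, and invariant to jointly scaling a sample's counts and library size.
#'
#' @param counts complete count matrix.
#' @param factors normalization table from [tmm_factors()].
#' @param prior_count prior added to each count (default 0.5).
#' @return matrix of log2-CPM values, same dimnames as `counts`.
#' @export
log_cpm <- function(counts, factors, prior_count = 0.5) {
  check_count_matrix(counts)
  stop_if_not(identical(colnames(counts), factors$sample_id),
              "factors must match the count matrix columns")
  eff <- factors$eff_lib_size
  stop_if_not(all(eff > 0), "effective library sizes must be positive")
  sweep_den <- matrix(eff + 2 * prior_count, nrow(counts), ncol(counts), byrow = TRUE)
  log2((counts + prior_count) / sweep_den * 1e6)
}

#' Principal-component outlier and batch check
#'
#' Projects samples onto the first two principal components of the
#' log-expression matrix and flags samples lying beyond `sd_limit` standard
#' deviations on PC1 or PC2. Report only; nothing is removed.
#'
#' @param log_expr complete gene-by-sample log-expression matrix (>= 3 samples).
#' @param sd_limit flagging limit in SD units (default 3).
#' @return list with `scores` (samples x PC1/PC2), `flagged` (sample ids) and
#'   `var_explained` (fraction per component).
#' @export
pca_outlier_check <- function(log_expr, sd_limit = 3) {
  stop_if_not(is.matrix(log_expr) && !anyNA(log_expr), "need a complete matrix")
  stop_if_not(ncol(log_expr) >= 3, "PCA check needs at least three samples")
  pc <- stats::prcomp(t(log_expr), center = TRUE, scale. = FALSE)
  scores <- pc$x[, seq_len(min(2, ncol(pc$x))), drop = FALSE]
  sds <- apply(scores, 2, stats::sd)
  flagged <- apply(abs(scores) > rep(sd_limit * sds, each = nrow(scores)), 1, any)
  list(scores = scores,
       flagged = rownames(scores)[flagged],
       var_explained = pc$sdev^2 / sum(pc$sdev^2))
}

#' One-call preprocessing of a raw cohort count matrix
#'
#' Runs [filter_samples()], [mask_low_counts()], [knn_impute()] and
#' [tmm_factors()] in order, rounding imputed values to integers for the
#' downstream negative-binomial fits.
#'
#' @inheritParams filter_samples
#' @param k neighbours for imputation.
#' @return list with `counts` (complete, integer-valued), `factors`,
#'   `log_cpm`, and `dropped_genes` (genes lost to full masking).
#' @export
preprocess_counts <- function(counts, low_threshold = 10, max_low_fraction = 0.2,
                              k = 5) {
  filt <- filter_samples(counts, low_threshold, max_low_fraction)
  masked <- mask_low_counts(filt, low_threshold)
  imputed <- suppressWarnings(knn_impute(masked, k = k))
  imputed <- round(imputed)
  factors <- tmm_factors(imputed)
  list(counts = imputed,
       factors = factors,
       log_cpm = log_cpm(imputed, factors),
       dropped_genes = setdiff(rownames(filt), rownames(imputed)))
}
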