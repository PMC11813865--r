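#' Build a design matrix for a two-group negative-binomial contrast
#'
#' The contrast coefficient is always the last column. Unpaired designs adjust
#' for sex; paired (within-subject) designs use subject blocking instead, which
#' absorbs sex. Covariates that are constant over the included samples are
#' dropped with a message; a genuinely confounded design (covariate aliased
#' with the group after dropping constants) is an error.
#'
#' @param group factor (or coercible) with exactly two levels; the reported
#'   effect is level 2 relative to level 1.
#' @param sex optional sex covariate for unpaired designs.
#' @param subject optional subject identifier enabling a paired design.
#' @return list with `X` (full-rank design matrix), `coef` (index of the
#'   contrast column) and `dropped` (names of dropped covariates).
#' @export
build_design <- function(group, sex = NULL, subject = NULL) {
  group <- droplevels(as.factor(group))
  stop_if_not(nlevels(group) == 2, "group must have exactly two levels")
  dropped <- character(0)
  if (!is.null(subject)) {
    subject <- droplevels(as.factor(subject))
    df <- data.frame(subject = subject, group = group)
    X <- stats::model.matrix(~ subject + group, df)
  } else if (!is.null(sex)) {
    sex <- droplevels(as.factor(sex))
    if (nlevels(sex) < 2) {
      dropped <- "sex"
      message("build_design: dropping constant covariate 'sex'")
      X <- stats::model.matrix(~group, data.frame(group = group))
    } else {
      X <- stats::model.matrix(~ sex + group, data.frame(sex = sex, group = group))
    }
  } else {
    X <- stats::model.matrix(~group, data.frame(group = group))
  }
  if (qr(X)$rank < ncol(X)) {
    stop("design is rank-deficient (covariate confounded with the group)",
         call. = FALSE)
  }
  list(X = X, coef = ncol(X), dropped = dropped)
}

offset_from_factors <- function(factors, sample_ids) {
  if (is.numeric(factors)) {
    stop_if_not(length(factors) == length(sample_ids), "offset length mismatch")
    return(factors)
  }
  i <- match(sample_ids, factors$sample_id)
  stop_if_not(!anyNA(i), "normalization factors missing for some samples")
  log(factors$eff_lib_size[i])
}

# IRLS fit of a log-link NB GLM for every gene (shared design), computed in
# compiled code. y: G x n, X: n x p, offset: length n, phi: scalar or length
# G (phi = 0 is the Poisson limit). Returns per-gene coefficients, fitted
# means, log-likelihood, Cox-Reid log-determinant of the weighted
# information, and a convergence flag.
nb_fit_all <- function(y, X, offset, phi, tol = 1e-8, maxit = 50L) {
  G <- nrow(y); n <- ncol(y)
  stop_if_not(n == nrow(X), "count columns must match design rows")
  if (length(phi) == 1) phi <- rep(phi, G)
  stop_if_not(length(phi) == G, "phi must be scalar or one value per gene")
  .nb_irls_cpp(y, X, as.numeric(offset), as.numeric(phi),
               as.numeric(tol), as.integer(maxit))
}

# Quadratic interpolation of the maximizer over a log-phi grid.
grid_argmax <- function(log_phi, values) {
  i <- which.max(values)
  if (i == 1 || i == length(values)) return(exp(log_phi[i]))
  x <- log_phi[(i - 1):(i + 1)]
  v <- values[(i - 1):(i + 1)]
  den <- (v[1] - 2 * v[2] + v[3])
  if (!is.finite(den) || den >= 0) return(exp(x[2]))
  exp(x[2] - 0.5 * (x[3] - x[1]) / 2 * (v[3] - v[1]) / den)
}

#' Estimate common, gene-wise and shrunk negative-binomial dispersions
#'
#' Dispersions are profiled on a log-spaced grid using the Cox-Reid adjusted
#' profile likelihood (APL): the gene's GLM log-likelihood minus half the
#' log-determinant of the weighted information. The common dispersion
#' maximizes the summed APL; gene-wise values maximize each gene's APL; shrunk
#' values maximize the gene APL plus the mean APL across genes weighted by
#' `prior_df / residual df`, pulling small-sample estimates toward the common
#' value. Larger `prior_df` means stronger shrinkage; at `prior_df = Inf` every
#' gene collapses to the common dispersion.
#'
#' @param counts integer gene-by-sample matrix (all-zero genes are excluded
#'   with a warning).
#' @param design list from [build_design()].
#' @param offsets normalization table from [tmm_factors()] or a numeric offset
#'   vector (log effective library sizes).
#' @param prior_df prior degrees of freedom for shrinkage (default 10).
#' @param grid_length number of grid points over dispersions 1e-4..10.
#' @return object of class `dispersion_estimates`: `common`, named vectors
#'   `genewise` and `shrunk`, and `prior_df`.
#' @export
estimate_dispersions <- function(counts, design, offsets, prior_df = 10,
                                 grid_length = 15L) {
  check_count_matrix(counts)
  stop_if_not(prior_df > 0, "prior_df must be positive")
  X <- design$X
  keep <- rowSums(counts) > 0
  if (!all(keep)) {
    warning("excluding ", sum(!keep), " all-zero gene(s) from dispersion estimation")
    counts <- counts[keep, , drop = FALSE]
  }
  off <- offset_from_factors(offsets, colnames(counts))
  G <- nrow(counts)
  df_resid <- max(ncol(counts) - ncol(X), 1)
  log_grid <- seq(log(1e-4), log(10), length.out = grid_length)
  apl <- matrix(NA_real_, G, grid_length)
  for (k in seq_along(log_grid)) {
    # looser IRLS settings: the APL surface is smooth in phi and does not
    # need the final-fit precision
    fit <- nb_fit_all(counts, X, off, exp(log_grid[k]), tol = 1e-6, maxit = 25L)
    apl[, k] <- fit$loglik - 0.5 * fit$logdet
  }
  apl_mean <- colMeans(apl)
  common <- grid_argmax(log_grid, apl_mean)
  genewise <- vapply(seq_len(G), function(g) grid_argmax(log_grid, apl[g, ]), 0)
  wt <- prior_df / df_resid
  shrunk <- vapply(seq_len(G), function(g)
    grid_argmax(log_grid, apl[g, ] + wt * apl_mean), 0)
  # shrinkage is toward the common value: keep each estimate inside the
  # interval spanned by its own and the common maximizer
  shrunk <- pmin(pmax(shrunk, pmin(genewise, common)), pmax(genewise, common))
  structure(list(common = common,
                 genewise = stats::setNames(genewise, rownames(counts)),
                 shrunk = stats::setNames(shrunk, rownames(counts)),
                 prior_df = prior_df),
            class = "dispersion_estimates")
}

#' @export
print.dispersion_estimates <- function(x, ...) {
  cat("Dispersion estimates:", length(x$genewise), "genes\n")
  cat(sprintf("  common phi: %.4f  (prior_df = %g)\n", x$common, x$prior_df))
  cat(sprintf("  shrunk phi range: [%.4f, %.4f]\n",
              min(x$shrunk), max(x$shrunk)))
  invisible(x)
}

#' Fit the per-gene contrast and test it by likelihood ratio
#'
#' Per gene, a log-link negative-binomial GLM is fitted by iteratively
#' reweighted least squares with the log effective library size as offset,
#' using the shrunk dispersions. The contrast p-value comes from the
#' likelihood-ratio test of the last design column (chi-squared, 1 df); the
#' log2 fold change is the contrast coefficient divided by ln 2, clamped at
#' |log2FC| <= 30 for degenerate (separated) genes. Genes with zero counts in
#' more than `max_zero_fraction` of samples are excluded from testing;
#' non-convergent genes are flagged and assigned p = 1.
#'
#' @inheritParams estimate_dispersions
#' @param dispersions result of [estimate_dispersions()], or a single numeric
#'   dispersion used for every gene.
#' @param max_zero_fraction exclusion threshold for mostly-zero genes
#'   (default 0.9).
#' @return a `de_result` data frame with columns `gene`, `log2fc`, `pvalue`,
#'   `fdr`, `direction`, `converged`; excluded genes are listed in the
#'   `"excluded_genes"` attribute.
#' @export
fit_contrast <- function(counts, design, dispersions, offsets,
                         max_zero_fraction = 0.9) {
  check_count_matrix(counts)
  X <- design$X
  coef <- design$coef
  testable <- rowMeans(counts == 0) <= max_zero_fraction
  excluded <- rownames(counts)[!testable]
  if (length(excluded)) {
    message("fit_contrast: excluding ", length(excluded),
            " gene(s) with >", round(100 * max_zero_fraction),
            "% zero counts from testing")
    counts <- counts[testable, , drop = FALSE]
  }
  stop_if_not(nrow(counts) > 0, "no testable genes")
  off <- offset_from_factors(offsets, colnames(counts))
  phi <- if (inherits(dispersions, "dispersion_estimates")) {
    ph <- dispersions$shrunk[rownames(counts)]
    ph[is.na(ph)] <- dispersions$common
    unname(ph)
  } else {
    stop_if_not(is.numeric(dispersions) && length(dispersions) == 1,
                "dispersions must be a dispersion_estimates object or a scalar")
    dispersions
  }
  full <- nb_fit_all(counts, X, off, phi)
  red <- nb_fit_all(counts, X[, -coef, drop = FALSE], off, phi)
  lrt <- pmax(2 * (full$loglik - red$loglik), 0)
  pval <- stats::pchisq(lrt, df = 1, lower.tail = FALSE)
  log2fc <- full$beta[, coef] / log(2)
  clamped <- abs(log2fc) > 30
  log2fc <- pmin(pmax(log2fc, -30), 30)
  conv <- full$converged & red$converged
  pval[!conv] <- 1
  pval <- pmin(pmax(pval, .Machine$double.xmin), 1)
  out <- data.frame(gene = rownames(counts),
                    log2fc = log2fc,
                    pvalue = pval,
                    fdr = bh_adjust(pval),
                    direction = ifelse(log2fc >= 0, "up", "down"),
                    converged = conv,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "excluded_genes") <- excluded
  attr(out, "clamped_genes") <- out$gene[clamped]
  class(out) <- c("de_result", "data.frame")
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p_values numeric vector of p-values in (0, 1].
#' @return vector of BH-adjusted values (FDR), capped at 1.
#' @export
bh_adjust <- function(p_values) {
  stop_if_not(length(p_values) > 0, "empty p-value vector")
  stop_if_not(is.numeric(p_values) && !anyNA(p_values) &&
                all(p_values > 0 & p_values <= 1),
              "p-values must lie in (0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Call differentially expressed genes
#'
#' Strict thresholds on both statistics: `pvalue < p_max` and
#' `|log2fc| > lfc_min`.
#'
#' @param result a `de_result` from [fit_contrast()] (any data frame with
#'   `gene`, `log2fc`, `pvalue` columns works).
#' @param p_max p-value cutoff (default 0.05, strict).
#' @param lfc_min absolute log2-fold-change cutoff (default 0.7, strict).
#' @return subset of `result`, with attributes `n_up` and `n_down`.
#' @export
call_degs <- function(result, p_max = 0.05, lfc_min = 0.7) {
  stop_if_not(all(c("gene", "log2fc", "pvalue") %in% names(result)),
              "result must have gene, log2fc and pvalue columns")
  hit <- result$pvalue < p_max & abs(result$log2fc) > lfc_min
  out <- result[hit, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_up") <- sum(out$log2fc > 0)
  attr(out, "n_down") <- sum(out$log2fc < 0)
  out
}

#' Write a differential-expression result table
#'
#' TSV with columns `gene`, `log2FC`, `PV`, `FDR`, `direction`.
#'
#' @param result a `de_result`.
#' @param path output file.
#' @export
write_de_result <- function(result, path) {
  df <- data.frame(gene = result$gene, log2FC = result$log2fc,
                   PV = result$pvalue, FDR = result$fdr,
                   direction = result$direction)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
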