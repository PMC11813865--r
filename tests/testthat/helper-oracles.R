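# Independent brute-force oracles and small fixture builders used across the
# test files. Each oracle re-derives the quantity from its definition, sharing
# no code with the package implementation.

quiet <- function(expr) suppressMessages(suppressWarnings(expr))

# Random small count matrix for property tests.
random_counts <- function(n_genes, n_samples, mu_log_sd = 1.5) {
  m <- matrix(stats::rnbinom(n_genes * n_samples,
                             mu = exp(stats::rnorm(n_genes, 4, mu_log_sd)),
                             size = 5),
              n_genes, n_samples,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              sprintf("s%02d", seq_len(n_samples))))
  storage.mode(m) <- "double"
  m
}

# Benjamini-Hochberg step-up, written out literally: sort ascending, multiply
# by n / rank, enforce monotonicity from the largest p downward, cap at 1.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  for (i in rev(seq_len(n - 1))) {
    adj[i] <- min(adj[i], adj[i + 1])
  }
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# AUC by counting all positive/negative score pairs.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + (p > q) + 0.5 * (p == q)
    }
  }
  total / (length(pos) * length(neg))
}

# Youden operating point by exhaustive search over every distinct threshold
# (plus +Inf), classifying positive when score >= threshold; ties in J broken
# toward higher sensitivity.
oracle_youden <- function(scores, labels) {
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  best <- NULL
  for (t in thr) {
    sens <- sum(scores >= t & labels) / sum(labels)
    spec <- sum(scores < t & !labels) / sum(!labels)
    j <- sens + spec - 1
    if (is.null(best) || j > best$youden + 1e-15 ||
        (abs(j - best$youden) <= 1e-15 && sens > best$sensitivity)) {
      best <- list(threshold = t, sensitivity = sens, specificity = spec,
                   youden = j)
    }
  }
  best
}

# TMM factors by direct enumeration: pick the reference from the 75th
# percentile rule, then for each sample list every gene's M, A and weight,
# mark the genes surviving the double trim explicitly, and average.
oracle_tmm <- function(counts, trim_M = 0.30, trim_A = 0.05) {
  lib <- colSums(counts)
  f75 <- vapply(seq_len(ncol(counts)),
                function(j) stats::quantile(counts[, j], 0.75) / lib[j], 0)
  ref <- which.min(abs(f75 - mean(f75)))
  one <- function(j) {
    if (j == ref) return(1)
    o <- counts[, j]; r <- counts[, ref]
    keep0 <- o > 0 & r > 0
    o <- o[keep0]; r <- r[keep0]
    # same arithmetic formulation as the contract so exact count ties stay
    # exact ties in M (a different but algebraically equal expression breaks
    # them at the 1e-15 level and flips rank-boundary membership)
    M <- log2((o / lib[j]) / (r / lib[ref]))
    A <- (log2(o / lib[j]) + log2(r / lib[ref])) / 2
    w <- (lib[j] - o) / (lib[j] * o) + (lib[ref] - r) / (lib[ref] * r)
    fin <- is.finite(M) & is.finite(A)
    M <- M[fin]; A <- A[fin]; w <- w[fin]
    if (length(M) == 0 || max(abs(M)) < 1e-6) return(1)
    n <- length(M)
    kept <- logical(n)
    for (g in seq_len(n)) {
      rM <- rank(M)[g]; rA <- rank(A)[g]
      kept[g] <- rM >= floor(n * trim_M) + 1 & rM <= n - floor(n * trim_M) &
        rA >= floor(n * trim_A) + 1 & rA <= n - floor(n * trim_A)
    }
    if (!any(kept)) return(1)
    w <- pmax(w, 1e-12)
    2^(sum(M[kept] / w[kept]) / sum(1 / w[kept]))
  }
  f <- vapply(seq_len(ncol(counts)), one, 0)
  f / exp(mean(log(f)))
}

# Shared small two-cohort synthetic study (cached once per test run).
small_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(
        n_genes = 300,
        cohorts = list(cohort_spec("A", 12, 4, 0.25),
                       cohort_spec("B", 8, 4, 0.25,
                                   attrition = list(list(subject = 5,
                                                         timepoint = "HA")))),
        signal_sets = list(diagnostic = list(n = 10, lfc = 3),
                           predictive = list(n = 10, lfc = 1.2)),
        seed = 42L)
      cache <<- generate_study(cfg)
    }
    cache
  }
})
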