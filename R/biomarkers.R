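BIOMARKER_CATEGORIES <- c("diagnostic", "predictive", "pathogenic", "protective")

#' Sample grouping for the four AMS biomarker contrasts
#'
#' The taxonomy compares the four sample groups (AMS+/AMS- at SL/HA):
#' \describe{
#'   \item{diagnostic}{AMS+ vs AMS- among HA samples (unpaired, sex-adjusted);}
#'   \item{predictive}{AMS+ vs AMS- among SL samples (unpaired, sex-adjusted);}
#'   \item{pathogenic}{SL vs HA within AMS+ subjects (paired);}
#'   \item{protective}{SL vs HA within AMS- subjects (paired).}
#' }
#' The reported effect is the second group relative to the first (AMS+
#' relative to AMS-, or HA relative to SL).
#'
#' @param meta sample metadata (see [generate_study()]).
#' @param category one of `"diagnostic"`, `"predictive"`, `"pathogenic"`,
#'   `"protective"`.
#' @return list with `sample_id`, `group` (two-level factor), `paired`,
#'   `sex` and `subject` vectors for the included samples.
#' @export
contrast_groups <- function(meta, category) {
  category <- match.arg(category, BIOMARKER_CATEGORIES)
  if (category %in% c("diagnostic", "predictive")) {
    tp <- if (category == "diagnostic") "HA" else "SL"
    m <- meta[meta$timepoint == tp, , drop = FALSE]
    if (!any(m$severe_ams) || !any(!m$severe_ams)) {
      stop(category, " contrast needs both AMS+ and AMS- samples at ", tp,
           call. = FALSE)
    }
    group <- factor(ifelse(m$severe_ams, "AMSpos", "AMSneg"),
                    levels = c("AMSneg", "AMSpos"))
    list(sample_id = m$sample_id, group = group, paired = FALSE,
         sex = m$sex, subject = NULL, category = category)
  } else {
    want_severe <- category == "pathogenic"
    m <- meta[meta$severe_ams == want_severe, , drop = FALSE]
    complete <- names(which(table(m$subject_id) == 2))
    if (length(complete) < 2) {
      stop(category, " contrast needs >= 2 subjects with both timepoints",
           call. = FALSE)
    }
    m <- m[m$subject_id %in% complete, , drop = FALSE]
    group <- factor(m$timepoint, levels = c("SL", "HA"))
    list(sample_id = m$sample_id, group = group, paired = TRUE,
         sex = m$sex, subject = m$subject_id, category = category)
  }
}

#' Run one biomarker contrast on a cohort
#'
#' Subsets the cohort to the category's sample groups, builds the matching
#' design (sex-adjusted for unpaired contrasts, subject-blocked for paired
#' ones), estimates shrunk dispersions and fits the likelihood-ratio test.
#'
#' @param counts complete (preprocessed) gene-by-sample count matrix for one
#'   cohort.
#' @param meta sample metadata for the cohort.
#' @param category contrast category, see [contrast_groups()].
#' @param factors cohort-wide normalization table from [tmm_factors()];
#'   computed from `counts` when omitted.
#' @param prior_df dispersion-shrinkage prior degrees of freedom.
#' @param max_zero_fraction see [fit_contrast()].
#' @return a `de_result` with `"category"` and `"cohort"` attributes.
#' @export
run_contrast <- function(counts, meta, category, factors = NULL,
                         prior_df = 10, max_zero_fraction = 0.9) {
  meta <- meta[meta$sample_id %in% colnames(counts), , drop = FALSE]
  grp <- contrast_groups(meta, category)
  if (is.null(factors)) factors <- tmm_factors(counts)
  sub <- counts[, grp$sample_id, drop = FALSE]
  design <- if (grp$paired) {
    build_design(grp$group, subject = grp$subject)
  } else {
    build_design(grp$group, sex = grp$sex)
  }
  off <- offset_from_factors(factors, colnames(sub))
  disp <- suppressWarnings(
    estimate_dispersions(sub, design, off, prior_df = prior_df))
  res <- fit_contrast(sub, design, disp, off,
                      max_zero_fraction = max_zero_fraction)
  attr(res, "category") <- grp$category
  attr(res, "cohort") <- paste(unique(meta$cohort), collapse = "+")
  res
}

#' Same-direction cross-cohort replication filter
#'
#' A gene is a common biomarker when it passes the DEG thresholds
#' (`pvalue < p_max`, `|log2fc| > lfc_min`, both strict) in both cohorts'
#' results for the same contrast, with the same fold-change sign. Gene
#' universes are intersected first (logged via the `"universe"` attribute).
#'
#' @param a,b `de_result` tables (or any data frames with `gene`, `log2fc`,
#'   `pvalue`, `fdr` columns) from the two cohorts.
#' @param p_max,lfc_min DEG thresholds, as in [call_degs()].
#' @return a `biomarker_set` data frame with per-cohort statistics and the
#'   shared `direction`; attributes `n_up`, `n_down`, `category`.
#' @export
common_degs <- function(a, b, p_max = 0.05, lfc_min = 0.7) {
  universe <- intersect(a$gene, b$gene)
  da <- call_degs(a[a$gene %in% universe, , drop = FALSE], p_max, lfc_min)
  db <- call_degs(b[b$gene %in% universe, , drop = FALSE], p_max, lfc_min)
  shared <- intersect(da$gene, db$gene)
  ia <- da[match(shared, da$gene), ]
  ib <- db[match(shared, db$gene), ]
  same <- sign(ia$log2fc) == sign(ib$log2fc)
  ia <- ia[same, ]; ib <- ib[same, ]
  fdr_a <- if ("fdr" %in% names(ia)) ia$fdr else NA_real_
  fdr_b <- if ("fdr" %in% names(ib)) ib$fdr else NA_real_
  out <- data.frame(gene = ia$gene,
                    log2fc_a = ia$log2fc, pvalue_a = ia$pvalue, fdr_a = fdr_a,
                    log2fc_b = ib$log2fc, pvalue_b = ib$pvalue, fdr_b = fdr_b,
                    direction = ifelse(ia$log2fc > 0, "up", "down"),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "universe") <- length(universe)
  attr(out, "n_up") <- sum(out$direction == "up")
  attr(out, "n_down") <- sum(out$direction == "down")
  attr(out, "category") <- attr(a, "category")
  attr(out, "cohorts") <- c(attr(a, "cohort"), attr(b, "cohort"))
  class(out) <- c("biomarker_set", "data.frame")
  out
}

#' Up/down counts of a biomarker set
#'
#' @param set a `biomarker_set` from [common_degs()].
#' @return named integer vector `c(n_up, n_down)`; the two always sum to the
#'   set size.
#' @export
direction_counts <- function(set) {
  stop_if_not(!is.null(set$direction), "set must have a direction column")
  c(n_up = sum(set$direction == "up"), n_down = sum(set$direction == "down"))
}

#' Cross-category membership of biomarker genes
#'
#' Tabulates which genes appear in which biomarker categories; genes shared by
#' two or more categories (e.g. both predictive and diagnostic) are flagged as
#' converged.
#'
#' @param sets named list of at least two `biomarker_set` objects (names are
#'   the categories).
#' @return data frame with one logical column per category, `n_categories`,
#'   and `converged` (membership in >= 2 categories).
#' @export
converged_genes <- function(sets) {
  stop_if_not(length(sets) >= 2, "need at least two biomarker sets")
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    names(sets) <- vapply(sets, function(s)
      attr(s, "category") %||% "set", "")
  }
  genes <- sort(unique(unlist(lapply(sets, `[[`, "gene"))))
  out <- data.frame(gene = genes, stringsAsFactors = FALSE)
  for (nm in names(sets)) out[[nm]] <- genes %in% sets[[nm]]$gene
  out$n_categories <- rowSums(as.matrix(out[, names(sets), drop = FALSE]))
  out$converged <- out$n_categories >= 2
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-cohort severe-AMS incidence
#'
#' Subject-level counts of severe AMS per cohort, with the percentage rounded
#' to the nearest integer.
#'
#' @param meta sample metadata covering one or more cohorts.
#' @return data frame with columns `cohort`, `n_severe`, `n_total`, `percent`.
#' @export
incidence_summary <- function(meta) {
  subj <- unique(meta[, c("cohort", "subject_id", "severe_ams")])
  if (anyDuplicated(subj[, c("cohort", "subject_id")])) {
    bad <- subj$subject_id[duplicated(subj[, c("cohort", "subject_id")])]
    stop("conflicting severity flags for subject(s): ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  }
  agg <- stats::aggregate(severe_ams ~ cohort, subj, function(x)
    c(n_severe = sum(x), n_total = length(x)))
  out <- data.frame(cohort = agg$cohort,
                    n_severe = agg$severe_ams[, "n_severe"],
                    n_total = agg$severe_ams[, "n_total"])
  out$percent <- round(100 * out$n_severe / out$n_total)
  out
}

#' Published candidate-biomarker statistics
#'
#' Per-cohort p-values and log2 fold changes for the diagnostic (AMS+ vs AMS-
#' at HA) and predictive (AMS+ vs AMS- at SL) candidate gene lists reported
#' for the two-cohort AMS study the package targets (discovery: Pikes Peak;
#' validation: Chamber). Useful as a worked example for the replication
#' filter and as the gene pool for panel selection demos.
#'
#' @param category `"diagnostic"` or `"predictive"`.
#' @return list of two data frames (`pikespeak`, `chamber`), each with
#'   `gene`, `log2fc`, `pvalue`, `fdr` and a `"category"` attribute, ready for
#'   [common_degs()].
#' @export
published_candidates <- function(category = c("diagnostic", "predictive")) {
  category <- match.arg(category)
  path <- system.file("extdata", paste0(category, "_candidates.tsv"),
                      package = "amsbiomarkers", mustWork = TRUE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  mk <- function(suffix, cohort) {
    out <- data.frame(gene = df$gene,
                      log2fc = df[[paste0("log2fc_", suffix)]],
                      pvalue = df[[paste0("pv_", suffix)]],
                      fdr = df[[paste0("fdr_", suffix)]],
                      stringsAsFactors = FALSE)
    attr(out, "category") <- category
    attr(out, "cohort") <- cohort
    out
  }
  list(pikespeak = mk("pikespeak", "PikesPeak"),
       chamber = mk("chamber", "Chamber"))
}

#' Write a biomarker set as TSV
#'
#' Layout mirrors a two-cohort results table: gene, then PV/FDR/log2FC per
#' cohort, then the shared direction.
#'
#' @param set a `biomarker_set`.
#' @param path output file.
#' @export
write_biomarker_set <- function(set, path) {
  utils::write.table(set, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
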