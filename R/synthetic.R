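#' Severe-AMS call from the AMS cerebral factor score
#'
#' The cerebral factor score (AMS-C) of the shortened Environmental Symptoms
#' Questionnaire defines severe acute mountain sickness at a fixed cutoff:
#' a subject with AMS-C >= 1.4 is labelled severe (AMS+).
#'
#' @param ams_c numeric vector of nonnegative AMS-C scores.
#' @return logical vector, `TRUE` where the score meets the severe threshold.
#' @examples
#' ams_severity(c(0, 1.3999, 1.4, 2.2))
#' @export
ams_severity <- function(ams_c) {
  stop_if_not(is.numeric(ams_c) && !anyNA(ams_c), "ams_c must be numeric without NA")
  stop_if_not(all(ams_c >= 0), "AMS-C scores must be nonnegative")
  ams_c >= 1.4
}

#' Specify one cohort of a simulated two-timepoint AMS study
#'
#' @param name cohort identifier.
#' @param n_subjects number of subjects, each nominally sampled at sea level
#'   (SL) and after ascent to high altitude (HA).
#' @param n_severe number of subjects with severe AMS (AMS-C >= 1.4).
#' @param sex_ratio fraction of women in the cohort.
#' @param attrition list of `list(subject = i, timepoint = "SL"|"HA")` entries
#'   naming samples that were never collected (dropouts, QC failures).
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(name, n_subjects, n_severe, sex_ratio = 0.3,
                        attrition = list()) {
  stop_if_not(is.character(name) && length(name) == 1 && nzchar(name),
              "cohort name must be a non-empty string")
  stop_if_not(n_subjects >= 1 && n_severe >= 0 && n_severe <= n_subjects,
              "need 0 <= n_severe <= n_subjects")
  stop_if_not(sex_ratio >= 0 && sex_ratio <= 1, "sex_ratio must be in [0, 1]")
  for (a in attrition) {
    stop_if_not(is.list(a) && all(c("subject", "timepoint") %in% names(a)) &&
                  a$subject >= 1 && a$subject <= n_subjects &&
                  a$timepoint %in% c("SL", "HA"),
                "attrition entries must be list(subject = <1..n_subjects>, timepoint = 'SL'|'HA')")
  }
  structure(list(name = name, n_subjects = n_subjects, n_severe = n_severe,
                 sex_ratio = sex_ratio, attrition = attrition),
            class = "cohort_spec")
}

default_cohorts <- function() {
  list(
    # 18 subjects, 5 severe, 5 women, fully paired: 36 samples.
    cohort_spec("PikesPeak", n_subjects = 18, n_severe = 5, sex_ratio = 5 / 18),
    # 10 subjects, 5 severe, 2 women; dropouts leave 9 SL + 7 HA samples and
    # four severe HA samples among the 16 retained.
    cohort_spec("Chamber", n_subjects = 10, n_severe = 5, sex_ratio = 2 / 10,
                attrition = list(list(subject = 5, timepoint = "HA"),
                                 list(subject = 6, timepoint = "HA"),
                                 list(subject = 7, timepoint = "HA"),
                                 list(subject = 8, timepoint = "SL")))
  )
}

#' Default planted signal sets
#'
#' 20 genes per category; diagnostic effects are hemoglobin-like (|log2FC| 3),
#' predictive effects smaller (1.2), pathogenic 1.5, protective 1.0, each half
#' up / half down. Useful as a starting point for modified configurations.
#'
#' @return named list `category -> list(n, lfc, prop_up)`.
#' @export
default_signal_sets <- function() {
  list(
    diagnostic = list(n = 20, lfc = 3.0, prop_up = 0.5),
    predictive = list(n = 20, lfc = 1.2, prop_up = 0.5),
    pathogenic = list(n = 20, lfc = 1.5, prop_up = 0.5),
    protective = list(n = 20, lfc = 1.0, prop_up = 0.5)
  )
}

#' Configure the synthetic two-cohort study generator
#'
#' Defines a negative-binomial gene-by-sample count generator that emulates a
#' paired SL/HA blood transcriptome study run in two independent cohorts, with
#' four categories of planted differential signal:
#' \describe{
#'   \item{diagnostic}{shifted only in (severe, HA) samples — separates AMS+
#'     from AMS- at altitude, hemoglobin-like high fold changes by default;}
#'   \item{predictive}{shifted in severe subjects at both timepoints — already
#'     detectable at sea level;}
#'   \item{pathogenic}{shifted from SL to HA in severe subjects only;}
#'   \item{protective}{shifted from SL to HA in every subject (a pure altitude
#'     response).}
#' }
#'
#' @param n_genes number of genes.
#' @param cohorts list of [cohort_spec()] objects; the default reproduces the
#'   study design the package targets (an 18-subject fully paired discovery
#'   cohort and a 10-subject validation cohort with attrition).
#' @param baseline_log_mean_mu,baseline_log_mean_sd natural-log mean and SD of
#'   the log-normal distribution of baseline gene abundance.
#' @param dispersion negative-binomial dispersion `phi` (variance
#'   `mu + phi * mu^2`), applied globally, or the mean of gene-wise dispersions
#'   when `dispersion_genewise = TRUE`.
#' @param dispersion_genewise draw gene-wise `phi_g` from an inverse-gamma
#'   distribution with mean `dispersion` instead of a single global value.
#' @param libsize_log_sd SD of per-sample log library-size factors.
#' @param sex_effect_lfc log2 fold change applied to women on the designated
#'   sex-responsive gene subset.
#' @param sex_gene_fraction fraction of genes carrying the sex effect.
#' @param signal_sets named list `category -> list(n, lfc, prop_up)`; gene sets
#'   are disjoint and `lfc` is the planted |log2 fold change|.
#' @param signal_min_base_mean minimum baseline mean count for planted signal
#'   genes (default 100). Planted biomarkers emulate well-quantified
#'   transcripts (hemoglobins, HLA genes); a signal planted below the
#'   low-count masking floor would be erased by the preprocessing rules by
#'   construction, so baselines of signal genes are drawn from the abundance
#'   distribution truncated at this floor.
#' @param low_count_fraction fraction of genes forced into the low-count
#'   (< 10 reads) regime so masking/imputation is exercised.
#' @param seed integer seed; generation is fully reproducible given the config.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000,
                       cohorts = default_cohorts(),
                       baseline_log_mean_mu = 4.5,
                       baseline_log_mean_sd = 1.3,
                       dispersion = 0.1,
                       dispersion_genewise = FALSE,
                       libsize_log_sd = 0.2,
                       sex_effect_lfc = 1.0,
                       sex_gene_fraction = 0.05,
                       signal_sets = default_signal_sets(),
                       signal_min_base_mean = 100,
                       low_count_fraction = 0.05,
                       seed = 1L) {
  stop_if_not(n_genes >= 1, "n_genes must be positive")
  stop_if_not(length(cohorts) >= 1 && all(vapply(cohorts, inherits, TRUE, "cohort_spec")),
              "cohorts must be a list of cohort_spec objects")
  stop_if_not(baseline_log_mean_sd >= 0 && dispersion > 0 && libsize_log_sd >= 0,
              "scale parameters must be positive")
  stop_if_not(low_count_fraction >= 0 && low_count_fraction < 1,
              "low_count_fraction must be in [0, 1)")
  for (nm in names(signal_sets)) {
    s <- signal_sets[[nm]]
    stop_if_not(all(c("n", "lfc") %in% names(s)) && s$n >= 0 && s$lfc >= 0,
                "signal set '", nm, "' needs nonnegative n and lfc")
    if (is.null(s$prop_up)) signal_sets[[nm]]$prop_up <- 0.5
  }
  n_signal <- sum(vapply(signal_sets, function(s) s$n, 0))
  stop_if_not(n_signal <= n_genes, "signal sets exceed n_genes")
  stop_if_not(n_signal + ceiling(sex_gene_fraction * n_genes) +
                ceiling(low_count_fraction * n_genes) <= n_genes,
              "signal, sex and low-count gene sets exceed n_genes")
  structure(list(n_genes = n_genes, cohorts = cohorts,
                 baseline_log_mean_mu = baseline_log_mean_mu,
                 baseline_log_mean_sd = baseline_log_mean_sd,
                 dispersion = dispersion,
                 dispersion_genewise = dispersion_genewise,
                 libsize_log_sd = libsize_log_sd,
                 sex_effect_lfc = sex_effect_lfc,
                 sex_gene_fraction = sex_gene_fraction,
                 signal_sets = signal_sets,
                 signal_min_base_mean = signal_min_base_mean,
                 low_count_fraction = low_count_fraction,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Deterministic, severity-balanced placement of n_pick items over n slots.
spread_indices <- function(n, n_pick) {
  if (n_pick <= 0) return(integer(0))
  unique(round(seq(1, n, length.out = n_pick)))
}

build_cohort_meta <- function(spec) {
  n <- spec$n_subjects
  subject <- sprintf("%s_s%02d", spec$name, seq_len(n))
  severe <- seq_len(n) <= spec$n_severe
  sex <- rep("M", n)
  sex[spread_indices(n, round(spec$sex_ratio * n))] <- "W"
  ams_c <- numeric(n)
  ams_c[severe] <- 1.4 + abs(stats::rnorm(sum(severe), 0.4, 0.3))
  ams_c[!severe] <- stats::runif(sum(!severe), 0, 1.3)
  meta <- data.frame(
    sample_id = c(paste0(subject, "_SL"), paste0(subject, "_HA")),
    cohort = spec$name,
    subject_id = rep(subject, 2),
    timepoint = rep(c("SL", "HA"), each = n),
    sex = rep(sex, 2),
    ams_c = rep(ams_c, 2),
    severe_ams = rep(severe, 2),
    stringsAsFactors = FALSE
  )
  drop <- vapply(spec$attrition, function(a)
    paste0(subject[a$subject], "_", a$timepoint), "")
  meta <- meta[!meta$sample_id %in% drop, , drop = FALSE]
  rownames(meta) <- NULL
  meta
}

#' Generate a synthetic two-cohort AMS RNA-seq study
#'
#' Draws integer counts from a negative binomial with per-sample library-size
#' factors, an optional sex effect, and the planted category effects described
#' in [sim_config()]. AMS-C scores are drawn so that severe subjects exceed the
#' 1.4 cutoff; attrition samples are never emitted. Two calls with the same
#' config produce identical output.
#'
#' @param config a [sim_config()] object.
#' @return list with elements
#'   \item{counts}{named list of integer gene-by-sample matrices, one per cohort;}
#'   \item{meta}{combined sample metadata data frame;}
#'   \item{truth}{data frame of planted genes: `gene`, `category`, signed `lfc`.}
#' @export
generate_study <- function(config) {
  stop_if_not(inherits(config, "sim_config"), "config must come from sim_config()")
  with_seed(config$seed, {
    G <- config$n_genes
    genes <- sprintf("g%04d", seq_len(G))

    # Disjoint gene-role assignment: planted signal first, then sex-responsive,
    # then forced-low genes, all from distinct index blocks.
    idx <- seq_len(G)
    truth <- data.frame(gene = character(0), category = character(0),
                        lfc = numeric(0), stringsAsFactors = FALSE)
    signal_lfc <- list()
    pos <- 0L
    for (cat in names(config$signal_sets)) {
      s <- config$signal_sets[[cat]]
      if (s$n == 0) next
      gi <- idx[pos + seq_len(s$n)]
      pos <- pos + s$n
      n_up <- round(s$prop_up * s$n)
      sign <- rep(c(1, -1), c(n_up, s$n - n_up))
      signal_lfc[[cat]] <- stats::setNames(sign * s$lfc, genes[gi])
      truth <- rbind(truth, data.frame(gene = genes[gi], category = cat,
                                       lfc = sign * s$lfc,
                                       stringsAsFactors = FALSE))
    }
    n_sex <- ceiling(config$sex_gene_fraction * G)
    sex_genes <- idx[pos + seq_len(n_sex)]
    pos <- pos + n_sex
    n_low <- ceiling(config$low_count_fraction * G)
    low_genes <- if (n_low > 0) idx[pos + seq_len(n_low)] else integer(0)

    base_log_mean <- stats::rnorm(G, config$baseline_log_mean_mu,
                                  config$baseline_log_mean_sd)
    signal_idx <- match(truth$gene, genes)
    if (length(signal_idx) > 0 && config$signal_min_base_mean > 0) {
      # signal-gene baselines: same log-normal, left-truncated at the floor
      lo <- stats::pnorm(log(config$signal_min_base_mean),
                         config$baseline_log_mean_mu, config$baseline_log_mean_sd)
      u <- stats::runif(length(signal_idx), lo, 1)
      base_log_mean[signal_idx] <- stats::qnorm(u, config$baseline_log_mean_mu,
                                                config$baseline_log_mean_sd)
    }
    base_log_mean[low_genes] <- log(stats::runif(n_low, 1, 6))
    phi <- if (config$dispersion_genewise) {
      shape <- 5
      1 / stats::rgamma(G, shape = shape, rate = config$dispersion * (shape - 1))
    } else rep(config$dispersion, G)

    counts <- list()
    metas <- list()
    for (spec in config$cohorts) {
      meta <- build_cohort_meta(spec)
      n_s <- nrow(meta)
      libfac <- exp(stats::rnorm(n_s, 0, config$libsize_log_sd))
      # log2 effect matrix: genes x samples
      eff <- matrix(0, G, n_s)
      severe <- meta$severe_ams
      ha <- meta$timepoint == "HA"
      woman <- meta$sex == "W"
      add_eff <- function(eff, lfcs, cols) {
        gi <- match(names(lfcs), genes)
        eff[gi, cols] <- eff[gi, cols] + lfcs
        eff
      }
      if (!is.null(signal_lfc$diagnostic))
        eff <- add_eff(eff, signal_lfc$diagnostic, severe & ha)
      if (!is.null(signal_lfc$predictive))
        eff <- add_eff(eff, signal_lfc$predictive, severe)
      if (!is.null(signal_lfc$pathogenic))
        eff <- add_eff(eff, signal_lfc$pathogenic, severe & ha)
      if (!is.null(signal_lfc$protective))
        eff <- add_eff(eff, signal_lfc$protective, ha)
      eff[sex_genes, woman] <- eff[sex_genes, woman] + config$sex_effect_lfc

      mu <- exp(base_log_mean) %o% libfac * 2^eff
      cm <- matrix(stats::rnbinom(G * n_s, mu = mu, size = 1 / phi), G, n_s,
                   dimnames = list(genes, meta$sample_id))
      storage.mode(cm) <- "double"
      counts[[spec$name]] <- cm
      metas[[spec$name]] <- meta
    }
    list(counts = counts, meta = do.call(rbind, c(metas, make.row.names = FALSE)),
         truth = truth)
  })
}
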