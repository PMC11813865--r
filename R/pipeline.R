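default_run_config <- function() {
  list(
    seed = 1L,
    outdir = "ams_run",
    simulate = list(),          # sim_config() arguments; NULL disables simulation
    input = NULL,               # list(counts = named paths, meta = path)
    preprocess = list(low_threshold = 10, max_low_fraction = 0.2, k = 5),
    de = list(p_max = 0.05, lfc_min = 0.7, prior_df = 10),
    panel = list(n_trees = 10000, C = 1, max_k = NULL, label_rule = "sample")
  )
}

merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(base[[nm]]) && is.list(user[[nm]]) && !is.null(names(user[[nm]]))) {
      base[[nm]] <- merge_config(base[[nm]], user[[nm]])
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

#' Read a pipeline run configuration
#'
#' Accepts a YAML file path or a list; missing fields take the documented
#' defaults (thresholds of the preprocessing, DE and panel stages, plus either
#' a `simulate` block of [sim_config()] arguments or an `input` block with
#' paths to count/metadata TSVs).
#'
#' @param config list or path to a YAML file.
#' @return complete configuration list.
#' @export
read_run_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stop_if_not(is.list(config), "config must be a list or YAML path")
  cfg <- merge_config(default_run_config(), config)
  stop_if_not(cfg$de$p_max >= 0 && cfg$de$p_max <= 1 &&
                cfg$de$lfc_min >= 0 && cfg$de$prior_df > 0,
              "DE thresholds out of range")
  stop_if_not(cfg$preprocess$max_low_fraction >= 0 &&
                cfg$preprocess$max_low_fraction < 1 &&
                cfg$preprocess$k >= 1,
              "preprocessing parameters out of range")
  cfg
}

sim_config_from_list <- function(sim, seed) {
  args <- sim
  if (!is.null(args$cohorts)) {
    args$cohorts <- lapply(args$cohorts, function(cs) do.call(cohort_spec, cs))
  }
  if (is.null(args$seed)) args$seed <- seed
  do.call(sim_config, args)
}

load_study <- function(cfg) {
  if (!is.null(cfg$input)) {
    counts <- lapply(cfg$input$counts, read_count_matrix)
    meta <- read_sample_meta(cfg$input$meta)
    list(counts = counts, meta = meta, truth = NULL)
  } else {
    generate_study(sim_config_from_list(cfg$simulate, cfg$seed))
  }
}

#' Run the full biomarker-discovery pipeline
#'
#' Simulate (or load) a two-cohort study, preprocess each cohort, fit all four
#' biomarker contrasts per cohort, apply the same-direction cross-cohort
#' replication filter, and run Gini-ranked forward panel selection for the
#' diagnostic and predictive categories (first cohort trains, second cohort
#' tests). All result tables are written as TSV under `outdir` together with a
#' JSON manifest echoing the configuration; a rerun with the same
#' configuration reproduces identical outputs.
#'
#' @param config run configuration (list or YAML path), see
#'   [read_run_config()].
#' @param outdir output directory; overrides the config entry when given.
#' @return the manifest list, invisibly.
#' @export
run_all <- function(config = list(), outdir = NULL) {
  cfg <- read_run_config(config)
  if (!is.null(outdir)) cfg$outdir <- outdir
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  study <- load_study(cfg)
  cohorts <- names(study$counts)
  manifest <- list(parameters = cfg, seed = cfg$seed,
                   stages = list(), outputs = character(0), skipped = list())
  out_path <- function(...) file.path(cfg$outdir, paste0(...))
  emit <- function(writer, obj, name) {
    p <- out_path(name)
    writer(obj, p)
    manifest$outputs <<- c(manifest$outputs, p)
    p
  }

  # --- preprocess -----------------------------------------------------------
  prep <- list()
  for (co in cohorts) {
    pp <- preprocess_counts(study$counts[[co]],
                            low_threshold = cfg$preprocess$low_threshold,
                            max_low_fraction = cfg$preprocess$max_low_fraction,
                            k = cfg$preprocess$k)
    pca <- pca_outlier_check(pp$log_cpm)
    message(sprintf("[preprocess] %s: %d genes x %d samples (%d gene(s) dropped, %d PCA flag(s))",
                    co, nrow(pp$counts), ncol(pp$counts),
                    length(pp$dropped_genes), length(pca$flagged)))
    emit(write_count_matrix, pp$counts, paste0("counts_", co, ".tsv"))
    prep[[co]] <- pp
    manifest$stages$preprocess[[co]] <-
      list(n_genes = nrow(pp$counts), n_samples = ncol(pp$counts),
           dropped_genes = length(pp$dropped_genes), pca_flagged = pca$flagged)
  }
  emit(write_sample_meta, study$meta, "sample_meta.tsv")

  # --- differential expression: 4 contrasts x cohorts -----------------------
  de <- list()
  for (co in cohorts) {
    meta_co <- study$meta[study$meta$cohort == co, , drop = FALSE]
    for (cat in BIOMARKER_CATEGORIES) {
      res <- run_contrast(prep[[co]]$counts, meta_co, cat,
                          factors = prep[[co]]$factors,
                          prior_df = cfg$de$prior_df)
      degs <- call_degs(res, cfg$de$p_max, cfg$de$lfc_min)
      message(sprintf("[de] %s/%s: %d tested, %d up / %d down DEGs",
                      co, cat, nrow(res), attr(degs, "n_up"), attr(degs, "n_down")))
      de[[co]][[cat]] <- res
      emit(write_de_result, res, paste0("de_", co, "_", cat, ".tsv"))
      manifest$stages$de[[co]][[cat]] <-
        list(n_tested = nrow(res), n_up = attr(degs, "n_up"),
             n_down = attr(degs, "n_down"))
    }
  }

  # --- cross-cohort replication --------------------------------------------
  sets <- list()
  if (length(cohorts) >= 2) {
    a <- cohorts[1]; b <- cohorts[2]
    for (cat in BIOMARKER_CATEGORIES) {
      set <- common_degs(de[[a]][[cat]], de[[b]][[cat]],
                         cfg$de$p_max, cfg$de$lfc_min)
      dc <- direction_counts(set)
      message(sprintf("[biomarkers] %s: %d common genes (%d up / %d down)",
                      cat, nrow(set), dc["n_up"], dc["n_down"]))
      sets[[cat]] <- set
      emit(write_biomarker_set, set, paste0("biomarkers_", cat, ".tsv"))
      manifest$stages$biomarkers[[cat]] <-
        list(n_common = nrow(set), n_up = unname(dc["n_up"]),
             n_down = unname(dc["n_down"]))
    }
    conv <- converged_genes(sets)
    emit(function(x, p) utils::write.table(x, p, sep = "\t", quote = FALSE,
                                           row.names = FALSE),
         conv, "converged_genes.tsv")
  } else {
    manifest$skipped$biomarkers <- "replication filter needs two cohorts"
  }

  # --- panels ---------------------------------------------------------------
  if (length(cohorts) >= 2) {
    a <- cohorts[1]; b <- cohorts[2]
    for (cat in c("diagnostic", "predictive")) {
      pool <- intersect(sets[[cat]]$gene, rownames(prep[[b]]$log_cpm))
      if (length(pool) == 0) {
        reason <- paste0("empty ", cat, " biomarker set; panel stage skipped")
        message("[panel] ", reason)
        manifest$skipped[[paste0("panel_", cat)]] <- reason
        next
      }
      tr <- panel_features(prep[[a]]$log_cpm,
                           study$meta[study$meta$cohort == a, ], pool,
                           category = cat, label_rule = cfg$panel$label_rule)
      te <- panel_features(prep[[b]]$log_cpm,
                           study$meta[study$meta$cohort == b, ], pool,
                           category = cat, label_rule = cfg$panel$label_rule)
      ranking <- gini_rank(tr$x, tr$y, n_trees = cfg$panel$n_trees,
                           seed = cfg$seed)
      max_k <- min(cfg$panel$max_k %||% length(pool), length(pool))
      traj <- forward_trajectory(ranking, tr, te, max_k = max_k,
                                 C = cfg$panel$C)
      bk <- attr(traj, "best_k")
      message(sprintf("[panel] %s: best k = %d (test AUC %.3f)",
                      cat, bk, traj$auc[bk]))
      emit(write_trajectory, traj, paste0("panel_", cat, ".tsv"))
      manifest$stages$panel[[cat]] <-
        list(pool = pool, best_k = bk, best_genes = attr(traj, "best_genes"),
             auc = traj$auc[bk], sensitivity = traj$sensitivity[bk],
             specificity = traj$specificity[bk])
    }
  } else {
    manifest$skipped$panel <- "panel evaluation needs a test cohort"
  }

  manifest$input_hashes <- as.list(tools::md5sum(manifest$outputs))
  jsonlite::write_json(manifest, out_path("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null", force = TRUE)
  invisible(manifest)
}
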