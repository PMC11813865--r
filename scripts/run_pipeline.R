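#!/usr/bin/env Rscript
# Thin command-line wrapper around the exported pipeline stages. Every
# subcommand reads and writes the package's TSV dialects so stages compose on
# disk; `all` runs the whole pipeline from a YAML config.
#
# Usage:
#   Rscript scripts/run_pipeline.R all        --config cfg.yaml [--outdir DIR]
#   Rscript scripts/run_pipeline.R simulate   --config cfg.yaml --outdir DIR
#   Rscript scripts/run_pipeline.R preprocess --counts in.tsv --outdir DIR
#   Rscript scripts/run_pipeline.R de         --counts in.tsv --meta meta.tsv
#                                             --category diagnostic --out de.tsv
#   Rscript scripts/run_pipeline.R biomarkers --a de_a.tsv --b de_b.tsv --out set.tsv
#   Rscript scripts/run_pipeline.R panel      --config cfg.yaml --outdir DIR
#
# Exit codes: 0 success, 2 configuration error, 3 data/computation error.

suppressPackageStartupMessages(library(amsbiomarkers))

argv <- commandArgs(trailingOnly = TRUE)
if (length(argv) == 0) {
  cat("usage: run_pipeline.R <all|simulate|preprocess|de|biomarkers|panel> [options]\n")
  quit(status = 2)
}
cmd <- argv[1]
opts <- list()
i <- 2
while (i <= length(argv)) {
  key <- sub("^--", "", argv[i])
  opts[[key]] <- argv[i + 1]
  i <- i + 2
}

fail <- function(status, ...) {
  message("error: ", ...)
  quit(status = status)
}
need <- function(...) {
  for (k in c(...)) if (is.null(opts[[k]])) fail(2, "missing --", k)
}
get_config <- function() {
  tryCatch(read_run_config(if (is.null(opts$config)) list() else opts$config),
           error = function(e) fail(2, conditionMessage(e)))
}
run <- function(expr) {
  tryCatch(expr, error = function(e) fail(3, conditionMessage(e)))
}

if (cmd == "all") {
  cfg <- get_config()
  run(run_all(cfg, outdir = opts$outdir))
} else if (cmd == "simulate") {
  need("outdir")
  cfg <- get_config()
  run({
    st <- generate_study(do.call(
      sim_config, c(cfg$simulate, list(seed = cfg$seed))[
        !duplicated(names(c(cfg$simulate, list(seed = cfg$seed))),
                    fromLast = TRUE)]))
    dir.create(opts$outdir, recursive = TRUE, showWarnings = FALSE)
    for (co in names(st$counts)) {
      write_count_matrix(st$counts[[co]],
                         file.path(opts$outdir, paste0("counts_", co, ".tsv")))
    }
    write_sample_meta(st$meta, file.path(opts$outdir, "sample_meta.tsv"))
    write.table(st$truth, file.path(opts$outdir, "truth.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  })
} else if (cmd == "preprocess") {
  need("counts", "outdir")
  cfg <- get_config()
  run({
    pp <- preprocess_counts(read_count_matrix(opts$counts),
                            low_threshold = cfg$preprocess$low_threshold,
                            max_low_fraction = cfg$preprocess$max_low_fraction,
                            k = cfg$preprocess$k)
    dir.create(opts$outdir, recursive = TRUE, showWarnings = FALSE)
    write_count_matrix(pp$counts, file.path(opts$outdir, "counts_clean.tsv"))
    write.table(pp$factors, file.path(opts$outdir, "norm_factors.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write_count_matrix(pp$log_cpm, file.path(opts$outdir, "log_cpm.tsv"))
  })
} else if (cmd == "de") {
  need("counts", "meta", "category", "out")
  cfg <- get_config()
  run({
    res <- run_contrast(read_count_matrix(opts$counts),
                        read_sample_meta(opts$meta),
                        opts$category, prior_df = cfg$de$prior_df)
    write_de_result(res, opts$out)
  })
} else if (cmd == "biomarkers") {
  need("a", "b", "out")
  cfg <- get_config()
  run({
    load_de <- function(p) {
      df <- read.delim(p)
      data.frame(gene = df$gene, log2fc = df$log2FC,
                 pvalue = df$PV, fdr = df$FDR)
    }
    set <- common_degs(load_de(opts$a), load_de(opts$b),
                       p_max = cfg$de$p_max, lfc_min = cfg$de$lfc_min)
    write_biomarker_set(set, opts$out)
  })
} else if (cmd == "panel") {
  # panel selection needs the cross-cohort context; delegate to the full run
  cfg <- get_config()
  run(run_all(cfg, outdir = opts$outdir))
} else {
  fail(2, "unknown subcommand: ", cmd)
}
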