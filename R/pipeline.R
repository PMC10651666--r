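#' Pipeline configuration
#'
#' Builds and validates the configuration driving [run_pipeline()]. Accepts
#' a YAML file path or a named list; unknown keys are rejected. Fields:
#' `alpha` (DEG threshold, default 0.01), `seed`, `scenario` (free label),
#' `sim` (arguments for [sim_config()]; ignored when `counts_path` is set),
#' `counts_path`/`meta_path` (load user counts instead of simulating),
#' `gene_lists` (named list of gene-list file paths), `cohorts` (named list
#' of lists with `male`/`female` probe-table TSV paths).
#'
#' @param config YAML path or named list.
#' @return Validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stopf("'config' must be a list or a YAML file path")
  known <- c("alpha", "seed", "scenario", "sim", "counts_path", "meta_path",
             "gene_lists", "cohorts")
  unknown <- setdiff(names(config), known)
  if (length(unknown)) {
    stopf("unknown config keys: %s", paste(unknown, collapse = ", "))
  }
  cfg <- list(
    alpha = config$alpha %||% 0.01,
    seed = as.integer(config$seed %||% 1L),
    scenario = config$scenario %||% "paper-structure",
    sim = config$sim %||% list(),
    counts_path = config$counts_path,
    meta_path = config$meta_path,
    gene_lists = config$gene_lists %||% list(),
    cohorts = config$cohorts %||% list()
  )
  if (!is.numeric(cfg$alpha) || cfg$alpha <= 0 || cfg$alpha >= 1) {
    stopf("'alpha' must lie in (0, 1)")
  }
  for (p in c(cfg$counts_path, cfg$meta_path,
              unlist(cfg$gene_lists), unlist(cfg$cohorts))) {
    if (!is.null(p) && !file.exists(p)) stopf("path does not exist: %s", p)
  }
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full two-sex concordance pipeline
#'
#' Chains the stages: obtain counts (simulate with the configured scenario,
#' or load `counts_path`), per-sex old-vs-young DE, DEG partition at
#' `alpha`, concordance statistics for the shared and sex-specific sets,
#' optional gene-list-restricted concordance, and optional external-cohort
#' harmonization (probe collapse + replication report). Deterministic given
#' the config seed.
#'
#' @param config A [pipeline_config()], list, or YAML path.
#' @param out_dir Optional directory; when given, per-sex DE tables, the
#'   partition gene lists and the JSON report are written there.
#' @return Report list of class `pipeline_report` (also serialized to
#'   `report.json` under `out_dir` when given).
#' @export
run_pipeline <- function(config = list(), out_dir = NULL) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  stage <- "input"
  report <- list(package_version = as.character(utils::packageVersion("myoconcord")),
                 scenario = config$scenario, seed = config$seed,
                 alpha = config$alpha)
  tryCatch({
    truth <- NULL
    if (!is.null(config$counts_path)) {
      cm <- read_counts(config$counts_path, config$meta_path)
    } else {
      sim_args <- config$sim
      sim_args$seed <- sim_args$seed %||% config$seed
      sim <- simulate_counts(do.call(sim_config, sim_args))
      cm <- sim$counts
      truth <- sim$truth
    }
    report$n_genes <- nrow(cm$counts)
    report$n_samples <- ncol(cm$counts)

    stage <- "diffexpr"
    de_m <- de_test(cm, "male")
    de_f <- de_test(cm, "female")
    report$de <- list(
      male = as.list(summarize_de(de_m, config$alpha)),
      female = as.list(summarize_de(de_f, config$alpha))
    )
    n_m <- sum(de_m$p_value < config$alpha)
    n_f <- sum(de_f$p_value < config$alpha)
    report$female_excess_pct <- if (n_m > 0) 100 * (n_f - n_m) / n_m else NA

    stage <- "concordance"
    part <- partition_degs(de_m, de_f, config$alpha)
    report$partition <- as.list(part$counts)
    conc <- lapply(list(shared = part$shared,
                        male_specific = part$male_specific,
                        female_specific = part$female_specific),
                   function(set) {
      if (length(set) < 2) return(NULL)
      i <- match(set, de_m$gene)
      unclass(concordance_stats(de_m$log2fc[i],
                                de_f$log2fc[match(set, de_f$gene)]))
    })
    report$concordance <- conc

    if (length(config$gene_lists)) {
      stage <- "gene_lists"
      report$gene_lists <- lapply(names(config$gene_lists), function(nm) {
        gl <- read_gene_list(config$gene_lists[[nm]])
        st <- geneset_concordance(de_m, de_f, gl, list_name = nm,
                                  alpha = config$alpha)
        attr(st, "pairs") <- NULL
        unclass(st)
      })
      names(report$gene_lists) <- names(config$gene_lists)
    }

    if (length(config$cohorts)) {
      stage <- "harmonize"
      cohorts <- lapply(config$cohorts, function(co) {
        list(male = collapse_probes(read_probe_table(co$male), config$alpha),
             female = collapse_probes(read_probe_table(co$female), config$alpha))
      })
      rep_rep <- cohort_replication(cohorts, config$alpha)
      report$cohorts <- lapply(rep_rep, function(co) {
        list(n_degs_male = co$n_degs_male, n_degs_female = co$n_degs_female,
             female_excess_pct = co$female_excess_pct,
             partition = as.list(co$partition$counts),
             concordance = lapply(co$concordance, function(s) {
               if (is.null(s)) NULL else unclass(s)
             }))
      })
    }

    if (!is.null(out_dir)) {
      stage <- "write"
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      write_de(de_m, file.path(out_dir, "de_male.tsv"))
      write_de(de_f, file.path(out_dir, "de_female.tsv"))
      for (set in c("shared", "male_specific", "female_specific", "neither")) {
        writeLines(part[[set]], file.path(out_dir, paste0(set, ".txt")))
      }
      if (!is.null(truth)) {
        utils::write.table(truth, file.path(out_dir, "truth.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
      jsonlite::write_json(report, file.path(out_dir, "report.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
    structure(report, class = "pipeline_report")
  }, error = function(e) {
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      writeLines(c("INCOMPLETE", paste("failed stage:", stage),
                   conditionMessage(e)),
                 file.path(out_dir, "MANIFEST"))
    }
    stopf("pipeline failed at stage '%s': %s", stage, conditionMessage(e))
  })
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("pipeline_report ('%s', seed %d, alpha %g)\n",
              x$scenario, x$seed, x$alpha))
  cat(sprintf("  %d genes x %d samples\n", x$n_genes, x$n_samples))
  cat(sprintf("  DEGs: male %d up / %d down; female %d up / %d down (excess %.1f%%)\n",
              x$de$male$n_up, x$de$male$n_down,
              x$de$female$n_up, x$de$female$n_down, x$female_excess_pct))
  cat("  partition: ", paste(names(x$partition), unlist(x$partition),
                             sep = "=", collapse = ", "), "\n")
  if (!is.null(x$concordance$shared)) {
    s <- x$concordance$shared
    cat(sprintf("  shared concordance: same %.1f%%, R=%.2f, m=%.2f\n",
                s$pct_same_direction, s$pearson_R, s$slope_m))
  }
  invisible(x)
}
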