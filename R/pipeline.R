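# Pipeline orchestration: simulate -> table1 -> reduce -> search -> report,
# with a single configuration object, per-stage manifests and seeded
# reproducibility.

#' Univariate screening report (Table-1 style)
#'
#' Per covariate: group summaries and the appropriate univariate test —
#' Welch's t-test for continuous covariates (mean +/- sd per group),
#' Fisher's exact test for categorical ones (level counts per group).
#' Covariates with a single observed level are dropped with a warning.
#'
#' @param table cohort data.frame with a binary outcome column.
#' @param outcome outcome column name (default `"pCR"`).
#' @return A data.frame: `covariate`, `type`, `summary_pos`,
#'   `summary_neg`, `test`, `p`.
#' @export
make_table1_report <- function(table, outcome = "pCR") {
  if (!outcome %in% names(table)) stop("no outcome column", call. = FALSE)
  y <- table[[outcome]]
  pos <- y == 1; neg <- y == 0
  rows <- list()
  for (nm in setdiff(names(table), outcome)) {
    v <- table[[nm]]
    if (is.numeric(v)) {
      w <- welch_t(v[pos], v[neg])
      rows[[nm]] <- data.frame(
        covariate = nm, type = "continuous",
        summary_pos = sprintf("%.3g (+/-%.3g)", mean(v[pos]), sd(v[pos])),
        summary_neg = sprintf("%.3g (+/-%.3g)", mean(v[neg]), sd(v[neg])),
        test = "Welch t", p = w$p, stringsAsFactors = FALSE)
    } else {
      lev <- sort(unique(as.character(v)))
      if (length(lev) < 2) {
        warning("dropping single-level covariate ", nm)
        next
      }
      tab <- rbind(pos = table(factor(v[pos], levels = lev)),
                   neg = table(factor(v[neg], levels = lev)))
      rows[[nm]] <- data.frame(
        covariate = nm, type = "categorical",
        summary_pos = paste(lev, tab["pos", ], sep = ":", collapse = " "),
        summary_neg = paste(lev, tab["neg", ], sep = ":", collapse = " "),
        test = "Fisher exact", p = fisher_exact(t(tab)),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pipeline configuration
#'
#' Collects every tunable of the analysis chain in one structured object:
#' stage toggles, seeds, preprocessing parameters (0.90 mm isotropic
#' target spacing, 8 gray levels, normalization scale 100), the variable
#' groups searched, the classifiers, the subset cap and the CI level.
#'
#' @param stages character vector of stages to run, a subset of
#'   `c("simulate", "table1", "reduce", "search")` in that order.
#' @param seed master seed; every stage derives its own stream from it.
#' @param groups variable groups to search (default all five).
#' @param classifiers classifiers to search with (default `"Logit"`).
#' @param subset_cap cap on subsets per group search.
#' @param target,n_bins,norm_scale preprocessing parameters.
#' @param ci_level confidence level for AUC intervals.
#' @param cohort_config optional [synthetic_config()]; defaults to the
#'   published cohort layout with the master seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(stages = c("simulate", "table1", "reduce",
                                       "search"),
                            seed = 1,
                            groups = names(variable_groups()),
                            classifiers = "Logit",
                            subset_cap = 2^14,
                            target = 0.9, n_bins = 8, norm_scale = 100,
                            ci_level = 0.95,
                            cohort_config = NULL) {
  stages <- match.arg(stages, c("simulate", "table1", "reduce", "search"),
                      several.ok = TRUE)
  structure(list(stages = stages, seed = as.integer(seed), groups = groups,
                 classifiers = classifiers, subset_cap = subset_cap,
                 target = target, n_bins = n_bins, norm_scale = norm_scale,
                 ci_level = ci_level,
                 cohort_config = cohort_config %||% synthetic_config(seed = seed)),
            class = "pipeline_config")
}

write_manifest <- function(dir, stage, config, extra = list()) {
  manifest <- c(list(stage = stage, seed = config$seed,
                     package_version = as.character(
                       utils::packageVersion("pcrradiomics")),
                     timestamp_free = TRUE), extra)
  jsonlite::write_json(manifest, file.path(dir, paste0(stage, "_manifest.json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order inside `out_dir`: `simulate`
#' writes the synthetic cohort; `table1` the univariate screening report;
#' `reduce` the L1 feature reduction of the radiomic block; `search` one
#' report per variable group and classifier (JSON), including ranked
#' models, best-6 frequencies and aggregated coefficients. Each stage
#' writes a manifest recording parameters and seed; rerunning with the
#' same configuration reproduces identical outputs.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if missing).
#' @param cohort optional existing cohort data.frame; required when the
#'   `simulate` stage is disabled.
#' @return The output directory, invisibly; side effect: files per stage.
#' @export
run_pipeline <- function(config, out_dir, cohort = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if ("simulate" %in% config$stages) {
    cohort <- generate_cohort(config$cohort_config)
    write_cohort(cohort, file.path(out_dir, "cohort.tsv"))
    write_manifest(out_dir, "simulate", config,
                   list(n = nrow(cohort),
                        n_responders = sum(cohort$pCR == 1)))
  }
  if (is.null(cohort)) stop("no cohort: enable the simulate stage or pass one",
                            call. = FALSE)
  if ("table1" %in% config$stages) {
    rep1 <- make_table1_report(cohort)
    write.table(rep1, file.path(out_dir, "table1.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write_manifest(out_dir, "table1", config, list(n_covariates = nrow(rep1)))
  }
  if ("reduce" %in% config$stages) {
    rad <- intersect(paste0("F", 1:5), names(cohort))
    red <- lasso_reduce(as.matrix(cohort[rad]), cohort$pCR)
    jsonlite::write_json(
      list(selected = red$selected, lambda_min = red$lambda_min,
           lambda = red$cv$lambda, cv_deviance = red$cv$cv_deviance),
      file.path(out_dir, "reduction.json"), auto_unbox = TRUE, digits = NA)
    write_manifest(out_dir, "reduce", config,
                   list(selected = red$selected))
  }
  if ("search" %in% config$stages) {
    reports <- list()
    for (cl in config$classifiers) {
      for (g in config$groups) {
        r <- run_group_search(cohort, g, classifier = cl,
                              subset_cap = config$subset_cap,
                              seed = config$seed, level = config$ci_level)
        reports[[paste(g, cl, sep = "_")]] <- list(
          group = r$group, classifier = r$classifier,
          n_evaluated = r$n_evaluated, truncated = r$truncated,
          best6 = r$best6, frequency = as.list(r$frequency),
          m_agg = as.list(r$m_agg),
          mean_p_adj_best6 = r$mean_p_adj_best6)
      }
    }
    jsonlite::write_json(reports, file.path(out_dir, "search_report.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    write_manifest(out_dir, "search", config,
                   list(groups = config$groups,
                        classifiers = config$classifiers,
                        subset_cap = config$subset_cap))
  }
  invisible(out_dir)
}
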