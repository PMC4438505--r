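# One-call orchestration: simulate (or read) -> preprocess -> normalize ->
# screen -> model comparison -> PLS-VIP panel -> accuracy -> clustering ->
# power, with per-stage counts, reproducible seeding (one master seed fans
# out to per-stage substreams) and optional tab-delimited intermediates.

#' Pipeline settings
#'
#' Every numeric threshold used by any stage is settable here; defaults are
#' the study's analytical thresholds.
#'
#' @param cohort A [cohort_config()] to simulate, a `meth_cohort`, or a
#'   directory path written by [write_cohort()].
#' @param control_multiplier Spot informativeness floor multiplier
#'   (default 2).
#' @param min_informative_spots Minimum informative replicate spots per
#'   gene (default 2).
#' @param max_missing_frac Gene missingness ceiling (default 0.25,
#'   strict >).
#' @param fc_min,p_max Differential-screen cutoffs (defaults 1.5, 0.05).
#' @param vip_min Panel-selection VIP threshold (default 1.0).
#' @param call_threshold_log2 Binary-call threshold (default 1).
#' @param alpha Significance level for the power stage (default 0.05).
#' @param cv_folds,cv_runs Cross-validation scheme (defaults 5, 10).
#' @param families Model families compared (default all six).
#' @param seed Master seed.
#' @param output_dir If non-NULL, every intermediate table is written here.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            control_multiplier = 2,
                            min_informative_spots = 2,
                            max_missing_frac = 0.25,
                            fc_min = 1.5, p_max = 0.05,
                            vip_min = 1.0,
                            call_threshold_log2 = 1,
                            alpha = 0.05,
                            cv_folds = 5, cv_runs = 10,
                            families = .FAMILIES,
                            seed = 1L,
                            output_dir = NULL) {
  structure(
    list(
      cohort = cohort,
      control_multiplier = control_multiplier,
      min_informative_spots = min_informative_spots,
      max_missing_frac = max_missing_frac,
      fc_min = fc_min, p_max = p_max, vip_min = vip_min,
      call_threshold_log2 = call_threshold_log2, alpha = alpha,
      cv_folds = cv_folds, cv_runs = cv_runs, families = families,
      seed = as.integer(seed), output_dir = output_dir
    ),
    class = "pipeline_config"
  )
}

#' Run the full analysis pipeline
#'
#' Executes every stage in order on a simulated or on-disk cohort and
#' returns a consolidated report. Bit-identical on re-run with the same
#' config.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `run_report`: `cohort`, `matrix` (with calls),
#'   `differential`, `candidates`, `cv` (`cv_models`), `ranking`
#'   (`gene_ranking`), `panel`, `metrics_resub`, `metrics_cv`,
#'   `single_genes`, `cluster`, `power`, `stage_counts`, `provenance`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  # per-stage substreams from the master seed
  stage_seed <- with_seed(config$seed, sample.int(2^31 - 2, 4))
  out_dir <- config$output_dir
  emit <- function(tbl, name) {
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      write_tsv(as_tibble(tbl), file.path(out_dir, paste0(name, ".tsv")))
    }
  }

  cohort <- config$cohort
  if (inherits(cohort, "cohort_config")) {
    cohort$seed <- stage_seed[1]
    cohort <- generate_cohort(cohort)
  } else if (is.character(cohort)) {
    cohort <- read_cohort(cohort)
  }
  stopifnot(inherits(cohort, "meth_cohort"))
  labels <- cohort$samples

  summaries <- preprocess_cohort(cohort,
    control_multiplier = config$control_multiplier,
    min_informative = config$min_informative_spots
  )
  emit(summaries, "gene_summaries")
  mm <- build_matrix(summaries, max_missing_frac = config$max_missing_frac)
  mm <- categorize_calls(mm, config$call_threshold_log2)
  emit(mm, "methylation_matrix")

  diff_tbl <- differential_table(mm, labels)
  emit(diff_tbl, "differential_table")
  candidates <- apply_cutoffs(diff_tbl,
    fc_min = config$fc_min,
    p_max = config$p_max
  )
  emit(candidates, "candidate_set")
  if (nrow(candidates) < 2) {
    abort(sprintf(
      "screen stage retained %d gene(s); need >= 2 to model",
      nrow(candidates)
    ))
  }

  mm_imp <- impute_missing(mm)
  cv <- cross_validate_models(mm_imp, labels,
    genes = candidates$gene_id,
    families = config$families,
    k = config$cv_folds, runs = config$cv_runs, seed = stage_seed[2]
  )
  emit(cv, "model_comparison")

  ranking <- rank_and_select_panel(mm_imp, labels, candidates$gene_id,
    vip_min = config$vip_min,
    k = config$cv_folds, runs = config$cv_runs, seed = stage_seed[3]
  )
  emit(ranking, "gene_ranking")
  panel <- attr(ranking, "panel")
  if (length(panel) == 0) {
    abort("selection stage: no gene passed the VIP threshold")
  }

  metrics_resub <- evaluate_panel(mm_imp, labels, panel,
    mode = "resubstitution"
  )
  metrics_cv <- evaluate_panel(mm_imp, labels, panel,
    mode = "cross_validated",
    k = config$cv_folds, runs = config$cv_runs, seed = stage_seed[4]
  )
  single <- evaluate_single_genes(mm_imp, labels, panel)
  metrics <- bind_rows(
    as_tibble(metrics_resub), as_tibble(metrics_cv), single
  )
  emit(metrics, "panel_metrics")

  cluster <- cluster_and_concordance(mm, labels, panel)
  emit(cluster$branches, "cluster_branches")
  emit(cluster$concordance, "cluster_concordance")

  power <- panel_power(mm, labels, panel, alpha = config$alpha)
  emit(power, "power_table")

  n_genes_layout <- length(unique(
    cohort$layout$gene_id[cohort$layout$role == "gene_probe"]
  ))
  stage_counts <- tibble(
    stage = c(
      "samples", "spots", "genes_on_layout", "genes_retained",
      "candidates", "panel"
    ),
    count = c(
      nrow(labels), nrow(cohort$spots), n_genes_layout,
      length(unique(mm$gene_id)), nrow(candidates), length(panel)
    )
  )
  emit(stage_counts, "stage_counts")

  report <- structure(
    list(
      cohort = cohort, matrix = mm, differential = diff_tbl,
      candidates = candidates, cv = cv, ranking = ranking, panel = panel,
      metrics_resub = metrics_resub, metrics_cv = metrics_cv,
      single_genes = single, cluster = cluster, power = power,
      stage_counts = stage_counts,
      provenance = list(
        seed = config$seed,
        config_hash = hash(config[setdiff(names(config), "output_dir")]),
        package_version = as.character(utils::packageVersion("methdet"))
      )
    ),
    class = "run_report"
  )
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  print(x$stage_counts)
  cat("\nbest model family:", attr(x$cv, "best"), "\n")
  cat("selected panel:", toString(x$panel), "\n")
  cat(sprintf(
    "panel (resubstitution): sens %.2f spec %.2f ppv %.2f npv %.2f auc %.3f\n",
    x$metrics_resub$sensitivity, x$metrics_resub$specificity,
    x$metrics_resub$ppv, x$metrics_resub$npv, x$metrics_resub$auc
  ))
  cat(sprintf(
    "panel (cross-validated): sens %.2f spec %.2f auc %.3f\n",
    x$metrics_cv$sensitivity, x$metrics_cv$specificity, x$metrics_cv$auc
  ))
  cat(sprintf("panel power: %.4f\n", x$power$power[x$power$scope == "panel"]))
  invisible(x)
}
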