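# Per-gene two-group comparison on the normalized log2 ratios, and the
# fold-change / p-value screen. Fold change is defined on the group means:
# fc_abs = 2^|mean(relapse) - mean(control)|. The published screen used a
# plain (unadjusted) two-sample t-test; a Benjamini-Hochberg column is
# emitted for information only.

normalize_labels <- function(labels) {
  if (is.data.frame(labels)) {
    stopifnot(all(c("sample_id", "label") %in% names(labels)))
    labels <- setNames(labels$label, labels$sample_id)
  }
  bad <- setdiff(unique(labels), c(.POS, .NEG))
  if (length(bad) > 0) {
    abort(paste0(
      "labels must be '", .POS, "' or '", .NEG, "'; got ", toString(bad)
    ))
  }
  labels
}

#' Per-gene differential methylation table
#'
#' Two-sample t-test of the normalized log2 ratios per gene, relapse versus
#' control. Genes with fewer than two non-missing values in either group are
#' skipped with a warning. With `var_equal = TRUE` (default) the pooled
#' Student form is used; `FALSE` gives the Welch form.
#'
#' @param matrix A `meth_matrix`.
#' @param labels Sample labels: a tibble with `sample_id`/`label`, or a
#'   named character vector of `"relapse"`/`"control"`.
#' @param var_equal Pooled-variance Student t (default) or Welch.
#' @return A tibble with one row per tested gene: `gene_id`, `n_relapse`,
#'   `n_control`, `mean_relapse`, `mean_control`, `log2_fc` (signed
#'   difference of means), `fc_abs`, `t_stat`, `df`, `p_value`, `p_adj`
#'   (Benjamini-Hochberg, informational).
#' @examples
#' # two groups separated by one log2 unit at one gene
#' mm <- tibble::tibble(
#'   gene_id = "G1", sample_id = sprintf("S%d", 1:6),
#'   log2_ratio = c(1, 2, 3, 4, 5, 6), call = NA_character_
#' )
#' labs <- tibble::tibble(
#'   sample_id = sprintf("S%d", 1:6),
#'   label = rep(c("control", "relapse"), each = 3)
#' )
#' differential_table(mm, labs)
#' @export
differential_table <- function(matrix, labels, var_equal = TRUE) {
  labels <- normalize_labels(labels)
  d <- matrix %>%
    mutate(label = unname(labels[.data$sample_id])) %>%
    filter(!is.na(.data$log2_ratio))
  if (anyNA(d$label)) abort("unlabeled samples in matrix")
  res <- d %>%
    group_by(.data$gene_id) %>%
    group_split() %>%
    lapply(function(g) {
      x <- g$log2_ratio[g$label == .POS]
      y <- g$log2_ratio[g$label == .NEG]
      if (length(x) < 2 || length(y) < 2) {
        warn(paste(
          "gene", g$gene_id[1],
          "skipped: fewer than 2 values in a group"
        ))
        return(NULL)
      }
      diff <- mean(x) - mean(y)
      if (sd(x) == 0 && sd(y) == 0) {
        # degenerate: no within-group variance
        tt <- list(
          statistic = if (diff == 0) 0 else sign(diff) * Inf,
          parameter = length(x) + length(y) - 2,
          p.value = if (diff == 0) 1 else 0
        )
      } else {
        ht <- t.test(x, y, var.equal = var_equal)
        tt <- list(
          statistic = unname(ht$statistic),
          parameter = unname(ht$parameter), p.value = ht$p.value
        )
      }
      tibble(
        gene_id = g$gene_id[1],
        n_relapse = length(x), n_control = length(y),
        mean_relapse = mean(x), mean_control = mean(y),
        log2_fc = diff, fc_abs = 2^abs(diff),
        t_stat = tt$statistic, df = tt$parameter, p_value = tt$p.value
      )
    }) %>%
    bind_rows()
  if (nrow(res) == 0) {
    return(mutate(res, p_adj = numeric(0)))
  }
  mutate(res, p_adj = p.adjust(.data$p_value, method = "BH"))
}

#' Apply the fold-change and p-value screen
#'
#' Retains genes with `fc_abs >= fc_min` and `p_value < p_max`. The default
#' thresholds (1.5, 0.05) reproduce the published 21-gene screen; the
#' stricter fold-change cutoff of 2 quoted elsewhere in the source study is
#' available by flag.
#'
#' @param results A differential table from [differential_table()].
#' @param fc_min Minimum absolute fold change (default 1.5).
#' @param p_max Exclusive p-value ceiling (default 0.05).
#' @return The retained rows as a tibble of class `candidate_set`, with the
#'   thresholds in attributes `fc_min` / `p_max`.
#' @export
apply_cutoffs <- function(results, fc_min = 1.5, p_max = 0.05) {
  stopifnot(fc_min >= 1, p_max > 0, p_max <= 1)
  kept <- filter(results, .data$fc_abs >= fc_min, .data$p_value < p_max)
  structure(kept,
    fc_min = fc_min, p_max = p_max,
    class = c("candidate_set", class(kept))
  )
}
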