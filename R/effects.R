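# Published per-gene screen outcome used to calibrate the simulator: the 21
# differentially methylated CpG islands with their reported two-group
# p-values and absolute fold changes, and the 7-gene prognostic panel picked
# by PLS-VIP. Fold changes are absolute; the direction of each shift is not
# public, so the generator applies a configurable default direction.

.TABLE1 <- tibble::tribble(
  ~gene_id, ~p_published, ~fc_published,
  "BRCA1", 1.53e-05, 5.52,
  "CALCA", 1.96e-04, 1.66,
  "CASP8", 3.54e-03, 1.82,
  "CCND2", 2.81e-04, 1.62,
  "DAPK1", 1.13e-06, 12.37,
  "EDNRB", 2.00e-04, 2.42,
  "FHIT", 6.95e-03, 1.79,
  "ICAM1", 1.60e-04, 2.06,
  "MCTS1", 3.36e-02, 1.56,
  "FABP3", 3.04e-04, 2.78,
  "DNAJC15", 2.03e-03, 3.01,
  "MSH2", 3.10e-05, 13.66,
  "MYOD1", 1.40e-04, 1.74,
  "CDKN2A", 1.29e-02, 1.83,
  "PAX5", 6.82e-03, 1.77,
  "PGK1", 1.77e-03, 1.79,
  "PGR", 2.54e-03, 2.90,
  "RARB", 1.39e-04, 2.05,
  "PRKCDBP", 7.68e-04, 3.63,
  "THBS1", 1.26e-03, 2.08,
  "RANKL", 1.10e-02, 2.14
)

.PANEL7 <- c("BRCA1", "DAPK1", "MSH2", "CDKN2A", "PGR", "PRKCDBP", "RANKL")

# panel-level within-group standard deviations reported for the 7-gene
# average (relapse group vs non-relapse group), reused as per-gene defaults
# because per-gene spreads were not published
.SD_RELAPSE_DEFAULT <- 1.16809
.SD_CONTROL_DEFAULT <- 0.708074

#' Published differential-methylation effect table
#'
#' The 21 CpG-island probes that passed the published screen (absolute
#' fold-change at least 1.5, p < 0.05), with effect sizes on the log2 scale
#' (`log2_mean_diff = log2(fc_published)`) ready for the cohort simulator.
#' The seven prognostic-panel genes (BRCA1, DAPK1, MSH2, CDKN2A, PGR,
#' PRKCDBP, RANKL) are flagged in `panel`.
#'
#' @param sd_relapse,sd_control Within-group standard deviations of the
#'   log2 methylation ratio assigned to every informative gene. Defaults are
#'   the published panel-level group spreads.
#' @param direction Sign (+1/-1) of the relapse-group shift on the log2
#'   control/test ratio, recycled over genes. The published fold changes are
#'   absolute, so direction is a modelling choice. The default models the
#'   seven panel genes as hypermethylated in relapse (protected templates
#'   keep test-channel signal, so the ratio drops: -1) and the remaining
#'   screened genes as shifted the other way (+1), which keeps the
#'   simulated arrays globally balanced -- the regime in which per-sample
#'   lowess normalization is unbiased.
#' @return A tibble with columns `gene_id`, `p_published`, `fc_published`,
#'   `log2_mean_diff`, `direction`, `sd_relapse`, `sd_control`, `panel`.
#' @examples
#' eff <- default_effect_table()
#' eff[eff$gene_id == "BRCA1", c("fc_published", "log2_mean_diff")]
#' @export
default_effect_table <- function(sd_relapse = .SD_RELAPSE_DEFAULT,
                                 sd_control = .SD_CONTROL_DEFAULT,
                                 direction = NULL) {
  stopifnot(sd_relapse > 0, sd_control > 0)
  if (is.null(direction)) {
    direction <- ifelse(.TABLE1$gene_id %in% .PANEL7, -1, 1)
  }
  stopifnot(all(direction %in% c(-1, 1)))
  .TABLE1 %>%
    mutate(
      log2_mean_diff = log2(.data$fc_published),
      direction = rep_len(direction, nrow(.TABLE1)),
      sd_relapse = sd_relapse,
      sd_control = sd_control,
      panel = .data$gene_id %in% .PANEL7
    )
}

#' The seven prognostic panel genes
#'
#' @return Character vector of the seven PLS-selected panel genes.
#' @export
panel_genes <- function() .PANEL7

#' Construct a gene-effect table
#'
#' Helper to declare the ground-truth effects of a simulated cohort: one row
#' per informative gene with the between-group difference of mean log2
#' methylation ratio and within-group spreads.
#'
#' @param gene_id Probe names.
#' @param log2_mean_diff Non-negative between-group differences of the mean
#'   log2 ratio (`direction` carries the sign).
#' @param direction +1 or -1, recycled.
#' @param sd_relapse,sd_control Positive within-group standard deviations,
#'   recycled.
#' @return A tibble of gene effects accepted by [cohort_config()].
#' @export
gene_effects <- function(gene_id, log2_mean_diff, direction = 1,
                         sd_relapse = .SD_RELAPSE_DEFAULT,
                         sd_control = .SD_CONTROL_DEFAULT) {
  out <- tibble(
    gene_id = as.character(gene_id),
    log2_mean_diff = as.numeric(log2_mean_diff),
    direction = rep_len(direction, length(gene_id)),
    sd_relapse = rep_len(sd_relapse, length(gene_id)),
    sd_control = rep_len(sd_control, length(gene_id))
  )
  if (any(out$log2_mean_diff < 0)) {
    abort("`log2_mean_diff` must be >= 0; use `direction` for the sign")
  }
  if (any(out$sd_relapse <= 0) || any(out$sd_control <= 0)) {
    abort("within-group standard deviations must be positive")
  }
  if (!all(out$direction %in% c(-1, 1))) abort("`direction` must be +1 or -1")
  out
}
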