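# Two-sample power for a difference of group means without assuming equal
# variances: noncentral-t computation with Welch-Satterthwaite degrees of
# freedom. Used both for the published panel-level reproduction and for the
# per-gene power screen against the 80% adequacy threshold.

#' Welch two-sample power (noncentral t)
#'
#' Power of the two-sided unequal-variance t-test for a difference of group
#' means:
#' noncentrality `delta = mean_diff / sqrt(sd1^2/n1 + sd2^2/n2)`,
#' Welch-Satterthwaite degrees of freedom, and
#' `power = P(|T'(df, delta)| > t_crit)` under the noncentral t.
#'
#' @param mean_diff Difference of group means (log2-ratio units).
#' @param sd_relapse,sd_control Group standard deviations (> 0).
#' @param n_relapse,n_control Group sizes (>= 2; default 19/19, the matched
#'   design).
#' @param alpha Two-sided significance level (default 0.05).
#' @return A one-row tibble of class `power_result`: the inputs plus
#'   `noncentrality`, `df`, `critical_t`, `power`.
#' @examples
#' welch_power(1, 1, 1, 10, 10) # approx 0.56
#' @export
welch_power <- function(mean_diff, sd_relapse, sd_control,
                        n_relapse = 19, n_control = 19, alpha = 0.05) {
  stopifnot(
    sd_relapse > 0, sd_control > 0, n_relapse >= 2, n_control >= 2,
    alpha > 0, alpha < 1
  )
  v1 <- sd_relapse^2 / n_relapse
  v2 <- sd_control^2 / n_control
  se <- sqrt(v1 + v2)
  ncp <- mean_diff / se
  df <- (v1 + v2)^2 / (v1^2 / (n_relapse - 1) + v2^2 / (n_control - 1))
  t_crit <- qt(1 - alpha / 2, df)
  power <- pt(-t_crit, df, ncp) + pt(t_crit, df, ncp, lower.tail = FALSE)
  structure(
    tibble(
      mean_diff = mean_diff, sd_relapse = sd_relapse,
      sd_control = sd_control, n_relapse = n_relapse,
      n_control = n_control, alpha = alpha,
      noncentrality = ncp, df = df, critical_t = t_crit, power = power
    ),
    class = c("power_result", class(tibble()))
  )
}

#' Observed power of a gene panel and its members
#'
#' Computes each sample's average normalized log2 ratio over the panel
#' genes, takes the observed group mean difference and group standard
#' deviations of that average, and feeds them to [welch_power()]. Per-gene
#' power is computed the same way from each gene's own values and flagged
#' against the adequacy threshold.
#'
#' @param matrix A `meth_matrix`.
#' @param labels Sample labels (see [differential_table()]).
#' @param panel Panel genes.
#' @param alpha Two-sided significance level (default 0.05).
#' @param power_threshold Adequacy flag threshold (default 0.8).
#' @return A tibble of class `power_result` with one row for the panel
#'   average (`scope = "panel"`) and one per gene, each carrying the
#'   observed `mean_diff`, group sds, group sizes, `power` and `adequate`.
#' @export
panel_power <- function(matrix, labels, panel, alpha = 0.05,
                        power_threshold = 0.8) {
  labels <- normalize_labels(labels)
  x <- as_sample_matrix(matrix, panel)
  y <- unname(labels[rownames(x)])
  one <- function(scope, v) {
    v1 <- v[y == .POS & !is.na(v)]
    v2 <- v[y == .NEG & !is.na(v)]
    if (length(v1) < 2 || length(v2) < 2) {
      abort(paste("fewer than 2 usable values per group for", scope))
    }
    pw <- welch_power(
      mean_diff = mean(v1) - mean(v2),
      sd_relapse = sd(v1), sd_control = sd(v2),
      n_relapse = length(v1), n_control = length(v2), alpha = alpha
    )
    mutate(as_tibble(pw), scope = scope, .before = 1L)
  }
  rows <- bind_rows(
    one("panel", rowMeans(x, na.rm = TRUE)),
    bind_rows(lapply(panel, function(g) one(g, x[, g])))
  )
  structure(
    mutate(rows, adequate = .data$power >= power_threshold),
    class = c("power_result", class(tibble()))
  )
}
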