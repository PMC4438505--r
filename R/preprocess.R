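# Spot-level QC and normalization. Per slide:
#   1. background per channel and subarray = mean foreground of that
#      subarray's empty spots, subtracted and floored at a small epsilon;
#   2. a spot is informative iff it is unflagged and BOTH channels'
#      background-subtracted signals reach `control_multiplier` (default 2)
#      times the slide-level mean of the hybridization-control spots for
#      that channel (the nonspecific-binding floor);
#   3. a gene needs at least `min_informative` (default 2) of its 3
#      replicate spots, else it is missing for the sample; otherwise its
#      value is the mean over informative spots of R = control/test, plus
#      the mean log-intensity A = mean(log2(control * test)) / 2 used by the
#      lowess fit.
# Boundary semantics: signals exactly at the floor pass ("< 2x" removes).

#' Summarize one sample's slide to per-gene ratios
#'
#' Applies background subtraction, the informativeness filter and
#' replicate-spot summarization to a single sample's spot table.
#'
#' @param spots Spot tibble for one sample.
#' @param control_multiplier Informativeness floor as a multiple of the mean
#'   hybridization-control signal (default 2).
#' @param min_informative Minimum informative replicate spots per gene
#'   (default 2).
#' @param eps Positive floor applied to background-subtracted signals.
#' @return A tibble with one row per gene probe plus one row for the pooled
#'   positive-control spots (`gene_id = ".pos_ctrl"`): `role`, `gene_id`,
#'   `ratio` (mean control/test over informative spots, `NA` if missing),
#'   `a_value` (mean log2 control-channel intensity, the abscissa of the
#'   lowess fit), `n_informative`. The positive-control row anchors the
#'   normalization level in [build_matrix()]: those spots carry full signal
#'   in both channels, so their expected log-ratio is zero.
#'
#' @details The intensity axis used for lowess is the mock-digested
#'   (control) channel rather than the conventional two-channel average A:
#'   in this assay the test channel is proportional to the methylated
#'   fraction, so an abscissa containing it would follow the biology and
#'   the fit would absorb genuine group differences. The control channel
#'   measures template abundance independently of methylation.
#' @export
preprocess_sample <- function(spots, control_multiplier = 2,
                              min_informative = 2, eps = 1) {
  stopifnot(control_multiplier >= 0, min_informative >= 1, eps > 0)
  if ("sample_id" %in% names(spots) &&
    length(unique(spots$sample_id)) > 1) {
    abort("`spots` must contain a single sample; see preprocess_cohort()")
  }
  empties <- spots[spots$role == "empty" & spots$flag == "ok", ]
  if (nrow(empties) == 0) {
    abort("processing error: no usable empty (background) spots on slide")
  }
  bg <- empties %>%
    group_by(.data$subarray) %>%
    summarise(
      bg_t = mean(.data$fg_test), bg_c = mean(.data$fg_control),
      .groups = "drop"
    )
  # subarrays whose empties all dropped out inherit the slide mean
  slide_bg_t <- mean(bg$bg_t)
  slide_bg_c <- mean(bg$bg_c)
  all_sub <- tibble(subarray = unique(spots$subarray))
  bg <- left_join(all_sub, bg, by = "subarray") %>%
    mutate(
      bg_t = ifelse(is.na(.data$bg_t), slide_bg_t, .data$bg_t),
      bg_c = ifelse(is.na(.data$bg_c), slide_bg_c, .data$bg_c)
    )
  net <- spots %>%
    left_join(bg, by = "subarray") %>%
    mutate(
      net_t = pmax(.data$fg_test - .data$bg_t, eps),
      net_c = pmax(.data$fg_control - .data$bg_c, eps)
    )
  hyb <- net[net$role == "hybridization_control" & net$flag == "ok", ]
  if (nrow(hyb) == 0) {
    abort("processing error: no usable hybridization-control spots on slide")
  }
  floor_t <- control_multiplier * mean(hyb$net_t)
  floor_c <- control_multiplier * mean(hyb$net_c)
  probes <- net[net$role %in% c("gene_probe", "positive_control"), ] %>%
    mutate(
      gene_id = ifelse(.data$role == "positive_control",
        ".pos_ctrl", .data$gene_id
      ),
      informative = .data$flag == "ok" &
        .data$net_t >= floor_t & .data$net_c >= floor_c
    )
  probes %>%
    group_by(.data$role, .data$gene_id) %>%
    summarise(
      n_informative = sum(.data$informative),
      ratio = ifelse(n_informative >= min_informative,
        mean(.data$net_c[.data$informative] / .data$net_t[.data$informative]),
        NA_real_
      ),
      a_value = ifelse(n_informative >= min_informative,
        mean(log2(.data$net_c[.data$informative])),
        NA_real_
      ),
      .groups = "drop"
    ) %>%
    select(all_of(c("role", "gene_id", "ratio", "a_value", "n_informative")))
}

#' Summarize every sample of a cohort
#'
#' @param cohort A `meth_cohort` (or any list with `spots` carrying a
#'   `sample_id` column).
#' @inheritParams preprocess_sample
#' @return A tibble with columns `sample_id`, `gene_id`, `ratio`,
#'   `a_value`, `n_informative`.
#' @export
preprocess_cohort <- function(cohort, control_multiplier = 2,
                              min_informative = 2, eps = 1) {
  spots <- if (is.data.frame(cohort)) cohort else cohort$spots
  spots %>%
    group_by(.data$sample_id) %>%
    group_split() %>%
    lapply(function(s) {
      mutate(
        preprocess_sample(s, control_multiplier, min_informative, eps),
        sample_id = s$sample_id[1], .before = 1L
      )
    }) %>%
    bind_rows()
}

#' Assemble the normalized methylation matrix
#'
#' Log2-transforms the per-gene ratios, removes intensity-dependent bias by
#' subtracting a per-sample lowess fit of M = log2(R) on the intensity axis,
#' anchors the fitted curve at the positive-control spots (expected
#' log-ratio zero) so a genuine global methylation shift is not absorbed,
#' drops genes missing in strictly more than `max_missing_frac` of samples,
#' and returns the long gene-by-sample table with the missing mask
#' preserved.
#'
#' @param summaries Per-sample gene summaries from [preprocess_cohort()].
#' @param max_missing_frac Genes missing in strictly more than this fraction
#'   of samples are dropped (default 0.25).
#' @param span Lowess span (default 2/3, the classic lowess default; with
#'   only 56 genes per sample smaller spans overfit biological scatter).
#' @param iter Lowess robustifying iterations (default 3). Robust
#'   reweighting keeps strongly shifted probes from dragging the local fit;
#'   the level bias it could otherwise introduce on arrays where many
#'   probes shift is removed by the positive-control anchor.
#' @param min_fit_points Below this many observed genes the per-sample fit
#'   degenerates to subtracting the median M (default 10).
#' @return A tibble of class `meth_matrix` with columns `gene_id`,
#'   `sample_id`, `log2_ratio` (`NA` = missing), `call` (unset until
#'   [categorize_calls()]); per-sample pre/post fit diagnostics in
#'   `attr(, "diagnostics")`.
#' @export
build_matrix <- function(summaries, max_missing_frac = 0.25,
                         span = 2 / 3, iter = 3, min_fit_points = 10) {
  stopifnot(max_missing_frac >= 0, max_missing_frac <= 1, span > 0)
  samples <- unique(summaries$sample_id)
  if (length(samples) < 2) abort("need at least 2 samples")
  if (!"role" %in% names(summaries)) {
    summaries <- mutate(summaries, role = "gene_probe")
  }
  per_sample <- summaries %>%
    group_by(.data$sample_id) %>%
    group_split() %>%
    lapply(function(s) {
      g <- s[s$role == "gene_probe", ]
      ctl <- s[s$role == "positive_control" & !is.na(s$ratio), ]
      obs <- !is.na(g$ratio)
      if (!any(obs)) {
        warn(paste("sample", s$sample_id[1], "has no usable genes; excluded"))
        return(NULL)
      }
      m <- log2(g$ratio)
      a <- g$a_value
      if (sum(obs) < min_fit_points) {
        fitat <- function(x) rep(median(m[obs]), length(x))
      } else {
        lw <- lowess(a[obs], m[obs], f = span, iter = iter)
        fitat <- function(x) approx(lw$x, lw$y, xout = x, rule = 2,
          ties = mean)$y
      }
      fit <- fitat(a)
      # positive controls carry full template in both channels, so their
      # log-ratio is zero by design; anchoring the fitted curve at them
      # stops the fit from absorbing a genuine global methylation shift
      offset <- if (nrow(ctl) > 0) {
        mean(log2(ctl$ratio) - fitat(ctl$a_value))
      } else {
        0
      }
      tibble(
        sample_id = s$sample_id[1], gene_id = g$gene_id,
        a_value = a, m_raw = m, m_fit = fit + offset,
        m_norm = m - fit - offset
      )
    }) %>%
    bind_rows()
  keep <- per_sample %>%
    group_by(.data$gene_id) %>%
    summarise(miss = mean(is.na(.data$m_norm)), .groups = "drop") %>%
    filter(.data$miss <= max_missing_frac)
  mm <- per_sample %>%
    filter(.data$gene_id %in% keep$gene_id) %>%
    transmute(
      gene_id = .data$gene_id, sample_id = .data$sample_id,
      log2_ratio = .data$m_norm, call = NA_character_
    )
  new_meth_matrix(mm, diagnostics = per_sample)
}

new_meth_matrix <- function(mm, diagnostics = NULL) {
  structure(
    as_tibble(mm),
    diagnostics = diagnostics,
    class = c("meth_matrix", class(as_tibble(mm)))
  )
}

#' Binary methylation calls
#'
#' Categorizes each entry as methylated or unmethylated. Under the
#' digestion model the analysis ratio is control/test, so retained
#' test-channel signal (methylation) drives log2 ratios down: entries at or
#' below `-threshold_log2` are called methylated, at or above
#' `+threshold_log2` unmethylated, and entries in between take the nearer
#' category (ties at 0 go to unmethylated). Missing entries stay missing.
#'
#' @param matrix A `meth_matrix`.
#' @param threshold_log2 Log2 call threshold (default 1, i.e. 2-fold).
#' @return The `meth_matrix` with its `call` column filled
#'   (`"methylated"`, `"unmethylated"` or `"missing"`).
#' @export
categorize_calls <- function(matrix, threshold_log2 = 1) {
  stopifnot(threshold_log2 >= 0)
  mm <- matrix %>%
    mutate(call = case_when(
      is.na(.data$log2_ratio) ~ "missing",
      .data$log2_ratio <= -threshold_log2 ~ "methylated",
      .data$log2_ratio >= threshold_log2 ~ "unmethylated",
      .data$log2_ratio < 0 ~ "methylated",
      TRUE ~ "unmethylated"
    ))
  new_meth_matrix(mm, diagnostics = attr(matrix, "diagnostics"))
}

#' Median-impute missing entries per gene
#'
#' Downstream classifiers need a complete matrix; clustering keeps the mask.
#'
#' @param matrix A `meth_matrix`.
#' @return The matrix with `log2_ratio` imputed by each gene's median
#'   (0 where a gene is entirely missing).
#' @export
impute_missing <- function(matrix) {
  mm <- matrix %>%
    group_by(.data$gene_id) %>%
    mutate(log2_ratio = ifelse(is.na(.data$log2_ratio),
      median(.data$log2_ratio, na.rm = TRUE), .data$log2_ratio
    )) %>%
    ungroup() %>%
    mutate(log2_ratio = ifelse(is.na(.data$log2_ratio), 0, .data$log2_ratio))
  new_meth_matrix(mm, diagnostics = attr(matrix, "diagnostics"))
}

#' Sample-by-gene value matrix
#'
#' @param matrix A `meth_matrix` (long).
#' @param genes Optional probe subset (order preserved).
#' @return A numeric matrix, samples in rows, genes in columns.
#' @export
as_sample_matrix <- function(matrix, genes = NULL) {
  wide <- matrix %>%
    select(all_of(c("gene_id", "sample_id", "log2_ratio"))) %>%
    pivot_wider(names_from = "gene_id", values_from = "log2_ratio")
  out <- as.matrix(wide[-1])
  rownames(out) <- wide$sample_id
  if (!is.null(genes)) {
    missing_genes <- setdiff(genes, colnames(out))
    if (length(missing_genes) > 0) {
      abort(paste("genes absent from matrix:", toString(missing_genes)))
    }
    out <- out[, genes, drop = FALSE]
  }
  out
}

#' Export a methylation matrix as a tab-delimited table
#'
#' Genes in rows, samples in columns, `NA` for missing entries.
#'
#' @param matrix A `meth_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(matrix, path) {
  wide <- matrix %>%
    select(all_of(c("gene_id", "sample_id", "log2_ratio"))) %>%
    pivot_wider(names_from = "sample_id", values_from = "log2_ratio")
  write_tsv(wide, path, na = "NA")
  invisible(path)
}

#' MA diagnostic plot of the per-sample lowess fits
#'
#' @param matrix A `meth_matrix` built by [build_matrix()].
#' @param samples Optional sample ids to show (default: first 6).
#' @return A ggplot.
#' @export
plot_ma <- function(matrix, samples = NULL) {
  d <- attr(matrix, "diagnostics")
  if (is.null(d)) abort("matrix carries no diagnostics")
  if (is.null(samples)) samples <- head(unique(d$sample_id), 6)
  d <- filter(d, .data$sample_id %in% samples, !is.na(.data$m_raw))
  ggplot(d, aes(x = .data$a_value)) +
    geom_point(aes(y = .data$m_raw), alpha = 0.5, size = 0.8) +
    geom_line(aes(y = .data$m_fit), colour = "red") +
    geom_point(aes(y = .data$m_norm), alpha = 0.5, size = 0.8,
      colour = "blue") +
    facet_wrap(~sample_id) +
    labs(
      x = "A (mean log2 intensity)", y = "M (log2 control/test)",
      title = "Per-sample lowess normalization",
      subtitle = "black: raw M, red: lowess fit, blue: normalized M"
    )
}
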