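# Independent oracles and small fixture builders used across the suite.

# AUC by exhaustive pair counting (ties count 1/2)
brute_force_auc <- function(scores, y01) {
  pos <- scores[y01 == 1]
  neg <- scores[y01 == 0]
  tot <- 0
  for (p in pos) {
    for (q in neg) {
      tot <- tot + (p > q) + 0.5 * (p == q)
    }
  }
  tot / (length(pos) * length(neg))
}

# brute-force centroid-linkage agglomeration on complete data: at every step
# merge the two clusters whose centroids are closest (squared euclidean);
# returns the sets merged at each step and the squared merge heights
centroid_oracle <- function(x) {
  clusters <- lapply(seq_len(nrow(x)), identity)
  merges <- list()
  heights <- numeric()
  while (length(clusters) > 1) {
    cents <- t(vapply(clusters, function(ix) {
      colMeans(x[ix, , drop = FALSE])
    }, numeric(ncol(x))))
    best <- c(NA, NA)
    bestd <- Inf
    for (i in seq_len(length(clusters) - 1)) {
      for (j in (i + 1):length(clusters)) {
        d <- sum((cents[i, ] - cents[j, ])^2)
        if (d < bestd) {
          bestd <- d
          best <- c(i, j)
        }
      }
    }
    merges[[length(merges) + 1]] <-
      sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    heights <- c(heights, bestd)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  list(merges = merges, heights = heights)
}

# extract the member sets merged at each hclust step
hclust_merge_sets <- function(hc) {
  n <- length(hc$height)
  sets <- vector("list", n)
  members <- function(k) {
    if (k < 0) {
      return(-k)
    }
    sets[[k]]
  }
  for (i in seq_len(n)) {
    sets[[i]] <- sort(c(members(hc$merge[i, 1]), members(hc$merge[i, 2])))
  }
  sets
}

# Monte-Carlo rejection rate of the two-sided Welch t-test
mc_welch_power <- function(mean_diff, sd1, sd2, n1, n2, alpha = 0.05,
                           reps = 1e5) {
  m1 <- stats::rnorm(reps, mean_diff, sd1 / sqrt(n1))
  m2 <- stats::rnorm(reps, 0, sd2 / sqrt(n2))
  v1 <- sd1^2 * stats::rchisq(reps, n1 - 1) / (n1 - 1)
  v2 <- sd2^2 * stats::rchisq(reps, n2 - 1) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  mean(abs(tstat) > stats::qt(1 - alpha / 2, df))
}

# long meth_matrix tibble from a genes x samples value matrix
make_mm <- function(values) {
  stopifnot(!is.null(rownames(values)), !is.null(colnames(values)))
  tibble::tibble(
    gene_id = rep(rownames(values), times = ncol(values)),
    sample_id = rep(colnames(values), each = nrow(values)),
    log2_ratio = as.vector(values),
    call = NA_character_
  )
}

# matrix-level gaussian cohort: n1 relapse / n2 control samples,
# `effects` named vector of group mean differences, `n_null` extra nulls
sim_mm <- function(n1, n2, effects = c(), n_null = 10, sd = 1) {
  genes <- c(names(effects), sprintf("null%02d", seq_len(n_null)))
  eff <- c(effects, rep(0, n_null))
  n <- n1 + n2
  lab <- rep(c("relapse", "control"), c(n1, n2))
  vals <- matrix(stats::rnorm(length(genes) * n, 0, sd),
    nrow = length(genes),
    dimnames = list(genes, sprintf("S%03d", seq_len(n)))
  )
  vals <- vals + outer(eff, as.numeric(lab == "relapse"))
  list(
    mm = make_mm(vals),
    labels = tibble::tibble(
      sample_id = colnames(vals),
      label = lab
    )
  )
}

# small 2-subarray toy layout spots table for QC unit tests: genes get 3
# replicate spots like the real design
toy_spots <- function(gene_vals_test, gene_vals_control,
                      hyb = 100, empty = 50, flag_dropout = character()) {
  genes <- names(gene_vals_test)
  rows <- list()
  k <- 0
  for (b in 0:2) {
    k <- k + 1
    rows[[k]] <- tibble::tibble(
      subarray = b, row = 0, col = 0, role = "empty",
      gene_id = NA_character_,
      fg_test = empty, bg_test = 0, fg_control = empty, bg_control = 0
    )
    k <- k + 1
    rows[[k]] <- tibble::tibble(
      subarray = b, row = 0, col = 1, role = "hybridization_control",
      gene_id = NA_character_,
      fg_test = empty + hyb, bg_test = 0,
      fg_control = empty + hyb, bg_control = 0
    )
    for (gi in seq_along(genes)) {
      k <- k + 1
      rows[[k]] <- tibble::tibble(
        subarray = b, row = 1 + (gi - 1) %/% 8, col = (gi - 1) %% 8,
        role = "gene_probe", gene_id = genes[gi],
        fg_test = empty + gene_vals_test[[gi]][b + 1], bg_test = 0,
        fg_control = empty + gene_vals_control[[gi]][b + 1], bg_control = 0
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  out$flag <- ifelse(
    paste(out$gene_id, out$subarray) %in% flag_dropout, "dropout", "ok"
  )
  out
}
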