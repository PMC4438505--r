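# Unsupervised hierarchical clustering of samples on the selected panel and
# concordance of the top two branches with outcome. Values are
# median-centred per gene; missing entries are excluded pairwise from the
# euclidean distances, each pair's squared distance being rescaled by
# (total genes / observed genes) to keep distances comparable. Centroid
# linkage is applied to the squared distances (the convention of
# stats::hclust); centroid linkage can produce height inversions, which are
# permitted and counted rather than silently repaired.

#' Hierarchical clustering and branch-outcome concordance
#'
#' Clusters samples on the panel genes with euclidean distance and centroid
#' linkage, splits the dendrogram into its two top-level branches, and
#' cross-tabulates branch membership against the outcome labels. Samples
#' are ordered lexicographically by id before clustering so the result does
#' not depend on input order.
#'
#' @param matrix A `meth_matrix` (missing values allowed; the mask is used,
#'   not imputed).
#' @param labels Sample labels (see [differential_table()]).
#' @param panel Panel genes to cluster on.
#' @return A list of class `cluster_report`:
#'   \describe{
#'     \item{hclust}{the `stats::hclust` tree (heights on the squared-
#'       distance scale)}
#'     \item{branches}{tibble `sample_id`, `label`, `branch`
#'       (`"left"`/`"right"`)}
#'     \item{concordance}{per-branch relapse / control counts}
#'     \item{inversions}{number of non-monotone merge heights}
#'     \item{excluded}{ids of all-missing samples dropped with a warning}
#'   }
#' @export
cluster_and_concordance <- function(matrix, labels, panel) {
  labels <- normalize_labels(labels)
  x <- as_sample_matrix(matrix, panel)
  x <- x[order(rownames(x)), , drop = FALSE]
  all_missing <- rowSums(!is.na(x)) == 0
  excluded <- rownames(x)[all_missing]
  if (length(excluded) > 0) {
    warn(paste("excluding all-missing sample(s):", toString(excluded)))
    x <- x[!all_missing, , drop = FALSE]
  }
  if (nrow(x) < 2) abort("need at least 2 usable samples")
  x <- sweep(x, 2, apply(x, 2, median, na.rm = TRUE))
  d2 <- pairwise_sqdist(x)
  hc <- hclust(as.dist(d2), method = "centroid")
  hc$labels <- rownames(x)
  inv <- sum(diff(hc$height) < 0)
  grp <- cutree(hc, k = 2)
  # the branch holding the leftmost leaf of the dendrogram is "left"
  left_id <- grp[hc$labels[hc$order[1]]]
  branches <- tibble(
    sample_id = names(grp),
    label = unname(labels[names(grp)]),
    branch = ifelse(grp == left_id, "left", "right")
  )
  concordance <- branches %>%
    count(.data$branch, .data$label) %>%
    pivot_wider(
      names_from = "label", values_from = "n",
      values_fill = 0L
    )
  structure(
    list(
      hclust = hc, branches = branches, concordance = concordance,
      inversions = inv, excluded = excluded
    ),
    class = "cluster_report"
  )
}

# pairwise-complete squared euclidean distances, scaled by
# p / (observed dimensions) per pair
pairwise_sqdist <- function(x) {
  n <- nrow(x)
  p <- ncol(x)
  obs <- !is.na(x)
  x0 <- x
  x0[!obs] <- 0
  d2 <- matrix(0, n, n, dimnames = list(rownames(x), rownames(x)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      o <- obs[i, ] & obs[j, ]
      m <- sum(o)
      if (m == 0) {
        abort(sprintf(
          "samples %s and %s share no observed genes",
          rownames(x)[i], rownames(x)[j]
        ))
      }
      d2[i, j] <- d2[j, i] <- sum((x0[i, o] - x0[j, o])^2) * p / m
    }
  }
  d2
}

#' @export
print.cluster_report <- function(x, ...) {
  cat(sprintf(
    "<cluster_report> %d samples, %d height inversion(s)\n",
    length(x$branches$sample_id), x$inversions
  ))
  print(x$concordance)
  invisible(x)
}

#' Tidy a cluster report
#'
#' @param x A `cluster_report`.
#' @param ... Unused.
#' @return The per-sample branch assignment tibble.
#' @export
tidy.cluster_report <- function(x, ...) x$branches

#' Glance at a cluster report
#'
#' @param x A `cluster_report`.
#' @param ... Unused.
#' @return One row: sample count, majority-branch purity for each label,
#'   inversion count.
#' @export
glance.cluster_report <- function(x, ...) {
  b <- x$branches
  purity <- function(lab) {
    n_lab <- sum(b$label == lab)
    if (n_lab == 0) {
      return(NA_real_)
    }
    max(table(b$branch[b$label == lab])) / n_lab
  }
  tibble(
    n = nrow(b),
    relapse_purity = purity(.POS),
    control_purity = purity(.NEG),
    inversions = x$inversions
  )
}

#' Export the sample dendrogram as newick
#'
#' Centroid linkage may produce height inversions that newick cannot
#' represent; heights are made monotone (running maximum) for export only.
#'
#' @param report A `cluster_report`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(report, path) {
  hc <- report$hclust
  hc$height <- cummax(hc$height)
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}
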