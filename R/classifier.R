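# Cross-validated comparison of six classifier families, PLS-VIP panel
# selection and panel/per-gene accuracy evaluation. Model families follow
# the procedures named in the source workflow, mapped to their closest
# standard R implementations: PLS discriminant (in-package), k-nearest
# neighbours (class::knn, k = 3), logistic regression (glm), linear
# discriminant analysis (MASS::lda), a single classification tree (rpart),
# and forward stepwise logistic selection by AIC ("general linear model
# selection", stats::step).

.FAMILIES <- c("pls", "knn", "logistic", "discriminant", "tree",
               "glm_forward")

#' Rank-based AUC
#'
#' Area under the ROC curve by the Mann-Whitney construction: the
#' probability that a random positive outscores a random negative, counting
#' ties as 1/2.
#'
#' @param scores Numeric classifier scores (larger = more positive).
#' @param y Labels (`"relapse"`/`"control"`, factor, or 0/1).
#' @return AUC in \[0, 1\].
#' @export
auc_rank <- function(scores, y) {
  y01 <- to_binary(y)
  n_pos <- sum(y01 == 1)
  n_neg <- sum(y01 == 0)
  if (n_pos == 0 || n_neg == 0) {
    return(NA_real_)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[y01 == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# stratified k-fold assignment; every class is shuffled then dealt
# round-robin so each training fold keeps both classes. Uses the current
# RNG stream (callers seed per run).
stratified_folds <- function(y01, k) {
  fold <- integer(length(y01))
  for (cls in unique(y01)) {
    idx <- sample(which(y01 == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# fit one family on training rows and score the test rows
score_family <- function(family, x_tr, y_tr, x_te) {
  df_tr <- data.frame(x_tr, check.names = FALSE)
  df_tr$.y <- factor(y_tr, levels = c(0, 1))
  df_te <- data.frame(x_te, check.names = FALSE)
  switch(family,
    pls = {
      fit <- pls_fit(x_tr, y_tr, ncomp = 2)
      predict(fit, x_te)
    },
    knn = {
      pr <- class::knn(x_tr, x_te, factor(y_tr), k = 3, prob = TRUE)
      p_win <- attr(pr, "prob")
      ifelse(pr == "1", p_win, 1 - p_win)
    },
    logistic = {
      fit <- suppressWarnings(glm(.y ~ ., data = df_tr, family = binomial()))
      suppressWarnings(predict(fit, df_te, type = "response"))
    },
    discriminant = {
      fit <- suppressWarnings(MASS::lda(.y ~ ., data = df_tr))
      predict(fit, df_te)$posterior[, "1"]
    },
    tree = {
      fit <- rpart::rpart(.y ~ .,
        data = df_tr, method = "class",
        control = rpart::rpart.control(minsplit = 5, cp = 0.01)
      )
      predict(fit, df_te, type = "prob")[, "1"]
    },
    glm_forward = {
      null_fit <- suppressWarnings(
        glm(.y ~ 1, data = df_tr, family = binomial())
      )
      scope <- as.formula(paste(
        "~", paste0("`", colnames(x_tr), "`", collapse = " + ")
      ))
      fit <- suppressWarnings(step(null_fit,
        scope = list(lower = ~1, upper = scope),
        direction = "forward", trace = 0, steps = 8
      ))
      suppressWarnings(predict(fit, df_te, type = "response"))
    },
    abort(paste("unknown model family:", family))
  )
}

#' Cross-validated comparison of classifier families
#'
#' Runs stratified k-fold cross-validation `runs` times for each model
#' family; per run, out-of-fold scores are pooled into a single AUC. The
#' best family is the one with the highest mean AUC across runs (ties
#' broken by the order of `families`). Deterministic given `seed`.
#'
#' @param matrix A complete (imputed) `meth_matrix`.
#' @param labels Sample labels (see [differential_table()]).
#' @param genes Candidate genes to model (default: all genes in the
#'   matrix).
#' @param families Model families to compare (default: all six).
#' @param k Folds (default 5).
#' @param runs Repetitions with re-shuffled folds (default 10).
#' @param seed Master seed for fold shuffling.
#' @return A tibble of class `cv_models` with columns `family`, `run`,
#'   `auc`; the per-family summary in `attr(, "summary")` and the winning
#'   family in `attr(, "best")`.
#' @export
cross_validate_models <- function(matrix, labels, genes = NULL,
                                  families = .FAMILIES,
                                  k = 5, runs = 10, seed = 1L) {
  stopifnot(all(families %in% .FAMILIES), k >= 2, runs >= 1)
  x <- as_sample_matrix(matrix, genes)
  if (anyNA(x)) abort("matrix has missing values; impute_missing() first")
  labels <- normalize_labels(labels)
  y01 <- to_binary(unname(labels[rownames(x)]))
  if (length(unique(y01)) < 2) abort("both classes must be present")
  run_seeds <- with_seed(seed, sample.int(2^31 - 2, runs))
  out <- list()
  for (r in seq_len(runs)) {
    out[[r]] <- with_seed(run_seeds[r], {
      fold <- stratified_folds(y01, k)
      scores <- numeric(length(y01))
      rows <- list()
      for (fam in families) {
        for (f in seq_len(k)) {
          te <- fold == f
          scores[te] <- score_family(
            fam, x[!te, , drop = FALSE], y01[!te], x[te, , drop = FALSE]
          )
        }
        rows[[fam]] <- tibble(
          family = fam, run = r, auc = auc_rank(scores, y01)
        )
      }
      bind_rows(rows)
    })
  }
  res <- bind_rows(out)
  summ <- res %>%
    group_by(.data$family) %>%
    summarise(
      auc_mean = mean(.data$auc), auc_sd = sd(.data$auc),
      .groups = "drop"
    ) %>%
    arrange(match(.data$family, families))
  best <- summ$family[which.max(summ$auc_mean)]
  structure(res,
    summary = summ, best = best,
    fold_scheme = list(k = k, runs = runs, seed = seed),
    class = c("cv_models", class(res))
  )
}

#' @export
print.cv_models <- function(x, ...) {
  cat("<cv_models> mean out-of-fold AUC by family\n")
  print(attr(x, "summary"))
  cat("best family:", attr(x, "best"), "\n")
  invisible(x)
}

#' Tidy a model-comparison result
#'
#' @param x A `cv_models` object.
#' @param ... Unused.
#' @return Per-family mean and sd of the run AUCs.
#' @export
tidy.cv_models <- function(x, ...) attr(x, "summary")

#' Glance at a model-comparison result
#'
#' @param x A `cv_models` object.
#' @param ... Unused.
#' @return One row: best family, its mean AUC, folds and runs.
#' @export
glance.cv_models <- function(x, ...) {
  summ <- attr(x, "summary")
  best <- attr(x, "best")
  scheme <- attr(x, "fold_scheme")
  tibble(
    best_family = best,
    auc_mean = summ$auc_mean[summ$family == best],
    k = scheme$k, runs = scheme$runs
  )
}

#' PLS-VIP gene ranking and panel selection
#'
#' Fits the PLS discriminant model on each cross-validation training fold
#' (`k` folds times `runs` repetitions), averages each gene's VIP score
#' over the fits and selects the panel as the genes with mean VIP above
#' `vip_min` (default 1, the conventional VIP rule); alternatively the top
#' `top_k` genes.
#'
#' @inheritParams cross_validate_models
#' @param candidates Candidate gene set (>= 2 genes), typically the
#'   differential-screen survivors.
#' @param vip_min Selection threshold on the mean VIP (default 1.0).
#' @param top_k If given, select the `top_k` highest-VIP genes instead.
#' @param ncomp PLS components (default 2).
#' @return A tibble of class `gene_ranking` with columns `gene_id`, `vip`
#'   (mean over fits) and `selected`; the selected panel in
#'   `attr(, "panel")`.
#' @export
rank_and_select_panel <- function(matrix, labels, candidates,
                                  vip_min = 1.0, top_k = NULL,
                                  k = 5, runs = 10, seed = 1L, ncomp = 2) {
  candidates <- unique(as.character(candidates))
  if (length(candidates) < 2) abort("need at least 2 candidate genes")
  x <- as_sample_matrix(matrix, candidates)
  if (anyNA(x)) abort("matrix has missing values; impute_missing() first")
  labels <- normalize_labels(labels)
  y01 <- to_binary(unname(labels[rownames(x)]))
  run_seeds <- with_seed(seed, sample.int(2^31 - 2, runs))
  vip_sum <- numeric(length(candidates))
  n_fits <- 0L
  for (r in seq_len(runs)) {
    fold <- with_seed(run_seeds[r], stratified_folds(y01, k))
    for (f in seq_len(k)) {
      tr <- fold != f
      fit <- pls_fit(x[tr, , drop = FALSE], y01[tr], ncomp = ncomp)
      vip_sum <- vip_sum + fit$vip[candidates]
      n_fits <- n_fits + 1L
    }
  }
  vip_mean <- vip_sum / n_fits
  ranking <- tibble(gene_id = candidates, vip = unname(vip_mean)) %>%
    arrange(desc(.data$vip))
  if (!is.null(top_k)) {
    ranking$selected <- seq_len(nrow(ranking)) <= top_k
  } else {
    ranking$selected <- ranking$vip > vip_min
  }
  structure(ranking,
    panel = ranking$gene_id[ranking$selected],
    rule = if (is.null(top_k)) paste0("vip>", vip_min) else paste0("top", top_k),
    class = c("gene_ranking", class(ranking))
  )
}

#' @export
print.gene_ranking <- function(x, ...) {
  cat(
    "<gene_ranking> rule", attr(x, "rule"), "-> panel:",
    toString(attr(x, "panel")), "\n"
  )
  NextMethod()
}

confusion_metrics <- function(scores, y01, threshold) {
  pred <- as.numeric(scores >= threshold)
  tp <- sum(pred == 1 & y01 == 1)
  fp <- sum(pred == 1 & y01 == 0)
  tn <- sum(pred == 0 & y01 == 0)
  fn <- sum(pred == 0 & y01 == 1)
  safe_div <- function(a, b) if (b == 0) NA_real_ else a / b
  tibble(
    tp = tp, fp = fp, tn = tn, fn = fn,
    sensitivity = safe_div(tp, tp + fn),
    specificity = safe_div(tn, tn + fp),
    ppv = safe_div(tp, tp + fp),
    npv = safe_div(tn, tn + fn)
  )
}

# threshold maximizing Youden's J over midpoints of adjacent distinct
# scores (plus outer sentinels); ties -> higher threshold
youden_threshold <- function(scores, y01) {
  s <- sort(unique(scores))
  cand <- c(
    s[1] - 1,
    if (length(s) > 1) (s[-1] + s[-length(s)]) / 2 else numeric(),
    s[length(s)] + 1
  )
  j <- vapply(cand, function(th) {
    m <- confusion_metrics(scores, y01, th)
    sens <- ifelse(is.na(m$sensitivity), 0, m$sensitivity)
    spec <- ifelse(is.na(m$specificity), 0, m$specificity)
    sens + spec - 1
  }, numeric(1))
  cand[max(which(j == max(j)))]
}

roc_points <- function(scores, y01) {
  ths <- c(Inf, sort(unique(scores), decreasing = TRUE))
  pts <- lapply(ths, function(th) {
    m <- confusion_metrics(scores, y01, th)
    tibble(
      threshold = th,
      fpr = ifelse(is.na(m$specificity), 0, 1 - m$specificity),
      tpr = ifelse(is.na(m$sensitivity), 0, m$sensitivity)
    )
  })
  out <- bind_rows(pts)
  structure(out, class = c("meth_roc", class(out)))
}

#' Evaluate a gene panel as a binary classifier
#'
#' Fits the PLS discriminant model on the panel and reports confusion
#' counts, sensitivity, specificity, PPV, NPV and AUC. Two evaluation
#' modes: `"resubstitution"` (whole-model fit: train and score on all
#' samples, the optimistic headline figure) and `"cross_validated"`
#' (metrics from out-of-fold scores, averaged over `runs` repetitions of
#' stratified k-fold CV). The score threshold maximizes Youden's J on the
#' scores being evaluated.
#'
#' @inheritParams cross_validate_models
#' @param panel Non-empty character vector of panel genes.
#' @param mode `"resubstitution"` or `"cross_validated"`.
#' @param ncomp PLS components (default 2).
#' @return A one-row tibble of class `panel_metrics`: `scope`,
#'   `evaluation`, confusion counts (averaged over runs under CV),
#'   `sensitivity`, `specificity`, `ppv`, `npv`, `auc`, `threshold`.
#'   Undefined ratios are `NA`. ROC coordinates (of the resubstitution or
#'   first-run scores) are attached as `attr(, "roc")`.
#' @export
evaluate_panel <- function(matrix, labels, panel,
                           mode = c("resubstitution", "cross_validated"),
                           k = 5, runs = 10, seed = 1L, ncomp = 2) {
  mode <- match.arg(mode)
  if (length(panel) == 0) abort("`panel` must be non-empty")
  x <- as_sample_matrix(matrix, panel)
  if (anyNA(x)) abort("matrix has missing values; impute_missing() first")
  labels <- normalize_labels(labels)
  y01 <- to_binary(unname(labels[rownames(x)]))
  if (mode == "resubstitution") {
    fit <- pls_fit(x, y01, ncomp = ncomp)
    scores <- fit$fitted
    th <- youden_threshold(scores, y01)
    m <- confusion_metrics(scores, y01, th)
    out <- bind_cols(
      tibble(
        scope = paste(length(panel), "genes"),
        evaluation = "resubstitution"
      ),
      m,
      tibble(auc = auc_rank(scores, y01), threshold = th)
    )
    roc <- roc_points(scores, y01)
  } else {
    run_seeds <- with_seed(seed, sample.int(2^31 - 2, runs))
    per_run <- lapply(seq_len(runs), function(r) {
      fold <- with_seed(run_seeds[r], stratified_folds(y01, k))
      scores <- numeric(length(y01))
      for (f in seq_len(k)) {
        te <- fold == f
        fit <- pls_fit(x[!te, , drop = FALSE], y01[!te], ncomp = ncomp)
        scores[te] <- predict(fit, x[te, , drop = FALSE])
      }
      th <- youden_threshold(scores, y01)
      list(
        metrics = bind_cols(
          confusion_metrics(scores, y01, th),
          tibble(auc = auc_rank(scores, y01), threshold = th)
        ),
        scores = scores
      )
    })
    mr <- bind_rows(lapply(per_run, `[[`, "metrics"))
    out <- bind_cols(
      tibble(
        scope = paste(length(panel), "genes"),
        evaluation = "cross_validated"
      ),
      summarise(mr, across(everything(), mean))
    )
    roc <- roc_points(per_run[[1]]$scores, y01)
  }
  structure(out, roc = roc, class = c("panel_metrics", class(out)))
}

#' Evaluate each panel gene as a single-feature classifier
#'
#' Fits a one-gene PLS model per panel gene (equivalent to an oriented
#' threshold on that gene's values) and evaluates it exactly as
#' [evaluate_panel()] does, producing a per-gene accuracy table.
#'
#' @inheritParams evaluate_panel
#' @return A tibble with one `panel_metrics`-shaped row per gene (`scope`
#'   = gene id).
#' @export
evaluate_single_genes <- function(matrix, labels, panel,
                                  mode = c(
                                    "resubstitution",
                                    "cross_validated"
                                  ),
                                  k = 5, runs = 10, seed = 1L) {
  mode <- match.arg(mode)
  if (length(panel) == 0) abort("`panel` must be non-empty")
  rows <- lapply(panel, function(g) {
    r <- evaluate_panel(matrix, labels, g,
      mode = mode, k = k, runs = runs,
      seed = seed, ncomp = 1
    )
    r$scope <- g
    as_tibble(r)
  })
  bind_rows(rows)
}
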