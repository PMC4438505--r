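test_that("rank AUC equals brute-force pair counting, with ties", {
  # worked example: positives {0.9, 0.8, 0.7}, negatives {0.75, 0.6}
  expect_equal(
    auc_rank(c(0.9, 0.8, 0.7, 0.75, 0.6), c(1, 1, 1, 0, 0)),
    5 / 6
  )
  set.seed(30)
  for (i in 1:25) {
    n <- sample(4:200, 1)
    y <- sample(c(0, 1), n, replace = TRUE)
    if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
    scores <- sample(round(rnorm(n), sample(0:2, 1))) # induces ties
    expect_equal(auc_rank(scores, y), brute_force_auc(scores, y))
  }
})

test_that("rank AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(31)
  y <- sample(c(0, 1), 60, replace = TRUE)
  scores <- rnorm(60) + y
  ref <- as.numeric(pROC::auc(pROC::roc(y, scores, quiet = TRUE)))
  expect_equal(auc_rank(scores, y), ref)
})

test_that("cross-validation returns one AUC per run per family", {
  set.seed(32)
  d <- sim_mm(10, 12, effects = c(A = 2, B = 1.5), n_null = 4)
  cv <- cross_validate_models(d$mm, d$labels,
    families = c("pls", "knn"),
    k = 5, runs = 10, seed = 3
  )
  expect_equal(nrow(cv), 20)
  expect_equal(as.integer(table(cv$family)), c(10L, 10L))
  expect_true(all(cv$auc >= 0 & cv$auc <= 1))
  # deterministic given the seed
  cv2 <- cross_validate_models(d$mm, d$labels,
    families = c("pls", "knn"),
    k = 5, runs = 10, seed = 3
  )
  expect_identical(as.data.frame(cv), as.data.frame(cv2))
  expect_equal(glance(cv)$k, 5)
})

test_that("every family separates a linearly separable cohort", {
  set.seed(33)
  d <- sim_mm(12, 12, effects = c(BIG = 10), n_null = 3, sd = 0.4)
  cv <- cross_validate_models(d$mm, d$labels, k = 4, runs = 2, seed = 5)
  summ <- tidy(cv)
  expect_true(all(summ$auc_mean > 0.95))
  expect_equal(attr(cv, "best"), summ$family[which.max(summ$auc_mean)])
})

test_that("permuted labels keep every family near chance AUC", {
  set.seed(34)
  d <- sim_mm(50, 50, effects = c(A = 2), n_null = 9)
  perm <- d$labels
  perm$label <- sample(perm$label)
  cv <- cross_validate_models(d$mm, perm, k = 5, runs = 2, seed = 6)
  summ <- tidy(cv)
  expect_true(all(summ$auc_mean > 0.3 & summ$auc_mean < 0.7))
})

test_that("panel metrics reproduce confusion arithmetic and perfection", {
  # perfect classifier: single gene identical to the labels
  labs <- tibble::tibble(
    sample_id = sprintf("S%02d", 1:20),
    label = rep(c("relapse", "control"), each = 10)
  )
  vals <- matrix(as.numeric(labs$label == "relapse"),
    nrow = 1,
    dimnames = list("G1", labs$sample_id)
  )
  m <- evaluate_panel(make_mm(vals), labs, "G1", mode = "resubstitution")
  expect_equal(m$sensitivity, 1)
  expect_equal(m$specificity, 1)
  expect_equal(m$ppv, 1)
  expect_equal(m$npv, 1)
  expect_equal(m$auc, 1)

  # 14 tp / 1 fn / 19 tn / 0 fp
  y <- c(rep(1, 15), rep(0, 19))
  scores <- c(rep(0.9, 14), 0.1, rep(0.5, 19))
  labs2 <- tibble::tibble(
    sample_id = sprintf("S%02d", seq_along(y)),
    label = ifelse(y == 1, "relapse", "control")
  )
  vals2 <- matrix(scores, nrow = 1, dimnames = list("G1", labs2$sample_id))
  m2 <- evaluate_panel(make_mm(vals2), labs2, "G1")
  expect_equal(m2[, c("tp", "fp", "tn", "fn")],
    tibble::tibble(tp = 14, fp = 0, tn = 19, fn = 1),
    ignore_attr = TRUE
  )
  expect_equal(m2$sensitivity, 14 / 15, tolerance = 1e-12)
  expect_equal(m2$specificity, 1)
  expect_equal(m2$ppv, 1)
  expect_equal(m2$npv, 0.95)
})

test_that("swapping labels and score orientation transposes the metrics", {
  set.seed(35)
  d <- sim_mm(12, 15, effects = c(A = 1.5, B = 1), n_null = 3)
  m <- evaluate_panel(d$mm, d$labels, c("A", "B"))
  flipped_mm <- dplyr::mutate(d$mm, log2_ratio = -log2_ratio)
  swapped <- dplyr::mutate(
    d$labels,
    label = ifelse(label == "relapse", "control", "relapse")
  )
  m2 <- evaluate_panel(flipped_mm, swapped, c("A", "B"))
  expect_equal(m2$sensitivity, m$specificity)
  expect_equal(m2$specificity, m$sensitivity)
  expect_equal(m2$ppv, m$npv)
  expect_equal(m2$npv, m$ppv)
  expect_equal(m2$auc, m$auc)
  # AUC of the same scores against swapped labels is the complement
  y <- as.numeric(d$labels$label == "relapse")
  s <- rnorm(length(y)) + y
  expect_equal(auc_rank(s, 1 - y), 1 - auc_rank(s, y))
})

test_that("single-gene evaluation yields one row per gene", {
  set.seed(36)
  d <- sim_mm(10, 10, effects = c(A = 2, B = 1), n_null = 2)
  rows <- evaluate_single_genes(d$mm, d$labels, c("A", "B"))
  expect_equal(rows$scope, c("A", "B"))
  expect_true(all(rows$auc >= 0.5))
})

test_that("a standardized separation of 2 gives the Gaussian AUC", {
  # closed form: AUC = pnorm(d / sqrt(2)) ~ 0.921 at d = 2
  set.seed(37)
  d <- sim_mm(2000, 2000, effects = c(G = 2), n_null = 0, sd = 1)
  rows <- evaluate_single_genes(d$mm, d$labels, "G")
  expect_equal(rows$auc, pnorm(2 / sqrt(2)), tolerance = 0.015)
})

test_that("resubstitution is optimistic relative to cross-validation", {
  set.seed(38)
  deltas <- vapply(1:20, function(s) {
    set.seed(7000 + s)
    d <- sim_mm(12, 12, effects = c(A = 1, B = 0.8), n_null = 8, sd = 1)
    r <- evaluate_panel(d$mm, d$labels, c("A", "B"), mode = "resubstitution")
    cv <- evaluate_panel(d$mm, d$labels, c("A", "B"),
      mode = "cross_validated", runs = 2, seed = s
    )
    r$auc - cv$auc
  }, numeric(1))
  expect_gt(mean(deltas), 0)
})

test_that("planted seven-gene panels are recovered from full arrays", {
  # recovery invariant: the planted genes are selected (and top-ranked) in
  # >= 90% of cohorts; the VIP > 1 rule may admit an occasional lucky null
  hits <- vapply(1:10, function(s) {
    eff <- default_effect_table(sd_relapse = 0.5, sd_control = 0.5)
    eff <- eff[eff$panel, ]
    cfg <- cohort_config(
      n_relapse = 19, n_control = 19, effects = eff,
      n_null_genes = 49, null_sd = 0.5, seed = 40 + s
    )
    co <- generate_cohort(cfg)
    mm <- impute_missing(
      suppressWarnings(build_matrix(preprocess_cohort(co)))
    )
    r <- rank_and_select_panel(mm, co$samples,
      candidates = unique(mm$gene_id),
      seed = 41
    )
    all(panel_genes() %in% attr(r, "panel")) &&
      setequal(r$gene_id[1:7], panel_genes())
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
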