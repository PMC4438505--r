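# QC boundary semantics use hand-built slides: hybridization-control net
# signal is 100 per channel, so the informativeness floor is 200.

test_that("informativeness boundary keeps spots at exactly 2x the floor", {
  vals_at <- list(G1 = c(200, 200, 200)) # exactly at threshold -> kept
  s_at <- toy_spots(vals_at, lapply(vals_at, function(v) v * 2))
  out_at <- preprocess_sample(s_at)
  expect_equal(out_at$n_informative, 3)
  expect_equal(out_at$ratio, 2)

  vals_below <- list(G1 = c(199, 199, 199)) # just below -> removed
  s_below <- toy_spots(vals_below, lapply(vals_below, function(v) v * 2))
  out_below <- preprocess_sample(s_below)
  expect_equal(out_below$n_informative, 0)
  expect_true(is.na(out_below$ratio))
})

test_that("genes with fewer than two informative spots become missing", {
  # one replicate above the floor, two below
  vals <- list(G1 = c(500, 100, 100))
  s <- toy_spots(vals, lapply(vals, function(v) pmax(v, 300)))
  out <- preprocess_sample(s)
  expect_equal(out$n_informative, 1)
  expect_true(is.na(out$ratio))
  # dropout flags exclude spots even when bright
  vals2 <- list(G1 = c(500, 500, 500))
  s2 <- toy_spots(vals2, vals2, flag_dropout = c("G1 0", "G1 1"))
  out2 <- preprocess_sample(s2)
  expect_equal(out2$n_informative, 1)
  expect_true(is.na(out2$ratio))
})

test_that("gene value is the mean of informative-spot ratios", {
  # control/test ratios 1, 2, 3 -> 2
  vals_t <- list(G1 = c(600, 600, 600))
  vals_c <- list(G1 = c(600, 1200, 1800))
  out <- preprocess_sample(toy_spots(vals_t, vals_c))
  expect_equal(out$ratio, 2)
  # background (the empty-spot mean) is subtracted before ratios: with a
  # different background level the same net signals give the same ratio
  vals_t2 <- list(G1 = c(200, 200, 200))
  vals_c2 <- list(G1 = c(400, 400, 400))
  out2 <- preprocess_sample(toy_spots(vals_t2, vals_c2, empty = 80))
  expect_equal(out2$ratio, 2)
})

test_that("slides without usable background or hyb controls error", {
  vals <- list(G1 = c(300, 300, 300))
  s <- toy_spots(vals, vals)
  s_noempty <- s[s$role != "empty", ]
  expect_error(preprocess_sample(s_noempty), "empty")
  s_nohyb <- s[s$role != "hybridization_control", ]
  expect_error(preprocess_sample(s_nohyb), "hybridization")
})

test_that("raising the control multiplier never adds informative spots", {
  cfg <- cohort_config(n_relapse = 3, n_control = 3, seed = 31)
  co <- generate_cohort(cfg)
  one <- co$spots[co$spots$sample_id == "S001", ]
  counts <- vapply(
    c(0.5, 1, 2, 4, 8),
    function(m) sum(preprocess_sample(one, control_multiplier = m)$n_informative),
    numeric(1)
  )
  expect_true(all(diff(counts) <= 0))
})

test_that("missingness filter applies a strict 25% rule", {
  # 8 samples: 2 missing = 25% retained, 3 missing = 37.5% dropped
  sids <- sprintf("S%d", 1:8)
  summ <- tidyr::expand_grid(
    sample_id = sids,
    gene_id = c("keep", "drop", "full")
  ) %>%
    dplyr::mutate(
      ratio = 2, a_value = 10,
      ratio = dplyr::case_when(
        gene_id == "keep" & sample_id %in% sids[1:2] ~ NA_real_,
        gene_id == "drop" & sample_id %in% sids[1:3] ~ NA_real_,
        TRUE ~ ratio
      )
    )
  mm <- suppressWarnings(build_matrix(summ))
  expect_setequal(unique(mm$gene_id), c("keep", "full"))
  # the mask survives assembly
  expect_equal(sum(is.na(mm$log2_ratio[mm$gene_id == "keep"])), 2)
})

test_that("normalization removes a constant offset and an A-linear bias", {
  # constant M: everything normalizes to 0
  sids <- sprintf("S%d", 1:3)
  genes <- sprintf("G%02d", 1:30)
  summ <- tidyr::expand_grid(sample_id = sids, gene_id = genes) %>%
    dplyr::mutate(ratio = 4, a_value = rep(seq(8, 14, length.out = 30), 3))
  mm <- build_matrix(summ)
  expect_lt(max(abs(mm$log2_ratio)), 1e-9)

  # synthetic intensity-dependent bias M = 0.5 A + e, against an
  # independent local-linear-regression oracle
  set.seed(4)
  a <- runif(56, 8, 14)
  e <- rnorm(56, 0, 0.05)
  m <- 0.5 * a + e
  summ2 <- tidyr::expand_grid(sample_id = c("S1", "S2"), gene_id = sprintf("g%02d", 1:56)) %>%
    dplyr::mutate(a_value = rep(a, each = 2), ratio = 2^rep(m, each = 2))
  mm2 <- build_matrix(summ2, span = 2 / 3, iter = 0)
  one <- mm2[mm2$sample_id == "S1", ]
  ord <- match(sprintf("g%02d", 1:56), one$gene_id)
  oracle <- stats::loess(m ~ a, span = 2 / 3, degree = 1,
    family = "gaussian")
  oracle_resid <- m - predict(oracle)
  # lowess and loess differ slightly in boundary handling; agreement is
  # checked at that granularity, and the bias itself must be gone
  expect_lt(max(abs(one$log2_ratio[ord] - oracle_resid)), 0.15)
  expect_lt(max(abs(one$log2_ratio[ord])), 0.25)
  expect_lt(sd(one$log2_ratio), 0.08) # raw M spans ~3 log2 units
})

test_that("zero-noise pipelines recover latent values up to a constant", {
  cfg <- cohort_config(
    n_relapse = 5, n_control = 5,
    effects = default_effect_table(sd_relapse = 0.3, sd_control = 0.3),
    null_sd = 0.3, noise_cv = 0, background_sd = 0, dropout_rate = 0,
    seed = 3
  )
  co <- generate_cohort(cfg)
  mm <- suppressWarnings(build_matrix(preprocess_cohort(co)))
  cmp <- dplyr::inner_join(mm, co$latent,
    by = c("gene_id", "sample_id"),
    suffix = c("_rec", "_lat")
  )
  resid <- cmp$log2_ratio_rec - cmp$log2_ratio_lat
  resid <- resid - mean(resid, na.rm = TRUE)
  expect_lt(sd(resid, na.rm = TRUE), 0.2)
  expect_gt(
    cor(cmp$log2_ratio_rec, cmp$log2_ratio_lat, use = "complete.obs"),
    0.97
  )
})

test_that("renormalizing an already-normalized matrix changes little", {
  cfg <- cohort_config(n_relapse = 5, n_control = 5, seed = 17)
  co <- generate_cohort(cfg)
  # the idempotence property concerns the smoother itself, so both passes
  # run without the positive-control anchor (a per-sample level choice that
  # is only available on first import)
  summ <- preprocess_cohort(co)
  summ <- summ[summ$role == "gene_probe", setdiff(names(summ), "role")]
  mm1 <- suppressWarnings(build_matrix(summ))
  # reconstruct summaries from the normalized values and renormalize
  summ2 <- dplyr::left_join(
    dplyr::transmute(mm1,
      sample_id = sample_id, gene_id = gene_id,
      ratio = 2^log2_ratio
    ),
    dplyr::select(summ, sample_id, gene_id, a_value),
    by = c("sample_id", "gene_id")
  )
  mm2 <- suppressWarnings(build_matrix(summ2))
  cmp <- dplyr::inner_join(mm1, mm2,
    by = c("gene_id", "sample_id"),
    suffix = c("_1", "_2")
  )
  # lowess is not an exact projection, so a second pass wiggles values by
  # a bounded amount (worst case at robust-weight flips near outliers)
  ch <- abs(cmp$log2_ratio_1 - cmp$log2_ratio_2)
  expect_lt(max(ch, na.rm = TRUE), 0.3)
  expect_lt(median(ch, na.rm = TRUE), 0.05)
  expect_gt(
    cor(cmp$log2_ratio_1, cmp$log2_ratio_2, use = "complete.obs"), 0.99
  )
})

test_that("binary calls follow the ratio orientation and keep the mask", {
  mm <- make_mm(matrix(c(-2, 2, -0.4, 0.4, NA, 0),
    nrow = 6,
    dimnames = list(sprintf("g%d", 1:6), "S1")
  ))
  mm2 <- rbind(mm, make_mm(matrix(0, 6, 1,
    dimnames = list(sprintf("g%d", 1:6), "S2")
  )))
  called <- categorize_calls(mm2, threshold_log2 = 1)
  calls <- called$call[called$sample_id == "S1"]
  names(calls) <- called$gene_id[called$sample_id == "S1"]
  expect_equal(unname(calls["g1"]), "methylated") # beyond -threshold
  expect_equal(unname(calls["g2"]), "unmethylated") # beyond +threshold
  expect_equal(unname(calls["g3"]), "methylated") # nearer category
  expect_equal(unname(calls["g4"]), "unmethylated")
  expect_equal(unname(calls["g5"]), "missing")
  expect_equal(unname(calls["g6"]), "unmethylated") # tie at 0
})

test_that("median imputation completes the matrix for classifiers", {
  vals <- matrix(c(1, 2, NA, 4, 5, 6), nrow = 2, dimnames = list(
    c("g1", "g2"), c("S1", "S2", "S3")
  ))
  mm <- impute_missing(make_mm(vals))
  wide <- as_sample_matrix(mm)
  expect_false(anyNA(wide))
  expect_equal(wide["S2", "g1"], 3) # median of 1, 5
})
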