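test_that("cohorts have the configured composition", {
  cfg <- cohort_config(n_relapse = 19, n_control = 104, seed = 5)
  co <- generate_cohort(cfg)
  expect_equal(nrow(co$samples), 123)
  expect_equal(sum(co$samples$label == "relapse"), 19)
  # one full slide per sample
  spots_per_sample <- dplyr::count(co$spots, sample_id)
  expect_true(all(spots_per_sample$n == 192))
  # truth covers every probe on the layout
  expect_setequal(
    co$truth$gene_id,
    unique(na.omit(co$layout$gene_id))
  )
  expect_equal(nrow(co$truth), 56)
})

test_that("cohorts are a deterministic function of the config", {
  cfg <- cohort_config(n_relapse = 4, n_control = 5, seed = 99)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$spots, b$spots)
  expect_identical(a$latent, b$latent)
  c2 <- generate_cohort(cohort_config(n_relapse = 4, n_control = 5, seed = 100))
  expect_false(identical(a$spots, c2$spots))
})

test_that("latent group differences equal the declared effects exactly", {
  eff <- default_effect_table(sd_relapse = 0.4, sd_control = 0.4)
  # MC check of the generator's calibration on a large cohort
  co <- generate_cohort(cohort_config(
    n_relapse = 300, n_control = 300,
    effects = eff, seed = 21
  ))
  lat <- dplyr::left_join(co$latent, co$samples, by = "sample_id")
  means <- lat %>%
    dplyr::group_by(gene_id, label) %>%
    dplyr::summarise(m = mean(log2_ratio), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = label, values_from = m) %>%
    dplyr::mutate(d = relapse - control) %>%
    dplyr::left_join(
      dplyr::mutate(co$truth, eff = direction * log2_mean_diff),
      by = "gene_id"
    )
  # per-gene empirical effect within the MC 99% interval of the target
  se <- sqrt(0.4^2 / 300 + 0.4^2 / 300)
  se_null <- sqrt(1^2 / 300 + 1^2 / 300)
  z <- (means$d - means$eff) / ifelse(means$eff == 0, se_null, se)
  expect_true(all(abs(z) < qnorm(0.995) + 0.5)) # small slack for 56 tests
  # and the planted fold changes are recovered on the FC scale
  inf <- means[means$eff != 0, ]
  expect_equal(2^abs(inf$d), 2^abs(inf$eff), tolerance = 0.1)
})

test_that("null effects show no systematic latent group difference", {
  cfg <- cohort_config(
    n_relapse = 500, n_control = 500,
    effects = gene_effects(character(0), numeric(0)),
    n_null_genes = 56, seed = 8
  )
  co <- generate_cohort(cfg)
  lat <- dplyr::left_join(co$latent, co$samples, by = "sample_id")
  d <- lat %>%
    dplyr::group_by(gene_id, label) %>%
    dplyr::summarise(m = mean(log2_ratio), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = label, values_from = m) %>%
    dplyr::mutate(d = relapse - control)
  expect_lt(max(abs(d$d)), 4 * sqrt(2 / 500)) # null_sd = 1
})

test_that("null-gene t-tests reject at the nominal rate across seeds", {
  rejections <- unlist(lapply(1:100, function(s) {
    cfg <- cohort_config(
      n_relapse = 6, n_control = 6,
      effects = gene_effects(character(0), numeric(0)),
      n_null_genes = 56, dropout_rate = 0, seed = 3000 + s
    )
    co <- generate_cohort(cfg)
    lat <- dplyr::left_join(co$latent, co$samples, by = "sample_id")
    vapply(split(lat, lat$gene_id), function(g) {
      t.test(
        g$log2_ratio[g$label == "relapse"],
        g$log2_ratio[g$label == "control"],
        var.equal = TRUE
      )$p.value < 0.05
    }, logical(1))
  }))
  n <- length(rejections)
  band <- 4 * sqrt(0.05 * 0.95 / n)
  expect_equal(mean(rejections), 0.05, tolerance = band / 0.05)
})

test_that("spot physics honours protection and digestion limits", {
  cfg <- cohort_config(
    n_relapse = 2, n_control = 2,
    noise_cv = 0, background_mean = 0, background_sd = 0,
    dropout_rate = 0, seed = 1
  )
  layout <- default_layout(c("G1", "G2"))
  templates <- setNames(rep(1000, 56), unique(na.omit(layout$gene_id)))
  # fully protected template (latent log2 ratio 0 -> fraction 1):
  # test equals control at that gene's spots
  lat <- setNames(rep(0, 56), names(templates))
  arr <- withr::with_seed(
    1,
    simulate_sample_array(lat, layout, templates, cfg)
  )
  g <- arr[arr$role == "gene_probe", ]
  expect_equal(g$fg_test, g$fg_control, tolerance = 1e-12)
  expect_equal(g$fg_test, rep(1000, nrow(g)))
  # complete digestion (fraction 0): test channel is background only
  lat0 <- setNames(rep(Inf, 56), names(templates))
  arr0 <- withr::with_seed(
    1,
    simulate_sample_array(lat0, layout, templates, cfg)
  )
  g0 <- arr0[arr0$role == "gene_probe", ]
  expect_true(all(g0$fg_test == 0))
  expect_true(all(g0$fg_control > 0))
  # full slide structure
  expect_equal(nrow(arr), 192)
  # empty spots carry only background (zero here)
  expect_true(all(arr$fg_test[arr$role == "empty"] == 0))
})
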