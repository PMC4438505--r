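# Synthetic cohort generator. Emulates the two-colour restriction-digest
# assay: each patient's DNA is split, one aliquot digested with a
# methylation-sensitive enzyme (test channel, Cy3/532 nm), the other
# mock-digested (control channel, Cy5/635 nm). Methylated (protected)
# templates survive digestion, so test-channel intensity is proportional to
# the methylated fraction while the control channel sees the full template.
# The analysis ratio is R = control/test; log2 R rises as methylation falls.
#
# Latent model per gene g and sample i in group k:
#   log2 R_gi ~ Normal(mu_gk, sd_gk),
#   mu_control = -log2(baseline_methylation),
#   mu_relapse = mu_control + direction_g * log2_mean_diff_g,
# so the generating between-group difference of mean log2 R equals the
# declared effect exactly. The protected fraction f = 2^(-log2 R) feeds the
# spot intensity model (values > 1 are tolerated and read as amplification
# efficiency variation).

#' Cohort simulation settings
#'
#' Collects every knob of the synthetic-cohort generator. Defaults emulate
#' the published study: 123 patients (19 relapse / 104 non-relapse), the 21
#' published gene effects among null probes filling the 56-probe layout, and
#' two-colour spot physics with multiplicative noise, additive background
#' and spot dropout.
#'
#' @param n_relapse,n_control Group sizes (>= 2 each).
#' @param effects Tibble of informative gene effects (see
#'   [default_effect_table()] / [gene_effects()]).
#' @param n_null_genes Number of additional no-effect probes; by default
#'   fills the 56-probe layout.
#' @param null_sd Within-group standard deviation of null probes.
#' @param baseline_methylation Mean methylated fraction in the control group
#'   (0 < x < 1); fixes the baseline mean log2 ratio at `-log2(x)`.
#' @param noise_cv Coefficient of variation of multiplicative (lognormal)
#'   spot noise, per channel.
#' @param background_mean,background_sd Additive background intensity.
#' @param nonspecific Nonspecific-binding intensity of hybridization-control
#'   spots (the informativeness floor reference).
#' @param template_log2_mean,template_log2_sd Per-gene amplifiable-template
#'   intensity drawn as `2^Normal(mean, sd)`, fixed per gene across samples.
#' @param dropout_rate Probability a spot is flagged unusable.
#' @param seed Integer seed; the cohort is a deterministic function of the
#'   config.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_relapse = 19, n_control = 104,
                          effects = default_effect_table(),
                          n_null_genes = NULL,
                          null_sd = 1.0,
                          baseline_methylation = 0.5,
                          noise_cv = 0.1,
                          background_mean = 50, background_sd = 10,
                          nonspecific = 20,
                          template_log2_mean = 11, template_log2_sd = 1.2,
                          dropout_rate = 0.02,
                          seed = 1L) {
  if (n_relapse < 2 || n_control < 2) {
    abort("need at least 2 samples per group")
  }
  if (baseline_methylation <= 0 || baseline_methylation >= 1) {
    abort("`baseline_methylation` must be in (0, 1)")
  }
  if (dropout_rate < 0 || dropout_rate >= 1) {
    abort("`dropout_rate` must be in [0, 1)")
  }
  stopifnot(noise_cv >= 0, background_mean >= 0, background_sd >= 0,
            nonspecific >= 0, null_sd > 0)
  effects <- as_tibble(effects)
  needed <- c("gene_id", "log2_mean_diff", "direction",
              "sd_relapse", "sd_control")
  if (!all(needed %in% names(effects))) {
    abort(paste("`effects` needs columns", toString(needed)))
  }
  if (is.null(n_null_genes)) {
    n_null_genes <- max(.N_GENE_SPOTS - nrow(effects), 0L)
  }
  if (nrow(effects) + n_null_genes > .N_GENE_SPOTS) {
    abort(sprintf(
      "%d informative + %d null genes exceed the %d-probe layout",
      nrow(effects), n_null_genes, .N_GENE_SPOTS
    ))
  }
  structure(
    list(
      n_relapse = as.integer(n_relapse),
      n_control = as.integer(n_control),
      effects = effects,
      n_null_genes = as.integer(n_null_genes),
      null_sd = null_sd,
      baseline_methylation = baseline_methylation,
      noise_cv = noise_cv,
      background_mean = background_mean,
      background_sd = background_sd,
      nonspecific = nonspecific,
      template_log2_mean = template_log2_mean,
      template_log2_sd = template_log2_sd,
      dropout_rate = dropout_rate,
      seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
}

# ground-truth table covering every probe on the layout
cohort_truth <- function(config) {
  eff <- config$effects %>%
    select(all_of(c("gene_id", "log2_mean_diff", "direction",
                    "sd_relapse", "sd_control"))) %>%
    mutate(informative = .data$log2_mean_diff > 0)
  if (config$n_null_genes > 0) {
    nulls <- tibble(
      gene_id = null_probe_names(config$n_null_genes, eff$gene_id),
      log2_mean_diff = 0, direction = 1,
      sd_relapse = config$null_sd, sd_control = config$null_sd,
      informative = FALSE
    )
    eff <- bind_rows(eff, nulls)
  }
  eff
}

#' Generate a simulated two-colour cohort
#'
#' Draws latent per-sample log2 methylation ratios from the configured group
#' model, then renders each sample as a full slide of spot intensities via
#' [simulate_sample_array()]. Deterministic given the config (including its
#' seed).
#'
#' @param config A [cohort_config()].
#' @return A list of class `meth_cohort` with elements
#'   \describe{
#'     \item{samples}{tibble `sample_id`, `label` (`"relapse"`/`"control"`)}
#'     \item{spots}{tibble of spot records for all samples (long)}
#'     \item{latent}{tibble `gene_id`, `sample_id`, `log2_ratio` of the
#'       pre-noise latent values (ground truth)}
#'     \item{truth}{per-gene generating parameters for every probe}
#'     \item{layout}{the slide layout used}
#'     \item{config}{the config}
#'   }
#' @examples
#' cfg <- cohort_config(n_relapse = 3, n_control = 4, seed = 7)
#' cohort <- generate_cohort(cfg)
#' table(cohort$samples$label)
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  truth <- cohort_truth(config)
  layout <- default_layout(truth$gene_id)
  n <- config$n_relapse + config$n_control
  samples <- tibble(
    sample_id = sprintf("S%03d", seq_len(n)),
    label = rep(c(.POS, .NEG), c(config$n_relapse, config$n_control))
  )
  with_seed(config$seed, {
    templates <- setNames(
      2^rnorm(nrow(truth), config$template_log2_mean,
              config$template_log2_sd),
      truth$gene_id
    )
    base <- -log2(config$baseline_methylation)
    latent <- tidyr::expand_grid(
      truth[c("gene_id", "log2_mean_diff", "direction",
              "sd_relapse", "sd_control")],
      samples
    ) %>%
      mutate(
        mu = base + ifelse(.data$label == .POS,
                           .data$direction * .data$log2_mean_diff, 0),
        sdv = ifelse(.data$label == .POS, .data$sd_relapse,
                     .data$sd_control),
        log2_ratio = rnorm(n(), .data$mu, .data$sdv)
      ) %>%
      select(all_of(c("gene_id", "sample_id", "label", "log2_ratio")))
    spots <- lapply(samples$sample_id, function(sid) {
      lat <- latent[latent$sample_id == sid, ]
      arr <- simulate_sample_array(
        setNames(lat$log2_ratio, lat$gene_id), layout, templates, config
      )
      mutate(arr, sample_id = sid, .before = 1L)
    })
    spots <- bind_rows(spots)
  })
  structure(
    list(
      samples = samples, spots = spots,
      latent = select(latent, -all_of("label")),
      truth = truth, layout = layout, config = config,
      templates = templates
    ),
    class = "meth_cohort"
  )
}

#' @export
print.meth_cohort <- function(x, ...) {
  cat(sprintf(
    "<meth_cohort> %d samples (%d relapse / %d control), %d probes, seed %d\n",
    nrow(x$samples), sum(x$samples$label == .POS),
    sum(x$samples$label == .NEG), nrow(x$truth), x$config$seed
  ))
  invisible(x)
}

#' Render one sample's slide from latent methylation values
#'
#' Converts latent per-gene log2 ratios into a full slide of two-channel
#' spot intensities: gene spots carry `template * protected-fraction` signal
#' in the test channel and full template in the control channel, positive
#' controls carry full signal in both, hybridization controls carry only
#' nonspecific signal, empty spots only background. Triplicate gene spots
#' share the latent value but receive independent multiplicative noise.
#' Consumes the current RNG stream.
#'
#' @param latent_log2_ratio Named numeric vector, one latent log2
#'   (control/test) ratio per gene probe on the layout. `Inf` encodes a
#'   fully digested (methylated fraction 0) template.
#' @param layout Slide layout from [default_layout()].
#' @param templates Named per-gene template intensities.
#' @param config A [cohort_config()] supplying the noise model.
#' @return A tibble of spot records with columns `subarray`, `row`, `col`,
#'   `role`, `gene_id`, `fg_test`, `bg_test`, `fg_control`, `bg_control`,
#'   `flag` (`"ok"`/`"dropout"`).
#' @export
simulate_sample_array <- function(latent_log2_ratio, layout, templates,
                                  config) {
  genes <- layout$gene_id[layout$role == "gene_probe" & layout$subarray == 0]
  missing_genes <- setdiff(genes, names(latent_log2_ratio))
  if (length(missing_genes) > 0) {
    abort(paste("no latent value for probes:", toString(missing_genes)))
  }
  n <- nrow(layout)
  sigma <- sqrt(log1p(config$noise_cv^2))
  mnoise <- function(k) exp(rnorm(k, -sigma^2 / 2, sigma))
  bgdraw <- function(k) {
    pmax(rnorm(k, config$background_mean, config$background_sd), 0)
  }
  f <- 2^(-latent_log2_ratio) # protected (methylated) fraction
  tmpl <- templates[layout$gene_id]
  t_pos <- 2^config$template_log2_mean
  sig_test <- dplyr::case_match(
    layout$role,
    "gene_probe" ~ unname(tmpl * f[layout$gene_id]),
    "positive_control" ~ t_pos,
    "hybridization_control" ~ config$nonspecific,
    "empty" ~ 0
  )
  sig_control <- dplyr::case_match(
    layout$role,
    "gene_probe" ~ unname(tmpl),
    "positive_control" ~ t_pos,
    "hybridization_control" ~ config$nonspecific,
    "empty" ~ 0
  )
  layout %>%
    mutate(
      fg_test = bgdraw(n) + sig_test * mnoise(n),
      bg_test = bgdraw(n),
      fg_control = bgdraw(n) + sig_control * mnoise(n),
      bg_control = bgdraw(n),
      flag = ifelse(runif(n) < config$dropout_rate, "dropout", "ok")
    )
}
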