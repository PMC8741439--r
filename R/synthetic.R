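#' Configuration for the synthetic study generator
#'
#' Defaults mirror the study design the package analyses: 3 prototypical
#' responders against 10 non-responders with paired core (pre-treatment) and
#' surgical (post-treatment) RNA-seq samples, a 30-gene planted late-cell-cycle
#' signature downregulated 4-fold in responders after treatment, negative
#' binomial counts (variance `mu + dispersion * mu^2`), and a validation
#' cohort whose hazard follows the response score.
#'
#' @param n_responders,n_nonresponders patients per group (defaults 3 and 10).
#' @param n_genes genes simulated (default 2000).
#' @param n_signature planted signature genes (default 30).
#' @param effect_fold fold downregulation of signature genes in responders'
#'   surgical samples (default 4).
#' @param baseline_mean_log,baseline_sd_log log-normal parameters of gene
#'   baseline means (defaults `log(100)` and 1).
#' @param dispersion shared negative-binomial dispersion phi (default 0.2).
#' @param library_size_range sampled library sizes, in counts (default
#'   0.5e6 to 2e6).
#' @param patient_effect_sd log-normal sd of the shared patient effect that
#'   correlates a patient's core and surgical samples (default 0.3).
#' @param censoring_fraction target fraction of censored survival records
#'   (default 0.4).
#' @param hazard_ratio hazard multiplier per group indicator / standardized
#'   score unit in the survival generator (default 3).
#' @param seed default seed carried by the config.
#' @return a list of class `synth_config`.
#' @export
synth_config <- function(n_responders = 3, n_nonresponders = 10,
                         n_genes = 2000, n_signature = 30, effect_fold = 4,
                         baseline_mean_log = log(100), baseline_sd_log = 1,
                         dispersion = 0.2,
                         library_size_range = c(0.5e6, 2e6),
                         patient_effect_sd = 0.3,
                         censoring_fraction = 0.4, hazard_ratio = 3,
                         seed = 1) {
  stopifnot(is_count(n_responders), is_count(n_nonresponders),
            is_count(n_genes), is_count(n_signature),
            effect_fold >= 1, dispersion > 0,
            length(library_size_range) == 2L,
            library_size_range[1] > 0,
            library_size_range[2] >= library_size_range[1],
            hazard_ratio > 0)
  if (censoring_fraction < 0 || censoring_fraction >= 1)
    stop_("censoring_fraction must lie in [0, 1)")
  if (n_signature > n_genes) stop_("n_signature exceeds n_genes")
  structure(as.list(environment()), class = "synth_config")
}

#' Simulate a paired core/surgical expression study
#'
#' Per patient, one core and one surgical negative-binomial count sample.
#' Gene baseline means are log-normal; each patient carries a shared
#' log-normal random effect so their two samples correlate; library sizes
#' vary per sample. In responders only, the planted signature genes'
#' surgical means are divided by `effect_fold`. Deterministic given
#' `(config, seed)`; each output object draws from its own substream so
#' adding outputs never perturbs existing ones.
#'
#' @param config a [synth_config()].
#' @param seed integer seed (default: the config's).
#' @param signature_genes optional gene ids to plant instead of a random
#'   draw — lets a validation cohort share the training cohort's planted
#'   signature.
#' @return `list(matrix, meta, truth)`: a raw-count [expression_matrix()]
#'   (`n_genes x 2*(n_responders+n_nonresponders)`), a sample sheet, and a
#'   ground-truth list (`signature_genes`, per-sample `linear_predictor` for
#'   survival simulation).
#' @export
generate_paired_study <- function(config = synth_config(), seed = config$seed,
                                  signature_genes = NULL) {
  n_pat <- config$n_responders + config$n_nonresponders
  gene_ids <- sprintf("G%05d", seq_len(config$n_genes))
  pat_ids <- sprintf("P%02d", seq_len(n_pat))
  group <- rep(c("responder", "nonresponder"),
               c(config$n_responders, config$n_nonresponders))

  mu <- with_local_seed(substream_seed(seed, 1L),
                        exp(rnorm(config$n_genes, config$baseline_mean_log,
                                  config$baseline_sd_log)))
  sig_idx <- if (is.null(signature_genes)) {
    with_local_seed(substream_seed(seed, 2L),
                    sort(sample.int(config$n_genes, config$n_signature)))
  } else {
    idx <- match(toupper(as.character(signature_genes)), gene_ids)
    if (anyNA(idx)) stop_("signature_genes outside the simulated gene ids")
    sort(idx)
  }
  pat_eff <- with_local_seed(substream_seed(seed, 3L),
                             exp(rnorm(n_pat, 0, config$patient_effect_sd)))
  lib <- with_local_seed(substream_seed(seed, 4L),
                         runif(2L * n_pat, config$library_size_range[1],
                               config$library_size_range[2]))

  sample_ids <- as.vector(rbind(paste0(pat_ids, "_C"), paste0(pat_ids, "_S")))
  meta <- data.frame(sample_id = sample_ids,
                     patient_id = rep(pat_ids, each = 2L),
                     timepoint = rep(c("core", "surgical"), n_pat),
                     group = rep(group, each = 2L),
                     stringsAsFactors = FALSE)

  counts <- with_local_seed(substream_seed(seed, 5L), {
    m <- matrix(0, config$n_genes, 2L * n_pat,
                dimnames = list(gene_ids, sample_ids))
    for (s in seq_len(2L * n_pat)) {
      p <- (s + 1L) %/% 2L
      mean_s <- mu * pat_eff[p]
      if (meta$timepoint[s] == "surgical" && meta$group[s] == "responder")
        mean_s[sig_idx] <- mean_s[sig_idx] / config$effect_fold
      mean_s <- mean_s * lib[s] / sum(mean_s)
      m[, s] <- rnbinom(config$n_genes, mu = mean_s, size = 1 / config$dispersion)
    }
    m
  })

  truth <- list(
    signature_genes = gene_set(gene_ids[sig_idx], "planted_signature"),
    group = setNames(meta$group, meta$sample_id),
    timepoint = setNames(meta$timepoint, meta$sample_id),
    linear_predictor = setNames(log(config$hazard_ratio) * (meta$group == "responder"),
                                meta$sample_id))
  list(matrix = expression_matrix(counts, "raw_counts"), meta = meta,
       truth = truth)
}

#' Simulate a Table-1-like paired clinical table
#'
#' Emits one row per patient with paired Ki67 and ROR measurements in the
#' ranges seen in low-grade ER+ windows-of-opportunity cohorts (Ki67 roughly
#' 0.1-15 percent, ROR 15-65, biopsy-surgery intervals 28-66 days).
#' Responder patients receive ROR decreases of 30-50 points while
#' non-responder deltas stay within +/-12, so by construction the responder
#' deltas fall more than one standard deviation below the cohort mean and
#' [select_responders()] recovers exactly the planted responders. With
#' `effect_fold = 1` all patients draw null deltas instead.
#'
#' @param config a [synth_config()].
#' @param seed integer seed.
#' @return a clinical data.frame in the [read_clinical_table()] layout.
#' @export
generate_clinical_table <- function(config = synth_config(), seed = config$seed) {
  n <- config$n_responders + config$n_nonresponders
  responder <- rep(c(TRUE, FALSE), c(config$n_responders, config$n_nonresponders))
  null_effect <- config$effect_fold == 1

  with_local_seed(substream_seed(seed, 11L), {
    age <- round(runif(n, 55, 76), 1)
    size <- round(runif(n, 0.6, 2.8), 1)
    hist <- sample(c(1L, 1L, 1L, 2L, 3L, 5L), n, replace = TRUE)
    grade <- sample(1:2, n, replace = TRUE)
    interval <- round(runif(n, 28, 66))
    e2_base <- ifelse(runif(n) < 0.5, NA, round(runif(n, 30, 80)))
    below <- is.na(e2_base)
    e2_base[below] <- 30
    e2_post <- round(runif(n, 100, 1600))

    ki67_bx <- round(exp(runif(n, log(0.5), log(15))), 1)
    ki67_lfc <- ifelse(responder & !null_effect, rnorm(n, -1.2, 0.3), rnorm(n, 0, 0.4))
    ki67_sx <- pmax(0.1, round(ki67_bx * exp(ki67_lfc), 1))

    ror_bx <- round(runif(n, 30, 65))
    delta <- ifelse(responder & !null_effect,
                    -runif(n, 30, 50),
                    pmin(12, pmax(-12, rnorm(n, -3, 6))))
    ror_sx <- pmin(100, pmax(0, round(ror_bx + delta)))

    data.frame(patient_id = sprintf("SIM-%03d", seq_len(n)),
               age = age, tumour_size = size, histology = hist, grade = grade,
               interval_days = interval, e2_baseline = e2_base,
               e2_below_detection = below, e2_post = e2_post,
               ki67_bx = ki67_bx, ki67_sx = ki67_sx,
               ror_bx = ror_bx, ror_sx = ror_sx,
               stringsAsFactors = FALSE)
  })
}

#' Simulate a survival validation cohort
#'
#' Exponential event times with the hazard multiplied by
#' `hazard_ratio^indicator` (group indicator, when no scores are given) or
#' `hazard_ratio^z` (standardized response score). Censoring is independent
#' uniform on `(0, b)` with `b` solved so the expected censored fraction
#' matches `censoring_fraction`.
#'
#' @param config a [synth_config()].
#' @param scores optional named [score_samples()] vector; groups are then the
#'   median split of the scores and hazards follow the standardized score.
#' @param n cohort size when `scores` is not given (default 200).
#' @param baseline_hazard events per month in the low-hazard group (default
#'   `log(2)/60`: median 60 months).
#' @param seed integer seed.
#' @return data.frame `sample_id, time, event, group` (class as in
#'   [read_survival_table()]).
#' @export
generate_survival_cohort <- function(config = synth_config(), scores = NULL,
                                     n = 200, baseline_hazard = log(2) / 60,
                                     seed = config$seed) {
  if (!is.null(scores)) {
    if (is.null(names(scores))) stop_("scores must be named by sample id")
    ids <- names(scores)
    z <- if (sd(scores) > 0) (scores - mean(scores)) / sd(scores) else scores * 0
    lp <- log(config$hazard_ratio) * z
    group <- unname(dichotomize_scores(scores, rule = "median"))
  } else {
    ids <- sprintf("V%04d", seq_len(n))
    indicator <- rep(c(1, 0), length.out = n)
    lp <- log(config$hazard_ratio) * indicator
    group <- ifelse(indicator == 1, "high", "low")
  }
  hazard <- baseline_hazard * exp(lp)

  with_local_seed(substream_seed(seed, 21L), {
    t_event <- rexp(length(ids), rate = hazard)
    cf <- config$censoring_fraction
    if (cf > 0) {
      mean_h <- mean(hazard)
      # b such that P(censored) = E[(1 - exp(-h b)) / (h b)] matches cf
      f <- function(b) mean((1 - exp(-hazard * b)) / (hazard * b)) - cf
      b <- uniroot(f, lower = 1e-6, upper = 1e6 / mean_h, extendInt = "downX")$root
      t_cens <- runif(length(ids), 0, b)
      event <- as.integer(t_event <= t_cens)
      time <- pmin(t_event, t_cens)
    } else {
      event <- rep(1L, length(ids))
      time <- t_event
    }
    data.frame(sample_id = ids, time = pmax(time, 1e-6), event = event,
               group = group, stringsAsFactors = FALSE)
  })
}
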