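#' Replicated type-I-error study for the DIF screen
#'
#' Repeatedly simulates DIF-free two-group cohorts (10 items with the study
#' preset's baseline parameters), runs the full detection procedure, and
#' records which items the total 2-df likelihood-ratio screen flags at
#' `alpha`. With `impact_shift > 0` the second group's latent mean is shifted
#' (impact without DIF) -- the scenario in which a valid DIF procedure must
#' still not flag items.
#'
#' @param n_reps number of replicate cohorts.
#' @param n_per_group respondents per group.
#' @param impact_shift latent-mean difference between the groups (SD units).
#' @param alpha screening significance level.
#' @param purify purification setting passed to [detect_dif()].
#' @param seed base seed; per-replicate seeds are drawn from it.
#' @return list with `flag_rate`, `n_flags`, `n_tests`, and the exact
#'   central 95% binomial acceptance interval for a true rate of `alpha`.
#' @export
dif_type1_study <- function(n_reps = 200, n_per_group = 300,
                            impact_shift = 0, alpha = 0.01, purify = TRUE,
                            seed = 1L) {
  preset <- india_like_preset(n_items = 10, dif = FALSE, impact = FALSE,
                              dependent_pair = FALSE)
  set.seed(seed)
  rep_seeds <- sample.int(2^30, n_reps)
  impact <- if (impact_shift != 0) {
    data.frame(group = c("A", "B"), mean = c(0, impact_shift), sd = c(1, 1))
  }
  n_flags <- 0L
  for (i in seq_len(n_reps)) {
    cfg <- simulation_config(n_per_group = c(A = n_per_group, B = n_per_group),
                             a = preset$a, b = preset$b, impact = impact,
                             item_labels = preset$item_labels,
                             covariate = "g", seed = rep_seeds[i])
    co <- generate_cohort(cfg)
    res <- detect_dif(co$matrix, "g", purify = purify, alpha = alpha)
    n_flags <- n_flags + sum(res$flagged)
  }
  n_tests <- n_reps * 10L
  list(flag_rate = n_flags / n_tests, n_flags = n_flags, n_tests = n_tests,
       binom_interval = stats::qbinom(c(0.025, 0.975), n_tests, alpha) / n_tests)
}

#' Replicated power-and-classification study for injected DIF
#'
#' Injects DIF of a known kind into one item of DIF-free two-group cohorts
#' and scores how often the procedure flags it through the appropriate
#' sequential likelihood-ratio test and classifies it correctly.
#'
#' @param kind "uniform" (difficulty offset `delta_b`) or "nonuniform"
#'   (slope multiplier `delta_a_mult`).
#' @param n_reps number of replicate cohorts.
#' @param n_per_group respondents per group.
#' @param item the item carrying the injected DIF.
#' @param delta_b difficulty offset for uniform DIF (logits).
#' @param delta_a_mult slope multiplier for non-uniform DIF.
#' @param alpha significance level.
#' @param purify purification setting passed to [detect_dif()].
#' @param seed base seed.
#' @return list with detection rate through the matching LRT
#'   (`detection_rate`), correct-classification rate (`classification_rate`),
#'   rate at which the matching R2 difference reaches the lower magnitude
#'   band (`band_rate`), and the per-replicate statistics.
#' @export
dif_power_study <- function(kind = c("uniform", "nonuniform"), n_reps = 100,
                            n_per_group = 500, item = 4L, delta_b = 1,
                            delta_a_mult = 2, alpha = 0.01, purify = TRUE,
                            seed = 1L) {
  kind <- match.arg(kind)
  preset <- india_like_preset(n_items = 10, dif = FALSE, impact = FALSE,
                              dependent_pair = FALSE)
  dif <- if (kind == "uniform") {
    data.frame(item = item, group = "B", delta_b = delta_b, delta_a_mult = 1)
  } else {
    data.frame(item = item, group = "B", delta_b = 0,
               delta_a_mult = delta_a_mult)
  }
  set.seed(seed + 1L)
  rep_seeds <- sample.int(2^30, n_reps)
  rows <- vector("list", n_reps)
  for (i in seq_len(n_reps)) {
    cfg <- simulation_config(n_per_group = c(A = n_per_group, B = n_per_group),
                             a = preset$a, b = preset$b, dif = dif,
                             item_labels = preset$item_labels,
                             covariate = "g", seed = rep_seeds[i])
    co <- generate_cohort(cfg)
    res <- detect_dif(co$matrix, "g", purify = purify, alpha = alpha)
    rows[[i]] <- res[res$item == item, ]
  }
  per_rep <- do.call(rbind, rows)
  detected <- if (kind == "uniform") per_rep$p21 < alpha else per_rep$p32 < alpha
  correct <- per_rep$type == if (kind == "uniform") "uniform" else "non-uniform"
  dr <- if (kind == "uniform") per_rep$dr21 else per_rep$dr32
  list(detection_rate = mean(detected), classification_rate = mean(correct),
       band_rate = mean(dr >= 0.035), per_rep = per_rep)
}
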