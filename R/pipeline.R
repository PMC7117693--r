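#' Run the full questionnaire DIF study workflow
#'
#' Executes, in the order the analysis is designed to follow: load or
#' simulate the cohort; descriptive endorsement table with chi-square
#' subgroup flags (computed on the raw coding, *before* reversal); item
#' reversal; GRM fit; IRT condition diagnostics; removal of the
#' recommended locally dependent item(s) followed by a re-fit and
#' re-diagnosis; pairwise DIF detection per covariate; DIF impact
#' assessment; Cronbach's alpha on the full and reduced item sets; MCA with
#' varimax-type rotation on the whole sample and per group, with the full
#' and reduced item sets; and a manifest recording configuration and seed.
#' All machine outputs are deterministic given the same input and seed.
#'
#' @param input a [response_matrix()], a CSV path, or a
#'   [simulation_config()].
#' @param covariates covariate names to analyse (defaults to all declared).
#' @param out_dir run directory (created; one directory per invocation).
#' @param reversal_items items to direction-flip before model-based stages
#'   (EPICES: 1 and 5).
#' @param alpha DIF LRT significance level.
#' @param bands McFadden R2 magnitude bands.
#' @param ld_threshold local-dependence flag threshold.
#' @param mca_dims retained MCA dimensions.
#' @param score_cfg a [score_config()]; defaults to the unit-weight preset.
#' @param purify iterate DIF purification.
#' @param seed RNG seed recorded in the manifest (only simulation draws
#'   random numbers; estimation is deterministic).
#' @param verbose narrate stages.
#' @return (invisibly) a list of all stage results; files under `out_dir`.
#' @export
run_pipeline <- function(input, covariates = NULL, out_dir,
                         reversal_items = c(1, 5), alpha = 0.01,
                         bands = c(0.035, 0.07), ld_threshold = 0.4,
                         mca_dims = 4, score_cfg = NULL, purify = TRUE,
                         seed = NULL, verbose = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    msg(sprintf("[%s]", name), verbose = verbose)
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  results <- list()

  m <- stage("load", {
    if (inherits(input, "response_matrix")) input
    else if (inherits(input, "simulation_config")) {
      if (!is.null(seed)) input$seed <- as.integer(seed)
      co <- generate_cohort(input)
      write_cohort(co, file.path(out_dir, "cohort"))
      results$ground_truth <- co[c("theta", "params", "dif_truth")]
      co$matrix
    } else load_responses(input, covariates = covariates %||% character(),
                          verbose = verbose)
  })
  if (is.null(covariates)) covariates <- names(m$groups)
  missing_cov <- setdiff(covariates, names(m$groups))
  if (length(missing_cov)) {
    stop(sprintf("covariate(s) not in input: %s",
                 paste(missing_cov, collapse = ", ")))
  }
  J_full <- n_items(m)

  results$descriptives <- stage("descriptives", {
    tab <- endorsement_table(m)
    write_tsv_file(tab, file.path(out_dir, "table1_endorsement.tsv"))
    tab
  })

  results$score <- stage("score", {
    cfg <- score_cfg %||% epices_unit_config(J_full)
    sc <- epices_score(m, cfg)
    write_tsv_file(sc, file.path(out_dir, "scores.tsv"))
    sc
  })

  m <- stage("reversal", {
    msg(sprintf("  reversing item(s): %s",
                paste(reversal_items, collapse = ", ")), verbose = verbose)
    reverse_items(m, reversal_items)
  })

  bank_full <- stage("grm_fit", fit_grm(m))
  theta_full <- eap_scores(m, bank_full)
  write_item_bank(bank_full, file.path(out_dir, "grm_items_full.tsv"))

  diag_full <- stage("diagnostics", {
    d <- irt_diagnostics(m, bank_full, theta_full,
                         flag_threshold = ld_threshold,
                         covariate = covariates[1])
    write_tsv_file(d$item_fit, file.path(out_dir, "item_fit_full.tsv"))
    jsonlite::write_json(
      list(eigenvalues = d$residual_pca$eigenvalues,
           unidimensional = d$residual_pca$unidimensional,
           flagged_pairs = d$local_independence$flagged,
           removal_recommendation = d$removal_recommendation),
      file.path(out_dir, "diagnostics_full.json"),
      auto_unbox = TRUE, digits = 10)
    d
  })
  results$diagnostics_full <- diag_full

  removed <- diag_full$removal_recommendation
  m_red <- m
  bank <- bank_full
  theta <- theta_full
  if (length(removed)) {
    stage("item_removal", {
      msg(sprintf("  removing item(s) %s (%d -> %d items)",
                  paste(removed, collapse = ", "), J_full,
                  J_full - length(removed)), verbose = verbose)
      m_red <- subset_responses(m, items = setdiff(seq_len(J_full), removed))
      bank <- fit_grm(m_red)
      theta <- eap_scores(m_red, bank)
      write_item_bank(bank, file.path(out_dir, "grm_items_reduced.tsv"))
      results$diagnostics_reduced <-
        irt_diagnostics(m_red, bank, theta, flag_threshold = ld_threshold)
    })
  }
  results$removed_items <- removed
  utils::write.table(
    data.frame(respondent_id = theta$respondent_id, theta = theta$theta,
               se = theta$se),
    file.path(out_dir, "theta_eap.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)

  results$dif <- stage("dif", {
    out <- list()
    for (cv in covariates) {
      res <- detect_dif(m_red, cv, theta = theta, purify = purify,
                        alpha = alpha, bands = bands)
      write_tsv_file(dif_table(res),
                     file.path(out_dir, sprintf("table3_dif_%s.tsv", cv)))
      out[[cv]] <- res
    }
    out
  })

  results$impact <- stage("impact", {
    out <- list()
    for (cv in covariates) {
      th_aware <- theta_dif_aware(m_red, cv, results$dif[[cv]])
      rep <- correlation_report(results$score$score, theta, th_aware)
      out[[cv]] <- rep
      jsonlite::write_json(unclass(rep),
                           file.path(out_dir, sprintf("impact_%s.json", cv)),
                           auto_unbox = TRUE, digits = 10)
    }
    out
  })

  results$alpha <- stage("cronbach_alpha", {
    al <- list(full = cronbach_alpha(m))
    if (length(removed)) al$reduced <- cronbach_alpha(m_red)
    jsonlite::write_json(al, file.path(out_dir, "cronbach_alpha.json"),
                         auto_unbox = TRUE, digits = 10)
    al
  })

  results$mca <- stage("mca", {
    run_mca <- function(mm) contribution_table(rotate_mca(mca_fit(mm, mca_dims)))
    out <- list(full = list(whole = run_mca(m)))
    if (length(removed)) out$reduced <- list(whole = run_mca(m_red))
    g <- m$groups[[covariates[1]]]
    for (lev in sort(unique(g))) {
      sel <- which(g == lev)
      out$full[[lev]] <- run_mca(subset_responses(m, respondents = sel))
      if (length(removed)) {
        out$reduced[[lev]] <- run_mca(subset_responses(m_red, respondents = sel))
      }
    }
    tab4 <- do.call(rbind, lapply(names(out$full), function(nm) {
      ct <- out$full[[nm]]
      data.frame(sample = nm, item = rownames(ct$values),
                 round(ct$values, 3), check.names = FALSE)
    }))
    write_tsv_file(tab4, file.path(out_dir, "table4_mca_contributions.tsv"))
    out
  })

  stage("manifest", {
    manifest <- list(
      package_version = as.character(utils::packageVersion("epicesdif")),
      r_version = R.version.string,
      seed = seed,
      settings = list(reversal_items = reversal_items, alpha = alpha,
                      bands = bands, ld_threshold = ld_threshold,
                      mca_dims = mca_dims, purify = purify,
                      covariates = covariates),
      n_respondents = n_respondents(m),
      items_full = J_full, items_removed = removed)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, null = "null")
  })
  invisible(results)
}
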