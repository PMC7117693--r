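#' Fit the three nested logistic DIF models for one item
#'
#' The hybrid ordinal logistic regression procedure conditions on the
#' IRT-estimated latent trait and compares, per item and group pair:
#' model 1 (no DIF) `logit P(y=1) = b0 + b1 theta`; model 2 (uniform DIF)
#' adds a group main effect; model 3 (non-uniform DIF) adds the
#' theta-by-group interaction. With binary items the ordinal logistic
#' reduces to ordinary binary logistic regression. An intercept-only fit
#' supplies the null log-likelihood for McFadden pseudo-R2.
#'
#' @param y binary item responses.
#' @param theta latent trait estimates (finite).
#' @param group factor (or coercible) with at least two observed levels;
#'   treatment coding with the first level as reference (likelihood-ratio
#'   statistics and pseudo-R2 differences are invariant to this choice).
#' @return list with log-likelihoods `ll0` (null), `ll1`, `ll2`, `ll3`, and
#'   `unstable` (TRUE when quasi-perfect separation was detected).
#' @export
fit_nested_models <- function(y, theta, group) {
  group <- droplevels(as.factor(group))
  if (nlevels(group) < 2) stop("need at least two groups in the comparison")
  if (any(!is.finite(theta))) stop("theta must be finite")
  dat <- data.frame(y = y, theta = theta, group = group)
  ctl <- stats::glm.control(epsilon = 1e-10, maxit = 100)
  # separation is detected below via coefficient size, so glm's own
  # "fitted probabilities 0 or 1" warnings are redundant noise
  m0 <- suppressWarnings(stats::glm(y ~ 1, family = stats::binomial(),
                                    data = dat, control = ctl))
  m1 <- suppressWarnings(stats::glm(y ~ theta, family = stats::binomial(),
                                    data = dat, control = ctl))
  m2 <- suppressWarnings(stats::glm(y ~ theta + group,
                                    family = stats::binomial(), data = dat,
                                    control = ctl))
  m3 <- suppressWarnings(stats::glm(y ~ theta * group,
                                    family = stats::binomial(), data = dat,
                                    control = ctl))
  unstable <- any(vapply(list(m1, m2, m3), function(m) {
    !m$converged || any(abs(stats::coef(m)[-1]) > 15, na.rm = TRUE)
  }, logical(1)))
  list(ll0 = as.numeric(stats::logLik(m0)), ll1 = as.numeric(stats::logLik(m1)),
       ll2 = as.numeric(stats::logLik(m2)), ll3 = as.numeric(stats::logLik(m3)),
       unstable = unstable)
}

#' Likelihood ratio test between nested fits
#'
#' @param ll_small,ll_big log-likelihoods of the smaller and larger model.
#' @param df difference in parameter count.
#' @param tolerance allowed negative slack before an inverted nesting is an
#'   error.
#' @return list with `chisq` and `p`.
#' @export
lrt <- function(ll_small, ll_big, df, tolerance = 1e-6) {
  chisq <- 2 * (ll_big - ll_small)
  if (chisq < -tolerance) stop("nesting violated: larger model has lower likelihood")
  chisq <- max(chisq, 0)
  list(chisq = chisq, p = stats::pchisq(chisq, df = df, lower.tail = FALSE))
}

#' McFadden pseudo-R2 difference between nested fits
#'
#' `R2(M) = 1 - ll(M)/ll(null)`; the difference between the larger and
#' smaller model's R2 gauges DIF magnitude (conventional bands 0.035, 0.07).
#'
#' @param ll_null intercept-only log-likelihood for the same item and
#'   observations.
#' @param ll_small,ll_big nested model log-likelihoods.
#' @return the R2 difference (non-negative up to numerical tolerance).
#' @export
mcfadden_delta <- function(ll_null, ll_small, ll_big) {
  if (ll_null == 0) stop("degenerate item: null log-likelihood is zero")
  (1 - ll_big / ll_null) - (1 - ll_small / ll_null)
}

#' Classify DIF type and magnitude from the three-model statistics
#'
#' Non-uniform DIF is declared when the model-3 vs model-2 likelihood-ratio
#' test is significant (magnitude read from its R2 difference); otherwise
#' uniform DIF when the model-2 vs model-1 test is significant (magnitude
#' from that R2 difference); otherwise no DIF and the magnitude is not
#' assessed. Magnitude bands: below `bands[1]` negligible, from `bands[1]`
#' up to (but excluding) `bands[2]` moderate, `bands[2]` and above important.
#'
#' @param p21,p32 likelihood-ratio p-values (model 2 vs 1, model 3 vs 2).
#' @param dr21,dr32 McFadden R2 differences for the same comparisons.
#' @param alpha significance level (0.01).
#' @param bands magnitude thresholds (0.035, 0.07).
#' @return data.frame with `type` in {no-DIF, uniform, non-uniform} and
#'   `magnitude` in {negligible, moderate, important, not-assessed}
#'   (vectorized over the inputs).
#' @export
classify_dif <- function(p21, p32, dr21, dr32, alpha = 0.01,
                         bands = c(0.035, 0.07)) {
  stopifnot(length(bands) == 2, bands[1] < bands[2])
  n <- max(length(p21), length(p32), length(dr21), length(dr32))
  p21 <- rep_len(p21, n); p32 <- rep_len(p32, n)
  dr21 <- rep_len(dr21, n); dr32 <- rep_len(dr32, n)
  band_of <- function(dr) {
    ifelse(dr < bands[1], "negligible",
           ifelse(dr < bands[2], "moderate", "important"))
  }
  type <- ifelse(p32 < alpha, "non-uniform",
                 ifelse(p21 < alpha, "uniform", "no-DIF"))
  magnitude <- ifelse(type == "non-uniform", band_of(dr32),
                      ifelse(type == "uniform", band_of(dr21), "not-assessed"))
  near <- (abs(dr21 - bands[1]) < 1e-6 | abs(dr21 - bands[2]) < 1e-6 |
           abs(dr32 - bands[1]) < 1e-6 | abs(dr32 - bands[2]) < 1e-6)
  if (any(near & type != "no-DIF")) {
    message("R2 difference within 1e-6 of a magnitude boundary; assigned to the higher band")
  }
  data.frame(type = type, magnitude = magnitude, stringsAsFactors = FALSE)
}

# run the three-model procedure for every item x one group pair
dif_one_comparison <- function(Y, theta, group, comparison, alpha, bands) {
  J <- ncol(Y)
  out <- vector("list", J)
  for (j in seq_len(J)) {
    fits <- fit_nested_models(Y[, j], theta, group)
    t21 <- lrt(fits$ll1, fits$ll2, df = 1)
    t32 <- lrt(fits$ll2, fits$ll3, df = 1)
    t31 <- lrt(fits$ll1, fits$ll3, df = 2)
    dr21 <- mcfadden_delta(fits$ll0, fits$ll1, fits$ll2)
    dr32 <- mcfadden_delta(fits$ll0, fits$ll2, fits$ll3)
    cls <- classify_dif(t21$p, t32$p, dr21, dr32, alpha, bands)
    out[[j]] <- data.frame(
      item = j, label = colnames(Y)[j], comparison = comparison,
      chisq21 = t21$chisq, p21 = t21$p, chisq32 = t32$chisq, p32 = t32$p,
      chisq31 = t31$chisq, p31 = t31$p, dr21 = dr21, dr32 = dr32,
      type = cls$type, magnitude = cls$magnitude,
      flagged = t31$p < alpha, unstable = fits$unstable,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Detect differential item functioning via hybrid logistic regression
#'
#' For every item and every pairwise group comparison of the chosen covariate,
#' runs the three-model procedure on the GRM-based EAP trait estimate. The
#' screening flag for an item is the 2-df total likelihood-ratio test (model 3
#' vs model 1) at `alpha`, so the per-item false-positive rate under no DIF is
#' alpha; the uniform/non-uniform classification and its magnitude follow the
#' sequential 2-vs-1 and 3-vs-2 tests. With `purify = TRUE` the latent trait
#' is iteratively re-estimated from the currently unflagged (anchor) items
#' until the flag set stabilises.
#'
#' @param m a [response_matrix()] (direction-aligned coding).
#' @param covariate name of the grouping covariate.
#' @param theta optional precomputed `theta_estimates`; fitted from `m` when
#'   NULL.
#' @param pairwise analyse all group pairs (TRUE) or require exactly two
#'   groups.
#' @param purify iterate anchor-based trait re-estimation.
#' @param max_purify_iter cap on purification rounds.
#' @param alpha LRT significance level.
#' @param bands McFadden R2 magnitude thresholds.
#' @param quadrature_points for internal GRM refits during purification.
#' @return object of class `dif_result`: data.frame of per item x comparison
#'   statistics with attributes `purify_iterations`, `anchors`, `theta`.
#' @export
detect_dif <- function(m, covariate, theta = NULL, pairwise = TRUE,
                       purify = TRUE, max_purify_iter = 10, alpha = 0.01,
                       bands = c(0.035, 0.07), quadrature_points = 49) {
  if (!covariate %in% names(m$groups)) {
    stop(sprintf("covariate '%s' not declared", covariate))
  }
  grp <- m$groups[[covariate]]
  levels_g <- sort(unique(grp))
  if (length(levels_g) < 2) stop("fewer than two groups")
  if (!pairwise && length(levels_g) != 2) {
    stop("pairwise = FALSE requires exactly two groups")
  }
  pair_list <- utils::combn(levels_g, 2, simplify = FALSE)
  Y <- m$responses
  J <- ncol(Y)
  if (is.null(theta)) theta <- eap_scores(m, fit_grm(m, quadrature_points))
  run_all <- function(th) {
    do.call(rbind, lapply(pair_list, function(pr) {
      keep <- grp %in% pr
      dif_one_comparison(Y[keep, , drop = FALSE], th$theta[keep],
                         factor(grp[keep], levels = pr),
                         paste(pr, collapse = " vs "), alpha, bands)
    }))
  }
  res <- run_all(theta)
  flags <- sort(unique(res$item[res$flagged]))
  iters <- 0L
  if (purify) {
    repeat {
      if (iters >= max_purify_iter) break
      anchors <- setdiff(seq_len(J), flags)
      if (length(anchors) < 2) break   # cannot anchor on fewer than 2 items
      anchor_m <- subset_responses(m, items = anchors)
      theta <- eap_scores(anchor_m, fit_grm(anchor_m, quadrature_points))
      res <- run_all(theta)
      new_flags <- sort(unique(res$item[res$flagged]))
      iters <- iters + 1L
      if (identical(new_flags, flags)) break
      flags <- new_flags
    }
  }
  structure(res, class = c("dif_result", "data.frame"),
            purify_iterations = iters,
            anchors = setdiff(seq_len(J), flags), theta = theta,
            alpha = alpha, bands = bands, covariate = covariate)
}

#' Format a DIF result as a publication-style table
#'
#' One row per item and comparison with the two sequential LRT p-values and,
#' where the corresponding test is significant, the McFadden R2 difference;
#' magnitudes at or above the moderate band are marked.
#'
#' @param res a `dif_result`
#' @return data.frame in display format.
#' @export
dif_table <- function(res) {
  fmt_p <- function(p) ifelse(p < 0.001, "<0.001", sprintf("%.3f", p))
  alpha <- attr(res, "alpha")
  show21 <- res$p21 < alpha & res$type == "uniform"
  show32 <- res$p32 < alpha & res$type == "non-uniform"
  mark <- function(dr, show) {
    ifelse(!show, "-",
           ifelse(dr < attr(res, "bands")[1], sprintf("<%.3f", attr(res, "bands")[1]),
                  sprintf("*%.3f*", dr)))
  }
  data.frame(comparison = res$comparison, item = res$item, label = res$label,
             chi21_p = fmt_p(res$p21), chi32_p = fmt_p(res$p32),
             dR2_21 = mark(res$dr21, show21), dR2_32 = mark(res$dr32, show32),
             classification = paste(res$type, res$magnitude, sep = "/"),
             stringsAsFactors = FALSE)
}
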