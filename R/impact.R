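#' Multi-group GRM with group-specific parameters for DIF items
#'
#' EM estimation in which "free" (DIF-flagged) items receive separate slope
#' and difficulty per group while anchor items share parameters across
#' groups and identify a common latent scale. The reference group's latent
#' distribution is fixed at Normal(0, 1); the other groups' means and SDs are
#' estimated (standard anchor-item scale linking). Quadrature uses a fixed
#' equally spaced grid with normal prior weights per group so that node
#' locations do not move as group distributions are updated.
#'
#' @param m a [response_matrix()]
#' @param covariate grouping covariate name.
#' @param free_items integer indices of items given group-specific parameters.
#' @param grid_points,grid_range latent grid resolution and extent.
#' @param tol,max_iter EM convergence controls.
#' @return object of class `multigroup_bank`: `items` (anchor rows with
#'   `group = NA`, free rows per group), `group_dist` (per-group mean/sd),
#'   fit metadata.
#' @export
fit_grm_multigroup <- function(m, covariate, free_items,
                               grid_points = 81, grid_range = c(-8, 8),
                               tol = 1e-4, max_iter = 300) {
  grp <- m$groups[[covariate]]
  if (is.null(grp)) stop(sprintf("covariate '%s' not declared", covariate))
  groups <- sort(unique(grp))
  G <- length(groups)
  Y <- m$responses
  J <- ncol(Y)
  free_items <- sort(unique(as.integer(free_items)))
  anchors <- setdiff(seq_len(J), free_items)
  if (!length(anchors)) stop("all items are DIF-flagged: no anchor items left to link the scale")
  nodes <- seq(grid_range[1], grid_range[2], length.out = grid_points)
  # parameters: a,b as G x J matrices (anchor columns kept identical)
  pbar <- colMeans(Y)
  a <- matrix(1, G, J, dimnames = list(groups, colnames(Y)))
  b <- matrix(rep(-stats::qlogis(pbar), each = G), G, J,
              dimnames = list(groups, colnames(Y)))
  mu <- stats::setNames(rep(0, G), groups)
  sg <- stats::setNames(rep(1, G), groups)
  idx_g <- lapply(groups, function(g) which(grp == g))
  names(idx_g) <- groups
  X <- cbind(1, nodes)
  ll_trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  fit_logistic <- function(r, n, a0, b0) {
    fit <- suppressWarnings(
      stats::glm.fit(X, clamp(r / pmax(n, 1e-12), 0, 1), weights = n,
                     family = stats::binomial(), start = c(-a0 * b0, a0)))
    beta <- fit$coefficients
    aj <- beta[2]; bj <- -beta[1] / beta[2]
    if (!is.finite(aj) || !is.finite(bj) || aj <= 0) c(a0, b0)
    else c(clamp(aj, 0.05, 10), clamp(bj, -8, 8))
  }
  for (iter in seq_len(max_iter)) {
    ll <- 0
    nk <- matrix(0, G, grid_points, dimnames = list(groups, NULL))
    rk <- array(0, c(G, grid_points, J))
    for (gi in seq_len(G)) {
      g <- groups[gi]
      w <- stats::dnorm(nodes, mu[g], sg[g])
      w <- w / sum(w)
      P <- stats::plogis(outer(nodes, b[g, ], "-") *
                           rep(a[g, ], each = grid_points))
      post <- posterior_over_nodes(Y[idx_g[[g]], , drop = FALSE], P, w)
      ll <- ll + post$loglik
      nk[gi, ] <- colSums(post$posterior)
      rk[gi, , ] <- crossprod(post$posterior, Y[idx_g[[g]], , drop = FALSE])
    }
    ll_trace <- c(ll_trace, ll)
    if (abs(ll - ll_old) < tol && iter > 1) { converged <- TRUE; break }
    ll_old <- ll
    # M-step: anchors pooled over groups, free items per group
    for (j in anchors) {
      rj <- if (G > 1) colSums(rk[, , j]) else rk[1, , j]
      ab <- fit_logistic(rj, colSums(nk), a[1, j], b[1, j])
      a[, j] <- ab[1]; b[, j] <- ab[2]
    }
    for (j in free_items) for (gi in seq_len(G)) {
      ab <- fit_logistic(rk[gi, , j], nk[gi, ], a[gi, j], b[gi, j])
      a[gi, j] <- ab[1]; b[gi, j] <- ab[2]
    }
    # latent distribution update (reference group fixed at N(0,1))
    for (g in groups[-1]) {
      ng <- sum(nk[g, ])
      mu[g] <- sum(nk[g, ] * nodes) / ng
      sg[g] <- sqrt(max(sum(nk[g, ] * nodes^2) / ng - mu[g]^2, 1e-4))
    }
  }
  if (!converged) warning("multi-group GRM EM did not converge")
  items <- rbind(
    if (length(anchors)) data.frame(item = anchors,
                                    label = colnames(Y)[anchors],
                                    group = NA_character_,
                                    a = a[1, anchors], b = b[1, anchors],
                                    stringsAsFactors = FALSE),
    do.call(rbind, lapply(free_items, function(j) {
      data.frame(item = j, label = colnames(Y)[j], group = groups,
                 a = a[, j], b = b[, j], stringsAsFactors = FALSE)
    })))
  items <- items[order(items$item), ]
  rownames(items) <- NULL
  structure(list(items = items, a = a, b = b,
                 group_dist = data.frame(group = groups, mean = unname(mu),
                                         sd = unname(sg),
                                         stringsAsFactors = FALSE),
                 free_items = free_items, anchors = anchors,
                 covariate = covariate, loglik = ll,
                 loglik_trace = ll_trace, converged = converged,
                 nodes = nodes),
            class = "multigroup_bank")
}

# EAP under the multi-group model: each respondent scored with their group's
# item parameters and latent prior
eap_scores_multigroup <- function(m, mg) {
  grp <- m$groups[[mg$covariate]]
  Y <- m$responses
  n <- nrow(Y)
  theta <- numeric(n)
  se <- numeric(n)
  K <- length(mg$nodes)
  for (g in unique(grp)) {
    i <- which(grp == g)
    d <- mg$group_dist[mg$group_dist$group == g, ]
    w <- stats::dnorm(mg$nodes, d$mean, d$sd)
    w <- w / sum(w)
    P <- stats::plogis(outer(mg$nodes, mg$b[g, ], "-") *
                         rep(mg$a[g, ], each = K))
    post <- posterior_over_nodes(Y[i, , drop = FALSE], P, w)
    theta[i] <- as.numeric(post$posterior %*% mg$nodes)
    m2 <- as.numeric(post$posterior %*% mg$nodes^2)
    se[i] <- sqrt(pmax(m2 - theta[i]^2, 0))
  }
  structure(data.frame(respondent_id = m$respondent_id, theta = theta,
                       se = se, stringsAsFactors = FALSE),
            class = c("theta_estimates", "data.frame"))
}

#' DIF-aware latent trait estimation
#'
#' Re-estimates the latent trait while letting DIF-flagged items carry
#' group-specific parameters (anchored multi-group model); unflagged items
#' link the scale. With no flagged items this reduces exactly to the plain
#' single-group fit and EAP scoring.
#'
#' @param m a [response_matrix()]
#' @param covariate grouping covariate name.
#' @param dif_flags either a `dif_result` (from [detect_dif()]) or integer
#'   item indices to free.
#' @param free_magnitude when `dif_flags` is a `dif_result`, free the items
#'   whose classified magnitude falls in this set in any comparison
#'   (default: moderate and important); use
#'   `free_magnitude = "significant"` to free every LRT-flagged item.
#' @param ... passed to [fit_grm_multigroup()].
#' @return a `theta_estimates` data.frame, with the fitted model in
#'   attribute `bank`.
#' @export
theta_dif_aware <- function(m, covariate, dif_flags,
                            free_magnitude = c("moderate", "important"),
                            ...) {
  if (inherits(dif_flags, "dif_result")) {
    if (identical(free_magnitude, "significant")) {
      free_items <- unique(dif_flags$item[dif_flags$flagged])
    } else {
      free_items <- unique(dif_flags$item[dif_flags$magnitude %in% free_magnitude])
    }
  } else {
    free_items <- as.integer(dif_flags)
  }
  if (!length(free_items)) {
    bank <- fit_grm(m)
    th <- eap_scores(m, bank)
    attr(th, "bank") <- bank
    return(th)
  }
  mg <- fit_grm_multigroup(m, covariate, free_items, ...)
  th <- eap_scores_multigroup(m, mg)
  attr(th, "bank") <- mg
  th
}

#' Correlation-based DIF impact report
#'
#' Pearson correlations between the questionnaire sum score and the latent
#' trait estimated without and with DIF-specific parameters, and between the
#' two latent estimates. Under the convention that a high score means high
#' precariousness while a high latent value means low precariousness, the
#' score-trait correlations are negative.
#'
#' @param score per-respondent sum scores.
#' @param theta_naive latent estimates ignoring DIF (vector or
#'   `theta_estimates`).
#' @param theta_aware latent estimates with DIF-specific parameters.
#' @return object of class `impact_report` with the three correlations.
#' @export
correlation_report <- function(score, theta_naive, theta_aware) {
  if (is.data.frame(theta_naive)) theta_naive <- theta_naive$theta
  if (is.data.frame(theta_aware)) theta_aware <- theta_aware$theta
  if (is.data.frame(score)) score <- score$score
  n <- length(score)
  if (length(theta_naive) != n || length(theta_aware) != n) {
    stop("inputs must align by respondent")
  }
  if (stats::sd(score) == 0 || stats::sd(theta_naive) == 0 ||
      stats::sd(theta_aware) == 0) stop("zero-variance input")
  structure(list(
    r_score_naive = stats::cor(score, theta_naive),
    r_score_aware = stats::cor(score, theta_aware),
    r_naive_aware = stats::cor(theta_naive, theta_aware),
    n = n), class = "impact_report")
}

#' @export
print.impact_report <- function(x, ...) {
  cat(sprintf("DIF impact (n = %d):\n", x$n))
  cat(sprintf("  r(score, theta ignoring DIF)   = %.3f\n", x$r_score_naive))
  cat(sprintf("  r(score, theta with DIF)       = %.3f\n", x$r_score_aware))
  cat(sprintf("  r(theta ignoring, theta with)  = %.3f\n", x$r_naive_aware))
  invisible(x)
}
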