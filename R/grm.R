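#' Gauss-Hermite quadrature for a standard normal latent trait
#'
#' Nodes and weights of n-point Gauss-Hermite quadrature, rescaled so that
#' `sum(weights * f(nodes))` approximates `E[f(theta)]` with
#' `theta ~ Normal(0, 1)`.
#'
#' @param n number of nodes.
#' @return list with `nodes` and `weights` (weights sum to 1).
#' @export
grm_quadrature <- function(n = 49) {
  gh <- pracma::gaussHermite(n)
  list(nodes = gh$x * sqrt(2), weights = gh$w / sqrt(pi))
}

#' Two-parameter logistic item characteristic curve
#'
#' `P(yes | theta) = logistic(a (theta - b))`: the binary-item case of the
#' graded response model. The difficulty `b` is the latent level at which the
#' probability of a "yes" answer is 50%; the slope `a` is the item's
#' discriminating capacity.
#'
#' @param theta latent trait value(s).
#' @param a slope (> 0).
#' @param b difficulty.
#' @return probability in (0, 1), strictly increasing in theta.
#' @export
icc_probability <- function(theta, a, b) {
  if (any(a <= 0)) stop("slope must be positive")
  stats::plogis(a * (theta - b))
}

# n x K log-likelihood of each respondent's pattern at each quadrature node.
# Y: n x J binary matrix; P: K x J node-by-item probabilities.
pattern_loglik <- function(Y, P) {
  P <- clamp(P, 1e-12, 1 - 1e-12)   # plogis saturates at extreme nodes
  logP <- log(P)
  log1P <- log1p(-P)
  Y %*% t(logP) + (1 - Y) %*% t(log1P)
}

# marginal log-likelihood and posterior node weights, numerically stabilised
posterior_over_nodes <- function(Y, P, weights) {
  ll_nodes <- pattern_loglik(Y, P)
  ll_nodes <- sweep(ll_nodes, 2, log(weights), "+")
  mx <- apply(ll_nodes, 1, max)
  W <- exp(ll_nodes - mx)
  norm <- rowSums(W)
  list(loglik = sum(log(norm) + mx), posterior = W / norm)
}

#' Fit the binary graded response model (2PL) by marginal maximum likelihood
#'
#' EM with Gauss-Hermite quadrature under a fixed Normal(0, 1) latent prior
#' (the identification constraint). The E-step computes each respondent's
#' posterior over the quadrature nodes; the M-step refits each item's slope
#' and difficulty by a weighted logistic regression of the expected response
#' counts on the node locations. The marginal log-likelihood is monitored and
#' must be non-decreasing across iterations.
#'
#' @param m a [response_matrix()] (or plain 0/1 matrix).
#' @param quadrature_points number of Gauss-Hermite nodes.
#' @param tol convergence tolerance on the change in marginal log-likelihood.
#' @param max_iter maximum EM iterations; non-convergence is flagged, not
#'   silent.
#' @param a_bounds,b_bounds stabilising bounds on slope and difficulty for
#'   near-degenerate items; activations are recorded in the result.
#' @return an object of class `item_bank`: data.frame of per-item `a`, `b`
#'   plus fit metadata (`loglik`, `iterations`, `converged`, `loglik_trace`).
#' @export
fit_grm <- function(m, quadrature_points = 49, tol = 1e-4, max_iter = 500,
                    a_bounds = c(0.05, 10), b_bounds = c(-6, 6)) {
  Y <- if (inherits(m, "response_matrix")) m$responses else as.matrix(m)
  labels <- colnames(Y) %||% paste0("item", seq_len(ncol(Y)))
  J <- ncol(Y)
  if (J < 2) stop("at least two items are required")
  pbar <- colMeans(Y)
  const <- which(pbar %in% c(0, 1))
  if (length(const)) {
    stop(sprintf("degenerate (constant) item(s): %s",
                 paste(labels[const], collapse = ", ")))
  }
  q <- grm_quadrature(quadrature_points)
  a <- rep(1, J)
  b <- -stats::qlogis(pbar)
  ll_trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  clamped <- rep(FALSE, J)
  for (iter in seq_len(max_iter)) {
    P <- stats::plogis(outer(q$nodes, b, "-") * rep(a, each = quadrature_points))
    post <- posterior_over_nodes(Y, P, q$weights)
    ll <- post$loglik
    ll_trace <- c(ll_trace, ll)
    if (ll < ll_old - 1e-6) {
      warning(sprintf("marginal log-likelihood decreased at iteration %d", iter))
    }
    if (abs(ll - ll_old) < tol && iter > 1) { converged <- TRUE; break }
    ll_old <- ll
    nk <- colSums(post$posterior)
    rjk <- crossprod(post$posterior, Y)     # K x J expected "yes" counts
    X <- cbind(1, q$nodes)
    for (j in seq_len(J)) {
      fit <- suppressWarnings(
        stats::glm.fit(X, clamp(rjk[, j] / pmax(nk, 1e-12), 0, 1), weights = nk,
                       family = stats::binomial(),
                       start = c(-a[j] * b[j], a[j])))
      beta <- fit$coefficients
      aj <- beta[2]
      bj <- -beta[1] / beta[2]
      if (!is.finite(aj) || !is.finite(bj)) { aj <- a[j]; bj <- b[j] }
      if (aj < a_bounds[1] || aj > a_bounds[2] ||
          bj < b_bounds[1] || bj > b_bounds[2]) clamped[j] <- TRUE
      a[j] <- clamp(aj, a_bounds[1], a_bounds[2])
      b[j] <- clamp(bj, b_bounds[1], b_bounds[2])
    }
  }
  if (!converged) {
    warning(sprintf("GRM EM did not converge in %d iterations (|dll| = %.2e)",
                    max_iter, abs(ll - ll_old)))
  }
  structure(list(items = data.frame(item = seq_len(J), label = labels,
                                    a = a, b = b, clamped = clamped,
                                    stringsAsFactors = FALSE),
                 loglik = ll, iterations = length(ll_trace),
                 converged = converged, loglik_trace = ll_trace,
                 quadrature_points = quadrature_points),
            class = "item_bank")
}

#' @export
print.item_bank <- function(x, ...) {
  cat(sprintf("item_bank: %d items, logLik = %.2f, %s after %d EM iterations\n",
              nrow(x$items), x$loglik,
              if (x$converged) "converged" else "NOT converged", x$iterations))
  print(x$items[, c("item", "label", "a", "b")], row.names = FALSE, digits = 3)
  invisible(x)
}

#' Write / read an item bank as TSV
#' @param bank an `item_bank`
#' @param path TSV path
#' @export
write_item_bank <- function(bank, path) {
  write_tsv_file(bank$items, path)
}

#' Expected a posteriori latent trait scores
#'
#' Posterior mean and SD of theta for each respondent under the Normal(0, 1)
#' prior and the item bank's parameters, evaluated on a Gauss-Hermite grid.
#' Respondents with identical response patterns receive identical scores.
#'
#' @param m a [response_matrix()] (or plain 0/1 matrix) whose items all appear
#'   in `bank`.
#' @param bank an `item_bank` from [fit_grm()].
#' @param quadrature_points nodes for the posterior integral.
#' @return object of class `theta_estimates`: data.frame with
#'   `respondent_id`, `theta` (EAP) and `se` (posterior SD).
#' @export
eap_scores <- function(m, bank, quadrature_points = 101) {
  Y <- if (inherits(m, "response_matrix")) m$responses else as.matrix(m)
  ids <- if (inherits(m, "response_matrix")) m$respondent_id
         else as.character(seq_len(nrow(Y)))
  labels <- colnames(Y) %||% paste0("item", seq_len(ncol(Y)))
  idx <- match(labels, bank$items$label)
  if (anyNA(idx)) {
    stop(sprintf("item(s) missing from bank: %s",
                 paste(labels[is.na(idx)], collapse = ", ")))
  }
  a <- bank$items$a[idx]
  b <- bank$items$b[idx]
  q <- grm_quadrature(quadrature_points)
  P <- stats::plogis(outer(q$nodes, b, "-") * rep(a, each = quadrature_points))
  post <- posterior_over_nodes(Y, P, q$weights)
  theta <- as.numeric(post$posterior %*% q$nodes)
  m2 <- as.numeric(post$posterior %*% q$nodes^2)
  se <- sqrt(pmax(m2 - theta^2, 0))
  structure(data.frame(respondent_id = ids, theta = theta, se = se,
                       stringsAsFactors = FALSE),
            class = c("theta_estimates", "data.frame"))
}
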