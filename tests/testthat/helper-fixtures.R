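# Shared fixture builders. Everything is generated in code at test time.

# a 10-item configuration matching the study preset's item parameters but
# without DIF, impact or the dependent pair; small knobs for group structure
flat_config <- function(n_per_group = c(A = 300, B = 300), seed = 1,
                        n_items = 10, dif = NULL, impact = NULL,
                        dependent_pair = NULL) {
  preset <- india_like_preset(n_items = n_items, dif = FALSE, impact = FALSE,
                              dependent_pair = FALSE)
  simulation_config(n_per_group = n_per_group,
                    a = preset$a, b = preset$b, dif = dif, impact = impact,
                    dependent_pair = dependent_pair,
                    item_labels = preset$item_labels,
                    covariate = "g", seed = seed)
}

# write a small response CSV and return its path
write_fixture_csv <- function(df) {
  path <- tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

# independent dense-grid EAP oracle: trapezoidal integration of the posterior
# over a 10,001-point grid, written without reference to the package internals
eap_dense_oracle <- function(y, a, b, lo = -8, hi = 8, n_grid = 10001) {
  th <- seq(lo, hi, length.out = n_grid)
  log_lik <- rep(0, n_grid)
  for (j in seq_along(y)) {
    p <- 1 / (1 + exp(-a[j] * (th - b[j])))
    log_lik <- log_lik + y[j] * log(p) + (1 - y[j]) * log(1 - p)
  }
  dens <- exp(log_lik) * stats::dnorm(th)
  sum(th * dens) / sum(dens)
}

# independent logistic log-likelihood maximisation by iterative grid
# refinement (no glm); X includes the intercept column
grid_search_loglik <- function(y, X, rounds = 6, span = 8, pts = 21) {
  k <- ncol(X)
  centre <- rep(0, k)
  ll_fun <- function(beta) {
    eta <- as.numeric(X %*% beta)
    sum(y * eta - log(1 + exp(eta)))
  }
  best <- -Inf
  for (r in seq_len(rounds)) {
    grids <- lapply(seq_len(k), function(i) {
      seq(centre[i] - span, centre[i] + span, length.out = pts)
    })
    combos <- as.matrix(expand.grid(grids))
    lls <- apply(combos, 1, ll_fun)
    best <- max(lls)
    centre <- combos[which.max(lls), ]
    span <- span * 2.2 / (pts - 1)   # shrink around the incumbent
  }
  list(loglik = best, beta = centre)
}

# independent maximum-likelihood logistic fit via optim (for McFadden checks)
optim_logistic_loglik <- function(y, X) {
  nll <- function(beta) {
    eta <- as.numeric(X %*% beta)
    -sum(y * eta - log(1 + exp(eta)))
  }
  fit <- stats::optim(rep(0, ncol(X)), nll, method = "BFGS",
                      control = list(reltol = 1e-14, maxit = 2000))
  -fit$value
}

# two independent blocks of internally correlated binary items (MCA fixtures)
make_block_matrix <- function(n = 1200, seed = 14) {
  set.seed(seed)
  u1 <- rnorm(n); u2 <- rnorm(n)
  Y <- cbind(b1a = rbinom(n, 1, plogis(2.5 * u1)),
             b1b = rbinom(n, 1, plogis(2.5 * u1 - 0.3)),
             b1c = rbinom(n, 1, plogis(2.5 * u1 + 0.3)),
             b2a = rbinom(n, 1, plogis(2.5 * u2)),
             b2b = rbinom(n, 1, plogis(2.5 * u2 - 0.3)),
             b2c = rbinom(n, 1, plogis(2.5 * u2 + 0.3)))
  response_matrix(Y)
}
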