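test_that("the item characteristic curve has 2PL semantics", {
  # at theta = b the yes-probability is exactly one half
  expect_equal(icc_probability(1.3, a = 2, b = 1.3), 0.5)
  # closed form one logit above the difficulty
  expect_equal(icc_probability(1, a = 1, b = 0), 1 / (1 + exp(-1)),
               tolerance = 1e-12)
  # steeper slopes give more extreme probabilities either side of b
  expect_gt(icc_probability(1, a = 2, b = 0), icc_probability(1, a = 0.5, b = 0))
  expect_lt(icc_probability(-1, a = 2, b = 0), icc_probability(-1, a = 0.5, b = 0))
  # strictly increasing in theta
  th <- seq(-4, 4, by = 0.5)
  expect_true(all(diff(icc_probability(th, 1.2, 0.3)) > 0))
  expect_error(icc_probability(0, a = -1, b = 0), "positive")
})

test_that("MML estimation recovers known generating parameters", {
  # tolerances pre-registered from an 8-seed pilot at these conditions
  # (max observed RMSE 0.15 for slopes, 0.16 for difficulties)
  cfg <- flat_config(c(A = 1000, B = 1000), seed = 42)
  co <- generate_cohort(cfg)
  bank <- fit_grm(co$matrix)
  expect_true(bank$converged)
  expect_lt(sqrt(mean((bank$items$a - cfg$a)^2)), 0.25)
  expect_lt(sqrt(mean((bank$items$b - cfg$b)^2)), 0.25)
  # likelihood is non-decreasing across EM iterations
  expect_true(all(diff(bank$loglik_trace) > -1e-6))
})

test_that("degenerate items are refused by name", {
  Y <- cbind(ok = rbinom(50, 1, 0.5), stuck = rep(1L, 50))
  expect_error(fit_grm(response_matrix(Y)), "stuck")
  expect_error(fit_grm(response_matrix(Y[, 1, drop = FALSE])), "two items")
})

test_that("estimates are stable under quadrature refinement", {
  co <- generate_cohort(flat_config(c(A = 400), seed = 8))
  b41 <- fit_grm(co$matrix, quadrature_points = 41, tol = 1e-8)
  b81 <- fit_grm(co$matrix, quadrature_points = 81, tol = 1e-8)
  expect_lt(max(abs(b41$items$a - b81$items$a)), 1e-3)
  expect_lt(max(abs(b41$items$b - b81$items$b)), 1e-3)
})

test_that("reversing every item negates theta and difficulties", {
  co <- generate_cohort(flat_config(c(A = 600), seed = 15))
  m <- co$matrix
  m_rev <- reverse_items(m, seq_len(n_items(m)))
  bank <- fit_grm(m, tol = 1e-7)
  bank_rev <- fit_grm(m_rev, tol = 1e-7)
  expect_equal(bank_rev$items$a, bank$items$a, tolerance = 0.02)
  expect_equal(bank_rev$items$b, -bank$items$b, tolerance = 0.02)
  th <- eap_scores(m, bank)
  th_rev <- eap_scores(m_rev, bank_rev)
  expect_equal(th_rev$theta, -th$theta, tolerance = 0.02)
})

test_that("EAP scoring matches dense-grid numerical integration", {
  a <- c(1.2, 0.8, 1.6)
  b <- c(-0.5, 0.4, 1.1)
  bank <- structure(list(items = data.frame(
    item = 1:3, label = paste0("item", 1:3), a = a, b = b)),
    class = "item_bank")
  patterns <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  colnames(patterns) <- paste0("item", 1:3)
  got <- eap_scores(response_matrix(patterns), bank)$theta
  want <- apply(patterns, 1, eap_dense_oracle, a = a, b = b)
  expect_lt(max(abs(got - want)), 1e-4)
})

test_that("EAP orders extreme patterns and ignores item order", {
  co <- generate_cohort(flat_config(c(A = 500), seed = 23))
  bank <- fit_grm(co$matrix)
  ex <- response_matrix(rbind(rep(0L, 10), rep(1L, 10)),
                        item_labels = co$matrix$item_labels)
  th <- eap_scores(ex, bank)$theta
  expect_lt(th[1], 0)   # all-precarious pattern sits below the mean
  expect_gt(th[2], 0)
  expect_lt(th[1], th[2])
  # permuting item columns leaves the scores unchanged
  perm <- sample(10)
  m_perm <- subset_responses(co$matrix, items = perm)
  expect_equal(eap_scores(m_perm, bank)$theta,
               eap_scores(co$matrix, bank)$theta, tolerance = 1e-12)
  # identical response patterns receive identical scores
  full <- eap_scores(co$matrix, bank)
  key <- apply(co$matrix$responses, 1, paste, collapse = "")
  expect_true(all(tapply(full$theta, key, function(v) diff(range(v))) < 1e-12))
  # item/bank mismatch is an error
  bad <- response_matrix(ex$responses, item_labels = paste0("other", 1:10))
  expect_error(eap_scores(bad, bank), "missing from bank")
})

test_that("latent recovery on the study-sized cohort is strong", {
  cfg <- india_like_preset(n_items = 10, dif = FALSE, impact = FALSE,
                           dependent_pair = FALSE, seed = 2)
  co <- generate_cohort(cfg)
  m <- reverse_items(co$matrix, c(1, 5))
  th <- eap_scores(m, fit_grm(m))
  expect_gt(cor(th$theta, co$theta), 0.8)
})
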