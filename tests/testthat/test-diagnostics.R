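make_residuals <- function(z, p) structure(list(z = z, p = p, n_clamped = 0),
                                           class = "irt_residuals")

test_that("standardized residuals follow their closed form", {
  bank <- structure(list(items = data.frame(
    item = 1:2, label = c("i1", "i2"), a = c(1, 1),
    b = c(0, -stats::qlogis(0.8)))), class = "item_bank")
  m <- response_matrix(cbind(i1 = c(1L, 0L), i2 = c(1L, 0L)))
  th <- data.frame(respondent_id = c("1", "2"), theta = c(0, 0))
  res <- standardized_residuals(m, bank, th)
  # P = 0.5: hit gives +1, miss gives -1
  expect_equal(unname(res$z[1, 1]), 1)
  expect_equal(unname(res$z[2, 1]), -1)
  # P = 0.8: a miss standardises to -2
  expect_equal(unname(res$p[1, 2]), 0.8)
  expect_equal(unname(res$z[2, 2]), -2)
})

test_that("mean squared residual is about 1 under a correct model", {
  cfg <- flat_config(c(A = 4000), seed = 19)
  co <- generate_cohort(cfg)
  bank <- structure(list(items = data.frame(
    item = seq_along(cfg$a), label = cfg$item_labels,
    a = cfg$a, b = cfg$b)), class = "item_bank")
  th <- data.frame(respondent_id = co$matrix$respondent_id, theta = co$theta)
  res <- standardized_residuals(co$matrix, bank, th)
  expect_equal(mean(res$z^2), 1, tolerance = 0.05)
})

test_that("infit and outfit are 1 for unit residuals and flag misfit", {
  z <- matrix(rep(c(1, -1), 10), 20, 2)
  p <- matrix(0.5, 20, 2)
  colnames(z) <- colnames(p) <- c("i1", "i2")
  fit <- infit_outfit(make_residuals(z, p))
  expect_equal(fit$infit, c(1, 1))
  expect_equal(fit$outfit, c(1, 1))
  expect_true(all(fit$in_range))

  # a coin-flip item scored against a confidently discriminating bank misfits
  set.seed(101)
  n <- 3000
  theta <- rnorm(n)
  a <- c(rep(1.5, 5), 2)
  b <- rep(0, 6)
  Y <- sapply(1:5, function(j) rbinom(n, 1, plogis(a[j] * theta)))
  Y <- cbind(Y, coin = rbinom(n, 1, 0.5))
  colnames(Y) <- c(paste0("i", 1:5), "coin")
  bank <- structure(list(items = data.frame(
    item = 1:6, label = colnames(Y), a = a, b = b)), class = "item_bank")
  th <- data.frame(respondent_id = as.character(1:n), theta = theta)
  fit <- infit_outfit(standardized_residuals(response_matrix(Y), bank, th))
  expect_gt(fit$outfit[6], 1.3)
  expect_false(fit$in_range[6])
  expect_true(all(fit$in_range[1:5]))
})

test_that("residual PCA sees white noise as dimensionless", {
  set.seed(7)
  z <- matrix(rnorm(5000 * 8), 5000, 8,
              dimnames = list(NULL, paste0("i", 1:8)))
  pca <- residual_pca(make_residuals(z, matrix(0.5, 5000, 8)))
  expect_true(all(abs(pca$eigenvalues - 1) < 0.12))
  expect_true(pca$unidimensional)
  # trace conservation: eigenvalues of a correlation matrix sum to J
  expect_equal(sum(pca$eigenvalues), 8, tolerance = 1e-8)
  expect_true(all(diff(pca$eigenvalues) <= 1e-12))
})

test_that("a locally dependent pair shows up in residual structure", {
  cfg <- india_like_preset(dif = FALSE, impact = FALSE, seed = 3)
  co <- generate_cohort(cfg)
  m <- reverse_items(co$matrix, c(1, 5))
  bank <- suppressWarnings(fit_grm(m))
  th <- eap_scores(m, bank)
  res <- standardized_residuals(m, bank, th)
  pca <- residual_pca(res)
  # the pair loads together on the top residual component
  l <- pca$loadings
  expect_gt(abs(l[10] * l[11]), 0)
  expect_equal(order(abs(l), decreasing = TRUE)[1:2] %in% c(10, 11),
               c(TRUE, TRUE))
  li <- local_independence(res)
  expect_true(any(li$flagged$item_a == 10 & li$flagged$item_b == 11))
  expect_gt(li$flagged$r[li$flagged$item_a == 10 & li$flagged$item_b == 11],
            0.4)
  # removal rule recommends the later-indexed partner
  expect_true(11 %in% li$removal_recommendation)
})

test_that("independent items are not flagged and duplicates maximally are", {
  co <- generate_cohort(flat_config(c(A = 2000), seed = 13))
  bank <- fit_grm(co$matrix)
  res <- standardized_residuals(co$matrix, bank, eap_scores(co$matrix, bank))
  li <- local_independence(res)
  expect_equal(nrow(li$flagged), 0)

  # two identical residual columns correlate maximally
  z <- res$z
  z[, 2] <- z[, 1]
  li2 <- local_independence(make_residuals(z, res$p))
  expect_true(any(li2$flagged$item_a == 1 & li2$flagged$item_b == 2))
  expect_equal(max(li2$flagged$r), 1, tolerance = 1e-10)
})

test_that("removing the recommended item improves local independence", {
  cfg <- india_like_preset(dif = FALSE, impact = FALSE, seed = 3)
  co <- generate_cohort(cfg)
  m <- reverse_items(co$matrix, c(1, 5))
  diag_full <- irt_diagnostics(m, suppressWarnings(fit_grm(m)))
  removed <- diag_full$removal_recommendation
  expect_length(removed, 1)
  max_off <- function(R) max(abs(R[upper.tri(R)]))
  m_red <- subset_responses(m, items = setdiff(1:11, removed))
  diag_red <- irt_diagnostics(m_red, fit_grm(m_red))
  expect_lt(max_off(diag_red$local_independence$correlations),
            max_off(diag_full$local_independence$correlations))
})

test_that("diagnostics are invariant to respondent ordering", {
  co <- generate_cohort(flat_config(c(A = 300), seed = 17))
  bank <- fit_grm(co$matrix)
  th <- eap_scores(co$matrix, bank)
  d1 <- irt_diagnostics(co$matrix, bank, th)
  set.seed(1)
  perm <- sample(n_respondents(co$matrix))
  m2 <- subset_responses(co$matrix, respondents = perm)
  th2 <- th[perm, ]
  d2 <- irt_diagnostics(m2, bank, th2)
  expect_equal(d2$item_fit$infit, d1$item_fit$infit, tolerance = 1e-12)
  expect_equal(d2$residual_pca$eigenvalues, d1$residual_pca$eigenvalues,
               tolerance = 1e-9)
  expect_equal(d2$local_independence$correlations,
               d1$local_independence$correlations, tolerance = 1e-9)
})
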