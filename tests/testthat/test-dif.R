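test_that("nested model log-likelihoods are ordered and match grid search", {
  # hand-sized dataset: 8 observations, 2 groups, overlapping trait ranges
  y <- c(1, 0, 1, 1, 0, 0, 1, 0)
  theta <- c(0.5, -1.2, 1.8, -0.3, 0.4, -2.0, -1.1, 0.2)
  group <- factor(c("A", "A", "A", "A", "B", "B", "B", "B"))
  fits <- fit_nested_models(y, theta, group)
  expect_true(fits$ll1 >= fits$ll0 - 1e-10)
  expect_true(fits$ll2 >= fits$ll1 - 1e-10)
  expect_true(fits$ll3 >= fits$ll2 - 1e-10)
  # independent oracle: iterative grid search over the coefficient space
  X1 <- cbind(1, theta)
  expect_lt(abs(fits$ll1 - grid_search_loglik(y, X1)$loglik), 1e-4)
  X2 <- cbind(1, theta, as.numeric(group == "B"))
  expect_lt(abs(fits$ll2 - grid_search_loglik(y, X2)$loglik), 1e-4)
})

test_that("group-independent items show no spurious uniform-DIF signal", {
  set.seed(5)
  n <- 4000
  theta <- rnorm(n)
  y <- rbinom(n, 1, plogis(1.2 * theta))
  group <- factor(rep(c("A", "B"), each = n / 2))
  fits <- fit_nested_models(y, theta, group)
  expect_lt(fits$ll2 - fits$ll1, qchisq(0.99, 1) / 2)
})

test_that("the likelihood ratio test follows its chi-square reference", {
  t0 <- lrt(-100, -100, df = 1)
  expect_equal(t0$chisq, 0)
  expect_equal(t0$p, 1)
  # the 1-df critical value at alpha = 0.01
  t1 <- lrt(-100, -100 + 6.6349 / 2, df = 1)
  expect_equal(t1$p, 0.01, tolerance = 1e-4)
  expect_error(lrt(-99, -100, df = 1), "nesting")
})

test_that("McFadden R2 differences match independently maximised fits", {
  # saturated model: R2 reaches its upper bound of 1
  expect_equal(mcfadden_delta(-50, -50, 0), 1)
  expect_equal(mcfadden_delta(-50, -20, -20), 0)
  set.seed(9)
  n <- 150
  theta <- rnorm(n)
  group <- factor(rep(c("A", "B"), length.out = n))
  y <- rbinom(n, 1, plogis(theta + 0.8 * (group == "B")))
  fits <- fit_nested_models(y, theta, group)
  d_pkg <- mcfadden_delta(fits$ll0, fits$ll1, fits$ll2)
  # oracle: each likelihood independently maximised with optim/BFGS
  g <- as.numeric(group == "B")
  ll0 <- optim_logistic_loglik(y, cbind(rep(1, n)))
  ll1 <- optim_logistic_loglik(y, cbind(1, theta))
  ll2 <- optim_logistic_loglik(y, cbind(1, theta, g))
  expect_lt(abs(d_pkg - ((1 - ll2 / ll0) - (1 - ll1 / ll0))), 1e-6)
})

test_that("DIF classification covers every branch of the decision rule", {
  sig <- 0.001; ns <- 0.5
  # exhaustive grid over significance pattern x magnitude band
  grid <- expand.grid(p21 = c(sig, ns), p32 = c(sig, ns),
                      dr = c(0.01, 0.034999, 0.035, 0.05, 0.07, 0.2))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    cls <- classify_dif(g$p21, g$p32, g$dr, g$dr)
    expected_type <- if (g$p32 < 0.01) "non-uniform"
                     else if (g$p21 < 0.01) "uniform" else "no-DIF"
    expect_equal(cls$type, expected_type)
    if (expected_type == "no-DIF") {
      expect_equal(cls$magnitude, "not-assessed")
    } else {
      expect_equal(cls$magnitude,
                   if (g$dr < 0.035) "negligible"
                   else if (g$dr < 0.07) "moderate" else "important")
    }
  }
  # boundary values land in the higher band
  expect_equal(classify_dif(sig, ns, 0.035, 0)$magnitude, "moderate")
  expect_equal(classify_dif(sig, ns, 0.07, 0)$magnitude, "important")
})

test_that("published worked cases classify as reported", {
  # area comparison, insurance item: uniform and important
  c1 <- classify_dif(p21 = 1e-4, p32 = 0.044, dr21 = 0.172, dr32 = 0)
  expect_equal(c1$type, "uniform")
  expect_equal(c1$magnitude, "important")
  # area comparison, social-worker item: non-uniform and important
  c2 <- classify_dif(p21 = 0.016, p32 = 1e-4, dr21 = 0, dr32 = 0.116)
  expect_equal(c2$type, "non-uniform")
  expect_equal(c2$magnitude, "important")
  # neither test significant: no DIF, magnitude not assessed
  c3 <- classify_dif(p21 = 0.448, p32 = 0.2, dr21 = 0.01, dr32 = 0.01)
  expect_equal(c3$type, "no-DIF")
  expect_equal(c3$magnitude, "not-assessed")
})

test_that("injected uniform DIF is detected and classified as uniform", {
  hits <- 0; correct <- 0; reps <- 8
  for (s in seq_len(reps)) {
    cfg <- flat_config(c(A = 500, B = 500), seed = 100 + s,
                       dif = data.frame(item = 4L, group = "B",
                                        delta_b = 1, delta_a_mult = 1))
    co <- generate_cohort(cfg)
    res <- detect_dif(co$matrix, "g")
    r4 <- res[res$item == 4, ]
    hits <- hits + (r4$p21 < 0.01)
    correct <- correct + (r4$type == "uniform")
  }
  expect_gt(hits / reps, 0.5)
  expect_gt(correct / reps, 0.5)
})

test_that("slope-only DIF is flagged through the non-uniform comparison", {
  hits <- 0; reps <- 8
  for (s in seq_len(reps)) {
    cfg <- flat_config(c(A = 500, B = 500), seed = 200 + s,
                       dif = data.frame(item = 4L, group = "B",
                                        delta_b = 0, delta_a_mult = 2))
    co <- generate_cohort(cfg)
    res <- detect_dif(co$matrix, "g")
    r4 <- res[res$item == 4, ]
    hits <- hits + (r4$p32 < 0.01 && r4$type == "non-uniform")
  }
  expect_gt(hits / reps, 0.5)
})

test_that("pairwise comparisons cover all group pairs and validate input", {
  cfg <- india_like_preset(n_items = 10, dependent_pair = FALSE, seed = 6)
  co <- generate_cohort(cfg)
  m <- reverse_items(co$matrix, c(1, 5))
  res <- detect_dif(m, "area", purify = FALSE)
  expect_setequal(unique(res$comparison),
                  c("Dijon vs FG", "Dijon vs FWI", "FG vs FWI"))
  expect_equal(nrow(res), 3 * 10)
  expect_true(all(res$p21 >= 0 & res$p21 <= 1))
  expect_true(all(res$dr21 > -1e-8 & res$dr32 > -1e-8))
  expect_error(detect_dif(m, "nonexistent"), "not declared")
  one <- subset_responses(m, respondents = m$groups$area == "Dijon")
  expect_error(detect_dif(one, "area"), "fewer than two")
})

test_that("results are invariant to group reference and theta orientation", {
  cfg <- flat_config(c(A = 300, B = 300), seed = 33,
                     dif = data.frame(item = 2L, group = "B",
                                      delta_b = 0.8, delta_a_mult = 1))
  co <- generate_cohort(cfg)
  th <- eap_scores(co$matrix, fit_grm(co$matrix))
  res_ab <- detect_dif(co$matrix, "g", theta = th, purify = FALSE)
  # relabel so the alphabetical reference flips
  m2 <- co$matrix
  m2$groups$g <- ifelse(m2$groups$g == "A", "Z", "B")
  res_ba <- detect_dif(m2, "g", theta = th, purify = FALSE)
  expect_equal(res_ba$chisq21, res_ab$chisq21, tolerance = 1e-6)
  expect_equal(res_ba$dr21, res_ab$dr21, tolerance = 1e-8)
  expect_equal(res_ba$dr32, res_ab$dr32, tolerance = 1e-8)
  # negating the conditioning trait changes nothing
  th_neg <- th; th_neg$theta <- -th$theta
  res_neg <- detect_dif(co$matrix, "g", theta = th_neg, purify = FALSE)
  expect_equal(res_neg$chisq21, res_ab$chisq21, tolerance = 1e-6)
  expect_equal(res_neg$chisq32, res_ab$chisq32, tolerance = 1e-6)
})

test_that("purification agrees with the unpurified analysis on one DIF item", {
  cfg <- flat_config(c(A = 500, B = 500), seed = 55,
                     dif = data.frame(item = 4L, group = "B",
                                      delta_b = 1, delta_a_mult = 1))
  co <- generate_cohort(cfg)
  res_on <- detect_dif(co$matrix, "g", purify = TRUE)
  res_off <- detect_dif(co$matrix, "g", purify = FALSE)
  expect_gt(cor(res_on$dr21, res_off$dr21), 0.95)
  expect_true(attr(res_on, "purify_iterations") >= 1)
})
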