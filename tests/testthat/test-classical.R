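test_that("alpha reproduces the Spearman-Brown identity for two items", {
  # two binary items with exactly equal variance and r = 0.5
  x <- c(1, 1, 1, 1, 0, 0, 0, 0)
  y <- c(1, 1, 1, 0, 1, 0, 0, 0)
  expect_equal(cor(x, y), 0.5, tolerance = 1e-12)
  expect_equal(cronbach_alpha(cbind(x, y)), 2 * 0.5 / (1 + 0.5),
               tolerance = 1e-10)
  # duplicated items are perfectly consistent
  expect_equal(cronbach_alpha(cbind(x, x)), 1, tolerance = 1e-12)
  expect_error(cronbach_alpha(cbind(x)), "two items")
  expect_error(cronbach_alpha(cbind(x, 1 - x)), "zero total")
})

test_that("alpha is near zero for independent items and drops 11 -> 10", {
  set.seed(2)
  Y <- matrix(rbinom(5000 * 6, 1, 0.5), 5000, 6)
  expect_lt(abs(cronbach_alpha(Y)), 0.05)
  # structural echo: the full and reduced item sets give different alphas
  co <- generate_cohort(india_like_preset(seed = 8))
  m <- reverse_items(co$matrix, c(1, 5))
  a11 <- cronbach_alpha(m)
  a10 <- cronbach_alpha(m, items = 1:10)
  expect_false(isTRUE(all.equal(a11, a10)))
  # double reversal leaves alpha untouched
  expect_equal(cronbach_alpha(reverse_items(reverse_items(m, 3), 3)), a11)
})

test_that("chi-square endorsement comparison matches the hand formula", {
  # groups with counts (20 yes, 80 no) vs (40 yes, 60 no)
  Y <- matrix(c(rep(1L, 20), rep(0L, 80), rep(1L, 40), rep(0L, 60)), ncol = 1)
  m <- response_matrix(Y, groups = list(g = rep(c("A", "B"), each = 100)),
                       item_labels = "it")
  res <- chi2_endorsement(m, "g")
  expect_equal(res$chisq, 9.5238, tolerance = 1e-4)
  expect_true(res$significant)
  # Yates correction is off by default and changes the statistic when on
  res_c <- chi2_endorsement(m, "g", correct = TRUE)
  expect_false(isTRUE(all.equal(res$chisq, res_c$chisq)))
  # identical group proportions are not flagged
  Y2 <- matrix(rep(c(1L, 0L), 100), ncol = 1)
  m2 <- response_matrix(Y2, groups = list(g = rep(c("A", "B"), each = 100)),
                        item_labels = "it")
  res2 <- chi2_endorsement(m2, "g")
  expect_false(res2$significant)
  expect_equal(res2$p, 1, tolerance = 1e-10)
})

test_that("MCA conserves inertia and orders dimensions", {
  m <- make_block_matrix()
  res <- mca_fit(m, n_keep = 2)
  # eigenvalue sum equals the total inertia of the indicator matrix, which
  # for J complete binary items is (2J/J) - 1 = 1
  expect_equal(sum(res$eigenvalues), res$total_inertia, tolerance = 1e-8)
  expect_equal(res$total_inertia, 1, tolerance = 1e-8)
  expect_true(all(diff(res$eigenvalues) <= 1e-12))
  expect_true(all(res$pct_var >= 0 & res$pct_var <= 100))
  expect_equal(sum(res$pct_var), 100, tolerance = 1e-8)
  # contributions of all items to a dimension sum to one
  expect_equal(unname(colSums(res$contrib_item)),
               rep(1, ncol(res$contrib_item)), tolerance = 1e-8)
  expect_error(mca_fit(subset_responses(m, respondents = 1:10)), "respondents")
})

test_that("independent item blocks separate onto the leading dimensions", {
  res <- rotate_mca(mca_fit(make_block_matrix(), n_keep = 2))
  ct <- contribution_table(res)
  top1 <- rownames(ct$values)[which.max(ct$values[, 1])]
  top2 <- rownames(ct$values)[which.max(ct$values[, 2])]
  blocks <- list(c("b1a", "b1b", "b1c"), c("b2a", "b2b", "b2c"))
  in_block <- function(x) which(vapply(blocks, function(b) x %in% b, TRUE))
  expect_false(in_block(top1) == in_block(top2))
  # every member of the top dimension's block contributes more to it than
  # any member of the other block
  b1 <- blocks[[in_block(top1)]]
  b2 <- blocks[[in_block(top2)]]
  expect_gt(min(ct$values[b1, 1]), max(ct$values[b2, 1]))
})

test_that("rotation preserves the retained block's variance", {
  m <- make_block_matrix(seed = 15)
  res <- mca_fit(m, n_keep = 4)
  rot <- rotate_mca(res)
  expect_equal(sum(rot$eigenvalues[1:4]), sum(res$eigenvalues[1:4]),
               tolerance = 1e-8)
  expect_equal(sum(rot$pct_var[1:4]), sum(res$pct_var[1:4]),
               tolerance = 1e-8)
  # contributions still normalised after rotation
  expect_equal(unname(colSums(rot$contrib_item[, 1:4])), rep(1, 4),
               tolerance = 1e-8)
  # rotating an already-rotated solution is the identity (fixed point)
  rot2 <- rotate_mca(rot)
  angle <- acos(pmin(abs(diag(rot2$rotation)), 1)) * 180 / pi
  expect_lt(max(angle), 1)
  # rotation sharpens or preserves the maximum contribution per dimension
  expect_true(all(apply(rot$contrib_item[, 1:2], 2, max) >=
                  apply(res$contrib_item[, 1:2], 2, max) - 1e-8))
})

test_that("contribution tables blank below threshold but keep full values", {
  res <- rotate_mca(mca_fit(make_block_matrix(), n_keep = 2))
  ct <- contribution_table(res, display_threshold = 0.2)
  expect_true(all(ct$display[ct$values < 0.2] == ""))
  expect_true(all(ct$display[ct$values >= 0.2] != ""))
  # a threshold above every contribution blanks the whole display
  ct_hi <- contribution_table(res, display_threshold = 1.01)
  expect_true(all(ct_hi$display == ""))
  expect_equal(ct_hi$values, ct$values)
})

test_that("the MCA pipeline is deterministic and respondent-order invariant", {
  m <- make_block_matrix()
  r1 <- rotate_mca(mca_fit(m, n_keep = 2))
  r2 <- rotate_mca(mca_fit(m, n_keep = 2))
  expect_identical(r1$contrib_item, r2$contrib_item)
  set.seed(3)
  mp <- subset_responses(m, respondents = sample(n_respondents(m)))
  r3 <- rotate_mca(mca_fit(mp, n_keep = 2))
  expect_equal(r3$eigenvalues, r1$eigenvalues, tolerance = 1e-9)
  expect_equal(abs(unname(r3$contrib_item)), abs(unname(r1$contrib_item)),
               tolerance = 1e-6)
})
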