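test_that("spearman_rho matches the rank-then-Pearson definition", {
  expect_equal(spearman_rho(1:10, (1:10)^3), 1)
  expect_equal(spearman_rho(1:10, rev(1:10)), -1)

  # explicit average-rank oracle for tied data
  x <- c(1, 2, 2, 3); y <- c(3, 1, 2, 2)
  rx <- c(1, 2.5, 2.5, 4); ry <- c(4, 1, 2.5, 2.5)
  expect_equal(spearman_rho(x, y), cor(rx, ry), tolerance = 1e-12)

  for (rep in 1:25) {
    set.seed(rep)
    a <- sample(1:6, 30, replace = TRUE)
    b <- a + sample(-2:2, 30, replace = TRUE)
    expect_equal(spearman_rho(a, b), cor(a, b, method = "spearman"),
                 tolerance = 1e-12)
  }
  expect_error(spearman_rho(rep(1, 5), 1:5), "constant")
  expect_error(spearman_rho(1:4, 1:5), "equal length")
})

test_that("partial correlation equals residualize-both-then-correlate", {
  # no covariates: plain Pearson
  set.seed(3)
  edges <- matrix(rnorm(20 * 8), 20, 8)
  y <- rnorm(20)
  pc <- partial_corr_edges(edges, y)
  expect_equal(pc$r_partial, drop(cor(edges, y)), tolerance = 1e-12)

  # printed 6-row toy table, one covariate
  toy_edges <- cbind(e1 = c(0.10, 0.40, 0.25, 0.80, 0.55, 0.05),
                     e2 = c(0.90, 0.20, 0.70, 0.30, 0.10, 0.60))
  toy_y <- c(12, 25, 18, 41, 30, 9)
  toy_x <- matrix(c(31, 45, 22, 58, 40, 27), ncol = 1)
  pc_toy <- partial_corr_edges(toy_edges, toy_y, toy_x)
  for (e in 1:2) {
    expect_equal(unname(pc_toy$r_partial[e]),
                 partial_corr_oracle(toy_edges[, e], toy_y, toy_x),
                 tolerance = 1e-10)
  }
  # p from the t distribution with n - 2 - c df
  r <- pc_toy$r_partial[1]
  expect_equal(pc_toy$p[1], 2 * pt(-abs(r) * sqrt(3 / (1 - r^2)), df = 3),
               tolerance = 1e-12)

  # randomized oracle equivalence
  for (rep in 1:40) {
    set.seed(200 + rep)
    n <- sample(15:40, 1)
    X <- matrix(rnorm(n * 2), n, 2)
    e <- rnorm(n); yv <- rnorm(n)
    pcr <- partial_corr_edges(matrix(e), yv, X)
    expect_equal(pcr$r_partial, partial_corr_oracle(e, yv, X),
                 tolerance = 1e-10)
  }

  expect_error(partial_corr_edges(edges, rep(2, 20)), "constant")
  expect_error(partial_corr_edges(edges, y, cbind(y, y)), "collinear")
})

test_that("edge selection partitions by sign at the threshold", {
  r <- c(0.5, -0.4, 0.1, -0.9, 0.0)
  p <- c(0.01, 0.20, 0.03, 0.001, 0.5)
  sel <- select_edges(r, p, alpha = 0.05)
  # brute-force elementwise rule
  expect_equal(sel$pos_mask, r > 0 & p < 0.05)
  expect_equal(sel$neg_mask, r < 0 & p < 0.05)
  expect_false(any(sel$pos_mask & sel$neg_mask))

  none <- select_edges(r, rep(1, 5))
  expect_equal(none$n_pos + none$n_neg, 0L)

  all_in <- select_edges(r, p, alpha = 1)
  expect_equal(all_in$n_pos + all_in$n_neg, sum(r != 0))
})

test_that("feature summary is the masked sum of edge strengths", {
  sel <- select_edges(c(1, -1, 1, -1), c(0, 0, 1, 1), alpha = 0.05)
  row <- c(0.2, -0.3, 5, 7)
  expect_equal(summarize_features(row, sel), c(pos_sum = 0.2, neg_sum = -0.3))
  empty <- select_edges(c(1, -1, 1, -1), rep(1, 4))
  expect_equal(summarize_features(row, empty), c(pos_sum = 0, neg_sum = 0))
  set.seed(5)
  for (rep in 1:10) {
    rr <- runif(30, -1, 1); pp <- runif(30)
    s <- select_edges(rr, pp, alpha = 0.3)
    v <- rnorm(30)
    expect_equal(unname(summarize_features(v, s)),
                 c(sum(v[rr > 0 & pp < 0.3]), sum(v[rr < 0 & pp < 0.3])))
  }
})

test_that("fit_cpm recovers an exactly linear positive-sum outcome", {
  set.seed(11)
  n <- 50
  base <- rnorm(n)
  edges <- base + matrix(rnorm(n * 12, sd = 0.1), n, 12)
  fit0 <- fit_cpm(edges, 2 + 3 * rowSums(edges))
  # all edges share the common factor, so all are selected positive and
  # pos_sum = rowSums(edges): the slope and intercept come back exactly
  expect_equal(fit0$selection$n_pos, 12L)
  expect_equal(fit0$selection$n_neg, 0L)
  expect_equal(fit0$coef_pos, 3, tolerance = 1e-8)
  expect_equal(fit0$intercept, 2, tolerance = 1e-8)
  expect_equal(fit0$coef_neg, 0)

  # no selected edges: the model degrades to the training mean
  set.seed(12)
  noise <- matrix(rnorm(40 * 6), 40, 6)
  yv <- rnorm(40)
  fit1 <- fit_cpm(noise, yv, alpha = 1e-12)
  expect_equal(unname(predict(fit1, noise)), rep(mean(yv), 40))
})

test_that("out-of-fold rho on pure noise is centered at zero", {
  meds <- vapply(1:200, function(s) {
    set.seed(s)
    run_cv(matrix(rnorm(100 * 500), 100, 500), rnorm(100),
           k = 10, repeats = 5, seed = 1000 + s)$median_rho
  }, numeric(1))
  expect_lt(abs(mean(meds)), 0.03)
})

test_that("fold partitions are valid and near-equal", {
  f <- make_folds(162, 10, 5, seed = 1)
  for (r in 1:5) {
    sizes <- sort(tabulate(f[, r], 10))
    # 162 = 8 folds of 16 plus 2 of 17
    expect_equal(sizes, c(rep(16L, 8), 17L, 17L))
  }
  for (rep in 1:50) {
    set.seed(rep)
    n <- sample(25:200, 1); k <- sample(2:10, 1)
    fm <- make_folds(n, k, 2, seed = rep)
    expect_equal(sort(unique(fm[, 1])), 1:k)
    expect_lte(diff(range(tabulate(fm[, 1], k))), 1L)
    expect_equal(sum(tabulate(fm[, 1], k)), n)
  }
})

test_that("held-out labels never influence their own predictions", {
  coh <- small_cohort()
  mf <- model_frame(coh, "1m")
  run1 <- run_cv(mf$edges, mf$y, mf$X, k = 5, repeats = 1, seed = 21)
  heldout <- run1$fold_assignments[, 1] == 1
  y2 <- mf$y
  y2[heldout] <- rev(y2[heldout]) + 13
  run2 <- run_cv(mf$edges, y2, mf$X, k = 5, repeats = 1, seed = 21)
  expect_equal(run2$predictions[heldout, 1], run1$predictions[heldout, 1],
               tolerance = 1e-12)
})

test_that("run_cv is deterministic and backend-agnostic", {
  coh <- small_cohort()
  mf <- model_frame(coh, "1m")
  a <- run_cv(mf$edges, mf$y, mf$X, k = 5, repeats = 4, seed = 2)
  b <- run_cv(mf$edges, mf$y, mf$X, k = 5, repeats = 4, seed = 2)
  expect_identical(a$rho_per_repeat, b$rho_per_repeat)
  expect_identical(a$predictions, b$predictions)
  expect_identical(a$fold_assignments, b$fold_assignments)

  r_ref <- run_cv(mf$edges, mf$y, mf$X, k = 5, repeats = 4, seed = 2,
                  backend = "R")
  expect_equal(r_ref$rho_per_repeat, a$rho_per_repeat, tolerance = 1e-10)
  expect_equal(r_ref$predictions, a$predictions, tolerance = 1e-10)
  expect_equal(r_ref$selection_freq_pos, a$selection_freq_pos)
  expect_equal(r_ref$selection_freq_neg, a$selection_freq_neg)
  expect_true(all(abs(a$rho_per_repeat) <= 1))
})

test_that("a constant training outcome aborts the repeat with a warning", {
  set.seed(8)
  edges <- matrix(rnorm(20 * 30), 20, 30)
  y <- c(rep(0, 18), 3, 5)
  # fold 10 holds both nonzero outcomes, so its training fold is constant
  folds <- matrix(c(rep(1:9, each = 2), 10L, 10L), ncol = 1)
  expect_warning(
    run <- run_cv(edges, y, k = 10, repeats = 1, seed = 1, folds = folds),
    "aborted")
  expect_true(is.na(run$rho_per_repeat[1]))
  expect_error(run_cv(edges, rep(1, 20), k = 10, repeats = 1, seed = 1),
               "constant")
})

test_that("cv_score is the median across repeats", {
  run <- structure(list(rho_per_repeat = c(0.1, 0.2, 0.3)), class = "cpm_cv")
  expect_equal(cv_score(run), 0.2)
  run1 <- structure(list(rho_per_repeat = 0.42), class = "cpm_cv")
  expect_equal(cv_score(run1), 0.42)
  set.seed(30)
  v <- runif(100, -1, 1)
  runv <- structure(list(rho_per_repeat = v), class = "cpm_cv")
  sv <- sort(v)  # sort-based oracle: mean of the middle two for even counts
  expect_equal(cv_score(runv), (sv[50] + sv[51]) / 2)
})
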