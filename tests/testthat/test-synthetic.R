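test_that("trajectory mixture draws follow the configured weights", {
  only_low <- trajectory_model(weights = c(low = 1, remitting = 0, moderate = 0,
                                           high = 0, delayed = 0))
  s <- sample_trajectories(200, only_low, seed = 1)
  expect_true(all(s$class == "low"))

  expect_error(trajectory_model(weights = c(low = 0.9, remitting = 0.2,
                                            moderate = 0, high = 0, delayed = 0)),
               "sum to 1")

  m <- trajectory_model()
  big <- sample_trajectories(20000, m, seed = 2)
  share <- mean(big$class == "low")
  se <- sqrt(m$weights["low"] * (1 - m$weights["low"]) / 20000)
  expect_lt(abs(share - m$weights["low"]), 3 * se)

  # class-conditional latent profile means recover the configured profiles
  s10k <- sample_trajectories(10000, m, seed = 3)
  for (cl in c("low", "high", "delayed")) {
    idx <- s10k$class == cl
    se_cl <- m$subject_sd / sqrt(sum(idx))
    for (tp in 1:3) {
      expect_lt(abs(mean(s10k$latent[idx, tp]) - m$profiles[cl, tp]), 3 * se_cl)
    }
  }
})

test_that("trajectory profiles respect class semantics", {
  m <- trajectory_model()
  expect_gt(m$profiles["remitting", 1], m$profiles["remitting", 3])
  expect_lt(m$profiles["delayed", 1], m$profiles["delayed", 3])
  bad <- m$profiles
  bad["remitting", ] <- c(0, 0.5, 1)
  expect_error(trajectory_model(profiles = bad), "remitting")
})

test_that("simulated CAPS-5 scores respect the instrument's structure", {
  n <- 200
  lat_lo <- matrix(-1e9, n, 3)
  lo <- simulate_caps(lat_lo, seed = 1)
  expect_true(all(lo$total == 0))

  lat_hi <- matrix(1e9, n, 3)
  hi <- simulate_caps(lat_hi, seed = 1)
  expect_true(all(hi$total == 80))  # 20 items x maximum rating 4

  set.seed(4)
  lat <- matrix(rnorm(n * 3, 0.5, 1), n, 3)
  sc <- simulate_caps(lat, seed = 2)
  expect_true(all(sc$items >= 0 & sc$items <= 4))
  expect_true(all(sc$total >= 0 & sc$total <= 80))
  for (tp in 1:3) {
    expect_equal(unname(rowSums(sc$clusters[[tp]])), unname(sc$total[, tp]))
  }
  expect_error(caps_config(items_per_cluster = c(B = 5, C = 2, D = 7, E = 7)),
               "sum to 20")

  # raising latent severity never lowers the expected total
  grid <- c(-1, 0, 1, 2)
  means <- vapply(grid, function(g) {
    mean(simulate_caps(matrix(g, 10000, 1), seed = 3)$total[, 1])
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("planted connectome effects have the configured sign and location", {
  atlas <- synthetic_atlas(20)
  lat <- rnorm(2000)

  # null model: edge-severity correlations centered at 0
  sim0 <- simulate_connectomes(lat, atlas, truth_config(beta = 0, n_planted = 0),
                               seed = 1)
  r0 <- drop(cor(sim0$edges, lat))
  expect_lt(abs(mean(r0)), 0.01)

  # planted negative effects: correlations negative in expectation
  cfg <- truth_config(beta = 0.15, n_planted = 20, pos_fraction = 0)
  sim1 <- simulate_connectomes(lat, atlas, cfg, seed = 2)
  r1 <- drop(cor(sim1$edges, lat))
  expect_true(all(r1[sim1$ground_truth$planted_edges] < 0))
  expect_lt(mean(r1[sim1$ground_truth$planted_edges]), -0.4)
  expect_lt(abs(mean(r1[-sim1$ground_truth$planted_edges])), 0.01)
  expect_true(all(sim1$ground_truth$effects == -0.15))

  # zero scan noise: the scans coincide with their average
  sim2 <- simulate_connectomes(rnorm(30), atlas,
                               truth_config(scan_sd = 0, n_planted = 10),
                               seed = 3)
  expect_equal(sim2$scan_edges[[1]], sim2$scan_edges[[3]])
  expect_equal(sim2$scan_edges[[1]], sim2$edges)

  expect_error(
    simulate_connectomes(lat[1:30], atlas,
                         truth_config(n_planted = 5000, concentration = 1)),
    "infeasible")
})

test_that("planted edges concentrate in the target networks", {
  for (s in 1:5) {
    coh <- small_cohort(seed = s)
    gt <- coh$ground_truth
    in_target <- gt$target_mask[gt$planted_edges]
    expect_gte(mean(in_target), gt$config$concentration - 1e-9)
  }
})

test_that("dropout matches the configured retention and is non-informative", {
  coh <- small_cohort(seed = 2)
  full <- apply_dropout(coh$phenotype, 1, 1, seed = 1)
  expect_false(anyNA(full$caps_total_6m))
  expect_false(anyNA(full$caps_total_14m))

  ph <- generate_cohort(n = 162, n_nodes = 20,
                        truth = truth_config(n_planted = 15), seed = 5)$phenotype
  n6 <- sum(!is.na(ph$caps_total_6m))
  n14 <- sum(!is.na(ph$caps_total_14m))
  expect_gte(n6, qbinom(0.025, 162, 0.84))
  expect_lte(n6, qbinom(0.975, 162, 0.84))
  expect_gte(n14, qbinom(0.025, 162, 0.821))
  expect_lte(n14, qbinom(0.975, 162, 0.821))
  # 14-month completers nest within 6-month completers by default
  expect_true(all(!ph$retained_14m | ph$retained_6m))
  expect_true(all(!is.na(ph$caps_total_6m[!is.na(ph$caps_total_14m)])))

  # retention independent of trajectory class at scale
  m <- trajectory_model()
  s <- sample_trajectories(10000, m, seed = 6)
  ph2 <- data.frame(caps_total_6m = rep(1, 10000))
  drop2 <- apply_dropout(ph2, seed = 7)
  tab <- table(s$class, drop2$retained_6m)
  expect_gt(suppressWarnings(chisq.test(tab)$p.value), 0.001)
})

test_that("generated cohorts are reproducible and pipeline-valid end to end", {
  c1 <- small_cohort(seed = 3)
  c2 <- small_cohort(seed = 3)
  expect_identical(c1$edges, c2$edges)
  expect_identical(c1$phenotype, c2$phenotype)
  expect_identical(c1$scan_edges, c2$scan_edges)

  expect_silent(validate_phenotype(c1$phenotype))
  expect_true(all(c1$phenotype$caps_total_1m >= 0 &
                    c1$phenotype$caps_total_1m <= 80))

  # round trip through disk formats feeds the modeling stage unchanged
  dir <- withr::local_tempdir()
  write_cohort(c1, dir)
  back <- read_cohort(dir)
  expect_equal(unname(back$edges), unname(c1$edges), tolerance = 1e-15)
  mf <- model_frame(back, "1m")
  run <- run_cv(mf$edges, mf$y, mf$X, k = 5, repeats = 2, seed = 1)
  expect_length(run$rho_per_repeat, 2L)
})

test_that("edge selection is enriched in the planted networks across seeds", {
  hits <- 0L
  for (s in 1:20) {
    coh <- generate_cohort(n = 80, n_nodes = 30, seed = 100 + s)
    pc <- partial_corr_edges(coh$edges, coh$phenotype$caps_total_1m,
                             as.matrix(coh$phenotype[, c("age", "sex", "motion")]))
    sel <- select_edges(pc$r_partial, pc$p)
    selected <- sel$pos_mask | sel$neg_mask
    or <- fisher.test(table(factor(selected, c(FALSE, TRUE)),
                            factor(coh$ground_truth$target_mask,
                                   c(FALSE, TRUE))))$estimate
    if (or > 1) hits <- hits + 1L
  }
  expect_gte(hits, 18L)
})
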