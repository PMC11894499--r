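toy_atlas <- function(sizes) {
  data.frame(node_id = paste0("n", seq_len(sum(sizes))),
             network = rep(names(sizes), sizes))
}

test_that("lesion mask keeps edges with at least one endpoint in the network", {
  atlas <- toy_atlas(c(A = 3L, B = 2L))
  mask <- lesion_mask(atlas, "A")
  # exhaustive pair enumeration: 3 within-A + 6 A-B of the 10 edges
  pairs <- edge_pairs(5)
  oracle <- atlas$network[pairs$i] == "A" | atlas$network[pairs$j] == "A"
  expect_identical(mask, oracle)
  expect_equal(sum(mask), 9L)

  all_in <- lesion_mask(toy_atlas(c(A = 5L)), "A")
  expect_true(all(all_in))

  # union over all networks covers every edge
  cover <- lesion_mask(atlas, "A") | lesion_mask(atlas, "B")
  expect_true(all(cover))

  # overlap of two masks is exactly the spanning pairs
  expect_equal(sum(lesion_mask(atlas, "A") & lesion_mask(atlas, "B")), 3L * 2L)

  expect_error(lesion_mask(atlas, "Z"), "not present")
})

test_that("degree centrality satisfies the handshake identity", {
  expect_equal(degree_centrality(rep(FALSE, n_edges(6)), n_nodes = 6),
               rep(0L, 6))
  one <- rep(FALSE, n_edges(6))
  pairs <- edge_pairs(6)
  one[which(pairs$i == 2 & pairs$j == 5)] <- TRUE
  deg <- degree_centrality(one, n_nodes = 6)
  expect_equal(deg, c(0L, 1L, 0L, 0L, 1L, 0L))

  for (rep in 1:20) {
    set.seed(rep)
    n <- sample(4:15, 1)
    mask <- runif(n_edges(n)) < 0.3
    d <- degree_centrality(mask, n_nodes = n)
    expect_equal(sum(d), 2L * sum(mask))
    # per-node enumeration oracle
    ep <- edge_pairs(n)
    for (v in sample(n, 3)) {
      expect_equal(d[v], sum(mask & (ep$i == v | ep$j == v)))
    }
  }
})

test_that("network contribution matrices tally selected edges per pair", {
  atlas <- toy_atlas(c(A = 4L, B = 3L))
  E <- n_edges(7)
  zero <- network_contribution(rep(FALSE, E), atlas = atlas)
  expect_true(all(zero$counts == 0))

  full <- network_contribution(rep(TRUE, E), atlas = atlas)
  expect_true(all(abs(full$density - 1) < 1e-12))
  expect_equal(full$counts["A", "A"], choose(4, 2))
  expect_equal(full$counts["A", "B"], 4 * 3)

  for (rep in 1:15) {
    set.seed(rep)
    mask <- runif(E) < 0.4
    cm <- network_contribution(mask, atlas = atlas)
    expect_identical(cm$counts, t(cm$counts))
    # conservation: unique pairs (incl. diagonal) sum to total selected
    expect_equal(sum(cm$counts[upper.tri(cm$counts, diag = TRUE)]), sum(mask))
    # exhaustive per-pair tally
    ep <- edge_pairs(7)
    lab <- function(v) atlas$network[v]
    aa <- sum(mask & lab(ep$i) == "A" & lab(ep$j) == "A")
    ab <- sum(mask & lab(ep$i) != lab(ep$j))
    bb <- sum(mask & lab(ep$i) == "B" & lab(ep$j) == "B")
    expect_equal(unname(cm$counts["A", "A"]), aa)
    expect_equal(unname(cm$counts["A", "B"]), ab)
    expect_equal(unname(cm$counts["B", "B"]), bb)
    expect_equal(unname(cm$density["A", "B"]), ab / 12)
  }
})

test_that("virtual lesion analysis flags the planted network as driving", {
  coh <- small_cohort(seed = 7, n = 60, n_nodes = 20, beta = 0.3)
  mf <- model_frame(coh, "1m")
  les <- run_lesion_cpm(mf$edges, mf$y, mf$X, coh$atlas, k = 5, repeats = 10,
                        seed = 7)
  expect_equal(nrow(les$summary), 10L)
  expect_true("aDMN" %in% les$driving_networks)
  expect_identical(les$driving_networks,
                   les$summary$network[les$summary$median_rho > les$whole_brain_median])

  # ablating the signal network's edges from the whole brain lowers the score
  mask <- lesion_mask(coh$atlas, "aDMN")
  folds <- make_folds(length(mf$y), 5, 10, seed = 7)
  whole <- run_cv(mf$edges, mf$y, mf$X, k = 5, repeats = 10, seed = 7,
                  folds = folds)
  ablated <- run_cv(mf$edges[, !mask], mf$y, mf$X, k = 5, repeats = 10,
                    seed = 7, folds = folds)
  expect_lt(cv_score(ablated), cv_score(whole))
})
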