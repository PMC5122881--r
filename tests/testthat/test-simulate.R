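# synthetic truth graphs, precision construction, mixed-type simulation

test_that("truth-graph structures have the expected edges", {
  chain <- make_truth_graph(simulation_config(
    n_samples = 10, n_continuous = 4, n_binary = 0, structure = "chain",
    rho = 0.4, n_families = 10))
  expect_equal(truth_edge_keys(chain),
               c("v001|v002", "v002|v003", "v003|v004"))
  blocks <- make_truth_graph(simulation_config(
    n_samples = 10, n_continuous = 6, n_binary = 0,
    structure = "modular_blocks", n_blocks = 2, rho = 0.4, n_families = 10))
  expect_equal(nrow(blocks$edges), 2 * 3 + 1)
  expect_equal(sort(unique(blocks$blocks)), c(1, 2))
  r1 <- make_truth_graph(simulation_config(
    n_samples = 10, n_continuous = 8, n_binary = 0,
    structure = "random_sparse", density = 0.3, rho = 0.4, n_families = 10,
    seed = 12))
  r2 <- make_truth_graph(simulation_config(
    n_samples = 10, n_continuous = 8, n_binary = 0,
    structure = "random_sparse", density = 0.3, rho = 0.4, n_families = 10,
    seed = 12))
  expect_identical(r1$edges, r2$edges)
  expect_error(make_truth_graph(simulation_config(
    n_samples = 10, n_continuous = 7, n_binary = 0,
    structure = "modular_blocks", n_blocks = 2, rho = 0.4,
    n_families = 10)), "divide")
})

test_that("the precision construction hits exact partial correlations", {
  # empty graph -> identity precision
  empty <- make_truth_graph(simulation_config(
    n_samples = 10, n_continuous = 3, n_binary = 0,
    structure = "random_sparse", density = 0, rho = 0.4, n_families = 10))
  pr <- precision_from_graph(empty)
  expect_equal(unname(pr$precision), diag(3), tolerance = 1e-12)
  # single edge at rho = 0.5: realized partial correlation exactly 0.5
  single <- make_truth_graph(simulation_config(
    n_samples = 10, n_continuous = 2, n_binary = 0, structure = "chain",
    rho = 0.5, n_families = 10))
  pr2 <- precision_from_graph(single)
  expect_equal(pr2$partial["v001", "v002"], 0.5, tolerance = 1e-12)
  # chain of 5 at rho = 0.4: positive definite, zero pattern matches chain
  chain <- make_truth_graph(simulation_config(
    n_samples = 10, n_continuous = 5, n_binary = 0, structure = "chain",
    rho = 0.4, n_families = 10))
  pr3 <- precision_from_graph(chain)
  ev <- eigen(pr3$precision, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0)
  on_edge <- abs(pr3$partial[cbind(1:4, 2:5)])
  expect_true(all(on_edge > 0.2))      # within 50% of |rho| = 0.4
  expect_true(all(on_edge <= 0.4 + 1e-9))
  off <- pr3$partial
  off[cbind(1:4, 2:5)] <- off[cbind(2:5, 1:4)] <- 0
  diag(off) <- 0
  expect_equal(max(abs(off)), 0, tolerance = 1e-10)
})

test_that("latent covariance reproduces zero partials off the edge set", {
  cfg <- simulation_config(n_samples = 10, n_continuous = 8, n_binary = 0,
                           structure = "random_sparse", density = 0.25,
                           rho = 0.35, n_families = 10, seed = 77)
  truth <- make_truth_graph(cfg)
  pr <- precision_from_graph(truth)
  inv <- solve(pr$covariance)  # inverse-covariance oracle
  pc <- -inv / sqrt(outer(diag(inv), diag(inv)))
  keys <- truth_edge_keys(truth)
  nms <- truth$variables$name
  for (i in 1:7) for (j in (i + 1):8) {
    expected_zero <- !(pair_key(nms[i], nms[j]) %in% keys)
    if (expected_zero) expect_lt(abs(pc[i, j]), 1e-10)
    else expect_gt(abs(pc[i, j]), 0.1)
  }
})

test_that("simulated data match the configured marginals and mask", {
  cfg <- simulation_config(n_samples = 5000, n_continuous = 4, n_binary = 2,
                           structure = "random_sparse", density = 0,
                           rho = 0.4, missing_rate = 0, n_families = 5000,
                           seed = 30)
  truth <- make_truth_graph(cfg)
  ds <- simulate_mixed(truth, cfg)
  expect_true(all(ds$observed))
  # independent variables: all pairwise sample correlations near zero
  num <- as.matrix(ds$values)
  cors <- cor(num)
  expect_lt(max(abs(cors[upper.tri(cors)])), 0.05)
  # thresholded-at-zero latents give ~50% binary prevalence
  expect_lt(abs(mean(ds$values$v005) - 0.5), 0.03)
  expect_lt(abs(mean(ds$values$v006) - 0.5), 0.03)
})

test_that("simulation is reproducible and masks at the configured rate", {
  cfg <- simulation_config(n_samples = 400, n_continuous = 6, n_binary = 2,
                           structure = "chain", rho = 0.5,
                           missing_rate = 0.1, n_families = 300, seed = 9)
  truth <- make_truth_graph(cfg)
  d1 <- simulate_mixed(truth, cfg)
  d2 <- simulate_mixed(truth, cfg)
  expect_identical(d1$values, d2$values)
  expect_identical(d1$observed, d2$observed)
  expect_lt(abs(mean(!d1$observed) - 0.1), 0.02)
  # twins share families: pairs then singletons
  expect_equal(length(unique(d1$family_ids)), 300)
  expect_equal(sum(table(d1$family_ids) == 2), 100)
})

test_that("family intercepts correlate twins on continuous variables", {
  cfg <- simulation_config(n_samples = 2000, n_continuous = 2, n_binary = 0,
                           structure = "random_sparse", density = 0,
                           rho = 0.4, missing_rate = 0, n_families = 1000,
                           seed = 14)
  truth <- make_truth_graph(cfg)
  ds <- simulate_mixed(truth, cfg)
  pairs <- split(seq_len(2000), ds$family_ids)
  pairs <- pairs[lengths(pairs) == 2]
  first <- vapply(pairs, `[`, 0L, 1)
  second <- vapply(pairs, `[`, 0L, 2)
  r <- cor(ds$values$v001[first], ds$values$v001[second])
  # shared intercept of variance 0.2 on unit latents: r ~ 0.2/1.2
  expect_gt(r, 0.08)
  expect_lt(r, 0.26)
})

test_that("recovery metrics follow the set-overlap arithmetic", {
  cfg <- simulation_config(n_samples = 10, n_continuous = 5, n_binary = 0,
                           structure = "chain", rho = 0.4, n_families = 10)
  truth <- make_truth_graph(cfg)  # 4 edges
  expect_equal(unname(recovery_metrics(truth_edge_keys(truth), truth)),
               c(1, 1, 1))
  expect_equal(unname(recovery_metrics(c("v001|v003", "v002|v004"), truth)),
               c(0, 0, 0))
  inferred <- c(truth_edge_keys(truth)[1:3], "v001|v005", "v002|v005")
  m <- recovery_metrics(inferred, truth)
  expect_equal(unname(m["precision"]), 0.6)
  expect_equal(unname(m["recall"]), 0.75)
  expect_equal(unname(m["f1"]), 2 * 0.6 * 0.75 / 1.35)
})
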