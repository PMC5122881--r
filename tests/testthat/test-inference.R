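# subsampling plan, importance ranking, CPSS aggregation, signs, infer_mgm

test_that("complementary pairs partition the samples with floor/ceil sizes", {
  plan <- make_subsample_plan(4, 1, seed = 2)
  h <- plan$pairs[[1]]
  expect_length(h$first, 2)
  expect_length(h$second, 2)
  expect_setequal(c(h$first, h$second), 1:4)
  plan5 <- make_subsample_plan(5, 3, seed = 2)
  for (h in plan5$pairs) {
    expect_equal(sort(c(length(h$first), length(h$second))), c(2, 3))
    expect_setequal(c(h$first, h$second), 1:5)
  }
  expect_error(make_subsample_plan(10, 0), "B")
})

test_that("B = 100 pairs yield 200 half-sample models and fixed seeds reproduce", {
  plan <- make_subsample_plan(510, 100, seed = 7)
  expect_length(plan$pairs, 100)
  expect_equal(2 * length(plan$pairs), 200)
  again <- make_subsample_plan(510, 100, seed = 7)
  expect_identical(plan, again)
  other <- make_subsample_plan(510, 100, seed = 8)
  expect_false(identical(plan, other))
})

test_that("pair ranks are the worse directional rank with documented ties", {
  # A-row: B best (1), C 2; B-row: A 1, C 2; C-row: B 1, A 2
  M <- matrix(NA_real_, 3, 3, dimnames = list(c("A", "B", "C"),
                                              c("A", "B", "C")))
  M["A", c("B", "C")] <- c(10, 5)
  M["B", c("A", "C")] <- c(8, 2)
  M["C", c("B", "A")] <- c(9, 1)
  r <- rank_pairs(M)
  ranks <- setNames(r$max_rank, paste(r$var1, r$var2))
  expect_equal(ranks[c("A B", "A C", "B C")],
               c("A B" = 1, "A C" = 2, "B C" = 2))
  # tie between {A,C} and {B,C} broken by the smaller rank sum: {B,C} has
  # directional ranks (2, 1), {A,C} has (2, 2)
  expect_equal(paste(r$var1, r$var2), c("A B", "B C", "A C"))
  expect_equal(select_top_q(r, 1), "A|B")
  expect_equal(select_top_q(r, 3), c("A|B", "B|C", "A|C"))
  expect_error(select_top_q(r, 4), "exceeds")
  # matrix with mutually consistent rows: both directional ranks equal
  S <- matrix(c(NA, 3, 1, 3, NA, 2, 1, 2, NA), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  rs <- rank_pairs(S)
  expect_equal(setNames(rs$max_rank, paste(rs$var1, rs$var2))[c("A B", "A C")],
               c("A B" = 1, "A C" = 2))
  # p = 2: the single pair has rank 1
  M2 <- matrix(c(NA, 1, 2, NA), 2, 2, dimnames = list(c("x", "y"),
                                                      c("x", "y")))
  expect_equal(rank_pairs(M2)$max_rank, 1)
})

test_that("selection frequencies count half-sample models", {
  sets <- list(c("a|b", "a|c"), c("a|b", "b|c"), c("a|b", "a|c"),
               c("a|b", "a|c"))
  tab <- aggregate_stability(sets)
  freq <- setNames(tab$frequency, paste(tab$var1, tab$var2, sep = "|"))
  expect_equal(unname(freq["a|b"]), 1.0)
  expect_equal(unname(freq["a|c"]), 0.75)
  expect_equal(unname(freq["b|c"]), 0.25)
  expect_true(all(tab$frequency * attr(tab, "n_subsamples") ==
                    round(tab$frequency * attr(tab, "n_subsamples"))))
  empty <- aggregate_stability(list(character(0), character(0)))
  expect_equal(nrow(empty), 0)
})

test_that("thresholding is strict and monotone in tau", {
  tab <- aggregate_stability(rep(list("e|f"), 0))
  tab <- structure(data.frame(var1 = c("e", "f", "g"),
                              var2 = c("x", "x", "x"),
                              frequency = c(0.85, 0.80, 0.79)),
                   n_subsamples = 100, class = c("stability_table",
                                                 "data.frame"))
  expect_equal(threshold_edges(tab, 0.8), "e|x")
  expect_equal(threshold_edges(tab, 1.0), character(0))
  for (t1 in c(0.55, 0.7, 0.8)) for (t2 in c(0.85, 0.95, 1)) {
    expect_true(all(threshold_edges(tab, t2) %in% threshold_edges(tab, t1)))
  }
})

test_that("importance concentrates on a duplicated predictor and is reproducible", {
  set.seed(31)
  n <- 200
  x <- rnorm(n)
  X <- cbind(x = x, y = x, a = rnorm(n), b = rnorm(n), c = rnorm(n))
  ds <- complete_dataset(X)
  cfg <- inference_config(rf_trees = 100, seed = 12)
  M <- importance_matrix(ds, cfg, subsample_index = 1)
  expect_equal(names(which.max(M["y", ])), "x")
  expect_equal(names(which.max(M["x", ])), "y")
  M2 <- importance_matrix(ds, cfg, subsample_index = 1)
  expect_identical(M, M2)
  # a different subsample index re-seeds the forests
  M3 <- importance_matrix(ds, cfg, subsample_index = 2)
  expect_false(identical(M, M3))
})

test_that("importance under an independent null stays below the permuted-target bar", {
  set.seed(77)
  n <- 200
  X <- matrix(rnorm(n * 6), n, 6,
              dimnames = list(NULL, paste0("v", 1:6)))
  ds <- complete_dataset(X)
  cfg <- inference_config(rf_trees = 100, seed = 4)
  M <- importance_matrix(ds, cfg, subsample_index = 1)
  # permuted-target null for v1: break any association, keep the design
  null_imp <- c()
  for (r in 1:20) {
    Xp <- X
    set.seed(1000 + r)
    Xp[, "v1"] <- sample(Xp[, "v1"])
    Mp <- importance_matrix(complete_dataset(Xp),
                            inference_config(rf_trees = 100, seed = 1000 + r),
                            subsample_index = r)
    null_imp <- c(null_imp, Mp["v1", -1])
  }
  expect_lt(max(M["v1", -1]), quantile(null_imp, 0.99) + 1e-9)
})

test_that("signs come from regression coefficients on both directions", {
  set.seed(8)
  n <- 500
  x <- rnorm(n)
  up <- 2 * x + rnorm(n)
  down <- -2 * x + rnorm(n)
  z <- rnorm(n)
  ds <- complete_dataset(cbind(x = x, up = up, down = down, z = z))
  signs <- estimate_signs(ds, c("up|x", "down|x"))
  expect_equal(unname(signs["up|x"]), "+")
  expect_equal(unname(signs["down|x"]), "-")
  # signs are only computed for supplied edges
  expect_length(estimate_signs(ds, character(0)), 0)
})

test_that("infer_mgm recovers a strong chain and is deterministic", {
  cfg <- simulation_config(n_samples = 500, n_continuous = 6, n_binary = 0,
                           structure = "chain", rho = 0.6, missing_rate = 0,
                           n_families = 500, seed = 21)
  truth <- make_truth_graph(cfg)
  ds <- inverse_normal_dataset(simulate_mixed(truth, cfg))
  icfg <- inference_config(B = 10, q = 6, rf_trees = 60, seed = 14)
  fit <- infer_mgm(ds, icfg)
  expect_setequal(graph_edge_keys(fit$graph), truth_edge_keys(truth))
  fit2 <- infer_mgm(ds, icfg)
  expect_identical(igraph::as_data_frame(fit2$graph),
                   igraph::as_data_frame(fit$graph))
})

test_that("edge sets ignore sample-row and variable-column permutations", {
  cfg <- simulation_config(n_samples = 150, n_continuous = 5, n_binary = 0,
                           structure = "chain", rho = 0.6, missing_rate = 0,
                           n_families = 150, seed = 33)
  truth <- make_truth_graph(cfg)
  ds <- inverse_normal_dataset(simulate_mixed(truth, cfg))
  icfg <- inference_config(B = 4, q = 4, rf_trees = 50, seed = 2)
  base_fit <- infer_mgm(ds, icfg)
  set.seed(1)
  perm_s <- sample(n_samples(ds))
  perm_v <- sample(n_variables(ds))
  shuffled <- subset_dataset_for_test(ds, perm_s, perm_v)
  fit2 <- infer_mgm(shuffled, icfg)
  expect_setequal(graph_edge_keys(fit2$graph),
                  graph_edge_keys(base_fit$graph))
})

test_that("both-halves CPSS mode is at least as conservative as frequency mode", {
  cfg <- simulation_config(n_samples = 200, n_continuous = 5, n_binary = 0,
                           structure = "chain", rho = 0.7, missing_rate = 0,
                           n_families = 200, seed = 61)
  ds <- inverse_normal_dataset(simulate_mixed(make_truth_graph(cfg), cfg))
  freq_fit <- infer_mgm(ds, inference_config(B = 6, q = 4, rf_trees = 40,
                                             seed = 8))
  both_fit <- infer_mgm(ds, inference_config(B = 6, q = 4, rf_trees = 40,
                                             cpss_mode = "both_halves",
                                             seed = 8))
  # an edge in >80% of the B pairwise intersections is in >80% of all 2B
  # half-sample models, so both-halves selections are a subset
  expect_true(all(graph_edge_keys(both_fit$graph) %in%
                    graph_edge_keys(freq_fit$graph)))
})

test_that("the family meta-variable joins the forests but leaves the graph", {
  cfg <- simulation_config(n_samples = 120, n_continuous = 4, n_binary = 0,
                           structure = "chain", rho = 0.5, missing_rate = 0,
                           n_families = 70, seed = 5)
  truth <- make_truth_graph(cfg)
  ds <- attach_family_variable(inverse_normal_dataset(
    simulate_mixed(truth, cfg)))
  icfg <- inference_config(B = 3, q = 3, rf_trees = 40, seed = 6)
  fit <- infer_mgm(ds, icfg)
  expect_false("family" %in% igraph::V(fit$graph)$name)
  expect_false(any(fit$stability$var1 == "family" |
                     fit$stability$var2 == "family"))
})
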