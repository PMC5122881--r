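# cutoff sweeps, centrality correlations, adjusted Rand index, split halves

make_tab <- function(var1, var2, freq) {
  structure(data.frame(var1 = var1, var2 = var2, frequency = freq,
                       stringsAsFactors = FALSE),
            n_subsamples = 100, class = c("stability_table", "data.frame"))
}

test_that("cutoff sweep produces nested graphs with the >= top endpoint", {
  tab <- make_tab(c("a", "a", "b", "c"), c("b", "c", "c", "d"),
                  c(1.0, 0.85, 0.5, 0.25))
  sweep <- cutoff_sweep(tab)
  expect_length(sweep, 5)
  keys <- lapply(sweep, graph_edge_keys)
  for (i in 1:4)
    expect_true(all(keys[[i + 1]] %in% keys[[i]]))
  # 100% cutoff keeps always-selected edges (non-strict at the endpoint)
  expect_equal(keys[[5]], "a|b")
  expect_setequal(keys[[4]], c("a|b", "a|c"))
})

test_that("centrality correlations are 1 against self and -1 for complements", {
  set.seed(2)
  g <- igraph::sample_gnp(8, 0.4)
  igraph::V(g)$name <- letters[1:8]
  self <- centrality_correlation(g, g)
  expect_equal(unname(self["degree"]), 1.0)
  expect_equal(unname(self["clustering"]), 1.0)
  # degree of the complement is n - 1 - degree
  star5 <- graph_from_edges(list(c("a", "b"), c("a", "c"), c("a", "d"),
                                 c("a", "e")))
  comp <- igraph::complementer(star5)
  expect_equal(unname(centrality_correlation(star5, comp)["degree"]), -1.0)
  expect_error(centrality_correlation(graph_from_edges(list(c("a", "b"))),
                                      graph_from_edges(list(c("x", "y")))),
               "shared")
})

test_that("centralities of independent random graphs are uncorrelated", {
  set.seed(41)
  rs <- replicate(20, {
    g1 <- igraph::sample_gnp(20, 0.25)
    g2 <- igraph::sample_gnp(20, 0.25)
    igraph::V(g1)$name <- igraph::V(g2)$name <- letters[1:20]
    unname(centrality_correlation(g1, g2)["degree"])
  })
  expect_lt(abs(mean(rs, na.rm = TRUE)), 0.5)
})

test_that("adjusted Rand index matches its pair-counting brute force", {
  m1 <- setNames(c(1, 1, 1, 2, 2, 2), letters[1:6])
  m2 <- setNames(c(1, 1, 2, 1, 2, 2), letters[1:6])  # {a,b,d | c,e,f}
  ari <- adjusted_rand_index(m1, m2)
  expect_equal(ari, brute_force_ari(m1, m2), tolerance = 1e-12)
  # contingency [[2,1],[1,2]]: (2 - 2.4) / (6 - 2.4) = -1/9
  expect_equal(ari, -1 / 9, tolerance = 1e-12)
  # identity and label invariance
  expect_equal(adjusted_rand_index(m1, m1), 1.0)
  relab <- setNames(c(7, 7, 7, 5, 5, 5), letters[1:6])
  expect_equal(adjusted_rand_index(m1, relab), 1.0)
  expect_error(adjusted_rand_index(m1, setNames(m2, LETTERS[1:6])),
               "node set")
})

test_that("ARI formula, brute force and an independent library agree", {
  skip_if_not_installed("mclust")
  set.seed(23)
  for (rep in 1:20) {
    n <- sample(4:7, 1)
    m1 <- setNames(sample(1:3, n, replace = TRUE), letters[1:n])
    m2 <- setNames(sample(1:3, n, replace = TRUE), letters[1:n])
    mine <- adjusted_rand_index(m1, m2)
    expect_equal(mine, adjusted_rand_index(m2, m1))  # symmetry
    if (length(unique(m1)) > 1 || length(unique(m2)) > 1) {
      expect_equal(mine, brute_force_ari(m1, m2), tolerance = 1e-12)
      expect_equal(mine, mclust::adjustedRandIndex(m1, m2[names(m1)]),
                   tolerance = 1e-12)
    }
  }
})

test_that("the random background is centered at zero and reproducible", {
  mem <- setNames(rep(1:7, length.out = 96), sprintf("n%02d", 1:96))
  bg <- ari_background(mem, n_draws = 1000, seed = 6)
  expect_length(bg, 1000)
  expect_lt(abs(mean(bg)), 0.05)
  expect_identical(bg, ari_background(mem, n_draws = 1000, seed = 6))
  expect_warning(one <- ari_background(setNames(rep(1, 5), letters[1:5]),
                                       n_draws = 10, seed = 1), "single")
  expect_equal(one, rep(1, 10))
})

test_that("twin splits partition families and count reference overlap", {
  # overlap arithmetic on a trivially strong structure
  cfg <- simulation_config(n_samples = 200, n_continuous = 4, n_binary = 0,
                           structure = "chain", rho = 0.7, missing_rate = 0,
                           n_families = 120, seed = 19)
  truth <- make_truth_graph(cfg)
  ds <- inverse_normal_dataset(simulate_mixed(truth, cfg))
  icfg <- inference_config(B = 4, q = 4, rf_trees = 40, seed = 3)
  ref <- infer_mgm(ds, icfg)$graph
  sp <- split_half_models(ds, icfg, ref, seed = 11)
  expect_equal(igraph::vcount(sp$graph1), 4)
  expect_equal(igraph::vcount(sp$graph2), 4)
  expect_true(sp$split_overlap >= 0 && sp$split_overlap <= 1)
  expect_equal(sp$unique_to_reference,
               round((1 - sp$split_overlap) * igraph::ecount(ref)))
  # deterministic split for a fixed seed
  sp2 <- split_half_models(ds, icfg, ref, seed = 11)
  expect_identical(igraph::as_data_frame(sp$graph1),
                   igraph::as_data_frame(sp2$graph1))
  # family with 3 members violates the twin assumption
  bad <- ds
  bad$family_ids[1:3] <- "famX"
  bad <- mixed_dataset(bad$values, bad$variables, bad$sample_ids,
                       bad$family_ids)
  expect_error(split_half_models(bad, icfg, ref), "more than 2")
})

test_that("restricting a larger model preserves intact blocks", {
  big <- graph_from_edges(list(c("a", "b"), c("b", "c"), c("a", "c"),
                               c("x", "y"), c("y", "z"), c("x", "z"),
                               c("c", "x"), c("z", "w")))
  ref <- setNames(c(1, 1, 1, 2, 2, 2), c("a", "b", "c", "x", "y", "z"))
  out <- restrict_and_compare(big, names(ref), ref, method = "greedy")
  expect_equal(out$ari, 1.0)
  expect_equal(igraph::vcount(out$graph), 6)
  # restriction to isolated nodes gives singleton modules
  iso <- graph_from_edges(list(c("a", "b")), nodes = c("a", "b", "u", "v"))
  out2 <- restrict_and_compare(iso, c("u", "v"),
                               setNames(c(1, 2), c("u", "v")))
  expect_equal(igraph::ecount(out2$graph), 0)
  expect_equal(length(unique(out2$partition$membership)), 2)
  expect_error(restrict_and_compare(iso, "nope", setNames(1, "nope")),
               "not in graph")
})
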