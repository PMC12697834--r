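# Explainability: layer-wise features + UMAP, fidelity identities, induced
# subgraphs and the important-subgraph search against a brute-force oracle.

# reference model whose output depends only on the presence of a marked
# cluster (feature 1 above the threshold)
marker_model <- function(threshold = 0.9) {
  function(graph) {
    if (!is.null(graph$cluster_features) &&
        any(graph$cluster_features[, 1] > threshold)) c(0.95, 0.05)
    else c(0.1, 0.9)
  }
}

# graph with one marked cluster (id returned alongside)
marked_graph <- function(m = 8, seed = 1) {
  cs <- rand_cluster_set(m = m, seed = seed)
  g <- featurized_graph(cs)
  target <- withr::with_seed(seed + 500, sample(m, 1))
  g$cluster_features[, 1] <- 0.1
  g$cluster_features[target, 1] <- 1
  list(graph = g, target = target)
}

test_that("layer-wise feature extraction has the right shapes and centering", {
  ds <- make_graph_dataset(n_per_class = 2, seed = 1)
  model <- clusternet_init(model_config(ds$classes, mode = "hcf",
                                        hidden_dim = 8, seed = 1))
  fx <- extract_features(model, ds$graphs, level = "hcf", ref_idx = 1:6)
  expect_equal(ncol(fx$raw), 8)
  expect_equal(length(fx$graph), nrow(fx$raw))
  ref_rows <- fx$graph %in% 1:6
  expect_equal(max(abs(colMeans(fx$features[ref_rows, ]))), 0, tolerance = 1e-9)
  wg <- extract_features(model, ds$graphs, level = "whole_graph")
  expect_equal(nrow(wg$raw), length(ds$graphs))
  expect_equal(ncol(wg$raw), 8)        # hidden_dim
  pm <- extract_features(model, ds$graphs, level = "post_mp")
  expect_equal(nrow(pm$raw), nrow(fx$raw))
  expect_error(extract_features(NULL, ds$graphs, level = "whole_graph"),
               "model")
  # "sd" scaling differs from the variance-normalized default
  fx_sd <- extract_features(model, ds$graphs, level = "hcf", ref_idx = 1:6,
                            scale = "sd")
  expect_false(isTRUE(all.equal(fx$features, fx_sd$features)))
})

test_that("UMAP embeds to 2D deterministically and separates distant blobs", {
  withr::with_seed(2, {
    blob1 <- matrix(rnorm(25 * 6, 0, 0.3), 25, 6)
    blob2 <- matrix(rnorm(25 * 6, 8, 0.3), 25, 6)
  })
  x <- rbind(blob1, blob2)
  e1 <- umap_embed(x, n_neighbors = 10, seed = 4)
  expect_equal(dim(e1), c(50, 2))
  e2 <- umap_embed(x, n_neighbors = 10, seed = 4)
  expect_equal(unname(as.matrix(e1)), unname(as.matrix(e2)))
  c1 <- colMeans(e1[1:25, ]); c2 <- colMeans(e1[26:50, ])
  sep <- sqrt(sum((c1 - c2)^2))
  r1 <- quantile(sqrt(rowSums(sweep(as.matrix(e1[1:25, ]), 2, c1)^2)), 0.95)
  r2 <- quantile(sqrt(rowSums(sweep(as.matrix(e1[26:50, ]), 2, c2)^2)), 0.95)
  expect_gt(sep, max(r1, r2))
  expect_error(umap_embed(x[1:5, ], n_neighbors = 10), "rows")
})

test_that("induced subgraphs keep members, features and internal edges only", {
  cs <- rand_cluster_set(m = 6, seed = 3)
  g <- featurized_graph(cs)
  sub <- induced_subgraph(g, c(2, 5))
  expect_equal(nrow(sub$cluster_pos), 2)
  expect_equal(sub$cluster_pos, g$cluster_pos[c(2, 5), ])   # no re-normalization
  expect_equal(sub$cluster_features, g$cluster_features[c(2, 5), ])
  expect_equal(sum(g$loc_cluster %in% c(2, 5)), length(sub$loc_cluster))
  expect_true(all(sub$edges >= 1 & sub$edges <= 2))
  expect_error(induced_subgraph(g, integer(0)), "non-empty")
  expect_error(induced_subgraph(g, 99), "subset")
})

test_that("fidelity identities hold exactly", {
  mg <- marked_graph(m = 7, seed = 4)
  # subgraph = entire graph: Fid- is exactly 0, Fid+ undefined
  fr <- fidelity(marker_model(), mg$graph, seq_len(7))
  expect_identical(fr$fid_minus, 0)
  expect_true(is.na(fr$fid_plus))
  # constant model: both fidelities are 0 for any proper subgraph
  const_model <- function(graph) c(0.6, 0.4)
  fr2 <- fidelity(const_model, mg$graph, c(1, 3))
  expect_identical(fr2$fid_plus, 0)
  expect_identical(fr2$fid_minus, 0)
  # empty subgraph: Fid- undefined
  fr3 <- fidelity(marker_model(), mg$graph, integer(0))
  expect_true(is.na(fr3$fid_minus))
  expect_false(is.na(fr3$fid_plus))
})

test_that("fidelity detects the decisive cluster of the marker model", {
  mg <- marked_graph(m = 8, seed = 5)
  fr <- fidelity(marker_model(), mg$graph, mg$target)
  expect_equal(fr$fid_plus, 0.85)   # removing the marker flips the prediction
  expect_equal(fr$fid_minus, 0)     # the marker alone suffices
  fr_other <- fidelity(marker_model(), mg$graph, setdiff(1:8, mg$target)[1:3])
  expect_equal(fr_other$fid_plus, 0)
})

test_that("the subgraph search finds the decisive node and is deterministic", {
  hits <- 0
  for (s in 1:5) {
    mg <- marked_graph(m = 8, seed = 10 + s)
    cfg <- explain_config(max_subgraph_nodes = 4, rollouts = 50,
                          shapley_samples = 20, seed = 1)
    res <- subgraphx_search(marker_model(), mg$graph, cfg)
    if (mg$target %in% res$nodes) hits <- hits + 1
    res2 <- subgraphx_search(marker_model(), mg$graph, cfg)
    expect_identical(res$nodes, res2$nodes)
    expect_equal(res$score, res2$score)
  }
  expect_equal(hits, 5)
})

test_that("the searched subgraph is more sufficient than a random one", {
  diffs <- vapply(1:10, function(s) {
    mg <- marked_graph(m = 8, seed = 40 + s)
    cfg <- explain_config(max_subgraph_nodes = 4, rollouts = 40,
                          shapley_samples = 20, seed = 2)
    res <- subgraphx_search(marker_model(), mg$graph, cfg)
    rnd <- withr::with_seed(s, sample(8, length(res$nodes)))
    f_rand <- fidelity(marker_model(), mg$graph, rnd)
    f_rand$fid_minus - res$fidelity$fid_minus
  }, numeric(1))
  expect_gt(mean(diffs), 0)
})

test_that("the search handles disconnected cluster graphs per component", {
  cs <- rand_cluster_set(m = 6, seed = 6)
  g <- featurized_graph(cs)
  # split into two components {1,2,3} and {4,5,6}
  e <- g$edges
  keep <- (e[, 1] <= 3 & e[, 2] <= 3) | (e[, 1] >= 4 & e[, 2] >= 4)
  g$edges <- e[keep, , drop = FALSE]
  need <- rbind(c(1L, 2L), c(2L, 3L), c(4L, 5L), c(5L, 6L))
  g$edges <- unique(rbind(g$edges, need))
  g$cluster_features[, 1] <- 0.1
  g$cluster_features[5, 1] <- 1        # decisive node in the second component
  res <- subgraphx_search(marker_model(), g,
                          explain_config(max_subgraph_nodes = 2, rollouts = 30,
                                         shapley_samples = 20, seed = 3))
  expect_true(5 %in% res$nodes)
  expect_true(all(res$nodes >= 4))
})
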