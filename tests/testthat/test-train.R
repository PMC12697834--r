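# Partitioning, sampling, augmentation, the training loop and metrics.

test_that("stratified splits have the 64/16/20 structure per class", {
  labels <- rep(c("a", "b", "c", "d"), each = 25)
  folds <- make_splits(labels, "stratified_cv", seed = 3)
  expect_length(folds, 5)
  all_test <- unlist(lapply(folds, `[[`, "test"))
  expect_equal(sort(all_test), 1:100)            # non-overlapping, exhaustive
  for (f in folds) {
    expect_equal(as.integer(table(labels[f$test])), rep(5L, 4))   # 20% of 25
    expect_equal(as.integer(table(labels[f$val])), rep(4L, 4))    # 16% of 25
    expect_equal(as.integer(table(labels[f$train])), rep(16L, 4)) # 64% of 25
    expect_length(intersect(f$train, f$val), 0)
    expect_length(intersect(f$train, f$test), 0)
  }
  expect_identical(folds, make_splits(labels, "stratified_cv", seed = 3))
})

test_that("grouped splits keep each group in exactly one fold", {
  withr::with_seed(1, {
    groups <- rep(sprintf("p%02d", 1:23), times = sample(1:10, 23, TRUE))
    labels <- sample(c("resp", "nonresp"), length(groups), TRUE, c(0.3, 0.7))
  })
  folds <- make_splits(labels, "grouped_cv", groups = groups, seed = 2)
  for (g in unique(groups)) {
    rows <- which(groups == g)
    in_fold <- vapply(folds, function(f) any(rows %in% f$test), logical(1))
    expect_equal(sum(in_fold), 1)                 # test sets partition groups
  }
  for (f in folds) {
    # validation groups never overlap training groups
    expect_length(intersect(unique(groups[f$val]), unique(groups[f$train])), 0)
    expect_gt(length(f$val), 0)
  }
  expect_error(make_splits(labels, "grouped_cv", groups = rep("p1", length(labels)),
                           n_folds = 5, seed = 1), "fewer groups")
  expect_error(make_splits(labels, "grouped_cv", seed = 1), "group key")
})

test_that("sampler weights equalize expected class frequencies", {
  labels <- rep(c("A", "B"), c(100, 300))
  w <- sampler_weights(labels)
  expect_equal(w[1] / w[101], 3)
  expect_equal(sum(w[labels == "A"]), sum(w[labels == "B"]))
  expect_equal(sampler_weights(rep(c("A", "B"), each = 5)), rep(0.2, 10))
  # multinomial check: expected draws per class equal within 3 s.e.
  draws <- withr::with_seed(1, sample(labels, 1e4, TRUE, prob = w))
  expect_lt(abs(sum(draws == "A") - 5000), 3 * sqrt(1e4 * 0.25))
  expect_error(sampler_weights(rep("A", 10)), "2 classes")
})

test_that("rotation augmentation is an isometry that leaves features alone", {
  cs <- rand_cluster_set(m = 8, seed = 5)
  g <- featurized_graph(cs)
  expect_equal(augment_rotation(g, angle = 0), g)
  gr <- augment_rotation(g, angle = 1.2)
  expect_equal(as.numeric(dist(gr$cluster_pos)),
               as.numeric(dist(g$cluster_pos)), tolerance = 1e-9)
  expect_identical(gr$cluster_features, g$cluster_features)
  expect_identical(gr$edges, g$edges)
  expect_identical(augment_rotation(g, seed = 7), augment_rotation(g, seed = 7))
})

test_that("a training step back-propagates into LocNet (end-to-end gradient flow)", {
  ds <- make_graph_dataset(n_per_class = 2, seed = 6)
  model <- clusternet_init(model_config(ds$classes, mode = "lcf",
                                        hidden_dim = 8, seed = 1))
  before <- model$params
  trained <- train(model, ds$graphs, train_idx = 1:6, val_idx = 7:8,
                   cfg = train_config(epochs = 1, batch_size = 4, seed = 1))
  locnet_names <- grep("^ln\\.", names(before), value = TRUE)
  deltas <- vapply(locnet_names, function(nm) {
    max(abs(trained$params[[nm]] - before[[nm]]))
  }, numeric(1))
  expect_true(all(deltas[c("ln.W0", "ln.W_e", "ln.b_e")] > 0))
  expect_gt(max(deltas), 0)
})

test_that("the checkpoint with minimum validation loss is returned", {
  ds <- make_graph_dataset(n_per_class = 2, seed = 7)
  model <- clusternet_init(model_config(ds$classes, mode = "hcf",
                                        hidden_dim = 8, seed = 1))
  trained <- train(model, ds$graphs, train_idx = 1:6, val_idx = 7:8,
                   cfg = train_config(epochs = 4, batch_size = 8, seed = 2))
  expect_equal(nrow(trained$log), 4)
  expect_equal(trained$best_epoch, which.min(trained$log$val_loss))
  # deterministic re-run reproduces the loss trajectory
  rerun <- train(clusternet_init(model_config(ds$classes, mode = "hcf",
                                              hidden_dim = 8, seed = 1)),
                 ds$graphs, 1:6, 7:8, train_config(epochs = 4, batch_size = 8,
                                                   seed = 2))
  expect_identical(trained$log, rerun$log)
})

test_that("evaluation metrics follow their definitions", {
  classes <- c("a", "b")
  model <- structure(list(cfg = list(classes = classes, n_classes = 2)),
                     class = "clusternet_model")
  graphs <- lapply(c("a", "a", "b", "b"), function(l) {
    structure(list(label = l), class = "hier_graph")
  })
  # perfect separation
  probs <- rbind(c(0.9, 0.1), c(0.8, 0.2), c(0.2, 0.8), c(0.4, 0.6))
  rep <- evaluate(model, graphs, probs = probs)
  expect_equal(unname(rep$recall), c(1, 1))
  expect_equal(rep$balanced_accuracy, 1)
  expect_equal(unname(rep$auroc), c(1, 1))
  # one class half right: balanced accuracy is the mean of recalls
  probs2 <- rbind(c(0.9, 0.1), c(0.4, 0.6), c(0.2, 0.8), c(0.4, 0.6))
  rep2 <- evaluate(model, graphs, probs = probs2)
  expect_equal(unname(rep2$recall), c(0.5, 1))
  expect_equal(rep2$balanced_accuracy, 0.75)
  # constant scores: AUROC 0.5
  expect_equal(unname(evaluate(model, graphs,
                               probs = matrix(0.5, 4, 2))$auroc), c(0.5, 0.5))
})

test_that("evaluation warns when a class is missing from the test set", {
  ds <- make_graph_dataset(n_per_class = 1, seed = 9)
  model <- clusternet_init(model_config(ds$classes, mode = "hcf",
                                        hidden_dim = 8, seed = 1))
  expect_warning(rep <- evaluate(model, ds$graphs[1:2]), "absent")
  expect_true(any(is.nan(rep$recall)))
})
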