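# Shared fixtures: all test data is generated in code.

feature_names <- c("count", "rg2", "perimeter", "linearity", "planarity",
                   "length", "area", "density")

# random non-degenerate 2D cluster
rand_cluster <- function(n = 20, seed = 1, sd = c(4, 2)) {
  withr::with_seed(seed, cbind(rnorm(n, 0, sd[1]), rnorm(n, 0, sd[2])))
}

# a cluster_set built directly from known member blobs (bypasses kmeans)
manual_cluster_set <- function(blobs, label = "grid") {
  xy <- do.call(rbind, blobs)
  assignment <- rep(seq_along(blobs), vapply(blobs, nrow, integer(1)))
  structure(list(
    table = loc_table(data.frame(x = xy[, 1], y = xy[, 2]), gt_label = label),
    assignment = assignment, n_clusters = length(blobs)),
    class = "cluster_set")
}

# random cluster set: m Gaussian blobs of varying size at random centres
rand_cluster_set <- function(m = 8, seed = 1, n_per = 12, label = "grid") {
  withr::with_seed(seed, {
    centres <- cbind(runif(m, -80, 80), runif(m, -80, 80))
    sizes <- sample(n_per:(2 * n_per), m, replace = TRUE)
    blobs <- lapply(seq_len(m), function(i) {
      cbind(rnorm(sizes[i], centres[i, 1], 3), rnorm(sizes[i], centres[i, 2], 3))
    })
    manual_cluster_set(blobs, label)
  })
}

# featurized graph from a cluster_set (scaler fitted on its own features)
featurized_graph <- function(cs, n_neighbors = 5) {
  f <- cluster_features(cs)
  sc <- fit_scaler(as.matrix(f[, feature_names]))
  build_graph(cs, scale_features(f, sc), n_neighbors = n_neighbors)
}

# small labeled synthetic graph dataset (all 4 template classes)
make_graph_dataset <- function(n_per_class = 3, seed = 1, k = 6) {
  lib <- make_default_templates()
  tabs <- sample_dataset(lib, n_per_class,
                         simulation_params(seed = seed, background_rate = 2))
  css <- lapply(tabs, function(tb) cluster(tb, clustering_config(k = k, seed = 1)))
  featl <- lapply(css, cluster_features)
  sc <- fit_scaler(do.call(rbind, lapply(featl, function(f)
    as.matrix(f[, feature_names]))))
  graphs <- mapply(function(cs, f) build_graph(cs, scale_features(f, sc)),
                   css, featl, SIMPLIFY = FALSE)
  list(graphs = graphs,
       labels = vapply(tabs, function(t) t$gt_label, character(1)),
       classes = names(lib$classes))
}

# independent radius-of-gyration oracle via the pairwise-distance identity:
# rg2 = sum_ij d_ij^2 / (2 n^2)
rg2_oracle <- function(points) {
  d <- as.matrix(dist(points))
  sum(d^2) / (2 * nrow(points)^2)
}

# independent convex-hull perimeter oracle: Jarvis gift-wrapping march
perimeter_oracle <- function(points) {
  pts <- unique(points)
  n <- nrow(pts)
  if (n < 3) stop("degenerate")
  start <- which.min(pts[, 1] + 1e-9 * pts[, 2])
  hull <- start
  repeat {
    p <- hull[length(hull)]
    cand <- setdiff(seq_len(n), p)
    q <- cand[1]
    for (r in cand[-1]) {
      cr <- (pts[q, 1] - pts[p, 1]) * (pts[r, 2] - pts[p, 2]) -
            (pts[q, 2] - pts[p, 2]) * (pts[r, 1] - pts[p, 1])
      d_r <- sum((pts[r, ] - pts[p, ])^2)
      d_q <- sum((pts[q, ] - pts[p, ])^2)
      if (cr < 0 || (abs(cr) < 1e-12 && d_r > d_q)) q <- r
    }
    if (q == start) break
    hull <- c(hull, q)
    if (length(hull) > n) stop("hull walk failed")
  }
  hp <- pts[c(hull, hull[1]), , drop = FALSE]
  sum(sqrt(rowSums(diff(hp)^2)))
}
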