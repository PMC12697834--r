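# Explainability: layer-wise feature extraction with UMAP embedding, and an
# important-subgraph search (Monte-Carlo tree search over connected node
# subsets with Monte-Carlo Shapley scoring) with positive/negative fidelity.

#' Extract layer-wise features for a set of graphs
#'
#' Four feature levels are available: `"hcf"` (handcrafted cluster features as
#' stored on the graphs), `"locnet"` (cluster features embedded by LocNet),
#' `"post_mp"` (cluster features after the last message passing layer) and
#' `"whole_graph"` (pooled graph features). Rows are normalized per feature by
#' subtracting the mean and dividing by either the variance (`scale =
#' "variance"`, the default) or the standard deviation (`scale = "sd"`),
#' with statistics measured over `ref_idx` (the dataset excluding any reserved
#' test set) to avoid leakage.
#'
#' @param model a `clusternet_model`; not needed for level `"hcf"`.
#' @param graphs list of `hier_graph`s.
#' @param level feature level (see Description).
#' @param ref_idx indices of the graphs whose rows define the normalization
#'   statistics (default: all).
#' @param scale `"variance"` or `"sd"`.
#' @return list with `features` (normalized matrix), `raw`, and per-row
#'   metadata `graph` (parent index), `gt`, `pred` (predicted class, when a
#'   model is given).
#' @export
extract_features <- function(model = NULL, graphs,
                             level = c("hcf", "locnet", "post_mp", "whole_graph"),
                             ref_idx = seq_along(graphs),
                             scale = c("variance", "sd")) {
  level <- match.arg(level)
  scale <- match.arg(scale)
  if (level != "hcf" && is.null(model)) stop("level '", level, "' requires a model")
  gt <- vapply(graphs, function(g) g$label, character(1))
  pred <- rep(NA_character_, length(graphs))
  rows <- list(); parent <- list()
  if (!is.null(model) && inherits(model, "clusternet_model")) {
    for (i in seq_along(graphs)) {
      fw <- clusternet_forward(model, graphs[[i]])
      pred[i] <- fw$predicted_class
      rows[[i]] <- switch(level,
        hcf = graphs[[i]]$cluster_features,
        locnet = fw$input_features,
        post_mp = fw$cluster_features,
        whole_graph = matrix(fw$graph_feature, 1L))
      parent[[i]] <- rep(i, nrow(rows[[i]]))
    }
  } else {
    if (level != "hcf") stop("level '", level, "' requires a model")
    for (i in seq_along(graphs)) {
      if (is.null(graphs[[i]]$cluster_features)) {
        stop("graph ", i, " carries no cluster features")
      }
      rows[[i]] <- graphs[[i]]$cluster_features
      parent[[i]] <- rep(i, nrow(rows[[i]]))
    }
  }
  raw <- do.call(rbind, rows)
  parent <- unlist(parent)
  ref_rows <- parent %in% ref_idx
  mu <- colMeans(raw[ref_rows, , drop = FALSE])
  dev <- apply(raw[ref_rows, , drop = FALSE], 2L, stats::var)
  if (scale == "sd") dev <- sqrt(dev)
  dev[dev <= 0] <- 1
  norm <- sweep(sweep(raw, 2L, mu), 2L, dev, "/")
  list(features = norm, raw = raw, graph = parent, gt = gt[parent],
       pred = pred[parent])
}

#' 2D UMAP embedding of a feature matrix
#'
#' Delegates to the umap-learn implementation (via the system `python`), with
#' a fixed `random_state` so the embedding is deterministic given the seed.
#'
#' @param features numeric matrix (rows = items).
#' @param n_neighbors UMAP neighbourhood size (default 20).
#' @param min_dist minimum distance in the embedded space (default 0.5).
#' @param seed integer seed.
#' @param python python executable with umap-learn available.
#' @return numeric matrix (rows x 2) of embedded coordinates.
#' @export
umap_embed <- function(features, n_neighbors = 20, min_dist = 0.5, seed = 1L,
                       python = Sys.which("python")) {
  features <- as.matrix(features)
  if (nrow(features) < n_neighbors + 1) {
    stop("need at least n_neighbors + 1 rows for UMAP")
  }
  if (!nzchar(python)) stop("no python executable found for umap-learn")
  fin <- tempfile(fileext = ".csv"); fout <- tempfile(fileext = ".csv")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  utils::write.table(features, fin, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  script <- sprintf(paste0(
    "import warnings, numpy as np\n",
    "warnings.filterwarnings('ignore')\n",
    "import umap\n",
    "x = np.loadtxt(%s, delimiter=',', ndmin=2)\n",
    "e = umap.UMAP(n_neighbors=%d, min_dist=%f, n_components=2, ",
    "random_state=%d).fit_transform(x)\n",
    "np.savetxt(%s, e, delimiter=',')\n"),
    deparse(fin), as.integer(n_neighbors), min_dist, as.integer(seed),
    deparse(fout))
  status <- system2(python, "-", input = script, stdout = FALSE, stderr = FALSE)
  if (status != 0 || !file.exists(fout)) {
    stop("umap-learn subprocess failed (python exit status ", status, ")")
  }
  as.matrix(utils::read.table(fout, sep = ","))
}

#' Induced subgraph on a subset of cluster nodes
#'
#' Keeps the named cluster nodes, their member localizations and the edges with
#' both endpoints in the subset; node positions are kept as-is (no
#' re-normalization), so occlusion is not confounded with a geometry change.
#'
#' @param graph a `hier_graph`.
#' @param nodes integer cluster-node indices to keep.
#' @return The induced `hier_graph`.
#' @export
induced_subgraph <- function(graph, nodes) {
  stopifnot(inherits(graph, "hier_graph"))
  nodes <- sort(unique(as.integer(nodes)))
  m <- n_cluster_nodes(graph)
  if (length(nodes) == 0 || any(nodes < 1 | nodes > m)) {
    stop("nodes must be a non-empty subset of the cluster nodes")
  }
  remap <- match(seq_len(m), nodes)
  keep_loc <- graph$loc_cluster %in% nodes
  e <- graph$edges
  keep_e <- e[, 1] %in% nodes & e[, 2] %in% nodes
  e <- cbind(remap[e[keep_e, 1]], remap[e[keep_e, 2]])
  storage.mode(e) <- "integer"
  structure(list(
    loc_pos = graph$loc_pos[keep_loc, , drop = FALSE],
    loc_cluster = remap[graph$loc_cluster[keep_loc]],
    cluster_pos = graph$cluster_pos[nodes, , drop = FALSE],
    cluster_features = if (is.null(graph$cluster_features)) NULL else
      graph$cluster_features[nodes, , drop = FALSE],
    edges = e, label = graph$label, source_id = graph$source_id),
    class = "hier_graph")
}

#' Explainability configuration
#'
#' @param max_subgraph_nodes maximum size of the returned subgraph (default 8).
#' @param rollouts Monte-Carlo tree search rollouts (default 100).
#' @param shapley_samples coalition samples per Shapley estimate (default 100).
#' @param l_hop neighbourhood radius restricting Shapley coalition players.
#' @param c_puct exploration constant of the tree search.
#' @param seed integer seed.
#' @return An object of class `explain_config`.
#' @export
explain_config <- function(max_subgraph_nodes = 8, rollouts = 100,
                           shapley_samples = 100, l_hop = 2, c_puct = 5,
                           seed = 1L) {
  stopifnot(max_subgraph_nodes >= 1, rollouts >= 1, shapley_samples >= 1)
  structure(list(max_subgraph_nodes = as.integer(max_subgraph_nodes),
                 rollouts = as.integer(rollouts),
                 shapley_samples = as.integer(shapley_samples),
                 l_hop = as.integer(l_hop), c_puct = c_puct,
                 seed = as.integer(seed)),
            class = "explain_config")
}

# probability of class `cls` when only `nodes` are kept; empty set -> uniform
occluded_prob <- function(model, graph, nodes, cls, n_classes) {
  if (length(nodes) == 0) return(1 / n_classes)
  model_probs_one(model, induced_subgraph(graph, nodes))[cls]
}

#' Positive and negative fidelity of a subgraph
#'
#' Both metrics are anchored on the model's predicted class for the full graph:
#' `fid_plus` is the drop in its probability when the subgraph's nodes are
#' removed (necessity); `fid_minus` is the drop when only the subgraph is kept
#' (sufficiency). Best performance: `fid_plus -> 1`, `fid_minus -> 0`. An empty
#' complement makes `fid_plus` undefined (`NA`); an empty subgraph makes
#' `fid_minus` undefined.
#'
#' @param model a `clusternet_model` or a function `graph -> probability
#'   vector`.
#' @param graph a `hier_graph`.
#' @param nodes integer cluster-node indices of the explaining subgraph.
#' @return An object of class `fidelity_report` with `fid_plus`, `fid_minus`,
#'   `nodes` and `predicted_class` (index).
#' @export
fidelity <- function(model, graph, nodes) {
  nodes <- sort(unique(as.integer(nodes)))
  m <- n_cluster_nodes(graph)
  p_all <- unname(model_probs_one(model, graph))
  cls <- which.max(p_all)
  p_full <- p_all[cls]
  n_classes <- length(p_all)
  comp <- setdiff(seq_len(m), nodes)
  fid_plus <- if (length(comp) == 0) NA_real_ else
    p_full - occluded_prob(model, graph, comp, cls, n_classes)
  fid_minus <- if (length(nodes) == 0) NA_real_ else
    p_full - occluded_prob(model, graph, nodes, cls, n_classes)
  structure(list(fid_plus = fid_plus, fid_minus = fid_minus, nodes = nodes,
                 predicted_class = cls),
            class = "fidelity_report")
}

#' @export
print.fidelity_report <- function(x, ...) {
  cat(sprintf("<fidelity_report> nodes {%s}: Fid+ %.4g, Fid- %.4g (class %d)\n",
              paste(x$nodes, collapse = ","), x$fid_plus, x$fid_minus,
              x$predicted_class))
  invisible(x)
}

# igraph of the cluster graph without self-loops
cluster_igraph <- function(graph) {
  e <- graph$edges
  e <- e[e[, 1] != e[, 2], , drop = FALSE]
  ig <- igraph::make_empty_graph(n = n_cluster_nodes(graph), directed = FALSE)
  if (nrow(e) > 0) ig <- igraph::add_edges(ig, as.integer(t(e)))
  igraph::simplify(ig)
}

# Monte-Carlo Shapley contribution of node set S to the predicted-class
# probability: S is treated as one player among the nodes within l_hop of S;
# coalitions are the players preceding S in random permutations. The sampling
# seed is derived from (cfg$seed, S) so a subset's score is reproducible no
# matter where in the search it is evaluated.
shapley_score <- function(model, graph, S, cls, n_classes, ig, cfg) {
  S <- sort(S)
  nb <- unlist(igraph::ego(ig, order = cfg$l_hop, nodes = S))
  players <- setdiff(unique(as.integer(nb)), S)
  if (length(players) == 0) {
    return(occluded_prob(model, graph, S, cls, n_classes) - 1 / n_classes)
  }
  key <- as.numeric(cfg$seed)
  for (v in S) key <- (key * 131 + v) %% 2147483647
  with_seed(as.integer(key), {
    tot <- 0
    for (t in seq_len(cfg$shapley_samples)) {
      perm <- sample(players)
      pos <- sample.int(length(players) + 1L, 1L) - 1L
      C <- if (pos > 0) perm[seq_len(pos)] else integer(0)
      v1 <- occluded_prob(model, graph, union(C, S), cls, n_classes)
      v0 <- occluded_prob(model, graph, C, cls, n_classes)
      tot <- tot + (v1 - v0)
    }
    tot / cfg$shapley_samples
  })
}

# all connected subsets of the component `comp` with size <= max_nodes
# (brute-force enumeration; used as the oracle in tests and for tiny graphs)
enumerate_connected_subsets <- function(ig, comp, max_nodes) {
  res <- list()
  seen <- new.env(parent = emptyenv())
  key <- function(s) paste(sort(s), collapse = ",")
  grow <- function(s) {
    k <- key(s)
    if (!is.null(seen[[k]])) return()
    assign(k, TRUE, envir = seen)
    res[[length(res) + 1L]] <<- sort(s)
    if (length(s) >= max_nodes) return()
    nb <- setdiff(unique(as.integer(unlist(igraph::ego(ig, 1, s)))), s)
    for (v in intersect(nb, comp)) grow(c(s, v))
  }
  for (v in comp) grow(v)
  res
}

#' Search for the most important connected subgraph
#'
#' Monte-Carlo tree search over connected subsets of the cluster nodes: the
#' root is the full node set (per connected component), each action removes one
#' node while preserving connectivity, and leaves (subsets of at most
#' `max_subgraph_nodes` nodes) are scored by a Monte-Carlo Shapley estimate of
#' their contribution to the predicted-class probability. The best-scoring leaf
#' over all rollouts is returned with its fidelity report. Deterministic given
#' `cfg$seed`. On a disconnected cluster graph the search runs per component
#' and the best subgraph overall is returned.
#'
#' @param model a `clusternet_model` or a function `graph -> probability
#'   vector`.
#' @param graph a `hier_graph` with >= 2 cluster nodes.
#' @param cfg an [explain_config()].
#' @return list with `nodes` (the subgraph), `score` (its Shapley estimate) and
#'   `fidelity` (a `fidelity_report`).
#' @export
subgraphx_search <- function(model, graph, cfg = explain_config()) {
  stopifnot(inherits(graph, "hier_graph"))
  m <- n_cluster_nodes(graph)
  if (m < 2) stop("need at least 2 cluster nodes")
  p_all <- unname(model_probs_one(model, graph))
  cls <- which.max(p_all)
  n_classes <- length(p_all)
  ig <- cluster_igraph(graph)
  comps <- igraph::components(ig)
  best <- list(score = -Inf, nodes = integer(0))
  with_seed(cfg$seed, {
    for (ci in seq_len(comps$no)) {
      comp <- which(comps$membership == ci)
      res <- mcts_component(model, graph, comp, cls, n_classes, ig, cfg)
      if (res$score > best$score) best <- res
    }
  })
  list(nodes = best$nodes, score = best$score,
       fidelity = fidelity(model, graph, best$nodes))
}

mcts_component <- function(model, graph, comp, cls, n_classes, ig, cfg) {
  score_cache <- new.env(parent = emptyenv())
  get_score <- function(s) {
    k <- paste(s, collapse = ",")
    v <- score_cache[[k]]
    if (is.null(v)) {
      v <- shapley_score(model, graph, s, cls, n_classes, ig, cfg)
      assign(k, v, envir = score_cache)
    }
    v
  }
  # tree nodes keyed by subset; store visit count N, total value W, children
  tree <- new.env(parent = emptyenv())
  node_of <- function(s) {
    k <- paste(s, collapse = ",")
    nd <- tree[[k]]
    if (is.null(nd)) {
      nd <- new.env(parent = emptyenv())
      nd$set <- s; nd$N <- 0; nd$W <- 0; nd$children <- NULL
      assign(k, nd, envir = tree)
    }
    nd
  }
  children_sets <- function(s) {
    if (length(s) <= 1) return(list())
    out <- list()
    for (v in s) {
      rest <- setdiff(s, v)
      sub <- igraph::induced_subgraph(ig, rest)
      if (igraph::is_connected(sub)) out[[length(out) + 1L]] <- rest
    }
    out
  }
  root <- node_of(sort(comp))
  best <- list(score = -Inf, nodes = comp)
  if (length(comp) <= cfg$max_subgraph_nodes) {
    sc <- get_score(sort(comp))
    if (sc > best$score) best <- list(score = sc, nodes = sort(comp))
  }
  for (r in seq_len(cfg$rollouts)) {
    nd <- root
    path <- list(nd)
    while (length(nd$set) > cfg$max_subgraph_nodes) {
      if (is.null(nd$children)) {
        nd$children <- lapply(children_sets(nd$set), node_of)
        if (length(nd$children) == 0) break
      }
      if (length(nd$children) == 0) break
      ucb <- vapply(nd$children, function(ch) {
        q <- if (ch$N > 0) ch$W / ch$N else 0
        prior <- get_score(ch$set)
        q + cfg$c_puct * prior * sqrt(nd$N + 1) / (1 + ch$N)
      }, numeric(1))
      nd <- nd$children[[which.max(ucb)]]
      path[[length(path) + 1L]] <- nd
    }
    leaf_score <- get_score(nd$set)
    if (length(nd$set) <= cfg$max_subgraph_nodes && leaf_score > best$score) {
      best <- list(score = leaf_score, nodes = nd$set)
    }
    for (p in path) {
      p$N <- p$N + 1
      p$W <- p$W + leaf_score
    }
  }
  best
}
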