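# ClusterNet and LocNet: graph classification of clustered SMLM ROIs with
# PointTransformer-style vector attention. ClusterNet applies four message
# passing layers over cluster nodes, global max pooling and a linear readout
# (log-softmax). In LCF mode, LocNet first embeds each cluster's member
# localizations into an 8-vector end-to-end with the classifier.

#' Model configuration
#'
#' @param classes character vector of class names (length >= 2).
#' @param mode `"hcf"` (handcrafted cluster features) or `"lcf"` (features
#'   learned by LocNet).
#' @param embed_dim length of the per-cluster feature vector (default 8, the
#'   same dimension as the handcrafted features for a fair comparison).
#' @param hidden_dim width of the message passing layers (default 96). The
#'   architecture does not pin this down; 96 is the package default, chosen for
#'   reliable class recovery on the synthetic reference task.
#' @param n_message_layers number of PointTransformer message passing layers
#'   over cluster nodes (default 4).
#' @param locnet_hidden internal width of LocNet (default 8).
#' @param locnet_k neighbourhood size of LocNet's attention over member
#'   localizations (default 8, capped at cluster size; a CPU-friendly default,
#'   larger values cost proportionally more per training step).
#' @param seed seed for parameter initialization.
#' @return An object of class `model_config`.
#' @export
model_config <- function(classes, mode = c("hcf", "lcf"), embed_dim = 8,
                         hidden_dim = 96, n_message_layers = 4,
                         locnet_hidden = 8, locnet_k = 8, seed = 1L) {
  mode <- match.arg(mode)
  classes <- as.character(classes)
  stopifnot(length(classes) >= 2, embed_dim >= 1, hidden_dim >= 1,
            n_message_layers >= 1, locnet_hidden >= 1, locnet_k >= 1)
  structure(list(classes = classes, n_classes = length(classes), mode = mode,
                 embed_dim = as.integer(embed_dim),
                 hidden_dim = as.integer(hidden_dim),
                 n_message_layers = as.integer(n_message_layers),
                 locnet_hidden = as.integer(locnet_hidden),
                 locnet_k = as.integer(locnet_k), seed = as.integer(seed)),
            class = "model_config")
}

he_mat <- function(nin, nout) matrix(stats::rnorm(nin * nout, 0, sqrt(2 / nin)), nin, nout)
zeros_row <- function(n) matrix(0, 1L, n)

# parameters of one PointTransformer convolution block (vector attention):
# query/key/value projections, a 2-layer relative-position MLP, a 2-layer
# attention MLP producing per-channel logits, and an output projection
init_pt_conv <- function(prefix, din, dout) {
  p <- list(
    Wo = he_mat(dout, dout), bo = zeros_row(dout),
    Wq = he_mat(din, dout), Wk = he_mat(din, dout), Wv = he_mat(din, dout),
    Wp1 = he_mat(2L, dout), bp1 = zeros_row(dout),
    Wp2 = he_mat(dout, dout), bp2 = zeros_row(dout),
    Wa1 = he_mat(dout, dout), ba1 = zeros_row(dout),
    # zero attention logits at init: uniform attention over each neighbourhood
    Wa2 = matrix(0, dout, dout), ba2 = zeros_row(dout)
  )
  names(p) <- paste0(prefix, ".", names(p))
  p
}

#' Initialize a ClusterNet model
#'
#' @param cfg a [model_config()].
#' @return An object of class `clusternet_model` holding the configuration and
#'   a flat named list of parameter matrices.
#' @export
clusternet_init <- function(cfg) {
  stopifnot(inherits(cfg, "model_config"))
  with_seed(cfg$seed, {
    H <- cfg$hidden_dim
    p <- list(W_in = he_mat(cfg$embed_dim, H), b_in = zeros_row(H))
    for (l in seq_len(cfg$n_message_layers)) {
      p <- c(p, init_pt_conv(sprintf("conv%d", l), H, H))
    }
    # small readout init keeps the initial loss near log(n_classes)
    p$W_out <- he_mat(H, cfg$n_classes) * 0.1
    p$b_out <- zeros_row(cfg$n_classes)
    if (cfg$mode == "lcf") {
      Hl <- cfg$locnet_hidden
      p <- c(p, list(ln.W0 = he_mat(2L, Hl), ln.b0 = zeros_row(Hl)))
      p <- c(p, init_pt_conv("ln.conv1", Hl, Hl), init_pt_conv("ln.conv2", Hl, Hl))
      p$ln.W_e <- he_mat(Hl, cfg$embed_dim)
      p$ln.b_e <- zeros_row(cfg$embed_dim)
    }
    structure(list(cfg = cfg, params = p), class = "clusternet_model")
  })
}

#' @export
print.clusternet_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, integer(1)))
  cat(sprintf("<clusternet_model> mode %s, %d classes, %d message layers, %d parameters\n",
              toupper(x$cfg$mode), x$cfg$n_classes, x$cfg$n_message_layers, np))
  invisible(x)
}

# one PointTransformer convolution on the tape.
# x: node features (n x d) node; rel: constant relative positions per edge
# (E x 2, shared across layers); src/dst: directed edges (attention of dst
# over src); P: named param nodes.
pt_conv_fwd <- function(P, prefix, x, rel, src, dst, nseg) {
  g <- function(s) P[[paste0(prefix, ".", s)]]
  q <- ad_mm(x, g("Wq")); k <- ad_mm(x, g("Wk")); v <- ad_mm(x, g("Wv"))
  d1 <- ad_affine(rel, g("Wp1"), g("bp1"), relu = TRUE)
  delta <- ad_affine(d1, g("Wp2"), g("bp2"))
  t1 <- ad_qk_rel(q, k, delta, src, dst)
  a1 <- ad_affine(t1, g("Wa1"), g("ba1"), relu = TRUE)
  logits <- ad_affine(a1, g("Wa2"), g("ba2"))
  alpha <- ad_segment_softmax(logits, dst, nseg)
  msg <- ad_msg(alpha, v, delta, src)
  agg <- ad_segment_sum(msg, dst, nseg)
  ad_affine(agg, g("Wo"), g("bo"))   # output projection of the block
}

# directed localization kNN edges within each cluster of a graph (self-loops
# included); cached on the graph by callers that reuse it
loc_knn_edges <- function(graph, k) {
  if (!is.null(graph$loc_edges) && isTRUE(attr(graph$loc_edges, "k") == k)) {
    return(graph$loc_edges)
  }
  src <- integer(0); dst <- integer(0)
  for (cl in seq_len(n_cluster_nodes(graph))) {
    rows <- which(graph$loc_cluster == cl)
    m <- length(rows)
    src <- c(src, rows); dst <- c(dst, rows)           # self-loops
    if (m > 1) {
      kk <- min(k, m - 1)
      d <- as.matrix(stats::dist(graph$loc_pos[rows, , drop = FALSE]))
      for (a in seq_len(m)) {
        ord <- order(d[a, -a], seq_len(m)[-a])
        nb <- rows[(seq_len(m)[-a])[ord[seq_len(kk)]]]
        src <- c(src, nb); dst <- c(dst, rep(rows[a], kk))
      }
    }
  }
  e <- cbind(src = src, dst = dst)
  attr(e, "k") <- k
  e
}

# concatenate graphs into one batch for the forward pass
make_batch <- function(graphs, mode, locnet_k = 16, angles = NULL) {
  ng <- length(graphs)
  cpos <- list(); feat <- list(); gid <- list(); src <- list(); dst <- list()
  lpos <- list(); lclu <- list(); lsrc <- list(); ldst <- list()
  coff <- 0L; loff <- 0L
  for (i in seq_len(ng)) {
    g <- graphs[[i]]
    m <- n_cluster_nodes(g)
    cp <- g$cluster_pos
    lp <- g$loc_pos
    if (!is.null(angles)) {
      a <- angles[i]
      R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2L, 2L)
      cp <- cp %*% R
      lp <- lp %*% R
    }
    cpos[[i]] <- cp
    gid[[i]] <- rep(i, m)
    de <- directed_edges(g)
    src[[i]] <- de[, 1] + coff
    dst[[i]] <- de[, 2] + coff
    if (mode == "hcf") {
      if (is.null(g$cluster_features)) stop("HCF mode requires cluster features on every graph")
      feat[[i]] <- g$cluster_features
    } else {
      ctr <- cp[g$loc_cluster, , drop = FALSE]
      lpos[[i]] <- lp - ctr                 # member positions relative to centroid
      lclu[[i]] <- g$loc_cluster + coff
      le <- loc_knn_edges(g, locnet_k)
      lsrc[[i]] <- le[, 1] + loff
      ldst[[i]] <- le[, 2] + loff
      loff <- loff + nrow(lp)
    }
    coff <- coff + m
  }
  out <- list(n_graphs = ng, n_clusters = coff,
              cpos = do.call(rbind, cpos), graph_id = unlist(gid),
              src = unlist(src), dst = unlist(dst),
              labels = vapply(graphs, function(g) g$label, character(1)))
  if (mode == "hcf") {
    out$feat <- do.call(rbind, feat)
  } else {
    out$lpos <- do.call(rbind, lpos)
    out$lcluster <- unlist(lclu)
    out$lsrc <- unlist(lsrc)
    out$ldst <- unlist(ldst)
  }
  out
}

# forward pass over a batch; returns tape nodes for the loss and the exposed
# intermediate features
cn_forward <- function(model, batch, labels_idx = NULL) {
  cfg <- model$cfg
  P <- lapply(model$params, ad_param)
  if (cfg$mode == "lcf") {
    h <- ad_affine(ad_const(batch$lpos), P$ln.W0, P$ln.b0, relu = TRUE)
    nl <- nrow(batch$lpos)
    lrel <- ad_const(batch$lpos[batch$lsrc, , drop = FALSE] -
                     batch$lpos[batch$ldst, , drop = FALSE])
    for (l in 1:2) {
      h <- ad_add(ad_relu(pt_conv_fwd(P, sprintf("ln.conv%d", l), h, lrel,
                                      batch$lsrc, batch$ldst, nl)), h)
    }
    pooled <- ad_segment_max(h, batch$lcluster, batch$n_clusters)
    feat <- ad_sigmoid(ad_affine(pooled, P$ln.W_e, P$ln.b_e))
  } else {
    feat <- ad_const(batch$feat)
  }
  h <- ad_affine(feat, P$W_in, P$b_in, relu = TRUE)
  crel <- ad_const(batch$cpos[batch$src, , drop = FALSE] -
                   batch$cpos[batch$dst, , drop = FALSE])
  for (l in seq_len(cfg$n_message_layers)) {
    h <- ad_add(ad_relu(pt_conv_fwd(P, sprintf("conv%d", l), h, crel,
                                    batch$src, batch$dst, batch$n_clusters)), h)
  }
  gfeat <- ad_segment_max(h, batch$graph_id, batch$n_graphs)
  logits <- ad_affine(gfeat, P$W_out, P$b_out)
  logp <- ad_log_softmax(logits)
  out <- list(logp = logp, graph_feat = gfeat, post_mp = h,
              cluster_feat = feat, param_nodes = P)
  if (!is.null(labels_idx)) out$loss <- ad_nll(logp, labels_idx)
  out
}

#' Forward pass of ClusterNet on one graph
#'
#' @param model a trained or freshly initialized `clusternet_model`.
#' @param graph a `hier_graph`; HCF mode requires `cluster_features`.
#' @return A `class_prediction`: `log_probs` (named), `predicted_class`
#'   (character; ties broken towards the lowest class index),
#'   `graph_feature` (pooled vector), `cluster_features` (post message passing,
#'   one row per cluster) and `input_features` (handcrafted or LocNet).
#' @export
clusternet_forward <- function(model, graph) {
  stopifnot(inherits(model, "clusternet_model"), inherits(graph, "hier_graph"))
  batch <- make_batch(list(graph), model$cfg$mode, model$cfg$locnet_k)
  fw <- cn_forward(model, batch)
  lp <- as.numeric(ad_val(fw$logp))
  names(lp) <- model$cfg$classes
  structure(list(log_probs = lp,
                 predicted_class = model$cfg$classes[which.max(lp)],
                 graph_feature = as.numeric(ad_val(fw$graph_feat)),
                 cluster_features = ad_val(fw$post_mp),
                 input_features = ad_val(fw$cluster_feat)),
            class = "class_prediction")
}

#' Class probabilities for a list of graphs
#'
#' @param model a `clusternet_model`, or a plain function `graph -> probability
#'   vector` (used by the explainability tools for rule-based reference models).
#' @param graphs list of `hier_graph`s.
#' @param batch_size forward batch size.
#' @return matrix (graphs x classes) of probabilities.
#' @export
predict_probs <- function(model, graphs, batch_size = 128) {
  if (is.function(model)) {
    return(do.call(rbind, lapply(graphs, function(g) as.numeric(model(g)))))
  }
  stopifnot(inherits(model, "clusternet_model"))
  out <- matrix(NA_real_, length(graphs), model$cfg$n_classes,
                dimnames = list(NULL, model$cfg$classes))
  i <- 1L
  while (i <= length(graphs)) {
    j <- min(i + batch_size - 1L, length(graphs))
    b <- make_batch(graphs[i:j], model$cfg$mode, model$cfg$locnet_k)
    fw <- cn_forward(model, b)
    out[i:j, ] <- exp(ad_val(fw$logp))
    i <- j + 1L
  }
  out
}

#' Embed one cluster's localizations with LocNet
#'
#' Runs only the LocNet stage of an LCF model on a set of member positions
#' (normalized, centred internally), returning the length-`embed_dim` feature
#' vector, each component strictly in (0, 1) by the sigmoid output.
#'
#' @param model an LCF-mode `clusternet_model`.
#' @param points matrix (n x 2) of member positions (normalized coordinates),
#'   n >= 3.
#' @return numeric vector of length `embed_dim`.
#' @export
locnet_embed <- function(model, points) {
  stopifnot(inherits(model, "clusternet_model"))
  if (model$cfg$mode != "lcf") stop("locnet_embed requires an LCF-mode model")
  points <- as.matrix(points)
  if (nrow(points) < 3) stop("need at least 3 member localizations")
  g <- structure(list(
    loc_pos = points, loc_cluster = rep(1L, nrow(points)),
    cluster_pos = matrix(colMeans(points), 1L),
    cluster_features = NULL, edges = matrix(c(1L, 1L), 1L),
    label = NA_character_, source_id = NA_character_), class = "hier_graph")
  batch <- make_batch(list(g), "lcf", model$cfg$locnet_k)
  fw <- cn_forward(model, batch)
  as.numeric(ad_val(fw$cluster_feat))
}

model_probs_one <- function(model, graph) {
  if (is.function(model)) as.numeric(model(graph))
  else as.numeric(exp(clusternet_forward(model, graph)$log_probs))
}

#' Save a model checkpoint
#'
#' Writes a single JSON archive holding the configuration and all parameter
#' matrices (versioned header), readable with [load_model()].
#'
#' @param model a `clusternet_model`.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "clusternet_model"))
  obj <- list(format = "clusternet-model", version = 1L,
              config = unclass(model$cfg),
              params = model$params,
              best_epoch = model$best_epoch)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path file written by [save_model()].
#' @return A `clusternet_model`.
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "clusternet-model")) {
    stop("format error: not a clusternet-model file: ", path)
  }
  cfg <- do.call(model_config, obj$config[c("classes", "mode", "embed_dim",
                                            "hidden_dim", "n_message_layers",
                                            "locnet_hidden", "locnet_k", "seed")])
  params <- lapply(obj$params, function(p) {
    m <- as.matrix(p); dimnames(m) <- NULL; storage.mode(m) <- "double"; m
  })
  structure(list(cfg = cfg, params = params,
                 best_epoch = obj$best_epoch), class = "clusternet_model")
}
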