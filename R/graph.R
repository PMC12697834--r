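# Hierarchical graph construction: localization nodes + cluster nodes with
# per-graph position normalization, min-max feature scaling fitted on training
# data, and symmetrized k-nearest-neighbour cluster edges with self-loops.

#' Normalize positions to [-1, 1] preserving aspect ratio
#'
#' Applies `x -> 2 (x - min x) / max(xrange, yrange) - 1` with the same divisor
#' for y, so the larger extent maps to the full [-1, 1] range and the aspect
#' ratio is preserved. The minimum and ranges are measured over the supplied
#' positions (the parent graph).
#'
#' @param positions numeric matrix (n x 2), nm.
#' @return matrix of normalized (dimensionless) positions.
#' @export
normalize_positions <- function(positions) {
  positions <- as.matrix(positions)
  if (nrow(positions) < 1) stop("need at least one position")
  t <- position_transform(positions)
  apply_position_transform(positions, t)
}

position_transform <- function(positions) {
  mins <- c(min(positions[, 1]), min(positions[, 2]))
  rng <- max(max(positions[, 1]) - mins[1], max(positions[, 2]) - mins[2])
  if (rng <= 0) stop("degenerate positions: all points identical")
  list(mins = mins, range = rng)
}

apply_position_transform <- function(positions, t) {
  cbind(2 * (positions[, 1] - t$mins[1]) / t$range - 1,
        2 * (positions[, 2] - t$mins[2]) / t$range - 1)
}

#' Fit a min-max feature scaler on training clusters
#'
#' Records the per-feature minimum and maximum over the training set, the
#' statistics later used by [apply_scaler()] to map features into [0, 1].
#' Fit this on training data only to avoid test-set leakage; the returned
#' object is stamped `fitted_on = "train"`.
#'
#' @param features numeric matrix or data.frame of per-cluster feature rows.
#' @return An object of class `feature_scaler`.
#' @export
fit_scaler <- function(features) {
  m <- as.matrix(features)
  structure(list(min = apply(m, 2L, min), max = apply(m, 2L, max),
                 fitted_on = "train"),
            class = "feature_scaler")
}

#' Apply a fitted min-max scaler
#'
#' `h -> (h - min) / (max - min)` per feature, then clamped to [0, 1] so that
#' out-of-training-range values at test time cannot leave the model's input
#' domain. A feature with `max == min` maps to 0 with a warning.
#'
#' @param h feature matrix (rows = clusters) or vector.
#' @param scaler a [fit_scaler()] result.
#' @return matrix of scaled features in [0, 1].
#' @export
apply_scaler <- function(h, scaler) {
  stopifnot(inherits(scaler, "feature_scaler"))
  m <- if (is.null(dim(h))) matrix(as.numeric(h), 1L) else as.matrix(h)
  rng <- scaler$max - scaler$min
  flat <- rng <= 0
  if (any(flat)) {
    warning("feature(s) with zero training range mapped to 0: ",
            paste(which(flat), collapse = ", "))
    rng[flat] <- 1
  }
  out <- sweep(sweep(m, 2L, scaler$min), 2L, rng, "/")
  out[, flat] <- 0
  out[out < 0] <- 0
  out[out > 1] <- 1
  out
}

#' Scale the feature columns of a cluster-feature table
#'
#' Convenience wrapper applying [apply_scaler()] to the 8 feature columns of a
#' [cluster_features()] data.frame, leaving the id/centroid columns intact.
#'
#' @param features data.frame from [cluster_features()].
#' @param scaler a [fit_scaler()] result fitted on the training set's features.
#' @return The data.frame with scaled feature columns.
#' @export
scale_features <- function(features, scaler) {
  features[, .feature_names] <- apply_scaler(
    as.matrix(features[, .feature_names, drop = FALSE]), scaler)
  features
}

# k-nearest-neighbour lists on a position matrix; ties broken by lowest id
knn_pairs <- function(pos, k) {
  m <- nrow(pos)
  if (m <= 1 || k <= 0) return(matrix(integer(0), 0L, 2L))
  k <- min(k, m - 1)
  d <- as.matrix(stats::dist(pos))
  pairs <- matrix(integer(0), 0L, 2L)
  for (i in seq_len(m)) {
    ord <- order(d[i, -i], seq_len(m)[-i])  # distance, then lowest id
    nb <- (seq_len(m)[-i])[ord[seq_len(k)]]
    pairs <- rbind(pairs, cbind(i, nb))
  }
  pairs
}

#' Build the hierarchical graph for one clustered ROI/cell
#'
#' Cluster node positions are the unweighted centroids of their member
#' localizations; localization and cluster positions are normalized jointly
#' with the same per-graph transform ([normalize_positions()]). Undirected
#' edges connect each cluster node to itself (self-loop) and to its
#' `n_neighbors` nearest neighbours (Euclidean distance on normalized
#' positions, union-symmetrized); with fewer than `n_neighbors` other clusters
#' every pair is connected.
#'
#' @param clusters a `cluster_set` from [cluster()].
#' @param features optional per-cluster features: a matrix with one row per
#'   cluster, or a data.frame with a `cluster` id column as returned by
#'   [cluster_features()] (clusters without a feature row are dropped from the
#'   graph). Pass features already scaled with [apply_scaler()].
#' @param n_neighbors number of nearest neighbours per cluster node (default 5).
#' @return An object of class `hier_graph` with elements `loc_pos`,
#'   `loc_cluster`, `cluster_pos`, `cluster_features`, `edges` (undirected
#'   unique pairs, including one self-loop per cluster), `label`, `source_id`.
#' @export
build_graph <- function(clusters, features = NULL, n_neighbors = 5) {
  stopifnot(inherits(clusters, "cluster_set"))
  if (clusters$n_clusters < 1) stop("empty cluster set")
  keep <- seq_len(clusters$n_clusters)
  fmat <- NULL
  if (!is.null(features)) {
    if (is.data.frame(features) && "cluster" %in% names(features)) {
      keep <- features$cluster
      fmat <- as.matrix(features[, .feature_names, drop = FALSE])
    } else {
      fmat <- as.matrix(features)
      if (nrow(fmat) != clusters$n_clusters) {
        stop("features must have one row per cluster")
      }
    }
  }
  assignment <- match(clusters$assignment, keep)   # reindex to kept clusters
  m <- length(keep)
  loc_rows <- which(!is.na(assignment))
  xy <- cbind(clusters$table$locs$x, clusters$table$locs$y)[loc_rows, , drop = FALSE]
  parent <- assignment[loc_rows]
  cpos <- rowsum(xy, parent) / as.vector(table(factor(parent, levels = seq_len(m))))
  dimnames(cpos) <- NULL
  t <- position_transform(xy)
  loc_pos <- apply_position_transform(xy, t)
  cluster_pos <- apply_position_transform(cpos, t)
  nb <- knn_pairs(cluster_pos, n_neighbors)
  if (nrow(nb) > 0) {
    und <- unique(cbind(pmin(nb[, 1], nb[, 2]), pmax(nb[, 1], nb[, 2])))
  } else {
    und <- matrix(integer(0), 0L, 2L)
  }
  edges <- rbind(cbind(seq_len(m), seq_len(m)), und)
  dimnames(edges) <- NULL
  storage.mode(edges) <- "integer"
  structure(list(loc_pos = loc_pos, loc_cluster = parent,
                 cluster_pos = cluster_pos, cluster_features = fmat,
                 edges = edges, label = clusters$table$gt_label,
                 source_id = clusters$table$source_id),
            class = "hier_graph")
}

#' @export
print.hier_graph <- function(x, ...) {
  cat(sprintf("<hier_graph> %d cluster nodes, %d localization nodes, %d edges, label: %s\n",
              nrow(x$cluster_pos), length(x$loc_cluster), nrow(x$edges), x$label))
  invisible(x)
}

# directed edge arrays (src -> dst) for message passing: both directions for
# each undirected pair, self-loops once
directed_edges <- function(graph) {
  e <- graph$edges
  self <- e[, 1] == e[, 2]
  und <- e[!self, , drop = FALSE]
  src <- c(e[self, 1], und[, 1], und[, 2])
  dst <- c(e[self, 2], und[, 2], und[, 1])
  cbind(src = src, dst = dst)
}

n_cluster_nodes <- function(graph) nrow(graph$cluster_pos)
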