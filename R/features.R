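# Eight handcrafted per-cluster shape features, computed from the constituent
# localizations: count, radius of gyration squared, convex-hull perimeter,
# linearity, planarity, length, area and density.

#' Principal-component variances of a 2D point set
#'
#' Returns the eigenvalues of the covariance matrix of the points, sorted
#' descending: `lambda0 >= lambda1`, with `lambda2 = 0` since the data are 2D.
#' Values are variances in nm^2.
#'
#' @param points numeric matrix (n x 2) of positions in nm, n >= 3.
#' @param denom covariance denominator: `"n-1"` (sample covariance, default)
#'   or `"n"`.
#' @return list with `lambda0`, `lambda1`, `lambda2`.
#' @export
pca_variances <- function(points, denom = c("n-1", "n")) {
  denom <- match.arg(denom)
  points <- as.matrix(points)
  if (nrow(points) < 3) stop("need at least 3 points for PCA")
  ctr <- sweep(points, 2L, colMeans(points))
  if (all(abs(ctr) < .Machine$double.eps * 100)) {
    stop("degenerate cluster: all points identical")
  }
  S <- crossprod(ctr) / (nrow(points) - if (denom == "n-1") 1 else 0)
  ev <- sort(eigen(S, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  ev <- pmax(ev, 0)
  list(lambda0 = ev[1], lambda1 = ev[2], lambda2 = 0)
}

# convex hull perimeter; 0 would indicate degenerate input
hull_perimeter <- function(points) {
  h <- grDevices::chull(points)
  hp <- points[c(h, h[1]), , drop = FALSE]
  sum(sqrt(rowSums(diff(hp)^2)))
}

.feature_names <- c("count", "rg2", "perimeter", "linearity", "planarity",
                    "length", "area", "density")

#' Handcrafted features of one cluster
#'
#' Computes, for a cluster of >= 3 non-collinear localizations:
#' * `count` - number of localizations;
#' * `rg2` - radius of gyration squared: mean squared distance from the
#'   centroid (nm^2);
#' * `perimeter` - convex hull perimeter (nm);
#' * `linearity` - `(lambda0 - lambda1) / lambda0`;
#' * `planarity` - `lambda1 / lambda0`;
#' * `length` - `2.35 * sqrt(lambda0)` (nm; full width at half maximum of a
#'   Gaussian is 2.35 standard deviations);
#' * `area` - `2.35^2 * sqrt(lambda0 * lambda1)` (nm^2);
#' * `density` - `count / area` (nm^-2).
#'
#' @param points numeric matrix (n x 2), positions in nm.
#' @param denom covariance denominator passed to [pca_variances()].
#' @return named numeric vector of the 8 features.
#' @export
compute_features <- function(points, denom = c("n-1", "n")) {
  points <- as.matrix(points)
  pv <- pca_variances(points, denom)
  if (pv$lambda1 <= 0) {
    stop("degenerate cluster: collinear points have zero area")
  }
  ctr <- sweep(points, 2L, colMeans(points))
  rg2 <- mean(rowSums(ctr^2))
  perim <- hull_perimeter(points)
  linearity <- (pv$lambda0 - pv$lambda1) / pv$lambda0
  planarity <- pv$lambda1 / pv$lambda0
  len <- 2.35 * sqrt(pv$lambda0)
  area <- 2.35^2 * sqrt(pv$lambda0 * pv$lambda1)
  c(count = nrow(points), rg2 = rg2, perimeter = perim,
    linearity = linearity, planarity = planarity,
    length = len, area = area, density = nrow(points) / area)
}

#' Handcrafted features for every cluster in a cluster set
#'
#' Degenerate (collinear) clusters are dropped with a warning; the returned
#' rows are aligned with the surviving cluster ids.
#'
#' @param cs a `cluster_set` from [cluster()].
#' @param denom covariance denominator passed to [pca_variances()].
#' @return data.frame with `cluster`, `centroid_x`, `centroid_y` and the 8
#'   feature columns.
#' @export
cluster_features <- function(cs, denom = c("n-1", "n")) {
  stopifnot(inherits(cs, "cluster_set"))
  members <- cluster_members(cs)
  rows <- vector("list", length(members))
  for (i in seq_along(members)) {
    f <- tryCatch(compute_features(members[[i]], denom), error = function(e) NULL)
    if (is.null(f)) next
    rows[[i]] <- data.frame(cluster = i,
                            centroid_x = mean(members[[i]][, 1]),
                            centroid_y = mean(members[[i]][, 2]),
                            as.list(f))
  }
  dropped <- sum(vapply(rows, is.null, logical(1)))
  if (dropped > 0) {
    warning(dropped, " degenerate (collinear) cluster(s) dropped from features")
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(out) <- NULL
  out
}
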