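# Preprocessing: quality filtering, temporal grouping of blinking events,
# assignment of localizations to annotated cells, cell-level filters, and
# clustering (k-means or DBSCAN) with a small-cluster filter.

#' Quality thresholds for localization filtering
#'
#' Defaults follow common dSTORM practice: localizations with more than 30000
#' photons, a fitted PSF standard deviation outside 75-200 nm, a PSF fit
#' p-value above 0.01, or a localization precision above 25 nm are removed.
#'
#' @param max_photons,psf_sigma_min,psf_sigma_max,psf_pvalue_max,precision_max
#'   thresholds; see Details.
#' @return An object of class `quality_thresholds`.
#' @export
quality_thresholds <- function(max_photons = 30000, psf_sigma_min = 75,
                               psf_sigma_max = 200, psf_pvalue_max = 0.01,
                               precision_max = 25) {
  stopifnot(psf_sigma_min < psf_sigma_max, max_photons > 0, psf_pvalue_max > 0,
            precision_max > 0)
  structure(list(max_photons = max_photons, psf_sigma_min = psf_sigma_min,
                 psf_sigma_max = psf_sigma_max, psf_pvalue_max = psf_pvalue_max,
                 precision_max = precision_max),
            class = "quality_thresholds")
}

#' Temporal grouping parameters
#'
#' Localizations within `radius` nm of each other and no more than
#' `max_frame_gap` frames apart are chained into one blinking-event track;
#' tracks spanning more than `max_lifetime` frames are removed entirely.
#'
#' @param radius chaining radius in nm.
#' @param max_frame_gap maximum frame gap within a track.
#' @param max_lifetime maximum track span in frames.
#' @return An object of class `grouping_params`.
#' @export
grouping_params <- function(radius = 60, max_frame_gap = 2, max_lifetime = 5) {
  stopifnot(radius > 0, max_frame_gap > 0, max_lifetime > 0)
  structure(list(radius = radius, max_frame_gap = max_frame_gap,
                 max_lifetime = max_lifetime),
            class = "grouping_params")
}

#' Clustering configuration
#'
#' @param method `"kmeans"` or `"dbscan"`.
#' @param k number of k-means clusters (default 12).
#' @param eps DBSCAN neighbourhood radius in nm.
#' @param min_pts DBSCAN minimum neighbourhood size (including the point).
#' @param min_cluster_size clusters with fewer localizations than this are
#'   discarded; the default 3 discards clusters with two or fewer localizations
#'   so that the convex hull and principal components are always computable.
#' @param seed integer seed for k-means restarts.
#' @return An object of class `clustering_config`.
#' @export
clustering_config <- function(method = c("kmeans", "dbscan"), k = 12, eps = 50,
                              min_pts = 3, min_cluster_size = 3, seed = 1L) {
  method <- match.arg(method)
  stopifnot(k >= 1, eps > 0, min_pts >= 1, min_cluster_size >= 3)
  structure(list(method = method, k = as.integer(k), eps = eps,
                 min_pts = as.integer(min_pts),
                 min_cluster_size = as.integer(min_cluster_size),
                 seed = as.integer(seed)),
            class = "clustering_config")
}

#' Quality-filter a localization table
#'
#' Retains rows with `photons <= max_photons`,
#' `psf_sigma_min <= psf_sigma <= psf_sigma_max`, `psf_pvalue <= psf_pvalue_max`
#' and `precision <= precision_max`. Thresholds whose column is absent are
#' skipped with a warning.
#'
#' @param table a [loc_table()].
#' @param thr a [quality_thresholds()].
#' @return The filtered [loc_table()].
#' @export
filter_localizations <- function(table, thr = quality_thresholds()) {
  stopifnot(inherits(table, "loc_table"), inherits(thr, "quality_thresholds"))
  df <- table$locs
  keep <- rep(TRUE, nrow(df))
  skipped <- character(0)
  apply_thr <- function(col, ok) {
    if (col %in% names(df)) keep <<- keep & ok(df[[col]])
    else skipped <<- c(skipped, col)
  }
  apply_thr("photons", function(v) v <= thr$max_photons)
  apply_thr("psf_sigma", function(v) v >= thr$psf_sigma_min & v <= thr$psf_sigma_max)
  apply_thr("psf_pvalue", function(v) v <= thr$psf_pvalue_max)
  apply_thr("precision", function(v) v <= thr$precision_max)
  if (length(skipped)) {
    warning("quality columns absent, thresholds skipped: ",
            paste(skipped, collapse = ", "))
  }
  if (!any(keep)) stop("empty result: all localizations removed by quality filter")
  loc_table(df[keep, , drop = FALSE], table$gt_label, table$source_id)
}

#' Temporally group localizations into blinking events
#'
#' Localizations are chained greedily in frame order: a localization joins the
#' track whose most recent member is within `radius` nm and no more than
#' `max_frame_gap` frames earlier (nearest such track if several). Tracks
#' spanning at most `max_lifetime` frames are replaced by one localization at
#' the track's unweighted mean position with the first frame number; tracks
#' spanning more frames are removed entirely.
#'
#' @param table a [loc_table()] with a `frame` column.
#' @param gp a [grouping_params()].
#' @return The grouped [loc_table()].
#' @export
temporal_group <- function(table, gp = grouping_params()) {
  stopifnot(inherits(table, "loc_table"), inherits(gp, "grouping_params"))
  df <- table$locs
  if (!"frame" %in% names(df)) stop("temporal grouping requires a frame column")
  ord <- order(df$frame)
  df <- df[ord, , drop = FALSE]
  n <- nrow(df)
  track <- integer(n)          # track id per row
  last_x <- numeric(0); last_y <- numeric(0); last_f <- numeric(0)
  first_f <- numeric(0)
  ntr <- 0L
  for (i in seq_len(n)) {
    f <- df$frame[i]
    cand <- which(last_f >= f - gp$max_frame_gap & last_f < f)
    if (length(cand)) {
      d2 <- (last_x[cand] - df$x[i])^2 + (last_y[cand] - df$y[i])^2
      j <- cand[which.min(d2)]
      if (min(d2) <= gp$radius^2) {
        track[i] <- j
        last_x[j] <- df$x[i]; last_y[j] <- df$y[i]; last_f[j] <- f
        next
      }
    }
    ntr <- ntr + 1L
    track[i] <- ntr
    last_x[ntr] <- df$x[i]; last_y[ntr] <- df$y[i]
    last_f[ntr] <- f; first_f[ntr] <- f
  }
  span <- last_f - first_f + 1
  keep_tr <- which(span <= gp$max_lifetime)
  rows <- split(seq_len(n), track)
  out <- lapply(keep_tr, function(tr) {
    r <- rows[[as.character(tr)]]
    rec <- df[r[1], , drop = FALSE]
    rec$x <- mean(df$x[r]); rec$y <- mean(df$y[r])
    rec$frame <- min(df$frame[r])
    for (cl in intersect(c("photons", "psf_sigma", "psf_pvalue", "precision"),
                         names(df))) {
      rec[[cl]] <- mean(df[[cl]][r])
    }
    rec
  })
  res <- if (length(out)) do.call(rbind, out) else df[0, , drop = FALSE]
  rownames(res) <- NULL
  loc_table(res, table$gt_label, table$source_id)
}

# distance from points (n x 2) to a polyline (m x 2), per point
dist_to_polyline <- function(pts, line) {
  if (nrow(line) == 1) {
    return(sqrt((pts[, 1] - line[1, 1])^2 + (pts[, 2] - line[1, 2])^2))
  }
  dmin <- rep(Inf, nrow(pts))
  for (s in seq_len(nrow(line) - 1)) {
    a <- line[s, ]; b <- line[s + 1, ]
    ab <- b - a
    len2 <- sum(ab^2)
    t <- if (len2 == 0) rep(0, nrow(pts)) else
      pmin(1, pmax(0, ((pts[, 1] - a[1]) * ab[1] + (pts[, 2] - a[2]) * ab[2]) / len2))
    dx <- pts[, 1] - (a[1] + t * ab[1])
    dy <- pts[, 2] - (a[2] + t * ab[2])
    dmin <- pmin(dmin, sqrt(dx^2 + dy^2))
  }
  dmin
}

#' Assign localizations to annotated cells
#'
#' Splits a field of view into per-cell localization tables using provided cell
#' regions, labels every retained localization `membrane` or `interior`, and
#' drops localizations outside all cells.
#'
#' Cell regions are either a list of polygons (matrices of nm vertices) or a
#' label mask (`list(mask = <integer matrix>, nm_per_pixel = <scale>)`, row =
#' y pixel, column = x pixel, 0 = background). Membrane regions are a list of
#' polylines (nm); when omitted, each cell's polygon boundary is used. A
#' localization is `membrane` when within `membrane_width` nm of a membrane
#' polyline (or, for masks, inside a pixel of the membrane mask).
#'
#' @param table a [loc_table()].
#' @param cell_regions polygons, a label mask (see Details), or the path of a
#'   GeoJSON file of Polygon features (coordinates in nm).
#' @param membrane_regions polylines or logical mask; optional.
#' @param membrane_width nm band width for membrane labeling (default 100).
#' @return list of per-cell [loc_table()] objects (possibly empty tables).
#' @export
assign_cells <- function(table, cell_regions, membrane_regions = NULL,
                         membrane_width = 100) {
  stopifnot(inherits(table, "loc_table"))
  if (is.character(cell_regions) && length(cell_regions) == 1) {
    cell_regions <- read_geojson_polygons(cell_regions)
  }
  df <- table$locs
  pts <- cbind(df$x, df$y)
  if (is.list(cell_regions) && !is.null(cell_regions$mask)) {
    mask <- cell_regions$mask
    s <- cell_regions$nm_per_pixel
    px <- floor(pts[, 1] / s) + 1L
    py <- floor(pts[, 2] / s) + 1L
    inside <- px >= 1 & px <= ncol(mask) & py >= 1 & py <= nrow(mask)
    cell_of <- rep(0L, nrow(pts))
    cell_of[inside] <- mask[cbind(py[inside], px[inside])]
    ids <- sort(setdiff(unique(as.vector(mask)), 0L))
    memb <- rep(FALSE, nrow(pts))
    if (!is.null(membrane_regions)) {
      mm <- membrane_regions
      memb[inside] <- mm[cbind(py[inside], px[inside])] > 0
    }
    cells <- lapply(ids, function(id) list(rows = which(cell_of == id)))
    membranes_for <- function(i, rows) memb[rows]
  } else {
    if (!is.list(cell_regions) || length(cell_regions) == 0) {
      stop("no cell regions provided")
    }
    polys <- lapply(cell_regions, function(p) {
      p <- as.matrix(p)
      if (!isTRUE(all.equal(p[1, ], p[nrow(p), ]))) p <- rbind(p, p[1, ])
      p
    })
    cells <- lapply(polys, function(p) list(rows = which(mgcv::in.out(p, pts))))
    mem_lines <- if (is.null(membrane_regions)) polys else
      lapply(membrane_regions, as.matrix)
    membranes_for <- function(i, rows) {
      if (length(rows) == 0) return(logical(0))
      sub <- pts[rows, , drop = FALSE]
      if (is.null(membrane_regions)) {
        dist_to_polyline(sub, mem_lines[[i]]) <= membrane_width
      } else {
        d <- rep(Inf, nrow(sub))
        for (ml in mem_lines) d <- pmin(d, dist_to_polyline(sub, ml))
        d <= membrane_width
      }
    }
  }
  if (length(cells) == 0) stop("no cell regions provided")
  out <- vector("list", length(cells))
  for (i in seq_along(cells)) {
    rows <- cells[[i]]$rows
    sub <- df[rows, , drop = FALSE]
    if (nrow(sub) > 0) {
      sub$region <- ifelse(membranes_for(i, rows), "membrane", "interior")
    } else {
      sub$region <- character(0)
    }
    rownames(sub) <- NULL
    out[[i]] <- loc_table(sub, table$gt_label,
                          sprintf("%s_cell%02d", table$source_id, i))
  }
  out
}

#' Filter cells by localization counts
#'
#' Keeps cells with at least `min_locs` localizations and at least
#' `min_interior` interior and `min_membrane` membrane localizations.
#'
#' @param cells list of per-cell [loc_table()]s with a `region` column.
#' @param min_locs,min_interior,min_membrane thresholds (defaults 500, 5, 5).
#' @return The surviving cells (possibly an empty list).
#' @export
filter_cells <- function(cells, min_locs = 500, min_interior = 5, min_membrane = 5) {
  keep <- vapply(cells, function(cl) {
    df <- cl$locs
    if (!"region" %in% names(df)) stop("cells must carry a region column")
    nrow(df) >= min_locs &&
      sum(df$region == "interior") >= min_interior &&
      sum(df$region == "membrane") >= min_membrane
  }, logical(1))
  cells[keep]
}

# polygons (list of n x 2 matrices) from a GeoJSON FeatureCollection
read_geojson_polygons <- function(path) {
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  feats <- if (!is.null(gj$features)) gj$features else list(gj)
  polys <- list()
  for (ft in feats) {
    geom <- if (!is.null(ft$geometry)) ft$geometry else ft
    if (!identical(geom$type, "Polygon")) next
    ring <- geom$coordinates[[1]]          # outer ring only
    polys[[length(polys) + 1L]] <-
      do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
  }
  if (length(polys) == 0) stop("no Polygon features in ", path)
  polys
}

# k-means with k-means++ seeding and multiple restarts (best total
# within-cluster sum of squares wins); Lloyd refinement via stats::kmeans
kmeanspp <- function(xy, k, restarts = 10, iter.max = 100) {
  n <- nrow(xy)
  best <- NULL
  for (r in seq_len(restarts)) {
    centers <- matrix(NA_real_, k, 2)
    centers[1, ] <- xy[sample.int(n, 1), ]
    d2 <- rowSums(sweep(xy, 2L, centers[1, ])^2)
    for (j in seq_len(k - 1) + 1) {
      pick <- if (sum(d2) <= 0) sample.int(n, 1) else
        sample.int(n, 1, prob = d2)
      centers[j, ] <- xy[pick, ]
      d2 <- pmin(d2, rowSums(sweep(xy, 2L, centers[j, ])^2))
    }
    fit <- suppressWarnings(stats::kmeans(xy, centers = centers,
                                          iter.max = iter.max))
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  best$cluster
}

# brute-force DBSCAN; neighbourhoods include the point itself
dbscan_assign <- function(xy, eps, min_pts) {
  n <- nrow(xy)
  eps2 <- eps^2
  neigh <- vector("list", n)
  for (i in seq_len(n)) {
    d2 <- (xy[, 1] - xy[i, 1])^2 + (xy[, 2] - xy[i, 2])^2
    neigh[[i]] <- which(d2 <= eps2)
  }
  core <- vapply(neigh, length, integer(1)) >= min_pts
  lab <- rep(NA_integer_, n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (!is.na(lab[i]) || !core[i]) next
    cl <- cl + 1L
    queue <- i
    lab[i] <- cl
    while (length(queue)) {
      j <- queue[[1]]
      queue <- queue[-1]
      for (q in neigh[[j]]) {
        if (is.na(lab[q])) {
          lab[q] <- cl
          if (core[q]) queue <- c(queue, q)
        }
      }
    }
  }
  lab
}

#' Cluster a localization table
#'
#' Partitions an ROI/cell into clusters using seeded k-means (fixed `k`,
#' multiple restarts) or DBSCAN (noise points excluded), then discards clusters
#' smaller than `min_cluster_size` localizations.
#'
#' @param table a [loc_table()].
#' @param cfg a [clustering_config()].
#' @return An object of class `cluster_set`: the parent table, an `assignment`
#'   vector (surviving cluster id 1..m per localization, `NA` for noise or
#'   filtered clusters) and `n_clusters`.
#' @export
cluster <- function(table, cfg = clustering_config()) {
  stopifnot(inherits(table, "loc_table"), inherits(cfg, "clustering_config"))
  xy <- cbind(table$locs$x, table$locs$y)
  if (cfg$method == "kmeans") {
    if (nrow(xy) < cfg$k) {
      stop("fewer localizations (", nrow(xy), ") than k (", cfg$k, ")")
    }
    lab <- with_seed(cfg$seed, kmeanspp(xy, cfg$k, restarts = 10))
  } else {
    if (nrow(xy) < 1) stop("empty localization table")
    lab <- dbscan_assign(xy, cfg$eps, cfg$min_pts)
  }
  sizes <- table(lab)
  keep <- as.integer(names(sizes)[sizes >= cfg$min_cluster_size])
  if (length(keep) == 0) stop("empty result: no clusters survive the size filter")
  assignment <- match(lab, sort(keep))   # NA for noise and filtered clusters
  structure(list(table = table, assignment = assignment,
                 n_clusters = length(keep)),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("<cluster_set> %d clusters over %d localizations (%d unassigned)\n",
              x$n_clusters, length(x$assignment), sum(is.na(x$assignment))))
  invisible(x)
}

# member coordinate matrices per surviving cluster
cluster_members <- function(cs) {
  xy <- cbind(cs$table$locs$x, cs$table$locs$y)
  lapply(seq_len(cs$n_clusters), function(i) {
    xy[which(cs$assignment == i), , drop = FALSE]
  })
}
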