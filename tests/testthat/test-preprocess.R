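# Preprocessing rules: quality filter, temporal grouping, cell assignment and
# filters, clustering with the small-cluster filter.

quality_df <- function(...) {
  base <- data.frame(x = 0, y = 0, photons = 5000, psf_sigma = 100,
                     psf_pvalue = 0.005, precision = 10)
  mod <- list(...)
  for (nm in names(mod)) base[[nm]] <- mod[[nm]]
  base
}

test_that("quality filter applies each printed threshold", {
  rows <- rbind(quality_df(),                      # retained
                quality_df(precision = 30),        # precision > 25 nm
                quality_df(photons = 40000),       # photons > 30000
                quality_df(psf_sigma = 60),        # PSF sigma < 75 nm
                quality_df(psf_sigma = 250),       # PSF sigma > 200 nm
                quality_df(psf_pvalue = 0.02))     # p-value > 0.01
  out <- filter_localizations(loc_table(rows))
  expect_equal(nrow(out$locs), 1)
  # boundary values are retained (thresholds are inclusive)
  edge <- rbind(quality_df(precision = 25), quality_df(photons = 30000),
                quality_df(psf_sigma = 75), quality_df(psf_sigma = 200),
                quality_df(psf_pvalue = 0.01))
  expect_equal(nrow(filter_localizations(loc_table(edge))$locs), 5)
})

test_that("quality filter without quality columns warns and is a no-op", {
  tab <- loc_table(data.frame(x = 1:5, y = 1:5))
  expect_warning(out <- filter_localizations(tab), "skipped")
  expect_equal(out$locs, tab$locs)
})

test_that("quality filter rejects a fully filtered table and is idempotent", {
  expect_error(
    suppressWarnings(filter_localizations(loc_table(quality_df(precision = 99)))),
    "empty")
  tab <- loc_table(rbind(quality_df(), quality_df(precision = 30)))
  once <- filter_localizations(tab)
  expect_equal(filter_localizations(once)$locs, once$locs)
})

test_that("temporal grouping merges, splits and drops tracks by the rules", {
  # 30 nm apart at frames 1 and 2: grouped to the midpoint
  tab <- loc_table(data.frame(x = c(0, 30), y = c(0, 0), frame = c(1, 2)))
  out <- temporal_group(tab)
  expect_equal(nrow(out$locs), 1)
  expect_equal(out$locs$x, 15)
  expect_equal(out$locs$frame, 1)
  # same positions but frames 1 and 4: gap 3 > 2, two outputs
  tab2 <- loc_table(data.frame(x = c(0, 30), y = c(0, 0), frame = c(1, 4)))
  expect_equal(nrow(temporal_group(tab2)$locs), 2)
  # 70 nm apart: outside the 60 nm radius, two outputs
  tab3 <- loc_table(data.frame(x = c(0, 70), y = c(0, 0), frame = c(1, 2)))
  expect_equal(nrow(temporal_group(tab3)$locs), 2)
  # a track persisting frames 1-6 spans 6 > 5 frames: removed entirely
  tab4 <- loc_table(data.frame(x = rep(0, 6), y = rep(0, 6), frame = 1:6))
  expect_equal(nrow(temporal_group(tab4)$locs), 0)
  # frames 1-5 spans exactly 5: kept
  tab5 <- loc_table(data.frame(x = rep(0, 5), y = rep(0, 5), frame = 1:5))
  expect_equal(nrow(temporal_group(tab5)$locs), 1)
  expect_error(temporal_group(loc_table(data.frame(x = 1, y = 1))), "frame")
})

test_that("cell assignment drops outside localizations and labels the membrane", {
  withr::with_seed(5, {
    inside <- data.frame(x = runif(100, 10, 990), y = runif(100, 10, 990))
    outside <- data.frame(x = runif(10, 2000, 3000), y = runif(10, 0, 1000))
    tab <- loc_table(rbind(inside, outside), gt_label = "resp")
    square <- rbind(c(0, 0), c(1000, 0), c(1000, 1000), c(0, 1000))
    cells <- assign_cells(tab, list(square), membrane_width = 50)
    expect_length(cells, 1)
    expect_equal(nrow(cells[[1]]$locs), 100)
    # membrane = within 50 nm of the boundary polygon
    df <- cells[[1]]$locs
    d_edge <- pmin(df$x, df$y, 1000 - df$x, 1000 - df$y)
    expect_equal(df$region == "membrane", d_edge <= 50)
    expect_error(assign_cells(tab, list()), "no cell")
  })
})

test_that("GeoJSON polygon files work as cell regions", {
  gj <- list(type = "FeatureCollection", features = list(list(
    type = "Feature", properties = list(name = "cell1"),
    geometry = list(type = "Polygon", coordinates = list(list(
      list(0, 0), list(1000, 0), list(1000, 1000), list(0, 1000), list(0, 0)))))))
  f <- withr::local_tempfile(fileext = ".geojson")
  jsonlite::write_json(gj, f, auto_unbox = TRUE)
  tab <- loc_table(data.frame(x = c(500, 1500), y = c(500, 500)))
  cells <- assign_cells(tab, f)
  expect_length(cells, 1)
  expect_equal(nrow(cells[[1]]$locs), 1)
})

test_that("label-mask cell assignment matches pixel membership", {
  mask <- matrix(0L, 10, 10)
  mask[2:9, 2:5] <- 1L     # cell 1: x pixels 2..5
  mask[2:9, 7:9] <- 2L     # cell 2: x pixels 7..9
  tab <- loc_table(data.frame(x = c(25, 45, 75, 95), y = rep(50, 4)))
  cells <- assign_cells(tab, list(mask = mask, nm_per_pixel = 10))
  expect_length(cells, 2)
  expect_equal(nrow(cells[[1]]$locs), 2)
  expect_equal(nrow(cells[[2]]$locs), 1)   # x = 95 is in pixel 10 -> background
})

test_that("cell filter enforces the 500/5/5 rule", {
  mk_cell <- function(n, n_mem) {
    df <- data.frame(x = seq_len(n), y = seq_len(n),
                     region = rep(c("membrane", "interior"),
                                  c(n_mem, n - n_mem)))
    loc_table(df)
  }
  cells <- list(mk_cell(499, 10),   # too few localizations
                mk_cell(600, 4),    # too few membrane
                mk_cell(600, 596),  # too few interior
                mk_cell(600, 10))   # kept
  out <- filter_cells(cells)
  expect_length(out, 1)
  expect_equal(nrow(out[[1]]$locs), 600)
})

test_that("k-means clustering recovers the 12 grid sites and is deterministic", {
  lib <- make_default_templates()
  roi <- sample_roi(lib$classes$grid,
                    simulation_params(seed = 2, background_rate = 0,
                                      misfold_prob = 0), label = "grid")
  cfg <- clustering_config(k = 12, seed = 7)
  cs1 <- cluster(roi, cfg)
  cs2 <- cluster(roi, cfg)
  expect_equal(cs1$n_clusters, 12)
  expect_identical(cs1$assignment, cs2$assignment)
  expect_error(cluster(loc_table(data.frame(x = 1:5, y = 1:5)), cfg), "fewer")
})

test_that("row order changes k-means cluster ids but not the partition", {
  # well-separated blobs: the optimal partition is unambiguous
  withr::with_seed(6, {
    centres <- as.matrix(expand.grid(x = c(0, 300, 600), y = c(0, 300, 600, 900)))
    xy <- do.call(rbind, lapply(seq_len(12), function(i) {
      cbind(rnorm(25, centres[i, 1], 5), rnorm(25, centres[i, 2], 5))
    }))
  })
  tab <- loc_table(data.frame(x = xy[, 1], y = xy[, 2]))
  cfg <- clustering_config(k = 12, seed = 7)
  cs1 <- cluster(tab, cfg)
  perm <- withr::with_seed(3, sample(nrow(xy)))
  cs_p <- cluster(loc_table(tab$locs[perm, ]), cfg)
  # pairs (label before, label after) form a bijection
  expect_equal(length(unique(paste(cs1$assignment[perm], cs_p$assignment))), 12)
})

test_that("clusters with two or fewer localizations are discarded", {
  blobs <- list(cbind(rep(0, 2), c(0, 1)),          # size 2: discarded
                cbind(rep(100, 3), c(0, 1, 2)),     # size 3: kept
                cbind(rep(200, 10), seq_len(10)))   # size 10: kept
  xy <- do.call(rbind, blobs)
  tab <- loc_table(data.frame(x = xy[, 1], y = xy[, 2]))
  cs <- cluster(tab, clustering_config(method = "dbscan", eps = 5, min_pts = 2))
  sizes <- sort(as.integer(table(cs$assignment)))
  expect_equal(sizes, c(3, 10))
  expect_true(all(is.na(cs$assignment[1:2])))
})

test_that("dbscan separates well-spaced blobs and drops isolated noise", {
  withr::with_seed(8, {
    blobs <- lapply(list(c(0, 0), c(500, 0), c(0, 500)), function(ctr) {
      cbind(rnorm(20, ctr[1], 5), rnorm(20, ctr[2], 5))
    })
    xy <- rbind(do.call(rbind, blobs), c(250, 250))   # one isolated point
    tab <- loc_table(data.frame(x = xy[, 1], y = xy[, 2]))
    cs <- cluster(tab, clustering_config(method = "dbscan", eps = 50, min_pts = 3))
    expect_equal(cs$n_clusters, 3)
    expect_true(is.na(cs$assignment[61]))
    # each blob ends up in exactly one cluster
    for (b in 1:3) {
      expect_equal(length(unique(cs$assignment[(b - 1) * 20 + 1:20])), 1)
    }
  })
})

test_that("zero surviving clusters is an error", {
  tab <- loc_table(data.frame(x = c(0, 500, 1000), y = c(0, 500, 1000)))
  expect_error(cluster(tab, clustering_config(method = "dbscan", eps = 10,
                                              min_pts = 2)), "empty result")
})
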