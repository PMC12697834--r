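#' Localization table
#'
#' Container for one region of interest (ROI) or cell worth of 2D SMLM
#' localizations. Coordinates are always in nanometres. Optional per-localization
#' quality columns (`frame`, `channel`, `photons`, `psf_sigma`, `psf_pvalue`,
#' `precision`, `region`) are carried through when present.
#'
#' @param locs data.frame with at least numeric columns `x` and `y` (nm).
#' @param gt_label optional ground-truth class label (character scalar).
#' @param source_id optional identifier of the originating ROI/cell.
#' @return An object of class `loc_table`.
#' @export
loc_table <- function(locs, gt_label = NA_character_, source_id = NA_character_) {
  if (!is.data.frame(locs)) stop("`locs` must be a data.frame")
  if (!all(c("x", "y") %in% names(locs))) stop("localization table requires x and y columns")
  if (nrow(locs) > 0 && !all(is.finite(locs$x) & is.finite(locs$y))) {
    stop("x and y must be finite")
  }
  structure(
    list(locs = as.data.frame(locs), gt_label = as.character(gt_label),
         source_id = as.character(source_id)),
    class = "loc_table"
  )
}

#' @export
print.loc_table <- function(x, ...) {
  cat(sprintf("<loc_table> %d localizations, label: %s, source: %s\n",
              nrow(x$locs), x$gt_label, x$source_id))
  invisible(x)
}

# run expr under a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Template library of binding-site layouts
#'
#' A template library holds one binding-site layout (2D points, nm) per class.
#' Layouts emulate DNA-origami designs: localizations are later scattered around
#' each site.
#'
#' @param classes named list; each element a numeric matrix (n_sites x 2) of
#'   site coordinates in nm, centred near the origin.
#' @param roi_extent side length (nm) of the square ROI each layout must fit in.
#' @return An object of class `template_library`.
#' @export
template_library <- function(classes, roi_extent = 200) {
  if (length(classes) < 2) stop("need at least 2 classes")
  if (is.null(names(classes)) || any(names(classes) == "")) stop("classes must be named")
  for (nm in names(classes)) {
    m <- classes[[nm]]
    if (!is.matrix(m) || ncol(m) != 2 || nrow(m) < 3) {
      stop("each layout must be a matrix of >= 3 sites with 2 columns")
    }
    if (any(abs(m) > roi_extent / 2)) {
      stop(sprintf("layout '%s' does not fit in the %g nm ROI extent", nm, roi_extent))
    }
  }
  structure(list(classes = classes, roi_extent = roi_extent),
            class = "template_library")
}

#' Default synthetic template library
#'
#' Four distinguishable DNA-origami-like layouts on a 13 nm site pitch: a
#' 3 x 4 rectangular grid of 12 binding sites, a 6-site line, an 8-site ring and
#' a 9-site cross. The 13 nm pitch keeps the layouts on the physical scale of
#' typical origami designs.
#'
#' @param spacing site pitch in nm (default 13).
#' @param roi_extent square ROI side length in nm (default 200).
#' @return A [template_library()].
#' @export
make_default_templates <- function(spacing = 13, roi_extent = 200) {
  centre <- function(m) sweep(m, 2L, colMeans(m))
  grid <- centre(as.matrix(expand.grid(x = spacing * 0:2, y = spacing * 0:3)))
  line <- centre(cbind(spacing * 0:5, 0))
  th <- 2 * pi * (0:7) / 8
  ring <- cbind(2 * spacing * cos(th), 2 * spacing * sin(th))
  cross <- centre(rbind(cbind(0, spacing * (-2:2)),
                        cbind(spacing * c(-2, -1, 1, 2), 0)))
  template_library(list(grid = grid, line = line, ring = ring, cross = cross),
                   roi_extent = roi_extent)
}

#' Simulation parameters for the synthetic SMLM generator
#'
#' @param locs_per_site_mean Poisson mean localization count per binding site.
#' @param site_sigma isotropic Gaussian spread (nm) of localizations about a site.
#' @param background_rate Poisson mean count of uniform background localizations
#'   per ROI.
#' @param misfold_prob probability that each binding site is independently
#'   dropped ("misfolded" structure).
#' @param rotation apply a uniform random in-plane rotation to each ROI's layout.
#' @param seed integer seed; fully determines the generator's output.
#' @return An object of class `simulation_params`.
#' @export
simulation_params <- function(locs_per_site_mean = 30, site_sigma = 5,
                              background_rate = 5, misfold_prob = 0.05,
                              rotation = TRUE, seed = 1L) {
  stopifnot(locs_per_site_mean >= 0, site_sigma > 0, background_rate >= 0,
            misfold_prob >= 0, misfold_prob < 1)
  structure(list(locs_per_site_mean = locs_per_site_mean, site_sigma = site_sigma,
                 background_rate = background_rate, misfold_prob = misfold_prob,
                 rotation = isTRUE(rotation), seed = as.integer(seed)),
            class = "simulation_params")
}

#' Sample one synthetic SMLM ROI
#'
#' Localizations are drawn per retained binding site as
#' `Poisson(locs_per_site_mean)` isotropic Gaussian draws with standard
#' deviation `site_sigma`, plus `Poisson(background_rate)` uniform background
#' localizations over the ROI extent. Sites are independently dropped with
#' probability `misfold_prob`.
#'
#' @param template numeric matrix (n_sites x 2) of site coordinates in nm, or a
#'   class name together with `library`.
#' @param params a [simulation_params()] object.
#' @param label class label stored in the output's metadata.
#' @param roi_extent square ROI side (nm); background is uniform over it.
#' @param source_id identifier stored in the output's metadata.
#' @return A [loc_table()].
#' @export
sample_roi <- function(template, params = simulation_params(), label = NA_character_,
                       roi_extent = 200, source_id = NA_character_) {
  stopifnot(inherits(params, "simulation_params"))
  if (!is.matrix(template) || ncol(template) != 2) stop("template must be an n x 2 matrix")
  with_seed(params$seed, {
    sites <- template
    if (params$rotation) {
      a <- stats::runif(1, 0, 2 * pi)
      R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2L, 2L)
      sites <- sites %*% R
    }
    keep <- stats::runif(nrow(sites)) >= params$misfold_prob
    pts <- matrix(numeric(0), 0L, 2L)
    for (i in which(keep)) {
      n <- stats::rpois(1, params$locs_per_site_mean)
      if (n > 0) {
        pts <- rbind(pts, cbind(stats::rnorm(n, sites[i, 1], params$site_sigma),
                                stats::rnorm(n, sites[i, 2], params$site_sigma)))
      }
    }
    nb <- stats::rpois(1, params$background_rate)
    if (nb > 0) {
      half <- roi_extent / 2
      pts <- rbind(pts, cbind(stats::runif(nb, -half, half),
                              stats::runif(nb, -half, half)))
    }
    if (nrow(pts) == 0) {
      stop("degenerate sample: all sites dropped and no background localizations")
    }
    loc_table(data.frame(x = pts[, 1], y = pts[, 2]),
              gt_label = label, source_id = source_id)
  })
}

#' Sample a labeled synthetic dataset
#'
#' Generates exactly `n_per_class` ROIs for every class in the template library.
#' Per-ROI seeds are derived deterministically from `params$seed`, so the same
#' master seed reproduces the dataset exactly.
#'
#' @param library a [template_library()].
#' @param n_per_class number of ROIs per class (>= 1).
#' @param params a [simulation_params()]; its `seed` is the master seed.
#' @return list of [loc_table()] objects, `n_per_class` per class.
#' @export
sample_dataset <- function(library, n_per_class, params = simulation_params()) {
  stopifnot(inherits(library, "template_library"))
  if (n_per_class < 1) stop("n_per_class must be >= 1")
  out <- list()
  i <- 0L
  for (cls in names(library$classes)) {
    for (j in seq_len(n_per_class)) {
      i <- i + 1L
      p <- params
      p$seed <- as.integer((as.numeric(params$seed) * 7919 + i * 104729) %% 2147483647)
      out[[i]] <- sample_roi(library$classes[[cls]], p, label = cls,
                             roi_extent = library$roi_extent,
                             source_id = sprintf("%s_%04d", cls, j))
    }
  }
  out
}
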