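# On-disk formats: localization tables as Apache Parquet (label in file
# metadata) or CSV (label as a repeated gt_label column, since CSV has no
# metadata); hierarchical graphs as a versioned JSON container.

.loc_optional_cols <- c("frame", "channel", "photons", "psf_sigma",
                        "psf_pvalue", "precision", "region")

#' Read a localization table
#'
#' @param path file path.
#' @param dialect one of `"auto"` (by extension), `"parquet"`, `"csv"`.
#' @param col_map optional named character vector mapping on-disk column names
#'   to canonical names, e.g. `c("x [nm]" = "x")`, for externally produced files.
#' @return A [loc_table()].
#' @export
read_locs <- function(path, dialect = c("auto", "parquet", "csv"), col_map = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.parquet$", path, ignore.case = TRUE)) "parquet" else "csv"
  }
  if (!file.exists(path)) stop("file not found: ", path)
  gt <- NA_character_; src <- NA_character_
  if (dialect == "parquet") {
    tb <- arrow::read_parquet(path, as_data_frame = FALSE)
    if (!is.null(tb$metadata$gt_label)) gt <- tb$metadata$gt_label
    if (!is.null(tb$metadata$source_id)) src <- tb$metadata$source_id
    df <- as.data.frame(tb)
  } else {
    df <- utils::read.csv(path, check.names = FALSE)
  }
  if (!is.null(col_map)) {
    hit <- names(df) %in% names(col_map)
    names(df)[hit] <- col_map[names(df)[hit]]
  }
  if ("gt_label" %in% names(df)) {
    if (is.na(gt) && nrow(df) > 0) gt <- as.character(df$gt_label[1])
    df$gt_label <- NULL
  }
  if ("source_id" %in% names(df)) {
    if (is.na(src) && nrow(df) > 0) src <- as.character(df$source_id[1])
    df$source_id <- NULL
  }
  if (!all(c("x", "y") %in% names(df))) {
    stop("format error: missing x/y coordinate columns in ", path)
  }
  if (nrow(df) == 0) stop("empty input: no localizations in ", path)
  loc_table(df, gt_label = gt, source_id = src)
}

#' Write a localization table
#'
#' Lossless counterpart of [read_locs()] for both dialects.
#'
#' @param table a [loc_table()].
#' @param path destination file.
#' @param dialect `"auto"` (by extension), `"parquet"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_locs <- function(table, path, dialect = c("auto", "parquet", "csv")) {
  stopifnot(inherits(table, "loc_table"))
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.parquet$", path, ignore.case = TRUE)) "parquet" else "csv"
  }
  if (dialect == "parquet") {
    tb <- arrow::arrow_table(table$locs)
    if (!is.na(table$gt_label)) tb$metadata$gt_label <- table$gt_label
    if (!is.na(table$source_id)) tb$metadata$source_id <- table$source_id
    arrow::write_parquet(tb, path)
  } else {
    df <- table$locs
    if (!is.na(table$gt_label)) df$gt_label <- table$gt_label
    if (!is.na(table$source_id)) df$source_id <- table$source_id
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}

.graph_format <- "clusternet-graph"
.graph_version <- 1L

#' Write a hierarchical graph to a JSON container
#'
#' The container has a versioned header (`format`, `version`) followed by the
#' node/edge arrays; see [read_graph()] for the inverse.
#'
#' @param graph a `hier_graph` (see [build_graph()]).
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_graph <- function(graph, path) {
  stopifnot(inherits(graph, "hier_graph"))
  obj <- list(
    format = .graph_format, version = .graph_version,
    label = graph$label, source_id = graph$source_id,
    loc_pos = graph$loc_pos, loc_cluster = graph$loc_cluster,
    cluster_pos = graph$cluster_pos,
    cluster_features = graph$cluster_features,
    feature_names = colnames(graph$cluster_features),
    edges = graph$edges
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' Read a hierarchical graph from a JSON container
#'
#' @param path file written by [write_graph()].
#' @return A `hier_graph`.
#' @export
read_graph <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) stop("format error: cannot parse ", path))
  if (!identical(obj$format, .graph_format)) {
    stop("format error: not a ", .graph_format, " file: ", path)
  }
  if (is.null(obj$cluster_pos) || NROW(obj$cluster_pos) == 0) {
    stop("format error: empty graph in ", path)
  }
  as_mat <- function(m, nc) {
    if (is.null(m)) return(NULL)
    m <- as.matrix(m)
    dimnames(m) <- NULL
    storage.mode(m) <- "double"
    if (ncol(m) != nc) stop("format error: bad array width in ", path)
    m
  }
  g <- list(
    loc_pos = as_mat(obj$loc_pos, 2L),
    loc_cluster = as.integer(obj$loc_cluster),
    cluster_pos = as_mat(obj$cluster_pos, 2L),
    cluster_features = if (is.null(obj$cluster_features)) NULL else {
      m <- as.matrix(obj$cluster_features); dimnames(m) <- NULL
      storage.mode(m) <- "double"
      if (!is.null(obj$feature_names)) colnames(m) <- obj$feature_names
      m
    },
    edges = {
      e <- as.matrix(obj$edges); dimnames(e) <- NULL
      storage.mode(e) <- "integer"; e
    },
    label = if (is.null(obj$label)) NA_character_ else as.character(obj$label),
    source_id = if (is.null(obj$source_id)) NA_character_ else as.character(obj$source_id)
  )
  class(g) <- "hier_graph"
  g
}
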