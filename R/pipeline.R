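# End-to-end pipeline: generate (or read) localization tables, preprocess and
# cluster, featurize, build graphs, train, evaluate and optionally explain,
# writing all stage outputs plus a reproducibility manifest to a run directory.

.pipeline_keys <- list(
  top = c("seed", "out", "input", "generate", "quality", "grouping",
          "preprocess", "graph", "model", "train", "explain"),
  quality = c("max_photons", "psf_sigma_min", "psf_sigma_max",
              "psf_pvalue_max", "precision_max"),
  grouping = c("radius", "max_frame_gap", "max_lifetime"),
  generate = c("classes", "n_per_class", "locs_per_site_mean", "site_sigma",
               "background_rate", "misfold_prob", "rotation", "roi_extent",
               "site_spacing"),
  preprocess = c("method", "k", "eps", "min_pts", "min_cluster_size"),
  graph = c("n_neighbors"),
  model = c("mode", "hidden_dim", "embed_dim", "n_message_layers",
            "locnet_hidden", "locnet_k"),
  train = c("epochs", "batch_size", "lr", "weight_decay"),
  explain = c("enabled", "n_graphs", "rollouts", "max_subgraph_nodes",
              "shapley_samples")
)

validate_config <- function(cfg) {
  bad <- setdiff(names(cfg), .pipeline_keys$top)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  for (sec in intersect(names(cfg), setdiff(names(.pipeline_keys), "top"))) {
    bad <- setdiff(names(cfg[[sec]]), .pipeline_keys[[sec]])
    if (length(bad)) {
      stop("unknown config key(s) in '", sec, "': ", paste(bad, collapse = ", "))
    }
  }
  if (is.null(cfg$seed)) stop("config must set an explicit seed")
  invisible(cfg)
}

cfg_get <- function(cfg, sec, key, default) {
  v <- cfg[[sec]][[key]]
  if (is.null(v)) default else v
}

#' Run the full classification pipeline
#'
#' Stages: synthetic data generation (or reading localization files from
#' `input`), clustering and small-cluster filtering, handcrafted feature
#' extraction, graph construction (min-max feature scaler fitted on the
#' training split only), training with validation-best checkpointing,
#' evaluation on the held-out test split, and (optionally) SubgraphX
#' explanation of a few test graphs. All outputs are written to the run
#' directory: `model.json`, `metrics.json`, `training_log.csv`,
#' `predictions.csv`, `graphs/` (test-set graphs), `explain.json` (optional)
#' and a `manifest.json` with the config snapshot, seeds, package version and
#' output hashes.
#'
#' @param config path to a YAML config file, or an equivalent named list.
#'   Unknown keys are rejected before any computation. The config must set a
#'   `seed`; see the package vignette for the schema.
#' @param out output run directory (overrides the config's `out`).
#' @return Invisibly, a list with `metrics`, `model`, `run_dir`.
#' @export
run_pipeline <- function(config, out = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  validate_config(cfg)
  run_dir <- out %||% cfg$out %||% stop("config must set an output directory")
  dir.create(run_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(cfg$seed)

  # --- data ------------------------------------------------------------------
  if (!is.null(cfg$input)) {
    files <- list.files(cfg$input, pattern = "\\.(parquet|csv)$", full.names = TRUE)
    if (length(files) == 0) stop("stage data: no localization files in ", cfg$input)
    tabs <- lapply(files, read_locs)
  } else {
    lib <- make_default_templates(
      spacing = cfg_get(cfg, "generate", "site_spacing", 13),
      roi_extent = cfg_get(cfg, "generate", "roi_extent", 200))
    cls <- cfg_get(cfg, "generate", "classes", names(lib$classes))
    lib$classes <- lib$classes[cls]
    sim <- simulation_params(
      locs_per_site_mean = cfg_get(cfg, "generate", "locs_per_site_mean", 30),
      site_sigma = cfg_get(cfg, "generate", "site_sigma", 5),
      background_rate = cfg_get(cfg, "generate", "background_rate", 5),
      misfold_prob = cfg_get(cfg, "generate", "misfold_prob", 0.05),
      rotation = cfg_get(cfg, "generate", "rotation", TRUE),
      seed = seed)
    tabs <- sample_dataset(lib, cfg_get(cfg, "generate", "n_per_class", 50), sim)
  }
  labels <- vapply(tabs, function(t) t$gt_label, character(1))
  if (anyNA(labels)) stop("stage data: unlabeled localization tables")

  # optional quality filtering / temporal grouping (field names mirror
  # quality_thresholds() and grouping_params())
  if (!is.null(cfg$quality)) {
    thr <- do.call(quality_thresholds, cfg$quality)
    tabs <- lapply(tabs, filter_localizations, thr = thr)
  }
  if (!is.null(cfg$grouping)) {
    gp <- do.call(grouping_params, cfg$grouping)
    tabs <- lapply(tabs, temporal_group, gp = gp)
  }

  # --- preprocess + featurize ------------------------------------------------
  ccfg <- clustering_config(
    method = cfg_get(cfg, "preprocess", "method", "kmeans"),
    k = cfg_get(cfg, "preprocess", "k", 12),
    eps = cfg_get(cfg, "preprocess", "eps", 50),
    min_pts = cfg_get(cfg, "preprocess", "min_pts", 3),
    min_cluster_size = cfg_get(cfg, "preprocess", "min_cluster_size", 3),
    seed = seed)
  css <- lapply(tabs, function(tb) cluster(tb, ccfg))
  featl <- lapply(css, cluster_features)

  # --- splits, scaler, graphs ------------------------------------------------
  sp <- make_splits(labels, "stratified_cv", seed = seed)[[1]]
  scaler <- fit_scaler(do.call(rbind, lapply(featl[sp$train], function(f)
    as.matrix(f[, .feature_names, drop = FALSE]))))
  graphs <- mapply(function(cs, f) {
    build_graph(cs, scale_features(f, scaler),
                n_neighbors = cfg_get(cfg, "graph", "n_neighbors", 5))
  }, css, featl, SIMPLIFY = FALSE)

  # --- train -----------------------------------------------------------------
  mcfg <- model_config(
    classes = sort(unique(labels)),
    mode = cfg_get(cfg, "model", "mode", "hcf"),
    embed_dim = cfg_get(cfg, "model", "embed_dim", 8),
    hidden_dim = cfg_get(cfg, "model", "hidden_dim", 96),
    n_message_layers = cfg_get(cfg, "model", "n_message_layers", 4),
    locnet_hidden = cfg_get(cfg, "model", "locnet_hidden", 8),
    locnet_k = cfg_get(cfg, "model", "locnet_k", 8),
    seed = seed)
  tcfg <- train_config(
    epochs = cfg_get(cfg, "train", "epochs", 100),
    batch_size = cfg_get(cfg, "train", "batch_size", 128),
    lr = cfg_get(cfg, "train", "lr", 0.001),
    weight_decay = cfg_get(cfg, "train", "weight_decay", 0.0001),
    seed = seed)
  model <- train(clusternet_init(mcfg), graphs, sp$train, sp$val, tcfg)

  # --- evaluate --------------------------------------------------------------
  rep <- evaluate(model, graphs[sp$test])
  probs <- predict_probs(model, graphs[sp$test])
  pred_df <- data.frame(
    source_id = vapply(graphs[sp$test], function(g) g$source_id, character(1)),
    gt = labels[sp$test],
    pred = mcfg$classes[max.col(probs, ties.method = "first")])
  pred_df <- cbind(pred_df, as.data.frame(probs))

  # --- write outputs ---------------------------------------------------------
  save_model(model, file.path(run_dir, "model.json"))
  utils::write.csv(model$log, file.path(run_dir, "training_log.csv"),
                   row.names = FALSE)
  utils::write.csv(pred_df, file.path(run_dir, "predictions.csv"),
                   row.names = FALSE)
  metrics <- list(balanced_accuracy = rep$balanced_accuracy,
                  recall = as.list(rep$recall),
                  auroc = as.list(rep$auroc),
                  macro_auroc = rep$macro_auroc,
                  best_epoch = model$best_epoch)
  jsonlite::write_json(metrics, file.path(run_dir, "metrics.json"),
                       digits = NA, auto_unbox = TRUE)
  utils::write.csv(as.data.frame(rep$confusion),
                   file.path(run_dir, "confusion.csv"), row.names = FALSE)
  gdir <- file.path(run_dir, "graphs")
  dir.create(gdir, showWarnings = FALSE)
  for (i in sp$test) {
    write_graph(graphs[[i]], file.path(gdir, paste0(graphs[[i]]$source_id, ".json")))
  }

  # --- optional explanation --------------------------------------------------
  if (isTRUE(cfg_get(cfg, "explain", "enabled", FALSE))) {
    ecfg <- explain_config(
      max_subgraph_nodes = cfg_get(cfg, "explain", "max_subgraph_nodes", 8),
      rollouts = cfg_get(cfg, "explain", "rollouts", 100),
      shapley_samples = cfg_get(cfg, "explain", "shapley_samples", 100),
      seed = seed)
    ng <- min(cfg_get(cfg, "explain", "n_graphs", 2), length(sp$test))
    ex <- lapply(sp$test[seq_len(ng)], function(i) {
      res <- subgraphx_search(model, graphs[[i]], ecfg)
      list(source_id = graphs[[i]]$source_id, nodes = res$nodes,
           score = res$score, fid_plus = res$fidelity$fid_plus,
           fid_minus = res$fidelity$fid_minus)
    })
    jsonlite::write_json(ex, file.path(run_dir, "explain.json"),
                         digits = NA, auto_unbox = TRUE)
  }

  # --- manifest --------------------------------------------------------------
  outputs <- list.files(run_dir, recursive = TRUE)
  outputs <- setdiff(outputs, "manifest.json")
  manifest <- list(
    package = "clusternet",
    version = as.character(utils::packageVersion("clusternet")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = cfg,
    outputs = as.list(tools::md5sum(file.path(run_dir, outputs))))
  names(manifest$outputs) <- outputs
  jsonlite::write_json(manifest, file.path(run_dir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(list(metrics = rep, model = model, run_dir = run_dir))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
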