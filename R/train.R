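# Data partitioning, class-balanced sampling, rotation augmentation, the
# training loop (Adam, NLL loss, validation-best checkpointing) and evaluation
# metrics (per-class recall, balanced accuracy, one-vs-rest AUROC).

#' Training configuration
#'
#' Defaults: 100 epochs of Adam with learning rate 0.001, weight decay 0.0001
#' and batch size 128 (use 8 for small cell datasets).
#'
#' @param epochs,lr,weight_decay,batch_size,seed see Description.
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 100, lr = 0.001, weight_decay = 0.0001,
                         batch_size = 128, seed = 1L) {
  stopifnot(epochs >= 1, lr > 0, weight_decay >= 0, batch_size >= 1)
  structure(list(epochs = as.integer(epochs), lr = lr,
                 weight_decay = weight_decay,
                 batch_size = as.integer(batch_size), seed = as.integer(seed)),
            class = "train_config")
}

#' Cross-validation splits
#'
#' Stratified mode produces `n_folds` folds with non-overlapping test sets
#' (20\% each) and, within the remainder, a train (64\%) / validation (16\%)
#' split, all preserving per-class proportions up to rounding. Grouped mode
#' keeps each group (e.g. patient) in exactly one fold, greedily balancing fold
#' sizes and class ratios; validation is a held-out ~20\% of the training
#' groups.
#'
#' @param labels character vector of per-item class labels.
#' @param mode `"stratified_cv"` or `"grouped_cv"`.
#' @param n_folds number of folds (default 5).
#' @param groups group key per item (required for grouped mode).
#' @param seed integer seed; splits are deterministic given it.
#' @return list of `n_folds` folds, each `list(train, val, test)` index vectors.
#' @export
make_splits <- function(labels, mode = c("stratified_cv", "grouped_cv"),
                        n_folds = 5, groups = NULL, seed = 1L) {
  mode <- match.arg(mode)
  n <- length(labels)
  if (mode == "stratified_cv") {
    with_seed(seed, {
      fold_of <- integer(n)
      for (cls in unique(labels)) {
        idx <- sample(which(labels == cls))
        fold_of[idx] <- rep_len(seq_len(n_folds), length(idx))
      }
      lapply(seq_len(n_folds), function(f) {
        test <- which(fold_of == f)
        rest <- which(fold_of != f)
        val <- integer(0)
        for (cls in unique(labels)) {
          ridx <- sample(rest[labels[rest] == cls])
          nv <- round(length(ridx) * 0.2)   # 16% of the whole = 20% of the rest
          val <- c(val, ridx[seq_len(nv)])
        }
        list(train = setdiff(rest, val), val = sort(val), test = test)
      })
    })
  } else {
    if (is.null(groups)) stop("grouped mode requires a group key per item")
    ug <- unique(groups)
    if (length(ug) < n_folds) stop("fewer groups than folds")
    classes <- sort(unique(labels))
    overall <- as.numeric(table(factor(labels, classes))) / n
    with_seed(seed, {
      ug <- sample(ug)
      gsize <- vapply(ug, function(g) sum(groups == g), numeric(1))
      ug <- ug[order(gsize, decreasing = TRUE)]
      fold_items <- lapply(seq_len(n_folds), function(f) integer(0))
      cost <- function(items) {
        if (length(items) == 0) return(0)
        p <- as.numeric(table(factor(labels[items], classes))) / length(items)
        sum(abs(p - overall))
      }
      for (g in ug) {
        rows <- which(groups == g)
        sizes <- vapply(fold_items, length, integer(1))
        sc <- vapply(seq_len(n_folds), function(f) {
          cost(c(fold_items[[f]], rows)) + (sizes[f] + length(rows)) / n
        }, numeric(1))
        f <- which.min(sc)
        fold_items[[f]] <- c(fold_items[[f]], rows)
      }
      lapply(seq_len(n_folds), function(f) {
        test <- sort(fold_items[[f]])
        rest_groups <- unique(groups[-test])
        # greedy validation groups: ~20% of training items, best class ratio
        val_groups <- character(0)
        val_items <- integer(0)
        rest_items <- setdiff(seq_len(n), test)
        target <- 0.2 * length(rest_items)
        for (g in sample(rest_groups)) {
          rows <- rest_items[groups[rest_items] %in% g]
          if (length(val_items) + length(rows) <= target * 1.25) {
            cand <- c(val_items, rows)
            if (cost(cand) <= cost(val_items) + 0.5 || length(val_items) == 0) {
              val_groups <- c(val_groups, g)
              val_items <- cand
            }
          }
          if (length(val_items) >= target) break
        }
        list(train = setdiff(rest_items, val_items), val = sort(val_items),
             test = test)
      })
    })
  }
}

#' Inverse-class-frequency sampling weights
#'
#' Weight of each item is `1 / count(class)`, so sampling with replacement
#' draws every class with equal expected frequency (oversampling minority,
#' undersampling majority classes).
#'
#' @param labels class label per training item (>= 2 classes present).
#' @return numeric weight per item.
#' @export
sampler_weights <- function(labels) {
  tab <- table(labels)
  if (length(tab) < 2) stop("need at least 2 classes present")
  as.numeric(1 / tab[as.character(labels)])
}

#' Random in-plane rotation augmentation
#'
#' Rotates all node positions of a graph by one angle about the origin of the
#' normalized coordinate frame; features and topology are untouched.
#'
#' @param graph a `hier_graph`.
#' @param angle rotation angle in radians; when `NULL`, drawn uniformly from
#'   `[0, 2*pi)` using `seed`.
#' @param seed optional seed for the random angle.
#' @return The rotated `hier_graph`.
#' @export
augment_rotation <- function(graph, angle = NULL, seed = NULL) {
  stopifnot(inherits(graph, "hier_graph"))
  if (is.null(angle)) {
    angle <- if (is.null(seed)) stats::runif(1, 0, 2 * pi)
             else with_seed(seed, stats::runif(1, 0, 2 * pi))
  }
  R <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2L, 2L)
  graph$cluster_pos <- graph$cluster_pos %*% R
  graph$loc_pos <- graph$loc_pos %*% R
  graph
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0), v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, wd, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    g <- g + wd * params[[nm]]
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g^2
    mh <- state$m[[nm]] / (1 - b1^state$t)
    vh <- state$v[[nm]] / (1 - b2^state$t)
    params[[nm]] <- params[[nm]] - lr * mh / (sqrt(vh) + eps)
  }
  list(params = params, state = state)
}

batch_loss_and_grads <- function(model, graphs, idx, angles = NULL) {
  batch <- make_batch(graphs[idx], model$cfg$mode, model$cfg$locnet_k,
                      angles = angles)
  y <- match(batch$labels, model$cfg$classes)
  if (anyNA(y)) stop("graph label not among model classes")
  fw <- cn_forward(model, batch, labels_idx = y)
  ad_backward(fw$loss)
  grads <- lapply(fw$param_nodes, function(p) p$grad)
  list(loss = as.numeric(ad_val(fw$loss)), grads = grads)
}

# validation loss over fixed pre-built batches (no augmentation)
eval_loss_batches <- function(model, batches, n_total) {
  tot <- 0
  for (batch in batches) {
    y <- match(batch$labels, model$cfg$classes)
    fw <- cn_forward(model, batch, labels_idx = y)
    tot <- tot + as.numeric(ad_val(fw$loss)) * batch$n_graphs
  }
  tot / n_total
}

eval_loss <- function(model, graphs, idx, batch_size) {
  batches <- chunk_batches(model, graphs, idx, batch_size)
  eval_loss_batches(model, batches, length(idx))
}

chunk_batches <- function(model, graphs, idx, batch_size) {
  out <- list()
  i <- 1L
  while (i <= length(idx)) {
    j <- min(i + batch_size - 1L, length(idx))
    out[[length(out) + 1L]] <- make_batch(graphs[idx[i:j]], model$cfg$mode,
                                          model$cfg$locnet_k)
    i <- j + 1L
  }
  out
}

#' Train ClusterNet
#'
#' Runs `cfg$epochs` epochs of Adam on the negative log-likelihood, with
#' inverse-class-frequency weighted sampling (with replacement) of the training
#' graphs and a random in-plane rotation applied to every sampled graph. After
#' each epoch the model is evaluated on the validation set without
#' augmentation; the parameters with the lowest validation loss over all epochs
#' are returned.
#'
#' @param model an initialized `clusternet_model`.
#' @param graphs list of `hier_graph`s.
#' @param train_idx,val_idx integer indices into `graphs`.
#' @param cfg a [train_config()].
#' @param verbose print per-epoch losses.
#' @return The model with trained parameters, plus `$log` (data.frame of epoch,
#'   train_loss, val_loss) and `$best_epoch`.
#' @export
train <- function(model, graphs, train_idx, val_idx, cfg = train_config(),
                  verbose = FALSE) {
  stopifnot(inherits(model, "clusternet_model"), inherits(cfg, "train_config"))
  if (length(train_idx) == 0 || length(val_idx) == 0) {
    stop("train and validation sets must be non-empty")
  }
  if (model$cfg$mode == "lcf") {   # cache localization kNN edges once
    for (i in unique(c(train_idx, val_idx))) {
      graphs[[i]]$loc_edges <- loc_knn_edges(graphs[[i]], model$cfg$locnet_k)
    }
  }
  labels <- vapply(graphs[train_idx], function(g) g$label, character(1))
  w <- sampler_weights(labels)
  state <- adam_init(model$params)
  log <- data.frame(epoch = integer(0), train_loss = numeric(0),
                    val_loss = numeric(0))
  best <- list(val = Inf, params = model$params, epoch = 0L)
  val_batches <- chunk_batches(model, graphs, val_idx, cfg$batch_size)
  with_seed(cfg$seed, {
    for (ep in seq_len(cfg$epochs)) {
      order_idx <- sample(train_idx, length(train_idx), replace = TRUE, prob = w)
      i <- 1L
      ep_loss <- 0
      while (i <= length(order_idx)) {
        j <- min(i + cfg$batch_size - 1L, length(order_idx))
        idx <- order_idx[i:j]
        angles <- stats::runif(length(idx), 0, 2 * pi)
        bl <- batch_loss_and_grads(model, graphs, idx, angles)
        if (!is.finite(bl$loss)) stop("training diverged: non-finite loss at epoch ", ep)
        ep_loss <- ep_loss + bl$loss * length(idx)
        st <- adam_step(model$params, bl$grads, state, cfg$lr, cfg$weight_decay)
        model$params <- st$params
        state <- st$state
        i <- j + 1L
      }
      vl <- eval_loss_batches(model, val_batches, length(val_idx))
      log <- rbind(log, data.frame(epoch = ep,
                                   train_loss = ep_loss / length(order_idx),
                                   val_loss = vl))
      if (vl < best$val) best <- list(val = vl, params = model$params, epoch = ep)
      if (verbose) {
        message(sprintf("epoch %3d  train %.4f  val %.4f", ep,
                        ep_loss / length(order_idx), vl))
      }
    }
  })
  model$params <- best$params
  model$log <- log
  model$best_epoch <- best$epoch
  model
}

#' Evaluate a trained model
#'
#' Classifies each graph by its highest-probability class (no augmentation)
#' and reports per-class recall, balanced accuracy (arithmetic mean of the
#' recalls), the confusion matrix and one-vs-rest AUROC per class with a macro
#' average. Classes absent from the test set get `NaN` recall with a warning.
#'
#' @param model a trained `clusternet_model`.
#' @param graphs list of labeled `hier_graph`s to evaluate on.
#' @param probs optional precomputed probability matrix (graphs x classes);
#'   when given, the model is not re-run.
#' @return An object of class `metrics_report`.
#' @export
evaluate <- function(model, graphs, probs = NULL) {
  if (is.null(probs)) probs <- predict_probs(model, graphs)
  classes <- model$cfg$classes
  if (is.null(colnames(probs))) colnames(probs) <- classes
  truth <- vapply(graphs, function(g) g$label, character(1))
  pred <- classes[max.col(probs, ties.method = "first")]
  conf <- table(truth = factor(truth, classes), pred = factor(pred, classes))
  recalls <- vapply(classes, function(cls) {
    n <- sum(truth == cls)
    if (n == 0) NaN else sum(truth == cls & pred == cls) / n
  }, numeric(1))
  if (anyNA(recalls)) warning("class(es) absent from the evaluation set: ",
                              paste(classes[is.nan(recalls)], collapse = ", "))
  auroc <- vapply(classes, function(cls) {
    y <- as.integer(truth == cls)
    if (length(unique(y)) < 2) return(NaN)
    as.numeric(pROC::auc(y, probs[, cls], quiet = TRUE,
                         direction = "<", levels = c(0, 1)))
  }, numeric(1))
  structure(list(recall = recalls,
                 balanced_accuracy = mean(recalls, na.rm = TRUE),
                 auroc = auroc,
                 macro_auroc = mean(auroc, na.rm = TRUE),
                 confusion = conf),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report>\n")
  cat(sprintf("  balanced accuracy: %.4f   macro AUROC: %.4f\n",
              x$balanced_accuracy, x$macro_auroc))
  for (cls in names(x$recall)) {
    cat(sprintf("  %-10s recall %.3f  AUROC %.3f\n", cls, x$recall[cls],
                x$auroc[cls]))
  }
  invisible(x)
}
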