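# The user-facing classifier: loopflex() fits the E(3)-invariant residue-
# graph network on labelled graphs and returns a classed model object with
# the usual methods (print, summary, coef, predict, plot, residuals,
# simulate).

#' Training control parameters
#'
#' Defaults follow the training protocol of the flexibility classifier:
#' Adam with learning rate 2e-4 and weight decay 1e-6, random edge dropout
#' at probability 0.2 during training, early stopping monitored on the
#' validation PR AUC, and selection of the best of `n_restarts`
#' independently initialised runs by validation PR AUC.
#'
#' @param hidden_dim Embedding width (default 128).
#' @param n_layers Number of equivariant layers (default 3).
#' @param pooling Readout pooling, `"sum"` (default) or `"mean"`.
#' @param learning_rate Adam learning rate (default 2e-4).
#' @param weight_decay L2 weight decay (default 1e-6).
#' @param edge_dropout Per-edge drop probability during training
#'   (default 0.2).
#' @param batch_size Graphs per gradient step (default 32).
#' @param max_epochs Epoch cap (default 200).
#' @param patience Epochs without validation PR AUC improvement before
#'   stopping (default 10).
#' @param n_restarts Independent training runs; the best validation PR AUC
#'   wins (default 10).
#' @param seed Base RNG seed; restart r uses `seed + r - 1`.
#' @param verbose Print per-epoch progress.
#' @return A `loopflex_control` list.
#' @export
loopflex_control <- function(hidden_dim = 128L, n_layers = 3L,
                             pooling = c("sum", "mean"),
                             learning_rate = 2e-4, weight_decay = 1e-6,
                             edge_dropout = 0.2, batch_size = 32L,
                             max_epochs = 200L, patience = 10L,
                             n_restarts = 10L, seed = 1L, verbose = FALSE) {
  stopifnot(learning_rate > 0, edge_dropout >= 0, edge_dropout < 1,
            n_restarts >= 1L, patience >= 1L)
  structure(list(hidden_dim = as.integer(hidden_dim),
                 n_layers = as.integer(n_layers),
                 pooling = match.arg(pooling),
                 learning_rate = learning_rate,
                 weight_decay = weight_decay,
                 edge_dropout = edge_dropout,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 n_restarts = as.integer(n_restarts),
                 seed = as.integer(seed),
                 verbose = isTRUE(verbose)),
            class = "loopflex_control")
}

graph_labels <- function(graphs, labels) {
  if (is.null(labels)) {
    labels <- vapply(graphs, function(g) {
      if (is.null(g$label)) NA_real_ else as.numeric(g$label)
    }, 0)
  }
  if (anyNA(labels)) stop("every graph needs a 0/1 label")
  if (!all(labels %in% c(0, 1))) stop("labels must be 0 or 1")
  as.numeric(labels)
}

#' Fit the loop-flexibility graph classifier
#'
#' Trains the E(3)-invariant residue-graph network to classify loops as
#' flexible (label 1) or rigid (label 0) by minimising binary cross-entropy
#' with Adam. Training runs `control$n_restarts` times from independent
#' initialisations; each run applies random edge dropout, monitors the
#' validation PR AUC and stops early once it no longer improves; the restart
#' with the best validation PR AUC is returned.
#'
#' @param graphs List of labelled `ResidueGraph`s (training set).
#' @param labels Optional numeric 0/1 labels (default: taken from the
#'   graphs).
#' @param val_graphs,val_labels Validation set; both classes must be
#'   present.
#' @param control A [loopflex_control()].
#' @return An object of class `loopflex` with components `params` (fitted
#'   weights), `control`, `history` (per-epoch loss and validation PR AUC of
#'   the selected restart), `restart_pr_auc` (validation PR AUC of every
#'   restart), `fitted_scores` (training-set scores of the final model) and
#'   `labels`.
#' @export
loopflex <- function(graphs, labels = NULL, val_graphs, val_labels = NULL,
                     control = loopflex_control()) {
  stopifnot(length(graphs) > 0L, length(val_graphs) > 0L)
  y <- graph_labels(graphs, labels)
  yv <- graph_labels(val_graphs, val_labels)
  if (length(unique(yv)) < 2L) {
    stop("validation set must contain both classes (PR AUC undefined)")
  }
  best <- NULL
  restart_pr <- numeric(control$n_restarts)
  for (r in seq_len(control$n_restarts)) {
    run <- loopflex_train_once(graphs, y, val_graphs, yv, control,
                               seed = control$seed + r - 1L)
    restart_pr[r] <- run$best_val_pr_auc
    if (is.null(best) || run$best_val_pr_auc > best$best_val_pr_auc) {
      best <- run
    }
    if (control$verbose) {
      message(sprintf("restart %d/%d: val PR AUC %.4f", r,
                      control$n_restarts, run$best_val_pr_auc))
    }
  }
  fit <- structure(
    list(params = best$params, control = control,
         history = best$history, restart_pr_auc = restart_pr,
         best_val_pr_auc = best$best_val_pr_auc,
         fitted_scores = egnn_score(graphs, best$params),
         labels = y, n_train = length(graphs), n_val = length(val_graphs)),
    class = "loopflex")
  fit
}

loopflex_train_once <- function(graphs, y, val_graphs, yv, control, seed) {
  set.seed(seed)
  params <- egnn_init(n_node_features = ncol(graphs[[1]]$nodes),
                      n_edge_features = ncol(graphs[[1]]$edge_attr),
                      hidden_dim = control$hidden_dim,
                      n_layers = control$n_layers, seed = seed,
                      pooling = control$pooling)
  set.seed(seed + 10000L)
  state <- adam_init(params)
  n <- length(graphs)
  best_pr <- -Inf; best_params <- params; stale <- 0L
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        val_pr_auc = numeric(0))
  for (epoch in seq_len(control$max_epochs)) {
    ord <- sample.int(n)
    batches <- split(ord, ceiling(seq_along(ord) / control$batch_size))
    ep_loss <- 0
    for (bb in batches) {
      gs <- lapply(graphs[bb], drop_edges, p = control$edge_dropout)
      batch <- egnn_batch(gs)
      fwd <- egnn_forward(params, batch, keep_cache = TRUE)
      lo <- bce_loss(fwd$score, y[bb])
      grads <- egnn_backward(params, batch, fwd, lo$dz)
      st <- adam_step(params, grads, state, lr = control$learning_rate,
                      weight_decay = control$weight_decay)
      params <- st$params; state <- st$state
      ep_loss <- ep_loss + lo$loss * length(bb)
    }
    ep_loss <- ep_loss / n
    val_scores <- egnn_score(val_graphs, params)
    vpr <- pr_auc(yv, val_scores)
    history <- rbind(history,
                     data.frame(epoch = epoch, loss = ep_loss,
                                val_pr_auc = vpr))
    if (vpr > best_pr + 1e-6) {
      best_pr <- vpr; best_params <- params; stale <- 0L
    } else {
      stale <- stale + 1L
      if (stale >= control$patience) break
    }
    if (control$verbose) {
      message(sprintf("  epoch %d: loss %.4f, val PR AUC %.4f",
                      epoch, ep_loss, vpr))
    }
  }
  list(params = best_params, best_val_pr_auc = best_pr, history = history)
}

#' @export
print.loopflex <- function(x, ...) {
  cat("Loop-flexibility graph classifier\n")
  cat(sprintf("  %d equivariant layers, hidden dim %d\n",
              x$control$n_layers, x$control$hidden_dim))
  cat(sprintf("  trained on %d graphs (%d flexible), validated on %d\n",
              x$n_train, sum(x$labels == 1), x$n_val))
  cat(sprintf("  best validation PR AUC %.4f over %d restart(s)\n",
              x$best_val_pr_auc, x$control$n_restarts))
  invisible(x)
}

#' @export
summary.loopflex <- function(object, ...) {
  out <- list(
    control = object$control,
    n_train = object$n_train,
    n_val = object$n_val,
    base_rate = mean(object$labels),
    epochs_run = nrow(object$history),
    best_val_pr_auc = object$best_val_pr_auc,
    restart_pr_auc = object$restart_pr_auc,
    train_roc_auc = roc_auc(object$labels, object$fitted_scores))
  class(out) <- "summary.loopflex"
  out
}

#' @export
print.summary.loopflex <- function(x, ...) {
  cat("Loop-flexibility graph classifier\n")
  cat(sprintf("  training graphs: %d (flexible fraction %.3f)\n",
              x$n_train, x$base_rate))
  cat(sprintf("  epochs run (selected restart): %d\n", x$epochs_run))
  cat(sprintf("  validation PR AUC by restart: %s\n",
              paste(sprintf("%.3f", x$restart_pr_auc), collapse = ", ")))
  cat(sprintf("  best validation PR AUC: %.4f\n", x$best_val_pr_auc))
  cat(sprintf("  training ROC AUC (fitted): %.4f\n", x$train_roc_auc))
  invisible(x)
}

#' @export
coef.loopflex <- function(object, ...) object$params

#' Predict flexibility scores for new graphs
#'
#' @param object A fitted `loopflex` model.
#' @param newdata List of `ResidueGraph`s.
#' @param type `"score"` for probabilities, `"class"` for 0/1 calls at
#'   `threshold`.
#' @param threshold Classification threshold (default 0.5).
#' @param ... Unused.
#' @return Numeric vector of scores or integer class calls.
#' @export
predict.loopflex <- function(object, newdata, type = c("score", "class"),
                             threshold = 0.5, ...) {
  type <- match.arg(type)
  s <- egnn_score(newdata, object$params)
  if (type == "score") s else as.integer(s >= threshold)
}

#' @export
residuals.loopflex <- function(object, ...) {
  object$labels - object$fitted_scores
}

#' @export
fitted.loopflex <- function(object, ...) object$fitted_scores

#' @export
plot.loopflex <- function(x, ...) {
  h <- x$history
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(h$epoch, h$loss, type = "l", xlab = "epoch",
                 ylab = "training BCE loss", main = "Loss", ...)
  graphics::plot(h$epoch, h$val_pr_auc, type = "l", xlab = "epoch",
                 ylab = "validation PR AUC", main = "Validation PR AUC", ...)
  invisible(x)
}

#' Simulate labels from the fitted class probabilities
#'
#' @param object A fitted `loopflex` model.
#' @param nsim Number of simulated label vectors.
#' @param seed Optional RNG seed.
#' @param newdata Optional graphs to simulate for (default: training set
#'   fitted scores).
#' @param ... Unused.
#' @return data.frame with `nsim` columns of Bernoulli draws.
#' @export
simulate.loopflex <- function(object, nsim = 1, seed = NULL, newdata = NULL,
                              ...) {
  if (!is.null(seed)) set.seed(seed)
  p <- if (is.null(newdata)) object$fitted_scores
  else predict(object, newdata)
  out <- as.data.frame(replicate(nsim, stats::rbinom(length(p), 1L, p)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Per-structure prediction records
#'
#' Wraps [predict.loopflex()] into the record format used by evaluation:
#' one row per graph with its group key and structure id.
#'
#' @param graphs List of `ResidueGraph`s.
#' @param fit A fitted `loopflex` model (or an `egnn_params`).
#' @return data.frame with columns `group_key`, `structure_id`, `score`,
#'   `aggregated` (FALSE).
#' @export
predict_scores <- function(graphs, fit) {
  params <- if (inherits(fit, "loopflex")) fit$params else fit
  if (length(graphs) == 0L) {
    return(data.frame(group_key = character(0), structure_id = character(0),
                      score = numeric(0), aggregated = logical(0)))
  }
  s <- egnn_score(graphs, params)
  data.frame(
    group_key = vapply(graphs, function(g) {
      if (!is.null(g$meta$group_key)) g$meta$group_key
      else if (!is.null(g$meta$group_seq)) g$meta$group_seq
      else NA_character_
    }, ""),
    structure_id = vapply(graphs, function(g) {
      if (!is.null(g$meta$entry_id)) g$meta$entry_id else NA_character_
    }, ""),
    score = s, aggregated = FALSE, stringsAsFactors = FALSE)
}

#' Save / load fitted parameters as portable JSON
#'
#' @param fit A `loopflex` model or `egnn_params`.
#' @param path Checkpoint file.
#' @return `path` invisibly; `loopflex_load` returns an `egnn_params`.
#' @export
loopflex_save <- function(fit, path) {
  params <- if (inherits(fit, "loopflex")) fit$params else fit
  ser <- list(meta = params[c("hidden_dim", "n_layers", "n_node_features",
                              "n_edge_features", "pooling")],
              Wemb = params$Wemb, bemb = params$bemb,
              layers = params$layers, wout = params$wout, bout = params$bout)
  writeLines(jsonlite::toJSON(ser, digits = NA, auto_unbox = TRUE), path)
  invisible(path)
}

#' @rdname loopflex_save
#' @export
loopflex_load <- function(path) {
  ser <- jsonlite::fromJSON(paste(readLines(path, warn = FALSE),
                                  collapse = ""),
                            simplifyVector = TRUE,
                            simplifyDataFrame = FALSE,
                            simplifyMatrix = FALSE)
  d <- ser$meta$hidden_dim
  params <- egnn_init(ser$meta$n_node_features, ser$meta$n_edge_features,
                      d, ser$meta$n_layers, seed = 0L,
                      pooling = if (is.null(ser$meta$pooling)) "sum"
                      else ser$meta$pooling)
  # JSON stores matrices as row lists; rebuild against the template shapes
  fix <- function(v, tmpl) {
    if (is.matrix(tmpl)) {
      matrix(as.numeric(unlist(v)), nrow(tmpl), ncol(tmpl), byrow = TRUE)
    } else as.numeric(unlist(v))
  }
  params$Wemb <- fix(ser$Wemb, params$Wemb)
  params$bemb <- fix(ser$bemb, params$bemb)
  params$wout <- fix(ser$wout, params$wout)
  params$bout <- as.numeric(ser$bout)
  for (l in seq_len(ser$meta$n_layers)) {
    for (nm in names(params$layers[[l]])) {
      params$layers[[l]][[nm]] <- fix(ser$layers[[l]][[nm]],
                                      params$layers[[l]][[nm]])
    }
  }
  params
}
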