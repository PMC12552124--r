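# E(3)-invariant residue-graph network: message passing over squared CA
# distances with coordinate updates along relative-position vectors, mean
# pooling and a sigmoid readout. Forward, exact reverse-mode gradients and
# the Adam step are implemented directly on base-R matrices; graphs in a
# batch are concatenated as a disjoint union (no cross-graph edges).

silu <- function(z) z * stats::plogis(z)
silu_grad <- function(z) {
  s <- stats::plogis(z)
  s * (1 + z * (1 - s))
}

# squared-distance input scaling: keeps the message MLP input O(1) without
# touching E(3) invariance
D2_SCALE <- 100

#' Initialise EGNN parameters
#'
#' Glorot-normal weights for the message/update transforms, small weights
#' for the coordinate-scalar head, zero biases.
#'
#' @param n_node_features Node feature dimension (22).
#' @param n_edge_features Edge feature dimension (9).
#' @param hidden_dim Embedding width.
#' @param n_layers Number of equivariant layers.
#' @param seed RNG seed.
#' @param pooling Readout pooling over node embeddings: `"sum"` (default,
#'   size-aware) or `"mean"`.
#' @return List of class `egnn_params`.
#' @export
egnn_init <- function(n_node_features = 22L, n_edge_features = 9L,
                      hidden_dim = 128L, n_layers = 3L, seed = 1L,
                      pooling = c("sum", "mean")) {
  pooling <- match.arg(pooling)
  stopifnot(n_layers >= 1L, hidden_dim >= 1L)
  rng <- local({ set.seed(seed); NULL })
  glorot <- function(fi, fo) {
    matrix(stats::rnorm(fi * fo, sd = sqrt(2 / (fi + fo))), fi, fo)
  }
  d <- hidden_dim
  msg_in <- 2L * d + 1L + n_edge_features
  layers <- lapply(seq_len(n_layers), function(l) {
    list(W1 = glorot(msg_in, d), b1 = numeric(d),
         W2 = glorot(d, d), b2 = numeric(d),
         Wx = matrix(stats::rnorm(d, sd = 1e-2), d, 1), bx = 0,
         V1 = glorot(2L * d, d), c1 = numeric(d),
         V2 = glorot(d, d), c2 = numeric(d))
  })
  # small readout init: sum pooling over tens of nodes would otherwise
  # saturate the sigmoid at initialisation
  structure(list(Wemb = glorot(n_node_features, d), bemb = numeric(d),
                 layers = layers,
                 wout = matrix(stats::rnorm(d, sd = 0.01 / sqrt(d)), d, 1L),
                 bout = 0,
                 hidden_dim = d, n_layers = n_layers,
                 n_node_features = n_node_features,
                 n_edge_features = n_edge_features,
                 pooling = pooling),
            class = "egnn_params")
}

#' Concatenate graphs into one disjoint-union batch
#'
#' @param graphs List of `ResidueGraph`s.
#' @return List with stacked `nodes`, `coords`, `edges`, `edge_attr`, the
#'   graph index `gid` of every node, per-graph node counts `ng` and the
#'   label vector `y` (NA where unlabelled).
#' @export
egnn_batch <- function(graphs) {
  stopifnot(length(graphs) > 0L)
  sizes <- vapply(graphs, function(g) nrow(g$nodes), 1L)
  offs <- cumsum(c(0L, sizes[-length(sizes)]))
  nodes <- do.call(rbind, lapply(graphs, `[[`, "nodes"))
  coords <- do.call(rbind, lapply(graphs, `[[`, "coords"))
  edges <- do.call(rbind, Map(function(g, o) {
    if (nrow(g$edges) == 0L) matrix(integer(0), 0, 2) else g$edges + o
  }, graphs, offs))
  edge_attr <- do.call(rbind, lapply(graphs, `[[`, "edge_attr"))
  y <- vapply(graphs, function(g) {
    if (is.null(g$label)) NA_real_ else as.numeric(g$label)
  }, 0)
  list(nodes = nodes, coords = coords, edges = edges, edge_attr = edge_attr,
       gid = rep(seq_along(graphs), sizes), ng = as.numeric(sizes), y = y)
}

# scatter-add rows of m into an n-row accumulator by integer index
scatter_rows <- function(m, idx, n) {
  out <- matrix(0, n, ncol(m))
  if (length(idx) > 0L) {
    r <- rowsum(m, idx)
    out[as.integer(rownames(r)), ] <- r
  }
  out
}

#' EGNN forward pass
#'
#' @param params An `egnn_params`.
#' @param batch A batch from [egnn_batch()].
#' @param keep_cache Keep intermediate activations for [egnn_backward()].
#' @return List with `score` (per-graph, in (0,1)), `logit`, and `cache`
#'   when requested.
#' @export
egnn_forward <- function(params, batch, keep_cache = FALSE) {
  d <- params$hidden_dim
  N <- nrow(batch$nodes)
  E <- batch$edges
  M <- nrow(E)
  H <- batch$nodes %*% params$Wemb +
    matrix(params$bemb, N, d, byrow = TRUE)
  X <- batch$coords
  i <- E[, 1]; j <- E[, 2]
  deg <- rep(1, N)
  if (M > 0L) {
    tb <- table(i)
    deg[as.integer(names(tb))] <- as.numeric(tb)
  }
  caches <- vector("list", params$n_layers)
  for (l in seq_len(params$n_layers)) {
    p <- params$layers[[l]]
    if (M > 0L) {
      R <- X[i, , drop = FALSE] - X[j, , drop = FALSE]
      d2s <- rowSums(R^2) / D2_SCALE
      A <- cbind(H[i, , drop = FALSE], H[j, , drop = FALSE], d2s,
                 batch$edge_attr)
      Z1 <- A %*% p$W1 + matrix(p$b1, M, d, byrow = TRUE)
      S1 <- silu(Z1)
      Z2 <- S1 %*% p$W2 + matrix(p$b2, M, d, byrow = TRUE)
      Mm <- silu(Z2)
      q <- Mm %*% p$Wx + p$bx
      w <- tanh(q)
      Xn <- X + scatter_rows(R * as.numeric(w), i, N) / deg
      agg <- scatter_rows(Mm, i, N)
    } else {
      R <- matrix(0, 0, 3); d2s <- numeric(0)
      A <- matrix(0, 0, 2L * d + 1L + params$n_edge_features)
      Z1 <- S1 <- Z2 <- Mm <- matrix(0, 0, d)
      q <- w <- matrix(0, 0, 1)
      Xn <- X
      agg <- matrix(0, N, d)
    }
    B <- cbind(H, agg)
    U1 <- B %*% p$V1 + matrix(p$c1, N, d, byrow = TRUE)
    T1 <- silu(U1)
    U2 <- T1 %*% p$V2 + matrix(p$c2, N, d, byrow = TRUE)
    Hn <- H + U2
    if (keep_cache) {
      caches[[l]] <- list(H = H, X = X, R = R, A = A, Z1 = Z1, S1 = S1,
                          Z2 = Z2, Mm = Mm, q = q, w = w, B = B, U1 = U1,
                          T1 = T1)
    }
    H <- Hn; X <- Xn
  }
  G <- length(batch$ng)
  P <- scatter_rows(H, batch$gid, G)
  if (identical(params$pooling, "mean")) P <- P / batch$ng
  z <- as.numeric(P %*% params$wout + params$bout)
  score <- stats::plogis(z)
  out <- list(score = score, logit = z)
  if (keep_cache) {
    out$cache <- list(layers = caches, H_final = H, P = P,
                      i = i, j = j, deg = deg)
  }
  out
}

#' EGNN reverse-mode gradients
#'
#' Exact gradients of `sum_g dz_g * logit_g` with respect to every
#' parameter; with `dz = (score - y) / G` this is the gradient of the mean
#' binary cross-entropy.
#'
#' @param params An `egnn_params`.
#' @param batch The batch the cache was computed on.
#' @param fwd Output of `egnn_forward(..., keep_cache = TRUE)`.
#' @param dz Per-graph gradient of the loss with respect to the logit.
#' @return List mirroring the parameter structure.
#' @export
egnn_backward <- function(params, batch, fwd, dz) {
  cache <- fwd$cache
  d <- params$hidden_dim
  N <- nrow(batch$nodes)
  M <- nrow(batch$edges)
  i <- cache$i; j <- cache$j; deg <- cache$deg
  G <- length(batch$ng)
  grads <- list(layers = vector("list", params$n_layers))

  dzm <- matrix(dz, G, 1)
  grads$wout <- crossprod(cache$P, dzm)
  grads$bout <- sum(dz)
  dP <- dzm %*% t(params$wout)                 # G x d
  dH <- dP[batch$gid, , drop = FALSE]
  if (identical(params$pooling, "mean")) {
    dH <- dH / batch$ng[batch$gid]
  }
  dX <- matrix(0, N, 3)

  for (l in rev(seq_len(params$n_layers))) {
    p <- params$layers[[l]]
    cc <- cache$layers[[l]]
    # node update
    dU2 <- dH
    dT1 <- dU2 %*% t(p$V2)
    gV2 <- crossprod(cc$T1, dU2); gc2 <- colSums(dU2)
    dU1 <- dT1 * silu_grad(cc$U1)
    gV1 <- crossprod(cc$B, dU1); gc1 <- colSums(dU1)
    dB <- dU1 %*% t(p$V1)
    dH_in <- dH + dB[, seq_len(d), drop = FALSE]
    dagg <- dB[, d + seq_len(d), drop = FALSE]
    if (M > 0L) {
      dM <- dagg[i, , drop = FALSE]
      # coordinate update
      dX_in <- dX
      dCW <- dX[i, , drop = FALSE] / deg[i]
      dw <- rowSums(cc$R * dCW)
      dR <- dCW * as.numeric(cc$w)
      dq <- matrix(dw * (1 - as.numeric(cc$w)^2), M, 1)
      gWx <- crossprod(cc$Mm, dq); gbx <- sum(dq)
      dM <- dM + dq %*% t(p$Wx)
      # message MLP
      dZ2 <- dM * silu_grad(cc$Z2)
      gW2 <- crossprod(cc$S1, dZ2); gb2 <- colSums(dZ2)
      dS1 <- dZ2 %*% t(p$W2)
      dZ1 <- dS1 * silu_grad(cc$Z1)
      gW1 <- crossprod(cc$A, dZ1); gb1 <- colSums(dZ1)
      dA <- dZ1 %*% t(p$W1)
      dH_in <- dH_in + scatter_rows(dA[, seq_len(d), drop = FALSE], i, N) +
        scatter_rows(dA[, d + seq_len(d), drop = FALSE], j, N)
      dd2 <- dA[, 2L * d + 1L] / D2_SCALE
      dR <- dR + 2 * cc$R * dd2
      dX_in <- dX_in + scatter_rows(dR, i, N) - scatter_rows(dR, j, N)
    } else {
      dX_in <- dX
      gWx <- matrix(0, d, 1); gbx <- 0
      gW1 <- matrix(0, nrow(p$W1), d); gb1 <- numeric(d)
      gW2 <- matrix(0, d, d); gb2 <- numeric(d)
    }
    grads$layers[[l]] <- list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2,
                              Wx = gWx, bx = gbx, V1 = gV1, c1 = gc1,
                              V2 = gV2, c2 = gc2)
    dH <- dH_in
    dX <- dX_in
  }
  grads$Wemb <- crossprod(batch$nodes, dH)
  grads$bemb <- colSums(dH)
  grads
}

#' Mean binary cross-entropy and its logit gradient
#'
#' @param score Predicted probabilities.
#' @param y Binary labels.
#' @return List with `loss` and `dz` (gradient w.r.t. logits).
#' @export
bce_loss <- function(score, y) {
  eps <- 1e-12
  loss <- -mean(y * log(score + eps) + (1 - y) * log(1 - score + eps))
  list(loss = loss, dz = (score - y) / length(y))
}

# flatten/apply helpers shared by Adam and the finite-difference tests
egnn_param_paths <- function(params) {
  paths <- list(list("Wemb"), list("bemb"), list("wout"), list("bout"))
  for (l in seq_len(params$n_layers)) {
    for (nm in c("W1", "b1", "W2", "b2", "Wx", "bx", "V1", "c1", "V2", "c2")) {
      paths[[length(paths) + 1L]] <- list("layers", l, nm)
    }
  }
  paths
}

egnn_get <- function(params, path) {
  for (p in path) params <- params[[p]]
  params
}

egnn_set <- function(params, path, value) {
  if (length(path) == 1L) {
    params[[path[[1]]]] <- value
  } else {
    params[[path[[1]]]][[path[[2]]]][[path[[3]]]] <- value
  }
  params
}

# One Adam step over all parameters (weight decay as an L2 gradient term).
adam_step <- function(params, grads, state, lr, weight_decay,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  for (k in seq_along(state$paths)) {
    path <- state$paths[[k]]
    g <- egnn_get(grads, path) + weight_decay * egnn_get(params, path)
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * g
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * g^2
    mhat <- state$m[[k]] / (1 - beta1^t)
    vhat <- state$v[[k]] / (1 - beta2^t)
    params <- egnn_set(params, path,
                       egnn_get(params, path) - lr * mhat / (sqrt(vhat) + eps))
  }
  list(params = params, state = state)
}

adam_init <- function(params) {
  paths <- egnn_param_paths(params)
  zero <- lapply(paths, function(p) egnn_get(params, p) * 0)
  list(t = 0L, paths = paths, m = zero, v = zero)
}

# Independent edge dropout: each undirected edge kept with prob 1 - p; both
# directions of a dropped edge are removed.
drop_edges <- function(graph, p) {
  if (p <= 0 || nrow(graph$edges) == 0L) return(graph)
  m2 <- nrow(graph$edges)
  half <- m2 %/% 2L                   # edges are stored (i,j) block then (j,i)
  keep <- stats::runif(half) >= p
  sel <- c(which(keep), half + which(keep))
  graph$edges <- graph$edges[sel, , drop = FALSE]
  graph$edge_attr <- graph$edge_attr[sel, , drop = FALSE]
  graph
}

#' Score graphs with fitted EGNN parameters
#'
#' Deterministic forward pass (no dropout), one score per graph.
#'
#' @param graphs List of `ResidueGraph`s.
#' @param params An `egnn_params`.
#' @param batch_size Graphs per forward pass.
#' @return Numeric vector of scores in (0,1).
#' @export
egnn_score <- function(graphs, params, batch_size = 64L) {
  if (length(graphs) == 0L) return(numeric(0))
  idx <- split(seq_along(graphs),
               ceiling(seq_along(graphs) / batch_size))
  unlist(lapply(idx, function(ii) {
    egnn_forward(params, egnn_batch(graphs[ii]))$score
  }), use.names = FALSE)
}
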