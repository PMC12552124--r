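# Residue-graph construction: loop + structural context -> node features,
# CA coordinates, edge list and edge features for the classifier.

#' Graph construction configuration
#'
#' @param context_radius Context inclusion radius in Angstrom: residues whose
#'   CA lies within this distance of any loop CA become context nodes
#'   (default 10).
#' @param edge_cutoff CA-CA distance threshold for edges in Angstrom
#'   (default 10).
#' @param n_rbf Number of Gaussian radial basis functions encoding edge
#'   distance (default 8).
#' @param rbf_min,rbf_max Range over which RBF centers are equally spaced,
#'   endpoints included (defaults 0 and 10 Angstrom).
#' @param rbf_sigma RBF width in Angstrom; defaults to the center spacing
#'   `(rbf_max - rbf_min) / (n_rbf - 1)`.
#' @param chain_scope `"same_chain"` (mined PDB loops) or `"both_chains"`
#'   (antibody/TCR Fvs, context drawn from all chains present).
#' @param loop_only Ablation switch: use only the loop residues, no context.
#' @return A `graph_config` list.
#' @export
graph_config <- function(context_radius = 10, edge_cutoff = 10,
                         n_rbf = 8L, rbf_min = 0, rbf_max = 10,
                         rbf_sigma = NULL,
                         chain_scope = c("same_chain", "both_chains"),
                         loop_only = FALSE) {
  chain_scope <- match.arg(chain_scope)
  stopifnot(n_rbf >= 1L, rbf_max > rbf_min, context_radius > 0,
            edge_cutoff > 0)
  if (is.null(rbf_sigma)) {
    rbf_sigma <- (rbf_max - rbf_min) / max(n_rbf - 1L, 1L)
  }
  stopifnot(rbf_sigma > 0)
  structure(list(context_radius = context_radius, edge_cutoff = edge_cutoff,
                 n_rbf = as.integer(n_rbf), rbf_min = rbf_min,
                 rbf_max = rbf_max, rbf_sigma = rbf_sigma,
                 chain_scope = chain_scope, loop_only = isTRUE(loop_only)),
            class = "graph_config")
}

#' Select the residues forming a loop's structural context
#'
#' Returns the loop residues plus every residue whose CA lies within
#' `context_radius` of any loop CA, restricted to the loop's own chain
#' (`same_chain`) or drawn from all chains (`both_chains`). In `loop_only`
#' mode only the loop residues are returned.
#'
#' @param s A `StructureModel`.
#' @param loop A `LoopMotif` resolvable in `s`.
#' @param cfg A [graph_config()].
#' @return data.frame of selected residues (residue-table columns plus
#'   logical `in_loop`), in chain order.
#' @export
select_context <- function(s, loop, cfg = graph_config()) {
  rt <- residue_table(s)
  loop_idx <- match(loop$residues$key, rt$key)
  if (any(is.na(loop_idx))) {
    stop("loop residue(s) not present in the structure: ",
         paste(loop$residues$key[is.na(loop_idx)], collapse = ", "))
  }
  rt$in_loop <- seq_len(nrow(rt)) %in% loop_idx
  if (cfg$loop_only) {
    out <- rt[sort(loop_idx), , drop = FALSE]
    rownames(out) <- NULL
    return(out)
  }
  cand <- if (cfg$chain_scope == "same_chain") {
    which(rt$chain == loop$chain)
  } else seq_len(nrow(rt))
  ca <- ca_coords(s, rt$key)
  loop_ca <- ca[loop_idx, , drop = FALSE]
  keep <- vapply(cand, function(i) {
    if (rt$in_loop[i]) return(TRUE)
    if (!is.finite(ca[i, 1])) return(FALSE)
    d2 <- rowSums(sweep(loop_ca, 2, ca[i, ])^2)
    min(d2) <= cfg$context_radius^2
  }, TRUE)
  out <- rt[sort(cand[keep]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Node feature matrix
#'
#' One row per residue: positions 1..20 one-hot amino-acid type (order
#' `AA_STANDARD`), position 21 the unknown class, position 22 the
#' loop-membership indicator. Rows therefore sum to 1 for context residues
#' and 2 for loop residues.
#'
#' @param one_letter Character vector of 1-letter residue codes.
#' @param loop_mask Logical vector flagging loop residues.
#' @return n x 22 numeric matrix.
#' @export
node_features <- function(one_letter, loop_mask) {
  stopifnot(length(one_letter) == length(loop_mask))
  n <- length(one_letter)
  X <- matrix(0, n, 22L)
  X[cbind(seq_len(n), aa_slot(one_letter))] <- 1
  X[, 22L] <- as.numeric(loop_mask)
  X
}

#' Gaussian radial-basis encoding of a distance
#'
#' `exp(-(d - mu_k)^2 / (2 sigma^2))` with `n_rbf` centers `mu_k` equally
#' spaced over `[rbf_min, rbf_max]`, endpoints included.
#'
#' @param d Numeric vector of distances (Angstrom).
#' @param cfg A [graph_config()].
#' @return length(d) x n_rbf matrix.
#' @export
rbf_encode <- function(d, cfg = graph_config()) {
  mu <- seq(cfg$rbf_min, cfg$rbf_max, length.out = cfg$n_rbf)
  exp(-outer(d, mu, `-`)^2 / (2 * cfg$rbf_sigma^2))
}

#' Edge feature vector(s)
#'
#' Element 1 is the covalent-bond indicator (sequence-adjacent residues of
#' the same chain with no numbering gap); elements 2..(1+n_rbf) the Gaussian
#' RBF encoding of the CA distance.
#'
#' @param d Distances (Angstrom).
#' @param covalent Logical vector.
#' @param cfg A [graph_config()].
#' @return length(d) x (1 + n_rbf) matrix.
#' @export
edge_features <- function(d, covalent, cfg = graph_config()) {
  cbind(as.numeric(covalent), rbf_encode(d, cfg))
}

#' Build the residue graph for a loop
#'
#' Composes context selection, node featurization, distance-threshold edge
#' construction (directed both ways, no self loops) and edge featurization.
#' Everything downstream of the coordinates depends only on pairwise
#' distances and sequence, so the graph is invariant under rigid motions and
#' reflections of the structure.
#'
#' @param s A `StructureModel`.
#' @param loop A `LoopMotif`.
#' @param cfg A [graph_config()].
#' @param label Optional binary label (0/1) to attach.
#' @return List of class `ResidueGraph`: `nodes` (n x 22), `coords` (n x 3),
#'   `edges` (m x 2 integer, receiver then sender), `edge_attr`
#'   (m x (1+n_rbf)), `loop_mask`, `residue_keys`, `label`, `meta`.
#' @export
build_graph <- function(s, loop, cfg = graph_config(), label = NULL) {
  sel <- select_context(s, loop, cfg)
  ca <- ca_coords(s, sel$key)
  if (any(!is.finite(ca))) {
    stop("selected context contains residues without CA coordinates")
  }
  residue_graph(one_letter = sel$one, coords = ca, loop_mask = sel$in_loop,
                chain = sel$chain, resno = sel$resno, cfg = cfg,
                label = label,
                meta = list(entry_id = s$entry_id, origin = loop$origin,
                            group_seq = loop$sequence))
}

#' Assemble a ResidueGraph from residue-level vectors
#'
#' Lower-level constructor used by [build_graph()] and the synthetic dataset
#' generator.
#'
#' @param one_letter 1-letter residue codes.
#' @param coords n x 3 CA coordinates.
#' @param loop_mask Logical loop-membership flags.
#' @param chain,resno Chain ids and residue numbers (drive the covalent-bond
#'   indicator; consecutive numbering on one chain marks a bond).
#' @param cfg A [graph_config()].
#' @param label Optional 0/1 label.
#' @param meta Optional metadata list.
#' @return A `ResidueGraph`.
#' @export
residue_graph <- function(one_letter, coords, loop_mask,
                          chain = rep("A", length(one_letter)),
                          resno = seq_along(one_letter),
                          cfg = graph_config(), label = NULL, meta = list()) {
  n <- length(one_letter)
  coords <- unname(as.matrix(coords))
  stopifnot(nrow(coords) == n, length(loop_mask) == n)
  nodes <- node_features(one_letter, loop_mask)
  if (n >= 2L) {
    D <- as.matrix(stats::dist(coords))
    adj <- which(D <= cfg$edge_cutoff & upper.tri(D), arr.ind = TRUE)
  } else {
    adj <- matrix(integer(0), 0, 2)
  }
  if (nrow(adj) > 0L) {
    i <- adj[, 1]; j <- adj[, 2]
    cov <- chain[i] == chain[j] & abs(resno[i] - resno[j]) == 1L
    d <- sqrt(rowSums((coords[i, , drop = FALSE] -
                         coords[j, , drop = FALSE])^2))
    edges <- rbind(cbind(i, j), cbind(j, i))
    eattr <- rbind(edge_features(d, cov, cfg), edge_features(d, cov, cfg))
  } else {
    edges <- matrix(integer(0), 0, 2)
    eattr <- matrix(numeric(0), 0, 1L + cfg$n_rbf)
  }
  structure(list(nodes = nodes, coords = coords,
                 edges = unname(edges), edge_attr = unname(eattr),
                 loop_mask = as.logical(loop_mask),
                 residue_keys = res_key(chain, resno, ""),
                 label = label, meta = meta),
            class = "ResidueGraph")
}

#' @export
print.ResidueGraph <- function(x, ...) {
  cat(sprintf("ResidueGraph: %d nodes (%d loop), %d directed edges%s\n",
              nrow(x$nodes), sum(x$loop_mask), nrow(x$edges),
              if (!is.null(x$label)) sprintf(", label %d", x$label) else ""))
  invisible(x)
}

#' Biophysical summary features of a loop
#'
#' The two baseline inputs: loop length, and solvent exposure approximated
#' by the number of non-loop residues with CA within `radius` of any loop CA.
#'
#' @param s A `StructureModel`.
#' @param loop A `LoopMotif`.
#' @param radius Exposure radius in Angstrom (default 10).
#' @param chain_scope Passed to [select_context()].
#' @return Named numeric vector `c(length = ..., exposure = ...)`.
#' @export
biophysical_features <- function(s, loop, radius = 10,
                                 chain_scope = c("same_chain", "both_chains")) {
  cfg <- graph_config(context_radius = radius,
                      chain_scope = match.arg(chain_scope))
  sel <- select_context(s, loop, cfg)
  c(length = loop$loop_length, exposure = sum(!sel$in_loop))
}
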