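# Conformational-flexibility labelling: grouping of identical loops,
# superposed CA RMSDs, complete-linkage clustering at 1.25 A and the
# flexible/rigid/unknown decision rule.

#' Least-squares rigid superposition (Kabsch algorithm)
#'
#' Finds the proper rotation `R` and translation `t` minimising
#' `sum || R a_i + t - b_i ||^2` over corresponding points, via SVD of the
#' cross-covariance with a determinant correction that excludes reflections,
#' and returns the minimised RMSD.
#'
#' @param A,B n x 3 coordinate matrices with corresponding rows, n >= 3.
#' @return List with `rotation` (3 x 3), `translation` (length 3; the fit is
#'   `A %*% t(rotation) + translation`) and `rmsd` in Angstrom.
#' @export
superpose_kabsch <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (!all(dim(A) == dim(B))) stop("coordinate sets differ in shape")
  if (nrow(A) < 3L) stop("need at least 3 points for a rigid superposition")
  if (ncol(A) != 3L) stop("coordinates must be n x 3")
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2, ca); B0 <- sweep(B, 2, cb)
  H <- crossprod(A0, B0)              # 3x3 cross-covariance
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  fit <- A0 %*% t(R)
  rmsd <- sqrt(mean(rowSums((fit - B0)^2)))
  list(rotation = R, translation = as.numeric(cb - ca %*% t(R)), rmsd = rmsd)
}

#' Group loop motifs considered identical
#'
#' In `loop_sequence` mode loops are the same when their amino-acid sequence
#' matches exactly (case-sensitive, including `X`); in `fv_sequence` mode
#' (antibodies/TCRs) the entire Fv sequence must match, so identical CDR3s on
#' different frameworks form different groups.
#'
#' @param motifs List of `LoopMotif`s.
#' @param mode `"loop_sequence"` or `"fv_sequence"`.
#' @return List of `LoopGroup` objects: `group_key`, `members` (the motifs),
#'   `distinct_entry_ids`.
#' @export
group_motifs <- function(motifs, mode = c("loop_sequence", "fv_sequence")) {
  mode <- match.arg(mode)
  if (length(motifs) == 0L) return(list())
  keys <- vapply(motifs, function(m) {
    if (mode == "loop_sequence") return(m$sequence)
    if (is.null(m$fv_sequence)) {
      stop("fv_sequence grouping requested but motif from entry '",
           m$entry_id, "' has no Fv sequence attached", call. = FALSE)
    }
    m$fv_sequence
  }, "")
  split_idx <- split(seq_along(motifs), factor(keys, levels = unique(keys)))
  lapply(split_idx, function(idx) {
    members <- motifs[idx]
    structure(
      list(group_key = keys[idx[1]],
           members = members,
           distinct_entry_ids = unique(vapply(members, `[[`, "", "entry_id"))),
      class = "LoopGroup")
  })
}

#' @export
print.LoopGroup <- function(x, ...) {
  cat(sprintf("LoopGroup [%s]: %d member(s), %d distinct entries\n",
              x$group_key, length(x$members), length(x$distinct_entry_ids)))
  invisible(x)
}

#' Pairwise superposed CA RMSD matrix of a loop group
#'
#' Entry (i, j) is the loop-CA RMSD of members i and j after least-squares
#' superposition. The default aligns on the loop CAs themselves; the
#' `framework` variant aligns on the anchor-region CAs (when coordinates for
#' them are attached to the motifs as `$anchor_ca`) and measures RMSD on the
#' unfitted loop CAs.
#'
#' @param group A `LoopGroup`.
#' @param mode `"loop"` or `"framework"`.
#' @return Symmetric matrix of RMSDs (Angstrom) with zero diagonal.
#' @export
rmsd_matrix <- function(group, mode = c("loop", "framework")) {
  mode <- match.arg(mode)
  members <- group$members
  n <- length(members)
  D <- matrix(0, n, n)
  if (n < 2L) return(D)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    a <- members[[i]]; b <- members[[j]]
    if (mode == "loop") {
      r <- superpose_kabsch(a$ca, b$ca)$rmsd
    } else {
      if (is.null(a$anchor_ca) || is.null(b$anchor_ca)) {
        stop("framework mode needs anchor_ca coordinates on every member")
      }
      fit <- superpose_kabsch(a$anchor_ca, b$anchor_ca)
      moved <- a$ca %*% t(fit$rotation) +
        matrix(fit$translation, nrow(a$ca), 3, byrow = TRUE)
      r <- sqrt(mean(rowSums((moved - b$ca)^2)))
    }
    D[i, j] <- r; D[j, i] <- r
  }
  D
}

#' Complete-linkage conformational clustering
#'
#' Agglomerative clustering with complete linkage cut at threshold `tau`:
#' merging continues while the smallest complete-linkage distance between
#' clusters is `<= tau`, so every produced cluster has maximum intra-cluster
#' pairwise RMSD `<= tau`. Ties at equal merge distance are broken towards
#' the lexicographically smallest pair of cluster indices, making the result
#' platform-independent.
#'
#' @param D Symmetric distance matrix with zero diagonal.
#' @param tau Distance threshold in Angstrom (default 1.25).
#' @return List of class `ConformationClustering` with `assignment` (integer
#'   cluster id per member, numbered by first appearance), `n_clusters`,
#'   `linkage = "complete"` and `threshold`.
#' @export
cluster_conformations <- function(D, tau = 1.25) {
  D <- as.matrix(D)
  n <- nrow(D)
  stopifnot(n == ncol(D), all(abs(diag(D)) < 1e-12),
            isTRUE(all.equal(D, t(D), tolerance = 1e-8)))
  clusters <- as.list(seq_len(n))
  if (n >= 2L) {
    repeat {
      k <- length(clusters)
      if (k == 1L) break
      best <- NULL; best_d <- Inf
      for (a in seq_len(k - 1L)) for (b in (a + 1L):k) {
        d_ab <- max(D[clusters[[a]], clusters[[b]]])
        if (d_ab < best_d - 1e-12) { best_d <- d_ab; best <- c(a, b) }
      }
      if (best_d > tau) break        # strict: merges above tau are refused
      clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
      clusters[[best[2]]] <- NULL
    }
  }
  assignment <- integer(n)
  for (ci in seq_along(clusters)) assignment[clusters[[ci]]] <- ci
  # renumber by first appearance for determinism
  assignment <- as.integer(factor(assignment, levels = unique(assignment)))
  structure(list(assignment = assignment,
                 n_clusters = max(assignment, 0L),
                 linkage = "complete",
                 threshold = tau),
            class = "ConformationClustering")
}

#' Labelling criteria for loop flexibility
#'
#' @param tau RMSD clustering threshold in Angstrom (default 1.25).
#' @param min_rigid_entries Minimum number of distinct entries required to
#'   call a single-conformation loop rigid (default 5).
#' @param alignment_mode `"loop"` (default) or `"framework"`, passed to
#'   [rmsd_matrix()].
#' @return A `label_criteria` list.
#' @export
label_criteria <- function(tau = 1.25, min_rigid_entries = 5L,
                           alignment_mode = c("loop", "framework")) {
  stopifnot(tau > 0, min_rigid_entries >= 1L)
  structure(list(tau = tau, min_rigid_entries = as.integer(min_rigid_entries),
                 alignment_mode = match.arg(alignment_mode)),
            class = "label_criteria")
}

#' Assign a flexibility label to a clustered loop group
#'
#' `flexible` when at least two conformational clusters are observed;
#' `rigid` when a single conformation is evidenced by at least
#' `min_rigid_entries` distinct entries (separate PDB files, not separate
#' chains or altloc states); `unknown` otherwise.
#'
#' @param clustering A `ConformationClustering` for `group`.
#' @param group The `LoopGroup`.
#' @param criteria A [label_criteria()].
#' @return List of class `FlexLabel`: `label`, `n_conformations`,
#'   `n_distinct_entries`.
#' @export
assign_label <- function(clustering, group, criteria = label_criteria()) {
  n_conf <- clustering$n_clusters
  n_entries <- length(group$distinct_entry_ids)
  label <- if (n_conf >= 2L) "flexible"
  else if (n_conf == 1L && n_entries >= criteria$min_rigid_entries) "rigid"
  else "unknown"
  structure(list(label = label, n_conformations = n_conf,
                 n_distinct_entries = n_entries),
            class = "FlexLabel")
}

#' Label a set of loop groups
#'
#' Runs [rmsd_matrix()], [cluster_conformations()] and [assign_label()] on
#' each group and tabulates the result.
#'
#' @param groups List of `LoopGroup`s.
#' @param criteria A [label_criteria()].
#' @return data.frame with one row per group: `group_key`, `origin`,
#'   `loop_length`, `n_members`, `n_distinct_entries`, `n_conformations`,
#'   `label`.
#' @export
label_groups <- function(groups, criteria = label_criteria()) {
  rows <- lapply(groups, function(g) {
    D <- rmsd_matrix(g, mode = criteria$alignment_mode)
    cl <- cluster_conformations(D, tau = criteria$tau)
    lab <- assign_label(cl, g, criteria)
    data.frame(group_key = g$group_key,
               origin = g$members[[1]]$origin,
               loop_length = g$members[[1]]$loop_length,
               n_members = length(g$members),
               n_distinct_entries = lab$n_distinct_entries,
               n_conformations = lab$n_conformations,
               label = lab$label,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
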