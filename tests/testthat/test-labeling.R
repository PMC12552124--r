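motif_from_coords <- function(ca, sequence = NULL, entry_id = "E1") {
  n <- nrow(ca)
  if (is.null(sequence)) sequence <- paste(rep("A", n), collapse = "")
  res <- data.frame(chain = "A", resno = seq_len(n), insert = "",
                    resid = "ALA", stringsAsFactors = FALSE)
  res$one <- strsplit(sequence, "")[[1]]
  res$key <- loopflex:::res_key(res$chain, res$resno, res$insert)
  loop_motif(res, ca, entry_id = entry_id)
}

test_that("Kabsch superposition recovers exact and rigid-motion matches", {
  set.seed(1)
  A <- matrix(rnorm(15, sd = 3), 5, 3)
  expect_equal(superpose_kabsch(A, A)$rmsd, 0, tolerance = 1e-12)
  rigid <- random_rigid()
  B <- apply_rigid(A, rigid)
  fit <- superpose_kabsch(A, B)
  expect_lt(fit$rmsd, 1e-9)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)  # proper rotation
  # returned transform actually maps A onto B
  moved <- A %*% t(fit$rotation) +
    matrix(fit$translation, nrow(A), 3, byrow = TRUE)
  expect_equal(moved, B, tolerance = 1e-9)
})

test_that("superposition matches a dense rotation-grid oracle on toy sets", {
  set.seed(7)
  for (rep in 1:2) {
    A <- matrix(rnorm(12, sd = 2), 4, 3)
    B <- matrix(rnorm(12, sd = 2), 4, 3)
    ours <- superpose_kabsch(A, B)$rmsd
    oracle <- grid_rmsd_oracle(A, B, n_angle = 36)
    expect_lte(ours, oracle + 1e-9)          # least-squares optimum
    expect_equal(ours, oracle, tolerance = 1e-1 * oracle + 1e-3)
  }
})

test_that("degenerate superposition inputs raise errors", {
  A <- matrix(rnorm(9), 3, 3)
  expect_error(superpose_kabsch(A, A[1:2, ]), "shape")
  expect_error(superpose_kabsch(A[1:2, ], A[1:2, ]), "3 points")
})

test_that("motifs group by exact loop sequence or full Fv sequence", {
  ca <- matrix(rnorm(18), 6, 3)
  m1 <- motif_from_coords(ca, "GDSSGY", "E1")
  m2 <- motif_from_coords(ca, "GDSSGY", "E2")
  m3 <- motif_from_coords(ca, "GGSSGY", "E3")
  gs <- group_motifs(list(m1, m2, m3))
  expect_length(gs, 2L)
  expect_equal(sort(unname(vapply(gs, function(g) length(g$members), 1L))),
               c(1L, 2L))
  expect_equal(gs[[1]]$distinct_entry_ids, c("E1", "E2"))

  # identical CDR3 on two different Fvs: separate groups in fv mode
  m1$fv_sequence <- "QVQLGDSSGYWGQG"
  m2$fv_sequence <- "EVQLGDSSGYWGQG"
  expect_length(group_motifs(list(m1, m2), mode = "fv_sequence"), 2L)
  expect_length(group_motifs(list(m1, m2), mode = "loop_sequence"), 1L)
  m2$fv_sequence <- NULL
  expect_error(group_motifs(list(m1, m2), mode = "fv_sequence"), "Fv")
  expect_length(group_motifs(list()), 0L)
})

test_that("the RMSD matrix reproduces planted pairwise deviations", {
  pg <- generate_loop_group(n_entries = 3, n_conformations = 3,
                            rmsd_target = 3, jitter = 0, seed = 5)
  motifs <- unlist(lapply(pg$fixtures, function(f)
    mine_loops(f$structure, ann = f$ss)), recursive = FALSE)
  g <- group_motifs(motifs)[[1]]
  D <- rmsd_matrix(g)
  expect_equal(D, t(D))
  expect_equal(diag(D), rep(0, 3))
  off <- D[upper.tri(D)]
  # planted separation within 20% of the 3 A target for the direct pairs,
  # and at least 80% of it between any two conformations
  expect_true(all(off >= 0.8 * 3 - 0.05))
  expect_true(any(abs(off - 3) <= 0.2 * 3 + 0.05))
  # group of 1 and identical-up-to-rigid-motion pairs
  expect_equal(rmsd_matrix(group_motifs(motifs[1])[[1]]), matrix(0, 1, 1))
  m2 <- motifs[[1]]
  rigid <- random_rigid()
  m2$ca <- apply_rigid(m2$ca, rigid)
  g2 <- group_motifs(list(motifs[[1]], m2))[[1]]
  expect_lt(max(rmsd_matrix(g2)), 1e-9)
})

test_that("complete-linkage clustering obeys the worked examples", {
  expect_equal(cluster_conformations(matrix(0, 1, 1))$n_clusters, 1L)

  D <- matrix(c(0, 0.5, 2.0,
                0.5, 0, 2.0,
                2.0, 2.0, 0), 3, 3, byrow = TRUE)
  cl <- cluster_conformations(D, tau = 1.25)
  expect_equal(cl$n_clusters, 2L)
  expect_equal(cl$assignment[1], cl$assignment[2])
  expect_false(cl$assignment[1] == cl$assignment[3])

  # chain case: A-B and B-C close, A-C far; the 3-cluster merge is forbidden
  # and the lowest-index pair merges first
  D2 <- matrix(c(0, 1.0, 2.0,
                 1.0, 0, 1.0,
                 2.0, 1.0, 0), 3, 3, byrow = TRUE)
  cl2 <- cluster_conformations(D2, tau = 1.25)
  expect_equal(cl2$n_clusters, 2L)
  expect_equal(cl2$assignment, c(1L, 1L, 2L))   # lowest-index tie rule
})

test_that("clusters never contain a pair above the threshold", {
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(2:9, 1)
    P <- matrix(rnorm(n * 3, sd = 1.2), n, 3)
    D <- as.matrix(dist(P))
    tau <- runif(1, 0.5, 3)
    cl <- cluster_conformations(D, tau)
    for (g in seq_len(cl$n_clusters)) {
      idx <- which(cl$assignment == g)
      if (length(idx) > 1L) expect_lte(max(D[idx, idx]), tau)
    }
  }
})

test_that("cluster counts match the exhaustive-partition oracle on groups", {
  set.seed(23)
  for (rep in 1:6) {
    k <- sample(1:3, 1)
    n <- sample(k:7, 1)
    pg <- generate_loop_group(n_entries = n, n_conformations = k,
                              rmsd_target = 3, jitter = 0.1,
                              seed = 300 + rep)
    motifs <- unlist(lapply(pg$fixtures, function(f)
      mine_loops(f$structure, ann = f$ss)), recursive = FALSE)
    D <- rmsd_matrix(group_motifs(motifs)[[1]])
    cl <- cluster_conformations(D, 1.25)
    expect_equal(cl$n_clusters, min_clusters_oracle(D, 1.25), info = rep)
    expect_equal(cl$n_clusters, k, info = rep)
  }
})

test_that("labels follow the flexible/rigid/unknown evidence rules", {
  mk_group <- function(entry_ids) {
    members <- lapply(entry_ids, function(e)
      motif_from_coords(matrix(rnorm(12), 4, 3), "AAAA", e))
    structure(list(group_key = "AAAA", members = members,
                   distinct_entry_ids = unique(entry_ids)),
              class = "LoopGroup")
  }
  two_cl <- structure(list(assignment = c(1L, 2L), n_clusters = 2L,
                           linkage = "complete", threshold = 1.25),
                      class = "ConformationClustering")
  one_cl <- function(n) structure(list(assignment = rep(1L, n),
                                       n_clusters = 1L,
                                       linkage = "complete",
                                       threshold = 1.25),
                                  class = "ConformationClustering")
  # two conformations: flexible regardless of entry count
  expect_equal(assign_label(two_cl, mk_group(c("E1", "E1")))$label, "flexible")
  # one conformation in 5 distinct entries: rigid
  expect_equal(assign_label(one_cl(5), mk_group(paste0("E", 1:5)))$label,
               "rigid")
  # six occurrences but only 4 distinct entries: unknown
  g <- mk_group(c("E1", "E1", "E2", "E2", "E3", "E4"))
  lab <- assign_label(one_cl(6), g)
  expect_equal(lab$label, "unknown")
  expect_equal(lab$n_distinct_entries, 4L)
})

test_that("new conformations can only move labels towards flexible", {
  pg <- generate_loop_group(n_entries = 6, n_conformations = 1,
                            jitter = 0.05, seed = 41)
  motifs <- unlist(lapply(pg$fixtures, function(f)
    mine_loops(f$structure, ann = f$ss)), recursive = FALSE)
  g <- group_motifs(motifs)[[1]]
  lab0 <- label_groups(list(g))$label
  expect_equal(lab0, "rigid")
  # add a member in a genuinely new conformation
  pg2 <- generate_loop_group(n_entries = 2, n_conformations = 2,
                             rmsd_target = 4, jitter = 0.05, seed = 41,
                             loop_length = 8)
  far <- mine_loops(pg2$fixtures[[2]]$structure, ann = pg2$fixtures[[2]]$ss)[[1]]
  far$residues <- g$members[[1]]$residues        # same identity, new shape
  far$sequence <- g$members[[1]]$sequence
  g2 <- g
  g2$members <- c(g$members, list(far))
  expect_equal(label_groups(list(g2))$label, "flexible")
})
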