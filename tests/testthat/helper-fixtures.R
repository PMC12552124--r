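# Shared fixtures and independent oracles used across the test files.

# -- tiny hand-written PDB text ------------------------------------------------

minimal_pdb_lines <- function(resolution = "1.80", xray = TRUE,
                              altloc_residue2 = FALSE) {
  atom <- function(serial, name, alt, res, resno, x, y, z, occ = "1.00") {
    sprintf("ATOM  %5d %-4s%1s%3s A%4d    %8.3f%8.3f%8.3f  %s  0.00           %s",
            serial, paste0(" ", name), alt, res, resno, x, y, z, occ,
            substr(name, 1, 1))
  }
  lines <- c(
    "HEADER    HYDROLASE                               01-JAN-20   1ABC",
    if (xray) "EXPDTA    X-RAY DIFFRACTION" else "EXPDTA    SOLUTION NMR",
    if (!is.na(resolution))
      sprintf("REMARK   2 RESOLUTION. %s ANGSTROMS.", resolution),
    atom(1, "N", " ", "ALA", 1, 11.104, 6.134, -6.504),
    atom(2, "CA", " ", "ALA", 1, 11.639, 6.071, -5.147),
    atom(3, "C", " ", "ALA", 1, 12.685, 7.161, -4.922),
    atom(4, "O", " ", "ALA", 1, 13.339, 7.615, -5.855))
  if (altloc_residue2) {
    lines <- c(lines,
      atom(5, "N", " ", "GLY", 2, 12.866, 7.562, -3.661),
      atom(6, "CA", "A", "GLY", 2, 13.845, 8.601, -3.393, "0.50"),
      atom(7, "CA", "B", "GLY", 2, 13.945, 8.701, -3.293, "0.50"),
      atom(8, "C", " ", "GLY", 2, 13.254, 9.955, -3.760),
      atom(9, "O", " ", "GLY", 2, 12.094, 10.032, -4.160))
  } else {
    lines <- c(lines,
      atom(5, "N", " ", "GLY", 2, 12.866, 7.562, -3.661),
      atom(6, "CA", " ", "GLY", 2, 13.845, 8.601, -3.393),
      atom(7, "C", " ", "GLY", 2, 13.254, 9.955, -3.760),
      atom(8, "O", " ", "GLY", 2, 12.094, 10.032, -4.160))
  }
  c(lines,
    atom(10, "N", " ", "SER", 3, 13.990, 10.950, -3.606),
    atom(11, "CA", " ", "SER", 3, 13.600, 12.320, -3.900),
    atom(12, "C", " ", "SER", 3, 14.640, 13.340, -3.450),
    atom(13, "O", " ", "SER", 3, 15.720, 13.000, -2.970),
    "TER", "END")
}

write_minimal_pdb <- function(path, ...) {
  writeLines(minimal_pdb_lines(...), path)
  path
}

# mmCIF serialisation of the same content, written independently of the
# package reader
write_minimal_mmcif <- function(path, pdb_path) {
  s <- read_structure(pdb_path, "pdb")
  a <- s$atoms
  hdr <- c("data_fixture",
           "_entry.id 1ABC",
           "_exptl.method 'X-RAY DIFFRACTION'",
           if (is.finite(s$resolution))
             sprintf("_refine.ls_d_res_high %.2f", s$resolution),
           "loop_",
           paste0("_atom_site.",
                  c("group_PDB", "id", "type_symbol", "label_atom_id",
                    "label_alt_id", "label_comp_id", "auth_asym_id",
                    "auth_seq_id", "pdbx_PDB_ins_code", "Cartn_x", "Cartn_y",
                    "Cartn_z", "occupancy", "pdbx_PDB_model_num")))
  rows <- sprintf("ATOM %d %s %s %s %s %s %d %s %.3f %.3f %.3f %.2f 1",
                  seq_len(nrow(a)), a$elesy, a$elety,
                  ifelse(a$alt == "", ".", a$alt), a$resid, a$chain, a$resno,
                  ifelse(a$insert == "", "?", a$insert),
                  a$x, a$y, a$z, a$occ)
  writeLines(c(hdr, rows, "#"), path)
  path
}

# -- independent oracles -------------------------------------------------------

# dense rotation-grid RMSD oracle: minimum RMSD over sampled rotations with
# optimal translation (centroid matching) for each
grid_rmsd_oracle <- function(A, B, n_angle = 24) {
  A <- scale(A, scale = FALSE); B <- scale(B, scale = FALSE)
  angles <- seq(0, 2 * pi, length.out = n_angle + 1)[-(n_angle + 1)]
  half <- seq(0, pi, length.out = n_angle / 2 + 1)
  best <- Inf
  for (a1 in angles) for (a2 in half) for (a3 in angles) {
    cz <- cos(a1); sz <- sin(a1); cy <- cos(a2); sy <- sin(a2)
    cx <- cos(a3); sx <- sin(a3)
    Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE)
    Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE)
    Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
    R <- Rz %*% Ry %*% Rx
    r <- sqrt(mean(rowSums((A %*% t(R) - B)^2)))
    if (r < best) best <- r
  }
  best
}

# all set partitions of 1..n (restricted growth strings)
all_partitions <- function(n) {
  out <- list()
  rec <- function(assign, k) {
    i <- length(assign) + 1L
    if (i > n) { out[[length(out) + 1L]] <<- assign; return(invisible()) }
    for (g in seq_len(k + 1L)) rec(c(assign, g), max(k, g))
  }
  rec(integer(0), 0L)
  out
}

# minimum number of clusters over all partitions whose every cluster has
# pairwise diameter <= tau
min_clusters_oracle <- function(D, tau) {
  n <- nrow(D)
  if (n == 1L) return(1L)
  best <- n
  for (p in all_partitions(n)) {
    ok <- TRUE
    for (g in unique(p)) {
      idx <- which(p == g)
      if (length(idx) > 1L && max(D[idx, idx]) > tau) { ok <- FALSE; break }
    }
    if (ok) best <- min(best, max(p))
  }
  best
}

# brute-force pairwise ROC AUC (ties count one half)
pairwise_roc_oracle <- function(labels, scores) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# direct precision/recall enumeration of average precision over distinct
# thresholds
ap_oracle <- function(labels, scores) {
  ths <- sort(unique(scores), decreasing = TRUE)
  n_pos <- sum(labels == 1)
  prev_rec <- 0; ap <- 0
  for (t in ths) {
    called <- scores >= t
    prec <- sum(labels[called] == 1) / sum(called)
    rec <- sum(labels[called] == 1) / n_pos
    ap <- ap + prec * (rec - prev_rec)
    prev_rec <- rec
  }
  ap
}

# full Needleman-Wunsch score matrix oracle (match +1 / mismatch 0 / gap -1),
# returning the identity of an optimal alignment found by exhaustive
# enumeration of tracebacks (maximising matches among optimal alignments)
nw_identity_oracle <- function(a, b) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  S <- matrix(0, n + 1, m + 1)
  S[, 1] <- -(0:n); S[1, ] <- -(0:m)
  for (i in 1:n) for (j in 1:m) {
    S[i + 1, j + 1] <- max(S[i, j] + (A[i] == B[j]),
                           S[i, j + 1] - 1, S[i + 1, j] - 1)
  }
  # enumerate all optimal tracebacks, track best identity
  best <- -1
  rec <- function(i, j, matches, cols) {
    if (i == 0 && j == 0) {
      best <<- max(best, 100 * matches / cols)
      return(invisible())
    }
    if (i > 0 && j > 0 &&
        S[i + 1, j + 1] == S[i, j] + (A[i] == B[j])) {
      rec(i - 1, j - 1, matches + (A[i] == B[j]), cols + 1)
    }
    if (i > 0 && S[i + 1, j + 1] == S[i, j + 1] - 1) rec(i - 1, j, matches, cols + 1)
    if (j > 0 && S[i + 1, j + 1] == S[i + 1, j] - 1) rec(i, j - 1, matches, cols + 1)
  }
  rec(n, m, 0, 0)
  best
}

# random rigid motion (optionally with reflection)
random_rigid <- function(reflect = FALSE) {
  M <- matrix(rnorm(9), 3, 3)
  qr_d <- qr(M)
  R <- qr.Q(qr_d)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  if (reflect) R[, 1] <- -R[, 1]
  list(R = R, t = rnorm(3, sd = 20))
}

apply_rigid <- function(coords, rigid) {
  sweep(coords %*% t(rigid$R), 2, rigid$t, FUN = "+")
}

# small labelled graph for model tests
toy_graph <- function(n = 5, seed = 1, label = 1) {
  set.seed(seed)
  residue_graph(sample(AA_STANDARD, n, replace = TRUE),
                matrix(rnorm(3 * n, sd = 4), n, 3),
                seq_len(n) <= ceiling(n / 2),
                cfg = graph_config(edge_cutoff = 30), label = label)
}
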