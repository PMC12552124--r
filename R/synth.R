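# Synthetic structure generators: beta-hairpins with ground-truth secondary
# structure, loop ensembles with planted flexibility labels, and a
# planted-signal classification dataset. Backbones are built by sequential
# internal-coordinate placement with standard bond geometry; no energy
# function is involved -- the fixtures only need the geometric and
# statistical structure the pipeline assumes.

# standard backbone geometry (Angstrom / degrees)
BOND_N_CA <- 1.458
BOND_CA_C <- 1.525
BOND_C_N  <- 1.329
BOND_C_O  <- 1.231
ANG_N_CA_C <- 111.2
ANG_CA_C_N <- 116.2
ANG_C_N_CA <- 121.7
ANG_CA_C_O <- 120.8

# place D given A-B-C with |CD| = bond, angle(BCD) = ang, dihedral(ABCD) = chi
nerf_place <- function(A, B, C, bond, ang, chi) {
  th <- ang * pi / 180; ch <- chi * pi / 180
  bc <- C - B; bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d2 <- bond * c(-cos(th), sin(th) * cos(ch), sin(th) * sin(ch))
  C + d2[1] * bc + d2[2] * m + d2[3] * n
}

#' Build a backbone from phi/psi dihedrals
#'
#' Sequential natural-extension placement of N, CA, C, O atoms with standard
#' bond lengths and angles, omega fixed at 180 degrees. The carbonyl O is
#' placed in the peptide plane opposite the next amide nitrogen.
#'
#' @param phi,psi Dihedral vectors in degrees, one value per residue
#'   (`phi[1]` is unused).
#' @param sequence 1-letter amino-acid sequence (defaults to poly-alanine).
#' @param chain Chain id.
#' @param resno_start First author residue number.
#' @return Atom data.frame suitable for [structure_model()].
#' @export
build_backbone <- function(phi, psi, sequence = NULL, chain = "A",
                           resno_start = 1L) {
  n <- length(phi)
  stopifnot(length(psi) == n, n >= 1L)
  if (is.null(sequence)) sequence <- strsplit(paste(rep("A", n),
                                                    collapse = ""), "")[[1]]
  if (is.character(sequence) && length(sequence) == 1L) {
    sequence <- strsplit(sequence, "")[[1]]
  }
  stopifnot(length(sequence) == n)
  three <- names(AA_THREE_TO_ONE)[match(sequence, AA_THREE_TO_ONE)]
  three[is.na(three)] <- "UNK"
  N <- CA <- C <- O <- matrix(NA_real_, n, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(BOND_N_CA, 0, 0)
  th <- ANG_N_CA_C * pi / 180
  C[1, ] <- CA[1, ] + BOND_CA_C * c(cos(pi - th), sin(pi - th), 0)
  for (i in seq_len(n)[-1]) {
    N[i, ] <- nerf_place(N[i - 1, ], CA[i - 1, ], C[i - 1, ],
                         BOND_C_N, ANG_CA_C_N, psi[i - 1])
    CA[i, ] <- nerf_place(CA[i - 1, ], C[i - 1, ], N[i, ],
                          BOND_N_CA, ANG_C_N_CA, 180)
    C[i, ] <- nerf_place(C[i - 1, ], N[i, ], CA[i, ],
                         BOND_CA_C, ANG_N_CA_C, phi[i])
  }
  for (i in seq_len(n)) {
    O[i, ] <- nerf_place(N[i, ], CA[i, ], C[i, ],
                         BOND_C_O, ANG_CA_C_O, psi[i] + 180)
  }
  rows <- lapply(seq_len(n), function(i) {
    data.frame(chain = chain, resno = resno_start + i - 1L, insert = "",
               resid = three[i],
               elety = c("N", "CA", "C", "O"),
               elesy = c("N", "C", "C", "O"),
               x = c(N[i, 1], CA[i, 1], C[i, 1], O[i, 1]),
               y = c(N[i, 2], CA[i, 2], C[i, 2], O[i, 2]),
               z = c(N[i, 3], CA[i, 3], C[i, 3], O[i, 3]),
               alt = "", occ = 1, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Rodrigues rotation matrix
rotation_about <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2],
                axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

#' Ideal alpha-helix fixture
#'
#' A poly-alanine helix built at (phi, psi) = (-57, -47).
#'
#' @param n Number of residues (default 12).
#' @param chain Chain id.
#' @return A `StructureModel`.
#' @export
generate_ideal_helix <- function(n = 12L, chain = "A") {
  atoms <- build_backbone(rep(-57, n), rep(-47, n), chain = chain)
  structure_model(atoms, entry_id = "HELX", experimental_method = "xray",
                  resolution = 1.5)
}

#' Ideal extended strand fixture
#'
#' A single extended poly-alanine strand at (phi, psi) = (-120, 120); with
#' no partner strand it carries no bridge partners.
#'
#' @param n Number of residues (default 8).
#' @param chain Chain id.
#' @return A `StructureModel`.
#' @export
generate_ideal_strand <- function(n = 8L, chain = "A") {
  atoms <- build_backbone(rep(-120, n), rep(120, n), chain = chain)
  structure_model(atoms, entry_id = "STRD", experimental_method = "xray",
                  resolution = 1.5)
}

#' Ideal two-strand antiparallel pair fixture
#'
#' Two extended strands on separate chains in antiparallel register. The
#' second strand is the first rotated 180 degrees about the in-plane
#' transverse axis (the carbonyl direction perpendicular to the strand
#' axis) and offset along that axis, which places the backbone amides and
#' carbonyls of the two strands in mutual hydrogen-bond geometry. Defaults
#' are calibrated for the standard extended-backbone geometry used by
#' [build_backbone()].
#'
#' @param n Residues per strand (default 6).
#' @param offset Inter-strand offset (Angstrom) along the transverse axis.
#' @param slide Offset along the strand axis (Angstrom).
#' @return A `StructureModel` with chains A and B.
#' @export
generate_antiparallel_pair <- function(n = 6L, offset = 4.0, slide = -1.8) {
  a <- build_backbone(rep(-120, n), rep(120, n), chain = "A")
  xyz <- as.matrix(a[, c("x", "y", "z")])
  ca <- xyz[a$elety == "CA", , drop = FALSE]
  u <- ca[n, ] - ca[1, ]; u <- u / sqrt(sum(u^2))
  co <- xyz[a$elety == "O", , drop = FALSE][1, ] -
    xyz[a$elety == "C", , drop = FALSE][1, ]
  tr <- co - sum(co * u) * u; tr <- tr / sqrt(sum(tr^2))
  center <- colMeans(ca)
  R <- rotation_about(tr, pi)
  xyz2 <- sweep(sweep(xyz, 2, center) %*% t(R), 2, -center)
  xyz2 <- sweep(xyz2, 2, offset * tr + slide * u, FUN = "+")
  b <- a
  b[, c("x", "y", "z")] <- xyz2
  b$chain <- "B"
  structure_model(rbind(a, b), entry_id = "APAR",
                  experimental_method = "xray", resolution = 1.5)
}

#' Generate a synthetic beta-hairpin structure
#'
#' Two extended strands connected by a loop whose dihedrals come from a
#' seeded draw (or are supplied), with optional Gaussian coordinate jitter.
#' The fixture carries its own ground-truth secondary-structure annotation
#' (strand labels with symmetric antiparallel partners by register) so that
#' mining logic can be exercised independently of the hydrogen-bond backend.
#'
#' @param loop_length Number of loop residues (>= 1).
#' @param strand_length Residues per flanking strand (default 5).
#' @param sequence Optional full 1-letter sequence (length
#'   `loop_length + 2 * strand_length`); sampled when `NULL`.
#' @param loop_dihedrals Optional `loop_length` x 2 matrix of (phi, psi)
#'   degrees; sampled from the seed when `NULL`.
#' @param jitter Gaussian coordinate noise sd in Angstrom (default 0).
#' @param seed RNG seed for sequence/dihedral sampling and jitter.
#' @param entry_id Entry id to stamp.
#' @param chain Chain id.
#' @return List of class `hairpin_fixture`: `structure` (a
#'   `StructureModel`), `ss` (ground-truth `SSAnnotation`), `loop_keys`,
#'   `loop_dihedrals`, `sequence`.
#' @export
generate_hairpin <- function(loop_length, strand_length = 5L,
                             sequence = NULL, loop_dihedrals = NULL,
                             jitter = 0, seed = 1L, entry_id = "SYN1",
                             chain = "A") {
  stopifnot(loop_length >= 1L, strand_length >= 2L, jitter >= 0)
  n <- loop_length + 2L * strand_length
  set.seed(seed)
  if (is.null(sequence)) {
    sequence <- paste(sample(AA_STANDARD, n, replace = TRUE), collapse = "")
  }
  stopifnot(nchar(sequence) == n)
  if (is.null(loop_dihedrals)) {
    loop_dihedrals <- cbind(stats::runif(loop_length, -150, -40),
                            stats::runif(loop_length, -60, 170))
  }
  loop_dihedrals <- matrix(loop_dihedrals, ncol = 2)
  phi <- c(rep(-120, strand_length), loop_dihedrals[, 1],
           rep(-120, strand_length))
  psi <- c(rep(120, strand_length), loop_dihedrals[, 2],
           rep(120, strand_length))
  atoms <- build_backbone(phi, psi, sequence = sequence, chain = chain)
  if (jitter > 0) {
    atoms[, c("x", "y", "z")] <- atoms[, c("x", "y", "z")] +
      matrix(stats::rnorm(3L * nrow(atoms), sd = jitter), ncol = 3)
  }
  s <- structure_model(atoms, entry_id = entry_id,
                       experimental_method = "xray", resolution = 1.5)
  rt <- residue_table(s)
  ss <- rep("other", n)
  s1 <- seq_len(strand_length)
  s2 <- n - strand_length + seq_len(strand_length)
  ss[c(s1, s2)] <- "strand"
  partners <- rep(list(character(0)), n)
  for (k in seq_len(strand_length)) {
    a <- s1[k]; b <- s2[strand_length + 1L - k]   # symmetric register
    partners[[a]] <- rt$key[b]
    partners[[b]] <- rt$key[a]
  }
  ann <- ss_annotation(rt, ss, partners)
  loop_keys <- rt$key[strand_length + seq_len(loop_length)]
  structure(list(structure = s, ss = ann, loop_keys = loop_keys,
                 loop_dihedrals = loop_dihedrals, sequence = sequence,
                 seed = seed),
            class = "hairpin_fixture")
}

# superposed loop-CA RMSD between two hairpin fixtures
fixture_loop_rmsd <- function(f1, f2) {
  a <- ca_coords(f1$structure, f1$loop_keys)
  b <- ca_coords(f2$structure, f2$loop_keys)
  superpose_kabsch(a, b)$rmsd
}

#' Generate a loop group with a planted flexibility label
#'
#' Produces `n_entries` structure instances of the same loop sequence in
#' `n_conformations` distinct conformations (assigned round-robin across
#' entries). Conformations are built by perturbing the base loop dihedrals
#' along a random direction whose scale is searched so that the superposed
#' loop-CA RMSD to every previous conformation lies within 20 percent of
#' `rmsd_target`; each instance additionally receives Gaussian coordinate
#' jitter. Ground truth follows the labelling rule: flexible when
#' `n_conformations >= 2`, rigid when one conformation is seen in at least 5
#' entries, otherwise unknown.
#'
#' @param n_entries Number of structure instances (distinct entry ids).
#' @param n_conformations Number of distinct planted conformations.
#' @param rmsd_target Planted inter-conformation RMSD in Angstrom (default
#'   3; ignored when `n_conformations == 1`).
#' @param jitter Per-instance coordinate noise sd in Angstrom (default 0.1).
#' @param loop_length Loop length (default 8).
#' @param strand_length Strand length (default 5).
#' @param seed RNG seed.
#' @param entry_prefix Prefix for stamped entry ids.
#' @return List of class `planted_group`: `fixtures` (one per entry),
#'   `ground_truth` (`"flexible"`, `"rigid"` or `"unknown"`),
#'   `conformation_of` (planted conformation index per entry),
#'   `rmsd_target`.
#' @export
generate_loop_group <- function(n_entries, n_conformations = 1L,
                                rmsd_target = 3, jitter = 0.1,
                                loop_length = 8L, strand_length = 5L,
                                seed = 1L, entry_prefix = "SG") {
  stopifnot(n_entries >= 1L, n_conformations >= 1L,
            n_entries >= n_conformations)
  if (n_conformations >= 2L) stopifnot(rmsd_target > 0)
  set.seed(seed)
  n <- loop_length + 2L * strand_length
  sequence <- paste(sample(AA_STANDARD, n, replace = TRUE), collapse = "")
  base <- cbind(stats::runif(loop_length, -150, -40),
                stats::runif(loop_length, -60, 170))
  confs <- list(base)
  tries <- 0L
  while (length(confs) < n_conformations) {
    tries <- tries + 1L
    if (tries > 50L) {
      stop("could not reach the planted RMSD target after 50 attempts")
    }
    # generate_hairpin reseeds the RNG internally, so draw each candidate
    # direction under its own derived seed
    set.seed((seed + 13L * tries + 101L * length(confs)) %% 2147483647L)
    delta <- matrix(stats::rnorm(2L * loop_length), ncol = 2)
    delta <- delta / max(abs(delta))
    ref <- generate_hairpin(loop_length, strand_length, sequence,
                            loop_dihedrals = confs[[1]], jitter = 0,
                            seed = seed)
    # search the perturbation scale for the target RMSD to conformation 1
    scales <- seq(5, 170, by = 5)
    rmsds <- vapply(scales, function(sc) {
      cand <- generate_hairpin(loop_length, strand_length, sequence,
                               loop_dihedrals = confs[[1]] + sc * delta,
                               jitter = 0, seed = seed)
      fixture_loop_rmsd(ref, cand)
    }, 0)
    best <- which.min(abs(rmsds - rmsd_target))
    if (abs(rmsds[best] - rmsd_target) > 0.2 * rmsd_target) next
    cand_dh <- confs[[1]] + scales[best] * delta
    # distinct from all previously accepted conformations as well
    cand_fix <- generate_hairpin(loop_length, strand_length, sequence,
                                 loop_dihedrals = cand_dh, jitter = 0,
                                 seed = seed)
    ok <- all(vapply(confs[-1], function(dh) {
      f <- generate_hairpin(loop_length, strand_length, sequence,
                            loop_dihedrals = dh, jitter = 0, seed = seed)
      fixture_loop_rmsd(f, cand_fix) >= 0.8 * rmsd_target
    }, TRUE))
    if (ok) confs[[length(confs) + 1L]] <- cand_dh
  }
  conformation_of <- rep(seq_len(n_conformations),
                         length.out = n_entries)
  fixtures <- lapply(seq_len(n_entries), function(i) {
    generate_hairpin(loop_length, strand_length, sequence,
                     loop_dihedrals = confs[[conformation_of[i]]],
                     jitter = jitter, seed = seed + 1000L + i,
                     entry_id = sprintf("%s%02d", entry_prefix, i))
  })
  ground_truth <- if (n_conformations >= 2L) "flexible"
  else if (n_entries >= 5L) "rigid" else "unknown"
  structure(list(fixtures = fixtures, ground_truth = ground_truth,
                 conformation_of = conformation_of,
                 rmsd_target = if (n_conformations >= 2L) rmsd_target else NA,
                 sequence = sequence, seed = seed),
            class = "planted_group")
}

#' Generate a planted-signal classification dataset
#'
#' Builds beta-hairpin residue graphs with varying loop length (4-20),
#' sequence composition and context density, and assigns label 1 with
#' probability `plogis(beta_length * (length - 10) + beta_motif *
#' [>= 2 loop glycines] + beta_exposure * (exposure - exposure_ref))`,
#' flipped with the noise rate. The
#' glycine-motif term carries signal a length-only classifier cannot see.
#'
#' @param n_graphs Number of graphs (default 800).
#' @param beta_length,beta_motif,beta_exposure Signal coefficients for loop
#'   length, the glycine motif and exposure (defaults 1.6, 8, 1).
#' @param exposure_ref Exposure centring constant (default 14).
#' @param noise Label flip probability in \[0, 0.5) (default 0.02).
#' @param seed RNG seed.
#' @param cfg A [graph_config()] used for featurization.
#' @return List of class `planted_dataset`: `graphs` (labelled
#'   `ResidueGraph`s), `labels`, `truth` (data.frame with `length`,
#'   `n_gly`, `exposure`, `p_signal`, `label`), `params`.
#' @export
generate_planted_dataset <- function(n_graphs = 800L, beta_length = 1.6,
                                     beta_motif = 8,
                                     beta_exposure = 1,
                                     exposure_ref = 14, noise = 0.02,
                                     seed = 1L, cfg = graph_config()) {
  stopifnot(noise >= 0, noise < 0.5)
  set.seed(seed)
  graphs <- vector("list", n_graphs)
  truth <- data.frame(length = integer(n_graphs), n_gly = integer(n_graphs),
                      exposure = integer(n_graphs),
                      p_signal = numeric(n_graphs),
                      label = integer(n_graphs))
  for (g in seq_len(n_graphs)) {
    L <- sample(4:20, 1L)
    sl <- sample(3:7, 1L)
    n <- L + 2L * sl
    # loop glycine content varies so that roughly half the loops carry the
    # >= 2 glycine motif
    p_gly <- sample(c(0.05, 0.3), 1L)
    seq_loop <- ifelse(stats::runif(L) < p_gly, "G",
                       sample(setdiff(AA_STANDARD, "G"), L, replace = TRUE))
    seq_all <- c(sample(AA_STANDARD, sl, replace = TRUE), seq_loop,
                 sample(AA_STANDARD, sl, replace = TRUE))
    fix <- generate_hairpin(L, sl, paste(seq_all, collapse = ""),
                            jitter = 0.15,
                            seed = (seed * 7919 + g) %% 2147483647,
                            entry_id = sprintf("PL%04d", g))
    rt <- residue_table(fix$structure)
    ca <- ca_coords(fix$structure, rt$key)
    in_loop <- rt$key %in% fix$loop_keys
    # extra context residues placed 4-9 A from random loop residues
    n_extra <- sample(0:12, 1L)
    if (n_extra > 0L) {
      anchor <- ca[sample(which(in_loop), n_extra, replace = TRUE), ,
                   drop = FALSE]
      dir <- matrix(stats::rnorm(3L * n_extra), ncol = 3)
      dir <- dir / sqrt(rowSums(dir^2))
      extra_ca <- anchor + dir * stats::runif(n_extra, 4, 9)
      ca <- rbind(ca, extra_ca)
      rt2_one <- c(rt$one, sample(AA_STANDARD, n_extra, replace = TRUE))
      chain <- c(rt$chain, rep("B", n_extra))
      resno <- c(rt$resno, 100L + seq_len(n_extra))
      in_loop <- c(in_loop, rep(FALSE, n_extra))
    } else {
      rt2_one <- rt$one
      chain <- rt$chain
      resno <- rt$resno
    }
    # restrict to loop residues plus context within the radius
    loop_ca <- ca[in_loop, , drop = FALSE]
    near <- vapply(seq_len(nrow(ca)), function(i) {
      if (in_loop[i]) return(TRUE)
      min(rowSums(sweep(loop_ca, 2, ca[i, ])^2)) <= cfg$context_radius^2
    }, TRUE)
    exposure <- sum(near & !in_loop)
    n_gly <- sum(seq_loop == "G")
    p_sig <- stats::plogis(beta_length * (L - 10) +
                             beta_motif * (n_gly >= 2) +
                             beta_exposure * (exposure - exposure_ref))
    y <- stats::rbinom(1L, 1L, p_sig)
    if (stats::runif(1) < noise) y <- 1L - y
    graphs[[g]] <- residue_graph(rt2_one[near], ca[near, , drop = FALSE],
                                 in_loop[near], chain = chain[near],
                                 resno = resno[near], cfg = cfg, label = y,
                                 meta = list(group_key = sprintf("PL%04d", g),
                                             entry_id = sprintf("PL%04d", g),
                                             length = L,
                                             exposure = exposure))
    truth[g, ] <- list(L, n_gly, exposure, p_sig, y)
  }
  structure(list(graphs = graphs, labels = truth$label, truth = truth,
                 params = list(beta_length = beta_length,
                               beta_motif = beta_motif,
                               beta_exposure = beta_exposure,
                               exposure_ref = exposure_ref, noise = noise,
                               seed = seed)),
            class = "planted_dataset")
}
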