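# Internal Kabsch-Sander secondary-structure assignment.
#
# Backbone amide hydrogens are inferred from the preceding peptide unit
# (H = N + unit(C_prev - O_prev), 1.0 A from N) and hydrogen bonds accepted
# when the Kabsch-Sander electrostatic energy falls below -0.5 kcal/mol.
# Residues in n-turn patterns are labelled helix, residues in (anti)parallel
# bridge patterns strand; antiparallel bridge partners are recorded because
# loop mining keys on them.

KS_Q <- 27.888          # 0.084 * 332 kcal*A/mol
KS_CUTOFF <- -0.5       # kcal/mol
KS_CLASH <- -9.9        # assigned when atoms overlap (< 0.5 A)

#' Assign secondary structure with the internal Kabsch-Sander backend
#'
#' Labels every residue `strand`, `helix` or `other` and records the
#' antiparallel bridge partners of strand residues. Residues lacking any of
#' the backbone atoms N, CA, C, O are labelled `other`. Chains shorter than
#' 3 residues get all labels `other`.
#'
#' @param s A `StructureModel`.
#' @return An object of class `SSAnnotation`: a data.frame with columns
#'   `chain`, `resno`, `insert`, `key`, `ss` and a list-column `partners`
#'   holding the residue keys of antiparallel bridge partners.
#' @export
assign_secondary_structure <- function(s) {
  rt <- residue_table(s)
  n <- nrow(rt)
  ann <- ss_annotation(rt, rep("other", n),
                       rep(list(character(0)), n))
  if (n == 0L) return(ann)

  bb <- lapply(c("N", "CA", "C", "O"), function(el) atom_coords(s, rt$key, el))
  names(bb) <- c("N", "CA", "C", "O")
  ok <- rowSums(is.na(bb$N) | is.na(bb$CA) | is.na(bb$C) | is.na(bb$O)) == 0

  # chain-relative predecessor: previous residue in the same chain with a
  # continuous peptide bond (C_prev - N < 2.5 A)
  prev <- rep(NA_integer_, n)
  for (i in seq_len(n)[-1]) {
    if (rt$chain[i] == rt$chain[i - 1] && ok[i] && ok[i - 1]) {
      d <- sqrt(sum((bb$C[i - 1, ] - bb$N[i, ])^2))
      if (is.finite(d) && d < 2.5) prev[i] <- i - 1L
    }
  }
  nxt <- rep(NA_integer_, n)
  nxt[prev[!is.na(prev)]] <- which(!is.na(prev))

  # inferred amide H; prolines and chain-start residues cannot donate
  H <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    p <- prev[i]
    if (!is.na(p) && ok[i] && rt$resid[i] != "PRO") {
      v <- bb$C[p, ] - bb$O[p, ]
      H[i, ] <- bb$N[i, ] + v / sqrt(sum(v^2))
    }
  }

  # hbond[j, i] = TRUE when CO of j accepts the NH of i
  ca_ok <- which(ok)
  hb <- matrix(FALSE, n, n)
  if (length(ca_ok) >= 2L) {
    D <- as.matrix(stats::dist(bb$CA[ca_ok, , drop = FALSE]))
    for (a in seq_along(ca_ok)) for (b in seq_along(ca_ok)) {
      j <- ca_ok[a]; i <- ca_ok[b]          # acceptor j, donor i
      if (i == j || D[a, b] > 9) next
      if (!is.na(prev[i]) && prev[i] == j) next  # no bond to own peptide unit
      if (any(is.na(H[i, ]))) next
      e <- ks_energy(bb$C[j, ], bb$O[j, ], bb$N[i, ], H[i, ])
      if (e < KS_CUTOFF) hb[j, i] <- TRUE
    }
  }

  # n-turns: CO(i) accepts NH(i+k), k = 3,4,5; 4-turns at i-1 and i make the
  # minimal alpha-helix i..i+3
  helix <- rep(FALSE, n)
  turn4 <- rep(FALSE, n)
  for (i in seq_len(n)) {
    j <- chain_step(nxt, i, 4L)
    if (!is.na(j) && hb[i, j]) turn4[i] <- TRUE
  }
  for (i in seq_len(n)) {
    p <- prev[i]
    if (!is.na(p) && turn4[p] && turn4[i]) {
      for (k in 0:3) {
        j <- chain_step(nxt, i, k)
        if (!is.na(j)) helix[j] <- TRUE
      }
    }
  }

  # bridges
  strand <- rep(FALSE, n)
  partners <- rep(list(character(0)), n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    same <- rt$chain[i] == rt$chain[j]
    if (same && (j - i) < 3L) next
    im1 <- prev[i]; ip1 <- nxt[i]; jm1 <- prev[j]; jp1 <- nxt[j]
    anti <- (hb[i, j] && hb[j, i]) ||
      (!is.na(im1) && !is.na(jp1) && !is.na(jm1) && !is.na(ip1) &&
         hb[im1, jp1] && hb[jm1, ip1])
    para <- (!is.na(im1) && !is.na(ip1) && hb[im1, j] && hb[j, ip1]) ||
      (!is.na(jm1) && !is.na(jp1) && hb[jm1, i] && hb[i, jp1])
    if (anti || para) {
      strand[i] <- TRUE; strand[j] <- TRUE
      if (anti) {
        partners[[i]] <- c(partners[[i]], rt$key[j])
        partners[[j]] <- c(partners[[j]], rt$key[i])
      }
    }
  }

  ss <- rep("other", n)
  ss[strand] <- "strand"
  ss[helix] <- "helix"              # helix wins on the rare overlap
  partners[ss != "strand"] <- list(character(0))
  ss_annotation(rt, ss, partners)
}

ks_energy <- function(C, O, N, H) {
  d <- c(ON = sqrt(sum((O - N)^2)), CH = sqrt(sum((C - H)^2)),
         OH = sqrt(sum((O - H)^2)), CN = sqrt(sum((C - N)^2)))
  if (any(d < 0.5)) return(KS_CLASH)
  KS_Q * (1 / d["ON"] + 1 / d["CH"] - 1 / d["OH"] - 1 / d["CN"])
}

chain_step <- function(nxt, i, k) {
  j <- i
  while (k > 0L && !is.na(j)) { j <- nxt[j]; k <- k - 1L }
  j
}

# Constructor shared by the internal backend, the TSV adapter and the
# fixture generator's ground truth.
ss_annotation <- function(rt, ss, partners) {
  stopifnot(length(ss) == nrow(rt), length(partners) == nrow(rt))
  out <- data.frame(chain = rt$chain, resno = rt$resno, insert = rt$insert,
                    key = rt$key, ss = ss, stringsAsFactors = FALSE)
  out$partners <- partners
  # symmetry and strand-only partner invariants
  has <- lengths(out$partners) > 0
  if (any(has & out$ss != "strand")) {
    stop("only strand residues may carry antiparallel bridge partners")
  }
  class(out) <- c("SSAnnotation", "data.frame")
  out
}

#' Read an externally produced secondary-structure annotation
#'
#' Adapter for annotations computed by an external tool. Expected TSV
#' columns: `chain`, `resno`, `insert` (empty for none), `ss`
#' (`strand`/`helix`/`other`) and `partners` (semicolon-separated
#' `chain:resno:insert` keys of antiparallel bridge partners, empty if none).
#'
#' @param path TSV file path.
#' @return An `SSAnnotation`.
#' @export
read_ss_tsv <- function(path) {
  tab <- utils::read.delim(path, colClasses = "character")
  need <- c("chain", "resno", "insert", "ss", "partners")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0L) stop("SS TSV missing columns: ",
                              paste(miss, collapse = ", "))
  rt <- data.frame(chain = tab$chain, resno = as.integer(tab$resno),
                   insert = ifelse(is.na(tab$insert), "", tab$insert),
                   stringsAsFactors = FALSE)
  rt$key <- res_key(rt$chain, rt$resno, rt$insert)
  partners <- lapply(tab$partners, function(p) {
    if (is.na(p) || !nzchar(p)) character(0) else strsplit(p, ";")[[1]]
  })
  ss_annotation(rt, tab$ss, partners)
}

#' Write an SSAnnotation to TSV
#'
#' Inverse of [read_ss_tsv()].
#' @param ann An `SSAnnotation`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ss_tsv <- function(ann, path) {
  tab <- data.frame(chain = ann$chain, resno = ann$resno, insert = ann$insert,
                    ss = ann$ss,
                    partners = vapply(ann$partners, paste, "", collapse = ";"),
                    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
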