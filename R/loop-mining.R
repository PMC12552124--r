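# Loop-motif mining: strand-pair detection, loop extraction between the
# strands, and antibody/TCR CDR3 extraction by IMGT position.

#' Construct a LoopMotif
#'
#' Normally produced by [extract_loop_motif()] or [extract_cdr3()]; exposed
#' for the fixture generator and tests.
#'
#' @param residues data.frame of the loop residues (`chain`, `resno`,
#'   `insert`, `resid`, `one`, `key`) in chain order.
#' @param ca n x 3 matrix of loop CA coordinates (Angstrom).
#' @param entry_id Source entry id.
#' @param anchors list with `n_anchor` and `c_anchor` residue keys (flanking
#'   strand residues), possibly empty.
#' @param origin One of `"pdb_mined"`, `"cdrh3"`, `"cdrl3"`, `"cdrb3"`,
#'   `"cdra3"`.
#' @param altloc_state Altloc state id (`""` when not applicable).
#' @param fv_sequence Optional full Fv amino-acid sequence (heavy+light or
#'   beta+alpha concatenated), used for antibody/TCR grouping.
#' @return An object of class `LoopMotif`.
#' @export
loop_motif <- function(residues, ca, entry_id, anchors = list(),
                       origin = "pdb_mined", altloc_state = "",
                       fv_sequence = NULL) {
  stopifnot(nrow(residues) == nrow(ca), ncol(ca) == 3)
  seq1 <- paste(residues$one, collapse = "")
  structure(
    list(entry_id = entry_id,
         chain = residues$chain[1],
         residues = residues,
         sequence = seq1,
         ca = unname(as.matrix(ca)),
         anchors = anchors,
         loop_length = nrow(residues),
         origin = origin,
         altloc_state = altloc_state,
         fv_sequence = fv_sequence),
    class = "LoopMotif")
}

#' @export
print.LoopMotif <- function(x, ...) {
  cat(sprintf("LoopMotif %s chain %s [%s] length %d (%s)\n",
              x$entry_id, x$chain, x$sequence, x$loop_length, x$origin))
  invisible(x)
}

#' Find adjacent antiparallel strand pairs in a chain
#'
#' Strand segments are maximal runs of residues labelled `strand`. A pair of
#' segments is returned when they are consecutive along the chain (no
#' intervening strand segment) and share at least one antiparallel bridge --
#' the topology of a beta-hairpin bounding a loop.
#'
#' @param ann An `SSAnnotation`.
#' @param chain_id Chain to scan.
#' @return List of `strand_pair` objects with fields `chain`, `n_strand` and
#'   `c_strand` (residue keys of the two segments) and `evidence` (number of
#'   antiparallel bridges linking them).
#' @export
find_hairpin_pairs <- function(ann, chain_id) {
  ch <- ann[ann$chain == chain_id, , drop = FALSE]
  if (nrow(ch) == 0L) return(list())
  is_strand <- ch$ss == "strand"
  if (!any(is_strand)) return(list())
  runs <- rle(is_strand)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  seg <- Map(function(s, e) s:e, starts[runs$values], ends[runs$values])
  if (length(seg) < 2L) return(list())
  out <- list()
  for (k in seq_len(length(seg) - 1L)) {
    a <- seg[[k]]; b <- seg[[k + 1L]]
    bkeys <- ch$key[b]
    ev <- sum(vapply(a, function(i) {
      sum(ch$partners[[i]] %in% bkeys)
    }, 0L))
    if (ev >= 1L) {
      out[[length(out) + 1L]] <- structure(
        list(chain = chain_id,
             n_strand = ch$key[a],
             c_strand = bkeys,
             evidence = as.integer(ev)),
        class = "strand_pair")
    }
  }
  out
}

#' Extract the loop between two antiparallel strands
#'
#' The loop is the run of residues strictly between the last residue of the
#' N-terminal strand and the first residue of the C-terminal strand.
#' An empty intervening region (a tight turn of length 0) is an error.
#'
#' @param s The `StructureModel` the pair was derived from.
#' @param pair A `strand_pair` from [find_hairpin_pairs()].
#' @return A `LoopMotif` with `origin = "pdb_mined"`.
#' @export
extract_loop_motif <- function(s, pair) {
  rt <- chain_residues(s, pair$chain)
  i0 <- match(pair$n_strand[length(pair$n_strand)], rt$key)
  i1 <- match(pair$c_strand[1], rt$key)
  if (is.na(i0) || is.na(i1) || i1 <= i0 + 1L) {
    stop("no loop residues between the two strands (tight turn)",
         call. = FALSE)
  }
  idx <- (i0 + 1L):(i1 - 1L)
  res <- rt[idx, , drop = FALSE]
  ca <- ca_coords(s, res$key)
  loop_motif(res, ca, entry_id = s$entry_id,
             anchors = list(n_anchor = pair$n_strand,
                            c_anchor = pair$c_strand),
             origin = "pdb_mined",
             altloc_state = if (is.null(s$altloc_state)) "" else s$altloc_state)
}

#' Mine all loop motifs from a structure
#'
#' Convenience wrapper: assigns secondary structure (or uses a supplied
#' annotation), finds hairpin strand pairs on every chain, extracts the
#' intervening loops and applies the loop-level filter.
#'
#' @param s A `StructureModel`.
#' @param ann Optional `SSAnnotation`; computed internally when `NULL`.
#' @param criteria A [loop_filter_criteria()].
#' @return List of `LoopMotif`s that pass the filter.
#' @export
mine_loops <- function(s, ann = NULL, criteria = loop_filter_criteria()) {
  if (is.null(ann)) ann <- assign_secondary_structure(s)
  out <- list()
  for (ch in unique(residue_table(s)$chain)) {
    for (pair in find_hairpin_pairs(ann, ch)) {
      m <- tryCatch(extract_loop_motif(s, pair), error = function(e) NULL)
      if (!is.null(m) && passes_loop_filter(m, ann, criteria)) {
        out[[length(out) + 1L]] <- m
      }
    }
  }
  out
}

#' Read an IMGT numbering map
#'
#' Adapter for externally computed IMGT numbering. Expected TSV columns:
#' `chain`, `resno`, `insert`, `imgt` (decimal notation for inserted
#' positions, e.g. `111.1`), `chain_role` (`heavy`/`light`/`beta`/`alpha`).
#'
#' @param path TSV file path.
#' @return data.frame with those columns plus a residue `key`.
#' @export
read_imgt_tsv <- function(path) {
  tab <- utils::read.delim(path, colClasses = "character")
  need <- c("chain", "resno", "insert", "imgt", "chain_role")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0L) stop("IMGT TSV missing columns: ",
                              paste(miss, collapse = ", "))
  tab$resno <- as.integer(tab$resno)
  tab$insert <- ifelse(is.na(tab$insert), "", tab$insert)
  tab$imgt <- as.numeric(tab$imgt)
  tab$key <- res_key(tab$chain, tab$resno, tab$insert)
  tab
}

CDR3_ORIGIN <- c(heavy = "cdrh3", light = "cdrl3",
                 beta = "cdrb3", alpha = "cdra3")

#' Extract a CDR3 loop by IMGT position
#'
#' The CDR3 is defined as the residues with IMGT number in 107..116
#' inclusive of inserted positions (e.g. 111.1), taken in chain order. The
#' full Fv sequence (all chains in the numbering map, heavy/beta before
#' light/alpha) is attached for Fv-identity grouping.
#'
#' @param s A `StructureModel`.
#' @param numbering data.frame as returned by [read_imgt_tsv()].
#' @param chain_role `"heavy"`, `"light"`, `"beta"` or `"alpha"`.
#' @return A `LoopMotif` with origin `cdrh3`/`cdrl3`/`cdrb3`/`cdra3`.
#' @export
extract_cdr3 <- function(s, numbering,
                         chain_role = c("heavy", "light", "beta", "alpha")) {
  chain_role <- match.arg(chain_role)
  num <- numbering[numbering$chain_role == chain_role, , drop = FALSE]
  if (nrow(num) == 0L) {
    stop("no IMGT numbering present for chain role '", chain_role, "'",
         call. = FALSE)
  }
  chain_id <- num$chain[1]
  rt <- chain_residues(s, chain_id)
  in_range <- num$key[num$imgt >= 107 & num$imgt <= 116]
  idx <- sort(match(in_range, rt$key))
  idx <- idx[!is.na(idx)]
  if (length(idx) == 0L) {
    stop("IMGT numbering yields no residues in 107..116 for chain '",
         chain_id, "' (malformed numbering?)", call. = FALSE)
  }
  res <- rt[idx, , drop = FALSE]
  ca <- ca_coords(s, res$key)
  if (any(!is.finite(ca[, 1]))) {
    stop("unresolved CDR3 residue (missing CA) in chain '", chain_id, "'",
         call. = FALSE)
  }
  # flanking anchor residues in chain order, when present
  anchors <- list(
    n_anchor = if (min(idx) > 1L) rt$key[min(idx) - 1L] else character(0),
    c_anchor = if (max(idx) < nrow(rt)) rt$key[max(idx) + 1L] else character(0))
  # Fv sequence: all numbered chains, receptor chain (heavy/beta) first
  role_order <- c("heavy", "beta", "light", "alpha")
  fv_chains <- unique(numbering$chain[order(match(numbering$chain_role,
                                                  role_order))])
  fv_seq <- paste(vapply(fv_chains, function(chv) {
    paste(chain_residues(s, chv)$one, collapse = "")
  }, ""), collapse = "")
  loop_motif(res, ca, entry_id = s$entry_id, anchors = anchors,
             origin = CDR3_ORIGIN[[chain_role]],
             altloc_state = if (is.null(s$altloc_state)) "" else s$altloc_state,
             fv_sequence = fv_seq)
}

#' Write loop motifs as JSON lines
#'
#' One motif per line with residue identifiers, sequence, CA coordinates,
#' anchors and provenance; [read_motifs_jsonl()] restores them.
#'
#' @param motifs List of `LoopMotif`s.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_motifs_jsonl <- function(motifs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (m in motifs) {
    rec <- list(entry_id = m$entry_id, chain = m$chain,
                sequence = m$sequence, origin = m$origin,
                altloc_state = m$altloc_state,
                fv_sequence = m$fv_sequence,
                residues = m$residues[, c("chain", "resno", "insert", "resid")],
                ca = m$ca, anchors = m$anchors)
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA,
                                null = "null"), con)
  }
  invisible(path)
}

#' Read loop motifs from JSON lines
#'
#' @param path File written by [write_motifs_jsonl()].
#' @return List of `LoopMotif`s.
#' @export
read_motifs_jsonl <- function(path) {
  lapply(readLines(path, warn = FALSE), function(line) {
    rec <- jsonlite::fromJSON(line)
    res <- as.data.frame(rec$residues, stringsAsFactors = FALSE)
    res$resno <- as.integer(res$resno)
    res$insert <- ifelse(is.na(res$insert), "", res$insert)
    res$one <- aa_one_letter(res$resid)
    res$key <- res_key(res$chain, res$resno, res$insert)
    anchors <- lapply(rec$anchors, function(a) unlist(a))
    loop_motif(res, matrix(unlist(rec$ca), ncol = 3,
                           byrow = is.null(dim(rec$ca))),
               entry_id = rec$entry_id, anchors = anchors,
               origin = rec$origin,
               altloc_state = if (is.null(rec$altloc_state)) "" else rec$altloc_state,
               fv_sequence = rec$fv_sequence)
  })
}
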