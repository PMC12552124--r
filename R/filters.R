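# Entry-level and loop-level quality filters.

#' Entry filter criteria
#'
#' Mined entries are kept only when solved by X-ray crystallography with
#' resolution strictly below the cutoff (default 3.5 Angstrom).
#'
#' @param require_xray Require `experimental_method == "xray"`.
#' @param max_resolution Strict upper bound on resolution in Angstrom.
#' @return An `entry_filter_criteria` list.
#' @export
entry_filter_criteria <- function(require_xray = TRUE, max_resolution = 3.5) {
  stopifnot(max_resolution > 0)
  structure(list(require_xray = require_xray,
                 max_resolution = max_resolution),
            class = "entry_filter_criteria")
}

#' Entry-level quality filter
#'
#' @param s A `StructureModel`.
#' @param criteria An [entry_filter_criteria()].
#' @return `TRUE` iff the entry passes: X-ray method (when required) and a
#'   known resolution strictly under `max_resolution`.
#' @export
passes_entry_filter <- function(s, criteria = entry_filter_criteria()) {
  if (criteria$require_xray && s$experimental_method != "xray") return(FALSE)
  if (!is.finite(s$resolution)) return(FALSE)
  s$resolution < criteria$max_resolution
}

#' Loop filter criteria
#'
#' @param max_ss_residues_in_loop Maximum number of loop residues that may be
#'   labelled strand or helix (default 3).
#' @param min_length,max_length Allowed loop length range (defaults 1 and 87,
#'   the observed range in large-scale mining).
#' @param require_no_gaps Reject loops with unresolved residues (an author
#'   numbering gap inside the loop span, or a loop residue without CA).
#' @return A `loop_filter_criteria` list.
#' @export
loop_filter_criteria <- function(max_ss_residues_in_loop = 3L,
                                 min_length = 1L, max_length = 87L,
                                 require_no_gaps = TRUE) {
  stopifnot(min_length >= 1L, max_length >= min_length,
            max_ss_residues_in_loop >= 0L)
  structure(list(max_ss_residues_in_loop = as.integer(max_ss_residues_in_loop),
                 min_length = as.integer(min_length),
                 max_length = as.integer(max_length),
                 require_no_gaps = isTRUE(require_no_gaps)),
            class = "loop_filter_criteria")
}

#' Loop-level quality filter
#'
#' A loop passes when (i) at most `max_ss_residues_in_loop` of its residues
#' are labelled strand or helix in `ann`, (ii) its length lies in the
#' configured range and (iii), if `require_no_gaps`, no loop residue is
#' unresolved.
#'
#' @param motif A [loop_motif()].
#' @param ann An `SSAnnotation` covering the loop residues.
#' @param criteria A [loop_filter_criteria()].
#' @return Logical flag.
#' @export
passes_loop_filter <- function(motif, ann,
                               criteria = loop_filter_criteria()) {
  len <- motif$loop_length
  if (len < criteria$min_length || len > criteria$max_length) return(FALSE)
  ss <- ann$ss[match(motif$residues$key, ann$key)]
  n_ss <- sum(ss %in% c("strand", "helix"), na.rm = TRUE)
  if (n_ss > criteria$max_ss_residues_in_loop) return(FALSE)
  if (criteria$require_no_gaps && motif_has_gap(motif)) return(FALSE)
  TRUE
}

# Unresolved-loop test: missing CA, or a numbering gap between consecutive
# loop residues on the same chain (insertion-coded residues share a number).
motif_has_gap <- function(motif) {
  r <- motif$residues
  if (any(!is.finite(motif$ca[, 1]))) return(TRUE)
  if (nrow(r) < 2L) return(FALSE)
  for (i in seq_len(nrow(r) - 1L)) {
    if (r$chain[i] != r$chain[i + 1]) return(TRUE)
    step <- r$resno[i + 1] - r$resno[i]
    if (step > 1L) return(TRUE)
  }
  FALSE
}
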