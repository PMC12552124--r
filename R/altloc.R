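# Alternate-location handling.

#' Enumerate alternate-location states of a structure
#'
#' Crystal structures may model several positions for the same atom,
#' distinguished by altloc codes. Following crystallographic convention the
#' states are enumerated by code letter across the whole model: the A-state
#' keeps all blank-altloc atoms plus every atom coded `A`, the B-state the
#' blank atoms plus every atom coded `B`, and so on. Each returned model has
#' exactly one coordinate set per atom and a blank `alt` column; states are
#' stamped in `$altloc_state`.
#'
#' @param s A `StructureModel`.
#' @return List of `StructureModel`s, one per altloc state (length 1 when the
#'   input has no altloc codes).
#' @export
enumerate_altloc_states <- function(s) {
  codes <- sort(unique(s$atoms$alt[s$atoms$alt != ""]))
  if (length(codes) == 0L) {
    s$altloc_state <- ""
    return(list(s))
  }
  lapply(codes, function(code) {
    keep <- s$atoms$alt == "" | s$atoms$alt == code
    a <- s$atoms[keep, , drop = FALSE]
    a$alt <- ""
    out <- structure_model(a, entry_id = s$entry_id,
                           experimental_method = s$experimental_method,
                           resolution = s$resolution)
    out$altloc_state <- code
    out
  })
}
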