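# The StructureModel container: a flat atom table plus entry-level metadata.
# Kept deliberately close to the bio3d atom data.frame so conversion is cheap.

#' Construct a StructureModel
#'
#' A `StructureModel` holds the atoms of one structural model as a flat table
#' together with entry-level metadata (entry id, experimental method,
#' resolution). Residues are identified by `(chain, resno, insert)` and kept
#' in chain order; this is the container consumed by every downstream stage
#' (secondary-structure assignment, loop mining, graph building).
#'
#' @param atoms data.frame with columns `chain`, `resno` (integer author
#'   residue number), `insert` (insertion code, `""` if none), `resid`
#'   (3-letter residue name), `elety` (atom name, e.g. `"CA"`), `elesy`
#'   (element symbol), `x`,`y`,`z` (coordinates in Angstrom), `alt` (altloc
#'   code, `""` if none) and `occ` (occupancy).
#' @param entry_id Entry identifier (e.g. a 4-character PDB id).
#' @param experimental_method `"xray"` or `"other"`.
#' @param resolution Resolution in Angstrom, or `NA` when unknown.
#' @return An object of class `StructureModel`.
#' @export
structure_model <- function(atoms, entry_id = "XXXX",
                            experimental_method = c("other", "xray"),
                            resolution = NA_real_) {
  experimental_method <- match.arg(experimental_method)
  need <- c("chain", "resno", "insert", "resid", "elety", "elesy",
            "x", "y", "z", "alt", "occ")
  miss <- setdiff(need, names(atoms))
  if (length(miss) > 0L) {
    stop("atoms table is missing columns: ", paste(miss, collapse = ", "))
  }
  atoms <- as.data.frame(atoms)[, need]
  atoms$chain <- as.character(atoms$chain)
  atoms$resno <- as.integer(atoms$resno)
  atoms$insert <- ifelse(is.na(atoms$insert), "", as.character(atoms$insert))
  atoms$alt <- ifelse(is.na(atoms$alt), "", as.character(atoms$alt))
  atoms$occ <- ifelse(is.na(atoms$occ), 1, as.numeric(atoms$occ))
  if (nrow(atoms) > 0L && !all(is.finite(as.matrix(atoms[, c("x", "y", "z")])))) {
    stop("all atom coordinates must be finite")
  }
  # order residues by chain, number, insertion code (atoms keep file order
  # within a residue)
  ord <- order(atoms$chain, atoms$resno, atoms$insert)
  atoms <- atoms[ord, , drop = FALSE]
  rownames(atoms) <- NULL
  structure(
    list(entry_id = entry_id,
         experimental_method = experimental_method,
         resolution = resolution,
         atoms = atoms),
    class = "StructureModel"
  )
}

#' @export
print.StructureModel <- function(x, ...) {
  rt <- residue_table(x)
  cat("StructureModel", x$entry_id,
      sprintf("(%s%s)\n", x$experimental_method,
              if (is.finite(x$resolution))
                sprintf(", %.2f A", x$resolution) else ""))
  cat(" ", nrow(x$atoms), "atoms,", nrow(rt), "residues,",
      length(unique(rt$chain)), "chain(s)\n")
  invisible(x)
}

# Unique residue key strings, vectorised.
res_key <- function(chain, resno, insert) {
  paste(chain, resno, ifelse(is.na(insert) | insert == "", ".", insert),
        sep = ":")
}

#' Residue table of a StructureModel
#'
#' One row per residue in chain order, with its 3-letter name, 1-letter code
#' and a unique key `"chain:resno:insert"`.
#'
#' @param s A `StructureModel`.
#' @return data.frame with columns `chain`, `resno`, `insert`, `resid`,
#'   `one`, `key`.
#' @export
residue_table <- function(s) {
  a <- s$atoms
  key <- res_key(a$chain, a$resno, a$insert)
  first <- !duplicated(key)
  out <- data.frame(chain = a$chain[first], resno = a$resno[first],
                    insert = a$insert[first], resid = a$resid[first],
                    key = key[first], stringsAsFactors = FALSE)
  out$one <- aa_one_letter(out$resid)
  rownames(out) <- NULL
  out
}

# Coordinates of one named atom per residue (NA rows where absent).
# keys: residue keys in the desired order.
atom_coords <- function(s, keys, elety = "CA") {
  a <- s$atoms
  sel <- a$elety == elety
  akey <- res_key(a$chain, a$resno, a$insert)[sel]
  m <- match(keys, akey)
  out <- cbind(a$x[sel][m], a$y[sel][m], a$z[sel][m])
  colnames(out) <- c("x", "y", "z")
  out
}

#' C-alpha coordinates of selected residues
#'
#' @param s A `StructureModel`.
#' @param keys Residue keys (`"chain:resno:insert"`); defaults to all residues.
#' @return Numeric matrix (n x 3), rows `NA` where the residue has no CA atom.
#' @export
ca_coords <- function(s, keys = residue_table(s)$key) {
  atom_coords(s, keys, "CA")
}

# Residues of one chain, in order.
chain_residues <- function(s, chain_id) {
  rt <- residue_table(s)
  rt[rt$chain == chain_id, , drop = FALSE]
}
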