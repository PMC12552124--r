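# Reading and writing structure files.
#
# PDB records are parsed by bio3d; mmCIF files are read by a small internal
# _atom_site reader (generic loop_ tokenizer restricted to the categories we
# need). Entry metadata (experimental method, resolution) is scanned from the
# raw text in both dialects and recorded as "other"/NA when absent -- never
# guessed.

#' Read a structure file into a StructureModel
#'
#' Reads a PDB or mmCIF file (model 1 only for multi-model files) and returns
#' a [structure_model()]. Experimental method and resolution are taken from
#' the file metadata when present (`EXPDTA`/`REMARK 2` or
#' `_exptl.method`/`_refine.ls_d_res_high`); missing metadata is recorded as
#' method `"other"` and resolution `NA`.
#'
#' @param path Path to the file.
#' @param format `"pdb"` or `"mmcif"`; default guesses from the extension.
#' @return A `StructureModel`.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "mmcif" else if (ext %in% c("pdb", "ent")) "pdb"
    else stop("cannot guess format from extension '", ext,
              "'; pass format = \"pdb\" or \"mmcif\"")
  }
  lines <- readLines(path, warn = FALSE)
  if (format == "pdb") {
    pdb <- tryCatch(
      bio3d::read.pdb(path, rm.alt = FALSE, multi = FALSE, verbose = FALSE),
      error = function(e) stop("failed to parse PDB file '", path, "': ",
                               conditionMessage(e))
    )
    at <- pdb$atom[pdb$atom$type %in% c("ATOM", "HETATM"), , drop = FALSE]
    atoms <- data.frame(
      chain = ifelse(is.na(at$chain), "A", at$chain),
      resno = at$resno, insert = at$insert, resid = at$resid,
      elety = at$elety, elesy = at$elesy,
      x = at$x, y = at$y, z = at$z,
      alt = at$alt, occ = at$o, stringsAsFactors = FALSE)
    meta <- pdb_metadata(lines)
  } else {
    atoms <- read_mmcif_atoms(lines, path)
    meta <- mmcif_metadata(lines)
  }
  if (is.na(meta$entry_id)) {
    meta$entry_id <- toupper(tools::file_path_sans_ext(basename(path)))
  }
  # non-xray entries should not carry a resolution per the model invariants
  structure_model(atoms, entry_id = meta$entry_id,
                  experimental_method = meta$method,
                  resolution = meta$resolution)
}

pdb_metadata <- function(lines) {
  method <- "other"
  resolution <- NA_real_
  entry_id <- NA_character_
  expdta <- grep("^EXPDTA", lines, value = TRUE)
  if (length(expdta) > 0L &&
      any(grepl("X-RAY DIFFRACTION", toupper(expdta), fixed = TRUE))) {
    method <- "xray"
  }
  rem2 <- grep("^REMARK   2 RESOLUTION", lines, value = TRUE)
  if (length(rem2) > 0L) {
    m <- regmatches(rem2[1],
                    regexpr("[0-9]+\\.?[0-9]*(?=[[:space:]]*ANGSTROM)",
                            rem2[1], perl = TRUE))
    if (length(m) == 1L) resolution <- as.numeric(m)
  }
  header <- grep("^HEADER", lines, value = TRUE)
  if (length(header) > 0L && nchar(header[1]) >= 66) {
    id <- trimws(substr(header[1], 63, 66))
    if (nzchar(id)) entry_id <- id
  }
  list(method = method, resolution = resolution, entry_id = entry_id)
}

mmcif_metadata <- function(lines) {
  grab <- function(tag) {
    hit <- grep(paste0("^", tag, "[[:space:]]"), lines, value = TRUE)
    if (length(hit) == 0L) return(NA_character_)
    val <- trimws(sub(paste0("^", tag), "", hit[1]))
    gsub("^['\"]|['\"]$", "", val)
  }
  method <- "other"
  m <- grab("_exptl\\.method")
  if (!is.na(m) && grepl("X-RAY DIFFRACTION", toupper(m), fixed = TRUE)) {
    method <- "xray"
  }
  resolution <- NA_real_
  for (tag in c("_refine\\.ls_d_res_high", "_reflns\\.d_resolution_high")) {
    v <- suppressWarnings(as.numeric(grab(tag)))
    if (!is.na(v)) { resolution <- v; break }
  }
  entry_id <- grab("_entry\\.id")
  list(method = method, resolution = resolution, entry_id = entry_id)
}

# Minimal mmCIF _atom_site reader: finds the loop_ carrying _atom_site.*
# items and splits each data row on whitespace (honouring single/double
# quotes). Sufficient for the standard atom_site category written by gemmi,
# the wwPDB and this package.
read_mmcif_atoms <- function(lines, path = "<mmcif>") {
  i <- 1L; n <- length(lines)
  header <- character(0); rows <- character(0)
  while (i <= n) {
    if (grepl("^[[:space:]]*loop_[[:space:]]*$", lines[i])) {
      j <- i + 1L; hdr <- character(0)
      while (j <= n && grepl("^[[:space:]]*_", lines[j])) {
        hdr <- c(hdr, trimws(lines[j])); j <- j + 1L
      }
      if (any(grepl("^_atom_site\\.", hdr))) {
        header <- hdr
        while (j <= n && !grepl("^[[:space:]]*(loop_|_|#|data_)", lines[j]) &&
               nzchar(trimws(lines[j]))) {
          rows <- c(rows, lines[j]); j <- j + 1L
        }
        break
      }
      i <- j
    } else i <- i + 1L
  }
  if (length(header) == 0L) {
    stop("no _atom_site loop found in mmCIF file '", path, "'")
  }
  fields <- sub("^_atom_site\\.", "", header)
  toks <- lapply(rows, cif_tokens)
  bad <- which(vapply(toks, length, 1L) != length(fields))
  if (length(bad) > 0L) {
    stop("malformed _atom_site row ", bad[1], " in '", path,
         "': expected ", length(fields), " fields")
  }
  tab <- as.data.frame(do.call(rbind, toks), stringsAsFactors = FALSE)
  names(tab) <- fields
  col <- function(nm, default = NA_character_) {
    for (k in nm) if (k %in% fields) return(tab[[k]])
    rep(default, nrow(tab))
  }
  grp <- col("group_PDB", "ATOM")
  keep <- grp %in% c("ATOM", "HETATM")
  # model 1 only
  mdl <- col("pdbx_PDB_model_num", "1")
  keep <- keep & (mdl == mdl[which(keep)[1]])
  tab <- tab[keep, , drop = FALSE]
  dot <- function(v, repl = "") ifelse(v %in% c(".", "?") | is.na(v), repl, v)
  col2 <- function(nm, default = NA_character_) {
    for (k in nm) if (k %in% fields) return(tab[[k]])
    rep(default, nrow(tab))
  }
  data.frame(
    chain = dot(col2(c("auth_asym_id", "label_asym_id")), "A"),
    resno = as.integer(dot(col2(c("auth_seq_id", "label_seq_id")), NA)),
    insert = dot(col2("pdbx_PDB_ins_code")),
    resid = dot(col2(c("auth_comp_id", "label_comp_id"))),
    elety = gsub("\"", "", dot(col2(c("auth_atom_id", "label_atom_id")))),
    elesy = dot(col2("type_symbol")),
    x = as.numeric(col2("Cartn_x")),
    y = as.numeric(col2("Cartn_y")),
    z = as.numeric(col2("Cartn_z")),
    alt = dot(col2("label_alt_id")),
    occ = suppressWarnings(as.numeric(dot(col2("occupancy", "1"), "1"))),
    stringsAsFactors = FALSE)
}

cif_tokens <- function(line) {
  out <- character(0); i <- 1L; n <- nchar(line)
  while (i <= n) {
    ch <- substr(line, i, i)
    if (grepl("[[:space:]]", ch)) { i <- i + 1L; next }
    if (ch %in% c("'", "\"")) {
      j <- i + 1L
      while (j <= n && substr(line, j, j) != ch) j <- j + 1L
      out <- c(out, substr(line, i + 1L, j - 1L)); i <- j + 1L
    } else {
      j <- i
      while (j <= n && !grepl("[[:space:]]", substr(line, j, j))) j <- j + 1L
      out <- c(out, substr(line, i, j - 1L)); i <- j
    }
  }
  out
}

#' Write a StructureModel as a PDB file
#'
#' Writes ATOM records (via `bio3d::write.pdb`) preceded by `EXPDTA` and
#' `REMARK 2` metadata records so that [read_structure()] round-trips the
#' experimental method and resolution.
#'
#' @param s A `StructureModel`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_structure_pdb <- function(s, path) {
  a <- s$atoms
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp), add = TRUE)
  bio3d::write.pdb(
    file = tmp,
    xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
    type = rep("ATOM", nrow(a)),
    resno = a$resno, resid = a$resid, eleno = seq_len(nrow(a)),
    elety = a$elety, chain = a$chain,
    insert = ifelse(a$insert == "", NA, a$insert),
    alt = ifelse(a$alt == "", NA, a$alt),
    o = a$occ, b = rep(0, nrow(a)), elesy = a$elesy)
  body <- readLines(tmp, warn = FALSE)
  hdr <- c(
    sprintf("HEADER    LOOP MOTIF                              01-JAN-26   %-4s",
            substr(s$entry_id, 1, 4)),
    if (s$experimental_method == "xray") "EXPDTA    X-RAY DIFFRACTION",
    if (is.finite(s$resolution))
      sprintf("REMARK   2 RESOLUTION. %7.2f ANGSTROMS.", s$resolution))
  writeLines(c(hdr, body), path)
  invisible(path)
}
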