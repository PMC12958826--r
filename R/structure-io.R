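# PDB / mmCIF structure model reading and PDB writing. No structural
# package ships with the target library set, so the fixed-width PDB
# reader/writer and a minimal mmCIF _atom_site loop parser are implemented
# here. Only heavy atoms are kept; AlphaFold models store the per-residue
# confidence (pLDDT, 0-100) in the temperature-factor column, which is
# lifted onto each residue when `plddt_in_bfactor = TRUE`.

#' Read a structure model from PDB or mmCIF
#'
#' Parses the first model of a `.pdb` or `.cif` file into a flat atom
#' table. Hydrogens are dropped; author chain ids and author residue
#' numbering are preserved (AlphaFold and UniProt-based numbering agree on
#' author numbering). Alternate locations other than `''`/`'A'` are
#' skipped.
#'
#' @param path Path to a `.pdb` or `.cif`/`.mmcif` file (format detected
#'   from content).
#' @param plddt_in_bfactor If `TRUE`, the temperature-factor column is
#'   interpreted as pLDDT and exposed per atom/residue.
#' @return An object of class `sps_structure`: list with `atoms` (data
#'   frame: `chain`, `resno`, `resname`, `aa`, `atom`, `element`, `x`,
#'   `y`, `z`, `plddt`) and `source`.
#' @export
read_structure <- function(path, plddt_in_bfactor = FALSE) {
  if (!file.exists(path)) stop("bad structure file: not found", call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  nonempty <- lines[nzchar(trimws(lines))]
  if (length(nonempty) == 0L) stop("bad structure file: empty", call. = FALSE)
  atoms <- if (any(grepl("^data_", nonempty)) || any(grepl("^_atom_site\\.", nonempty))) {
    .parse_cif_atoms(lines)
  } else if (any(startsWith(lines, "ATOM") | startsWith(lines, "HETATM"))) {
    .parse_pdb_atoms(lines)
  } else {
    stop("bad structure file", call. = FALSE)
  }
  if (nrow(atoms) == 0L) stop("bad structure file: no atoms", call. = FALSE)
  atoms <- atoms[!(atoms$element %in% c("H", "D")), , drop = FALSE]
  atoms$aa <- unname(AA_3TO1[atoms$resname])
  atoms$aa[is.na(atoms$aa)] <- "X"
  if (!plddt_in_bfactor) atoms$plddt <- NA_real_
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, source = path), class = "sps_structure")
}

#' @noRd
.parse_pdb_atoms <- function(lines) {
  end_model <- which(startsWith(lines, "ENDMDL"))
  if (length(end_model)) lines <- lines[seq_len(end_model[1] - 1L)]
  rec <- lines[startsWith(lines, "ATOM") | startsWith(lines, "HETATM")]
  if (length(rec) == 0L) {
    return(data.frame(chain = character(0), resno = integer(0),
                      resname = character(0), atom = character(0),
                      element = character(0), x = numeric(0), y = numeric(0),
                      z = numeric(0), plddt = numeric(0),
                      stringsAsFactors = FALSE))
  }
  fx <- function(a, b) trimws(substr(rec, a, b))
  alt <- fx(17, 17)
  keep <- alt %in% c("", "A")
  rec <- rec[keep]
  fx <- function(a, b) trimws(substr(rec, a, b))
  atom_name <- fx(13, 16)
  element <- fx(77, 78)
  # infer element from the atom name when column 77-78 is absent
  noelem <- !nzchar(element)
  if (any(noelem)) {
    element[noelem] <- substr(gsub("[0-9']", "", atom_name[noelem]), 1, 1)
  }
  suppressWarnings(data.frame(
    chain = fx(22, 22),
    resno = as.integer(fx(23, 26)),
    resname = fx(18, 20),
    atom = atom_name,
    element = toupper(element),
    x = as.numeric(fx(31, 38)),
    y = as.numeric(fx(39, 46)),
    z = as.numeric(fx(47, 54)),
    plddt = as.numeric(fx(61, 66)),
    stringsAsFactors = FALSE
  ))
}

# Minimal mmCIF reader: locates the _atom_site loop and tokenizes rows.
#' @noRd
.parse_cif_atoms <- function(lines) {
  tag_idx <- grep("^_atom_site\\.", lines)
  if (length(tag_idx) == 0L) stop("bad structure file: no _atom_site loop", call. = FALSE)
  fields <- sub("^_atom_site\\.", "", trimws(lines[tag_idx]))
  body_start <- max(tag_idx) + 1L
  rows <- list()
  for (i in body_start:length(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) next
    if (startsWith(ln, "#") || startsWith(ln, "_") || startsWith(ln, "loop_") ||
        startsWith(ln, "data_")) break
    toks <- scan(text = ln, what = character(), quiet = TRUE)
    if (length(toks) != length(fields)) stop("bad structure file: malformed _atom_site row", call. = FALSE)
    rows[[length(rows) + 1L]] <- toks
  }
  if (length(rows) == 0L) stop("bad structure file: empty _atom_site loop", call. = FALSE)
  m <- do.call(rbind, rows)
  colnames(m) <- fields
  getcol <- function(...) {
    for (nm in c(...)) if (nm %in% fields) return(m[, nm])
    rep(NA_character_, nrow(m))
  }
  model_num <- getcol("pdbx_PDB_model_num")
  keep <- if (all(is.na(model_num))) rep(TRUE, nrow(m)) else model_num == model_num[1]
  grp <- getcol("group_PDB")
  if (!all(is.na(grp))) keep <- keep & grp %in% c("ATOM", "HETATM")
  alt <- getcol("label_alt_id")
  if (!all(is.na(alt))) keep <- keep & alt %in% c(".", "?", "A", "")
  m <- m[keep, , drop = FALSE]
  suppressWarnings(data.frame(
    chain = getcol("auth_asym_id", "label_asym_id"),
    resno = as.integer(getcol("auth_seq_id", "label_seq_id")),
    resname = getcol("auth_comp_id", "label_comp_id"),
    atom = gsub('"', "", getcol("auth_atom_id", "label_atom_id"), fixed = TRUE),
    element = toupper(getcol("type_symbol")),
    x = as.numeric(getcol("Cartn_x")),
    y = as.numeric(getcol("Cartn_y")),
    z = as.numeric(getcol("Cartn_z")),
    plddt = as.numeric(getcol("B_iso_or_equiv")),
    stringsAsFactors = FALSE
  ))
}

#' @export
print.sps_structure <- function(x, ...) {
  a <- x$atoms
  ch <- unique(a$chain)
  nres <- sum(!duplicated(a[c("chain", "resno")]))
  cat("<sps_structure> ", length(ch), " chain(s) [",
      paste(ch, collapse = ","), "], ", nres, " residues, ",
      nrow(a), " heavy atoms\n", sep = "")
  invisible(x)
}

#' Build a structure model from an atom table
#'
#' @param atoms Data frame with columns `chain`, `resno`, `resname`,
#'   `atom`, `element`, `x`, `y`, `z` and optionally `plddt`.
#' @param source Free-text provenance label.
#' @return An `sps_structure`.
#' @export
new_structure <- function(atoms, source = "in-memory") {
  need <- c("chain", "resno", "resname", "atom", "element", "x", "y", "z")
  stopifnot(all(need %in% names(atoms)))
  if (!"plddt" %in% names(atoms)) atoms$plddt <- NA_real_
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    stop("non-finite coordinates", call. = FALSE)
  }
  atoms$aa <- unname(AA_3TO1[atoms$resname])
  atoms$aa[is.na(atoms$aa)] <- "X"
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, source = source), class = "sps_structure")
}

#' Write a structure model as PDB
#'
#' Coordinates are written at the standard PDB precision (0.001 A).
#'
#' @param model An `sps_structure`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path) {
  a <- model$atoms
  b <- ifelse(is.na(a$plddt), 0, a$plddt)
  lines <- sprintf(
    "ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(a)),
    ifelse(nchar(a$atom) < 4, paste0(" ", a$atom), a$atom),
    a$resname, a$chain, a$resno, a$x, a$y, a$z, 1.0, b, a$element
  )
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Extract the one-letter sequence of a chain
#'
#' @param model An `sps_structure`.
#' @param chain Chain id; defaults to the first chain.
#' @return Named character vector of one-letter codes, names are residue
#'   numbers.
#' @export
structure_sequence <- function(model, chain = model$atoms$chain[1]) {
  a <- model$atoms[model$atoms$chain == chain, , drop = FALSE]
  a <- a[!duplicated(a$resno), , drop = FALSE]
  a <- a[order(a$resno), , drop = FALSE]
  setNames(a$aa, a$resno)
}

#' Read a per-residue score track
#'
#' Two-column whitespace-separated text: residue number, score. Lines
#' starting with `#` are ignored.
#'
#' @param path File path.
#' @param kind `"disorder"` (scores in `[0, 1]`) or `"plddt"` (`[0, 100]`).
#' @return Data frame `residue`, `score`, with attribute `"kind"`.
#' @export
read_score_track <- function(path, kind = c("disorder", "plddt")) {
  kind <- match.arg(kind)
  df <- read.table(path, header = FALSE, comment.char = "#",
                   col.names = c("residue", "score"))
  new_score_track(df$residue, df$score, kind)
}

#' Build a score track in memory
#'
#' @param residue Integer residue numbers (strictly increasing).
#' @param score Numeric scores, same length.
#' @param kind `"disorder"` or `"plddt"`.
#' @return Data frame `residue`, `score` with attribute `"kind"`.
#' @export
new_score_track <- function(residue, score, kind = c("disorder", "plddt")) {
  kind <- match.arg(kind)
  stopifnot(length(residue) == length(score))
  if (is.unsorted(residue, strictly = TRUE)) {
    stop("residue numbering must be strictly increasing", call. = FALSE)
  }
  rng <- if (kind == "disorder") c(0, 1) else c(0, 100)
  if (any(score < rng[1] - 1e-9 | score > rng[2] + 1e-9)) {
    stop("scores outside the range of kind '", kind, "'", call. = FALSE)
  }
  out <- data.frame(residue = as.integer(residue), score = as.numeric(score))
  attr(out, "kind") <- kind
  out
}
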