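# Amino-acid alphabets, similarity groups and residue chemistry tables
# shared across the sequence and structure modules.

#' @noRd
AA_STANDARD <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' @noRd
GAP_CHAR <- "-"

# Non-standard one-letter codes folded into X on input.
#' @noRd
AA_NONSTANDARD <- c("B", "Z", "U", "O", "J")

#' Default physico-chemical similarity groups
#'
#' Used by [column_profiles()] (group conservation) and
#' [pairwise_identity_similarity()] (similarity percentage). Two residues
#' are "similar" when they fall in the same group: aliphatic/hydrophobic
#' \{A,V,L,I,M\}, aromatic \{F,W,Y\}, basic \{K,R,H\}, acidic \{D,E\},
#' polar \{S,T,N,Q\}, and glycine, proline and cysteine each on their own.
#' The grouping is a conventional physico-chemical partition, exposed so
#' that callers can substitute their own.
#'
#' @return A named list of character vectors partitioning the 20 standard
#'   amino acids.
#' @examples
#' similarity_groups()$aliphatic
#' @export
similarity_groups <- function() {
  list(
    aliphatic = c("A", "V", "L", "I", "M"),
    aromatic  = c("F", "W", "Y"),
    basic     = c("K", "R", "H"),
    acidic    = c("D", "E"),
    polar     = c("S", "T", "N", "Q"),
    glycine   = "G",
    proline   = "P",
    cysteine  = "C"
  )
}

# group id per letter (NA for letters outside all groups, e.g. X)
#' @noRd
.group_index <- function(groups = similarity_groups()) {
  idx <- setNames(rep(NA_integer_, 26), LETTERS)
  for (i in seq_along(groups)) idx[groups[[i]]] <- i
  idx
}

#' @noRd
AA_3TO1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V"
)

#' @noRd
AA_1TO3 <- setNames(names(AA_3TO1), unname(AA_3TO1))

# Backbone atom names; everything else on a residue is side chain.
#' @noRd
BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

# Charged-group atoms used for salt-bridge geometry (basic side: N atoms,
# acidic side: carboxylate O atoms).
#' @noRd
CHARGED_GROUP_ATOMS <- list(
  K = "NZ",
  R = c("NE", "NH1", "NH2"),
  H = c("ND1", "NE2"),
  D = c("OD1", "OD2"),
  E = c("OE1", "OE2")
)

# Aromatic ring atoms whose centroid defines pi-pi geometry.
#' @noRd
RING_ATOMS <- list(
  F = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  Y = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  W = c("CG", "CD1", "NE1", "CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  H = c("CG", "ND1", "CD2", "CE1", "NE2")
)

#' @noRd
HYDROPHOBIC_AA <- c("A", "V", "L", "I", "M", "F", "W", "Y", "P")

# Sanitize a raw residue string: upper-case, fold non-standard letters to X.
# Returns the string; warns once per offending letter kind.
#' @noRd
sanitize_residues <- function(x, allow_gap = FALSE) {
  x <- toupper(x)
  chars <- strsplit(x, "", fixed = TRUE)[[1]]
  if (length(chars) == 0L) return(x)
  bad <- chars %in% AA_NONSTANDARD
  if (any(bad)) {
    warning("non-standard residue letter(s) ",
            paste(sort(unique(chars[bad])), collapse = ","),
            " mapped to X", call. = FALSE)
    chars[bad] <- "X"
  }
  ok <- chars %in% c(AA_STANDARD, "X") | (allow_gap & chars == GAP_CHAR)
  if (!all(ok)) {
    stop("illegal residue character(s): ",
         paste(sort(unique(chars[!ok])), collapse = ","), call. = FALSE)
  }
  paste(chars, collapse = "")
}
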