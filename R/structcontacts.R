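# Typed noncovalent contact detection on structure models. All criteria
# are heavy-atom (or ring-centroid) distance cutoffs: the models analysed
# here (AlphaFold / Phyre2) carry no hydrogens, so no angular terms are
# applied. Salt bridges use the charged-group atom convention (Lys NZ;
# Arg NE/NH1/NH2; His ND1/NE2; Asp OD1/OD2; Glu OE1/OE2).

# ---- atom scoping -------------------------------------------------------

# atoms of one residue under a scope; data frame subset of model$atoms
#' @noRd
.residue_atoms <- function(model, chain, resno,
                           scope = c("all_heavy", "side_chain",
                                     "charged_group", "SG_only", "donor_acceptor")) {
  scope <- match.arg(scope)
  a <- model$atoms
  sel <- a$chain == chain & a$resno == resno
  if (!any(sel)) stop("residue not found: ", chain, resno, call. = FALSE)
  a <- a[sel, , drop = FALSE]
  out <- switch(scope,
    all_heavy = a,
    side_chain = a[!(a$atom %in% BACKBONE_ATOMS), , drop = FALSE],
    charged_group = {
      want <- CHARGED_GROUP_ATOMS[[a$aa[1]]]
      if (is.null(want)) a[0, , drop = FALSE] else a[a$atom %in% want, , drop = FALSE]
    },
    SG_only = a[a$atom == "SG", , drop = FALSE],
    donor_acceptor = a[a$element %in% c("N", "O"), , drop = FALSE]
  )
  out
}

# parse residue selector: list(chain=,resno=) or "A:123" or plain number
#' @noRd
.res_selector <- function(model, sel) {
  if (is.list(sel)) return(list(chain = sel$chain, resno = as.integer(sel$resno)))
  if (is.character(sel) && grepl(":", sel, fixed = TRUE)) {
    parts <- strsplit(sel, ":", fixed = TRUE)[[1]]
    return(list(chain = parts[1], resno = as.integer(parts[2])))
  }
  list(chain = model$atoms$chain[1], resno = as.integer(sel))
}

#' Minimum distance between two residues
#'
#' Minimum pairwise Euclidean distance between the scoped atom sets of two
#' residues, with the atom pair that achieves it.
#'
#' @param model An `sps_structure`.
#' @param res_a,res_b Residue selectors: a residue number (first chain), a
#'   `"chain:resno"` string, or `list(chain=, resno=)`.
#' @param atom_scope One of `"all_heavy"`, `"side_chain"`,
#'   `"charged_group"`, `"SG_only"`.
#' @return List with `distance` (Angstrom) and `atoms` (character vector
#'   of the two atom names).
#' @export
residue_min_distance <- function(model, res_a, res_b,
                                 atom_scope = "all_heavy") {
  sa <- .res_selector(model, res_a)
  sb <- .res_selector(model, res_b)
  aa <- .residue_atoms(model, sa$chain, sa$resno, atom_scope)
  ab <- .residue_atoms(model, sb$chain, sb$resno, atom_scope)
  if (nrow(aa) == 0L || nrow(ab) == 0L) stop("no atoms in scope", call. = FALSE)
  .min_atom_distance(aa, ab)
}

# min distance between two atom tables; returns list(distance, atoms)
#' @noRd
.min_atom_distance <- function(aa, ab) {
  pa <- as.matrix(aa[, c("x", "y", "z")])
  pb <- as.matrix(ab[, c("x", "y", "z")])
  d2 <- outer(rowSums(pa^2), rowSums(pb^2), "+") - 2 * pa %*% t(pb)
  d2[d2 < 0] <- 0
  idx <- arrayInd(which.min(d2), dim(d2))
  list(distance = sqrt(d2[idx]), atoms = c(aa$atom[idx[1]], ab$atom[idx[2]]))
}

# unique residues of a model as a data frame (chain, resno, aa), ordered
#' @noRd
.residue_table <- function(model) {
  a <- model$atoms
  r <- a[!duplicated(a[c("chain", "resno")]), c("chain", "resno", "aa")]
  r <- r[order(r$chain, r$resno), , drop = FALSE]
  rownames(r) <- NULL
  r
}

#' @noRd
.empty_edges <- function() {
  data.frame(kind = character(0), chain_a = character(0), resno_a = integer(0),
             aa_a = character(0), chain_b = character(0), resno_b = integer(0),
             aa_b = character(0), distance = numeric(0), atom_a = character(0),
             atom_b = character(0), stringsAsFactors = FALSE)
}

#' @noRd
.edge_row <- function(kind, ra, rb, d, atoms) {
  data.frame(kind = kind, chain_a = ra$chain, resno_a = ra$resno, aa_a = ra$aa,
             chain_b = rb$chain, resno_b = rb$resno, aa_b = rb$aa,
             distance = d, atom_a = atoms[1], atom_b = atoms[2],
             stringsAsFactors = FALSE)
}

# generic pair scan between two residue subsets, scoped per side
#' @noRd
.pair_scan <- function(model, res_a, res_b, scope_a, scope_b, cutoff, kind,
                       exclude_same = TRUE, min_seq_sep = 0L) {
  out <- list()
  for (i in seq_len(nrow(res_a))) {
    ra <- res_a[i, ]
    aa <- .residue_atoms(model, ra$chain, ra$resno, scope_a)
    if (nrow(aa) == 0L) next
    for (j in seq_len(nrow(res_b))) {
      rb <- res_b[j, ]
      if (exclude_same && ra$chain == rb$chain && ra$resno == rb$resno) next
      if (min_seq_sep > 0L && ra$chain == rb$chain &&
          abs(ra$resno - rb$resno) < min_seq_sep) next
      ab <- .residue_atoms(model, rb$chain, rb$resno, scope_b)
      if (nrow(ab) == 0L) next
      md <- .min_atom_distance(aa, ab)
      if (md$distance <= cutoff) {
        out[[length(out) + 1L]] <- .edge_row(kind, ra, rb, md$distance, md$atoms)
      }
    }
  }
  if (length(out) == 0L) return(.empty_edges())
  do.call(rbind, out)
}

# ---- detectors ----------------------------------------------------------

#' Detect salt bridges
#'
#' All (Lys/Arg/His charged-group nitrogen) x (Asp/Glu carboxylate oxygen)
#' residue pairs whose minimum charged-group atom distance is at most
#' `cutoff`; one edge per residue pair, at the minimum distance.
#'
#' @param model An `sps_structure`.
#' @param cutoff Distance cutoff in Angstrom.
#' @return Edge data frame (see [residue_min_distance()] conventions):
#'   `kind`, residue a/b (`chain_a`, `resno_a`, `aa_a`, ...), `distance`,
#'   `atom_a`, `atom_b`. Basic residue first.
#' @export
detect_salt_bridges <- function(model, cutoff = 4.5) {
  r <- .residue_table(model)
  basic <- r[r$aa %in% c("K", "R", "H"), , drop = FALSE]
  acidic <- r[r$aa %in% c("D", "E"), , drop = FALSE]
  if (nrow(basic) == 0L || nrow(acidic) == 0L) return(.empty_edges())
  .pair_scan(model, basic, acidic, "charged_group", "charged_group",
             cutoff, "salt_bridge")
}

#' Detect hydrogen-bond proxy pairs
#'
#' N/O donor-acceptor heavy-atom pairs (side chain and backbone) within
#' `cutoff`. With no hydrogens in the models, no angular criterion is
#' applied; the default 3.6 A covers reported H-bonds up to 3.1 A with
#' margin. In the exhaustive scan, residue pairs adjacent in sequence are
#' skipped (the peptide bond places backbone N/O trivially close);
#' explicitly requested `pairs` are always measured.
#'
#' @param model An `sps_structure`.
#' @param pairs Optional list of residue-selector pairs
#'   (`list(list(a, b), ...)`) restricting the scan.
#' @param cutoff Distance cutoff in Angstrom.
#' @return Edge data frame with kind `"hbond"`.
#' @export
detect_hbond_pairs <- function(model, pairs = NULL, cutoff = 3.6) {
  if (!is.null(pairs)) {
    out <- lapply(pairs, function(pr) {
      sa <- .res_selector(model, pr[[1]])
      sb <- .res_selector(model, pr[[2]])
      aa <- .residue_atoms(model, sa$chain, sa$resno, "donor_acceptor")
      ab <- .residue_atoms(model, sb$chain, sb$resno, "donor_acceptor")
      if (nrow(aa) == 0L || nrow(ab) == 0L) return(NULL)
      md <- .min_atom_distance(aa, ab)
      if (md$distance > cutoff) return(NULL)
      r <- .residue_table(model)
      ra <- r[r$chain == sa$chain & r$resno == sa$resno, ]
      rb <- r[r$chain == sb$chain & r$resno == sb$resno, ]
      .edge_row("hbond", ra, rb, md$distance, md$atoms)
    })
    out <- out[!vapply(out, is.null, logical(1))]
    if (length(out) == 0L) return(.empty_edges())
    return(do.call(rbind, out))
  }
  r <- .residue_table(model)
  edges <- .pair_scan(model, r, r, "donor_acceptor", "donor_acceptor",
                      cutoff, "hbond", min_seq_sep = 2L)
  # symmetric scan reports each pair twice; keep one direction
  if (nrow(edges)) {
    key_a <- paste(edges$chain_a, edges$resno_a)
    key_b <- paste(edges$chain_b, edges$resno_b)
    edges <- edges[key_a < key_b | (key_a == key_b & edges$resno_a < edges$resno_b), ,
                   drop = FALSE]
    ord <- order(edges$chain_a, edges$resno_a, edges$chain_b, edges$resno_b)
    edges <- edges[ord, , drop = FALSE]
    rownames(edges) <- NULL
  }
  edges
}

#' Detect pi-pi stacking pairs
#'
#' Aromatic (Phe/Tyr/Trp/His) ring-centroid pairs within
#' `centroid_cutoff`. The centroid is the mean of the ring heavy atoms.
#'
#' @param model An `sps_structure`.
#' @param centroid_cutoff Centroid-centroid cutoff in Angstrom.
#' @return Edge data frame with kind `"pipi"`; `atom_a`/`atom_b` are
#'   `"ring"`.
#' @export
detect_pipi <- function(model, centroid_cutoff = 5.5) {
  r <- .residue_table(model)
  arom <- r[r$aa %in% names(RING_ATOMS), , drop = FALSE]
  if (nrow(arom) < 2L) return(.empty_edges())
  cents <- t(vapply(seq_len(nrow(arom)), function(i) {
    ra <- arom[i, ]
    at <- .residue_atoms(model, ra$chain, ra$resno, "all_heavy")
    at <- at[at$atom %in% RING_ATOMS[[ra$aa]], , drop = FALSE]
    if (nrow(at) == 0L) return(c(NA_real_, NA_real_, NA_real_))
    c(mean(at$x), mean(at$y), mean(at$z))
  }, numeric(3)))
  out <- list()
  for (i in seq_len(nrow(arom) - 1L)) {
    for (j in (i + 1L):nrow(arom)) {
      if (anyNA(cents[i, ]) || anyNA(cents[j, ])) next
      d <- sqrt(sum((cents[i, ] - cents[j, ])^2))
      if (d <= centroid_cutoff) {
        out[[length(out) + 1L]] <-
          .edge_row("pipi", arom[i, ], arom[j, ], d, c("ring", "ring"))
      }
    }
  }
  if (length(out) == 0L) return(.empty_edges())
  do.call(rbind, out)
}

#' Detect hydrophobic or sulfur residue clusters
#'
#' Single-linkage clusters over residue contacts: hydrophobic clusters use
#' side-chain heavy atoms of A/V/L/I/M/F/W/Y/P (default cutoff 4.5 A);
#' sulfur clusters use cysteine SG atoms (default 4.0 A, capturing e.g. a
#' metal-binding Cys cluster with ~3.5 A S-S spacing). Deterministic:
#' residues and clusters are ordered by (chain, residue number).
#'
#' @param model An `sps_structure`.
#' @param kind `"hydrophobic"` or `"sulfur"`.
#' @param contact_cutoff Contact cutoff in Angstrom; defaults to 4.5
#'   (hydrophobic) or 4.0 (sulfur).
#' @param min_size Minimum cluster size.
#' @return List of clusters; each is a list with `kind`, `members` (data
#'   frame `chain`, `resno`, `aa`) and `max_internal_gap` (largest
#'   nearest-neighbour distance within the cluster, Angstrom).
#' @export
detect_clusters <- function(model, kind = c("hydrophobic", "sulfur"),
                            contact_cutoff = NULL, min_size = 2L) {
  kind <- match.arg(kind)
  if (is.null(contact_cutoff)) {
    contact_cutoff <- if (kind == "hydrophobic") 4.5 else 4.0
  }
  r <- .residue_table(model)
  scope <- if (kind == "hydrophobic") "side_chain" else "SG_only"
  r <- if (kind == "hydrophobic") {
    r[r$aa %in% HYDROPHOBIC_AA, , drop = FALSE]
  } else {
    r[r$aa == "C", , drop = FALSE]
  }
  n <- nrow(r)
  if (n < min_size) return(list())
  atom_sets <- lapply(seq_len(n), function(i)
    .residue_atoms(model, r$chain[i], r$resno[i], scope))
  nonempty <- vapply(atom_sets, nrow, integer(1)) > 0L
  r <- r[nonempty, , drop = FALSE]
  atom_sets <- atom_sets[nonempty]
  n <- nrow(r)
  if (n < min_size) return(list())
  dmat <- matrix(Inf, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i < j) {
        dmat[i, j] <- dmat[j, i] <-
          .min_atom_distance(atom_sets[[i]], atom_sets[[j]])$distance
      }
    }
  }
  # union-find single linkage at the cutoff
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i < j && dmat[i, j] <= contact_cutoff) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  clusters <- list()
  for (cid in sort(unique(comp))) {
    idx <- which(comp == cid)
    if (length(idx) < min_size) next
    nn <- vapply(idx, function(i) min(dmat[i, setdiff(idx, i)]), numeric(1))
    clusters[[length(clusters) + 1L]] <- list(
      kind = kind,
      members = r[idx, , drop = FALSE],
      max_internal_gap = max(nn)
    )
  }
  clusters
}

#' Segment a score track by threshold
#'
#' Reports maximal runs of consecutive residues whose (optionally
#' moving-average smoothed) score lies on the stated side of `threshold`,
#' keeping runs of at least `min_length` residues. Runs break at gaps in
#' the residue numbering. Used e.g. to call intrinsically disordered
#' regions from a disorder track or low-confidence segments from a pLDDT
#' track.
#'
#' @param track A score track from [read_score_track()] /
#'   [new_score_track()].
#' @param threshold Threshold on the (smoothed) score.
#' @param direction `"above"` (score >= threshold) or `"below"`
#'   (score <= threshold).
#' @param min_length Minimum segment length in residues.
#' @param smooth_window Odd moving-average window; 1 = no smoothing.
#'   Edge positions use the partial window that fits.
#' @return Data frame `start`, `end`, `mean_score` (mean raw score over
#'   the segment).
#' @export
segment_track <- function(track, threshold, direction = c("above", "below"),
                          min_length = 10L, smooth_window = 1L) {
  direction <- match.arg(direction)
  stopifnot(smooth_window >= 1L, smooth_window %% 2L == 1L)
  res <- track$residue
  sc <- track$score
  n <- length(sc)
  half <- (smooth_window - 1L) %/% 2L
  smoothed <- if (half == 0L) sc else vapply(seq_len(n), function(i) {
    mean(sc[max(1L, i - half):min(n, i + half)])
  }, numeric(1))
  ok <- if (direction == "above") smoothed >= threshold else smoothed <= threshold
  # break runs at numbering gaps
  newrun <- c(TRUE, diff(res) != 1L)
  run_id <- cumsum(newrun | c(TRUE, diff(ok) != 0L))
  segs <- list()
  for (g in unique(run_id)) {
    idx <- which(run_id == g)
    if (!ok[idx[1]]) next
    if (length(idx) < min_length) next
    segs[[length(segs) + 1L]] <- data.frame(
      start = res[idx[1]], end = res[idx[length(idx)]],
      mean_score = mean(sc[idx])
    )
  }
  if (length(segs) == 0L) {
    return(data.frame(start = integer(0), end = integer(0),
                      mean_score = numeric(0)))
  }
  do.call(rbind, segs)
}
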