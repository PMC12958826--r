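# Seeded synthetic fixtures with machine-readable planted ground truth.
# Realism is not the goal: controllable geometry is. Residues use
# idealized one-rotamer templates; structures place residues on a widely
# spaced line (40 A) so that un-planted residue pairs stay > 8 A apart,
# then rigid-translate planted partners so that the scoped atom-pair
# distance equals the request exactly.

# ---- residue templates --------------------------------------------------

# idealized heavy-atom template, CA at origin; data frame atom/element/xyz
#' @noRd
.residue_template <- function(aa) {
  bb <- data.frame(
    atom = c("N", "CA", "C", "O"),
    x = c(-1.458, 0, 1.207, 1.767),
    y = c(0.0, 0, 0.850, 1.900),
    z = c(0.45, 0, 0.45, 0.45),
    stringsAsFactors = FALSE
  )
  chain_atoms <- function(names) {
    k <- seq_along(names)
    data.frame(atom = names, x = 0.25 * (-1)^k, y = -1.5 * k, z = 0,
               stringsAsFactors = FALSE)
  }
  ring <- function(names, attach_y, radius = 1.39) {
    # first atom at the top of the ring, centre directly below the chain
    ang <- pi / 2 + 2 * pi * (seq_along(names) - 1) / length(names)
    cy <- attach_y - radius
    data.frame(atom = names, x = radius * cos(ang), y = cy + radius * sin(ang),
               z = 0, stringsAsFactors = FALSE)
  }
  sc <- switch(aa,
    G = NULL,
    A = chain_atoms("CB"),
    S = chain_atoms(c("CB", "OG")),
    C = chain_atoms(c("CB", "SG")),
    T = rbind(chain_atoms(c("CB", "OG1")),
              data.frame(atom = "CG2", x = 1.25, y = -1.9, z = 0)),
    V = rbind(chain_atoms(c("CB", "CG1")),
              data.frame(atom = "CG2", x = 1.25, y = -1.9, z = 0)),
    L = rbind(chain_atoms(c("CB", "CG", "CD1")),
              data.frame(atom = "CD2", x = 1.25, y = -3.2, z = 0)),
    I = rbind(chain_atoms(c("CB", "CG1", "CD1")),
              data.frame(atom = "CG2", x = 1.25, y = -1.9, z = 0)),
    M = chain_atoms(c("CB", "CG", "SD", "CE")),
    P = chain_atoms(c("CB", "CG", "CD")),
    K = chain_atoms(c("CB", "CG", "CD", "CE", "NZ")),
    D = rbind(chain_atoms(c("CB", "CG", "OD1")),
              data.frame(atom = "OD2", x = 1.25, y = -3.2, z = 0)),
    E = rbind(chain_atoms(c("CB", "CG", "CD", "OE1")),
              data.frame(atom = "OE2", x = 1.25, y = -4.7, z = 0)),
    N = rbind(chain_atoms(c("CB", "CG", "OD1")),
              data.frame(atom = "ND2", x = 1.25, y = -3.2, z = 0)),
    Q = rbind(chain_atoms(c("CB", "CG", "CD", "OE1")),
              data.frame(atom = "NE2", x = 1.25, y = -4.7, z = 0)),
    R = rbind(chain_atoms(c("CB", "CG", "CD", "NE", "CZ")),
              data.frame(atom = c("NH1", "NH2"),
                         x = c(-1.0, 1.2), y = c(-8.2, -8.2), z = 0)),
    F = rbind(chain_atoms("CB"),
              ring(c("CG", "CD1", "CE1", "CZ", "CE2", "CD2"), -2.9)),
    Y = rbind(chain_atoms("CB"),
              ring(c("CG", "CD1", "CE1", "CZ", "CE2", "CD2"), -2.9),
              data.frame(atom = "OH", x = 0, y = -2.9 - 2 * 1.39 - 1.36, z = 0)),
    H = rbind(chain_atoms("CB"),
              ring(c("CG", "ND1", "CE1", "NE2", "CD2"), -2.9, radius = 1.17)),
    W = rbind(chain_atoms("CB"),
              ring(c("CG", "CD1", "NE1", "CE2", "CD2"), -2.9, radius = 1.17),
              ring(c("CE3", "CZ3", "CH2", "CZ2"), -2.9 - 2.3, radius = 1.39)),
    stop("no template for residue type ", aa, call. = FALSE)
  )
  tpl <- rbind(bb, sc)
  tpl$element <- substr(gsub("[0-9]", "", tpl$atom), 1, 1)
  tpl$element[tpl$atom %in% c("CA", "CB", "CG", "CG1", "CG2", "CD", "CD1",
                              "CD2", "CE", "CE1", "CE2", "CE3", "CZ", "CZ2",
                              "CZ3", "CH2")] <- "C"
  tpl
}

# scope used to realize each planted contact kind
#' @noRd
.plant_scope <- function(kind) {
  switch(kind,
    salt_bridge = "charged_group",
    hbond = "donor_acceptor",
    hydrophobic_contact = "side_chain",
    sulfur_pair = "SG_only",
    pipi = "ring",
    stop("unknown contact kind: ", kind, call. = FALSE)
  )
}

#' @noRd
.scoped_coords <- function(model, chain, resno, scope) {
  if (scope == "ring") {
    a <- model$atoms
    sel <- a$chain == chain & a$resno == resno
    aa1 <- a$aa[sel][1]
    at <- a[sel & a$atom %in% RING_ATOMS[[aa1]], , drop = FALSE]
    if (nrow(at) == 0L) stop("unsatisfiable plan: residue ", chain, resno,
                             " has no aromatic ring", call. = FALSE)
    matrix(c(mean(at$x), mean(at$y), mean(at$z)), nrow = 1)
  } else {
    at <- .residue_atoms(model, chain, resno, scope)
    if (nrow(at) == 0L) stop("unsatisfiable plan: residue ", chain, resno,
                             " has no atoms in scope ", scope, call. = FALSE)
    as.matrix(at[, c("x", "y", "z")])
  }
}

# Cycle of placement directions so several partners of one anchor do not
# collide.
#' @noRd
.PLANT_DIRS <- rbind(c(1, 0, 0), c(0, 1, 0), c(-1, 0, 0),
                     c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))

#' Generate a synthetic structure with planted contacts
#'
#' Residues from `residue_plan` are placed on a line with 40 A spacing
#' (plus a small seeded rigid jitter per residue), then each entry of
#' `contact_plan` rigid-translates the second residue so that the
#' contact-defining atom-set distance (charged group for salt bridges,
#' N/O atoms for H-bonds, side chain for hydrophobic contacts, SG for
#' sulfur pairs, ring centroid for pi-pi) equals the requested distance
#' exactly; the translation direction guarantees that no other scoped
#' atom pair is closer. Un-planted residue pairs stay > 8 A apart.
#'
#' @param residue_plan Data frame with columns `aa` (one-letter), `chain`,
#'   `number`.
#' @param contact_plan Optional data frame with columns `res_a`, `res_b`
#'   (residue numbers in the plan; for multi-chain plans use
#'   `"chain:resno"` selectors), `kind` (`salt_bridge`, `hbond`, `pipi`,
#'   `hydrophobic_contact`, `sulfur_pair`) and `distance` (Angstrom).
#' @param seed Integer seed; the generator is deterministic given it.
#' @param chain_offset Per-chain x offset in Angstrom.
#' @param path Optional output path; when given the model is written as
#'   PDB and the truth as JSON beside it (`<path>.truth.json`).
#' @return List with `model` (an `sps_structure`) and `truth` (planted
#'   ground truth: the contact plan, generation parameters and seed).
#' @export
synth_structure <- function(residue_plan, contact_plan = NULL, seed = 1L,
                            chain_offset = 120, path = NULL) {
  stopifnot(all(c("aa", "chain", "number") %in% names(residue_plan)))
  set.seed(seed)
  chains <- unique(residue_plan$chain)
  rows <- vector("list", nrow(residue_plan))
  for (i in seq_len(nrow(residue_plan))) {
    aa1 <- toupper(residue_plan$aa[i])
    tpl <- .residue_template(aa1)
    ch <- residue_plan$chain[i]
    slot <- sum(residue_plan$chain[seq_len(i)] == ch) - 1L
    base <- c(chain_offset * (match(ch, chains) - 1L) + runif(1, -0.5, 0.5),
              runif(1, -0.5, 0.5),
              40 * slot + runif(1, -0.5, 0.5))
    rows[[i]] <- data.frame(
      chain = ch, resno = residue_plan$number[i], resname = AA_1TO3[[aa1]],
      atom = tpl$atom, element = tpl$element,
      x = tpl$x + base[1], y = tpl$y + base[2], z = tpl$z + base[3],
      plddt = 90, stringsAsFactors = FALSE
    )
  }
  model <- new_structure(do.call(rbind, rows), source = "synthetic")
  truth_contacts <- NULL
  if (!is.null(contact_plan) && nrow(contact_plan)) {
    seen_partner <- character(0)
    anchor_count <- list()
    for (i in seq_len(nrow(contact_plan))) {
      pl <- contact_plan[i, ]
      sa <- .res_selector(model, pl$res_a)
      sb <- .res_selector(model, pl$res_b)
      key_b <- paste(sb$chain, sb$resno)
      key_a <- paste(sa$chain, sa$resno)
      if (key_b %in% seen_partner) {
        stop("unsatisfiable plan: residue ", key_b,
             " is the moved partner of two contacts", call. = FALSE)
      }
      seen_partner <- c(seen_partner, key_b)
      n_prev <- if (is.null(anchor_count[[key_a]])) 0L else anchor_count[[key_a]]
      anchor_count[[key_a]] <- n_prev + 1L
      u <- .PLANT_DIRS[(n_prev %% nrow(.PLANT_DIRS)) + 1L, ]
      scope <- .plant_scope(pl$kind)
      pa <- .scoped_coords(model, sa$chain, sa$resno, scope)
      pb <- .scoped_coords(model, sb$chain, sb$resno, scope)
      ia <- which.max(pa %*% u)
      ib <- which.min(pb %*% u)
      target <- pa[ia, ] + pl$distance * u
      shift <- target - pb[ib, ]
      sel <- model$atoms$chain == sb$chain & model$atoms$resno == sb$resno
      model$atoms$x[sel] <- model$atoms$x[sel] + shift[1]
      model$atoms$y[sel] <- model$atoms$y[sel] + shift[2]
      model$atoms$z[sel] <- model$atoms$z[sel] + shift[3]
    }
    truth_contacts <- contact_plan
  }
  truth <- list(kind = "contact", contacts = truth_contacts,
                n_residues = nrow(residue_plan), seed = seed)
  if (!is.null(path)) {
    write_structure(model, path)
    jsonlite::write_json(truth, paste0(path, ".truth.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  list(model = model, truth = truth)
}

#' Generate a synthetic multi-chain complex with a planted interface
#'
#' Thin wrapper over [synth_structure()]: chains are laid out with a large
#' x offset (default 120 A, so chains without planted contacts share no
#' interface), and `interface_plan` plants cross-chain contacts using
#' `"chain:resno"` selectors.
#'
#' @param chain_plans Named list of per-chain residue plans; each element
#'   is a data frame with `aa` and `number`, the name is the chain id.
#' @param interface_plan Optional contact plan as in [synth_structure()],
#'   with `"chain:resno"` selectors crossing chains.
#' @param seed Integer seed.
#' @param path Optional output PDB path (truth JSON written beside it).
#' @return List with `model` and `truth` (kind `"interface"`).
#' @export
synth_complex <- function(chain_plans, interface_plan = NULL, seed = 1L,
                          path = NULL) {
  stopifnot(is.list(chain_plans), !is.null(names(chain_plans)))
  plan <- do.call(rbind, lapply(names(chain_plans), function(ch) {
    data.frame(aa = chain_plans[[ch]]$aa, chain = ch,
               number = chain_plans[[ch]]$number, stringsAsFactors = FALSE)
  }))
  out <- synth_structure(plan, interface_plan, seed = seed, path = path)
  out$truth$kind <- "interface"
  out
}

#' Generate a synthetic alignment with planted boxes and motifs
#'
#' Background columns are drawn uniformly per row from the 20 standard
#' letters. Planted boxes copy the reference residue down each column with
#' per-row corruption probability `1 - identity_level`. Planted motifs
#' place a concrete peptide matching the pattern in the reference and in a
#' controlled fraction of ortholog rows; the remaining rows carry a
#' blocker letter (outside every class of the pattern) across the window
#' and its +/-2 slack so they cannot match.
#'
#' @param n_rows Number of rows (reference + `n_rows - 1` orthologs).
#' @param length Alignment length in columns (no indels are generated, so
#'   columns equal reference positions).
#' @param boxes Optional data frame `start`, `end`, `identity_level`.
#' @param motifs Optional data frame `consensus`, `ref_start`,
#'   `ortholog_fraction`.
#' @param seed Integer seed.
#' @param slack Guard width in residues around each motif window.
#' @return List with `aln` (an `sps_alignment`, reference id `"ref"`,
#'   ortholog ids `"orth1"`...) and `truth` (planted coordinates, the ids
#'   of motif-carrying rows, parameters, seed).
#' @export
synth_alignment <- function(n_rows, length, boxes = NULL, motifs = NULL,
                            seed = 1L, slack = 2L) {
  stopifnot(n_rows >= 1, length >= 1)
  set.seed(seed)
  occupied <- rep(FALSE, length)
  claim <- function(lo, hi, what) {
    lo <- max(1L, lo); hi <- min(length, hi)
    if (any(occupied[lo:hi])) {
      stop("overlapping contradictory plants (", what, ")", call. = FALSE)
    }
    occupied[lo:hi] <<- TRUE
  }
  if (!is.null(boxes) && nrow(boxes)) {
    for (i in seq_len(nrow(boxes))) {
      if (boxes$end[i] > length) stop("box outside alignment", call. = FALSE)
      claim(boxes$start[i], boxes$end[i], "box")
    }
  }
  m <- matrix(sample(AA_STANDARD, n_rows * length, replace = TRUE),
              nrow = n_rows)
  ids <- c("ref", if (n_rows > 1) paste0("orth", seq_len(n_rows - 1L)))
  motif_truth <- NULL
  if (!is.null(motifs) && nrow(motifs)) {
    motif_truth <- vector("list", nrow(motifs))
    for (i in seq_len(nrow(motifs))) {
      pat <- compile_pattern(motifs$consensus[i])
      s <- motifs$ref_start[i]
      e <- s + pat$length - 1L
      if (e > length) stop("motif outside alignment", call. = FALSE)
      claim(s - slack, e + slack, "motif")
      classes <- pat$elements[!vapply(pat$elements, is.null, logical(1))]
      if (length(classes) == 0L) {
        stop("motif pattern must contain at least one residue class",
             call. = FALSE)
      }
      blockers <- setdiff(AA_STANDARD, unique(unlist(classes)))
      if (length(blockers) == 0L) {
        stop("no blocker letter available for pattern", call. = FALSE)
      }
      blocker <- blockers[1]
      peptide <- vapply(pat$elements, function(el) {
        if (is.null(el)) sample(AA_STANDARD, 1) else el[sample.int(length(el), 1)]
      }, character(1))
      n_orth <- n_rows - 1L
      k <- round(motifs$ortholog_fraction[i] * n_orth)
      carriers <- if (n_orth > 0L && k > 0L) 1L + sample.int(n_orth, k) else integer(0)
      glo <- max(1L, s - slack); ghi <- min(length, e + slack)
      for (row in seq_len(n_rows)) {
        if (row == 1L || row %in% carriers) {
          m[row, s:e] <- peptide
        } else {
          m[row, glo:ghi] <- blocker
        }
      }
      motif_truth[[i]] <- list(
        consensus = motifs$consensus[i], ref_start = s, ref_end = e,
        peptide = paste(peptide, collapse = ""),
        planted_rows = ids[carriers],
        planned_fraction = if (n_orth > 0) k / n_orth else NA_real_
      )
    }
  }
  if (!is.null(boxes) && nrow(boxes)) {
    for (i in seq_len(nrow(boxes))) {
      cols <- boxes$start[i]:boxes$end[i]
      for (j in cols) {
        refch <- m[1L, j]
        for (row in seq_len(n_rows)[-1L]) {
          if (runif(1) <= boxes$identity_level[i]) {
            m[row, j] <- refch
          } else {
            m[row, j] <- sample(setdiff(AA_STANDARD, refch), 1)
          }
        }
      }
    }
  }
  seqs <- apply(m, 1, paste, collapse = "")
  aln <- new_alignment(ids, seqs, "ref")
  truth <- list(kind = "alignment", boxes = boxes, motifs = motif_truth,
                n_rows = n_rows, length = length, seed = seed)
  list(aln = aln, truth = truth)
}

#' Generate a synthetic score track with step structure
#'
#' A piecewise-constant track (`baseline` outside the given segments) plus
#' Gaussian noise, clipped to the score range of `kind`.
#'
#' @param segments Data frame `start`, `end`, `level`.
#' @param length Track length in residues.
#' @param noise_sd Gaussian noise standard deviation.
#' @param seed Integer seed.
#' @param kind `"disorder"` or `"plddt"`.
#' @param baseline Score outside the planted segments.
#' @return List with `track` (see [new_score_track()]) and `truth`.
#' @export
synth_track <- function(segments, length, noise_sd = 0, seed = 1L,
                        kind = c("disorder", "plddt"), baseline = 0.1) {
  kind <- match.arg(kind)
  set.seed(seed)
  stopifnot(all(segments$start >= 1), all(segments$end <= length),
            all(segments$start <= segments$end))
  sc <- rep(baseline, length)
  for (i in seq_len(nrow(segments))) {
    sc[segments$start[i]:segments$end[i]] <- segments$level[i]
  }
  if (noise_sd > 0) sc <- sc + rnorm(length, 0, noise_sd)
  rng <- if (kind == "disorder") c(0, 1) else c(0, 100)
  sc <- pmin(pmax(sc, rng[1]), rng[2])
  track <- new_score_track(seq_len(length), sc, kind)
  truth <- list(kind = "segment", segments = segments, length = length,
                noise_sd = noise_sd, baseline = baseline, seed = seed)
  list(track = track, truth = truth)
}
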