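# Mutation parsing/validation, structural neighbourhoods of mutated
# residues, and cross-chain interface mapping. Mutant structures are never
# modelled: reports describe the wild-type environment of the mutated
# site.

#' Parse a point-mutation label
#'
#' @param text Label of the form `"T382K"` (wild-type residue, 1-based
#'   position, mutant residue).
#' @param phenotype Optional phenotype tag (`"gain_of_function"`,
#'   `"loss_of_function"`, `"hypo_responsive"`, `"other"`).
#' @return One-row data frame: `label`, `wt_aa`, `position`, `mut_aa`,
#'   `phenotype`.
#' @examples
#' parse_mutation("T382K")
#' @export
parse_mutation <- function(text, phenotype = NA_character_) {
  m <- regmatches(text, regexec("^([A-Za-z])([0-9]+)([A-Za-z])$", text))[[1]]
  if (length(m) != 4L) stop("bad mutation syntax: ", text, call. = FALSE)
  wt <- toupper(m[2]); mut <- toupper(m[4])
  if (!wt %in% AA_STANDARD || !mut %in% AA_STANDARD) {
    stop("bad mutation syntax: ", text, call. = FALSE)
  }
  if (wt == mut) stop("bad mutation syntax (silent): ", text, call. = FALSE)
  data.frame(label = paste0(wt, m[3], mut), wt_aa = wt,
             position = as.integer(m[3]), mut_aa = mut,
             phenotype = phenotype, stringsAsFactors = FALSE)
}

#' Validate mutation specs against a sequence
#'
#' Marks each spec valid iff the sequence carries the stated wild-type
#' residue at the stated position. Positions beyond the sequence are
#' flagged, not fatal.
#'
#' @param specs Data frame of mutation specs (rows as from
#'   [parse_mutation()]) or character vector of labels.
#' @param seq Sequence string, or named character vector of one-letter
#'   codes with residue-number names (as from [structure_sequence()]).
#' @return The specs with added columns `valid` and `observed`.
#' @export
validate_mutations <- function(specs, seq) {
  if (is.character(specs)) {
    specs <- do.call(rbind, lapply(specs, parse_mutation))
  }
  lookup <- if (length(seq) == 1L && is.null(names(seq))) {
    chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
    setNames(chars, seq_along(chars))
  } else {
    seq
  }
  observed <- unname(lookup[as.character(specs$position)])
  specs$observed <- ifelse(is.na(observed), NA_character_, observed)
  specs$valid <- !is.na(observed) & observed == specs$wt_aa
  specs
}

#' Packaged catalog of SPS-sensor point mutants
#'
#' The gain-of-function, loss-of-function and hypo-responsive point
#' mutants of Ssy1, Ptr3 and Ssy5 discussed throughout the package
#' documentation, shipped as a single annotation table.
#'
#' @return Data frame `protein`, `label`, `wt_aa`, `position`, `mut_aa`,
#'   `phenotype`.
#' @export
mutant_catalog <- function() {
  path <- system.file("extdata", "mutant_catalog.tsv", package = "spsmap")
  tab <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  parsed <- do.call(rbind, lapply(tab$label, parse_mutation))
  cbind(protein = tab$protein, parsed[, c("label", "wt_aa", "position", "mut_aa")],
        phenotype = tab$phenotype, stringsAsFactors = FALSE)
}

#' Structural neighbourhood of a residue
#'
#' All residues whose minimum side-chain heavy-atom distance (all-heavy
#' fallback for glycine) to the centre residue is at most `radius`, each
#' annotated with the typed interaction edges (salt bridge, H-bond proxy,
#' pi-pi) it shares with the centre.
#'
#' @param model An `sps_structure`.
#' @param position Residue selector for the centre (number,
#'   `"chain:resno"`, or list).
#' @param radius Neighbourhood radius in Angstrom.
#' @return List with `center` (chain, resno, aa), `radius` and
#'   `neighbors`: data frame `chain`, `resno`, `aa`, `distance`,
#'   `edge_kinds` (comma-joined, `""` if none).
#' @export
neighborhood <- function(model, position, radius = 5.0) {
  sc <- .res_selector(model, position)
  r <- .residue_table(model)
  center <- r[r$chain == sc$chain & r$resno == sc$resno, ]
  if (nrow(center) == 0L) stop("residue not found", call. = FALSE)
  scope_of <- function(aa) if (aa == "G") "all_heavy" else "side_chain"
  ca <- .residue_atoms(model, sc$chain, sc$resno, scope_of(center$aa))
  others <- r[!(r$chain == sc$chain & r$resno == sc$resno), , drop = FALSE]
  dist <- vapply(seq_len(nrow(others)), function(i) {
    ai <- .residue_atoms(model, others$chain[i], others$resno[i],
                         scope_of(others$aa[i]))
    if (nrow(ai) == 0L) return(Inf)
    .min_atom_distance(ca, ai)$distance
  }, numeric(1))
  keep <- dist <= radius
  nb <- others[keep, , drop = FALSE]
  nb$distance <- dist[keep]
  # typed edges restricted to pairs involving the centre
  edges <- rbind(detect_salt_bridges(model), detect_pipi(model))
  hb <- detect_hbond_pairs(model)
  edges <- rbind(edges, hb)
  kinds <- vapply(seq_len(nrow(nb)), function(i) {
    inv <- (edges$chain_a == sc$chain & edges$resno_a == sc$resno &
              edges$chain_b == nb$chain[i] & edges$resno_b == nb$resno[i]) |
           (edges$chain_b == sc$chain & edges$resno_b == sc$resno &
              edges$chain_a == nb$chain[i] & edges$resno_a == nb$resno[i])
    paste(sort(unique(edges$kind[inv])), collapse = ",")
  }, character(1))
  nb$edge_kinds <- if (nrow(nb)) kinds else character(0)
  nb <- nb[order(nb$distance), , drop = FALSE]
  rownames(nb) <- NULL
  list(center = center, radius = radius, neighbors = nb)
}

#' Cross-chain interface contacts
#'
#' All residue pairs across two chains whose any-heavy-atom minimum
#' distance is at most `cutoff`. Each pair is typed by the salt-bridge /
#' H-bond / pi-pi classifiers where their own criteria hold (tightest
#' applicable type wins: salt_bridge, then hbond, then pipi), otherwise
#' `hydrophobic_contact` when both side chains are hydrophobic, else
#' `generic`.
#'
#' @param model A multi-chain `sps_structure`.
#' @param chain_a,chain_b Chain ids.
#' @param cutoff Any-heavy-atom cutoff in Angstrom.
#' @return List with `chain_pair`, `cross_edges` (edge data frame) and
#'   `interface_residues` (list of per-chain sorted residue-number
#'   vectors).
#' @export
interface_contacts <- function(model, chain_a, chain_b, cutoff = 4.5) {
  chains <- unique(model$atoms$chain)
  if (length(chains) < 2L) stop("need two chains", call. = FALSE)
  if (!all(c(chain_a, chain_b) %in% chains)) stop("chain not found", call. = FALSE)
  r <- .residue_table(model)
  ra <- r[r$chain == chain_a, , drop = FALSE]
  rb <- r[r$chain == chain_b, , drop = FALSE]
  edges <- .pair_scan(model, ra, rb, "all_heavy", "all_heavy", cutoff,
                      "generic", exclude_same = FALSE)
  if (nrow(edges)) {
    # type each cross pair with the specific classifiers
    sb <- detect_salt_bridges(model)
    pp <- detect_pipi(model)
    for (i in seq_len(nrow(edges))) {
      pa <- list(chain = edges$chain_a[i], resno = edges$resno_a[i])
      pb <- list(chain = edges$chain_b[i], resno = edges$resno_b[i])
      has <- function(ed) any(
        (ed$chain_a == pa$chain & ed$resno_a == pa$resno &
           ed$chain_b == pb$chain & ed$resno_b == pb$resno) |
        (ed$chain_b == pa$chain & ed$resno_b == pa$resno &
           ed$chain_a == pb$chain & ed$resno_a == pb$resno))
      hb <- detect_hbond_pairs(model, pairs = list(list(pa, pb)))
      edges$kind[i] <- if (has(sb)) "salt_bridge"
        else if (nrow(hb) > 0L) "hbond"
        else if (has(pp)) "pipi"
        else if (edges$aa_a[i] %in% HYDROPHOBIC_AA &&
                 edges$aa_b[i] %in% HYDROPHOBIC_AA) "hydrophobic_contact"
        else "generic"
    }
  }
  list(
    chain_pair = c(chain_a, chain_b),
    cross_edges = edges,
    interface_residues = setNames(
      list(sort(unique(edges$resno_a)), sort(unique(edges$resno_b))),
      c(chain_a, chain_b))
  )
}
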