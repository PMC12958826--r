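# Alignment conservation analysis: reading, per-column profiles, fully
# conserved counts, reference mapping, conserved boxes, pairwise identity.
#
# Conventions (used throughout): coordinates are 1-based and ranges are
# inclusive. A column is "fully conserved" only if all rows carry the same
# residue and the column contains no gap. Column identity_fraction uses the
# total number of rows as denominator (gaps count as mismatches); pairwise
# identity uses co-aligned (both non-gap) columns -- two deliberately
# different conventions.

#' Read a multiple sequence alignment
#'
#' Reads an alignment from aligned FASTA or Clustal format (auto-detected
#' from the file content) and designates a reference row whose residue
#' numbering is used for all downstream coordinates.
#'
#' @param path Path to an aligned-FASTA or Clustal (`.aln`) file.
#' @param reference_id Identifier of the reference row (for FASTA, the
#'   first whitespace-delimited token of the header).
#' @return An object of class `sps_alignment`: a list with elements
#'   `ids`, `descriptions`, `seqs` (named character vector of gapped,
#'   upper-case rows), `n_cols` and `reference_id`.
#' @examples
#' tf <- tempfile(fileext = ".fasta")
#' writeLines(c(">a ref", "MK-L", ">b", "MKAL"), tf)
#' aln <- read_alignment(tf, "a")
#' aln$n_cols
#' @export
read_alignment <- function(path, reference_id) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  first <- lines[nzchar(trimws(lines))][1]
  if (is.na(first)) stop("unrecognized alignment format (empty file)", call. = FALSE)
  if (startsWith(trimws(first), ">")) {
    ss <- Biostrings::readBStringSet(path)
    headers <- names(ss)
    ids <- vapply(strsplit(headers, "\\s+"), `[`, character(1), 1L)
    desc <- sub("^\\S+\\s*", "", headers)
    seqs <- as.character(ss)
  } else if (grepl("^(CLUSTAL|MUSCLE)", trimws(first), ignore.case = TRUE)) {
    # normalize the header region (Biostrings insists on exactly two blank
    # lines after the CLUSTAL line; dialects vary)
    hdr <- which(nzchar(trimws(lines)))[1]
    body <- lines[-seq_len(hdr)]
    body <- body[cumsum(nzchar(trimws(body))) > 0]
    tmp <- tempfile(fileext = ".aln")
    on.exit(unlink(tmp), add = TRUE)
    writeLines(c(lines[hdr], "", "", body), tmp)
    aln <- Biostrings::readAAMultipleAlignment(tmp, format = "clustal")
    ss <- as(aln, "AAStringSet")
    ids <- names(ss)
    desc <- rep("", length(ss))
    seqs <- as.character(ss)
  } else {
    stop("unrecognized alignment format", call. = FALSE)
  }
  if (length(seqs) == 0L) stop("no rows", call. = FALSE)
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) stop("ragged alignment", call. = FALSE)
  seqs <- vapply(seqs, sanitize_residues, character(1), allow_gap = TRUE,
                 USE.NAMES = FALSE)
  new_alignment(ids, seqs, reference_id, descriptions = desc)
}

#' Construct an alignment from in-memory rows
#'
#' @param ids Character vector of row identifiers.
#' @param seqs Character vector of equal-length gapped sequences.
#' @param reference_id Identifier of the reference row.
#' @param descriptions Optional free-text descriptions, one per row.
#' @return An `sps_alignment` object; see [read_alignment()].
#' @export
new_alignment <- function(ids, seqs, reference_id,
                          descriptions = rep("", length(ids))) {
  stopifnot(length(ids) == length(seqs))
  if (length(seqs) == 0L) stop("no rows", call. = FALSE)
  if (anyDuplicated(ids)) stop("duplicate row ids", call. = FALSE)
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) stop("ragged alignment", call. = FALSE)
  if (!reference_id %in% ids) stop("reference row not found", call. = FALSE)
  structure(
    list(ids = ids, descriptions = descriptions,
         seqs = setNames(toupper(seqs), ids),
         n_cols = lens[1], reference_id = reference_id),
    class = "sps_alignment"
  )
}

#' @export
print.sps_alignment <- function(x, ...) {
  cat("<sps_alignment> ", length(x$ids), " rows x ", x$n_cols,
      " columns; reference: ", x$reference_id, "\n", sep = "")
  invisible(x)
}

#' Remove gaps from one alignment row
#'
#' @param aln An `sps_alignment`.
#' @param id Row identifier; defaults to the reference row.
#' @return The ungapped sequence as a single string.
#' @export
ungap_row <- function(aln, id = aln$reference_id) {
  if (!id %in% aln$ids) stop("reference row not found", call. = FALSE)
  gsub(GAP_CHAR, "", aln$seqs[[id]], fixed = TRUE)
}

# alignment as a character matrix (rows x columns)
#' @noRd
aln_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(unname(aln$seqs), "", fixed = TRUE))
  rownames(m) <- aln$ids
  m
}

#' Per-column conservation profiles
#'
#' For every alignment column, tallies residues and reports the identity
#' fraction (count of the most frequent residue divided by the total number
#' of rows, so gaps count as mismatches), strict conservation (all rows
#' identical, zero gaps) and group conservation (all residues non-gap and in
#' one physico-chemical similarity group).
#'
#' @param aln An `sps_alignment`.
#' @param groups Similarity groups, see [similarity_groups()].
#' @return A data frame with one row per column: `column`, `ref_pos`,
#'   `ref_aa`, `gap_count`, `identity_fraction`, `strictly_conserved`,
#'   `group_conserved`. The full residue-count matrix (letters x columns)
#'   is attached as attribute `"counts"`.
#' @export
column_profiles <- function(aln, groups = similarity_groups()) {
  m <- aln_matrix(aln)
  n_rows <- nrow(m)
  letters_seen <- sort(unique(as.vector(m)))
  counts <- vapply(seq_len(ncol(m)), function(j) {
    tab <- table(factor(m[, j], levels = letters_seen))
    as.integer(tab)
  }, integer(length(letters_seen)))
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = length(letters_seen))
  rownames(counts) <- letters_seen
  gap_row <- if (GAP_CHAR %in% letters_seen) counts[GAP_CHAR, ] else rep(0L, ncol(m))
  res_counts <- counts[setdiff(letters_seen, GAP_CHAR), , drop = FALSE]
  max_res <- if (nrow(res_counts)) apply(res_counts, 2, max) else rep(0L, ncol(m))
  identity_fraction <- max_res / n_rows
  strictly <- identity_fraction == 1          # implies zero gaps
  gidx <- .group_index(groups)
  group_cons <- vapply(seq_len(ncol(m)), function(j) {
    col <- m[, j]
    if (any(col == GAP_CHAR)) return(FALSE)
    g <- gidx[col]
    !anyNA(g) && length(unique(g)) == 1L
  }, logical(1))
  map <- map_columns_to_reference(aln)
  out <- data.frame(
    column = seq_len(ncol(m)),
    ref_pos = map$col_to_ref,
    ref_aa = ifelse(is.na(map$col_to_ref), NA_character_, m[aln$reference_id, ]),
    gap_count = as.integer(gap_row),
    identity_fraction = identity_fraction,
    strictly_conserved = strictly,
    group_conserved = group_cons,
    stringsAsFactors = FALSE
  )
  attr(out, "counts") <- counts
  out
}

#' Count fully conserved alignment columns
#'
#' A column counts as fully conserved when all rows carry the same residue
#' and the column has no gaps. With `ref_region`, only columns whose
#' reference residue number falls inside the given 1-based inclusive range
#' are counted.
#'
#' @param aln An `sps_alignment`.
#' @param ref_region Optional `c(start, end)` range on the reference
#'   sequence (ungapped numbering).
#' @return Integer count.
#' @export
count_fully_conserved <- function(aln, ref_region = NULL) {
  prof <- column_profiles(aln)
  keep <- prof$strictly_conserved
  if (!is.null(ref_region)) {
    stopifnot(length(ref_region) == 2L)
    ref_len <- nchar(ungap_row(aln))
    if (ref_region[1] < 1 || ref_region[2] > ref_len ||
        ref_region[1] > ref_region[2]) {
      stop("region out of range", call. = FALSE)
    }
    keep <- keep & !is.na(prof$ref_pos) &
      prof$ref_pos >= ref_region[1] & prof$ref_pos <= ref_region[2]
  }
  sum(keep)
}

#' Map alignment columns to reference residue numbers
#'
#' @param aln An `sps_alignment`.
#' @return A list with `col_to_ref` (integer vector, length `n_cols`, NA at
#'   reference-gap columns) and `ref_to_col` (integer vector, one entry per
#'   ungapped reference residue).
#' @export
map_columns_to_reference <- function(aln) {
  refchars <- strsplit(aln$seqs[[aln$reference_id]], "", fixed = TRUE)[[1]]
  is_res <- refchars != GAP_CHAR
  col_to_ref <- rep(NA_integer_, length(refchars))
  col_to_ref[is_res] <- seq_len(sum(is_res))
  list(col_to_ref = col_to_ref, ref_to_col = which(is_res))
}

#' Detect conserved sequence boxes
#'
#' Finds maximal runs of columns whose identity fraction is at least
#' `min_identity`, tolerating up to `max_below_run` consecutive
#' below-threshold columns inside a run, and reports them in reference
#' residue numbering. Runs whose reference span is shorter than
#' `min_length` residues are dropped. This mirrors how conserved "boxes"
#' (e.g. the A-F boxes in the Ssy1 N-terminal domain) are read off an
#' ortholog alignment; the thresholds are calibration knobs.
#'
#' @param aln An `sps_alignment`.
#' @param min_identity Identity-fraction threshold in `[0, 1]`.
#' @param min_length Minimum box span in reference residues.
#' @param max_below_run Longest tolerated run of sub-threshold columns
#'   inside a box.
#' @return Data frame with `label` ("Box1", "Box2", ...), `ref_start`,
#'   `ref_end`, `mean_identity` (mean column identity over the box's
#'   columns), sorted by `ref_start`.
#' @export
detect_conserved_boxes <- function(aln, min_identity = 0.7, min_length = 3,
                                   max_below_run = 2) {
  stopifnot(min_identity >= 0, min_identity <= 1,
            min_length >= 1, max_below_run >= 0)
  prof <- column_profiles(aln)
  good <- prof$identity_fraction >= min_identity
  n <- length(good)
  runs <- list()
  i <- 1L
  while (i <= n) {
    if (!good[i]) { i <- i + 1L; next }
    start <- i
    last_good <- i
    j <- i + 1L
    bad_run <- 0L
    while (j <= n) {
      if (good[j]) {
        last_good <- j
        bad_run <- 0L
      } else {
        bad_run <- bad_run + 1L
        if (bad_run > max_below_run) break
      }
      j <- j + 1L
    }
    runs[[length(runs) + 1L]] <- c(start, last_good)
    i <- last_good + 1L
  }
  out <- data.frame(label = character(0), ref_start = integer(0),
                    ref_end = integer(0), mean_identity = numeric(0),
                    stringsAsFactors = FALSE)
  for (r in runs) {
    cols <- r[1]:r[2]
    refs <- prof$ref_pos[cols]
    refs <- refs[!is.na(refs)]
    if (length(refs) == 0L) next
    if (max(refs) - min(refs) + 1L < min_length) next
    out <- rbind(out, data.frame(
      label = "",
      ref_start = min(refs), ref_end = max(refs),
      mean_identity = mean(prof$identity_fraction[cols]),
      stringsAsFactors = FALSE
    ))
  }
  out <- out[order(out$ref_start), , drop = FALSE]
  if (nrow(out)) out$label <- paste0("Box", seq_len(nrow(out)))
  rownames(out) <- NULL
  out
}

#' Pairwise identity and similarity against the reference row
#'
#' For each non-reference row, identity is the percentage of co-aligned
#' (both non-gap) columns with identical residues; similarity additionally
#' counts columns whose residues share a physico-chemical similarity group.
#'
#' @param aln An `sps_alignment` with at least two rows.
#' @param groups Similarity groups, see [similarity_groups()].
#' @return Data frame with `row_id`, `identity_pct`, `similarity_pct`
#'   (both `NA` for a pair with zero co-aligned columns).
#' @export
pairwise_identity_similarity <- function(aln, groups = similarity_groups()) {
  if (length(aln$ids) < 2L) stop("need at least 2 rows", call. = FALSE)
  m <- aln_matrix(aln)
  ref <- m[aln$reference_id, ]
  gidx <- .group_index(groups)
  others <- setdiff(aln$ids, aln$reference_id)
  res <- lapply(others, function(id) {
    row <- m[id, ]
    co <- ref != GAP_CHAR & row != GAP_CHAR
    n_co <- sum(co)
    if (n_co == 0L) {
      return(data.frame(row_id = id, identity_pct = NA_real_,
                        similarity_pct = NA_real_, stringsAsFactors = FALSE))
    }
    ident <- ref[co] == row[co]
    same_group <- !is.na(gidx[ref[co]]) & !is.na(gidx[row[co]]) &
      gidx[ref[co]] == gidx[row[co]]
    data.frame(
      row_id = id,
      identity_pct = 100 * sum(ident) / n_co,
      similarity_pct = 100 * sum(ident | same_group) / n_co,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Write an alignment as aligned FASTA
#'
#' @param aln An `sps_alignment`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_alignment_fasta <- function(aln, path) {
  hdr <- ifelse(nzchar(aln$descriptions),
                paste(aln$ids, aln$descriptions), aln$ids)
  writeLines(as.vector(rbind(paste0(">", hdr), unname(aln$seqs))), path)
  invisible(path)
}
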