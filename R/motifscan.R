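# Degenerate short-linear-motif (SLiM) scanning. Patterns are ordered
# element lists: each element is a residue-class set (a fixed letter is a
# one-member class) or a wildcard. Matching is case-insensitive; 'X' in a
# sequence matches only wildcards, never a class. Overlapping hits are
# reported: casein-kinase-1 sites such as TYGT / TGAS genuinely share a
# residue and both count.

#' Compile a degenerate consensus pattern
#'
#' Accepts the notations commonly used for SLiM consensi:
#' `"[ST]xx[ST]"`, `"(S/T)xx(S/T)"` and `"S/T-x-x-S/T"` all compile to the
#' same pattern. `x`/`X` is a wildcard position.
#'
#' @param consensus Consensus string.
#' @param name Pattern name (defaults to the consensus itself).
#' @return An object of class `sps_motif`: list with `name`, `consensus`,
#'   `elements` (list of character vectors; `NULL` marks a wildcard) and
#'   `length`.
#' @examples
#' p <- compile_pattern("(S/T)xx(S/T)", "CK1")
#' p$length
#' @export
compile_pattern <- function(consensus, name = consensus) {
  if (!is.character(consensus) || length(consensus) != 1L || !nzchar(consensus)) {
    stop("malformed consensus", call. = FALSE)
  }
  tokens <- if (grepl("-", consensus, fixed = TRUE)) {
    strsplit(consensus, "-", fixed = TRUE)[[1]]
  } else {
    .tokenize_consensus(consensus)
  }
  if (length(tokens) == 0L || any(!nzchar(tokens))) {
    stop("malformed consensus", call. = FALSE)
  }
  elements <- lapply(tokens, .parse_token)
  structure(
    list(name = name, consensus = consensus, elements = elements,
         length = length(elements)),
    class = "sps_motif"
  )
}

# split an undashed consensus into per-position tokens
#' @noRd
.tokenize_consensus <- function(consensus) {
  chars <- strsplit(consensus, "", fixed = TRUE)[[1]]
  tokens <- character(0)
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch %in% c("(", "[")) {
      close <- if (ch == "(") ")" else "]"
      j <- i
      while (j <= length(chars) && chars[j] != close) j <- j + 1L
      if (j > length(chars)) stop("malformed consensus", call. = FALSE)
      tokens <- c(tokens, paste(chars[i:j], collapse = ""))
      i <- j + 1L
    } else {
      tokens <- c(tokens, ch)
      i <- i + 1L
    }
  }
  tokens
}

# one token -> character vector of allowed letters, or NULL for wildcard
#' @noRd
.parse_token <- function(tok) {
  tok <- gsub("[][()]", "", tok)
  if (tok %in% c("x", "X", ".")) return(NULL)
  letters <- toupper(strsplit(gsub("/", "", tok), "", fixed = TRUE)[[1]])
  if (length(letters) == 0L) stop("malformed consensus", call. = FALSE)
  if (!all(letters %in% AA_STANDARD)) stop("malformed consensus", call. = FALSE)
  unique(letters)
}

#' @export
print.sps_motif <- function(x, ...) {
  cat("<sps_motif> ", x$name, " (length ", x$length, ")\n", sep = "")
  invisible(x)
}

# does the window (character vector, length = pattern length) match?
#' @noRd
.window_matches <- function(window, pattern) {
  for (k in seq_along(pattern$elements)) {
    el <- pattern$elements[[k]]
    if (is.null(el)) next            # wildcard: any letter, including X
    if (!(window[k] %in% el)) return(FALSE)
  }
  TRUE
}

#' Scan a sequence for motif hits
#'
#' Reports every window that matches the pattern, including overlapping
#' windows, sorted by start. A hit counts when its start position lies
#' inside `region` and the full window fits within the sequence (the
#' window may extend beyond the region's right edge).
#'
#' @param seq Either a plain string or a list/record with elements `id` and
#'   `residues`.
#' @param pattern An `sps_motif` from [compile_pattern()].
#' @param region Optional `c(start, end)` 1-based inclusive range
#'   restricting hit start positions.
#' @param seq_id Identifier used in the output when `seq` is a plain
#'   string.
#' @return Data frame with `seq_id`, `start`, `end`, `peptide`,
#'   `pattern_name`.
#' @export
scan_sequence <- function(seq, pattern, region = NULL, seq_id = "seq") {
  if (is.list(seq)) {
    seq_id <- seq$id
    seq <- seq$residues
  }
  stopifnot(inherits(pattern, "sps_motif"))
  seq <- toupper(seq)
  n <- nchar(seq)
  L <- pattern$length
  empty <- data.frame(seq_id = character(0), start = integer(0),
                      end = integer(0), peptide = character(0),
                      pattern_name = character(0), stringsAsFactors = FALSE)
  if (is.null(region)) region <- c(1L, n)
  if (n > 0 && (region[1] < 1 || region[2] > n || region[1] > region[2])) {
    stop("region out of range", call. = FALSE)
  }
  if (n < L) return(empty)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  starts <- seq.int(region[1], min(region[2], n - L + 1L))
  if (length(starts) == 0L || starts[1] > n - L + 1L) return(empty)
  hit <- vapply(starts, function(s) .window_matches(chars[s:(s + L - 1L)], pattern),
                logical(1))
  starts <- starts[hit]
  if (length(starts) == 0L) return(empty)
  data.frame(
    seq_id = seq_id,
    start = starts,
    end = starts + L - 1L,
    peptide = vapply(starts, function(s)
      paste(chars[s:(s + L - 1L)], collapse = ""), character(1)),
    pattern_name = pattern$name,
    stringsAsFactors = FALSE
  )
}

#' Classify reference motif hits by ortholog conservation
#'
#' Scans the reference row of an alignment for the pattern, then asks, for
#' each hit, whether each non-reference (ortholog) row also matches. The
#' ortholog window is the set of alignment columns spanning the hit,
#' widened by `slack` reference residues on each side to absorb small
#' indel-induced shifts; the window is ungapped and re-scanned.
#'
#' @param aln An `sps_alignment`.
#' @param pattern An `sps_motif`.
#' @param threshold Minimum ortholog fraction to call a hit conserved.
#' @param slack Slack in reference residues on each side of the hit window.
#' @return Data frame: one row per reference hit with `seq_id`, `start`,
#'   `end`, `peptide`, `pattern_name`, `ortholog_fraction`, `conserved`.
#' @export
scan_alignment_conservation <- function(aln, pattern, threshold = 0.5,
                                        slack = 2L) {
  ref_seq <- ungap_row(aln)
  hits <- scan_sequence(ref_seq, pattern, seq_id = aln$reference_id)
  map <- map_columns_to_reference(aln)
  others <- setdiff(aln$ids, aln$reference_id)
  n_orth <- length(others)
  ref_len <- nchar(ref_seq)
  frac <- vapply(seq_len(nrow(hits)), function(i) {
    lo <- max(1L, hits$start[i] - slack)
    hi <- min(ref_len, hits$end[i] + slack)
    cols <- map$ref_to_col[lo]:map$ref_to_col[hi]
    if (n_orth == 0L) return(NA_real_)
    n_match <- sum(vapply(others, function(id) {
      win <- gsub(GAP_CHAR, "",
                  substr(aln$seqs[[id]], cols[1], cols[length(cols)]),
                  fixed = TRUE)
      nrow(scan_sequence(win, pattern)) > 0L
    }, logical(1)))
    n_match / n_orth
  }, numeric(1))
  hits$ortholog_fraction <- frac
  hits$conserved <- !is.na(frac) & frac >= threshold
  hits
}
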