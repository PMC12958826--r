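# alignments module: reading, profiles, conserved counts, reference
# mapping, boxes, pairwise identity/similarity.

make_aln <- function(seqs, ids = paste0("s", seq_along(seqs)), ref = ids[1]) {
  new_alignment(ids, seqs, ref)
}

test_that("read_alignment parses FASTA and Clustal identically", {
  seqs <- c(a = "MK-LV", b = "MKALV", c = "MK-LI")
  fa <- tempfile(fileext = ".fasta")
  writeLines(as.vector(rbind(paste0(">", names(seqs)), seqs)), fa)
  cl <- tempfile(fileext = ".aln")
  writeLines(c("CLUSTAL W (1.83) multiple sequence alignment", "",
               paste(format(names(seqs), width = 10), seqs)), cl)
  a1 <- read_alignment(fa, "a")
  a2 <- read_alignment(cl, "a")
  expect_equal(a1$seqs, a2$seqs)
  expect_equal(a1$n_cols, 5L)
  expect_equal(a1$reference_id, "a")
  # round trip: ungapping reproduces the input sequence
  expect_equal(ungap_row(a1, "a"), "MKLV")
  expect_equal(ungap_row(a1, "b"), "MKALV")
})

test_that("read_alignment error paths", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">a", "MKL", ">b", "MKLV"), fa)
  expect_error(read_alignment(fa, "a"), "ragged")
  writeLines(c(">a", "MKL"), fa)
  expect_error(read_alignment(fa, "zz"), "reference row not found")
  writeLines(c("not a header", "MKL"), fa)
  expect_error(read_alignment(fa, "a"), "unrecognized")
  # non-standard letters fold to X with a warning
  writeLines(c(">a", "MBZ"), fa)
  expect_warning(a <- read_alignment(fa, "a"), "mapped to X")
  expect_equal(unname(a$seqs["a"]), "MXX")
})

test_that("column_profiles matches definitions and the naive tally", {
  aln <- make_aln(c("AAC", "AAC", "A-T"))
  prof <- column_profiles(aln)
  expect_true(prof$strictly_conserved[1])
  expect_equal(prof$identity_fraction[1], 1)
  # gap column: (A, A, -) -> 2/3, not strict
  expect_false(prof$strictly_conserved[2])
  expect_equal(prof$identity_fraction[2], 2 / 3)
  expect_equal(prof$gap_count[2], 1L)
  expect_equal(prof$identity_fraction[3], 2 / 3)
  # group conservation: C/T are in different groups, A alone is one group
  expect_true(prof$group_conserved[1])
  expect_false(prof$group_conserved[2]) # gap blocks group conservation
  # random alignment vs brute-force tally
  set.seed(11)
  seqs <- vapply(1:5, function(i) {
    paste(sample(c(AA20, "-"), 20, replace = TRUE), collapse = "")
  }, character(1))
  seqs[1] <- gsub("-", "A", seqs[1], fixed = TRUE) # reference ungapped
  aln2 <- make_aln(seqs)
  expect_equal(column_profiles(aln2)$identity_fraction,
               oracle_column_identity(seqs))
})

test_that("count_fully_conserved counts invariant gap-free columns", {
  rows <- rep(paste(rep("ACDEFGHIKL", 1), collapse = ""), 3)
  aln <- make_aln(rows)
  expect_equal(count_fully_conserved(aln), 10L)
  rows[2] <- sub("^A", "V", rows[2])
  expect_equal(count_fully_conserved(make_aln(rows)), 9L)
  # region restriction in reference numbering
  expect_equal(count_fully_conserved(make_aln(rows), c(2, 10)), 9L)
  expect_equal(count_fully_conserved(make_aln(rows), c(1, 5)), 4L)
  expect_error(count_fully_conserved(aln, c(5, 11)), "region out of range")
  # property: sum of strictly_conserved equals the unrestricted count
  g <- synth_alignment(8, 40, boxes = data.frame(start = 5, end = 12,
                                                 identity_level = 1), seed = 3)
  expect_equal(sum(column_profiles(g$aln)$strictly_conserved),
               count_fully_conserved(g$aln))
})

test_that("map_columns_to_reference handles gapped references", {
  aln <- make_aln(c("M-KL", "MAKL"))
  map <- map_columns_to_reference(aln)
  expect_equal(map$col_to_ref, c(1L, NA, 2L, 3L))
  expect_equal(map$ref_to_col, c(1L, 3L, 4L))
  # ungapped reference: identity mapping
  aln2 <- make_aln(c("MKL", "MKA"))
  expect_equal(map_columns_to_reference(aln2)$ref_to_col, 1:3)
  # naive cursor walk on a random gapped fixture
  set.seed(5)
  ref <- paste(sample(c("A", "C", "-"), 30, replace = TRUE), collapse = "")
  aln3 <- make_aln(c(ref, gsub("-", "G", ref, fixed = TRUE)))
  walk <- integer(0)
  pos <- 0L
  for (ch in strsplit(ref, "")[[1]]) {
    pos <- pos + 1L
    if (ch != "-") walk <- c(walk, pos)
  }
  expect_equal(map_columns_to_reference(aln3)$ref_to_col, walk)
})

test_that("detect_conserved_boxes recovers planted blocks and edge cases", {
  g <- synth_alignment(10, 60, boxes = data.frame(start = 21, end = 28,
                                                  identity_level = 1), seed = 9)
  boxes <- detect_conserved_boxes(g$aln, min_identity = 0.7, min_length = 3)
  expect_equal(nrow(boxes), 1L)
  expect_equal(boxes$ref_start, 21L)
  expect_equal(boxes$ref_end, 28L)
  # identical sequences: one box spanning the whole reference
  aln_id <- make_aln(rep("ACDEFGHIKLMNPQ", 4))
  b <- detect_conserved_boxes(aln_id)
  expect_equal(nrow(b), 1L)
  expect_equal(c(b$ref_start, b$ref_end), c(1L, 14L))
  expect_equal(b$mean_identity, 1)
  # all-distinct columns: nothing
  aln_bad <- make_aln(c("AAAA", "CCCC", "DDDD", "EEEE", "FFFF"))
  expect_equal(nrow(detect_conserved_boxes(aln_bad)), 0L)
  # a short sub-threshold gap inside a box is bridged
  seqs <- rep(paste(rep("A", 12), collapse = ""), 5)
  seqs[1] <- "AAAAACAAAAAA"   # one divergent column at 6 in one row only
  aln_gap <- make_aln(seqs)
  bb <- detect_conserved_boxes(aln_gap, min_identity = 0.9, min_length = 3,
                               max_below_run = 2)
  expect_equal(nrow(bb), 1L)
  expect_equal(c(bb$ref_start, bb$ref_end), c(1L, 12L))
})

test_that("pairwise identity and similarity follow the two conventions", {
  aln <- make_aln(c("AAAA", "AAVL"))
  ps <- pairwise_identity_similarity(aln)
  expect_equal(ps$identity_pct, 50)
  expect_equal(ps$similarity_pct, 100)   # A,V,L share the aliphatic group
  # identical rows
  ps2 <- pairwise_identity_similarity(make_aln(c("MKLV", "MKLV")))
  expect_equal(unlist(ps2[, 2:3]), c(identity_pct = 100, similarity_pct = 100))
  # symmetry of identity in the two rows
  a <- "MK-LVWD"
  b <- "MKAL-WE"
  id_of <- function(r1, r2) {
    aln <- make_aln(c(r1, r2))
    pairwise_identity_similarity(aln)$identity_pct
  }
  expect_equal(id_of(a, b), id_of(b, a))
  # brute-force column scan on a random pair
  set.seed(21)
  r1 <- paste(sample(c(AA20, "-"), 50, replace = TRUE), collapse = "")
  r2 <- paste(sample(c(AA20, "-"), 50, replace = TRUE), collapse = "")
  c1 <- strsplit(r1, "")[[1]]; c2 <- strsplit(r2, "")[[1]]
  co <- c1 != "-" & c2 != "-"
  expect_equal(id_of(r1, r2), 100 * sum(c1[co] == c2[co]) / sum(co))
  # zero co-aligned columns -> NA
  ps3 <- pairwise_identity_similarity(make_aln(c("AA--", "--AA")))
  expect_true(is.na(ps3$identity_pct) && is.na(ps3$similarity_pct))
})

test_that("identity_fraction invariants hold on random alignments", {
  for (seed in 1:5) {
    g <- synth_alignment(7, 30, seed = seed)
    prof <- column_profiles(g$aln)
    expect_true(all(prof$identity_fraction >= 0 & prof$identity_fraction <= 1))
    expect_true(all(prof$identity_fraction[prof$strictly_conserved] == 1))
    expect_true(all(prof$gap_count[prof$strictly_conserved] == 0))
  }
})
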