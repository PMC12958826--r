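# structcontacts module: structure I/O, distances, typed detectors,
# clusters, track segmentation.

test_that("read_structure parses a minimal hand-written PDB", {
  pdb <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00 88.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00 88.00           C",
    "ATOM      3  CB  ALA A   1       2.000   1.400   0.000  1.00 88.00           C",
    "ATOM      4  H   ALA A   1       9.000   9.000   9.000  1.00 88.00           H",
    "END"), pdb)
  m <- read_structure(pdb, plddt_in_bfactor = TRUE)
  expect_equal(unique(m$atoms$chain), "A")
  expect_equal(unique(m$atoms$resno), 1L)
  expect_equal(nrow(m$atoms), 3L)          # hydrogen dropped
  expect_equal(m$atoms$aa[1], "A")
  expect_equal(unique(m$atoms$plddt), 88)
  expect_error(read_structure(tempfile()), "not found")
  bad <- tempfile(); writeLines("gibberish", bad)
  expect_error(read_structure(bad), "bad structure file")
})

test_that("PDB and mmCIF readers agree; write/read round-trips coordinates", {
  s <- synth_structure(
    data.frame(aa = c("K", "D", "F"), chain = "A", number = c(1, 5, 9)),
    data.frame(res_a = 1, res_b = 5, kind = "salt_bridge", distance = 3.2),
    seed = 4)
  pdb <- tempfile(fileext = ".pdb")
  write_structure(s$model, pdb)
  back <- read_structure(pdb)
  expect_equal(back$atoms$atom, s$model$atoms$atom)
  expect_equal(back$atoms$x, round(s$model$atoms$x, 3))
  # distances survive the round trip to PDB precision
  d0 <- residue_min_distance(s$model, 1, 5, "charged_group")$distance
  d1 <- residue_min_distance(back, 1, 5, "charged_group")$distance
  expect_equal(d0, d1, tolerance = 1e-3)
  # equivalent hand-written mmCIF of the same atoms
  cif <- tempfile(fileext = ".cif")
  a <- s$model$atoms
  writeLines(c(
    "data_synth", "loop_",
    "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
    "_atom_site.auth_atom_id", "_atom_site.auth_comp_id",
    "_atom_site.auth_asym_id", "_atom_site.auth_seq_id",
    "_atom_site.Cartn_x", "_atom_site.Cartn_y", "_atom_site.Cartn_z",
    "_atom_site.B_iso_or_equiv", "_atom_site.pdbx_PDB_model_num",
    sprintf("ATOM %d %s %s %s %s %d %.3f %.3f %.3f %.2f 1",
            seq_len(nrow(a)), a$element, a$atom, a$resname, a$chain,
            a$resno, a$x, a$y, a$z, 90),
    "#"), cif)
  mc <- read_structure(cif, plddt_in_bfactor = TRUE)
  expect_equal(mc$atoms$x, round(a$x, 3))
  expect_equal(mc$atoms$atom, a$atom)
  expect_equal(unique(mc$atoms$plddt), 90)
})

test_that("residue_min_distance: scopes, trivial geometry, oracle", {
  atoms <- data.frame(
    chain = "A", resno = c(1, 2), resname = c("GLY", "GLY"),
    atom = "CA", element = "C",
    x = c(0, 3), y = c(0, 4), z = c(0, 0))
  m <- new_structure(atoms)
  expect_equal(residue_min_distance(m, 1, 2)$distance, 5)      # 3-4-5
  expect_equal(residue_min_distance(m, 1, 1)$distance, 0)
  expect_error(residue_min_distance(m, 1, 2, "side_chain"), "no atoms in scope")
  expect_error(residue_min_distance(m, 1, 99), "residue not found")
  # random synthetic pair vs all-pairs oracle
  for (seed in 1:10) {
    rm <- random_model(n_res = 5, seed = seed)
    res <- unique(rm$atoms$resno)
    d_pkg <- residue_min_distance(rm, res[1], res[2])$distance
    d_orc <- oracle_min_dist(rm, "A", res[1], "A", res[2])
    expect_equal(d_pkg, d_orc, tolerance = 1e-12)
  }
})

test_that("detect_salt_bridges finds planted bridges and nothing else", {
  s <- synth_structure(
    data.frame(aa = c("K", "D", "S", "L"), chain = "A", number = c(1, 5, 9, 13)),
    data.frame(res_a = 1, res_b = 5, kind = "salt_bridge", distance = 3.0),
    seed = 2)
  sb <- detect_salt_bridges(s$model)
  expect_equal(nrow(sb), 1L)
  expect_equal(sb$distance, 3.0, tolerance = 0.01)
  expect_equal(c(sb$resno_a, sb$resno_b), c(1L, 5L))
  expect_equal(sb$atom_a, "NZ")
  # no charged residues -> empty
  s2 <- synth_structure(data.frame(aa = c("A", "G"), chain = "A",
                                   number = c(1, 2)), seed = 1)
  expect_equal(nrow(detect_salt_bridges(s2$model)), 0L)
})

test_that("detect_hbond_pairs finds planted pairs; pair restriction works", {
  s <- synth_structure(
    data.frame(aa = c("S", "D", "G", "G"), chain = "A", number = c(1, 5, 20, 30)),
    data.frame(res_a = 1, res_b = 5, kind = "hbond", distance = 2.8),
    seed = 3)
  hb <- detect_hbond_pairs(s$model)
  expect_true(any(hb$resno_a == 1 & hb$resno_b == 5 &
                    abs(hb$distance - 2.8) < 0.01))
  # distant glycines: nothing
  hb2 <- detect_hbond_pairs(s$model, pairs = list(list(20, 30)))
  expect_equal(nrow(hb2), 0L)
  # restricted to the planted pair
  hb3 <- detect_hbond_pairs(s$model, pairs = list(list(1, 5)))
  expect_equal(nrow(hb3), 1L)
  expect_equal(hb3$distance, 2.8, tolerance = 0.01)
})

test_that("detect_pipi uses ring centroids", {
  s <- synth_structure(
    data.frame(aa = c("F", "F", "Y"), chain = "A", number = c(1, 5, 9)),
    data.frame(res_a = 1, res_b = 5, kind = "pipi", distance = 4.0),
    seed = 8)
  pp <- detect_pipi(s$model)
  expect_equal(nrow(pp), 1L)
  expect_equal(pp$distance, 4.0, tolerance = 0.01)
  # above cutoff -> empty
  s2 <- synth_structure(
    data.frame(aa = c("F", "F"), chain = "A", number = c(1, 5)),
    data.frame(res_a = 1, res_b = 5, kind = "pipi", distance = 8.0),
    seed = 8)
  expect_equal(nrow(detect_pipi(s2$model)), 0L)
  # a single aromatic residue -> empty
  s3 <- synth_structure(data.frame(aa = "W", chain = "A", number = 1), seed = 1)
  expect_equal(nrow(detect_pipi(s3$model)), 0L)
})

test_that("detect_clusters: single-linkage chains and kinds", {
  # 3 Cys with SG atoms in a 3.5 A chain -> one sulfur cluster of 3
  s <- synth_structure(
    data.frame(aa = c("C", "C", "C", "C"), chain = "A",
               number = c(1, 5, 9, 40)),
    data.frame(res_a = c(1, 5), res_b = c(5, 9), kind = "sulfur_pair",
               distance = c(3.5, 3.5)),
    seed = 5)
  cl <- detect_clusters(s$model, "sulfur")
  expect_equal(length(cl), 1L)
  expect_equal(cl[[1]]$members$resno, c(1, 5, 9))
  expect_equal(cl[[1]]$max_internal_gap, 3.5, tolerance = 0.01)
  # all residues far apart -> no clusters
  s2 <- synth_structure(data.frame(aa = c("L", "V", "F"), chain = "A",
                                   number = c(1, 5, 9)), seed = 6)
  expect_equal(length(detect_clusters(s2$model, "hydrophobic")), 0L)
  # hydrophobic pair within the cutoff
  s3 <- synth_structure(
    data.frame(aa = c("L", "V"), chain = "A", number = c(1, 5)),
    data.frame(res_a = 1, res_b = 5, kind = "hydrophobic_contact",
               distance = 4.0),
    seed = 7)
  cl3 <- detect_clusters(s3$model, "hydrophobic")
  expect_equal(length(cl3), 1L)
  expect_setequal(cl3[[1]]$members$aa, c("L", "V"))
})

test_that("detectors equal their oracles on random models", {
  for (seed in 1:15) {
    m <- random_model(n_res = 7, seed = 100 + seed)
    sb <- detect_salt_bridges(m)
    orc <- oracle_salt_bridges(m)
    expect_equal(nrow(sb), if (is.null(orc)) 0L else nrow(orc))
    if (!is.null(orc)) {
      expect_equal(sb$distance, orc$distance, tolerance = 1e-9)
    }
    hb <- detect_hbond_pairs(m)
    orc_h <- oracle_hbonds(m)
    expect_equal(nrow(hb), if (is.null(orc_h)) 0L else nrow(orc_h))
    if (!is.null(orc_h)) {
      expect_equal(sort(hb$distance), sort(orc_h$distance), tolerance = 1e-9)
    }
  }
})

test_that("cutoff monotonicity: raising a cutoff never removes edges", {
  m <- random_model(n_res = 10, seed = 77, box = 14)
  for (cuts in list(c(3.5, 4.5), c(4.5, 6))) {
    e1 <- detect_salt_bridges(m, cuts[1])
    e2 <- detect_salt_bridges(m, cuts[2])
    key <- function(e) paste(e$resno_a, e$resno_b)
    expect_true(all(key(e1) %in% key(e2)))
  }
})

test_that("edge distances are symmetric in argument order", {
  m <- random_model(n_res = 6, seed = 31, box = 12)
  res <- unique(m$atoms$resno)
  for (i in 1:3) {
    d_ab <- residue_min_distance(m, res[i], res[i + 1])$distance
    d_ba <- residue_min_distance(m, res[i + 1], res[i])$distance
    expect_identical(d_ab, d_ba)
  }
})

test_that("segment_track reproduces the step-function IDR example", {
  # disorder 0.8 on 1-108, 0.3 on 109-134, 0.8 on 135-260, 0.2 after
  sc <- c(rep(0.8, 108), rep(0.3, 26), rep(0.8, 126), rep(0.2, 40))
  tr <- new_score_track(seq_along(sc), sc, "disorder")
  seg <- segment_track(tr, 0.5, "above", min_length = 10)
  expect_equal(seg$start, c(1L, 135L))
  expect_equal(seg$end, c(108L, 260L))
  # constant track below threshold -> empty
  tr2 <- new_score_track(1:50, rep(0.2, 50), "disorder")
  expect_equal(nrow(segment_track(tr2, 0.5, "above")), 0L)
  # threshold below global minimum, direction above -> whole track
  seg3 <- segment_track(tr, 0.1, "above", min_length = 10)
  expect_equal(c(seg3$start, seg3$end), c(1L, 300L))
})

test_that("segment_track equals the naive run-length oracle", {
  set.seed(19)
  for (rep in 1:10) {
    sc <- runif(120)
    tr <- new_score_track(1:120, sc, "disorder")
    seg <- segment_track(tr, 0.5, "above", min_length = 5)
    orc <- oracle_segments(sc, 0.5, "above", 5)
    expect_equal(nrow(seg), if (is.null(orc)) 0L else nrow(orc))
    if (!is.null(orc)) {
      expect_equal(seg$start, orc[, 1])
      expect_equal(seg$end, orc[, 2])
    }
  }
})

test_that("score track I/O and validation", {
  tf <- tempfile()
  writeLines(c("# residue score", "1 0.9", "2 0.8", "3 0.1"), tf)
  tr <- read_score_track(tf, "disorder")
  expect_equal(tr$score, c(0.9, 0.8, 0.1))
  expect_equal(attr(tr, "kind"), "disorder")
  expect_error(new_score_track(c(1, 1, 2), c(0, 0, 0), "disorder"),
               "strictly increasing")
  expect_error(new_score_track(1:2, c(0.5, 1.5), "disorder"), "outside")
})
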