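# Independent oracles and fixture builders used across the suite. Each
# oracle deliberately takes a different implementation route than the
# package code it checks.

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# ---- motif oracle: regex with lookahead (overlapping matches) ----------
# Builds a PCRE from the compiled pattern and finds every window start.
oracle_scan <- function(seq, pattern) {
  body <- paste(vapply(pattern$elements, function(el) {
    if (is.null(el)) "." else paste0("[", paste(el, collapse = ""), "]")
  }, character(1)), collapse = "")
  rex <- paste0("(?=", body, ")")
  m <- gregexpr(rex, seq, perl = TRUE)[[1]]
  starts <- as.integer(m[m > 0])
  # lookahead can report starts whose window would overrun the end
  starts[starts + pattern$length - 1L <= nchar(seq)]
}

# ---- naive per-column tally --------------------------------------------
oracle_column_identity <- function(seqs) {
  m <- do.call(rbind, strsplit(seqs, ""))
  vapply(seq_len(ncol(m)), function(j) {
    col <- m[, j]
    res <- col[col != "-"]
    if (length(res) == 0) return(0)
    max(table(res)) / length(col)
  }, numeric(1))
}

# ---- naive all-atom-pairs minimum distance -----------------------------
oracle_min_dist <- function(model, chain_a, resno_a, chain_b, resno_b,
                            atoms_a = NULL, atoms_b = NULL) {
  a <- model$atoms
  sa <- a[a$chain == chain_a & a$resno == resno_a, ]
  sb <- a[a$chain == chain_b & a$resno == resno_b, ]
  if (!is.null(atoms_a)) sa <- sa[sa$atom %in% atoms_a, ]
  if (!is.null(atoms_b)) sb <- sb[sb$atom %in% atoms_b, ]
  best <- Inf
  for (i in seq_len(nrow(sa))) {
    for (j in seq_len(nrow(sb))) {
      d <- sqrt((sa$x[i] - sb$x[j])^2 + (sa$y[i] - sb$y[j])^2 +
                  (sa$z[i] - sb$z[j])^2)
      if (d < best) best <- d
    }
  }
  best
}

# charged-group atoms, duplicated here so the oracle is self-contained
ORACLE_CHARGED <- list(K = "NZ", R = c("NE", "NH1", "NH2"),
                       H = c("ND1", "NE2"), D = c("OD1", "OD2"),
                       E = c("OE1", "OE2"))

oracle_salt_bridges <- function(model, cutoff = 4.5) {
  a <- model$atoms
  res <- unique(a[c("chain", "resno", "aa")])
  res <- res[order(res$chain, res$resno), ]
  hits <- list()
  for (i in seq_len(nrow(res))) {
    if (!res$aa[i] %in% c("K", "R", "H")) next
    for (j in seq_len(nrow(res))) {
      if (!res$aa[j] %in% c("D", "E")) next
      d <- oracle_min_dist(model, res$chain[i], res$resno[i],
                           res$chain[j], res$resno[j],
                           ORACLE_CHARGED[[res$aa[i]]],
                           ORACLE_CHARGED[[res$aa[j]]])
      if (is.finite(d) && d <= cutoff) {
        hits[[length(hits) + 1L]] <- data.frame(
          chain_a = res$chain[i], resno_a = res$resno[i],
          chain_b = res$chain[j], resno_b = res$resno[j], distance = d)
      }
    }
  }
  if (!length(hits)) return(NULL)
  do.call(rbind, hits)
}

oracle_hbonds <- function(model, cutoff = 3.6) {
  a <- model$atoms
  res <- unique(a[c("chain", "resno", "aa")])
  res <- res[order(res$chain, res$resno), ]
  hits <- list()
  for (i in seq_len(nrow(res))) {
    for (j in seq_len(nrow(res))) {
      keyi <- paste(res$chain[i], res$resno[i])
      keyj <- paste(res$chain[j], res$resno[j])
      if (keyi >= keyj) next
      if (res$chain[i] == res$chain[j] &&
          abs(res$resno[i] - res$resno[j]) < 2) next
      no_i <- a$atom[a$chain == res$chain[i] & a$resno == res$resno[i] &
                       a$element %in% c("N", "O")]
      no_j <- a$atom[a$chain == res$chain[j] & a$resno == res$resno[j] &
                       a$element %in% c("N", "O")]
      if (!length(no_i) || !length(no_j)) next
      d <- oracle_min_dist(model, res$chain[i], res$resno[i],
                           res$chain[j], res$resno[j], no_i, no_j)
      if (is.finite(d) && d <= cutoff) {
        hits[[length(hits) + 1L]] <- data.frame(
          chain_a = res$chain[i], resno_a = res$resno[i],
          chain_b = res$chain[j], resno_b = res$resno[j], distance = d)
      }
    }
  }
  if (!length(hits)) return(NULL)
  do.call(rbind, hits)
}

# ---- random structure fixture ------------------------------------------
# Random residues dropped with random rigid rotations in a cube, built
# directly through new_structure() (independent of synth_structure's
# layout logic).
random_model <- function(n_res = 8, box = 18, seed = 1) {
  set.seed(seed)
  aas <- sample(AA20, n_res, replace = TRUE)
  rows <- lapply(seq_len(n_res), function(i) {
    tpl <- spsmap:::.residue_template(aas[i])
    # random rotation via QR of a random matrix
    q <- qr.Q(qr(matrix(rnorm(9), 3)))
    xyz <- as.matrix(tpl[, c("x", "y", "z")]) %*% q
    ctr <- runif(3, 0, box)
    data.frame(chain = "A", resno = i * 3, resname = spsmap:::AA_1TO3[[aas[i]]],
               atom = tpl$atom, element = tpl$element,
               x = xyz[, 1] + ctr[1], y = xyz[, 2] + ctr[2],
               z = xyz[, 3] + ctr[3], stringsAsFactors = FALSE)
  })
  new_structure(do.call(rbind, rows), source = "random fixture")
}

# ---- naive run-length segmentation -------------------------------------
oracle_segments <- function(score, threshold, direction, min_length) {
  ok <- if (direction == "above") score >= threshold else score <= threshold
  out <- NULL
  i <- 1
  n <- length(ok)
  while (i <= n) {
    if (!ok[i]) { i <- i + 1; next }
    j <- i
    while (j < n && ok[j + 1]) j <- j + 1
    if (j - i + 1 >= min_length) out <- rbind(out, c(i, j))
    i <- j + 1
  }
  out
}
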