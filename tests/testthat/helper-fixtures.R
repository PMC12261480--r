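# In-code fixture builders shared across test files.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_seq <- function(n) paste(sample(AA20, n, replace = TRUE), collapse = "")

# Substitute a fixed number of positions, guaranteeing a different letter.
mutate_seq <- function(seq, n_mut) {
  s <- strsplit(seq, "")[[1]]
  pos <- sample(seq_along(s), n_mut)
  s[pos] <- vapply(s[pos], function(a) sample(setdiff(AA20, a), 1), "")
  paste(s, collapse = "")
}

# Minimal chain_structure built directly from vectors; linear Calpha trace
# along x unless coordinates are supplied.
mk_chain <- function(bfac, present = NULL, aa = NULL, xyz = NULL,
                     sid = "TEST", ch = "A", resolution = 2.0, r_value = 0.2,
                     molecule_class = "protein") {
  n <- length(bfac)
  if (is.null(present)) present <- rep(TRUE, n)
  if (is.null(aa)) aa <- sample(AA20, n, replace = TRUE)
  if (is.null(xyz)) xyz <- cbind(3.8 * (seq_len(n) - 1), 0, 0)
  bfac[!present] <- NA_real_
  chain_structure(sid, ch, data.frame(
    seq_index = seq_len(n), aa = aa, present = present,
    x = ifelse(present, xyz[, 1], NA_real_),
    y = ifelse(present, xyz[, 2], NA_real_),
    z = ifelse(present, xyz[, 3], NA_real_),
    bfactor = bfac, resno = seq_len(n), icode = "",
    stringsAsFactors = FALSE),
    resolution = resolution, r_value = r_value,
    molecule_class = molecule_class)
}

# Chain at arbitrary coordinates with constant B-factors.
mk_coord_chain <- function(xyz, sid = "TEST", ch = "A") {
  mk_chain(rep(20, nrow(xyz)), xyz = xyz, sid = sid, ch = ch)
}

# Population-statistics oracle written with bare arithmetic.
oracle_norm_b <- function(b) {
  obs <- !is.na(b)
  m <- sum(b[obs]) / sum(obs)
  s <- sqrt(sum((b[obs] - m)^2) / sum(obs))
  out <- rep(NA_real_, length(b))
  out[obs] <- if (s == 0) 0 else (b[obs] - m) / s
  out
}

# O(n^2) contact oracle over two coordinate sets.
oracle_contacts <- function(xyz_a, xyz_b, cutoff) {
  fa <- rep(FALSE, nrow(xyz_a))
  fb <- rep(FALSE, nrow(xyz_b))
  for (i in seq_len(nrow(xyz_a))) {
    for (j in seq_len(nrow(xyz_b))) {
      if (sum((xyz_a[i, ] - xyz_b[j, ])^2) <= cutoff^2) {
        fa[i] <- TRUE
        fb[j] <- TRUE
      }
    }
  }
  list(a = fa, b = fb)
}

# Pairwise-concordance AUC oracle (O(n_pos * n_neg)).
oracle_auc <- function(scores, labels) {
  sp <- scores[labels == 1]
  sn <- scores[labels == 0]
  tot <- 0
  for (p in sp) for (n in sn) tot <- tot + (p > n) + 0.5 * (p == n)
  tot / (length(sp) * length(sn))
}
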