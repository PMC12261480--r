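mk_record <- function(key, L, p_soft = 0.3, mask_at = integer(0)) {
  freq <- ifelse(runif(L) < p_soft, runif(L, 0.1, 1), 0)
  mask <- seq_len(L) %in% mask_at
  freq[mask] <- NA_real_
  bin <- ifelse(mask, NA_integer_, as.integer(freq > 0))
  dataset_record(key, random_seq(L), bin, freq, mask)
}

test_that("length filtering keeps the inclusive 20..2048 window", {
  set.seed(51)
  recs <- lapply(c(19, 20, 2048, 2049), function(L) mk_record(paste0("r", L), L))
  kept <- filter_lengths(recs)
  expect_equal(vapply(kept, function(r) nchar(r$sequence), 1L), c(20, 2048))
  expect_length(filter_lengths(list()), 0)
  expect_length(filter_lengths(recs, 1, 1e6), 4)
})

test_that("splits are exact under largest-remainder rounding and deterministic", {
  set.seed(52)
  recs <- lapply(1:100, function(i) mk_record(paste0("r", i), 30))
  s1 <- make_splits(recs, seed = 7)
  splits <- vapply(s1, function(r) r$split, "")
  expect_equal(unname(table(splits)[c("train", "val", "test")]),
               c(70, 10, 20), ignore_attr = TRUE)
  s2 <- make_splits(recs, seed = 7)
  expect_identical(vapply(s2, function(r) r$split, ""), splits)
  s3 <- make_splits(recs, seed = 8)
  expect_false(identical(vapply(s3, function(r) r$split, ""), splits))
  # 7 records at 0.7/0.1/0.2: raw 4.9/0.7/1.4 -> 5/1/1 by largest remainder
  s7 <- make_splits(recs[1:7], seed = 1)
  expect_equal(unname(table(vapply(s7, function(r) r$split, ""))[c("train", "val", "test")]),
               c(5, 1, 1), ignore_attr = TRUE)
  expect_error(make_splits(recs[1:2]), "at least 3")
})

test_that("split assignment is a partition of the input", {
  set.seed(53)
  recs <- lapply(1:37, function(i) mk_record(paste0("r", i), 25))
  s <- make_splits(recs, seed = 3)
  expect_identical(sort(vapply(s, function(r) r$key, "")),
                   sort(vapply(recs, function(r) r$key, "")))
  expect_false(any(vapply(s, function(r) is.na(r$split), TRUE)))
})

test_that("split pruning equals the exhaustive identity filter", {
  set.seed(54)
  base <- random_seq(40)
  seqs <- c(base,
            vapply(c(1, 4, 10, 18, 26, 32), function(k) mutate_seq(base, k), ""),
            vapply(1:5, function(i) random_seq(35), ""))
  recs <- lapply(seq_along(seqs), function(i) {
    L <- nchar(seqs[i])
    dataset_record(paste0("r", i), seqs[i], rep(0L, L), rep(0, L),
                   rep(FALSE, L))
  })
  s <- make_splits(recs, seed = 5)
  for (t in c(0.9, 0.5, 0.3)) {
    pruned <- prune_splits(s, t)
    got <- vapply(pruned, function(r) r$key, "")
    train <- Filter(function(r) r$split == "train", s)
    train_seqs <- vapply(train, function(r) r$sequence, "")
    want <- vapply(s, function(r) {
      if (r$split == "train") return(TRUE)
      all(vapply(train_seqs, function(ts)
        align_pair(r$sequence, ts)$identity < t, TRUE))
    }, TRUE)
    expect_identical(got, vapply(s[want], function(r) r$key, ""))
    # leakage bound holds for what remains
    for (r in pruned) {
      if (r$split == "train") next
      for (ts in train_seqs)
        expect_lt(align_pair(r$sequence, ts)$identity, t)
    }
  }
  # an exact duplicate of a train record is dropped at every threshold
  # (checked whenever the random split separates the duplicate pair)
  recs2 <- c(recs, list(dataset_record("dup", recs[[1]]$sequence,
                                       rep(0L, 40), rep(0, 40), rep(FALSE, 40))))
  s2 <- make_splits(recs2, seed = 11)
  k1 <- Filter(function(r) r$key %in% c("r1", "dup"), s2)
  if (length(unique(vapply(k1, function(r) r$split, ""))) > 1 &&
      any(vapply(k1, function(r) r$split, "") == "train")) {
    for (t in c(0.9, 0.7, 0.5, 0.3)) {
      kept <- vapply(prune_splits(s2, t), function(r) r$key, "")
      eval_key <- k1[[which(vapply(k1, function(r) r$split, "") != "train")]]$key
      expect_false(eval_key %in% kept)
    }
  }
  # threshold 1.0 with no duplicates drops nothing
  expect_length(prune_splits(s, 1.0), length(s))
})

test_that("export/import round trip is bit-exact and the manifest recounts", {
  set.seed(55)
  recs <- make_splits(lapply(1:12, function(i)
    mk_record(paste0("r", i), sample(25:40, 1), mask_at = i)), seed = 2)
  dir <- tempfile("ds")
  export_dataset(recs, dir)
  back <- import_dataset(dir)
  expect_equal(length(back), length(recs))
  for (i in seq_along(recs)) {
    expect_identical(back[[i]]$key, recs[[i]]$key)
    expect_identical(back[[i]]$sequence, recs[[i]]$sequence)
    expect_identical(back[[i]]$binary_labels, recs[[i]]$binary_labels)
    expect_equal(back[[i]]$freq_labels, recs[[i]]$freq_labels, tolerance = 1e-12)
    expect_identical(back[[i]]$mask, recs[[i]]$mask)
    expect_identical(back[[i]]$split, recs[[i]]$split)
  }
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  splits <- vapply(recs, function(r) r$split, "")
  expect_equal(manifest$counts$train, sum(splits == "train"))
  expect_equal(manifest$counts$test, sum(splits == "test"))
  # label balance from the manifest equals a recount over the TSVs
  tsvs <- list.files(file.path(dir, "labels"), full.names = TRUE)
  lab <- unlist(lapply(tsvs, function(f)
    utils::read.table(f, sep = "\t", header = TRUE,
                      colClasses = "character")$binary))
  expect_equal(manifest$overall_label_balance,
               mean(as.integer(lab[lab != "-"])))
  # masked positions carry the sentinel
  expect_true(any(lab == "-"))
})

test_that("records enforce the binary = (freq > 0) collapse", {
  expect_error(dataset_record("bad", "ACDEF", c(1L, 0L, 0L, 0L, 0L),
                              c(0, 0, 0, 0, 0), rep(FALSE, 5)),
               "binary labels")
  p <- structure(list(representative_key = "k", cluster_id = "C1", length = 4,
                      n_chains = 2,
                      table = data.frame(
                        position = 1:4, aa = c("A", "C", "D", "E"),
                        n_aligned = c(2, 2, 2, 0), n_missing = c(0, 2, 1, 0),
                        n_soft = c(0, 2, 1, 0),
                        n_interface_protein = 0, n_interface_nucleic = 0,
                        freq_soft = c(0, NA, 0.5, NA),
                        freq_interface = c(0, 0, 0, NA),
                        category = c("none", "ID", "SD", "unaligned"),
                        dto = c(FALSE, FALSE, TRUE, FALSE))),
                 class = "cluster_profile")
  r <- profile_to_record(p)
  expect_identical(r$binary_labels, c(0L, NA, 1L, NA))
  expect_identical(r$mask, c(FALSE, TRUE, FALSE, TRUE))
})
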