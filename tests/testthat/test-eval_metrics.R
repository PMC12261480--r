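prof <- function(scores, labels, key = "p") score_profile(key, scores, labels)

test_that("confusion counts follow the score >= threshold convention", {
  p <- prof(c(0.9, 0.2, 0.8, 0.1), c(1L, 1L, 0L, 0L))
  cc <- confusion(p, 0.5)
  expect_equal(unlist(cc[c("tp", "fp", "fn", "tn")]),
               c(tp = 1, fp = 1, fn = 1, tn = 1))
  # score exactly at the threshold counts positive
  cc <- confusion(prof(c(0.5, 0.5), c(1L, 0L)), 0.5)
  expect_equal(c(cc$tp, cc$fp, cc$fn, cc$tn), c(1, 1, 0, 0))
  # perfect scores leave no errors
  cc <- confusion(prof(c(1, 1, 0, 0), c(1L, 1L, 0L, 0L)), 0.5)
  expect_equal(c(cc$fp, cc$fn), c(0, 0))
  # masked / unscored residues are excluded; none left is an error
  expect_error(confusion(prof(c(NA, 0.5), c(1L, NA))), "no evaluable")
})

test_that("MCC and F1 match their closed forms and zero conventions", {
  cc <- structure(list(tp = 3, fp = 1, fn = 2, tn = 4),
                  class = "confusion_counts")
  expect_equal(mcc(cc), 10 / sqrt(600), tolerance = 1e-12)
  expect_equal(f1(cc), 6 / 9, tolerance = 1e-12)
  perfect <- structure(list(tp = 5, fp = 0, fn = 0, tn = 5),
                       class = "confusion_counts")
  expect_equal(mcc(perfect), 1.0)
  expect_equal(f1(perfect), 1.0)
  # all-positive predictor on mixed labels: a zero factor forces MCC = 0
  allpos <- confusion(prof(rep(1, 4), c(1L, 1L, 0L, 0L)), 0.5)
  expect_equal(mcc(allpos), 0)
  none <- structure(list(tp = 0, fp = 0, fn = 0, tn = 7),
                    class = "confusion_counts")
  expect_equal(f1(none), 0)
})

test_that("ROC AUC matches the pairwise-concordance oracle", {
  expect_equal(roc_auc(prof(c(0.9, 0.8, 0.2, 0.1), c(1L, 1L, 0L, 0L))), 1.0)
  expect_equal(roc_auc(prof(c(0.4, 0.4), c(1L, 0L))), 0.5)
  set.seed(61)
  for (i in 1:10) {
    n <- 12
    s <- round(runif(n), 2)   # rounding plants score ties
    l <- as.integer(runif(n) < 0.5)
    if (sum(l) %in% c(0, n)) next
    expect_equal(roc_auc(prof(s, l)), oracle_auc(s, l), tolerance = 1e-12)
  }
  expect_error(roc_auc(prof(c(0.1, 0.9), c(1L, 1L))), "no negative")
  expect_error(roc_auc(prof(c(0.1, 0.9), c(0L, 0L))), "no positive")
})

test_that("ROC AUC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(62)
  s <- runif(200)
  l <- as.integer(runif(200) < 0.4)
  got <- roc_auc(prof(s, l))
  want <- as.numeric(pROC::auc(pROC::roc(l, s, quiet = TRUE,
                                         direction = "<", levels = c(0, 1))))
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("average precision matches exhaustive threshold enumeration", {
  expect_equal(pr_auc(prof(c(0.9, 0.8, 0.2), c(1L, 1L, 0L))), 1.0)
  # uniform scores collapse to a single threshold: AP = prevalence
  expect_equal(pr_auc(prof(rep(0.5, 10), c(rep(1L, 3), rep(0L, 7)))), 0.3)
  set.seed(63)
  for (i in 1:10) {
    n <- 15
    s <- round(runif(n), 1)
    l <- as.integer(runif(n) < 0.4)
    if (sum(l) == 0) next
    # oracle: step-sum over the distinct observed scores as thresholds
    th <- sort(unique(s), decreasing = TRUE)
    prev_r <- 0; ap <- 0
    for (t in th) {
      tp <- sum(s >= t & l == 1L); fp <- sum(s >= t & l == 0L)
      r <- tp / sum(l == 1L); p <- tp / (tp + fp)
      ap <- ap + (r - prev_r) * p
      prev_r <- r
    }
    expect_equal(pr_auc(prof(s, l)), ap, tolerance = 1e-12)
  }
  expect_error(pr_auc(prof(c(0.2, 0.8), c(0L, 0L))), "no positive")
})

test_that("max F1 scans the grid and returns the smallest best threshold", {
  p <- prof(c(0.3, 0.7), c(0L, 1L))
  m <- max_f1(p)
  expect_equal(m$max_f1, 1.0)
  expect_equal(m$threshold, 0.31)   # first grid point separating the scores
  # max over the grid dominates the fixed 0.5 threshold
  set.seed(64)
  for (i in 1:5) {
    s <- runif(20); l <- as.integer(runif(20) < 0.5)
    if (sum(l) %in% c(0, 20)) next
    pp <- prof(s, l)
    expect_gte(max_f1(pp)$max_f1 + 1e-12, f1(confusion(pp, 0.5)))
    # exhaustive grid oracle
    grid <- seq(0, 1, by = 0.01)
    want <- max(vapply(grid, function(t) {
      tp <- sum(s >= t & l == 1L)
      d <- 2 * tp + sum(s >= t & l == 0L) + sum(s < t & l == 1L)
      if (d == 0) 0 else 2 * tp / d
    }, 1.0))
    expect_equal(max_f1(pp)$max_f1, want, tolerance = 1e-12)
  }
  # constant scores: every threshold <= the score gives the all-positive F1
  p <- prof(rep(0.4, 8), c(rep(1L, 3), rep(0L, 5)))
  allpos_f1 <- 2 * 3 / (2 * 3 + 5 + 0)
  expect_equal(max_f1(p)$max_f1, allpos_f1)
})

test_that("rank-based metrics are invariant under monotone score transforms", {
  set.seed(65)
  s <- sample(seq(0.1, 0.9, by = 0.1), 20, replace = TRUE)
  l <- as.integer(runif(20) < 0.5)
  l[1:2] <- c(0L, 1L)
  p1 <- prof(s, l)
  p2 <- prof(s / 2 + 0.25, l)   # strictly increasing, keeps grid separability
  expect_equal(roc_auc(p1), roc_auc(p2), tolerance = 1e-12)
  expect_equal(pr_auc(p1), pr_auc(p2), tolerance = 1e-12)
  expect_equal(max_f1(p1)$max_f1, max_f1(p2)$max_f1, tolerance = 1e-12)
})

test_that("complement symmetry holds for tie-free scores", {
  set.seed(66)
  s <- sample(seq(0.01, 0.99, by = 0.01), 30)
  l <- as.integer(runif(30) < 0.5)
  l[1:2] <- c(0L, 1L)
  expect_equal(roc_auc(prof(s, l)) + roc_auc(prof(1 - s, l)), 1.0,
               tolerance = 1e-12)
})

test_that("pooled confusion equals the sum of per-protein confusions", {
  set.seed(67)
  ps <- lapply(1:4, function(i) {
    n <- sample(10:20, 1)
    prof(runif(n), as.integer(runif(n) < 0.4), key = paste0("p", i))
  })
  pooled <- confusion(ps, 0.5)
  per <- lapply(ps, confusion, threshold = 0.5)
  expect_equal(pooled$tp, sum(vapply(per, function(c) c$tp, 1)))
  expect_equal(pooled$fp, sum(vapply(per, function(c) c$fp, 1)))
  expect_equal(pooled$fn, sum(vapply(per, function(c) c$fn, 1)))
  expect_equal(pooled$tn, sum(vapply(per, function(c) c$tn, 1)))
})

test_that("coverage filtering drops sparse profiles and reports the pool", {
  full <- prof(runif(10), rep(c(0L, 1L), 5), key = "full")
  half <- prof(c(runif(5), rep(NA, 5)), rep(c(0L, 1L), 5), key = "half")
  kept <- coverage_filter(list(full, half), 1.0)
  expect_length(kept, 1)
  expect_equal(kept[[1]]$key, "full")
  expect_equal(attr(kept, "retained_residue_fraction"), 0.5)
  expect_length(coverage_filter(list(full, half), 0.5), 2)
})

test_that("Spearman correlation handles masks, ties and reversals", {
  expect_equal(profile_spearman(1:10, 1:10), 1.0)
  expect_equal(profile_spearman(1:10, 10:1), -1.0)
  set.seed(68)
  a <- sample(1:5, 10, replace = TRUE)   # ties -> midranks
  b <- runif(10)
  ra <- rank(a); rb <- rank(b)
  want <- sum((ra - mean(ra)) * (rb - mean(rb))) /
    sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
  expect_equal(profile_spearman(a, b), want, tolerance = 1e-12)
  expect_equal(profile_spearman(c(NA, 1:5), c(0, 1:5)),
               profile_spearman(1:5, 1:5))
  expect_error(profile_spearman(1:4, 1:5), "lengths differ")
  expect_error(profile_spearman(c(1, 2, NA, NA), c(1, 2, 3, 4)), "at least 3")
})

test_that("prediction and reference files round-trip through the readers", {
  ref_path <- tempfile(fileext = ".txt")
  writeLines(c(">seq1", "01-10", ">seq2", "110"), ref_path)
  ref <- read_reference_labels(ref_path)
  expect_identical(ref$seq1, c(0L, 1L, NA, 1L, 0L))
  pred_path <- tempfile(fileext = ".txt")
  writeLines(c(">seq1",
               "1 M 0.90", "2 K 0.10", "3 T 0.50", "4 A -", "5 Y 0.75",
               ">seq2",
               "1 G 0.20", "2 G 0.80", "3 S 0.60"), pred_path)
  profs <- read_prediction_file(pred_path, reference = ref)
  expect_equal(profs$seq1$scores, c(0.9, 0.1, 0.5, NA, 0.75))
  expect_identical(profs$seq1$labels, ref$seq1)
  rep <- metrics_report(profs)
  expect_true(all(c("roc_auc", "pr_auc", "mcc", "f1", "max_f1") %in% names(rep)))
  expect_equal(rep$n_residues, 6)   # seq1 pos 3 masked, pos 4 unscored
})

test_that("scores outside the unit interval are rejected on load", {
  expect_error(score_profile("bad", c(0.5, 1.2), c(0L, 1L)), "outside")
  expect_error(score_profile("bad", c(0.5, 0.2), c(2L, 1L)), "labels")
})
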