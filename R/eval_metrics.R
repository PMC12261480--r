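# Per-residue binary-classification metrics with pooled-residue evaluation,
# coverage filtering and profile correlation.
#
# Conventions (documented because upstream descriptions are silent on them):
# a score exactly at the decision threshold counts positive; MCC and F1 are
# defined as 0 when a denominator vanishes; metrics pool all evaluable
# residues (unmasked label, non-missing score) across profiles.

#' Construct a score profile
#'
#' Per-residue prediction scores with reference labels for one sequence.
#'
#' @param key Profile key.
#' @param scores Numeric in [0, 1] per residue, \code{NA} where unscored.
#' @param labels Integer 0/1 per residue, \code{NA} where masked.
#' @return An object of class \code{score_profile}.
#' @export
score_profile <- function(key, scores, labels) {
  stopifnot(length(scores) == length(labels))
  bad <- !is.na(scores) & (scores < 0 | scores > 1)
  if (any(bad))
    stopf("profile %s: %d scores outside [0, 1]", key, sum(bad))
  if (!all(labels %in% c(0L, 1L, NA)))
    stopf("profile %s: labels must be 0, 1 or NA", key)
  structure(list(key = key, scores = as.numeric(scores),
                 labels = as.integer(labels)),
            class = "score_profile")
}

as_profile_list <- function(profiles) {
  if (inherits(profiles, "score_profile")) list(profiles) else profiles
}

# Pool evaluable residues across profiles.
pool_scores <- function(profiles) {
  profiles <- as_profile_list(profiles)
  s <- unlist(lapply(profiles, function(p) p$scores))
  l <- unlist(lapply(profiles, function(p) p$labels))
  ok <- !is.na(s) & !is.na(l)
  list(scores = s[ok], labels = l[ok])
}

#' Confusion counts at a decision threshold
#'
#' Prediction is positive iff \code{score >= threshold}; masked or unscored
#' residues are excluded.
#'
#' @param profiles A \code{score_profile} or list of them.
#' @param threshold Decision threshold, default 0.5.
#' @return A \code{confusion_counts} object with \code{tp}, \code{fp},
#'   \code{fn}, \code{tn}.
#' @export
confusion <- function(profiles, threshold = 0.5) {
  p <- pool_scores(profiles)
  if (length(p$scores) == 0) stopf("no evaluable residues")
  pred <- p$scores >= threshold
  structure(list(tp = sum(pred & p$labels == 1L),
                 fp = sum(pred & p$labels == 0L),
                 fn = sum(!pred & p$labels == 1L),
                 tn = sum(!pred & p$labels == 0L)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> TP=%d FP=%d FN=%d TN=%d\n",
              x$tp, x$fp, x$fn, x$tn))
  invisible(x)
}

#' Matthews correlation coefficient
#'
#' \code{(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))}; defined as 0
#' when any factor of the denominator is zero.
#'
#' @param c A \code{\link{confusion}} result.
#' @return MCC in [-1, 1].
#' @export
mcc <- function(c) {
  d <- prod(c(c$tp + c$fp, c$tp + c$fn, c$tn + c$fp, c$tn + c$fn))
  if (d == 0) return(0)
  (as.numeric(c$tp) * c$tn - as.numeric(c$fp) * c$fn) / sqrt(d)
}

#' F1 score
#'
#' \code{2*TP / (2*TP + FP + FN)}; 0 when the denominator is 0.
#'
#' @param c A \code{\link{confusion}} result.
#' @return F1 in [0, 1].
#' @export
f1 <- function(c) {
  d <- 2 * c$tp + c$fp + c$fn
  if (d == 0) return(0)
  2 * c$tp / d
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) computation with midrank tie handling, equal to
#' the trapezoidal area under the empirical ROC curve.
#'
#' @param profiles A \code{score_profile} or list of them.
#' @return AUC in [0, 1].
#' @export
roc_auc <- function(profiles) {
  p <- pool_scores(profiles)
  npos <- sum(p$labels == 1L)
  nneg <- sum(p$labels == 0L)
  if (npos == 0) stopf("ROC AUC undefined: no positive residues")
  if (nneg == 0) stopf("ROC AUC undefined: no negative residues")
  r <- rank(p$scores)   # midranks for ties
  (sum(r[p$labels == 1L]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Area under the precision-recall curve (average precision)
#'
#' Average-precision summation over recall steps,
#' \code{sum_k (R_k - R_{k-1}) * P_k}, with tied scores treated as one
#' threshold group (so uniform scores give AP equal to the positive
#' prevalence); no trapezoidal interpolation.
#'
#' @param profiles A \code{score_profile} or list of them.
#' @return AP in (0, 1].
#' @export
pr_auc <- function(profiles) {
  p <- pool_scores(profiles)
  npos <- sum(p$labels == 1L)
  if (npos == 0) stopf("PR AUC undefined: no positive residues")
  ord <- order(p$scores, decreasing = TRUE)
  s <- p$scores[ord]; l <- p$labels[ord]
  grp_end <- which(s != c(s[-1], NA_real_) | seq_along(s) == length(s))
  tp <- cumsum(l == 1L)[grp_end]
  nn <- grp_end                         # total predictions at each threshold
  prec <- tp / nn
  rec <- tp / npos
  sum(diff(c(0, rec)) * prec)
}

#' Maximum F1 over a threshold grid
#'
#' Scans decision thresholds from 0 to 1 inclusive at the given step and
#' returns the maximum F1 with the smallest threshold achieving it.
#'
#' @param profiles A \code{score_profile} or list of them.
#' @param step Grid step, default 0.01.
#' @return List with \code{max_f1} and \code{threshold}.
#' @export
max_f1 <- function(profiles, step = 0.01) {
  p <- pool_scores(profiles)
  if (length(p$scores) == 0) stopf("no evaluable residues")
  grid <- seq(0, 1, by = step)
  f1s <- vapply(grid, function(t) {
    pred <- p$scores >= t
    tp <- sum(pred & p$labels == 1L)
    d <- 2 * tp + sum(pred & p$labels == 0L) + sum(!pred & p$labels == 1L)
    if (d == 0) 0 else 2 * tp / d
  }, 1.0)
  best <- which.max(f1s)   # first (smallest) threshold achieving the max
  list(max_f1 = f1s[best], threshold = grid[best])
}

#' Filter profiles by scored-residue coverage
#'
#' Drops profiles whose fraction of labeled residues that carry a score is
#' below \code{min_fraction}; the retained-residue fraction of the labeled
#' pool is attached as an attribute.
#'
#' @param profiles List of \code{score_profile}.
#' @param min_fraction Minimum scored fraction in [0, 1].
#' @return Filtered list with attribute \code{retained_residue_fraction}.
#' @export
coverage_filter <- function(profiles, min_fraction) {
  profiles <- as_profile_list(profiles)
  labeled <- vapply(profiles, function(p) sum(!is.na(p$labels)), 1L)
  scored <- vapply(profiles, function(p)
    sum(!is.na(p$labels) & !is.na(p$scores)), 1L)
  frac <- ifelse(labeled == 0, 1, scored / labeled)
  keep <- frac >= min_fraction
  out <- profiles[keep]
  attr(out, "retained_residue_fraction") <-
    if (sum(labeled) == 0) NA_real_ else sum(labeled[keep]) / sum(labeled)
  out
}

#' Spearman correlation of two per-residue tracks
#'
#' Rank correlation with midrank tie handling, after removing positions where
#' either track is \code{NA}.
#'
#' @param track_a,track_b Numeric vectors of equal length.
#' @return Spearman rho.
#' @export
profile_spearman <- function(track_a, track_b) {
  if (length(track_a) != length(track_b))
    stopf("track lengths differ: %d vs %d", length(track_a), length(track_b))
  ok <- !is.na(track_a) & !is.na(track_b)
  if (sum(ok) < 3) stopf("need at least 3 jointly defined positions")
  stats::cor(track_a[ok], track_b[ok], method = "spearman")
}

#' Full metrics report
#'
#' @param profiles List of \code{score_profile}.
#' @param threshold Decision threshold for the thresholded metrics.
#' @param step Grid step for the max-F1 scan.
#' @return Named list: roc_auc, pr_auc, mcc, f1, max_f1, max_f1_threshold,
#'   n_residues.
#' @export
metrics_report <- function(profiles, threshold = 0.5, step = 0.01) {
  cc <- confusion(profiles, threshold)
  mf <- max_f1(profiles, step)
  list(roc_auc = roc_auc(profiles), pr_auc = pr_auc(profiles),
       mcc = mcc(cc), f1 = f1(cc),
       max_f1 = mf$max_f1, max_f1_threshold = mf$threshold,
       n_residues = cc$tp + cc$fp + cc$fn + cc$tn)
}

#' Read per-residue predictions in a CAID-like format
#'
#' Plain-text blocks: a \code{">key"} header line followed by one line per
#' residue with whitespace-separated columns (index, residue letter, score,
#' optional binary). Missing scores may be given as \code{"-"}.
#'
#' @param path File path.
#' @param reference Optional named list/vector of 0/1/\code{NA} label vectors
#'   keyed like the prediction blocks; when absent labels are \code{NA}.
#' @return List of \code{\link{score_profile}}.
#' @export
read_prediction_file <- function(path, reference = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grep("^>", lines)
  if (length(hdr) == 0) stopf("no '>' header lines in '%s'", path)
  bounds <- c(hdr, length(lines) + 1L)
  out <- list()
  for (h in seq_along(hdr)) {
    key <- trimws(sub("^>", "", lines[hdr[h]]))
    body <- lines[seq(hdr[h] + 1L, bounds[h + 1L] - 1L)]
    parts <- strsplit(trimws(body), "\\s+")
    idx <- as.integer(vapply(parts, `[`, "", 1L))
    sc <- vapply(parts, `[`, "", 3L)
    scores <- rep(NA_real_, max(idx))
    scores[idx] <- suppressWarnings(as.numeric(ifelse(sc == "-", NA, sc)))
    labels <- if (!is.null(reference) && !is.null(reference[[key]]))
      reference[[key]] else rep(NA_integer_, length(scores))
    out[[key]] <- score_profile(key, scores, labels)
  }
  out
}

#' Read reference labels from a FASTA-like label file
#'
#' Each record is a \code{">key"} header followed by a string of \code{0},
#' \code{1} and \code{-} characters (\code{-} = masked).
#'
#' @param path File path.
#' @return Named list of integer label vectors.
#' @export
read_reference_labels <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grep("^>", lines)
  bounds <- c(hdr, length(lines) + 1L)
  out <- list()
  for (h in seq_along(hdr)) {
    key <- trimws(sub("^>", "", lines[hdr[h]]))
    s <- paste(lines[seq(hdr[h] + 1L, bounds[h + 1L] - 1L)], collapse = "")
    ch <- strsplit(s, "")[[1]]
    out[[key]] <- suppressWarnings(ifelse(ch == "-", NA_integer_, as.integer(ch)))
  }
  out
}
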