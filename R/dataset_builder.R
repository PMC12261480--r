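# ML-ready dataset export: records, length filtering, randomized splits with
# largest-remainder rounding, identity pruning against the training set, and
# FASTA/TSV/JSON serialization.

#' Construct a dataset record
#'
#' A representative sequence with per-position binary soft-disorder labels,
#' soft-disorder frequencies, a mask for undefined positions (ID /
#' always-missing or unaligned sites) and a split assignment.
#'
#' @param key Record key (chain key of the cluster representative).
#' @param sequence Amino-acid string.
#' @param binary_labels Integer 0/1 per position (\code{NA} under the mask).
#' @param freq_labels Numeric fraction per position (\code{NA} under the mask).
#' @param mask Logical per position; \code{TRUE} = excluded from labels.
#' @param split \code{"train"}, \code{"val"}, \code{"test"} or \code{NA}.
#' @return An object of class \code{dataset_record}.
#' @export
dataset_record <- function(key, sequence, binary_labels, freq_labels, mask,
                           split = NA_character_) {
  L <- nchar(sequence)
  stopifnot(length(binary_labels) == L, length(freq_labels) == L,
            length(mask) == L)
  ok <- !mask
  if (any(ok & (binary_labels != (freq_labels > 0))))
    stopf("binary labels must equal (freq > 0) outside the mask (record %s)", key)
  structure(list(key = key, sequence = sequence,
                 binary_labels = as.integer(binary_labels),
                 freq_labels = as.numeric(freq_labels),
                 mask = as.logical(mask), split = split),
            class = "dataset_record")
}

#' Turn a cluster profile into a dataset record
#'
#' Binary collapse uses the at-least-once rule: a position is labeled 1 iff
#' its soft-disorder frequency is positive, i.e. some chain in the cluster
#' marks it soft. Positions with undefined frequency (ID or unaligned) are
#' masked. An optional minimum frequency raises the collapse cutoff.
#'
#' @param profile A \code{cluster_profile}.
#' @param min_freq Frequency strictly above which a position is labeled 1;
#'   default 0 (the at-least-once rule).
#' @return A \code{\link{dataset_record}}.
#' @export
profile_to_record <- function(profile, min_freq = 0) {
  t <- profile$table
  mask <- is.na(t$freq_soft)
  bin <- ifelse(mask, NA_integer_, as.integer(t$freq_soft > min_freq))
  frq <- ifelse(mask, NA_real_, t$freq_soft)
  dataset_record(profile$representative_key,
                 paste(t$aa, collapse = ""), bin, frq, mask)
}

record_length <- function(r) nchar(r$sequence)

#' Filter records by sequence length
#'
#' Keeps records whose length lies within the inclusive bounds; the defaults
#' drop sequences shorter than 20 or longer than 2048 residues.
#'
#' @param records List of \code{dataset_record}.
#' @param min_len,max_len Inclusive bounds.
#' @return Filtered list.
#' @export
filter_lengths <- function(records, min_len = 20L, max_len = 2048L) {
  Filter(function(r) {
    L <- record_length(r)
    L >= min_len && L <= max_len
  }, records)
}

# Largest-remainder apportionment of n into parts proportional to fractions.
largest_remainder <- function(n, fractions) {
  raw <- n * fractions
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Assign train/validation/test splits at random
#'
#' Uniform random assignment by record under a fixed seed; split sizes follow
#' the fractions with largest-remainder rounding, so round totals split
#' exactly (100 records at 0.7/0.1/0.2 give 70/10/20).
#'
#' @param records List of \code{dataset_record} (at least 3).
#' @param fractions Numeric of length 3 summing to 1 (train, val, test).
#' @param seed Integer seed; the same seed reproduces the assignment.
#' @return The records with \code{split} set; fractions and seed attached as
#'   attributes for the export manifest.
#' @export
make_splits <- function(records, fractions = c(0.70, 0.10, 0.20), seed = 1L) {
  stopifnot(length(fractions) == 3, abs(sum(fractions) - 1) < 1e-9)
  n <- length(records)
  if (n < 3) stopf("need at least 3 records to split, got %d", n)
  sizes <- largest_remainder(n, fractions)
  labels <- rep(c("train", "val", "test"), times = sizes)
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(seed)
  ord <- sample.int(n)
  assign_split <- character(n)
  assign_split[ord] <- labels
  out <- lapply(seq_len(n), function(i) {
    r <- records[[i]]
    r$split <- assign_split[i]
    r
  })
  attr(out, "fractions") <- fractions
  attr(out, "seed") <- seed
  out
}

#' Prune validation/test records against the training set
#'
#' Drops every validation or test record whose sequence identity to any
#' training record reaches the threshold (delegates to
#' \code{\link{prune_against}}); training records are never dropped.
#'
#' @param records List of split-assigned \code{dataset_record}.
#' @param threshold Identity threshold in (0, 1].
#' @return The pruned record list (attributes preserved).
#' @export
prune_splits <- function(records, threshold) {
  splits <- vapply(records, function(r) r$split, "")
  if (anyNA(splits) || any(splits == ""))
    stopf("records must have split assignments; run make_splits first")
  seqs <- stats::setNames(vapply(records, function(r) r$sequence, ""),
                          vapply(records, function(r) r$key, ""))
  train_keys <- names(seqs)[splits == "train"]
  eval_keys <- names(seqs)[splits != "train"]
  kept_eval <- names(prune_against(seqs[eval_keys], seqs[train_keys], threshold))
  keep <- splits == "train" | names(seqs) %in% kept_eval
  out <- records[keep]
  attributes(out) <- c(attributes(out),
                       attributes(records)[c("fractions", "seed")])
  out
}

label_balance <- function(records) {
  pos <- tot <- 0
  for (r in records) {
    ok <- !r$mask
    pos <- pos + sum(r$binary_labels[ok] == 1L)
    tot <- tot + sum(ok)
  }
  if (tot == 0) NA_real_ else pos / tot
}

#' Export a labeled dataset
#'
#' Writes \code{sequences.fasta}, one \code{labels/<key>.tsv} per record
#' (position, aa, binary, freq, mask; masked labels serialized as \code{"-"}),
#' and \code{manifest.json} with per-split record counts, label balance, the
#' split configuration echo and the seed.
#'
#' @param records Split-assigned \code{dataset_record} list.
#' @param out_dir Output directory (created if needed).
#' @return \code{out_dir}, invisibly.
#' @export
export_dataset <- function(records, out_dir) {
  dir.create(file.path(out_dir, "labels"), recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stopf("cannot create output directory '%s'", out_dir)
  keys <- vapply(records, function(r) r$key, "")
  write_fasta_seqs(stats::setNames(vapply(records, function(r) r$sequence, ""),
                                   keys),
                   file.path(out_dir, "sequences.fasta"))
  for (r in records) {
    t <- data.frame(
      position = seq_len(record_length(r)),
      aa = strsplit(r$sequence, "")[[1]],
      binary = ifelse(r$mask, "-", as.character(r$binary_labels)),
      freq = ifelse(r$mask, "-", format(r$freq_labels, digits = 15,
                                        scientific = FALSE, trim = TRUE)),
      mask = as.integer(r$mask),
      split = r$split,
      stringsAsFactors = FALSE)
    utils::write.table(t, file.path(out_dir, "labels",
                                    paste0(gsub("[^A-Za-z0-9_.-]", "_", r$key), ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  splits <- vapply(records, function(r) r$split, "")
  manifest <- list(
    n_records = length(records),
    counts = as.list(table(factor(splits, levels = c("train", "val", "test")))),
    label_balance = lapply(
      stats::setNames(nm = c("train", "val", "test")),
      function(s) label_balance(records[splits == s])),
    overall_label_balance = label_balance(records),
    fractions = attr(records, "fractions"),
    seed = attr(records, "seed"),
    keys = keys)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE)
  invisible(out_dir)
}

#' Re-import an exported dataset
#'
#' Inverse of \code{\link{export_dataset}}: reconstructs the record list
#' (sequences, labels, masks, splits) from the exported files.
#'
#' @param out_dir Directory written by \code{\link{export_dataset}}.
#' @return List of \code{dataset_record}.
#' @export
import_dataset <- function(out_dir) {
  manifest <- jsonlite::read_json(file.path(out_dir, "manifest.json"),
                                  simplifyVector = TRUE)
  seqs <- read_fasta_seqs(file.path(out_dir, "sequences.fasta"))
  records <- lapply(manifest$keys, function(key) {
    t <- utils::read.table(
      file.path(out_dir, "labels",
                paste0(gsub("[^A-Za-z0-9_.-]", "_", key), ".tsv")),
      sep = "\t", header = TRUE, colClasses = "character")
    mask <- t$mask == "1"
    dataset_record(key, seqs[[key]],
                   ifelse(mask, NA_integer_, suppressWarnings(as.integer(t$binary))),
                   ifelse(mask, NA_real_, suppressWarnings(as.numeric(t$freq))),
                   mask, split = t$split[1])
  })
  attr(records, "fractions") <- manifest$fractions
  attr(records, "seed") <- manifest$seed
  records
}

#' Read a pipeline configuration file
#'
#' YAML configuration for thresholds, split fractions and seed; missing keys
#' fall back to the documented defaults.
#'
#' @param path YAML file path.
#' @return Named list of configuration values.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- list(
    bfactor_threshold = 3.0, contact_cutoff = 5.0, probe = 1.4,
    asa_epsilon = 0.01, cluster_identity = 0.9, cluster_coverage = 0.9,
    reduce_identity = 0.5, reduce_coverage = 0.8,
    prune_thresholds = c(0.9, 0.7, 0.5, 0.3),
    min_len = 20L, max_len = 2048L,
    split_fractions = c(0.70, 0.10, 0.20), seed = 1L,
    xray_only = TRUE)
  utils::modifyList(defaults, cfg)
}
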