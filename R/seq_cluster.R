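# Identity/coverage clustering of chain sequences and leakage pruning.
#
# Pairwise global alignment goes through Biostrings::pairwiseAlignment
# (BLOSUM62, affine gaps). The identity denominator is the shorter sequence
# length, the CD-HIT convention; this one convention is used both for cluster
# construction and for train/test pruning so thresholds mean the same thing
# throughout.

#' Globally align two sequences
#'
#' Needleman-Wunsch global alignment with affine gap penalties. Identity is
#' the number of identical aligned residue pairs divided by the length of the
#' shorter sequence; coverage of each sequence is the fraction of it spanned
#' by the aligned region (terminal gaps excluded).
#'
#' @param seq_a,seq_b Non-empty amino-acid strings over the 20 standard
#'   letters plus \code{X}.
#' @param gap_open,gap_extend Affine gap penalties (positive costs).
#' @param submat Substitution matrix name, default \code{"BLOSUM62"}.
#' @return List with \code{identity}, \code{coverage_a}, \code{coverage_b}
#'   (fractions in [0,1]) and \code{mapping}, a two-column integer matrix of
#'   aligned position pairs (1-based, strictly increasing in both columns).
#' @export
align_pair <- function(seq_a, seq_b, gap_open = 11, gap_extend = 1,
                       submat = "BLOSUM62") {
  stopifnot(nchar(seq_a) >= 1, nchar(seq_b) >= 1)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seq_a), Biostrings::AAString(seq_b),
    substitutionMatrix = submat, gapOpening = gap_open,
    gapExtension = gap_extend, type = "global")
  pa <- strsplit(as.character(Biostrings::pattern(aln)), "")[[1]]
  pb <- strsplit(as.character(Biostrings::subject(aln)), "")[[1]]
  apos <- cumsum(pa != "-")
  bpos <- cumsum(pb != "-")
  both <- pa != "-" & pb != "-"
  mapping <- cbind(a = apos[both], b = bpos[both])
  nid <- sum(both & pa == pb)
  la <- nchar(seq_a); lb <- nchar(seq_b)
  if (any(both)) {
    span <- range(which(both))
    cov_a <- (apos[span[2]] - apos[span[1]] + 1) / la
    cov_b <- (bpos[span[2]] - bpos[span[1]] + 1) / lb
  } else {
    cov_a <- cov_b <- 0
  }
  list(identity = nid / min(la, lb), coverage_a = cov_a, coverage_b = cov_b,
       mapping = mapping)
}

#' Construct a cluster object
#'
#' A set of near-identical chains with one representative and, for every
#' member, a map of its positions onto representative positions.
#'
#' @param cluster_id Cluster identifier string.
#' @param representative_key Key of the representative member.
#' @param member_keys Character vector of member keys (includes the
#'   representative).
#' @param member_mappings Named list; for each member an integer vector of its
#'   sequence length giving the representative position each member position
#'   aligns to (\code{NA} where unaligned).
#' @param member_identities Named numeric vector of identities to the
#'   representative.
#' @return An object of class \code{seq_cluster}.
#' @export
seq_cluster <- function(cluster_id, representative_key, member_keys,
                        member_mappings, member_identities = NULL) {
  stopifnot(representative_key %in% member_keys,
            all(member_keys %in% names(member_mappings)))
  structure(list(cluster_id = cluster_id,
                 representative_key = representative_key,
                 member_keys = member_keys,
                 member_mappings = member_mappings,
                 member_identities = member_identities),
            class = "seq_cluster")
}

#' @export
print.seq_cluster <- function(x, ...) {
  cat(sprintf("<seq_cluster> %s: %d members, representative %s\n",
              x$cluster_id, length(x$member_keys), x$representative_key))
  invisible(x)
}

# mapping member -> representative as an NA-padded vector over member positions
mapping_vector <- function(mapping, member_len) {
  v <- rep(NA_integer_, member_len)
  v[mapping[, "a"]] <- mapping[, "b"]
  v
}

#' Greedy identity clustering of sequences
#'
#' Incremental greedy scheme: sequences are processed by decreasing length
#' (ties broken lexicographically by key); each sequence joins the first
#' existing cluster whose representative it matches at or above both the
#' identity and coverage thresholds, otherwise it founds a new cluster. The
#' result is deterministic and independent of the input order.
#'
#' @param seqs Named character vector of sequences (names are chain keys).
#' @param identity_threshold,coverage_threshold Fractions in (0, 1].
#' @return List of \code{\link{seq_cluster}} objects.
#' @export
greedy_cluster <- function(seqs, identity_threshold = 0.9,
                           coverage_threshold = 0.9) {
  stopifnot(identity_threshold > 0, identity_threshold <= 1,
            coverage_threshold > 0, coverage_threshold <= 1)
  if (length(seqs) == 0) return(list())
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stopf("seqs must be uniquely named")
  ord <- order(-nchar(seqs), names(seqs))
  seqs <- seqs[ord]
  reps <- character(0)      # representative sequences
  rep_keys <- character(0)
  members <- list()         # per cluster: list(keys=, mappings=, idents=)
  for (i in seq_along(seqs)) {
    key <- names(seqs)[i]; s <- seqs[[i]]
    placed <- FALSE
    for (k in seq_along(reps)) {
      a <- align_pair(s, reps[k])
      if (a$identity >= identity_threshold &&
          min(a$coverage_a, a$coverage_b) >= coverage_threshold) {
        members[[k]]$keys <- c(members[[k]]$keys, key)
        members[[k]]$mappings[[key]] <- mapping_vector(a$mapping, nchar(s))
        members[[k]]$idents[key] <- a$identity
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, s)
      rep_keys <- c(rep_keys, key)
      members[[length(reps)]] <- list(
        keys = key,
        mappings = stats::setNames(list(seq_len(nchar(s))), key),
        idents = stats::setNames(1.0, key))
    }
  }
  lapply(seq_along(reps), function(k)
    seq_cluster(sprintf("C%04d", k), rep_keys[k], members[[k]]$keys,
                members[[k]]$mappings, members[[k]]$idents))
}

#' Prune query sequences against a reference set
#'
#' Removes every query whose maximum pairwise identity to any reference
#' sequence reaches the threshold; used to control train/test leakage.
#'
#' @param query_seqs,reference_seqs Named character vectors.
#' @param identity_threshold Fraction in (0, 1]; queries with identity
#'   \code{>= identity_threshold} to any reference are dropped.
#' @return The retained subset of \code{query_seqs}.
#' @export
prune_against <- function(query_seqs, reference_seqs, identity_threshold) {
  stopifnot(identity_threshold > 0, identity_threshold <= 1)
  if (length(query_seqs) == 0 || length(reference_seqs) == 0) return(query_seqs)
  keep <- vapply(query_seqs, function(q) {
    for (r in reference_seqs) {
      if (align_pair(q, r)$identity >= identity_threshold) return(FALSE)
    }
    TRUE
  }, TRUE)
  query_seqs[keep]
}

#' Write cluster membership as TSV
#'
#' @param clusters List of \code{seq_cluster} objects.
#' @param path Output TSV path (columns: cluster_id, member_key,
#'   identity_to_representative).
#' @return \code{path}, invisibly.
#' @export
write_clusters_tsv <- function(clusters, path) {
  rows <- do.call(rbind, lapply(clusters, function(cl)
    data.frame(cluster_id = cl$cluster_id, member_key = cl$member_keys,
               identity_to_representative =
                 unname(cl$member_identities[cl$member_keys]),
               stringsAsFactors = FALSE)))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sequences from a FASTA file
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences.
#' @export
read_fasta_seqs <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_fasta_seqs <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), path)
  invisible(path)
}
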