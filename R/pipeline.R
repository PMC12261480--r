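# End-to-end orchestration: entries -> clusters -> per-chain annotations and
# interface tracks -> cluster profiles -> dataset records.

#' Re-anchor a cluster on its best-resolved member
#'
#' Greedy clustering anchors each cluster on its founder (the longest
#' member); the database representative, however, is the chain from the
#' experimental structure with the best resolution / R-value. This helper
#' re-selects the representative with \code{\link{select_representative}}
#' and recomputes every member's position map onto it.
#'
#' @param cluster A \code{\link{seq_cluster}}.
#' @param chains Named list of \code{chain_structure} covering the members.
#' @return A \code{\link{seq_cluster}} anchored on the selected member.
#' @export
reanchor_cluster <- function(cluster, chains) {
  members <- chains[cluster$member_keys]
  if (any(vapply(members, is.null, TRUE)))
    stopf("chains missing for cluster %s", cluster$cluster_id)
  rep_chain <- select_representative(members)
  rep_key <- chain_structure_key(rep_chain)
  if (identical(rep_key, cluster$representative_key)) return(cluster)
  rep_seq <- chain_sequence(rep_chain)
  mappings <- list()
  idents <- numeric(0)
  for (key in cluster$member_keys) {
    if (key == rep_key) {
      mappings[[key]] <- seq_len(nchar(rep_seq))
      idents[key] <- 1.0
    } else {
      a <- align_pair(chain_sequence(chains[[key]]), rep_seq)
      mappings[[key]] <- mapping_vector(a$mapping, nchar(chain_sequence(chains[[key]])))
      idents[key] <- a$identity
    }
  }
  seq_cluster(cluster$cluster_id, rep_key, cluster$member_keys,
              mappings, idents)
}

#' Run the annotation pipeline over a set of crystallographic entries
#'
#' Full path from parsed entries to per-cluster soft-disorder profiles:
#' clusters the protein chains at the given identity/coverage thresholds,
#' re-anchors each cluster on its best-resolved member, annotates every chain
#' (missing + normalized-B flags), detects protein-protein and
#' protein-nucleic interfaces within each entry, and aggregates everything
#' onto the representative sequences.
#'
#' @param entries List of entries; each entry is a list of
#'   \code{chain_structure} objects from one crystal (as returned by
#'   \code{\link{parse_structure}} or \code{\link{generate_cluster}}).
#' @param identity_threshold,coverage_threshold Clustering thresholds
#'   (defaults 0.9 / 0.9).
#' @param bfactor_threshold Normalized-B flagging threshold (default 3).
#' @param contact_cutoff Protein contact cutoff in Angstrom (default 5).
#' @param probe,asa_epsilon,asa_points ASA parameters for nucleic interfaces.
#' @return List with \code{chains} (all protein chains, keyed),
#'   \code{clusters}, \code{annotations}, \code{interfaces} and
#'   \code{profiles} (one \code{cluster_profile} per cluster, keyed by
#'   representative).
#' @export
run_pipeline <- function(entries, identity_threshold = 0.9,
                         coverage_threshold = 0.9, bfactor_threshold = 3.0,
                         contact_cutoff = 5.0, probe = 1.4,
                         asa_epsilon = 0.01, asa_points = 7680L) {
  chains <- list()
  annotations <- list()
  interfaces <- list()
  for (entry in entries) {
    prot <- Filter(function(c) c$molecule_class == "protein", entry)
    if (length(prot) == 0) next
    tracks <- entry_interfaces(entry, cutoff = contact_cutoff, probe = probe,
                               epsilon = asa_epsilon, points = asa_points)
    for (c in prot) {
      key <- chain_structure_key(c)
      chains[[key]] <- c
      annotations[[key]] <- annotate_chain(c, threshold = bfactor_threshold)
      interfaces[[key]] <- tracks[[key]]
    }
  }
  if (length(chains) == 0) stopf("no protein chains in the supplied entries")
  seqs <- vapply(chains, chain_sequence, "")
  clusters <- greedy_cluster(seqs, identity_threshold, coverage_threshold)
  clusters <- lapply(clusters, reanchor_cluster, chains = chains)
  profiles <- lapply(clusters, function(cl)
    aggregate_cluster(cl, annotations, interfaces,
                      rep_sequence = chain_sequence(chains[[cl$representative_key]])))
  names(profiles) <- vapply(clusters, function(cl) cl$representative_key, "")
  list(chains = chains, clusters = clusters, annotations = annotations,
       interfaces = interfaces, profiles = profiles)
}

#' Build dataset records from pipeline profiles
#'
#' Convenience wrapper: converts cluster profiles to records, applies the
#' length filter and assigns randomized splits.
#'
#' @param profiles Named list of \code{cluster_profile}.
#' @param min_len,max_len Length bounds (defaults 20 / 2048).
#' @param fractions Split fractions (train, val, test).
#' @param seed Split seed.
#' @return Split-assigned list of \code{dataset_record}.
#' @export
profiles_to_dataset <- function(profiles, min_len = 20L, max_len = 2048L,
                                fractions = c(0.70, 0.10, 0.20), seed = 1L) {
  records <- lapply(profiles, profile_to_record)
  records <- filter_lengths(records, min_len, max_len)
  make_splits(unname(records), fractions = fractions, seed = seed)
}
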