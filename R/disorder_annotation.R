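# Per-chain soft-disorder labels and their aggregation over a cluster.
#
# A residue is soft-disordered in a chain if it is missing from the model or
# its normalized Calpha B-factor exceeds a threshold (default 3). At the
# cluster level the per-site soft-disorder frequency is computed over the
# chains whose alignment covers the site, excluding sites missing in every
# observing chain (those are the intrinsically-disordered, ID, category).

#' Normalized Calpha B-factors of a chain
#'
#' b_i = (B_i - mean(B)) / sd(B), with mean and standard deviation taken over
#' the present residues that carry a Calpha B-factor. The population standard
#' deviation is used (the chain is the whole population of its residues). A
#' constant-B chain (sd = 0) yields all zeros, so no residue can exceed a
#' positive flagging threshold.
#'
#' @param chain A \code{chain_structure} with at least one Calpha B-factor.
#' @return Numeric vector over chain positions; \code{NA} where the residue
#'   has no B-factor (missing, or present without a Calpha).
#' @export
normalize_bfactors <- function(chain) {
  b <- chain$residues$bfactor
  obs <- !is.na(b)
  if (!any(obs))
    stopf("chain %s has no Calpha B-factors", chain_structure_key(chain))
  m <- mean(b[obs])
  s <- sqrt(mean((b[obs] - m)^2))
  out <- rep(NA_real_, length(b))
  out[obs] <- if (s == 0) 0 else (b[obs] - m) / s
  out
}

#' Annotate one chain with missing / flexible / soft-disorder tracks
#'
#' @param chain A \code{chain_structure}.
#' @param threshold Normalized-B flagging threshold; residues with
#'   \code{b_i > threshold} (strict) are flexible. Default 3.
#' @return A \code{chain_annotation}: logical tracks \code{missing},
#'   \code{high_b} and \code{soft = missing | high_b} over chain positions.
#' @export
annotate_chain <- function(chain, threshold = 3.0) {
  bnorm <- normalize_bfactors(chain)
  missing <- !chain$residues$present
  high_b <- !is.na(bnorm) & bnorm > threshold
  structure(list(chain_key = chain_structure_key(chain),
                 missing = missing, high_b = high_b,
                 soft = missing | high_b),
            class = "chain_annotation")
}

#' @export
print.chain_annotation <- function(x, ...) {
  cat(sprintf("<chain_annotation> %s: %d residues, %d missing, %d high-B, %d soft\n",
              x$chain_key, length(x$soft), sum(x$missing), sum(x$high_b),
              sum(x$soft)))
  invisible(x)
}

#' Aggregate per-chain annotations onto the cluster representative
#'
#' Accumulates missing / soft / interface counts from every cluster member
#' onto representative positions through the member-to-representative
#' alignment maps, then derives per-site frequencies and categories:
#' \describe{
#'   \item{ID}{missing in every chain observing the site; the soft-disorder
#'     frequency is undefined (masked) there.}
#'   \item{SD}{soft-disordered in at least one chain, and not ID.}
#'   \item{none}{aligned but never soft.}
#'   \item{unaligned}{no member alignment covers the site.}
#' }
#' A separate logical \code{dto} column marks disorder-to-order transition
#' sites: missing in at least one observing chain but resolved in another
#' (compatible with category SD).
#'
#' @param cluster A \code{\link{seq_cluster}}.
#' @param annotations Named list of \code{chain_annotation}, one per member.
#' @param interfaces Optional named list of \code{interface_track}, one per
#'   member; when omitted interface counts are zero.
#' @param rep_sequence Optional representative sequence (character scalar)
#'   used for the \code{aa} column; inferred length otherwise.
#' @return A \code{cluster_profile}: metadata plus a per-position data.frame
#'   with counts, \code{freq_soft}, \code{freq_interface}, \code{category}
#'   and \code{dto}.
#' @export
aggregate_cluster <- function(cluster, annotations, interfaces = NULL,
                              rep_sequence = NULL) {
  rep_key <- cluster$representative_key
  rep_map <- cluster$member_mappings[[rep_key]]
  L <- length(rep_map)
  n_aligned <- n_missing <- n_soft <- n_ip <- n_in <- integer(L)
  for (key in cluster$member_keys) {
    ann <- annotations[[key]]
    if (is.null(ann)) stopf("no annotation for cluster member %s", key)
    map <- cluster$member_mappings[[key]]
    if (length(ann$soft) != length(map))
      stopf("annotation length %d does not match mapping length %d for chain %s",
            length(ann$soft), length(map), key)
    ok <- !is.na(map)
    pos <- map[ok]
    n_aligned[pos] <- n_aligned[pos] + 1L
    n_missing[pos] <- n_missing[pos] + ann$missing[ok]
    n_soft[pos] <- n_soft[pos] + ann$soft[ok]
    if (!is.null(interfaces)) {
      tr <- interfaces[[key]]
      if (!is.null(tr)) {
        if (length(tr$protein_iface) != length(map))
          stopf("interface track length mismatch for chain %s", key)
        n_ip[pos] <- n_ip[pos] + tr$protein_iface[ok]
        n_in[pos] <- n_in[pos] + tr$nucleic_iface[ok]
      }
    }
  }
  id <- n_aligned > 0L & n_missing == n_aligned
  category <- rep("none", L)
  category[n_aligned == 0L] <- "unaligned"
  category[id] <- "ID"
  category[!id & n_aligned > 0L & n_soft >= 1L] <- "SD"
  dto <- n_missing >= 1L & n_missing < n_aligned
  freq_soft <- ifelse(n_aligned > 0L & !id, n_soft / n_aligned, NA_real_)
  freq_interface <- ifelse(n_aligned > 0L, (n_ip + n_in) / n_aligned, NA_real_)
  aa <- if (!is.null(rep_sequence)) strsplit(rep_sequence, "")[[1]] else rep("X", L)
  structure(list(
    representative_key = rep_key,
    cluster_id = cluster$cluster_id,
    length = L,
    n_chains = length(cluster$member_keys),
    table = data.frame(
      position = seq_len(L), aa = aa,
      n_aligned = n_aligned, n_missing = n_missing, n_soft = n_soft,
      n_interface_protein = n_ip, n_interface_nucleic = n_in,
      freq_soft = freq_soft, freq_interface = freq_interface,
      category = category, dto = dto, stringsAsFactors = FALSE)),
    class = "cluster_profile")
}

#' @export
print.cluster_profile <- function(x, ...) {
  t <- x$table
  cat(sprintf("<cluster_profile> %s (%s): %d positions, %d chains; SD %d, ID %d, DtO %d\n",
              x$representative_key, x$cluster_id, x$length, x$n_chains,
              sum(t$category == "SD"), sum(t$category == "ID"), sum(t$dto)))
  invisible(x)
}

#' Serialize a cluster profile
#'
#' @param profile A \code{cluster_profile}.
#' @param path Output path; \code{".json"} writes a JSON document, anything
#'   else a TSV of the per-position table.
#' @return \code{path}, invisibly.
#' @export
write_cluster_profile <- function(profile, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(
      list(representative_key = profile$representative_key,
           cluster_id = profile$cluster_id, length = profile$length,
           n_chains = profile$n_chains, table = profile$table),
      path, auto_unbox = TRUE, digits = NA, na = "null")
  } else {
    utils::write.table(profile$table, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
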