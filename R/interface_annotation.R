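# Interface residue detection.
#
# Protein-protein interfaces: Calpha-Calpha distance within a cutoff
# (default 5 A, boundary inclusive), computed with a cell-list grid that is
# contractually identical to the all-pairs search. Protein-nucleic
# interfaces: loss of solvent-accessible surface area on complexation,
# measured with a Shrake-Rupley numeric ASA (1.4 A probe). Chain records
# keep one representative atom per residue, so ASA uses one sphere per
# residue; the result object declares this approximation.

#' Construct an interface track
#'
#' @param chain_key Chain key the track belongs to.
#' @param protein_iface,nucleic_iface Logical per-residue flags.
#' @param partners Character vector of contacting chain keys.
#' @return An object of class \code{interface_track}.
#' @export
interface_track <- function(chain_key, protein_iface, nucleic_iface = NULL,
                            partners = character(0)) {
  if (is.null(nucleic_iface)) nucleic_iface <- rep(FALSE, length(protein_iface))
  stopifnot(length(protein_iface) == length(nucleic_iface))
  structure(list(chain_key = chain_key, protein_iface = protein_iface,
                 nucleic_iface = nucleic_iface, partners = partners),
            class = "interface_track")
}

#' @export
print.interface_track <- function(x, ...) {
  cat(sprintf("<interface_track> %s: %d protein-iface, %d nucleic-iface residues (partners: %s)\n",
              x$chain_key, sum(x$protein_iface), sum(x$nucleic_iface),
              if (length(x$partners)) paste(x$partners, collapse = ",") else "none"))
  invisible(x)
}

coord_matrix <- function(chain) {
  r <- chain$residues
  ok <- r$present & !is.na(r$x)
  cbind(idx = r$seq_index[ok], x = r$x[ok], y = r$y[ok], z = r$z[ok])
}

#' Protein-protein interface residues by Calpha contact distance
#'
#' A residue of one protein chain is an interface residue iff some residue of
#' a different protein chain in the same entry has a Calpha-Calpha distance
#' at or below the cutoff. The relation is symmetric. A spatial grid with
#' cells of the cutoff size restricts the candidate pairs; results are
#' identical to the quadratic all-pairs search (\code{method = "brute"}).
#'
#' @param chains List of \code{chain_structure} objects from one entry;
#'   non-protein chains are ignored here.
#' @param cutoff Contact cutoff in Angstrom, boundary inclusive. Default 5.
#' @param method \code{"grid"} (default) or \code{"brute"}.
#' @return Named list of \code{\link{interface_track}}, one per protein chain
#'   with coordinates.
#' @export
protein_contacts <- function(chains, cutoff = 5.0, method = c("grid", "brute")) {
  method <- match.arg(method)
  prot <- Filter(function(c) c$molecule_class == "protein", chains)
  if (length(prot) == 0) stopf("no protein chain supplied")
  keys <- vapply(prot, chain_structure_key, "")
  coords <- lapply(prot, coord_matrix)
  has_xyz <- vapply(coords, nrow, 1L) > 0
  for (k in which(!has_xyz))
    warnf("chain %s has no coordinates; skipped in contact search", keys[k])

  tracks <- lapply(seq_along(prot), function(k)
    interface_track(keys[k], rep(FALSE, nrow(prot[[k]]$residues))))
  names(tracks) <- keys
  use <- which(has_xyz)
  if (length(use) >= 2) {
    pool <- do.call(rbind, lapply(use, function(k)
      cbind(chain = k, coords[[k]])))
    xyz <- pool[, c("x", "y", "z"), drop = FALSE]
    n <- nrow(pool)
    pair_hit <- function(i, j) {   # indices into `all`
      d2 <- (xyz[i, 1] - xyz[j, 1])^2 + (xyz[i, 2] - xyz[j, 2])^2 +
        (xyz[i, 3] - xyz[j, 3])^2
      d2 <= cutoff^2
    }
    mark <- function(i, j) {
      for (k in c(i, j)) {
        ch <- pool[k, "chain"]
        tracks[[ch]]$protein_iface[pool[k, "idx"]] <<- TRUE
      }
      pi_ <- pool[i, "chain"]; pj <- pool[j, "chain"]
      tracks[[pi_]]$partners <<- union(tracks[[pi_]]$partners, keys[pj])
      tracks[[pj]]$partners <<- union(tracks[[pj]]$partners, keys[pi_])
    }
    if (method == "brute") {
      for (i in seq_len(n - 1)) for (j in seq((i + 1), n)) {
        if (pool[i, "chain"] != pool[j, "chain"] && pair_hit(i, j)) mark(i, j)
      }
    } else {
      cell <- floor(xyz / cutoff)
      key_of <- function(cx, cy, cz) paste(cx, cy, cz, sep = "_")
      bucket <- split(seq_len(n), key_of(cell[, 1], cell[, 2], cell[, 3]))
      offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
      for (i in seq_len(n)) {
        for (o in seq_len(nrow(offs))) {
          ky <- key_of(cell[i, 1] + offs[o, 1], cell[i, 2] + offs[o, 2],
                       cell[i, 3] + offs[o, 3])
          cand <- bucket[[ky]]
          if (is.null(cand)) next
          for (j in cand) {
            if (j > i && pool[i, "chain"] != pool[j, "chain"] && pair_hit(i, j))
              mark(i, j)
          }
        }
      }
    }
  }
  tracks
}

# Deterministic golden-spiral unit sphere points.
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- (seq_len(n) - 1) * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Numeric solvent-accessible surface area
#'
#' Shrake-Rupley ASA over the residue spheres of the supplied chains: each
#' present residue contributes one sphere at its representative atom with a
#' fixed van der Waals radius, sampled with a deterministic golden-spiral
#' point set. A surface point is accessible iff it lies outside every other
#' probe-expanded sphere.
#'
#' @param chains List of \code{chain_structure} objects (any molecule class).
#' @param probe Probe radius in Angstrom, default 1.4.
#' @param points Sample points per sphere, default 7680.
#' @param radius Residue sphere radius in Angstrom, default 1.9 (a carbon-like
#'   radius for the single-sphere-per-residue model).
#' @return An \code{asa_result}: named list \code{per_chain} of per-residue
#'   ASA vectors (Angstrom^2, \code{NA} for absent residues), with
#'   \code{probe}, \code{points}, \code{radius} and the approximation tag.
#' @export
compute_asa <- function(chains, probe = 1.4, points = 7680L, radius = 1.9) {
  mats <- lapply(chains, coord_matrix)
  ntot <- sum(vapply(mats, nrow, 1L))
  if (ntot == 0) stopf("no atoms with coordinates supplied")
  centers <- do.call(rbind, lapply(seq_along(chains), function(k)
    if (nrow(mats[[k]]) > 0) cbind(chain = k, mats[[k]])))
  xyz <- centers[, c("x", "y", "z"), drop = FALSE]
  R <- radius + probe
  pts0 <- sphere_points(points) * R
  n <- nrow(xyz)
  asa <- numeric(n)
  reach2 <- (2 * R)^2
  for (i in seq_len(n)) {
    d2 <- (xyz[, 1] - xyz[i, 1])^2 + (xyz[, 2] - xyz[i, 2])^2 +
      (xyz[, 3] - xyz[i, 3])^2
    nb <- which(d2 > 0 & d2 < reach2)
    if (length(nb) == 0) {
      asa[i] <- 4 * pi * R^2
      next
    }
    p <- sweep(pts0, 2, xyz[i, ], "+")
    free <- rep(TRUE, points)
    for (j in nb) {
      if (!any(free)) break
      dd <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
        (p[, 3] - xyz[j, 3])^2
      free <- free & dd >= R^2
    }
    asa[i] <- 4 * pi * R^2 * mean(free)
  }
  per_chain <- lapply(seq_along(chains), function(k) {
    v <- rep(NA_real_, nrow(chains[[k]]$residues))
    rows <- which(centers[, "chain"] == k)
    v[centers[rows, "idx"]] <- asa[rows]
    v
  })
  names(per_chain) <- vapply(chains, chain_structure_key, "")
  structure(list(per_chain = per_chain, probe = probe, points = points,
                 radius = radius,
                 approximation = "single-sphere-per-residue"),
            class = "asa_result")
}

#' Protein-nucleic interface residues by buried surface area
#'
#' A protein residue is flagged as a nucleic-acid interface residue iff its
#' ASA in the isolated protein chain exceeds its ASA in the protein +
#' nucleic-chain complex by more than \code{epsilon}.
#'
#' @param protein_chains,nucleic_chains Lists of \code{chain_structure}.
#' @param probe Probe radius (Angstrom), default 1.4.
#' @param epsilon Burial threshold in Angstrom^2 absorbing sampling noise;
#'   default 0.01.
#' @param points,radius Passed to \code{\link{compute_asa}}.
#' @return Named list of \code{\link{interface_track}} for the protein chains
#'   (only \code{nucleic_iface} set here).
#' @export
nucleic_interfaces <- function(protein_chains, nucleic_chains, probe = 1.4,
                               epsilon = 0.01, points = 7680L, radius = 1.9) {
  stopifnot(length(protein_chains) >= 1, length(nucleic_chains) >= 1)
  nuc_keys <- vapply(nucleic_chains, chain_structure_key, "")
  out <- lapply(protein_chains, function(p) {
    iso <- compute_asa(list(p), probe = probe, points = points,
                       radius = radius)$per_chain[[1]]
    cpl <- compute_asa(c(list(p), nucleic_chains), probe = probe,
                       points = points, radius = radius)$per_chain[[1]]
    delta <- iso - cpl
    flag <- !is.na(delta) & delta > epsilon
    interface_track(chain_structure_key(p),
                    rep(FALSE, nrow(p$residues)), flag,
                    partners = if (any(flag)) nuc_keys else character(0))
  })
  names(out) <- vapply(protein_chains, chain_structure_key, "")
  out
}

#' All interface tracks for one crystallographic entry
#'
#' Combines the Calpha-contact protein-protein search with the buried-ASA
#' protein-nucleic search over the chains of one entry.
#'
#' @param chains List of \code{chain_structure} of one entry.
#' @param cutoff Protein contact cutoff (Angstrom).
#' @param probe,epsilon,points,radius ASA parameters, see
#'   \code{\link{nucleic_interfaces}}.
#' @return Named list of merged \code{\link{interface_track}}, one per
#'   protein chain.
#' @export
entry_interfaces <- function(chains, cutoff = 5.0, probe = 1.4,
                             epsilon = 0.01, points = 7680L, radius = 1.9) {
  prot <- Filter(function(c) c$molecule_class == "protein", chains)
  nuc <- Filter(function(c) c$molecule_class == "nucleic", chains)
  tracks <- protein_contacts(chains, cutoff = cutoff)
  if (length(nuc) > 0 && length(prot) > 0) {
    ntr <- nucleic_interfaces(prot, nuc, probe = probe, epsilon = epsilon,
                              points = points, radius = radius)
    for (key in names(ntr)) {
      tracks[[key]]$nucleic_iface <- ntr[[key]]$nucleic_iface
      tracks[[key]]$partners <- union(tracks[[key]]$partners,
                                      ntr[[key]]$partners)
    }
  }
  tracks
}

#' Write interface tracks of one entry as TSV
#'
#' @param tracks Named list of \code{interface_track}.
#' @param path Output path (columns: chain, position, protein_iface,
#'   nucleic_iface, partner_chains).
#' @return \code{path}, invisibly.
#' @export
write_interfaces_tsv <- function(tracks, path) {
  rows <- do.call(rbind, lapply(tracks, function(tr)
    data.frame(chain = tr$chain_key,
               position = seq_along(tr$protein_iface),
               protein_iface = as.integer(tr$protein_iface),
               nucleic_iface = as.integer(tr$nucleic_iface),
               partner_chains = paste(tr$partners, collapse = ","),
               stringsAsFactors = FALSE)))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
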