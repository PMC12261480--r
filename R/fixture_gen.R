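# Synthetic crystallographic fixtures with controlled ground truth.
#
# Geometry is a simple extended-backbone model: a Calpha trace along x at
# 3.8 A spacing, a protein partner chain 4 A away over the planted contact
# span (inside the 5 A cutoff; sequence neighbors sit at 5.52 A, outside it),
# and an optional nucleic partner 6 A away over its span (inside the 6.6 A
# single-sphere occlusion reach, while neighbors at 7.1 A stay clear). No
# physical realism is claimed; the point is exact, analytically known truth.
#
# Base B-factors are drawn from a bounded uniform distribution so that no
# unplanted residue can reach a normalized B-factor of 3 (the uniform maximum
# is sqrt(3) population SDs); planted flexible segments are escalated until
# they exceed the threshold by construction.

#' Specify a synthetic fixture
#'
#' Defines a family of clusters of near-identical chains with planted missing
#' segments, flexible (high normalized B-factor) segments and inter-chain
#' contacts. Segment loci are chosen per cluster and shared by all members;
#' which members carry them is controlled by the carrier fractions, so the
#' expected per-site frequencies are known exactly.
#'
#' @param n_clusters Number of clusters.
#' @param chains_per_cluster Members per cluster.
#' @param length_range Inclusive chain length range (residues).
#' @param mutation_rate Per-residue substitution probability for members.
#' @param missing_segments List: \code{count}, \code{len_range},
#'   \code{carrier_fraction} (fraction of members in which the segment is
#'   unresolved; 1 plants an ID segment).
#' @param high_b_segments Same shape, for flexible segments.
#' @param b_base,b_noise Base B-factor level and half-width of its uniform
#'   noise (Angstrom^2).
#' @param b_high Initial B-factor for planted flexible segments (escalated
#'   automatically until the normalized value exceeds 3).
#' @param interface List: \code{enabled}, \code{span_len} for the protein
#'   partner chain contact span.
#' @param nucleic List: \code{enabled}, \code{span_len} for a nucleic partner.
#' @param seed Integer seed fixing every downstream draw.
#' @return An object of class \code{fixture_spec}.
#' @export
fixture_spec <- function(n_clusters = 1L, chains_per_cluster = 4L,
                         length_range = c(60L, 90L), mutation_rate = 0.02,
                         missing_segments = list(count = 1L,
                                                 len_range = c(4L, 8L),
                                                 carrier_fraction = 0.5),
                         high_b_segments = list(count = 1L,
                                                len_range = c(3L, 5L),
                                                carrier_fraction = 0.5),
                         b_base = 20, b_noise = 3, b_high = 150,
                         interface = list(enabled = TRUE, span_len = 6L),
                         nucleic = list(enabled = FALSE, span_len = 6L),
                         seed = 1L) {
  spec <- list(n_clusters = as.integer(n_clusters),
               chains_per_cluster = as.integer(chains_per_cluster),
               length_range = as.integer(length_range),
               mutation_rate = mutation_rate,
               missing_segments = missing_segments,
               high_b_segments = high_b_segments,
               b_base = b_base, b_noise = b_noise, b_high = b_high,
               interface = interface, nucleic = nucleic,
               seed = as.integer(seed))
  stopifnot(spec$n_clusters >= 1, spec$chains_per_cluster >= 1,
            length(spec$length_range) == 2,
            spec$length_range[1] <= spec$length_range[2],
            mutation_rate >= 0, mutation_rate <= 1,
            missing_segments$carrier_fraction >= 0,
            missing_segments$carrier_fraction <= 1,
            high_b_segments$carrier_fraction >= 0,
            high_b_segments$carrier_fraction <= 1,
            b_noise >= 0)
  lmin <- spec$length_range[1]
  need <- missing_segments$count * max(missing_segments$len_range, 0) +
    high_b_segments$count * max(high_b_segments$len_range, 0) +
    (if (isTRUE(interface$enabled)) interface$span_len else 0) +
    (if (isTRUE(nucleic$enabled)) nucleic$span_len else 0)
  if (need > lmin)
    stopf("infeasible spec: planted segments need %d residues but chains may have only %d",
          need, lmin)
  # A flexible segment of k residues among n present ones can only exceed
  # normalized-B 3 if sqrt((n-k)/k) > 3, i.e. k < n/10.
  k <- high_b_segments$count * max(high_b_segments$len_range, 0)
  n_present_min <- lmin - missing_segments$count * max(missing_segments$len_range, 0)
  if (k > 0 && 10 * k >= n_present_min)
    stopf("infeasible spec: %d flexible residues in chains with as few as %d present residues can never exceed normalized-B 3 (need k < n/10)",
          k, n_present_min)
  structure(spec, class = "fixture_spec")
}

# Uniform integer in [lo, hi]; safe when lo == hi (sample() would misread a
# scalar as a range).
sample_range <- function(lo, hi) lo + sample.int(hi - lo + 1L, 1L) - 1L

# Pick a segment of `len` positions from the free mask; returns indices and
# updates nothing (caller marks them used). Errors when no run fits.
pick_segment <- function(free, len, what) {
  if (len == 0) return(integer(0))
  r <- rle(free)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  ok <- which(r$values & r$lengths >= len)
  if (length(ok) == 0)
    stopf("infeasible spec: no room for a %s segment of length %d", what, len)
  run <- ok[sample.int(length(ok), 1)]
  off <- sample.int(r$lengths[run] - len + 1, 1) - 1
  seq(starts[run] + off, length.out = len)
}

seg_positions <- function(free, seg_cfg, what) {
  segs <- list()
  if (seg_cfg$count > 0) {
    for (i in seq_len(seg_cfg$count)) {
      len <- sample_range(seg_cfg$len_range[1], seg_cfg$len_range[2])
      s <- pick_segment(free, len, what)
      free[s] <- FALSE
      segs[[i]] <- s
    }
  }
  list(segs = segs, free = free)
}

make_chain <- function(sid, chain_id, seq_letters, present, bfac, xyz,
                       resolution, r_value, molecule_class = "protein") {
  n <- length(seq_letters)
  residues <- data.frame(
    seq_index = seq_len(n), aa = seq_letters, present = present,
    x = ifelse(present, xyz[, 1], NA_real_),
    y = ifelse(present, xyz[, 2], NA_real_),
    z = ifelse(present, xyz[, 3], NA_real_),
    bfactor = ifelse(present, bfac, NA_real_),
    resno = seq_len(n), icode = "", stringsAsFactors = FALSE)
  chain_structure(sid, chain_id, residues, resolution = resolution,
                  r_value = r_value, molecule_class = molecule_class)
}

#' Generate synthetic clusters with known ground truth
#'
#' Builds \code{n_clusters} clusters of member entries per the spec. Each
#' member entry holds the mutated copy of the cluster's base chain (chain A)
#' with its planted missing and flexible segments, plus the protein partner
#' (chain B) and/or nucleic partner (chain C) when enabled. When \code{dir}
#' is given, each entry is also written as a PDB-format file parseable by
#' \code{\link{parse_structure}}.
#'
#' The returned ground truth is computed by direct counting over the planted
#' masks: per-member missing/flexible/interface tracks, and per-cluster
#' expected \code{freq_soft}, \code{freq_interface}, category and
#' disorder-to-order flags under the identity member-to-representative
#' mapping (members differ by substitutions only).
#'
#' @param spec A \code{\link{fixture_spec}}.
#' @param dir Optional output directory for PDB files.
#' @return List with \code{clusters} (each: \code{base_seq},
#'   \code{member_keys}, \code{entries}, \code{truth}, \code{files}) and the
#'   \code{spec}.
#' @export
generate_cluster <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  if (!is.null(dir)) dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(spec$seed)
  m <- spec$chains_per_cluster
  sid_counter <- 0L
  clusters <- vector("list", spec$n_clusters)
  for (ci in seq_len(spec$n_clusters)) {
    L <- sample_range(spec$length_range[1], spec$length_range[2])
    base_seq <- sample(.AA20, L, replace = TRUE)
    free <- rep(TRUE, L)
    ms <- seg_positions(free, spec$missing_segments, "missing")
    hs <- seg_positions(ms$free, spec$high_b_segments, "flexible")
    free <- hs$free
    iface_span <- if (isTRUE(spec$interface$enabled)) {
      s <- pick_segment(free, spec$interface$span_len, "interface")
      free[s] <- FALSE
      s
    } else integer(0)
    nuc_span <- if (isTRUE(spec$nucleic$enabled)) {
      s <- pick_segment(free, spec$nucleic$span_len, "nucleic interface")
      free[s] <- FALSE
      s
    } else integer(0)

    n_car <- function(cfg) {
      k <- round(cfg$carrier_fraction * m)
      max(0L, min(m, as.integer(k)))
    }
    mis_carriers <- lapply(ms$segs, function(s) sort(sample.int(m, n_car(spec$missing_segments))))
    hib_carriers <- lapply(hs$segs, function(s) sort(sample.int(m, n_car(spec$high_b_segments))))

    entries <- vector("list", m)
    member_keys <- character(m)
    tr_missing <- tr_highb <- tr_iface <- tr_niface <- vector("list", m)
    files <- character(0)
    for (mi in seq_len(m)) {
      sid_counter <- sid_counter + 1L
      sid <- sprintf("S%03d", sid_counter)
      seqm <- base_seq
      # Binomial substitution count truncated at 4% of the length: any two
      # members then differ at <= 8% of positions, so a planted cluster can
      # never split at the default 90% clustering identity.
      n_mut <- min(stats::rbinom(1, L, spec$mutation_rate), floor(0.04 * L))
      if (n_mut > 0) {
        mut <- sample.int(L, n_mut)
        seqm[mut] <- vapply(seqm[mut], function(a)
          sample(setdiff(.AA20, a), 1), "")
      }
      missing <- rep(FALSE, L)
      for (si in seq_along(ms$segs))
        if (mi %in% mis_carriers[[si]]) missing[ms$segs[[si]]] <- TRUE
      high <- rep(FALSE, L)
      for (si in seq_along(hs$segs))
        if (mi %in% hib_carriers[[si]]) high[hs$segs[[si]]] <- TRUE
      high <- high & !missing

      # 2 decimals: exactly representable in the PDB B-factor field, so the
      # file round trip is lossless.
      bfac <- round(stats::runif(L, spec$b_base - spec$b_noise,
                                 spec$b_base + spec$b_noise), 2)
      if (any(high)) {
        bh <- spec$b_high
        for (it in 1:60) {
          bfac[high] <- round(bh, 2)
          b <- bfac[!missing]
          z <- (bfac - mean(b)) / sqrt(mean((b - mean(b))^2))
          if (all(z[high & !missing] > 3)) break
          bh <- bh * 1.5
          if (it == 60)
            stopf("infeasible spec: flexible segment cannot exceed normalized-B 3")
        }
      }
      xyz <- cbind(3.8 * (seq_len(L) - 1), 0, 0)
      chainA <- make_chain(sid, "A", seqm, !missing, bfac, xyz,
                           resolution = 1.5 + 0.05 * (mi - 1),
                           r_value = 0.18 + 0.01 * (mi - 1))
      entry <- list(chainA)
      iface <- rep(FALSE, L)
      if (length(iface_span) > 0) {
        lb <- length(iface_span)
        seqb <- sample(.AA20, lb, replace = TRUE)
        xyzb <- cbind(3.8 * (iface_span - 1), 4.0, 0)
        entry <- c(entry, list(make_chain(sid, "B", seqb, rep(TRUE, lb),
                                          rep(spec$b_base, lb), xyzb,
                                          resolution = chainA$resolution,
                                          r_value = chainA$r_value)))
        iface[iface_span] <- TRUE
      }
      niface <- rep(FALSE, L)
      if (length(nuc_span) > 0) {
        ln <- length(nuc_span)
        seqn <- sample(c("A", "C", "G", "U"), ln, replace = TRUE)
        xyzn <- cbind(3.8 * (nuc_span - 1), 6.0, 0)
        entry <- c(entry, list(make_chain(sid, "C", seqn, rep(TRUE, ln),
                                          rep(spec$b_base, ln), xyzn,
                                          resolution = chainA$resolution,
                                          r_value = chainA$r_value,
                                          molecule_class = "nucleic")))
        niface[nuc_span] <- TRUE
      }
      entries[[mi]] <- entry
      member_keys[mi] <- chain_key(sid, "A")
      tr_missing[[mi]] <- missing
      tr_highb[[mi]] <- high
      tr_iface[[mi]] <- iface
      tr_niface[[mi]] <- niface
      if (!is.null(dir)) {
        f <- file.path(dir, paste0(sid, ".pdb"))
        write_entry_pdb(entry, f)
        files <- c(files, f)
      }
    }
    names(entries) <- names(tr_missing) <- names(tr_highb) <-
      names(tr_iface) <- names(tr_niface) <- member_keys

    # Expected cluster aggregate by direct counting (identity mappings).
    n_missing <- Reduce(`+`, lapply(tr_missing, as.integer))
    n_soft <- Reduce(`+`, lapply(seq_len(m), function(i)
      as.integer(tr_missing[[i]] | tr_highb[[i]])))
    n_iface <- Reduce(`+`, lapply(seq_len(m), function(i)
      as.integer(tr_iface[[i]] | tr_niface[[i]])))
    id <- n_missing == m
    category <- rep("none", L)
    category[id] <- "ID"
    category[!id & n_soft >= 1L] <- "SD"
    truth <- list(
      missing = tr_missing, high_b = tr_highb,
      interface = tr_iface, nucleic_iface = tr_niface,
      n_aligned = rep(m, L),
      freq_soft = ifelse(id, NA_real_, n_soft / m),
      freq_interface = n_iface / m,
      category = category,
      dto = n_missing >= 1L & n_missing < m)
    clusters[[ci]] <- list(cluster_index = ci,
                           base_seq = paste(base_seq, collapse = ""),
                           member_keys = member_keys,
                           entries = entries, truth = truth,
                           files = if (is.null(dir)) NULL else files)
  }
  list(clusters = clusters, spec = spec)
}

#' Generate score profiles with a target ROC AUC
#'
#' Draws scores from two Beta distributions whose analytic Mann-Whitney
#' concordance equals the target: negatives are Beta(1, 1) (uniform) and
#' positives Beta(a, 1) with \code{a = t/(1 - t)}, so
#' \code{P(score_pos > score_neg) = a/(a + 1) = t}. A target of 1 uses
#' disjoint supports.
#'
#' @param labels Named list of integer 0/1/\code{NA} label vectors (e.g. the
#'   binary labels of dataset records).
#' @param auc_target Target AUC in (0.5, 1].
#' @param seed Integer seed.
#' @return List of \code{\link{score_profile}}.
#' @export
generate_predictions <- function(labels, auc_target, seed = 1L) {
  stopifnot(auc_target > 0.5, auc_target <= 1)
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(seed)
  a <- if (auc_target < 1) auc_target / (1 - auc_target) else NA_real_
  out <- lapply(names(labels), function(key) {
    l <- labels[[key]]
    s <- rep(NA_real_, length(l))
    pos <- which(!is.na(l) & l == 1L)
    neg <- which(!is.na(l) & l == 0L)
    if (auc_target == 1) {
      s[pos] <- 0.5 + 0.5 * stats::runif(length(pos))
      s[neg] <- 0.499 * stats::runif(length(neg))
    } else {
      s[pos] <- stats::rbeta(length(pos), a, 1)
      s[neg] <- stats::runif(length(neg))
    }
    score_profile(key, s, l)
  })
  names(out) <- names(labels)
  out
}
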