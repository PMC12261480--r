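# Parsing of crystallographic structure files into chain-level records.
#
# Coordinate and SEQRES parsing is delegated to bio3d; header records that
# bio3d does not expose (EXPDTA, REMARK 2 resolution, REMARK 3 R-value,
# REMARK 465 missing residues) are read directly from the file.

#' Construct a chain structure record
#'
#' One protein (or nucleic) chain from a crystal structure: the full chain
#' sequence with per-residue presence flags, representative-atom coordinates
#' (Calpha for protein, C1' for nucleic) and isotropic B-factors, plus the
#' experiment metadata used to pick cluster representatives.
#'
#' @param structure_id 4-character entry identifier.
#' @param chain_id Author chain identifier.
#' @param residues data.frame with columns \code{seq_index} (contiguous
#'   1..length), \code{aa} (one-letter code, \code{"X"} for nonstandard),
#'   \code{present} (logical), \code{x,y,z} (Angstrom, \code{NA} when absent),
#'   \code{bfactor} (Angstrom^2, \code{NA} when absent), \code{resno}
#'   (author residue number) and \code{icode} (insertion code, \code{""}
#'   when none).
#' @param resolution Resolution in Angstrom, or \code{NA}.
#' @param r_value Crystallographic R-value (working set), or \code{NA}.
#' @param experiment Experimental method tag (e.g. \code{"X-RAY DIFFRACTION"}).
#' @param molecule_class \code{"protein"}, \code{"nucleic"} or \code{"other"}.
#' @return An object of class \code{chain_structure}.
#' @export
chain_structure <- function(structure_id, chain_id, residues,
                            resolution = NA_real_, r_value = NA_real_,
                            experiment = "X-RAY DIFFRACTION",
                            molecule_class = "protein") {
  stopifnot(is.data.frame(residues), nrow(residues) >= 1)
  needed <- c("seq_index", "aa", "present", "x", "y", "z", "bfactor",
              "resno", "icode")
  miss <- setdiff(needed, names(residues))
  if (length(miss) > 0) stopf("residues lacks columns: %s", paste(miss, collapse = ", "))
  if (!identical(as.integer(residues$seq_index), seq_len(nrow(residues))))
    stopf("seq_index must be contiguous 1..%d for chain %s", nrow(residues), chain_id)
  absent <- !residues$present
  if (any(absent & (!is.na(residues$x) | !is.na(residues$bfactor))))
    stopf("missing residues cannot carry coordinates or B-factors (chain %s)", chain_id)
  structure(
    list(structure_id = structure_id, chain_id = chain_id,
         residues = residues, resolution = resolution, r_value = r_value,
         experiment = experiment, molecule_class = molecule_class),
    class = "chain_structure")
}

#' @export
print.chain_structure <- function(x, ...) {
  cat(sprintf("<chain_structure> %s chain %s: %d residues (%d missing), %s, res %s A\n",
              x$structure_id, x$chain_id, nrow(x$residues),
              sum(!x$residues$present), x$molecule_class,
              ifelse(is.na(x$resolution), "NA", format(x$resolution))))
  invisible(x)
}

#' Full chain sequence as a one-letter string
#'
#' @param chain A \code{chain_structure}.
#' @return Character scalar of length-of-chain letters.
#' @export
chain_sequence <- function(chain) paste(chain$residues$aa, collapse = "")

#' Key of a chain structure
#' @param chain A \code{chain_structure}.
#' @return \code{"<structure_id>_<chain_id>"}.
#' @export
chain_structure_key <- function(chain) chain_key(chain$structure_id, chain$chain_id)

# ---- header record scraping -------------------------------------------------

parse_header_records <- function(lines) {
  out <- list(structure_id = NULL, experiment = NA_character_,
              resolution = NA_real_, r_value = NA_real_,
              remark465 = NULL)
  hdr <- grep("^HEADER", lines, value = TRUE)
  if (length(hdr) > 0) {
    id <- trimws(substr(hdr[1], 63, 66))
    if (nzchar(id)) out$structure_id <- id
  }
  exp <- grep("^EXPDTA", lines, value = TRUE)
  if (length(exp) > 0) out$experiment <- trimws(substr(exp[1], 11, nchar(exp[1])))
  res <- grep("^REMARK   2 RESOLUTION", lines, value = TRUE)
  if (length(res) > 0) {
    m <- regmatches(res[1], regexpr("[0-9]+\\.?[0-9]*(?=\\s+ANGSTROM)", res[1], perl = TRUE))
    if (length(m) == 1) out$resolution <- as.numeric(m)
  }
  rv <- grep("^REMARK   3.*R VALUE.*\\(WORKING SET\\)", lines, value = TRUE)
  if (length(rv) > 0) {
    m <- regmatches(rv[1], regexpr("(?<=:)\\s*[0-9]*\\.?[0-9]+", rv[1], perl = TRUE))
    if (length(m) == 1) out$r_value <- as.numeric(trimws(m))
  }
  r465 <- grep("^REMARK 465", lines, value = TRUE)
  pat <- "^REMARK 465\\s+(?:\\d+\\s+)?([A-Z0-9']{1,3})\\s+([A-Za-z0-9])\\s+(-?\\d+)([A-Za-z]?)\\s*$"
  hit <- regmatches(r465, regexec(pat, r465))
  hit <- hit[vapply(hit, length, 1L) == 5L]
  if (length(hit) > 0) {
    out$remark465 <- data.frame(
      resname = vapply(hit, `[`, "", 2L),
      chain   = vapply(hit, `[`, "", 3L),
      resno   = as.integer(vapply(hit, `[`, "", 4L)),
      icode   = vapply(hit, `[`, "", 5L),
      stringsAsFactors = FALSE)
  }
  out
}

# Deterministic residue ordering: author number, then insertion code with the
# blank code first.
order_residues <- function(resno, icode) order(resno, icode != "", icode)

# ---- main parser ------------------------------------------------------------

#' Parse a crystallographic structure file into chain records
#'
#' Reads a PDB-format file and returns one \code{chain_structure} per polymer
#' chain. The full chain sequence is reconstructed by merging observed ATOM
#' residues with REMARK 465 missing-residue records against SEQRES; files
#' without SEQRES fall back to observed residues, with author-numbering gaps
#' flagged as missing. Only the representative atom per residue is retained
#' (Calpha for protein, C1' for nucleic); among alternate locations the
#' highest-occupancy one is kept (ties: first encountered). Nucleic chains are
#' returned with \code{molecule_class = "nucleic"} so interface detection can
#' use them; chains with no recognizable polymer residues are skipped with a
#' warning.
#'
#' @param path Path to the structure file.
#' @param dialect File dialect; only \code{"pdb"} is supported.
#' @param xray_only If \code{TRUE} (default) non-X-ray entries yield an empty
#'   list with a warning, matching a pipeline restricted to crystallographic
#'   structures.
#' @return List of \code{chain_structure} objects.
#' @export
parse_structure <- function(path, dialect = c("pdb", "mmcif"), xray_only = TRUE) {
  dialect <- match.arg(dialect)
  if (dialect == "mmcif")
    stopf("mmCIF input is not implemented; supply a PDB-format file")
  if (!file.exists(path))
    stopf("cannot read structure file '%s': no such file", path)
  lines <- tryCatch(readLines(path, warn = FALSE),
                    error = function(e) stopf("cannot read '%s': %s", path, conditionMessage(e)))
  hdr <- parse_header_records(lines)
  structure_id <- hdr$structure_id %||%
    toupper(substr(tools::file_path_sans_ext(basename(path)), 1, 4))
  if (xray_only && !is.na(hdr$experiment) && !grepl("X-RAY", hdr$experiment)) {
    warnf("%s: experiment '%s' is not X-ray; skipped (set xray_only = FALSE to admit)",
          structure_id, hdr$experiment)
    return(list())
  }
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE)),
    error = function(e) stopf("parse error in '%s': %s", path, conditionMessage(e)))
  atoms <- pdb$atom
  atoms$insert[is.na(atoms$insert)] <- ""
  atoms$alt[is.na(atoms$alt)] <- ""
  keep <- (atoms$type == "ATOM" | (atoms$type == "HETATM" & atoms$resid == "MSE")) &
    !(atoms$resid %in% .SOLVENT_RESID)
  atoms <- atoms[keep, , drop = FALSE]

  seqres <- pdb$seqres
  chains <- unique(c(atoms$chain,
                     if (!is.null(hdr$remark465)) hdr$remark465$chain,
                     if (!is.null(seqres)) names(seqres)))
  chains <- sort(chains[!is.na(chains)])

  out <- list()
  for (ch in chains) {
    cs <- build_chain(structure_id, ch,
                      atoms[atoms$chain == ch, , drop = FALSE],
                      if (is.null(seqres)) NULL else unname(seqres[names(seqres) == ch]),
                      if (is.null(hdr$remark465)) NULL
                      else hdr$remark465[hdr$remark465$chain == ch, , drop = FALSE],
                      hdr)
    if (!is.null(cs)) out[[chain_key(structure_id, ch)]] <- cs
  }
  out
}

build_chain <- function(structure_id, ch, at, seqres3, r465, hdr) {
  resids <- if (length(seqres3) > 0) seqres3 else unique(at$resid)
  n_nuc <- sum(is_nucleic_resid(resids))
  n_aa <- sum(resids %in% names(.AA3TO1))
  if (n_aa == 0 && n_nuc == 0) {
    warnf("%s chain %s: no standard polymer residues; chain skipped", structure_id, ch)
    return(NULL)
  }
  mol <- if (n_nuc > n_aa) "nucleic" else "protein"
  rep_atom <- if (mol == "nucleic") "C1'" else "CA"

  # One row per observed residue (any atom counts as presence), file order.
  obs_id <- paste(at$resno, at$insert, sep = "|")
  first <- !duplicated(obs_id)
  obs <- data.frame(resno = at$resno[first], icode = at$insert[first],
                    resid = at$resid[first], stringsAsFactors = FALSE)

  # Representative-atom row per residue: highest occupancy, ties first in file.
  rep_rows <- at[at$elety == rep_atom, , drop = FALSE]
  coord <- list()
  if (nrow(rep_rows) > 0) {
    rid <- paste(rep_rows$resno, rep_rows$insert, sep = "|")
    for (u in unique(rid)) {
      g <- rep_rows[rid == u, , drop = FALSE]
      g <- g[which.max(ifelse(is.na(g$o), 1, g$o)), , drop = FALSE]
      coord[[u]] <- g
    }
  }

  if (!is.null(r465) && nrow(r465) > 0) {
    mis <- data.frame(resno = r465$resno, icode = r465$icode,
                      resid = r465$resname, stringsAsFactors = FALSE)
    dup <- paste(mis$resno, mis$icode) %in% paste(obs$resno, obs$icode)
    if (any(dup)) {
      warnf("%s chain %s: %d REMARK 465 residues also observed; treated as present",
            structure_id, ch, sum(dup))
      mis <- mis[!dup, , drop = FALSE]
    }
  } else if (nrow(obs) > 0 && length(seqres3) == 0 && all(obs$icode == "")) {
    # ATOM-only file: author-numbering gaps are missing residues.
    rng <- seq(min(obs$resno), max(obs$resno))
    gap <- setdiff(rng, obs$resno)
    mis <- if (length(gap) > 0)
      data.frame(resno = gap, icode = "", resid = "UNK", stringsAsFactors = FALSE)
    else mis0()
  } else {
    mis <- mis0()
  }

  obs$present <- rep(TRUE, nrow(obs))
  mis$present <- rep(FALSE, nrow(mis))
  comb <- rbind(obs, mis)
  comb <- comb[order_residues(comb$resno, comb$icode), , drop = FALSE]
  if (nrow(comb) == 0) return(NULL)

  aa <- residue_letter(comb$resid, mol)
  if (length(seqres3) > 0) {
    if (length(seqres3) == nrow(comb)) {
      aa <- residue_letter(seqres3, mol)
    } else {
      warnf("%s chain %s: SEQRES length %d != %d observed+missing residues; using observed records",
            structure_id, ch, length(seqres3), nrow(comb))
    }
  }

  n <- nrow(comb)
  x <- y <- z <- b <- rep(NA_real_, n)
  key <- paste(comb$resno, comb$icode, sep = "|")
  for (i in which(comb$present)) {
    g <- coord[[key[i]]]
    if (!is.null(g)) {
      x[i] <- g$x; y[i] <- g$y; z[i] <- g$z; b[i] <- g$b
    }
  }
  residues <- data.frame(seq_index = seq_len(n), aa = aa, present = comb$present,
                         x = x, y = y, z = z, bfactor = b,
                         resno = comb$resno, icode = comb$icode,
                         stringsAsFactors = FALSE)
  chain_structure(structure_id, ch, residues,
                  resolution = hdr$resolution, r_value = hdr$r_value,
                  experiment = hdr$experiment, molecule_class = mol)
}

mis0 <- function() data.frame(resno = integer(0), icode = character(0),
                              resid = character(0), stringsAsFactors = FALSE)

#' Select the representative chain of a set
#'
#' Picks the chain from the experimental structure with the best (lowest)
#' resolution; ties are broken by lowest R-value, then lexicographically by
#' (structure id, chain id). Chains without a resolution sort last.
#'
#' @param chains Non-empty list of \code{chain_structure} objects.
#' @return The selected \code{chain_structure}.
#' @export
select_representative <- function(chains) {
  if (length(chains) == 0) stopf("cannot select a representative from an empty list")
  res <- vapply(chains, function(c) c$resolution %||% NA_real_, 1)
  rv <- vapply(chains, function(c) c$r_value %||% NA_real_, 1)
  res[is.na(res)] <- Inf
  rv[is.na(rv)] <- Inf
  sid <- vapply(chains, function(c) c$structure_id, "")
  cid <- vapply(chains, function(c) c$chain_id, "")
  chains[[order(res, rv, sid, cid)[1]]]
}

# ---- writer -----------------------------------------------------------------

#' Write chains of one entry to a PDB-format file
#'
#' Emits HEADER, EXPDTA, REMARK 2 (resolution), REMARK 3 (R-value), REMARK 465
#' (missing residues), SEQRES and representative-atom ATOM records, in a form
#' \code{\link{parse_structure}} reads back losslessly (sequence, presence
#' flags, coordinates and B-factors). Entry-level metadata is taken from the
#' first chain.
#'
#' @param chains List of \code{chain_structure} objects sharing a structure id.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_entry_pdb <- function(chains, path) {
  stopifnot(length(chains) >= 1)
  first <- chains[[1]]
  out <- c(
    sprintf("HEADER    %-40s%-9s   %4s", "SYNTHETIC STRUCTURE", "01-JAN-26", first$structure_id),
    sprintf("EXPDTA    %s", first$experiment %||% "X-RAY DIFFRACTION"))
  out <- c(out, if (is.na(first$resolution))
    "REMARK   2 RESOLUTION. NOT APPLICABLE."
    else sprintf("REMARK   2 RESOLUTION.    %.2f ANGSTROMS.", first$resolution))
  if (!is.na(first$r_value))
    out <- c(out, sprintf("REMARK   3   R VALUE            (WORKING SET) : %.3f", first$r_value))
  mis_any <- any(vapply(chains, function(c) any(!c$residues$present), TRUE))
  if (mis_any) {
    out <- c(out, "REMARK 465", "REMARK 465 MISSING RESIDUES",
             "REMARK 465   M RES C SSSEQI")
    for (c in chains) {
      r <- c$residues[!c$residues$present, , drop = FALSE]
      if (nrow(r) > 0)
        out <- c(out, sprintf("REMARK 465     %3s %1s %5d%1s",
                              aa1to3(r$aa, c$molecule_class), c$chain_id, r$resno, r$icode))
    }
  }
  for (c in chains) {
    codes <- sprintf("%3s", aa1to3(c$residues$aa, c$molecule_class))
    n <- length(codes)
    rows <- split(codes, ceiling(seq_len(n) / 13))
    out <- c(out, vapply(seq_along(rows), function(i)
      sprintf("SEQRES %3d %1s %4d  %s", i, c$chain_id, n,
              paste(rows[[i]], collapse = " ")), ""))
  }
  serial <- 0L
  for (c in chains) {
    name4 <- if (c$molecule_class == "nucleic") " C1'" else " CA "
    r <- c$residues[c$residues$present, , drop = FALSE]
    for (i in seq_len(nrow(r))) {
      serial <- serial + 1L
      out <- c(out, sprintf("ATOM  %5d %4s %3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                            serial, name4, aa1to3(r$aa[i], c$molecule_class),
                            c$chain_id, r$resno[i], r$icode[i],
                            r$x[i], r$y[i], r$z[i], 1.00, r$bfactor[i], "C"))
    }
    out <- c(out, "TER")
  }
  out <- c(out, "END")
  writeLines(out, path)
  invisible(path)
}
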