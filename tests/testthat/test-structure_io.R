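test_that("SEQRES merged with REMARK 465 reconstructs the full chain", {
  set.seed(11)
  ch <- mk_chain(runif(50, 15, 25), present = c(rep(FALSE, 5), rep(TRUE, 45)),
                 sid = "S900")
  f <- tempfile(fileext = ".pdb")
  write_entry_pdb(list(ch), f)
  parsed <- parse_structure(f)
  expect_length(parsed, 1)
  r <- parsed[["S900_A"]]$residues
  expect_equal(nrow(r), 50)
  expect_false(any(r$present[1:5]))
  expect_true(all(r$present[6:50]))
  expect_identical(chain_sequence(parsed[[1]]), chain_sequence(ch))
})

test_that("protein and nucleic chains are typed and counted per entry", {
  set.seed(12)
  a <- mk_chain(runif(30, 15, 25), sid = "S901", ch = "A")
  b <- mk_chain(runif(25, 15, 25), sid = "S901", ch = "B",
                xyz = cbind(3.8 * (0:24), 30, 0))
  c <- mk_chain(rep(20, 8), aa = c("A", "C", "G", "T", "T", "G", "C", "A"),
                sid = "S901", ch = "C", xyz = cbind(3.8 * (0:7), 60, 0),
                molecule_class = "nucleic")
  f <- tempfile(fileext = ".pdb")
  write_entry_pdb(list(a, b, c), f)
  parsed <- parse_structure(f)
  expect_length(parsed, 3)
  expect_equal(parsed[["S901_C"]]$molecule_class, "nucleic")
  expect_equal(parsed[["S901_A"]]$molecule_class, "protein")
})

test_that("highest-occupancy altloc supplies the Calpha B-factor", {
  lines <- c(
    "HEADER    SYNTHETIC STRUCTURE                     01-JAN-26   S902",
    "EXPDTA    X-RAY DIFFRACTION",
    "REMARK   2 RESOLUTION.    1.80 ANGSTROMS.",
    "SEQRES   1 A    3  CYS ASP GLU",
    "ATOM      1  CA  CYS A   1       0.000   0.000   0.000  1.00 20.00           C",
    "ATOM      2  CA AASP A   2       3.800   0.000   0.000  0.70 25.00           C",
    "ATOM      3  CA BASP A   2       3.900   0.000   0.000  0.30 99.00           C",
    "ATOM      4  CA  GLU A   3       7.600   0.000   0.000  1.00 20.00           C",
    "TER", "END")
  f <- tempfile(fileext = ".pdb")
  writeLines(lines, f)
  parsed <- parse_structure(f)
  expect_equal(parsed[[1]]$residues$bfactor[2], 25.00)
  # occupancy tie: first altloc encountered wins
  lines[6] <- "ATOM      2  CA AASP A   2       3.800   0.000   0.000  0.50 25.00           C"
  lines[7] <- "ATOM      3  CA BASP A   2       3.900   0.000   0.000  0.50 99.00           C"
  writeLines(lines, f)
  expect_equal(parse_structure(f)[[1]]$residues$bfactor[2], 25.00)
})

test_that("ATOM-only files flag author-numbering gaps as missing", {
  set.seed(13)
  ch <- mk_chain(runif(12, 15, 25), present = rep(TRUE, 12), sid = "S903")
  f <- tempfile(fileext = ".pdb")
  write_entry_pdb(list(ch), f)
  lines <- readLines(f)
  # strip SEQRES and the ATOM records of residues 4-6
  lines <- lines[!grepl("^SEQRES", lines)]
  atom_idx <- grep("^ATOM", lines)
  resno <- as.integer(substr(lines[atom_idx], 23, 26))
  writeLines(lines[-atom_idx[resno %in% 4:6]], f)
  r <- parse_structure(f)[[1]]$residues
  expect_equal(nrow(r), 12)
  expect_identical(which(!r$present), 4:6)
})

test_that("non-X-ray entries are admitted only on request", {
  set.seed(14)
  ch <- mk_chain(runif(10, 15, 25), sid = "S904")
  ch$experiment <- "SOLUTION NMR"
  f <- tempfile(fileext = ".pdb")
  write_entry_pdb(list(ch), f)
  expect_warning(res <- parse_structure(f), "not X-ray")
  expect_length(res, 0)
  expect_length(parse_structure(f, xray_only = FALSE), 1)
})

test_that("chains without standard polymer residues are skipped with a warning", {
  lines <- c(
    "HEADER    SYNTHETIC STRUCTURE                     01-JAN-26   S905",
    "EXPDTA    X-RAY DIFFRACTION",
    "SEQRES   1 A    2  ALA GLY",
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00 20.00           C",
    "ATOM      2  CA  GLY A   2       3.800   0.000   0.000  1.00 20.00           C",
    "ATOM      3  C1  LIG B   1      10.000   0.000   0.000  1.00 20.00           C",
    "TER", "END")
  f <- tempfile(fileext = ".pdb")
  writeLines(lines, f)
  expect_warning(parsed <- parse_structure(f), "no standard polymer")
  expect_identical(names(parsed), "S905_A")
})

test_that("missing input and mmCIF dialect produce clear errors", {
  expect_error(parse_structure(tempfile()), "no such file")
  f <- tempfile(fileext = ".pdb")
  writeLines("END", f)
  expect_error(parse_structure(f, dialect = "mmcif"), "not implemented")
})

test_that("representative selection prefers resolution, then R-value, then key", {
  ch <- function(sid, cid, res, rv)
    mk_chain(rep(20, 5), sid = sid, ch = cid, resolution = res, r_value = rv)
  picked <- select_representative(list(ch("AAA1", "A", 2.0, 0.2),
                                       ch("AAA2", "A", 1.5, 0.2),
                                       ch("AAA3", "A", 3.1, 0.2)))
  expect_equal(picked$resolution, 1.5)
  picked <- select_representative(list(ch("AAA1", "A", 2.0, 0.25),
                                       ch("AAA2", "A", 2.0, 0.19)))
  expect_equal(picked$r_value, 0.19)
  picked <- select_representative(list(ch("AAA2", "B", 2.0, 0.2),
                                       ch("AAA2", "A", 2.0, 0.2)))
  expect_equal(picked$chain_id, "A")
  # absent resolution sorts last
  picked <- select_representative(list(ch("AAA1", "A", NA, NA),
                                       ch("AAA2", "A", 2.5, 0.3)))
  expect_equal(picked$structure_id, "AAA2")
  single <- ch("AAA9", "A", NA, NA)
  expect_identical(select_representative(list(single)), single)
  expect_error(select_representative(list()), "empty")
})

test_that("write/parse round trip preserves sequence, presence and B-factors", {
  fx <- generate_cluster(fixture_spec(n_clusters = 2, seed = 91),
                         dir = tempfile("rt"))
  for (cl in fx$clusters) {
    for (mi in seq_along(cl$entries)) {
      orig <- cl$entries[[mi]][[1]]
      parsed <- parse_structure(cl$files[mi])
      got <- parsed[[chain_structure_key(orig)]]
      expect_identical(chain_sequence(got), chain_sequence(orig))
      expect_identical(got$residues$present, orig$residues$present)
      expect_identical(got$residues$bfactor, orig$residues$bfactor)
      # count conservation
      expect_equal(sum(got$residues$present) + sum(!got$residues$present),
                   nrow(got$residues))
    }
  }
})
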