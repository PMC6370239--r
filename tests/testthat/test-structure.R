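test_that("a minimal file parses into chains, residues and HET records", {
  txt <- mini_pdb_text(c(
    "HETATM   10  C1  GOL A 101      12.000  12.000  12.000  1.00 10.00           C",
    "HETATM   11  O1  GOL A 101      13.200  12.000  12.000  1.00 10.00           O",
    "HETATM   12  O   HOH A 201       9.000   9.000   9.000  1.00 10.00           O"))
  s <- parse_structure(paste(txt, collapse = "\n"), role = "apo",
                       pdb_id = "mini")
  expect_s3_class(s, "structure_record")
  expect_equal(s$resolution, 1.9)
  expect_equal(length(unique(s$atom$chain[s$atom$type == "ATOM"])), 1L)
  expect_equal(nrow(residue_tab <- unique(
    s$atom[s$atom$type == "ATOM", c("chain", "resno")])), 3L)
  hets <- het_records(s)
  expect_setequal(hets$component_code, c("GOL", "HOH"))
  expect_equal(hets$n_atoms[hets$component_code == "GOL"], 2L)
})

test_that("non-contiguous serials parse to the same residues", {
  txt <- mini_pdb_text()
  renum <- sub("^(ATOM  )(.....)", "\\1     ", txt)  # blank serials differ
  txt2 <- txt
  # triple every serial number
  for (i in seq_along(txt2)) {
    if (grepl("^ATOM", txt2[i])) {
      old <- as.integer(substr(txt2[i], 7, 11))
      txt2[i] <- paste0(substr(txt2[i], 1, 6),
                        formatC(old * 3L, width = 5), substr(txt2[i], 12,
                                                             nchar(txt2[i])))
    }
  }
  s1 <- parse_structure(paste(txt, collapse = "\n"), role = "apo")
  s2 <- parse_structure(paste(txt2, collapse = "\n"), role = "apo")
  cols <- c("name", "resname", "chain", "resno", "x", "y", "z")
  expect_equal(s1$atom[, cols], s2$atom[, cols])
})

test_that("malformed coordinate lines fail naming the line number", {
  txt <- mini_pdb_text()
  txt[5] <- substr(txt[5], 1, 40)   # truncate a coordinate field
  expect_error(parse_structure(paste(txt, collapse = "\n"), role = "apo"),
               "line 5")
})

test_that("a missing resolution is an error, a supplied one overrides", {
  txt <- mini_pdb_text()[-1]
  expect_error(parse_structure(paste(txt, collapse = "\n"), role = "apo"),
               "resolution")
  s <- parse_structure(paste(txt, collapse = "\n"), role = "apo",
                       resolution = 2.1)
  expect_equal(s$resolution, 2.1)
})

test_that("PDB write/parse round-trips atoms and coordinates", {
  s <- make_ideal_chain(FIX_SEQ, pdb_id = "rt01")
  s$atom[, c("x", "y", "z")] <- round(s$atom[, c("x", "y", "z")], 3)
  tf <- withr::local_tempfile(fileext = ".pdb")
  write_structure(s, tf)
  s2 <- parse_structure(tf, role = "apo")
  cols <- c("name", "resname", "chain", "resno", "x", "y", "z", "occ")
  expect_equal(s2$atom[, cols], s$atom[, cols])
  expect_equal(s2$resolution, s$resolution)
})

test_that("altloc resolution keeps highest occupancy, first on ties", {
  ex <- c(
    "ATOM     10  CB ASER A   3       8.000   3.000   1.000  0.60 10.00           C",
    "ATOM     11  CB BSER A   3       8.100   3.100   1.100  0.40 10.00           C",
    "ATOM     12  OG ASER A   3       8.000   2.000   2.000  0.50 10.00           O",
    "ATOM     13  OG BSER A   3       8.500   2.500   2.500  0.50 10.00           O")
  s <- parse_structure(paste(mini_pdb_text(ex), collapse = "\n"),
                       role = "apo")
  r <- resolve_altlocs(s)
  cb <- r$atom[r$atom$name == "CB", ]
  og <- r$atom[r$atom$name == "OG", ]
  expect_equal(nrow(cb), 1L)
  expect_equal(cb$x, 8.0)            # higher occupancy copy
  expect_equal(og$x, 8.0)            # tie -> first listed
  # idempotent, and identity on altloc-free structures
  expect_equal(resolve_altlocs(r)$atom, r$atom)
  plain <- parse_structure(paste(mini_pdb_text(), collapse = "\n"),
                           role = "apo")
  expect_equal(resolve_altlocs(plain)$atom[, -4],
               plain$atom[, -4])     # altloc column normalised only
})

test_that("stripping removes hydrogens and waters, conserving atoms", {
  ex <- c(
    "ATOM     20  H   ALA A   1       0.500   0.500   0.500  1.00 10.00           H",
    "HETATM   21  O   HOH A 301       9.000   9.000   9.000  1.00 10.00           O",
    "HETATM   22  O   HOH A 302       9.500   9.500   9.500  1.00 10.00           O")
  s <- parse_structure(paste(mini_pdb_text(ex), collapse = "\n"),
                       role = "apo")
  n0 <- nrow(s$atom)
  st <- strip_for_analysis(s)
  expect_equal(sum(toupper(st$atom$element) %in% c("H", "D")), 0L)
  expect_equal(sum(st$atom$resname == "HOH"), 0L)
  expect_equal(n0 - nrow(st$atom), 3L)   # removed + retained = original
  # retained coordinates untouched
  expect_equal(st$atom[, c("x", "y", "z")],
               s$atom[s$atom$element != "H" & s$atom$resname != "HOH",
                      c("x", "y", "z")], ignore_attr = TRUE)
})

test_that("multi-HET ligands are extracted as one molecule", {
  ex <- c(
    "HETATM   30  C1  34H A 401      12.000  12.000  12.000  1.00 10.00           C",
    "HETATM   31  C1  DIL A 402      13.000  12.000  12.000  1.00 10.00           C",
    "HETATM   32  C1  XPR A 403      14.000  12.000  12.000  1.00 10.00           C",
    "HETATM   33  C1  AG2 A 404      15.000  12.000  12.000  1.00 10.00           C")
  s <- parse_structure(paste(mini_pdb_text(ex), collapse = "\n"),
                       role = "holo")
  spec <- data.frame(component_code = c("34H", "DIL", "XPR", "AG2"),
                     chain = "A", resno = 401:404, mol_weight = 575)
  s2 <- extract_ligand(s, spec)
  expect_equal(length(s2$ligand$component_codes), 4L)
  expect_equal(nrow(s2$ligand$atoms), 4L)
  expect_equal(s2$ligand$mol_weight, 575)
  expect_equal(nrow(het_records(s2)), 0L)
  # a selector matching nothing is an error
  bad <- data.frame(component_code = "ZZZ", chain = "A", resno = 999,
                    mol_weight = 1)
  expect_error(extract_ligand(s, bad), "matches nothing")
})

test_that("HET molecular weights come from metadata or composition", {
  ex <- c(
    "HETATM   30  C1  GOL A 401      12.000  12.000  12.000  1.00 10.00           C",
    "HETATM   31  O1  GOL A 401      13.000  12.000  12.000  1.00 10.00           O")
  s <- parse_structure(paste(mini_pdb_text(ex), collapse = "\n"),
                       role = "apo")
  h1 <- het_records(s)
  expect_equal(h1$mol_weight, 12.011 + 15.999)    # composition fallback
  h2 <- het_records(s, mw_table = data.frame(component_code = "GOL",
                                             mol_weight = 92.09))
  expect_equal(h2$mol_weight, 92.09)
})
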