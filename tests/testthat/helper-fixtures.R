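# Shared fixture builders. All structures are generated in code; nothing
# is read from disk except files the tests themselves write.

FIX_SEQ <- "AKLSVERTWLKNMHDEYFAQCILGSTVKRN"

# A small numbered family: n_apo + n_holo ideal-chain members with
# optional per-member chi1 settings and backbone perturbation, holo
# ligands contacting `ligand_resnos`. Returns the protein_family after
# numbering and site unification.
make_test_family <- function(n_apo = 2, n_holo = 2, sequence = FIX_SEQ,
                             backbone_rmsd = 0, chi1_settings = list(),
                             ligand_resnos = c(12, 13, 15), seed = 1) {
  spec <- family_fixture_spec(
    "FTST", sequence, n_apo = n_apo, n_holo = n_holo,
    backbone_rmsd = backbone_rmsd, chi1_settings = chi1_settings,
    ligand_resnos = ligand_resnos, seed = seed)
  fx <- make_family(spec, fam_index = 99)
  members <- fx$members
  for (id in names(members)) {
    s <- members[[id]]
    if (s$role == "holo") {
      ligspec <- fx$ligands[fx$ligands$pdb_id == id, , drop = FALSE]
      s <- extract_ligand(s, ligspec)
    }
    members[[id]] <- s
  }
  fams <- cluster_families(members)
  stopifnot(length(fams) == 1L)
  fam <- build_reference_numbering(fams[[1]])
  unify_sites(fam)
}

# A tiny constructed holo structure whose ligand atoms sit at exactly
# 4.49 A (residue 2) and 4.51 A (residue 4) from a CB heavy atom, to
# exercise the inclusive contact boundary.
boundary_fixture <- function() {
  s <- make_ideal_chain("AKLSV", pdb_id = "bnda", role = "holo")
  s$atom[, c("x", "y", "z")] <- round(s$atom[, c("x", "y", "z")], 3)
  cb2 <- as.numeric(s$atom[s$atom$resno == 2 & s$atom$name == "CB",
                           c("x", "y", "z")])
  cb4 <- as.numeric(s$atom[s$atom$resno == 4 & s$atom$name == "CB",
                           c("x", "y", "z")])
  lig <- data.frame(
    type = "HETATM", serial = 100:101, name = c("C1", "C2"), altloc = "",
    resname = "LIG", chain = "X", resno = 900L, icode = "",
    x = c(cb2[1], cb4[1]), y = c(cb2[2], cb4[2]),
    z = round(c(cb2[3] + 4.49, cb4[3] - 4.51), 3), occ = 1, b = 0,
    element = "C", stringsAsFactors = FALSE)
  s$atom <- rbind(s$atom, lig)
  spec <- data.frame(component_code = "LIG", chain = "X", resno = 900L,
                     mol_weight = 24)
  extract_ligand(s, spec)
}

# Two-chain record assembled from two ideal chains.
make_two_chain <- function(seq_a, seq_b, pdb_id = "twoc",
                           resolution = 1.8, role = "apo",
                           offset_b = c(30, 0, 0), start_b = 1L) {
  a <- make_ideal_chain(seq_a, chain = "A")
  b <- make_ideal_chain(seq_b, chain = "B", start_resno = start_b)
  bt <- b$atom
  bt$x <- bt$x + offset_b[1]; bt$y <- bt$y + offset_b[2]
  bt$z <- bt$z + offset_b[3]
  bt$serial <- bt$serial + max(a$atom$serial)
  structure_record(rbind(a$atom, bt), pdb_id = pdb_id,
                   resolution = resolution, role = role)
}

# Minimal hand-written PDB text: three residues, one chain, plus optional
# extra lines appended before END.
mini_pdb_text <- function(extra = character()) {
  c("REMARK   2 RESOLUTION.    1.90 ANGSTROMS.",
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00 10.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00 10.00           C",
    "ATOM      3  C   ALA A   1       2.009   1.420   0.000  1.00 10.00           C",
    "ATOM      4  N   GLY A   2       3.332   1.536   0.000  1.00 10.00           N",
    "ATOM      5  CA  GLY A   2       4.000   2.800   0.000  1.00 10.00           C",
    "ATOM      6  C   GLY A   2       5.500   2.700   0.100  1.00 10.00           C",
    "ATOM      7  N   SER A   3       6.100   3.900   0.100  1.00 10.00           N",
    "ATOM      8  CA  SER A   3       7.550   4.000   0.200  1.00 10.00           C",
    "ATOM      9  C   SER A   3       8.100   5.400   0.300  1.00 10.00           C",
    extra,
    "END")
}
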