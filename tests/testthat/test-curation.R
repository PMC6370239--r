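test_that("identical sequences cluster together, substitutions split", {
  a <- make_ideal_chain(FIX_SEQ, pdb_id = "aaaa")
  b <- make_ideal_chain(FIX_SEQ, pdb_id = "bbbb")
  mut <- paste0(substr(FIX_SEQ, 1, 14), "W",
                substr(FIX_SEQ, 16, nchar(FIX_SEQ)))
  c_ <- make_ideal_chain(mut, pdb_id = "cccc")
  fams <- cluster_families(list(a, b, c_), merge_terminal_extensions = TRUE)
  sizes <- sort(vapply(fams, function(f) length(f$members), integer(1)))
  expect_equal(sizes, c(1L, 2L))   # core substitution stays separate
  expect_equal(length(cluster_families(list())), 0L)
})

test_that("terminal extensions merge only when the pass is enabled", {
  a <- make_ideal_chain(FIX_SEQ, pdb_id = "aaaa")
  ext <- make_ideal_chain(paste0(FIX_SEQ, "GSH"), pdb_id = "eeee")
  # substring-containment oracle
  expect_true(grepl(FIX_SEQ, paste0(FIX_SEQ, "GSH"), fixed = TRUE))
  merged <- cluster_families(list(a, ext), merge_terminal_extensions = TRUE)
  expect_equal(length(merged), 1L)
  expect_equal(length(merged[[1]]$members), 2L)
  split <- cluster_families(list(a, ext), merge_terminal_extensions = FALSE)
  expect_equal(length(split), 2L)
})

test_that("reference numbering maps offsets and missing residues", {
  ref <- make_ideal_chain(FIX_SEQ, pdb_id = "refa", resolution = 1.5)
  off <- make_ideal_chain(FIX_SEQ, pdb_id = "offb", resolution = 2.0,
                          start_resno = 70L)
  fam <- cluster_families(list(ref, off))[[1]]
  fam <- build_reference_numbering(fam)
  expect_equal(fam$reference, "refa")   # best resolution wins
  nm <- fam$numbering[["offb"]]
  expect_equal(nm$ref_index, nm$resno - 69L)        # pure offset
  expect_equal(anyDuplicated(nm$ref_index), 0L)     # injective
  # a member missing residues 10..12 omits exactly those ref indices
  gap <- off
  gap$pdb_id <- "gapc"
  gap$atom <- gap$atom[!(gap$atom$resno %in% (70L + 9:11)), ]
  fam3 <- build_reference_numbering(
    structure(list(family_id = "F", members = list(refa = ref,
                                                   gapc = gap),
                   rejected = character()), class = "protein_family"))
  nmg <- fam3$numbering[["gapc"]]
  expect_setequal(setdiff(seq_len(nchar(FIX_SEQ)), nmg$ref_index), 10:12)
})

test_that("chain assignment matches the exhaustive pairing oracle", {
  seq_a <- "AKLSVERTWLKN"
  seq_b <- "MHDEYFAQCILG"
  ref <- make_two_chain(seq_a, seq_b, pdb_id = "r2ch", resolution = 1.5)
  mem <- make_two_chain(seq_a, seq_b, pdb_id = "m2ch", resolution = 1.9)
  fam <- build_reference_numbering(
    structure(list(family_id = "F2", members = list(r2ch = ref,
                                                    m2ch = mem),
                   rejected = character()), class = "protein_family"))
  nm <- fam$numbering[["m2ch"]]
  got <- unique(nm[, c("chain", "ref_chain")])
  # oracle: score every member-chain/ref-chain pairing exhaustively
  mat <- apoflex:::aa_submat()
  seqs <- chain_sequences(mem); refs <- chain_sequences(ref)
  perms <- list(c(1, 2), c(2, 1))
  scores <- vapply(perms, function(p)
    sum(vapply(seq_along(seqs), function(i)
      apoflex:::align_score(seqs[[i]], refs[[p[i]]], mat), numeric(1))),
    numeric(1))
  best <- perms[[which.max(scores)]]
  expect_equal(got$ref_chain[match(names(seqs), got$chain)],
               names(refs)[best])
})

test_that("ambiguous mappings are rejected with RENUMBER_FAIL", {
  ref <- make_ideal_chain(FIX_SEQ, pdb_id = "refa", resolution = 1.5)
  # two member chains covering the same reference chain stretch
  dup <- make_two_chain(FIX_SEQ, FIX_SEQ, pdb_id = "dupx",
                        resolution = 2.0)
  fam <- build_reference_numbering(
    structure(list(family_id = "F", members = list(refa = ref,
                                                   dupx = dup),
                   rejected = character()), class = "protein_family"))
  expect_false("dupx" %in% names(fam$members))
  expect_equal(unname(fam$rejected[["dupx"]]), "RENUMBER_FAIL")
})

test_that("holo validation applies resolution, ligand-count and site
          rules", {
  fam <- make_test_family()
  holo_id <- names(fam$members)[
    vapply(fam$members, `[[`, character(1), "role") == "holo"][1]
  s <- fam$members[[holo_id]]
  ok <- validate_holo(s)
  expect_true(ok$accepted)
  # resolution 2.6 rejected; 2.5 accepted (inclusive cutoff)
  s26 <- s; s26$resolution <- 2.6
  expect_equal(validate_holo(s26)$reasons, "RESOLUTION")
  s25 <- s; s25$resolution <- 2.5
  expect_true(validate_holo(s25)$accepted)
  # two valid ligands rejected before extraction
  raw <- s; raw$ligand <- NULL
  two <- data.frame(pdb_id = s$pdb_id, ligand_id = c("L1", "L2"),
                    component_code = c("LIG", "XYZ"), chain = "X",
                    resno = c(900L, 910L), mol_weight = 300)
  expect_equal(validate_holo(raw, ligspec = two)$reasons, "MULTI_LIGAND")
  # an additive right next to the ligand contaminates the site
  cont <- s
  lig1 <- as.numeric(s$ligand$atoms[1, c("x", "y", "z")])
  cont$atom <- rbind(cont$atom, data.frame(
    type = "HETATM", serial = max(cont$atom$serial) + 1L, name = "C1",
    altloc = "", resname = "EDO", chain = "Y", resno = 800L, icode = "",
    x = lig1[1] + 3, y = lig1[2], z = lig1[3], occ = 1, b = 0,
    element = "C"))
  expect_equal(validate_holo(cont)$reasons, "SITE_CONTAMINATION")
  # missing ligand spec is an error
  expect_error(validate_holo(raw, ligspec = NULL), "specification")
})

test_that("apo validation enforces the HET weight/allow-list and 4.5 A
          site rules", {
  fam <- make_test_family()
  apo_id <- names(fam$members)[
    vapply(fam$members, `[[`, character(1), "role") == "apo"][1]
  s <- fam$members[[apo_id]]
  expect_true(validate_apo(s, fam)$accepted)  # only protein (waters gone)

  site_xyz <- apoflex:::site_atom_coords(s, fam)
  add_het <- function(s, code, at_xyz) {
    s$atom <- rbind(s$atom, data.frame(
      type = "HETATM", serial = max(s$atom$serial) + 1L, name = "C1",
      altloc = "", resname = code, chain = "Y", resno = 850L, icode = "",
      x = at_xyz[1], y = at_xyz[2], z = at_xyz[3], occ = 1, b = 0,
      element = "C"))
    s
  }
  far <- colMeans(site_xyz) + c(100, 0, 0)
  near <- site_xyz[1, ] + c(4.0, 0, 0)   # within 4.5 of a site atom
  mw <- data.frame(component_code = c("GOL", "BIG"),
                   mol_weight = c(92, 180))
  # allow-listed glycerol far from the site: accepted
  expect_true(validate_apo(add_het(s, "GOL", far), fam,
                           allowlist = "GOL", mw_table = mw)$accepted)
  # same glycerol 4.0 A from a site residue: site contamination
  expect_equal(validate_apo(add_het(s, "GOL", near), fam,
                            allowlist = "GOL", mw_table = mw)$reasons,
               "SITE_CONTAMINATION")
  # heavy non-listed HET anywhere: disallowed
  expect_equal(validate_apo(add_het(s, "BIG", far), fam,
                            allowlist = "GOL", mw_table = mw)$reasons,
               "HET_DISALLOWED")
  # ordering contract: no site, no apo validation
  fam_nosite <- fam; fam_nosite$unified_site <- NULL
  expect_error(validate_apo(s, fam_nosite), "unified site")
})

test_that("the minimum-membership rule removes depleted families", {
  f1 <- make_test_family(n_apo = 2, n_holo = 2)
  f2 <- make_test_family(n_apo = 1, n_holo = 3, seed = 2)
  kept <- filter_min_members(list(f1, f2))
  expect_equal(length(kept), 1L)
  expect_equal(kept[[1]]$family_id, f1$family_id)
})

test_that("curation decisions are deterministic across reruns", {
  fam <- make_test_family()
  apo_id <- names(fam$members)[
    vapply(fam$members, `[[`, character(1), "role") == "apo"][1]
  d1 <- validate_apo(fam$members[[apo_id]], fam)
  d2 <- validate_apo(fam$members[[apo_id]], fam)
  expect_identical(d1, d2)
})
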