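# Ideal covalent geometry used by the builder (Engh-Huber-like means).
BOND <- c(N_CA = 1.458, CA_C = 1.525, C_N = 1.329, C_O = 1.231,
          CA_CB = 1.530, CB_CG = 1.520, CB_OG = 1.417, CB_SG = 1.808)
ANGLE <- c(N_CA_C = 111.2, CA_C_N = 116.2, C_N_CA = 121.7,
           CA_C_O = 120.8, N_CA_CB = 110.5, CA_CB_G = 114.0)

# Natural-extension-of-reference-frame placement: returns the point d with
# |c-d| = bond, angle(b,c,d) = angle and torsion(a,b,c,d) = torsion
# (degrees, same sign convention as dihedral()).
place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180; tor <- torsion * pi / 180
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  n <- cross3(b - a, bc); n <- n / sqrt(sum(n^2))
  m <- cross3(n, bc)
  d <- c(-bond * cos(ang), bond * sin(ang) * cos(tor),
         bond * sin(ang) * sin(tor))
  c + d[1] * bc + d[2] * m + d[3] * n
}

gamma_spec <- function(aa1) {
  # returns data.frame(name, bond, element) of gamma atoms; torsion offset
  # relative to chi1 in `off` (Val/Ile/Thr carry a second branch at +120).
  switch(aa1,
    V = data.frame(name = c("CG1", "CG2"), bond = BOND[["CB_CG"]],
                   element = "C", off = c(0, 120)),
    I = data.frame(name = c("CG1", "CG2"), bond = BOND[["CB_CG"]],
                   element = "C", off = c(0, 120)),
    T = data.frame(name = c("OG1", "CG2"), bond = c(BOND[["CB_OG"]],
                                                    BOND[["CB_CG"]]),
                   element = c("O", "C"), off = c(0, 120)),
    S = data.frame(name = "OG", bond = BOND[["CB_OG"]], element = "O",
                   off = 0),
    C = data.frame(name = "SG", bond = BOND[["CB_SG"]], element = "S",
                   off = 0),
    G = , A = , P = NULL,
    data.frame(name = "CG", bond = BOND[["CB_CG"]], element = "C",
               off = 0))
}

AA1TO3 <- stats::setNames(names(AA3TO1)[1:20], unname(AA3TO1[1:20]))

#' Build an ideal-geometry peptide chain
#'
#' Constructs a single chain with standard bond lengths and angles, all
#' backbone torsions set to the requested phi/psi (omega fixed at 180),
#' and side chains reduced to CB plus the gamma atom(s) that define chi1,
#' built at the requested chi1 (default -60). Gly has no side chain; Pro
#' and Ala carry only CB.
#'
#' @param sequence one-letter amino-acid string.
#' @param phi,psi backbone torsions in degrees (defaults: alpha helix).
#' @param chi1 default chi1 angle in degrees for every side chain.
#' @param chain chain identifier.
#' @param start_resno author numbering of the first residue.
#' @param pdb_id,resolution,role metadata for the record.
#' @return a `structure_record`.
#' @export
make_ideal_chain <- function(sequence, phi = -57, psi = -47, chi1 = -60,
                             chain = "A", start_resno = 1L,
                             pdb_id = "synt", resolution = 1.8,
                             role = "apo") {
  aa <- strsplit(toupper(sequence), "")[[1]]
  stopifnot(length(aa) >= 2L, all(aa %in% names(AA1TO3)))
  rows <- list(); serial <- 0L
  add <- function(name, el, resno, resname, xyz) {
    serial <<- serial + 1L
    rows[[length(rows) + 1L]] <<- data.frame(
      type = "ATOM", serial = serial, name = name, altloc = "",
      resname = resname, chain = chain, resno = resno, icode = "",
      x = xyz[1], y = xyz[2], z = xyz[3], occ = 1, b = 0, element = el,
      stringsAsFactors = FALSE)
  }
  N <- c(0, 0, 0); CA <- c(BOND[["N_CA"]], 0, 0)
  C <- place_atom(c(0, 1, 0), N, CA, BOND[["CA_C"]], ANGLE[["N_CA_C"]],
                  180)
  for (i in seq_along(aa)) {
    resno <- start_resno + i - 1L
    res3 <- AA1TO3[[aa[i]]]
    if (i > 1L) {
      Nn <- place_atom(N, CA, C, BOND[["C_N"]], ANGLE[["CA_C_N"]], psi)
      CAn <- place_atom(CA, C, Nn, BOND[["N_CA"]], ANGLE[["C_N_CA"]], 180)
      Cn <- place_atom(C, Nn, CAn, BOND[["CA_C"]], ANGLE[["N_CA_C"]], phi)
      N <- Nn; CA <- CAn; C <- Cn
    }
    add("N", "N", resno, res3, N)
    add("CA", "C", resno, res3, CA)
    add("C", "C", resno, res3, C)
    add("O", "O", resno, res3, place_atom(N, CA, C, BOND[["C_O"]],
                                          ANGLE[["CA_C_O"]], psi + 180))
    if (aa[i] != "G") {
      CB <- place_atom(C, N, CA, BOND[["CA_CB"]], ANGLE[["N_CA_CB"]],
                       122.6)
      add("CB", "C", resno, res3, CB)
      gs <- gamma_spec(aa[i])
      if (!is.null(gs)) {
        for (k in seq_len(nrow(gs)))
          add(gs$name[k], gs$element[k], resno, res3,
              place_atom(N, CA, CB, gs$bond[k], ANGLE[["CA_CB_G"]],
                         chi1 + gs$off[k]))
      }
    }
  }
  structure_record(do.call(rbind, rows), pdb_id = pdb_id,
                   resolution = resolution, role = role)
}

#' Set the chi1 angle of one residue
#'
#' Rotates every atom distal to CB about the CA-CB axis so the measured
#' chi1 equals the requested angle exactly; backbone and all other
#' residues are untouched. For gamma-branched residues (Val, Ile, Thr)
#' both branches rotate rigidly, so their angular offset is preserved.
#'
#' @param s a `structure_record`.
#' @param resno residue number (with `chain`, `icode` selectors).
#' @param angle target chi1 in degrees.
#' @param chain,icode residue selectors.
#' @return the modified record.
#' @export
set_chi1 <- function(s, resno, angle, chain = "A", icode = "") {
  at <- s$atom
  sel <- at$chain == chain & at$resno == resno & at$icode == icode &
    at$type == "ATOM"
  if (!any(sel)) stop("no residue ", chain, resno, " in ", s$pdb_id)
  ra <- at[sel, , drop = FALSE]
  cur <- chi1_of_residue(ra)
  if (isTRUE(attr(cur, "missing_atoms")) || !nrow(cur))
    stop("residue ", chain, resno, " has no measurable chi1")
  delta <- -(angle - cur$chi1[cur$which == "primary"]) * pi / 180
  ca <- as.numeric(ra[match("CA", ra$name), c("x", "y", "z")])
  cb <- as.numeric(ra[match("CB", ra$name), c("x", "y", "z")])
  axis <- cb - ca; axis <- axis / sqrt(sum(axis^2))
  distal <- sel & !(at$name %in% c("N", "CA", "C", "O", "CB"))
  if (any(distal)) {
    xyz <- as.matrix(at[distal, c("x", "y", "z")])
    xyz <- sweep(xyz, 2, cb)
    K <- matrix(c(0, axis[3], -axis[2],
                  -axis[3], 0, axis[1],
                  axis[2], -axis[1], 0), 3, 3)   # row-vector convention
    R <- diag(3) + sin(delta) * K + (1 - cos(delta)) * (K %*% K)
    xyz <- xyz %*% R
    at[distal, c("x", "y", "z")] <- sweep(xyz, 2, cb, `+`)
  }
  s$atom <- at
  s
}

#' Apply a smooth random backbone displacement of controlled magnitude
#'
#' Displaces every residue rigidly by a low-frequency sinusoidal field
#' along the chain (protein-like collective deformation rather than
#' per-atom noise; side-chain internal geometry, hence chi1, is
#' preserved). The field is rescaled iteratively so the achieved all-CA
#' RMSD after optimal superposition matches the target within 0.1 %.
#'
#' @param s a `structure_record`.
#' @param target_rmsd desired all-CA RMSD in Angstrom (0 returns the
#'   input unchanged).
#' @param seed integer seed (deterministic output).
#' @param n_modes number of sinusoidal modes (default 4).
#' @return list: `structure`, `achieved` (measured RMSD).
#' @export
perturb_backbone <- function(s, target_rmsd, seed = 1L, n_modes = 4L) {
  if (target_rmsd <= 0) return(list(structure = s, achieved = 0))
  at <- s$atom
  prot <- at$type == "ATOM"
  key <- res_key(at$chain, at$resno, at$icode)
  res_ids <- unique(key[prot])
  L <- length(res_ids)
  u <- (match(key, res_ids) - 1) / max(L - 1, 1)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  disp <- matrix(0, nrow(at), 3)
  for (k in seq_len(n_modes)) {
    amp <- stats::rnorm(3, sd = 1 / k)
    phase <- stats::runif(3, 0, 2 * pi)
    for (ax in 1:3)
      disp[, ax] <- disp[, ax] + amp[ax] * sin(2 * pi * k * u + phase[ax])
  }
  disp[is.na(u), ] <- 0                      # HET atoms stay put
  ca <- prot & at$name == "CA"
  X <- as.matrix(at[ca, c("x", "y", "z")])
  alpha <- target_rmsd
  achieved <- NA_real_
  for (iter in 1:20) {
    Y <- X + alpha * disp[ca, , drop = FALSE]
    achieved <- kabsch(X, Y)$rmsd
    if (abs(achieved - target_rmsd) <= 1e-3 * target_rmsd) break
    alpha <- alpha * target_rmsd / achieved
  }
  at[, c("x", "y", "z")] <- as.matrix(at[, c("x", "y", "z")]) +
    alpha * disp
  s$atom <- at
  list(structure = s, achieved = achieved)
}

# Attach a rigid ligand near target residues: one carbon per target
# residue, placed `dist` Angstrom outward (away from the protein centroid)
# from the residue's CB (CA for Gly). Codes may list several HET
# components; atoms are distributed over them (a multi-HET ligand is one
# molecule).
attach_ligand <- function(s, target_resnos, dist = 4.2,
                          codes = "LIG", het_chain = "X",
                          start_resno = 900L) {
  at <- s$atom
  prot <- at[at$type == "ATOM", , drop = FALSE]
  centroid <- colMeans(as.matrix(prot[, c("x", "y", "z")]))
  pts <- lapply(target_resnos, function(r) {
    ra <- prot[prot$resno == r, , drop = FALSE]
    if (!nrow(ra)) stop("target residue ", r, " absent")
    anchor_name <- if ("CB" %in% ra$name) "CB" else "CA"
    anchor <- as.numeric(ra[match(anchor_name, ra$name), c("x", "y", "z")])
    v <- anchor - centroid; v <- v / sqrt(sum(v^2))
    anchor + dist * v
  })
  comp <- rep(codes, length.out = length(pts))
  serial0 <- max(at$serial)
  lig <- do.call(rbind, lapply(seq_along(pts), function(i)
    data.frame(type = "HETATM", serial = serial0 + i,
               name = sprintf("C%d", i), altloc = "",
               resname = comp[i], chain = het_chain,
               resno = start_resno + match(comp[i], codes) - 1L,
               icode = "", x = pts[[i]][1], y = pts[[i]][2],
               z = pts[[i]][3], occ = 1, b = 0, element = "C",
               stringsAsFactors = FALSE)))
  s$atom <- rbind(at, lig)
  s
}

# Attach a single-atom decoy HET either near the binding site (within the
# contact cutoff of the first site residue) or remote from the protein.
attach_decoy <- function(s, code, position = c("near_site", "remote"),
                         site_resnos = NULL, dist = 4.0,
                         het_chain = "Y", resno = 950L) {
  position <- match.arg(position)
  at <- s$atom
  prot <- at[at$type == "ATOM", , drop = FALSE]
  centroid <- colMeans(as.matrix(prot[, c("x", "y", "z")]))
  if (position == "near_site") {
    stopifnot(length(site_resnos) >= 1L)
    ra <- prot[prot$resno == site_resnos[1], , drop = FALSE]
    anchor_name <- if ("CB" %in% ra$name) "CB" else "CA"
    anchor <- as.numeric(ra[match(anchor_name, ra$name), c("x", "y", "z")])
    v <- anchor - centroid; v <- v / sqrt(sum(v^2))
    p <- anchor + dist * v
  } else {
    p <- centroid + c(60, 0, 0)
  }
  s$atom <- rbind(at, data.frame(
    type = "HETATM", serial = max(at$serial) + 1L, name = "C1",
    altloc = "", resname = code, chain = het_chain, resno = resno,
    icode = "", x = p[1], y = p[2], z = p[3], occ = 1, b = 0,
    element = "C", stringsAsFactors = FALSE))
  s
}

round_coords <- function(s) {
  # snap to the PDB fixed-column precision grid so written files reproduce
  # in-memory coordinates exactly
  s$atom[, c("x", "y", "z")] <- round(s$atom[, c("x", "y", "z")], 3)
  if (!is.null(s$ligand))
    s$ligand$atoms[, c("x", "y", "z")] <-
      round(s$ligand$atoms[, c("x", "y", "z")], 3)
  s
}

#' Specification of one synthetic family
#'
#' @param family_id family identifier string.
#' @param sequence one-letter chain sequence.
#' @param n_apo,n_holo member counts.
#' @param backbone_rmsd target all-CA RMSD (vs the common ideal template)
#'   per member, recycled; 0 means identical backbones.
#' @param chi1_settings named list: residue number (as character) to a
#'   numeric vector of chi1 angles, one per member (apo members first).
#' @param ligand_resnos residues the holo ligand must contact.
#' @param ligand_dist placement distance in Angstrom (default 4.2).
#' @param ligand_codes HET component code(s) of the ligand.
#' @param ligand_mass ligand molecular weight in g/mol (metadata).
#' @param decoys list of decoy HETs: each
#'   `list(code, mw, position, member)` with position `"near_site"` or
#'   `"remote"` and `member` an index into the member list.
#' @param resolutions per-member resolution, recycled (default 1.8).
#' @param seed integer seed.
#' @return a `family_fixture_spec` list.
#' @export
family_fixture_spec <- function(family_id, sequence, n_apo = 2L,
                                n_holo = 2L, backbone_rmsd = 0.5,
                                chi1_settings = list(),
                                ligand_resnos = NULL, ligand_dist = 4.2,
                                ligand_codes = "LIG", ligand_mass = 300,
                                decoys = list(), resolutions = 1.8,
                                seed = 1L) {
  n <- n_apo + n_holo
  structure(list(
    family_id = family_id, sequence = toupper(sequence),
    n_apo = n_apo, n_holo = n_holo,
    backbone_rmsd = rep(backbone_rmsd, length.out = n),
    chi1_settings = chi1_settings,
    ligand_resnos = ligand_resnos, ligand_dist = ligand_dist,
    ligand_codes = ligand_codes, ligand_mass = ligand_mass,
    decoys = decoys, resolutions = rep(resolutions, length.out = n),
    seed = seed), class = "family_fixture_spec")
}

#' Generate one synthetic family with known ground truth
#'
#' Builds an ideal template chain, derives each member by a controlled
#' smooth backbone displacement and explicit chi1 settings, places the
#' holo ligands so they contact the requested residues, plants any decoy
#' HETs, snaps coordinates to PDB precision, and measures every manifest
#' quantity (unified-site membership, pairwise CA RMSDs, per-set chi1
#' ranges, expected curation decisions) from the final coordinates.
#'
#' @param spec a [family_fixture_spec()].
#' @param dir optional directory; when given, PDB files are written under
#'   `dir/structures/`.
#' @param fam_index integer used to build 4-character member ids.
#' @param cutoff site contact cutoff (default 4.5).
#' @return list: `members` (structure records), `manifest`, `index`
#'   (data.frame family_id/pdb_id/role/resolution), `ligands` (ligand
#'   spec rows), `het_weights`.
#' @export
make_family <- function(spec, dir = NULL, fam_index = 1L, cutoff = 4.5) {
  n <- spec$n_apo + spec$n_holo
  roles <- c(rep("apo", spec$n_apo), rep("holo", spec$n_holo))
  template <- make_ideal_chain(spec$sequence)
  members <- list()
  for (m in seq_len(n)) {
    pdb_id <- sprintf("%03d%s", fam_index, letters[m])
    pb <- perturb_backbone(template, spec$backbone_rmsd[m],
                           seed = (spec$seed %% 1999999L) * 1000L + m)
    s <- pb$structure
    for (rn in names(spec$chi1_settings))
      s <- set_chi1(s, as.integer(rn), spec$chi1_settings[[rn]][m])
    s$pdb_id <- pdb_id
    s$role <- roles[m]
    s$resolution <- spec$resolutions[m]
    if (roles[m] == "holo") {
      stopifnot(length(spec$ligand_resnos) >= 1L)
      s <- attach_ligand(s, spec$ligand_resnos, dist = spec$ligand_dist,
                         codes = spec$ligand_codes)
    }
    members[[pdb_id]] <- s
  }
  for (d in spec$decoys) {
    id <- names(members)[d$member]
    members[[id]] <- attach_decoy(members[[id]], d$code,
                                  position = d$position,
                                  site_resnos = spec$ligand_resnos)
  }
  members <- lapply(members, round_coords)
  manifest <- measure_family_truth(members, spec, cutoff = cutoff)
  index <- data.frame(family_id = spec$family_id,
                      pdb_id = names(members), role = roles,
                      resolution = spec$resolutions,
                      stringsAsFactors = FALSE)
  lig <- do.call(rbind, lapply(names(members)[roles == "holo"], function(id)
    data.frame(pdb_id = id, ligand_id = "L1",
               component_code = spec$ligand_codes,
               chain = "X",
               resno = 900L + seq_along(spec$ligand_codes) - 1L,
               mol_weight = spec$ligand_mass, stringsAsFactors = FALSE)))
  hw <- if (length(spec$decoys))
    unique(do.call(rbind, lapply(spec$decoys, function(d)
      data.frame(component_code = d$code, mol_weight = d$mw,
                 stringsAsFactors = FALSE))))
  else data.frame(component_code = character(), mol_weight = numeric())
  if (!is.null(dir)) {
    dir.create(file.path(dir, "structures"), recursive = TRUE,
               showWarnings = FALSE)
    for (id in names(members))
      write_structure(members[[id]],
                      file.path(dir, "structures", paste0(id, ".pdb")))
  }
  list(members = members, manifest = manifest, index = index,
       ligands = lig, het_weights = hw)
}

# Measure ground truth with direct, all-pairs arithmetic on the final
# (rounded) coordinates. Site and chi1-range truths are measured over the
# members that survive curation (decoy carriers and over-limit
# resolutions are planted to be rejected, so they never enter the
# analysed sets).
measure_family_truth <- function(members, spec, cutoff = 4.5) {
  roles <- vapply(members, `[[`, character(1), "role")
  decisions <- measure_expected_decisions(members, spec, cutoff)
  acc_ids <- decisions$pdb_id[decisions$accepted]
  holo_ids <- intersect(names(members)[roles == "holo"], acc_ids)
  # unified site: brute-force double loop over protein/ligand heavy atoms
  site <- integer()
  for (id in holo_ids) {
    at <- members[[id]]$atom
    prot <- at[at$type == "ATOM" & !is_hydrogen(at$element), , drop = FALSE]
    lig <- at[at$type == "HETATM" & at$resname %in% spec$ligand_codes, ,
              drop = FALSE]
    for (r in unique(prot$resno)) {
      P <- as.matrix(prot[prot$resno == r, c("x", "y", "z")])
      hit <- FALSE
      for (i in seq_len(nrow(P))) for (j in seq_len(nrow(lig))) {
        if (sum((P[i, ] - as.numeric(lig[j, c("x", "y", "z")]))^2) <=
            cutoff^2) { hit <- TRUE; break }
      }
      if (hit) site <- union(site, r)
    }
  }
  site <- sort(site)
  # pairwise CA RMSD
  ids <- names(members)
  ca_mat <- lapply(members, function(s) {
    at <- s$atom
    ca <- at[at$type == "ATOM" & at$name == "CA", , drop = FALSE]
    m <- as.matrix(ca[, c("x", "y", "z")])
    rownames(m) <- ca$resno
    m
  })
  pairs <- utils::combn(sort(ids), 2)
  pair_rmsd <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    shared <- intersect(rownames(ca_mat[[a]]), rownames(ca_mat[[b]]))
    cls <- paste(sort(c(substr(roles[a], 1, 1), substr(roles[b], 1, 1))),
                 collapse = "")
    cls <- c(aa = "AA", ah = "AH", hh = "HH")[tolower(cls)]
    data.frame(pdb_a = a, pdb_b = b, pairing_class = unname(cls),
               rmsd = kabsch(ca_mat[[a]][shared, ],
                             ca_mat[[b]][shared, ])$rmsd,
               stringsAsFactors = FALSE)
  }))
  # chi1 ranges for site residues, per set and stream
  chi_rows <- list()
  for (r in site) {
    s1 <- members[[1]]$atom
    resname <- s1$resname[s1$type == "ATOM" & s1$resno == r][1]
    if (!has_chi1(resname)) next
    obs <- list()
    for (id in intersect(ids, acc_ids)) {
      at <- members[[id]]$atom
      ra <- at[at$type == "ATOM" & at$resno == r, , drop = FALSE]
      ch <- chi1_of_residue(ra)
      if (!nrow(ch)) next
      ch$role <- roles[id]
      obs[[id]] <- ch
    }
    obs <- do.call(rbind, obs)
    for (w in unique(obs$which)) {
      o <- obs[obs$which == w, , drop = FALSE]
      chi_rows[[length(chi_rows) + 1L]] <- data.frame(
        resno = r, resname = resname, which = w,
        range_apo = chi1_range(o$chi1[o$role == "apo"]),
        range_holo = chi1_range(o$chi1[o$role == "holo"]),
        range_apo_holo = chi1_range(o$chi1), stringsAsFactors = FALSE)
    }
  }
  chi_ranges <- if (length(chi_rows)) do.call(rbind, chi_rows) else NULL
  list(family_id = spec$family_id, unified_site = site,
       pair_rmsd = pair_rmsd, chi1_ranges = chi_ranges,
       decisions = decisions)
}

# Expected curation decisions from the planted rules. The decoy's own
# contact test mirrors the apo filter: within the cutoff of any residue
# that any holo ligand touches.
measure_expected_decisions <- function(members, spec, cutoff = 4.5) {
  roles <- vapply(members, `[[`, character(1), "role")
  # contact residues of the (always accepted-geometry) holo ligands
  site <- integer()
  for (id in names(members)[roles == "holo"]) {
    at <- members[[id]]$atom
    prot <- at[at$type == "ATOM" & !is_hydrogen(at$element), ,
               drop = FALSE]
    lig <- at[at$type == "HETATM" & at$resname %in% spec$ligand_codes, ,
              drop = FALSE]
    if (!nrow(lig)) next
    for (r in unique(prot$resno)) {
      P <- as.matrix(prot[prot$resno == r, c("x", "y", "z")])
      d2 <- min_dist2_rows(P, as.matrix(lig[, c("x", "y", "z")]))
      if (any(d2 <= cutoff^2)) site <- union(site, r)
    }
  }
  do.call(rbind, lapply(names(members), function(id) {
    s <- members[[id]]
    reasons <- character()
    if (s$resolution > 2.5) reasons <- c(reasons, "RESOLUTION")
    at <- s$atom
    for (d in spec$decoys) {
      if (names(members)[d$member] != id) next
      if (d$mw > 100) reasons <- c(reasons, "HET_DISALLOWED")
      if (d$position == "near_site" && length(site)) {
        prot <- at[at$type == "ATOM" & at$resno %in% site, , drop = FALSE]
        dx <- as.matrix(at[at$type == "HETATM" & at$resname == d$code,
                           c("x", "y", "z"), drop = FALSE])
        d2 <- min_dist2_rows(dx, as.matrix(prot[, c("x", "y", "z")]))
        if (any(d2 <= cutoff^2))
          reasons <- c(reasons, "SITE_CONTAMINATION")
      }
    }
    data.frame(pdb_id = id, accepted = !length(reasons),
               reasons = paste(sort(unique(reasons)), collapse = ";"),
               stringsAsFactors = FALSE)
  }))
}

#' Generate a synthetic cohort of families
#'
#' Emits the full input bundle the pipeline consumes -- PDB files, family
#' index, ligand specifications, HET allow-list, HET weights -- plus a
#' ground-truth manifest. Defaults encode the study conditions the
#' analysis assumes: every family has at least two apo and two holo
#' members; apo and holo members draw their backbone displacement from
#' the same distribution (equal inherent flexibility); binding-site side
#' chains vary a few degrees within each state, and a fraction are pushed
#' to a rotamer well 120 degrees away in the holo state (induced shifts).
#'
#' @param dir output directory for the bundle.
#' @param n_families number of families (default 12).
#' @param seed integer seed.
#' @param n_members_range range of apo (and holo) member counts.
#' @param backbone_mean,backbone_sd lognormal-ish member displacement
#'   (Angstrom): |N(mean, sd)| clipped to [0.05, 1.5].
#' @param chi1_noise_sd within-state chi1 spread in degrees (default 8).
#' @param induced_fraction fraction of site residues whose holo chi1 is
#'   shifted by `induced_shift` degrees (default 0.3).
#' @param induced_shift induced rotamer displacement (default 120).
#' @param decoy_fraction fraction of families receiving one extra apo
#'   member that carries a disallowed decoy HET, and (independently) one
#'   extra apo with an allow-listed HET placed inside the site.
#' @param seq_length_range chain length range.
#' @return invisibly, the manifest list (also written as
#'   `manifest.json`).
#' @export
make_cohort <- function(dir, n_families = 12L, seed = 1L,
                        n_members_range = c(2L, 4L),
                        backbone_mean = 0.5, backbone_sd = 0.15,
                        chi1_noise_sd = 8, induced_fraction = 0.3,
                        induced_shift = 120, decoy_fraction = 0.25,
                        seq_length_range = c(28L, 34L)) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  aa_pool <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
               "K", "M", "F", "S", "T", "W", "Y", "V")
  pick <- function(v) v[sample.int(length(v), 1L)]   # safe for length 1
  manifest <- list(); index <- list(); ligands <- list(); hw <- list()
  for (f in seq_len(n_families)) {
    L <- pick(seq(seq_length_range[1], seq_length_range[2]))
    seqaa <- paste(sample(aa_pool, L, replace = TRUE), collapse = "")
    n_apo <- pick(seq(n_members_range[1], n_members_range[2]))
    n_holo <- pick(seq(n_members_range[1], n_members_range[2]))
    decoys <- list()
    extra_apo <- 0L
    if (stats::runif(1) < decoy_fraction) {
      extra_apo <- extra_apo + 1L
      decoys <- c(decoys, list(list(code = "DCY", mw = 150,
                                    position = "remote",
                                    member = n_apo + extra_apo)))
    }
    if (stats::runif(1) < decoy_fraction) {
      extra_apo <- extra_apo + 1L
      decoys <- c(decoys, list(list(code = "GOL", mw = 92,
                                    position = "near_site",
                                    member = n_apo + extra_apo)))
    }
    n_apo_total <- n_apo + extra_apo
    n <- n_apo_total + n_holo
    bb <- pmin(pmax(abs(stats::rnorm(n, backbone_mean, backbone_sd)),
                    0.05), 1.5)
    lig_res <- sort(sample(seq(8L, L - 8L), 4))
    chi1_settings <- list()
    for (r in lig_res) {
      aa1 <- substr(seqaa, r, r)
      if (aa1 %in% c("G", "P", "A")) next
      base <- sample(c(-60, 60, 180), 1)
      shift <- if (stats::runif(1) < induced_fraction) induced_shift else 0
      ang <- c(base + stats::rnorm(n_apo_total, sd = chi1_noise_sd),
               base + shift + stats::rnorm(n_holo, sd = chi1_noise_sd))
      chi1_settings[[as.character(r)]] <- ((ang + 180) %% 360) - 180
    }
    spec <- family_fixture_spec(
      family_id = sprintf("F%03d", f), sequence = seqaa,
      n_apo = n_apo_total, n_holo = n_holo, backbone_rmsd = bb,
      chi1_settings = chi1_settings, ligand_resnos = lig_res,
      ligand_mass = stats::runif(1, 150, 600), decoys = decoys,
      seed = seed + f)
    fam <- make_family(spec, dir = dir, fam_index = f)
    manifest[[spec$family_id]] <- fam$manifest
    index[[f]] <- fam$index
    ligands[[f]] <- fam$ligands
    hw[[f]] <- fam$het_weights
  }
  utils::write.csv(do.call(rbind, index), file.path(dir, "index.csv"),
                   row.names = FALSE)
  utils::write.csv(do.call(rbind, ligands), file.path(dir, "ligands.csv"),
                   row.names = FALSE)
  hw <- unique(do.call(rbind, hw))
  utils::write.csv(hw, file.path(dir, "het_weights.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(component_code = c("GOL", "EDO", "SO4")),
                   file.path(dir, "allowlist.csv"), row.names = FALSE)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
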