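# Residues deposited as HETATM but treated as part of the protein chain
# (selenomethionine and friends). They enter backbone RMSD but are excluded
# from chi1 analysis.
MODIFIED_AA <- c("MSE", "CSO", "SEP", "TPO", "PTR", "MLY", "HYP")

WATER_CODES <- c("HOH", "DOD", "WAT")

# Standard atomic weights (g/mol) for molecular-weight computation when a
# HET's weight is not supplied in metadata.
ATOMIC_WEIGHTS <- c(
  H = 1.008, D = 2.014, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
  P = 30.974, F = 18.998, CL = 35.45, BR = 79.904, I = 126.904,
  "NA" = 22.990, K = 39.098, MG = 24.305, CA = 40.078, MN = 54.938,
  FE = 55.845, CO = 58.933, NI = 58.693, CU = 63.546, ZN = 65.38,
  SE = 78.971, B = 10.81
)

#' Construct a structure record
#'
#' A `structure_record` holds one crystal structure as a flat atom table plus
#' metadata: the 4-character PDB id, the reported resolution, the apo/holo
#' role, and (after ligand extraction) the assembled biologically relevant
#' ligand.
#'
#' @param atom data.frame with columns `type` (ATOM/HETATM), `serial`,
#'   `name`, `altloc`, `resname`, `chain`, `resno`, `icode`, `x`, `y`, `z`,
#'   `occ`, `b`, `element`.
#' @param pdb_id 4-character identifier.
#' @param resolution crystallographic resolution in Angstrom (> 0).
#' @param role `"apo"` or `"holo"`.
#' @param ligand optional ligand instance (see [extract_ligand()]).
#' @return object of class `structure_record`.
#' @export
structure_record <- function(atom, pdb_id, resolution, role,
                             ligand = NULL) {
  stopifnot(is.data.frame(atom))
  role <- match.arg(role, c("apo", "holo"))
  if (!is.finite(resolution) || resolution <= 0)
    stop("resolution must be a positive number for ", pdb_id)
  atom$altloc[is.na(atom$altloc)] <- ""
  atom$icode[is.na(atom$icode)] <- ""
  atom$chain[is.na(atom$chain)] <- " "
  structure(
    list(atom = atom, pdb_id = pdb_id, resolution = resolution,
         role = role, ligand = ligand),
    class = "structure_record")
}

#' @export
print.structure_record <- function(x, ...) {
  cat(sprintf("<structure_record %s> role=%s resolution=%.2f A\n",
              x$pdb_id, x$role, x$resolution))
  cat(sprintf("  %d atoms, %d protein residues, %d HET groups%s\n",
              nrow(x$atom), nrow(unique(protein_atoms(x)[
                c("chain", "resno", "icode")])),
              nrow(het_records(x)),
              if (!is.null(x$ligand))
                paste0(", ligand ", paste(x$ligand$component_codes,
                                          collapse = "+")) else ""))
  invisible(x)
}

is_hydrogen <- function(element) toupper(element) %in% c("H", "D")

is_water <- function(resname) toupper(resname) %in% WATER_CODES

# Protein atoms: ATOM records plus modified amino acids deposited as HETATM.
protein_atoms <- function(s) {
  at <- s$atom
  at[at$type == "ATOM" | at$resname %in% MODIFIED_AA, , drop = FALSE]
}

# Non-protein HETATM rows (waters included unless stripped).
het_atoms <- function(s) {
  at <- s$atom
  at[at$type == "HETATM" & !(at$resname %in% MODIFIED_AA), , drop = FALSE]
}

res_key <- function(chain, resno, icode) {
  icode[is.na(icode)] <- ""
  paste(chain, resno, icode, sep = "|")
}

#' Parse a PDB-format coordinate file
#'
#' Reads the fixed-column PDB dialect (through `bio3d::read.pdb`, keeping
#' every alternate location), validates coordinate fields line by line, and
#' returns a [structure_record()]. Residue identity is the author-assigned
#' (chain, residue number, insertion code) triple. When the file holds
#' multiple MODELs only the first is used.
#'
#' @param path path to a PDB file, or a character vector of PDB lines.
#' @param role `"apo"` or `"holo"`.
#' @param resolution resolution in Angstrom; if `NULL` it is read from the
#'   `REMARK   2 RESOLUTION.` header line. Resolution is a curation filter,
#'   so a structure with no resolution from either source is an error.
#' @param pdb_id identifier; defaults to the file's base name.
#' @return a `structure_record`.
#' @export
parse_structure <- function(path, role, resolution = NULL, pdb_id = NULL) {
  if (length(path) == 1L && !grepl("\n", path) && file.exists(path)) {
    lines <- readLines(path, warn = FALSE)
    if (is.null(pdb_id))
      pdb_id <- sub("\\.(pdb|ent)$", "", basename(path))
  } else {
    lines <- unlist(strsplit(path, "\n", fixed = TRUE))
    if (is.null(pdb_id)) pdb_id <- "xxxx"
  }
  # keep only the first MODEL if the file has several
  mstart <- grep("^MODEL ", lines)
  if (length(mstart) >= 1L) {
    mend <- grep("^ENDMDL", lines)
    if (length(mend) >= 1L)
      lines <- lines[-(seq((mend[1] + 1L), length(lines)))]
  }
  coord <- grep("^(ATOM  |HETATM)", lines)
  if (!length(coord))
    stop("no ATOM/HETATM records in ", pdb_id)
  for (i in coord) {
    ln <- lines[i]
    if (nchar(ln) < 54 ||
        anyNA(suppressWarnings(as.numeric(c(substr(ln, 31, 38),
                                            substr(ln, 39, 46),
                                            substr(ln, 47, 54))))))
      stop("malformed coordinate line ", i, " in ", pdb_id, ": ", ln)
  }
  if (is.null(resolution)) {
    rl <- grep("^REMARK   2 RESOLUTION", lines, value = TRUE)
    if (length(rl)) {
      resolution <- suppressWarnings(
        as.numeric(sub(".*RESOLUTION\\.\\s*([0-9.]+).*", "\\1", rl[1])))
    }
  }
  if (is.null(resolution) || !length(resolution) || is.na(resolution))
    stop("no resolution available for ", pdb_id,
         " (REMARK 2 absent and none supplied)")

  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf))
  writeLines(lines, tf)
  pdb <- quiet(bio3d::read.pdb(tf, rm.alt = FALSE, verbose = FALSE,
                               multi = FALSE))
  a <- pdb$atom
  atom <- data.frame(
    type = a$type, serial = a$eleno, name = a$elety,
    altloc = ifelse(is.na(a$alt), "", a$alt),
    resname = a$resid, chain = ifelse(is.na(a$chain), " ", a$chain),
    resno = a$resno, icode = ifelse(is.na(a$insert), "", a$insert),
    x = a$x, y = a$y, z = a$z,
    occ = ifelse(is.na(a$o), 1, a$o), b = ifelse(is.na(a$b), 0, a$b),
    element = guess_element(a$elesy, a$elety),
    stringsAsFactors = FALSE)
  structure_record(atom, pdb_id = pdb_id, resolution = resolution,
                   role = role)
}

quiet <- function(expr) {
  out <- NULL
  invisible(utils::capture.output(out <- suppressWarnings(expr)))
  out
}

# Element from the element column when present, else from the atom name
# (leading digits stripped, first character).
guess_element <- function(elesy, name) {
  el <- toupper(ifelse(is.na(elesy) | elesy == "", NA, elesy))
  miss <- is.na(el)
  if (any(miss)) {
    nm <- gsub("[0-9']", "", toupper(name[miss]))
    two <- substr(nm, 1, 2)
    el[miss] <- ifelse(two %in% c("CL", "BR", "FE", "ZN", "MG", "MN", "SE",
                                  "NA", "CU", "NI", "CO"),
                       two, substr(nm, 1, 1))
  }
  el
}

#' Write a structure record to PDB format
#'
#' Emits a `REMARK   2` resolution header followed by the atom table in
#' fixed-column PDB format (via `bio3d::write.pdb`). Ligand atoms, if the
#' record carries an extracted ligand, are appended as HETATM records so the
#' file round-trips.
#'
#' @param s a `structure_record`.
#' @param file output path.
#' @export
write_structure <- function(s, file) {
  at <- s$atom
  if (!is.null(s$ligand)) at <- rbind(at, s$ligand$atoms)
  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf))
  quiet(bio3d::write.pdb(
    pdb = NULL, file = tf,
    type = at$type, eleno = at$serial, elety = at$name,
    alt = ifelse(at$altloc == "", NA, at$altloc),
    resid = at$resname, chain = ifelse(at$chain == " ", "", at$chain),
    resno = at$resno, insert = ifelse(at$icode == "", NA, at$icode),
    xyz = as.numeric(t(as.matrix(at[, c("x", "y", "z")]))),
    o = at$occ, b = at$b, elesy = at$element))
  body <- readLines(tf, warn = FALSE)
  writeLines(c(sprintf("REMARK   2 RESOLUTION.    %.2f ANGSTROMS.",
                       s$resolution), body), file)
  invisible(file)
}

#' Resolve alternate locations by occupancy
#'
#' For every atom modelled in several alternate locations, keep the copy
#' with the strictly highest occupancy; on a tie, keep the first listed.
#' Idempotent; a structure without altlocs is returned unchanged.
#'
#' @param s a `structure_record`.
#' @return the record with exactly one copy of each atom name per residue.
#' @export
resolve_altlocs <- function(s) {
  at <- s$atom
  key <- paste(res_key(at$chain, at$resno, at$icode), at$resname, at$name,
               sep = "|")
  keep <- unlist(lapply(split(seq_len(nrow(at)), key), function(idx) {
    if (length(idx) == 1L) return(idx)
    idx <- idx[order(-at$occ[idx], idx)]  # highest occ, tie -> file order
    idx[1]
  }), use.names = FALSE)
  at <- at[sort(keep), , drop = FALSE]
  at$altloc <- ""
  s$atom <- at
  rownames(s$atom) <- NULL
  s
}

#' Tabulate HET groups of a structure
#'
#' One row per HET instance (component code + chain + residue number +
#' insertion code), with heavy-atom count and a molecular weight either
#' looked up in the supplied metadata table or computed from atomic
#' composition.
#'
#' @param s a `structure_record`.
#' @param mw_table optional data.frame with columns `component_code`,
#'   `mol_weight`.
#' @return data.frame with columns `component_code`, `chain`, `resno`,
#'   `icode`, `n_atoms`, `mol_weight`.
#' @export
het_records <- function(s, mw_table = NULL) {
  ha <- het_atoms(s)
  if (!nrow(ha))
    return(data.frame(component_code = character(), chain = character(),
                      resno = integer(), icode = character(),
                      n_atoms = integer(), mol_weight = numeric()))
  key <- paste(ha$resname, res_key(ha$chain, ha$resno, ha$icode), sep = "|")
  idx <- split(seq_len(nrow(ha)), key)
  recs <- do.call(rbind, lapply(idx, function(i) {
    data.frame(component_code = ha$resname[i[1]], chain = ha$chain[i[1]],
               resno = ha$resno[i[1]], icode = ha$icode[i[1]],
               n_atoms = length(i),
               mol_weight = het_weight(ha$resname[i[1]], ha$element[i],
                                       mw_table),
               stringsAsFactors = FALSE)
  }))
  rownames(recs) <- NULL
  recs[order(recs$chain, recs$resno, recs$icode, recs$component_code), ,
       drop = FALSE]
}

het_weight <- function(code, elements, mw_table) {
  if (!is.null(mw_table)) {
    hit <- match(code, mw_table$component_code)
    if (!is.na(hit)) return(mw_table$mol_weight[hit])
  }
  w <- ATOMIC_WEIGHTS[toupper(elements)]
  if (anyNA(w))
    stop("no atomic weight for element(s) ",
         paste(unique(elements[is.na(w)]), collapse = ", "),
         " in HET ", code)
  sum(w)
}

#' Extract the biologically relevant ligand of a holo structure
#'
#' The ligand of a holo structure may span several HET groups (a multi-HET
#' ligand is one molecule). The selector names the component codes and the
#' chain/residue numbers of each part; every matching HETATM row is moved
#' out of the atom table into the record's `ligand` field as a heavy-atom
#' set (hydrogens discarded).
#'
#' @param s a `structure_record` with role `"holo"`.
#' @param spec data.frame with one row per HET component of the ligand:
#'   columns `component_code`, `chain`, `resno` and a shared `mol_weight`.
#' @return the record with `ligand` populated and ligand atoms removed from
#'   the chains.
#' @export
extract_ligand <- function(s, spec) {
  stopifnot(is.data.frame(spec), nrow(spec) >= 1L)
  at <- s$atom
  sel <- rep(FALSE, nrow(at))
  for (i in seq_len(nrow(spec))) {
    hit <- at$type == "HETATM" & at$resname == spec$component_code[i] &
      at$chain == spec$chain[i] & at$resno == spec$resno[i]
    if (!any(hit))
      stop("ligand selector matches nothing in ", s$pdb_id, ": ",
           spec$component_code[i], " ", spec$chain[i], " ", spec$resno[i])
    sel <- sel | hit
  }
  lig_at <- at[sel & !is_hydrogen(at$element), , drop = FALSE]
  if (!nrow(lig_at)) stop("ligand of ", s$pdb_id, " has no heavy atoms")
  s$ligand <- list(component_codes = unique(spec$component_code),
                   atoms = lig_at,
                   mol_weight = spec$mol_weight[1])
  s$atom <- at[!sel, , drop = FALSE]
  rownames(s$atom) <- NULL
  s
}

#' Prepare a structure for analysis
#'
#' Removes all hydrogens (deuterium included) and all waters, and for a holo
#' structure with a ligand selector extracts the ligand into the `ligand`
#' field. Coordinates of retained atoms are untouched. Non-water HET groups
#' other than the ligand stay in the record; they are needed by the apo
#' contamination filter and are excluded again where a computation demands
#' it (SASA, RMSD, chi1 all operate on protein atoms only).
#'
#' @param s a `structure_record`.
#' @param ligand_spec optional ligand selector (see [extract_ligand()]);
#'   required when `s$role == "holo"` and the ligand has not been extracted.
#' @return the stripped record.
#' @export
strip_for_analysis <- function(s, ligand_spec = NULL) {
  at <- s$atom
  at <- at[!is_hydrogen(at$element) & !is_water(at$resname), , drop = FALSE]
  rownames(at) <- NULL
  s$atom <- at
  if (!is.null(ligand_spec) && is.null(s$ligand))
    s <- extract_ligand(s, ligand_spec)
  s
}

#' Chain sequences of a structure
#'
#' One-letter sequence per chain, read off the CA atoms of protein residues
#' in (resno, icode) order. Modified residues translate through their parent
#' amino acid where known (e.g. MSE to M); unknown residues become X.
#'
#' @param s a `structure_record`.
#' @return named character vector, one sequence per chain.
#' @export
chain_sequences <- function(s) {
  pa <- protein_atoms(s)
  ca <- pa[pa$name == "CA", , drop = FALSE]
  ca <- ca[!duplicated(res_key(ca$chain, ca$resno, ca$icode)), , drop = FALSE]
  if (!nrow(ca)) return(character())
  vapply(split(seq_len(nrow(ca)), ca$chain), function(i) {
    i <- i[order(ca$resno[i], ca$icode[i])]
    paste(aa_one(ca$resname[i]), collapse = "")
  }, character(1))
}

AA3TO1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
            GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
            LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
            SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V",
            MSE = "M", CSO = "C", SEP = "S", TPO = "T", PTR = "Y",
            MLY = "K", HYP = "P")

aa_one <- function(resname) {
  out <- AA3TO1[toupper(resname)]
  out[is.na(out)] <- "X"
  unname(out)
}

# Residue table of a structure: one row per protein residue in chain order.
residue_table <- function(s) {
  pa <- protein_atoms(s)
  key <- res_key(pa$chain, pa$resno, pa$icode)
  first <- !duplicated(key)
  out <- pa[first, c("chain", "resno", "icode", "resname"), drop = FALSE]
  out <- out[order(out$chain, out$resno, out$icode), , drop = FALSE]
  rownames(out) <- NULL
  out
}
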