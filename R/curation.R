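# Alignment parameters for reference-numbering maps (Needleman-Wunsch,
# Needle-like defaults). Families are 100 %-identical by construction, so
# the scores mostly break chain-assignment ties; the values are recorded in
# the run config for reproducibility.
ALIGN_PARAMS <- list(match = 1, mismatch = -1, gap_open = 10,
                     gap_extend = 0.5)

#' Cluster structures into sequence-identical families
#'
#' Two structures share a family iff their chain sequence sets are
#' identical in both directions (exact string equality of the sorted
#' multiset of chain sequences). An optional merge pass joins families
#' whose sequences differ only by extension at the termini, emulating the
#' follow-up clustering used to catch simple N/C-terminal additions;
#' families differing in core sequence are never merged.
#'
#' @param structures list of `structure_record`s.
#' @param merge_terminal_extensions run the merge pass (default TRUE).
#' @return list of `protein_family` skeletons (members + family_id), in
#'   deterministic order.
#' @export
cluster_families <- function(structures, merge_terminal_extensions = TRUE) {
  if (!length(structures)) return(list())
  names(structures) <- vapply(structures, `[[`, character(1), "pdb_id")
  structures <- structures[order(names(structures))]
  sig <- vapply(structures, function(s)
    paste(sort(chain_sequences(s)), collapse = "/"), character(1))
  groups <- split(names(structures), sig)
  groups <- groups[order(vapply(groups, min, character(1)))]

  if (merge_terminal_extensions && length(groups) > 1L) {
    sigs <- names(groups)
    parent <- seq_along(groups)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (i in seq_along(sigs)) for (j in seq_along(sigs)) {
      if (i >= j) next
      if (terminal_extension(sigs[i], sigs[j]))
        parent[find(j)] <- find(i)
    }
    root <- vapply(seq_along(groups), find, integer(1))
    groups <- lapply(split(seq_along(groups), root),
                     function(idx) unlist(groups[idx], use.names = FALSE))
    groups <- groups[order(vapply(groups, min, character(1)))]
  }

  lapply(seq_along(groups), function(k) {
    ids <- sort(groups[[k]])
    structure(list(family_id = sprintf("F%03d", k),
                   members = structures[ids],
                   numbering = NULL, reference = NULL,
                   ref_sequences = NULL, unified_site = NULL,
                   rejected = character()),
              class = "protein_family")
  })
}

# TRUE when the two chain-sequence signatures (sorted, "/"-joined) match
# chain for chain with one sequence equal to the other extended only at the
# termini (substring containment).
terminal_extension <- function(sig_a, sig_b) {
  a <- strsplit(sig_a, "/", fixed = TRUE)[[1]]
  b <- strsplit(sig_b, "/", fixed = TRUE)[[1]]
  if (length(a) != length(b)) return(FALSE)
  all(mapply(function(x, y) {
    grepl(x, y, fixed = TRUE) || grepl(y, x, fixed = TRUE)
  }, a, b))
}

#' @export
print.protein_family <- function(x, ...) {
  roles <- vapply(x$members, `[[`, character(1), "role")
  cat(sprintf("<protein_family %s> %d members (%d apo, %d holo)%s\n",
              x$family_id, length(x$members), sum(roles == "apo"),
              sum(roles == "holo"),
              if (!is.null(x$unified_site))
                sprintf(", unified site %d residues",
                        nrow(x$unified_site)) else ""))
  invisible(x)
}

aa_submat <- function() {
  ab <- c(LETTERS)
  m <- matrix(ALIGN_PARAMS$mismatch, 26, 26, dimnames = list(ab, ab))
  diag(m) <- ALIGN_PARAMS$match
  m
}

align_score <- function(a, b, mat) {
  Biostrings::pairwiseAlignment(
    a, b, type = "global", substitutionMatrix = mat,
    gapOpening = ALIGN_PARAMS$gap_open,
    gapExtension = ALIGN_PARAMS$gap_extend, scoreOnly = TRUE)
}

# Global alignment of member sequence to reference sequence; returns
# data.frame(member_pos, ref_pos) for matched columns, or NULL when any
# aligned pair mismatches (ambiguous mapping).
align_map <- function(member_seq, ref_seq, mat) {
  pa <- Biostrings::pairwiseAlignment(
    member_seq, ref_seq, type = "global", substitutionMatrix = mat,
    gapOpening = ALIGN_PARAMS$gap_open,
    gapExtension = ALIGN_PARAMS$gap_extend)
  p <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  ip <- cumsum(p != "-"); is <- cumsum(s != "-")
  both <- p != "-" & s != "-"
  if (any(p[both] != s[both])) return(NULL)   # residue-name mismatch
  data.frame(member_pos = ip[both], ref_pos = is[both])
}

#' Assign a shared reference numbering to a family
#'
#' Chooses a reference structure (best resolution, ties broken by
#' lexicographically smallest PDB id) and maps every member chain onto a
#' reference chain by global alignment. The reference index of a residue is
#' its 1-based position in the reference chain. Member chains are assigned
#' to reference chains by best alignment score, ties broken by chain-id
#' order. A member whose mapping is ambiguous -- an aligned residue-name
#' mismatch, or two member chains claiming overlapping stretches of the
#' same reference chain -- is rejected with reason `RENUMBER_FAIL` and
#' removed from the family.
#'
#' @param fam a `protein_family` skeleton from [cluster_families()].
#' @return the family with `reference`, `ref_sequences` and per-member
#'   `numbering` data.frames (chain, resno, icode, ref_chain, ref_index);
#'   rejected members listed in `fam$rejected`.
#' @export
build_reference_numbering <- function(fam) {
  stopifnot(length(fam$members) >= 1L)
  res <- vapply(fam$members, `[[`, numeric(1), "resolution")
  ord <- order(res, names(fam$members))
  ref_id <- names(fam$members)[ord[1]]
  ref <- fam$members[[ref_id]]
  ref_seqs <- chain_sequences(ref)
  mat <- aa_submat()
  numbering <- list(); rejected <- character()

  for (id in names(fam$members)) {
    s <- fam$members[[id]]
    seqs <- chain_sequences(s)
    rt <- residue_table(s)
    maps <- list(); claimed <- list(); ok <- TRUE
    for (ch in names(seqs)) {
      scores <- vapply(names(ref_seqs), function(rc)
        align_score(seqs[[ch]], ref_seqs[[rc]], mat), numeric(1))
      best <- names(ref_seqs)[order(-scores, names(ref_seqs))][1]
      am <- align_map(seqs[[ch]], ref_seqs[[best]], mat)
      if (is.null(am)) { ok <- FALSE; break }
      prev <- claimed[[best]]
      if (!is.null(prev) && length(intersect(prev, am$ref_pos))) {
        ok <- FALSE; break   # two chains overlap on one reference chain
      }
      claimed[[best]] <- c(prev, am$ref_pos)
      chain_rt <- rt[rt$chain == ch, , drop = FALSE]
      maps[[ch]] <- data.frame(
        chain = ch,
        resno = chain_rt$resno[am$member_pos],
        icode = chain_rt$icode[am$member_pos],
        ref_chain = best, ref_index = am$ref_pos,
        stringsAsFactors = FALSE)
    }
    if (!ok) { rejected <- c(rejected, id); next }
    numbering[[id]] <- do.call(rbind, maps)
    rownames(numbering[[id]]) <- NULL
  }
  fam$members <- fam$members[setdiff(names(fam$members), rejected)]
  fam$numbering <- numbering
  fam$reference <- ref_id
  fam$ref_sequences <- ref_seqs
  fam$rejected <- c(fam$rejected,
                    stats::setNames(rep("RENUMBER_FAIL", length(rejected)),
                                    rejected))
  fam
}

curation_decision <- function(pdb_id, reasons) {
  data.frame(pdb_id = pdb_id, accepted = !length(reasons),
             reasons = paste(reasons, collapse = ";"),
             stringsAsFactors = FALSE)
}

#' Validate a holo structure
#'
#' A holo structure is accepted when it is resolved at the resolution
#' cutoff or better, carries exactly one valid ligand, and no additional
#' non-water molecule sits in its binding site (any non-water, non-ligand
#' HET heavy atom within the contact cutoff of a ligand heavy atom).
#'
#' @param s a stripped, altloc-resolved `structure_record` (role holo).
#'   Its ligand must already be extracted unless `ligspec` is given.
#' @param ligspec ligand specification rows for this structure: columns
#'   `ligand_id`, `component_code`, `chain`, `resno`, `mol_weight`. More
#'   than one distinct `ligand_id` means multiple valid ligands.
#' @param resolution_cutoff maximum resolution in Angstrom (default 2.5).
#' @param cutoff contact distance in Angstrom (default 4.5, inclusive).
#' @return one-row data.frame: `pdb_id`, `accepted`, `reasons`.
#' @export
validate_holo <- function(s, ligspec = NULL, resolution_cutoff = 2.5,
                          cutoff = 4.5) {
  reasons <- character()
  if (s$resolution > resolution_cutoff) reasons <- c(reasons, "RESOLUTION")
  if (is.null(s$ligand)) {
    if (is.null(ligspec) || !nrow(ligspec))
      stop("holo structure ", s$pdb_id, " has no ligand specification")
    if (length(unique(ligspec$ligand_id)) > 1L) {
      reasons <- c(reasons, "MULTI_LIGAND")
      return(curation_decision(s$pdb_id, reasons))
    }
    s <- extract_ligand(s, ligspec)
  }
  lig_xyz <- as.matrix(s$ligand$atoms[, c("x", "y", "z")])
  ha <- het_atoms(s)
  ha <- ha[!is_water(ha$resname) & !is_hydrogen(ha$element), , drop = FALSE]
  if (nrow(ha)) {
    d2 <- min_dist2_rows(as.matrix(ha[, c("x", "y", "z")]), lig_xyz)
    if (any(d2 <= cutoff^2)) reasons <- c(reasons, "SITE_CONTAMINATION")
  }
  curation_decision(s$pdb_id, reasons)
}

#' Validate an apo structure against its family's unified site
#'
#' Every non-water HET must have molecular weight at or below the cutoff or
#' be on the allow-list, else the structure is rejected with
#' `HET_DISALLOWED`. Any non-water HET heavy atom within the contact cutoff
#' (inclusive) of a heavy atom of any unified-site residue resolvable in
#' this structure rejects it with `SITE_CONTAMINATION`. Waters are always
#' permitted.
#'
#' @param s a stripped, altloc-resolved `structure_record` (role apo).
#' @param fam the `protein_family` (numbered) the structure belongs to;
#'   its unified site must be computed already (ordering contract: holo
#'   filtering, then sites, then apo filtering).
#' @param allowlist character vector of permissible HET component codes.
#' @param mw_cutoff molecular weight cutoff in g/mol (default 100).
#' @param cutoff contact distance in Angstrom (default 4.5, inclusive).
#' @param mw_table optional component-code to weight lookup.
#' @return one-row data.frame: `pdb_id`, `accepted`, `reasons`.
#' @export
validate_apo <- function(s, fam, allowlist = character(),
                         mw_cutoff = 100, cutoff = 4.5, mw_table = NULL) {
  if (is.null(fam$unified_site))
    stop("unified site of family ", fam$family_id,
         " not computed before apo validation")
  reasons <- character()
  hets <- het_records(s, mw_table = mw_table)
  hets <- hets[!is_water(hets$component_code), , drop = FALSE]
  if (nrow(hets)) {
    bad <- !(hets$mol_weight <= mw_cutoff |
               hets$component_code %in% allowlist)
    if (any(bad)) reasons <- c(reasons, "HET_DISALLOWED")
    site_xyz <- site_atom_coords(s, fam)
    if (nrow(site_xyz)) {
      ha <- het_atoms(s)
      ha <- ha[!is_water(ha$resname) & !is_hydrogen(ha$element), ,
               drop = FALSE]
      d2 <- min_dist2_rows(as.matrix(ha[, c("x", "y", "z")]), site_xyz)
      if (any(d2 <= cutoff^2)) reasons <- c(reasons, "SITE_CONTAMINATION")
    }
  }
  curation_decision(s$pdb_id, unique(reasons))
}

# Heavy-atom coordinates of the unified-site residues resolvable in s.
site_atom_coords <- function(s, fam) {
  nmap <- fam$numbering[[s$pdb_id]]
  if (is.null(nmap)) stop("structure ", s$pdb_id, " not numbered in family")
  us <- fam$unified_site
  hit <- merge(nmap, us[, c("ref_chain", "ref_index")],
               by = c("ref_chain", "ref_index"))
  pa <- protein_atoms(s)
  pa <- pa[!is_hydrogen(pa$element), , drop = FALSE]
  keep <- res_key(pa$chain, pa$resno, pa$icode) %in%
    res_key(hit$chain, hit$resno, hit$icode)
  as.matrix(pa[keep, c("x", "y", "z"), drop = FALSE])
}

# For each row of A, squared distance to the nearest row of B.
min_dist2_rows <- function(A, B) {
  if (!nrow(A) || !nrow(B)) return(numeric(0))
  d2 <- outer(rowSums(A^2), rep(1, nrow(B))) +
    outer(rep(1, nrow(A)), rowSums(B^2)) - 2 * tcrossprod(A, B)
  apply(pmax(d2, 0), 1, min)
}

#' Keep only families with at least two apo and two holo members
#'
#' @param families list of `protein_family`.
#' @return the subset meeting the inclusion rule.
#' @export
filter_min_members <- function(families, min_apo = 2L, min_holo = 2L) {
  Filter(function(f) {
    roles <- vapply(f$members, `[[`, character(1), "role")
    sum(roles == "apo") >= min_apo && sum(roles == "holo") >= min_holo
  }, families)
}
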