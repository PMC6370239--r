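#' Binding-site residues of one holo structure
#'
#' A protein residue belongs to the binding site iff the minimum Euclidean
#' distance between any of its heavy atoms and any ligand heavy atom is at
#' or below the cutoff (inclusive boundary). Hydrogens are never considered
#' on either side.
#'
#' The scan prefilters candidate atoms with a bounding box around the
#' ligand before the exact distance test; the result is identical to the
#' all-pairs double loop (property-tested).
#'
#' @param s a stripped, altloc-resolved holo `structure_record`.
#' @param lig ligand instance (defaults to `s$ligand`).
#' @param cutoff contact distance in Angstrom (default 4.5).
#' @return data.frame of site residues: `chain`, `resno`, `icode`,
#'   `resname`.
#' @export
site_residues <- function(s, lig = s$ligand, cutoff = 4.5) {
  if (is.null(lig) || !nrow(lig$atoms)) stop("empty ligand for ", s$pdb_id)
  lx <- as.matrix(lig$atoms[!is_hydrogen(lig$atoms$element),
                            c("x", "y", "z"), drop = FALSE])
  if (!nrow(lx)) stop("ligand of ", s$pdb_id, " has no heavy atoms")
  pa <- protein_atoms(s)
  pa <- pa[!is_hydrogen(pa$element), , drop = FALSE]
  if (!nrow(pa)) stop("no protein heavy atoms in ", s$pdb_id)
  px <- as.matrix(pa[, c("x", "y", "z")])
  # bounding-box prefilter (conservative; exact test below decides)
  lo <- apply(lx, 2, min) - cutoff; hi <- apply(lx, 2, max) + cutoff
  cand <- px[, 1] >= lo[1] & px[, 1] <= hi[1] &
    px[, 2] >= lo[2] & px[, 2] <= hi[2] &
    px[, 3] >= lo[3] & px[, 3] <= hi[3]
  contact <- logical(nrow(pa))
  if (any(cand)) {
    d2 <- min_dist2_rows(px[cand, , drop = FALSE], lx)
    contact[which(cand)[d2 <= cutoff^2]] <- TRUE
  }
  res <- pa[contact, c("chain", "resno", "icode", "resname"), drop = FALSE]
  res <- res[!duplicated(res_key(res$chain, res$resno, res$icode)), ,
             drop = FALSE]
  res <- res[order(res$chain, res$resno, res$icode), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Unified binding site of a family
#'
#' Union, over all holo members, of the residues within the cutoff of that
#' member's ligand, expressed in the family's reference numbering. Also
#' records which unified-site residues are resolvable in each member
#' (apo members included), for downstream per-structure extraction.
#'
#' @param fam a numbered `protein_family` whose holo members carry
#'   extracted ligands.
#' @param cutoff contact distance in Angstrom (default 4.5).
#' @return the family with `unified_site` set: data.frame `ref_chain`,
#'   `ref_index`, `resname` (sorted), plus attribute `per_structure`
#'   (named list of logical presence vectors) and `size`.
#' @export
unify_sites <- function(fam, cutoff = 4.5) {
  holo_ids <- names(fam$members)[
    vapply(fam$members, `[[`, character(1), "role") == "holo"]
  if (!length(holo_ids))
    stop("family ", fam$family_id, " has no holo members to define a site")
  ids <- list()
  for (id in holo_ids) {
    s <- fam$members[[id]]
    sr <- site_residues(s, cutoff = cutoff)
    nmap <- fam$numbering[[id]]
    hit <- match(res_key(sr$chain, sr$resno, sr$icode),
                 res_key(nmap$chain, nmap$resno, nmap$icode))
    keep <- !is.na(hit)
    ids[[id]] <- data.frame(ref_chain = nmap$ref_chain[hit[keep]],
                            ref_index = nmap$ref_index[hit[keep]],
                            resname = sr$resname[keep],
                            stringsAsFactors = FALSE)
  }
  us <- do.call(rbind, ids)
  us <- us[!duplicated(paste(us$ref_chain, us$ref_index)), , drop = FALSE]
  us <- us[order(us$ref_chain, us$ref_index), , drop = FALSE]
  rownames(us) <- NULL
  per_structure <- lapply(fam$members, function(s) {
    nmap <- fam$numbering[[s$pdb_id]]
    paste(us$ref_chain, us$ref_index) %in%
      paste(nmap$ref_chain, nmap$ref_index)
  })
  attr(us, "per_structure") <- per_structure
  attr(us, "size") <- nrow(us)
  fam$unified_site <- us
  fam
}
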