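# NACCESS-style (Chothia) van der Waals radii in Angstrom, by element.
# Values live here so the set can be tightened against an external SASA
# tool if desired.
VDW_RADII <- c(C = 1.87, N = 1.65, O = 1.40, S = 1.85, P = 1.80,
               SE = 1.90, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98)

# Deterministic golden-spiral point set on the unit sphere (no RNG, so
# SASA values are exactly reproducible for a fixed point count).
golden_spiral <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Shrake-Rupley solvent accessible surface area
#'
#' Per-atom accessible area from test points distributed on each atom's
#' expanded sphere (van der Waals radius + probe), counting points not
#' buried inside any neighbouring expanded sphere. Operates on protein
#' heavy atoms only: hydrogens, waters, ligands and other HET groups are
#' excluded before the calculation.
#'
#' @param s a `structure_record` (stripped; any remaining HETs ignored).
#' @param probe probe radius in Angstrom (default 1.4, a water molecule).
#' @param n_points test points per atom (default 960).
#' @return data.frame with one row per atom: `chain`, `resno`, `icode`,
#'   `resname`, `name`, `area` (Angstrom squared).
#' @export
shrake_rupley <- function(s, probe = 1.4, n_points = 960) {
  pa <- protein_atoms(s)
  pa <- pa[!is_hydrogen(pa$element), , drop = FALSE]
  sasa_atoms(pa, probe = probe, n_points = n_points)
}

# Core quadrature over an arbitrary atom table.
sasa_atoms <- function(pa, probe = 1.4, n_points = 960) {
  if (!nrow(pa)) stop("no atoms for SASA calculation")
  rad <- VDW_RADII[toupper(pa$element)]
  if (anyNA(rad))
    stop("no van der Waals radius for atom(s): ",
         paste(unique(sprintf("%s/%s %s%d", pa$name[is.na(rad)],
                              pa$element[is.na(rad)], pa$chain[is.na(rad)],
                              pa$resno[is.na(rad)])), collapse = ", "))
  xyz <- as.matrix(pa[, c("x", "y", "z")])
  R <- rad + probe
  pts <- golden_spiral(n_points)
  n <- nrow(pa)
  area <- numeric(n)
  # neighbour prefilter: atoms whose expanded spheres can intersect
  maxR <- max(R)
  for (i in seq_len(n)) {
    di2 <- rowSums(sweep(xyz, 2, xyz[i, ])^2)
    nb <- which(di2 > 0 & di2 < (R[i] + maxR)^2)
    nb <- nb[di2[nb] < (R[i] + R[nb])^2]
    if (!length(nb)) {
      area[i] <- 4 * pi * R[i]^2
      next
    }
    sp <- pts * R[i]
    sp <- sweep(sp, 2, xyz[i, ], `+`)
    free <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(free)) break
      dj2 <- rowSums(sweep(sp[free, , drop = FALSE], 2, xyz[j, ])^2)
      free[free] <- dj2 > R[j]^2
    }
    area[i] <- 4 * pi * R[i]^2 * sum(free) / n_points
  }
  out <- pa[, c("chain", "resno", "icode", "resname", "name"), drop = FALSE]
  out$area <- area
  rownames(out) <- NULL
  out
}

#' Per-structure SASA of the unified binding site
#'
#' SASA is computed for all residues of the protein first, then the
#' binding-site residues resolvable in this structure are extracted and
#' summed.
#'
#' @param s a member `structure_record`.
#' @param fam its numbered `protein_family` with unified site.
#' @param probe,n_points see [shrake_rupley()].
#' @return list: `pdb_id`, `role`, `per_residue` (data.frame ref_chain,
#'   ref_index, area), `site_total` (Angstrom squared).
#' @export
structure_site_sasa <- function(s, fam, probe = 1.4, n_points = 960) {
  at <- shrake_rupley(s, probe = probe, n_points = n_points)
  nmap <- fam$numbering[[s$pdb_id]]
  us <- fam$unified_site
  if (is.null(us)) stop("unified site not computed")
  key <- res_key(at$chain, at$resno, at$icode)
  hit <- match(key, res_key(nmap$chain, nmap$resno, nmap$icode))
  at$ref_chain <- nmap$ref_chain[hit]
  at$ref_index <- nmap$ref_index[hit]
  at <- at[!is.na(hit), , drop = FALSE]
  in_site <- paste(at$ref_chain, at$ref_index) %in%
    paste(us$ref_chain, us$ref_index)
  at <- at[in_site, , drop = FALSE]
  per_res <- stats::aggregate(area ~ ref_chain + ref_index, data = at, sum)
  per_res <- per_res[order(per_res$ref_chain, per_res$ref_index), ,
                     drop = FALSE]
  rownames(per_res) <- NULL
  list(pdb_id = s$pdb_id, role = s$role, per_residue = per_res,
       site_total = sum(per_res$area))
}

#' Family SASA summary and delta-SASA
#'
#' Median, minimum and maximum binding-site SASA per role, and the family
#' delta-SASA defined as the maximum holo site SASA minus the minimum apo
#' site SASA.
#'
#' @param sasa_records list of [structure_site_sasa()] outputs for the
#'   family's members.
#' @return one-row data.frame with `median_apo`, `min_apo`, `max_apo`,
#'   `median_holo`, `min_holo`, `max_holo`, `delta_sasa`.
#' @export
family_sasa_summary <- function(sasa_records) {
  tot <- vapply(sasa_records, `[[`, numeric(1), "site_total")
  role <- vapply(sasa_records, `[[`, character(1), "role")
  apo <- tot[role == "apo"]; holo <- tot[role == "holo"]
  st <- function(v, f) if (length(v)) f(v) else NA_real_
  data.frame(
    median_apo = st(apo, stats::median), min_apo = st(apo, min),
    max_apo = st(apo, max),
    median_holo = st(holo, stats::median), min_holo = st(holo, min),
    max_holo = st(holo, max),
    delta_sasa = if (length(apo) && length(holo)) max(holo) - min(apo)
                 else NA_real_)
}
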