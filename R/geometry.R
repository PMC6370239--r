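# chi1 gamma-atom conventions. Gly/Pro/Ala carry no chi1. Ile has two
# gamma carbons; the angle used is that of the longer carbon chain (CG1).
# Val is gamma-symmetric and contributes both angles (CG1 primary, CG2
# alternate).
CHI1_GAMMA <- c(ARG = "CG", ASN = "CG", ASP = "CG", CYS = "SG", GLN = "CG",
                GLU = "CG", HIS = "CG", ILE = "CG1", LEU = "CG", LYS = "CG",
                MET = "CG", PHE = "CG", SER = "OG", THR = "OG1", TRP = "CG",
                TYR = "CG")

#' Residue types with a defined chi1 angle
#' @param resname 3-letter residue code(s).
#' @return logical vector.
#' @export
has_chi1 <- function(resname) {
  resname <- toupper(resname)
  resname %in% c(names(CHI1_GAMMA), "VAL")
}

#' Optimal rigid superposition (Kabsch algorithm)
#'
#' Least-squares superposition of point set `X` onto `Y` with fixed
#' correspondences. Returns the proper rotation (det = +1), translation,
#' and the root-mean-square deviation after the fit.
#'
#' The convention is row-vector: `Y ~ X %*% R + t`.
#'
#' @param X,Y numeric N x 3 matrices, N >= 3, rows in correspondence.
#' @return list with `rotation` (3 x 3), `translation` (length 3), `rmsd`.
#' @export
kabsch <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y) || ncol(X) != 3L || ncol(Y) != 3L)
    stop("X and Y must be N x 3 matrices with equal N")
  n <- nrow(X)
  if (n < 3L) stop("need at least 3 points for superposition")
  cx <- colMeans(X); cy <- colMeans(Y)
  Xc <- sweep(X, 2, cx); Yc <- sweep(Y, 2, cy)
  sv <- svd(crossprod(Xc, Yc))
  if (sv$d[2] < 1e-8 * max(sv$d[1], 1))
    stop("degenerate (collinear) point set: superposition not unique")
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  t_vec <- cy - cx %*% R
  res <- Yc - Xc %*% R
  list(rotation = R, translation = as.numeric(t_vec),
       rmsd = sqrt(sum(res^2) / n))
}

#' Torsion angle of four points
#'
#' IUPAC sign convention: looking down the p2 -> p3 axis, a clockwise
#' rotation of p4 relative to p1 is positive. Result in degrees in
#' `[-180, 180)` (the planar trans arrangement maps to -180).
#'
#' @param p1,p2,p3,p4 numeric 3-vectors.
#' @return angle in degrees.
#' @export
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  if (sqrt(sum(b1^2)) < 1e-9 || sqrt(sum(b2^2)) < 1e-9 ||
      sqrt(sum(b3^2)) < 1e-9)
    stop("consecutive points coincide; torsion undefined")
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  m1 <- cross3(n1, b2 / sqrt(sum(b2^2)))
  ang <- -atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang >= 180) ang <- ang - 360
  ang
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' chi1 angle(s) of one residue
#'
#' chi1 = torsion(N, CA, CB, G) where G is SG for Cys, OG for Ser, OG1 for
#' Thr, CG1 for Ile (the longer carbon chain), CG otherwise. Valine is
#' gamma-symmetric and yields two records, `primary` (CG1) and
#' `valine_alt` (CG2); every other type yields one `primary` record.
#'
#' @param res_atoms data.frame of one residue's atoms (unique names).
#' @return data.frame with columns `which`, `chi1`; or `NULL` with
#'   attribute-free `NA` handling via [site_chi1_tables()] when atoms
#'   needed for the torsion are missing (`missing_atoms = TRUE` attribute).
#' @export
chi1_of_residue <- function(res_atoms) {
  resname <- toupper(res_atoms$resname[1])
  if (!has_chi1(resname))
    stop("residue ", resname, " has no chi1 angle")
  gam <- if (resname == "VAL") c(primary = "CG1", valine_alt = "CG2")
         else c(primary = unname(CHI1_GAMMA[resname]))
  need <- c("N", "CA", "CB", unname(gam))
  pos <- function(nm) {
    i <- match(nm, res_atoms$name)
    if (is.na(i)) return(NULL)
    as.numeric(res_atoms[i, c("x", "y", "z")])
  }
  if (any(vapply(need, function(nm) is.null(pos(nm)), logical(1)))) {
    out <- data.frame(which = character(), chi1 = numeric())
    attr(out, "missing_atoms") <- TRUE
    return(out)
  }
  out <- data.frame(
    which = names(gam),
    chi1 = vapply(unname(gam), function(g)
      dihedral(pos("N"), pos("CA"), pos("CB"), pos(g)), numeric(1)),
    stringsAsFactors = FALSE)
  attr(out, "missing_atoms") <- FALSE
  out
}

#' Minimal circular range of a set of angles
#'
#' The smallest angular arc that contains every observed angle: 360 degrees
#' minus the largest gap between circularly adjacent sorted angles. A
#' single observation has range 0. Example: angles 30, 45 and 100 degrees
#' span a range of 70 degrees.
#'
#' @param angles numeric vector of angles in degrees (any wrap).
#' @return range in degrees in `[0, 360)`.
#' @export
chi1_range <- function(angles) {
  angles <- angles[is.finite(angles)]
  if (!length(angles)) stop("no angles supplied")
  if (length(angles) == 1L) return(0)
  a <- sort(angles %% 360)
  gaps <- c(diff(a), a[1] + 360 - a[length(a)])
  360 - max(gaps)
}

# CA coordinate matrix of a structure keyed by reference residue id
# ("refchain|refindex"), for residues present in the numbering map.
ca_by_ref <- function(s, nmap) {
  pa <- protein_atoms(s)
  ca <- pa[pa$name == "CA", , drop = FALSE]
  key <- res_key(ca$chain, ca$resno, ca$icode)
  mkey <- res_key(nmap$chain, nmap$resno, nmap$icode)
  hit <- match(key, mkey)
  ca <- ca[!is.na(hit), , drop = FALSE]
  hit <- hit[!is.na(hit)]
  m <- as.matrix(ca[, c("x", "y", "z")])
  rownames(m) <- paste(nmap$ref_chain[hit], nmap$ref_index[hit], sep = "|")
  m[!duplicated(rownames(m)), , drop = FALSE]
}

#' Pairwise C-alpha RMSD between two family members
#'
#' Superposes the shared C-alpha set (intersection of reference indices
#' resolved in both structures) and reports the fitted RMSD. With
#' `selection = "unified_site"` only unified-site residues are used; by
#' default the superposition is performed on those same site C-alphas
#' (local fit). `fit = "global"` instead fits on all shared C-alphas and
#' measures over the site subset.
#'
#' @param fam a `protein_family` (see [build_reference_numbering()]).
#' @param pdb_a,pdb_b member ids.
#' @param selection `"all"` or `"unified_site"`.
#' @param fit `"local"` or `"global"` frame for the site RMSD.
#' @return list with `rmsd`, `n_atoms`, `flagged` (TRUE when fewer than 3
#'   shared C-alphas).
#' @export
ca_rmsd <- function(fam, pdb_a, pdb_b, selection = c("all", "unified_site"),
                    fit = c("local", "global")) {
  selection <- match.arg(selection); fit <- match.arg(fit)
  A <- ca_by_ref(fam$members[[pdb_a]], fam$numbering[[pdb_a]])
  B <- ca_by_ref(fam$members[[pdb_b]], fam$numbering[[pdb_b]])
  shared <- intersect(rownames(A), rownames(B))
  sel <- shared
  if (selection == "unified_site") {
    if (is.null(fam$unified_site)) stop("unified site not computed")
    site_ids <- paste(fam$unified_site$ref_chain,
                      fam$unified_site$ref_index, sep = "|")
    sel <- intersect(shared, site_ids)
  }
  if (length(sel) < 3L)
    return(list(rmsd = NA_real_, n_atoms = length(sel), flagged = TRUE))
  if (selection == "all" || fit == "local") {
    k <- kabsch(A[sel, , drop = FALSE], B[sel, , drop = FALSE])
    rmsd <- k$rmsd
  } else {
    k <- kabsch(A[shared, , drop = FALSE], B[shared, , drop = FALSE])
    Afit <- A[sel, , drop = FALSE] %*% k$rotation +
      matrix(k$translation, length(sel), 3, byrow = TRUE)
    d <- Afit - B[sel, , drop = FALSE]
    rmsd <- sqrt(sum(d^2) / length(sel))
  }
  list(rmsd = rmsd, n_atoms = length(sel), flagged = FALSE)
}

#' Score every structure pair of a family
#'
#' All unordered member pairs, classified apo-apo (AA), holo-holo (HH) or
#' apo-holo (AH), with global and unified-site C-alpha RMSD.
#'
#' @param fam a `protein_family` with unified site computed.
#' @param site_fit fit frame for site RMSD, `"local"` or `"global"`.
#' @return data.frame with columns `pdb_a`, `pdb_b`, `pairing_class`,
#'   `rmsd_global`, `rmsd_site`, `n_atoms_global`, `n_atoms_site`,
#'   `flagged`.
#' @export
family_pair_scores <- function(fam, site_fit = "local") {
  ids <- names(fam$members)
  if (length(ids) < 2L)
    return(data.frame(pdb_a = character(), pdb_b = character(),
                      pairing_class = character(), rmsd_global = numeric(),
                      rmsd_site = numeric(), n_atoms_global = integer(),
                      n_atoms_site = integer(), flagged = logical()))
  pairs <- utils::combn(sort(ids), 2)
  out <- lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    ra <- fam$members[[a]]$role; rb <- fam$members[[b]]$role
    cls <- if (ra == "apo" && rb == "apo") "AA"
           else if (ra == "holo" && rb == "holo") "HH" else "AH"
    g <- ca_rmsd(fam, a, b, "all")
    s <- if (!is.null(fam$unified_site))
      ca_rmsd(fam, a, b, "unified_site", fit = site_fit)
    else list(rmsd = NA_real_, n_atoms = 0L, flagged = TRUE)
    data.frame(pdb_a = a, pdb_b = b, pairing_class = cls,
               rmsd_global = g$rmsd, rmsd_site = s$rmsd,
               n_atoms_global = g$n_atoms, n_atoms_site = s$n_atoms,
               flagged = g$flagged, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Family maximum RMSD per pairing class
#'
#' @param scores output of [family_pair_scores()].
#' @param class `"AA"`, `"HH"` or `"AH"`.
#' @param metric `"rmsd_global"` or `"rmsd_site"`.
#' @return maximum over non-flagged pairs of the class, or `NA` when the
#'   class has no usable pair (never 0 by default).
#' @export
family_max <- function(scores, class, metric = "rmsd_global") {
  v <- scores[[metric]][scores$pairing_class == class]
  v <- v[is.finite(v)]
  if (!length(v)) return(NA_real_)
  max(v)
}

#' chi1 tables of a family's unified binding site
#'
#' For every unified-site residue with a defined chi1, measures chi1 in
#' every member and summarises the minimal circular range per structure set
#' (apo, holo, apo+holo). A residue whose chi1 atoms are missing in any
#' member -- or which is entirely unresolved in a member -- is dropped from
#' the chi1 analysis for all structures of the family. Valine contributes
#' two observation streams (`primary`, `valine_alt`), kept separate unless
#' `merge_val` is set.
#'
#' @param fam a `protein_family` with unified site computed.
#' @param merge_val merge valine's two streams into one range.
#' @return list with `records` (long table: one chi1 per residue, member,
#'   stream), `ranges` (per residue, stream and set), `dropped` (residue
#'   ids removed family-wide), `summary` (per-set family max and mean
#'   range).
#' @export
site_chi1_tables <- function(fam, merge_val = FALSE) {
  us <- fam$unified_site
  if (is.null(us)) stop("unified site not computed")
  elig <- us[has_chi1(us$resname) & !(us$resname %in% MODIFIED_AA), ,
             drop = FALSE]
  records <- list(); dropped <- character()
  for (i in seq_len(nrow(elig))) {
    rc <- elig$ref_chain[i]; ri <- elig$ref_index[i]
    per_member <- list(); ok <- TRUE
    for (id in names(fam$members)) {
      s <- fam$members[[id]]; nmap <- fam$numbering[[id]]
      hit <- which(nmap$ref_chain == rc & nmap$ref_index == ri)
      if (!length(hit)) { ok <- FALSE; break }          # residue unresolved
      pa <- protein_atoms(s)
      ra <- pa[pa$chain == nmap$chain[hit] & pa$resno == nmap$resno[hit] &
                 pa$icode == nmap$icode[hit], , drop = FALSE]
      ch <- chi1_of_residue(ra)
      if (isTRUE(attr(ch, "missing_atoms")) || !nrow(ch)) {
        ok <- FALSE; break                              # critical atoms gone
      }
      ch$pdb_id <- id; ch$role <- s$role
      per_member[[id]] <- ch
    }
    if (!ok) { dropped <- c(dropped, paste(rc, ri, sep = "|")); next }
    rec <- do.call(rbind, per_member)
    rec$family_id <- fam$family_id
    rec$ref_chain <- rc; rec$ref_index <- ri
    rec$resname <- elig$resname[i]
    records[[length(records) + 1L]] <- rec
  }
  records <- if (length(records)) do.call(rbind, records) else
    data.frame(which = character(), chi1 = numeric(), pdb_id = character(),
               role = character(), family_id = character(),
               ref_chain = character(), ref_index = integer(),
               resname = character())
  rownames(records) <- NULL
  ranges <- chi1_range_summary(records, merge_val = merge_val)
  summary <- chi1_set_summary(ranges)
  list(records = records, ranges = ranges, dropped = dropped,
       summary = summary)
}

chi1_range_summary <- function(records, merge_val = FALSE) {
  empty <- data.frame(ref_chain = character(), ref_index = integer(),
                      resname = character(), which = character(),
                      set = character(), range = numeric(),
                      n_obs = integer())
  if (!nrow(records)) return(empty)
  stream <- if (merge_val) "merged" else records$which
  key <- paste(records$ref_chain, records$ref_index, stream, sep = "|")
  out <- lapply(split(seq_len(nrow(records)), key), function(idx) {
    r <- records[idx, , drop = FALSE]
    one_set <- function(label, rows) {
      if (!nrow(rows)) return(NULL)
      data.frame(ref_chain = r$ref_chain[1], ref_index = r$ref_index[1],
                 resname = r$resname[1],
                 which = if (merge_val) "merged" else r$which[1],
                 set = label, range = chi1_range(rows$chi1),
                 n_obs = nrow(rows), stringsAsFactors = FALSE)
    }
    rbind(one_set("apo", r[r$role == "apo", , drop = FALSE]),
          one_set("holo", r[r$role == "holo", , drop = FALSE]),
          one_set("apo_holo", r))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$ref_chain, out$ref_index, out$which, out$set), , drop = FALSE]
}

chi1_set_summary <- function(ranges) {
  sets <- c("apo", "holo", "apo_holo")
  do.call(rbind, lapply(sets, function(st) {
    v <- ranges$range[ranges$set == st]
    data.frame(set = st,
               max_range = if (length(v)) max(v) else NA_real_,
               mean_range = if (length(v)) mean(v) else NA_real_,
               n_residues = length(v), stringsAsFactors = FALSE)
  }))
}
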