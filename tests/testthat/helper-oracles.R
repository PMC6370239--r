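# Independent oracles used across tests. Each deliberately recomputes its
# quantity by a different route than the package implementation.

cross_prod <- function(a, b)
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])

# Minimal circular arc by brute force: try every observed angle as the
# start of the arc and take the smallest arc that covers all angles.
oracle_arc_range <- function(angles) {
  a <- angles %% 360
  if (length(a) == 1L) return(0)
  best <- Inf
  for (start in a) {
    offs <- (a - start) %% 360
    best <- min(best, max(offs))
  }
  best
}

# RMSD after optimal rigid superposition, by numeric minimisation over
# Euler angles (translation handled by centering) from several starts.
oracle_superpose_rmsd <- function(X, Y, n_starts = 12L, seed = 99L) {
  Xc <- sweep(X, 2, colMeans(X)); Yc <- sweep(Y, 2, colMeans(Y))
  rotmat <- function(th) {
    cz <- cos(th[1]); sz <- sin(th[1])
    cy <- cos(th[2]); sy <- sin(th[2])
    cx <- cos(th[3]); sx <- sin(th[3])
    Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE)
    Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE)
    Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
    Rz %*% Ry %*% Rx
  }
  fn <- function(th) {
    R <- rotmat(th)
    sqrt(mean(rowSums((Yc - Xc %*% t(R))^2)))
  }
  set.seed(seed)
  best <- Inf
  for (k in seq_len(n_starts)) {
    th0 <- stats::runif(3, -pi, pi)
    op <- stats::optim(th0, fn, method = "BFGS",
                       control = list(reltol = 1e-14, maxit = 500))
    op <- stats::optim(op$par, fn, method = "Nelder-Mead",
                       control = list(reltol = 1e-14, maxit = 2000))
    best <- min(best, op$value)
  }
  best
}

# Exact two-sided Wilcoxon signed-rank p-value by enumerating every sign
# assignment of the absolute differences (re-ranking per assignment is
# unnecessary under the null since |d| are fixed; midranks recomputed here
# from scratch).
oracle_wilcoxon <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  if (!n) return(list(statistic = 0, p_value = 1))
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  total <- 2^n
  Wnull <- numeric(total)
  for (i in seq_len(total) - 1L) {
    bits <- as.integer(intToBits(i))[seq_len(n)]
    Wnull[i + 1L] <- sum(r[bits == 1L])
  }
  p <- min(1, 2 * min(mean(Wnull <= W), mean(Wnull >= W)))
  list(statistic = W, p_value = p)
}

# All-pairs double-loop binding-site residues (no prefilter).
oracle_site_residues <- function(s, lig, cutoff = 4.5) {
  pa <- s$atom[s$atom$type == "ATOM" &
                 !toupper(s$atom$element) %in% c("H", "D"), ]
  lx <- lig$atoms[!toupper(lig$atoms$element) %in% c("H", "D"), ]
  keys <- unique(paste(pa$chain, pa$resno, pa$icode, sep = "|"))
  hit <- character()
  for (k in keys) {
    parts <- strsplit(k, "|", fixed = TRUE)[[1]]
    ra <- pa[pa$chain == parts[1] & pa$resno == as.integer(parts[2]), ]
    found <- FALSE
    for (i in seq_len(nrow(ra))) {
      for (j in seq_len(nrow(lx))) {
        dd <- sqrt(sum((as.numeric(ra[i, c("x", "y", "z")]) -
                          as.numeric(lx[j, c("x", "y", "z")]))^2))
        if (dd <= cutoff) { found <- TRUE; break }
      }
      if (found) break
    }
    if (found) hit <- c(hit, k)
  }
  sort(hit)
}

# Analytic accessible area of sphere 1 (radius R1, expanded) partially
# occluded by sphere 2 at centre distance d: spherical-cap subtraction.
oracle_two_sphere_area <- function(R1, R2, d) {
  if (d >= R1 + R2) return(4 * pi * R1^2)
  h <- R1 - (d^2 + R1^2 - R2^2) / (2 * d)
  4 * pi * R1^2 - 2 * pi * R1 * h
}
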