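#' Wilcoxon signed-rank test for paired samples
#'
#' Zero differences are dropped before ranking (Wilcoxon's original
#' treatment); the count dropped is reported. For n up to 12 retained
#' pairs the two-sided p-value is computed by exact enumeration of all
#' sign assignments over the (mid)ranks of |differences|, which handles
#' ties exactly; for larger n the normal approximation with tie and
#' continuity correction is used (via `stats::wilcox.test`).
#'
#' @param a,b paired numeric vectors, or `b = NULL` with `a` the
#'   differences.
#' @return list: `statistic` (W, sum of positive ranks), `p_value`
#'   (two-sided), `n` (pairs retained), `n_zero` (pairs dropped),
#'   `degenerate` (TRUE when all differences were zero; p = 1 then),
#'   `method`.
#' @export
wilcoxon_signed_rank <- function(a, b = NULL) {
  d <- if (is.null(b)) as.numeric(a) else as.numeric(a) - as.numeric(b)
  d <- d[is.finite(d)]
  if (!length(d)) stop("no finite paired differences")
  n_zero <- sum(d == 0)
  d <- d[d != 0]
  if (!length(d))
    return(list(statistic = 0, p_value = 1, n = 0L, n_zero = n_zero,
                degenerate = TRUE, method = "degenerate"))
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= 12L) {
    # exact null: each sign equally likely, rank magnitudes fixed
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    Wnull <- as.numeric(signs %*% r)
    p <- min(1, 2 * min(mean(Wnull <= W), mean(Wnull >= W)))
    method <- "exact enumeration"
  } else {
    wt <- suppressWarnings(stats::wilcox.test(d, mu = 0, exact = FALSE,
                                              correct = TRUE))
    p <- wt$p.value
    method <- "normal approximation"
  }
  list(statistic = W, p_value = p, n = n, n_zero = n_zero,
       degenerate = FALSE, method = method)
}

#' Squared Pearson correlation
#'
#' Pairs with missing values are dropped; a degenerate screen (either
#' variable constant, or fewer than 3 pairs) reports `NA`, never 0.
#'
#' @param x,y numeric vectors.
#' @return squared correlation in `[0, 1]`, or `NA`.
#' @export
r_squared <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L || stats::sd(x) == 0 || stats::sd(y) == 0)
    return(NA_real_)
  stats::cor(x, y)^2
}

#' Jackknife confidence interval by repeated subsampling
#'
#' Draws `n_resamples` subsamples without replacement at `keep_fraction`
#' of the data size and returns the 2.5/97.5 percentiles of the resampled
#' statistic.
#'
#' @param values numeric vector.
#' @param statistic function of a numeric vector (default mean).
#' @param n_resamples number of resamples (default 1000).
#' @param keep_fraction fraction of the data kept per resample (0.9:
#'   "leaving 10 % out").
#' @param seed integer seed for reproducibility.
#' @return numeric `c(lo, hi)`.
#' @export
jackknife_ci <- function(values, statistic = mean, n_resamples = 1000,
                         keep_fraction = 0.9, seed = 1L) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (!n) stop("no values for jackknife")
  k <- max(1L, floor(n * keep_fraction))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  stat <- vapply(seq_len(n_resamples), function(i)
    statistic(values[sample.int(n, k)]), numeric(1))
  stats::quantile(stat, c(0.025, 0.975), names = FALSE, type = 7)
}

#' Aggregate per-family results into one row per family
#'
#' Each protein family contributes one overall value per metric: maximum
#' (and mean/median) RMSD per pairing class over global and binding-site
#' selections, per-set chi1 range maxima and means, SASA summaries, mean
#' ligand mass and per-role mean resolution.
#'
#' @param family_results list of per-family result lists as produced by
#'   [run_pipeline()] (fields `family_id`, `n_apo`, `n_holo`, `scores`,
#'   `chi1`, `sasa`, `ligand_mass`, `resolution_apo`, `resolution_holo`).
#' @return data.frame, one row per family.
#' @export
aggregate_families <- function(family_results) {
  rows <- lapply(family_results, function(fr) {
    sc <- fr$scores
    cls_stats <- function(cls, metric) {
      v <- sc[[metric]][sc$pairing_class == cls]
      v <- v[is.finite(v)]
      if (!length(v)) c(max = NA_real_, mean = NA_real_, median = NA_real_)
      else c(max = max(v), mean = mean(v), median = stats::median(v))
    }
    chs <- fr$chi1$summary
    chi_val <- function(set, what)
      chs[[what]][chs$set == set]
    out <- data.frame(family_id = fr$family_id, n_apo = fr$n_apo,
                      n_holo = fr$n_holo, stringsAsFactors = FALSE)
    for (cls in c("AA", "HH", "AH")) {
      g <- cls_stats(cls, "rmsd_global"); s <- cls_stats(cls, "rmsd_site")
      out[[paste0("rmsd_max_", cls)]] <- g["max"]
      out[[paste0("rmsd_mean_", cls)]] <- g["mean"]
      out[[paste0("rmsd_median_", cls)]] <- g["median"]
      out[[paste0("rmsd_site_max_", cls)]] <- s["max"]
      out[[paste0("rmsd_site_mean_", cls)]] <- s["mean"]
      out[[paste0("rmsd_site_median_", cls)]] <- s["median"]
    }
    for (st in c("apo", "holo", "apo_holo")) {
      out[[paste0("chi1_max_", st)]] <- chi_val(st, "max_range")
      out[[paste0("chi1_mean_", st)]] <- chi_val(st, "mean_range")
    }
    out$site_size <- fr$site_size
    out <- cbind(out, fr$sasa)
    out$ligand_mass <- fr$ligand_mass
    out$resolution_apo <- fr$resolution_apo
    out$resolution_holo <- fr$resolution_holo
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$family_id), , drop = FALSE]
}

#' Dataset-level averages and medians of family maxima
#'
#' @param summaries output of [aggregate_families()].
#' @return data.frame: pairing class x selection, with `average` and
#'   `median` of the per-family maximum RMSD, plus chi1-range rows per
#'   structure set (median/average of per-family mean and max ranges).
#' @export
dataset_stats <- function(summaries) {
  row <- function(metric, v) {
    v <- v[is.finite(v)]
    data.frame(metric = metric,
               average = if (length(v)) mean(v) else NA_real_,
               median = if (length(v)) stats::median(v) else NA_real_,
               n = length(v), stringsAsFactors = FALSE)
  }
  rbind(
    row("rmsd_max_AA", summaries$rmsd_max_AA),
    row("rmsd_max_HH", summaries$rmsd_max_HH),
    row("rmsd_max_AH", summaries$rmsd_max_AH),
    row("rmsd_site_max_AA", summaries$rmsd_site_max_AA),
    row("rmsd_site_max_HH", summaries$rmsd_site_max_HH),
    row("rmsd_site_max_AH", summaries$rmsd_site_max_AH),
    row("chi1_mean_apo", summaries$chi1_mean_apo),
    row("chi1_mean_holo", summaries$chi1_mean_holo),
    row("chi1_mean_apo_holo", summaries$chi1_mean_apo_holo),
    row("chi1_max_apo", summaries$chi1_max_apo),
    row("chi1_max_holo", summaries$chi1_max_holo),
    row("chi1_max_apo_holo", summaries$chi1_max_apo_holo),
    row("site_size", summaries$site_size),
    row("delta_sasa", summaries$delta_sasa))
}

#' Paired hypothesis tests across the family table
#'
#' The study's standard comparisons: family-maximum backbone RMSD apo-apo vs
#' holo-holo (inherent flexibility), apo-holo vs each single-state class
#' (induced flexibility), and family-average chi1 ranges apo vs holo and
#' combined set vs each single set.
#'
#' @param summaries output of [aggregate_families()].
#' @return data.frame with one row per comparison: statistic, p-value, n.
#' @export
dataset_tests <- function(summaries) {
  cmp <- list(
    rmsd_AA_vs_HH = c("rmsd_max_AA", "rmsd_max_HH"),
    rmsd_AH_vs_AA = c("rmsd_max_AH", "rmsd_max_AA"),
    rmsd_AH_vs_HH = c("rmsd_max_AH", "rmsd_max_HH"),
    chi1_apo_vs_holo = c("chi1_mean_apo", "chi1_mean_holo"),
    chi1_combined_vs_apo = c("chi1_mean_apo_holo", "chi1_mean_apo"),
    chi1_combined_vs_holo = c("chi1_mean_apo_holo", "chi1_mean_holo"))
  do.call(rbind, lapply(names(cmp), function(nm) {
    a <- summaries[[cmp[[nm]][1]]]; b <- summaries[[cmp[[nm]][2]]]
    ok <- is.finite(a) & is.finite(b)
    wt <- wilcoxon_signed_rank(a[ok], b[ok])
    data.frame(comparison = nm, statistic = wt$statistic,
               p_value = wt$p_value, n = wt$n, n_zero = wt$n_zero,
               method = wt$method, stringsAsFactors = FALSE)
  }))
}

#' Correlation screens against ligand mass and resolution
#'
#' Squared Pearson correlations between the per-family flexibility maxima
#' and mean ligand mass / mean structure resolution.
#'
#' @param summaries output of [aggregate_families()].
#' @return data.frame of screen name and R-squared.
#' @export
correlation_screens <- function(summaries) {
  res_all <- rowMeans(cbind(summaries$resolution_apo,
                            summaries$resolution_holo), na.rm = TRUE)
  screens <- list(
    rmsd_AH_vs_ligand_mass = list(summaries$rmsd_max_AH,
                                  summaries$ligand_mass),
    rmsd_HH_vs_ligand_mass = list(summaries$rmsd_max_HH,
                                  summaries$ligand_mass),
    rmsd_AH_vs_resolution = list(summaries$rmsd_max_AH, res_all),
    rmsd_AA_vs_resolution = list(summaries$rmsd_max_AA,
                                 summaries$resolution_apo),
    chi1_combined_vs_ligand_mass = list(summaries$chi1_mean_apo_holo,
                                        summaries$ligand_mass),
    chi1_combined_vs_resolution = list(summaries$chi1_mean_apo_holo,
                                       res_all))
  do.call(rbind, lapply(names(screens), function(nm)
    data.frame(screen = nm,
               r_squared = r_squared(screens[[nm]][[1]],
                                     screens[[nm]][[2]]),
               stringsAsFactors = FALSE)))
}

#' Per-amino-acid flexibility profiles and classes
#'
#' Cumulative distribution of chi1 ranges per residue type (fraction of
#' residues with range at or below each threshold), with jackknifed 95 %
#' confidence bands, and a rigid / semi-flexible / very-flexible class
#' assigned from confidence-interval overlap of the cumulative fraction at
#' the classification threshold (40 degrees): types are sorted by that
#' fraction and chained into groups wherever neighbouring intervals
#' overlap; the most rigid group is `rigid`, the least `very_flexible`,
#' anything between `semi_flexible`. A single undivided group is labelled
#' by its absolute level (>= 2/3 rigid, <= 1/3 very flexible, else
#' semi-flexible).
#'
#' @param range_records data.frame with columns `resname` and `range`
#'   (one row per unique binding-site residue stream).
#' @param thresholds grid of range thresholds in degrees.
#' @param class_threshold threshold used for classification (default 40).
#' @param n_resamples,keep_fraction,seed jackknife settings.
#' @return list: `curves` (long data.frame type, threshold, fraction, lo,
#'   hi), `classes` (data.frame type, fraction_at_threshold, lo, hi,
#'   class).
#' @export
amino_acid_profiles <- function(range_records,
                                thresholds = seq(0, 360, by = 10),
                                class_threshold = 40,
                                n_resamples = 1000, keep_fraction = 0.9,
                                seed = 1L) {
  stopifnot(all(c("resname", "range") %in% names(range_records)))
  types <- sort(unique(range_records$resname))
  curves <- list(); cls_rows <- list()
  for (ty in types) {
    v <- range_records$range[range_records$resname == ty]
    v <- v[is.finite(v)]
    frac <- vapply(thresholds, function(th) mean(v <= th), numeric(1))
    ci <- vapply(thresholds, function(th)
      jackknife_ci(v, statistic = function(z) mean(z <= th),
                   n_resamples = n_resamples,
                   keep_fraction = keep_fraction,
                   seed = seed + match(ty, types)), numeric(2))
    curves[[ty]] <- data.frame(type = ty, threshold = thresholds,
                               fraction = frac, lo = ci[1, ], hi = ci[2, ],
                               stringsAsFactors = FALSE)
    f40 <- mean(v <= class_threshold)
    ci40 <- jackknife_ci(v, statistic = function(z)
      mean(z <= class_threshold), n_resamples = n_resamples,
      keep_fraction = keep_fraction, seed = seed + match(ty, types))
    cls_rows[[ty]] <- data.frame(type = ty, fraction_at_threshold = f40,
                                 lo = ci40[1], hi = ci40[2],
                                 stringsAsFactors = FALSE)
  }
  classes <- do.call(rbind, cls_rows)
  rownames(classes) <- NULL
  classes <- classes[order(-classes$fraction_at_threshold, classes$type), ,
                     drop = FALSE]
  grp <- integer(nrow(classes))
  if (nrow(classes)) {
    g <- 1L; grp[1] <- g
    for (i in seq_len(nrow(classes))[-1]) {
      overlap <- classes$hi[i] >= min(classes$lo[seq_len(i - 1)][
        grp[seq_len(i - 1)] == g])
      if (!overlap) g <- g + 1L
      grp[i] <- g
    }
  }
  ng <- max(grp, 1L)
  lab <- if (ng == 1L) {
    est <- mean(classes$fraction_at_threshold)
    rep(if (est >= 2 / 3) "rigid" else if (est <= 1 / 3) "very_flexible"
        else "semi_flexible", nrow(classes))
  } else {
    c("rigid", rep("semi_flexible", max(ng - 2L, 0L)),
      "very_flexible")[grp]
  }
  classes$class <- lab
  list(curves = do.call(rbind, curves), classes = classes)
}

#' Normalised chi1 occupancy histograms per amino-acid type
#'
#' Each unique binding-site residue (one residue of one family, one
#' observation stream) gets its own histogram over chi1 bins, normalised
#' to sum to 1; histograms are then averaged over all residues of that
#' type in the dataset, so every unique residue carries equal weight
#' regardless of family size.
#'
#' @param records long chi1 table with columns `family_id`, `ref_chain`,
#'   `ref_index`, `which`, `resname`, `chi1`.
#' @param bin_width bin width in degrees (default 10; bins cover
#'   `[-180, 180)`).
#' @return data.frame: `type`, `bin_start`, `occupancy` (sums to 1 per
#'   type).
#' @export
bin_chi1 <- function(records, bin_width = 10) {
  stopifnot(360 %% bin_width == 0)
  breaks <- seq(-180, 180, by = bin_width)
  key <- paste(records$family_id, records$ref_chain, records$ref_index,
               records$which, sep = "|")
  out <- list()
  for (ty in sort(unique(records$resname))) {
    sel <- records$resname == ty
    per_res <- lapply(split(records$chi1[sel], key[sel]), function(a) {
      a <- ((a + 180) %% 360) - 180
      h <- tabulate(findInterval(a, breaks, rightmost.closed = TRUE),
                    nbins = length(breaks) - 1L)
      h / sum(h)
    })
    m <- do.call(rbind, per_res)
    out[[ty]] <- data.frame(type = ty, bin_start = breaks[-length(breaks)],
                            occupancy = colMeans(m),
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write the report bundle
#'
#' Emits the analysis tables as CSV plus a `stats.json` with the test
#' results and settings. Output is deterministic for a fixed seed: rows are
#' sorted before writing.
#'
#' @param results a [run_pipeline()] result.
#' @param dir output directory (created if absent).
#' @return invisibly, the directory.
#' @export
make_reports <- function(results, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name)
    utils::write.csv(df, file.path(dir, name), row.names = FALSE)
  wr(results$summaries, "summaries.csv")
  wr(results$dataset, "dataset_stats.csv")
  wr(results$pairs, "pairs.csv")
  wr(results$chi1_ranges, "chi1_ranges.csv")
  wr(results$chi1_records, "chi1_angles.csv")
  wr(results$sasa, "sasa.csv")
  wr(results$decisions, "decisions.csv")
  wr(results$unified_sites, "unified_sites.csv")
  if (!is.null(results$profiles)) {
    wr(results$profiles$curves, "profiles.csv")
    wr(results$profiles$classes, "flexibility_classes.csv")
  }
  if (!is.null(results$histograms)) wr(results$histograms, "chi1_bins.csv")
  stats_out <- list(tests = results$tests, screens = results$screens,
                    config = results$config,
                    n_families = nrow(results$summaries))
  jsonlite::write_json(stats_out, file.path(dir, "stats.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
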