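#' Pipeline configuration
#'
#' All tunable parameters of the analysis with their defaults: 4.5 A
#' contact cutoff (inclusive), 2.5 A resolution cutoff, 100 Da HET weight
#' cutoff, 1.4 A probe with 960 quadrature points for SASA, local-fit
#' binding-site RMSD, valine chi1 streams kept separate, 10-degree chi1
#' bins, and a 1000 x 90 % jackknife. The configuration is serialised into
#' every output bundle.
#'
#' @param input_dir bundle directory (structures/ + index.csv +
#'   ligands.csv + allowlist.csv, optional het_weights.csv).
#' @param output_dir optional report directory.
#' @param cutoff,resolution_cutoff,het_mw_cutoff,probe,sasa_points,site_fit,merge_val,bin_width,jackknife_n,jackknife_fraction,seed,merge_terminal_extensions
#'   see Description.
#' @param run_sasa set FALSE to skip the SASA stage.
#' @return a named list of class `run_config`.
#' @export
default_config <- function(input_dir, output_dir = NULL, cutoff = 4.5,
                           resolution_cutoff = 2.5, het_mw_cutoff = 100,
                           probe = 1.4, sasa_points = 960,
                           site_fit = c("local", "global"),
                           merge_val = FALSE, bin_width = 10,
                           jackknife_n = 1000, jackknife_fraction = 0.9,
                           seed = 1L, merge_terminal_extensions = TRUE,
                           run_sasa = TRUE) {
  site_fit <- match.arg(site_fit)
  stopifnot(cutoff > 0, resolution_cutoff > 0, het_mw_cutoff > 0,
            probe > 0, sasa_points > 0)
  structure(list(
    input_dir = input_dir, output_dir = output_dir, cutoff = cutoff,
    resolution_cutoff = resolution_cutoff,
    het_mw_cutoff = het_mw_cutoff, probe = probe,
    sasa_points = sasa_points, site_fit = site_fit,
    merge_val = merge_val, bin_width = bin_width,
    jackknife_n = jackknife_n, jackknife_fraction = jackknife_fraction,
    seed = as.integer(seed),
    merge_terminal_extensions = merge_terminal_extensions,
    run_sasa = run_sasa,
    align_params = ALIGN_PARAMS), class = c("run_config", "list"))
}

read_bundle <- function(config) {
  ind <- utils::read.csv(file.path(config$input_dir, "index.csv"),
                         stringsAsFactors = FALSE)
  stopifnot(all(c("pdb_id", "role") %in% names(ind)))
  ligp <- file.path(config$input_dir, "ligands.csv")
  lig <- if (file.exists(ligp))
    utils::read.csv(ligp, stringsAsFactors = FALSE) else NULL
  alp <- file.path(config$input_dir, "allowlist.csv")
  allow <- if (file.exists(alp))
    utils::read.csv(alp, stringsAsFactors = FALSE)$component_code
  else character()
  hwp <- file.path(config$input_dir, "het_weights.csv")
  hw <- if (file.exists(hwp))
    utils::read.csv(hwp, stringsAsFactors = FALSE) else NULL
  list(index = ind, ligands = lig, allowlist = allow, het_weights = hw)
}

#' Run the full apo/holo flexibility pipeline
#'
#' Executes the stages in curation order: parse and prepare every
#' structure (altloc resolution, hydrogen/water stripping, holo ligand
#' extraction); filter holo structures; cluster sequence-identical
#' families and assign reference numbering; build unified binding sites
#' from the accepted holo members; filter apo structures against the
#' sites; drop families below two apo or two holo members; then compute
#' pairwise RMSDs, chi1 tables, SASA, family summaries, dataset
#' statistics, paired tests, correlation screens, per-amino-acid
#' flexibility profiles and chi1 occupancy histograms. Deterministic for
#' a fixed configuration.
#'
#' @param config a [default_config()].
#' @return list with `families`, `family_results`, `summaries`,
#'   `dataset`, `tests`, `screens`, `profiles`, `histograms`, `pairs`,
#'   `chi1_ranges`, `chi1_records`, `sasa`, `decisions`,
#'   `unified_sites`, `config`. Written as a report bundle when
#'   `config$output_dir` is set.
#' @export
run_pipeline <- function(config) {
  bundle <- read_bundle(config)
  ind <- bundle$index
  decisions <- list()

  ## stage 1: parse + prepare
  structures <- list()
  for (i in seq_len(nrow(ind))) {
    id <- ind$pdb_id[i]
    path <- file.path(config$input_dir, "structures", paste0(id, ".pdb"))
    res <- if ("resolution" %in% names(ind)) ind$resolution[i] else NULL
    s <- parse_structure(path, role = ind$role[i], resolution = res,
                         pdb_id = id)
    s <- resolve_altlocs(s)
    ligspec <- NULL
    if (s$role == "holo" && !is.null(bundle$ligands)) {
      ligspec <- bundle$ligands[bundle$ligands$pdb_id == id, ,
                                drop = FALSE]
      if (nrow(ligspec) && length(unique(ligspec$ligand_id)) > 1L)
        ligspec <- NULL            # multi-ligand: reject later, no extract
    }
    s <- strip_for_analysis(s, ligand_spec =
                              if (!is.null(ligspec) && nrow(ligspec))
                                ligspec else NULL)
    structures[[id]] <- s
  }

  ## stage 2: holo filter
  holo_ok <- character()
  for (id in names(structures)) {
    s <- structures[[id]]
    if (s$role != "holo") next
    ligspec <- bundle$ligands[bundle$ligands$pdb_id == id, , drop = FALSE]
    dec <- validate_holo(s, ligspec = ligspec,
                         resolution_cutoff = config$resolution_cutoff,
                         cutoff = config$cutoff)
    dec$stage <- "holo_filter"
    decisions[[length(decisions) + 1L]] <- dec
    if (dec$accepted) holo_ok <- c(holo_ok, id)
  }
  apo_ids <- names(structures)[
    vapply(structures, `[[`, character(1), "role") == "apo"]

  ## stage 3: families + numbering
  fams <- cluster_families(structures[c(holo_ok, apo_ids)],
                           merge_terminal_extensions =
                             config$merge_terminal_extensions)
  fams <- lapply(fams, build_reference_numbering)
  for (f in fams) for (id in names(f$rejected))
    decisions[[length(decisions) + 1L]] <-
      cbind(curation_decision(id, f$rejected[[id]]),
            stage = "renumbering")

  ## stage 4: unified sites, then apo filter
  kept <- list()
  for (f in fams) {
    roles <- vapply(f$members, `[[`, character(1), "role")
    if (!any(roles == "holo")) {
      for (id in names(f$members)[roles == "apo"])
        decisions[[length(decisions) + 1L]] <-
          cbind(curation_decision(id, "NO_FAMILY"), stage = "apo_filter")
      next
    }
    f <- unify_sites(f, cutoff = config$cutoff)
    drop <- character()
    for (id in names(f$members)[roles == "apo"]) {
      dec <- validate_apo(f$members[[id]], f,
                          allowlist = bundle$allowlist,
                          mw_cutoff = config$het_mw_cutoff,
                          cutoff = config$cutoff,
                          mw_table = bundle$het_weights)
      dec$stage <- "apo_filter"
      decisions[[length(decisions) + 1L]] <- dec
      if (!dec$accepted) drop <- c(drop, id)
    }
    f$members <- f$members[setdiff(names(f$members), drop)]
    kept[[f$family_id]] <- f
  }
  families <- filter_min_members(kept)

  ## stage 5: metrics per family
  family_results <- lapply(families, function(f) {
    roles <- vapply(f$members, `[[`, character(1), "role")
    scores <- family_pair_scores(f, site_fit = config$site_fit)
    chi1 <- site_chi1_tables(f, merge_val = config$merge_val)
    sasa_records <- NULL
    sasa <- if (config$run_sasa) {
      sasa_records <- lapply(f$members, structure_site_sasa, fam = f,
                             probe = config$probe,
                             n_points = config$sasa_points)
      family_sasa_summary(sasa_records)
    } else {
      data.frame(median_apo = NA_real_, min_apo = NA_real_,
                 max_apo = NA_real_, median_holo = NA_real_,
                 min_holo = NA_real_, max_holo = NA_real_,
                 delta_sasa = NA_real_)
    }
    lig_mass <- vapply(f$members[roles == "holo"], function(s)
      if (!is.null(s$ligand)) s$ligand$mol_weight else NA_real_,
      numeric(1))
    list(family_id = f$family_id,
         n_apo = sum(roles == "apo"), n_holo = sum(roles == "holo"),
         scores = scores, chi1 = chi1, sasa = sasa,
         sasa_records = sasa_records,
         site_size = nrow(f$unified_site),
         ligand_mass = mean(lig_mass, na.rm = TRUE),
         resolution_apo = mean(vapply(f$members[roles == "apo"], `[[`,
                                      numeric(1), "resolution")),
         resolution_holo = mean(vapply(f$members[roles == "holo"], `[[`,
                                       numeric(1), "resolution")))
  })

  ## stage 6: aggregation + statistics
  if (length(family_results)) {
    summaries <- aggregate_families(family_results)
    dataset <- dataset_stats(summaries)
    tests <- dataset_tests(summaries)
    screens <- correlation_screens(summaries)
    pairs <- do.call(rbind, lapply(family_results, function(fr)
      cbind(family_id = fr$family_id, fr$scores)))
    chi1_ranges <- do.call(rbind, lapply(family_results, function(fr)
      if (nrow(fr$chi1$ranges))
        cbind(family_id = fr$family_id, fr$chi1$ranges) else NULL))
    chi1_records <- do.call(rbind, lapply(family_results, function(fr)
      if (nrow(fr$chi1$records)) fr$chi1$records else NULL))
    sasa_tab <- do.call(rbind, lapply(family_results, function(fr) {
      if (is.null(fr$sasa_records)) return(NULL)
      do.call(rbind, lapply(fr$sasa_records, function(r)
        data.frame(family_id = fr$family_id, pdb_id = r$pdb_id,
                   role = r$role, site_sasa = r$site_total,
                   stringsAsFactors = FALSE)))
    }))
    comb <- if (!is.null(chi1_ranges) && nrow(chi1_ranges))
      chi1_ranges[chi1_ranges$set == "apo_holo", , drop = FALSE]
    else NULL
    profiles <- if (!is.null(comb) && nrow(comb))
      amino_acid_profiles(comb, class_threshold = 40,
                          n_resamples = config$jackknife_n,
                          keep_fraction = config$jackknife_fraction,
                          seed = config$seed)
    else NULL
    histograms <- if (!is.null(chi1_records) && nrow(chi1_records))
      bin_chi1(chi1_records, bin_width = config$bin_width) else NULL
    unified_sites <- do.call(rbind, lapply(families, function(f)
      cbind(family_id = f$family_id, f$unified_site)))
  } else {
    summaries <- data.frame(); dataset <- data.frame()
    tests <- data.frame(); screens <- data.frame()
    pairs <- data.frame(); chi1_ranges <- data.frame()
    chi1_records <- data.frame(); sasa_tab <- data.frame()
    profiles <- NULL; histograms <- NULL
    unified_sites <- data.frame()
  }

  decisions <- if (length(decisions)) do.call(rbind, decisions)
  else data.frame(pdb_id = character(), accepted = logical(),
                  reasons = character(), stage = character())
  rownames(decisions) <- NULL
  decisions <- decisions[order(decisions$stage, decisions$pdb_id), ,
                         drop = FALSE]

  out <- list(families = families, family_results = family_results,
              summaries = summaries, dataset = dataset, tests = tests,
              screens = screens, profiles = profiles,
              histograms = histograms, pairs = pairs,
              chi1_ranges = chi1_ranges, chi1_records = chi1_records,
              sasa = sasa_tab, decisions = decisions,
              unified_sites = unified_sites,
              config = unclass(config))
  if (!is.null(config$output_dir)) make_reports(out, config$output_dir)
  out
}
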