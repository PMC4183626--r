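#' Read a flat key = value configuration file
#'
#' One `key = value` pair per line; blank lines and `#` comments are
#' ignored. Values are auto-typed (logical, numeric, else string). Used by
#' the command-line wrapper with precedence CLI flag > config file >
#' package default.
#'
#' @param path configuration file.
#' @return named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE))
      stop("malformed config line (expected key = value): '", ln, "'")
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    out[[key]] <- type_config_value(val)
  }
  out
}

type_config_value <- function(v) {
  if (tolower(v) %in% c("true", "false")) return(as.logical(v))
  num <- suppressWarnings(as.numeric(v))
  if (!is.na(num)) return(num)
  v
}

# Write a TSV report whose header comments record the full resolved
# configuration (provenance: a report re-states everything needed to
# reproduce it).
write_report <- function(df, path, config = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# pepaffinity %s report",
                     as.character(utils::packageVersion("pepaffinity"))), con)
  for (k in names(config)) {
    v <- config[[k]]
    writeLines(sprintf("# %s = %s", k,
                       paste(format(v, trim = TRUE), collapse = ",")), con)
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Parse the "# key = value" header of a report back into a list.
read_report_header <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^# .+ = ", lines, value = TRUE)
  out <- list()
  for (ln in hdr) {
    body <- sub("^# ", "", ln)
    key <- trimws(sub("=.*$", "", body))
    out[[key]] <- type_config_value(trimws(sub("^[^=]*=", "", body)))
  }
  out
}

#' Kinetics stage: experimental free-energy shifts
#'
#' Runs [shifts_table()] on a kinetics table and (optionally) writes the
#' five-numeric-column report.
#'
#' @param kinetics a [kinetic_table()] input (data frame or file); default
#'   the bundled Kemptide table.
#' @param temperature Kelvin.
#' @param out optional output TSV path.
#' @return the shifts data frame, invisibly when writing.
#' @export
run_kinetics <- function(kinetics = reference_tables()$kinetics,
                         temperature = 298.15, out = NULL) {
  sh <- shifts_table(kinetics, temperature)
  if (!is.null(out)) {
    write_report(sh, out, list(stage = "kinetics", temperature = temperature))
    return(invisible(sh))
  }
  sh
}

#' RMSD stage
#'
#' @param ensemble an `ensemble` (or multi-model PDB path).
#' @param selection selection for fit and measurement (default backbone).
#' @param reference_frame reference frame index.
#' @param out optional output TSV path.
#' @return data frame `(time_ps, rmsd)`.
#' @export
run_rmsd <- function(ensemble, selection = "backbone", reference_frame = 1L,
                     out = NULL) {
  if (is.character(ensemble)) ensemble <- read_ensemble(ensemble)
  rs <- rmsd_series(ensemble, reference_frame, selection)
  if (!is.null(out)) {
    write_report(rs, out, list(stage = "rmsd", selection = selection,
                               reference_frame = reference_frame))
    return(invisible(rs))
  }
  rs
}

#' Hydrogen-bond occupancy stage
#'
#' Enumerates candidate donor/acceptor pairs across the partition, computes
#' occupancies and keeps the stable set.
#'
#' @param ensemble an `ensemble`.
#' @param partition a `partition`.
#' @param cutoff hydrogen-bond distance cutoff (A).
#' @param stability_threshold stable-interaction occupancy threshold (%).
#' @param include_over_cutoff keep rows whose conditional mean distance
#'   exceeds the cutoff (comparison mode).
#' @param screen_distance candidate pre-screen distance (A); defaults to
#'   cutoff + 1.5.
#' @param out optional output TSV path.
#' @return stable `hbond_stats` data frame.
#' @export
run_hbonds <- function(ensemble, partition, cutoff = 3.5,
                       stability_threshold = 50,
                       include_over_cutoff = FALSE,
                       screen_distance = cutoff + 1.5, out = NULL) {
  pairs <- enumerate_candidate_pairs(ensemble, partition, screen_distance,
                                     kind = "hbond")
  if (!nrow(pairs))
    stats <- data.frame()
  else
    stats <- stable_interactions(
      hbond_occupancy(ensemble, pairs, cutoff = cutoff),
      threshold = stability_threshold,
      include_over_cutoff = include_over_cutoff)
  if (!is.null(out)) {
    write_report(stats, out,
                 list(stage = "hbonds", cutoff = cutoff,
                      stability_threshold = stability_threshold,
                      include_over_cutoff = include_over_cutoff))
    return(invisible(stats))
  }
  stats
}

#' Hydrophobic-contact stage
#'
#' @inheritParams run_hbonds
#' @param cutoff C-C contact cutoff (A).
#' @export
run_contacts <- function(ensemble, partition, cutoff = 4.5,
                         stability_threshold = 50,
                         screen_distance = cutoff + 1.5, out = NULL) {
  pairs <- enumerate_candidate_pairs(ensemble, partition, screen_distance,
                                     kind = "contact")
  if (!nrow(pairs))
    stats <- data.frame()
  else
    stats <- hydrophobic_contacts(ensemble, pairs, cutoff = cutoff,
                                  stability_threshold = stability_threshold)
  if (!is.null(out)) {
    write_report(stats, out, list(stage = "contacts", cutoff = cutoff,
                                  stability_threshold = stability_threshold))
    return(invisible(stats))
  }
  stats
}

#' MM/GBSA stage over a set of systems
#'
#' @param ensembles named list of `ensemble` objects (names are system ids).
#' @param partitions a single `partition` shared by all systems, or a named
#'   list parallel to `ensembles`.
#' @param settings a [gb_settings()].
#' @param reference_name system used as the ddG reference.
#' @param stride,first_frame,n_snapshots snapshot selection, as in
#'   [ensemble_binding()].
#' @param out optional output TSV path.
#' @return data frame mirroring the component tables: `system`, `dg_mean`,
#'   `dg_sd`, `e_vdw_mean`, `e_ele_mean`, `g_solv_mean`, `ddg`.
#' @export
run_mmgbsa <- function(ensembles, partitions, settings = gb_settings(),
                       reference_name = names(ensembles)[1L],
                       stride = 1L, first_frame = 1L, n_snapshots = NULL,
                       out = NULL) {
  if (inherits(partitions, "partition"))
    partitions <- setNames(rep(list(partitions), length(ensembles)),
                           names(ensembles))
  summaries <- lapply(names(ensembles), function(nm)
    ensemble_binding(ensembles[[nm]], partitions[[nm]], settings,
                     stride = stride, first_frame = first_frame,
                     n_snapshots = n_snapshots))
  names(summaries) <- names(ensembles)
  tab <- data.frame(
    system = names(summaries),
    dg_mean = vapply(summaries, function(s) s$mean[["total"]], numeric(1)),
    dg_sd = vapply(summaries, function(s) s$sd[["total"]], numeric(1)),
    e_vdw_mean = vapply(summaries, function(s) s$mean[["e_vdw"]], numeric(1)),
    e_ele_mean = vapply(summaries, function(s) s$mean[["e_elect"]], numeric(1)),
    g_solv_mean = vapply(summaries, function(s)
      s$mean[["g_polar"]] + s$mean[["g_nonpolar"]], numeric(1)),
    stringsAsFactors = FALSE)
  tab$ddg <- relative_ddg(tab, reference_name)$ddg
  if (!is.null(out)) {
    write_report(tab, out,
                 list(stage = "mmgbsa", reference = reference_name,
                      eps_solvent = settings$eps_solvent,
                      surface_tension = settings$surface_tension,
                      probe_radius = settings$probe_radius,
                      stride = stride, first_frame = first_frame))
    return(invisible(tab))
  }
  tab
}

#' Correlation stage: tautomer grid and full model
#'
#' @param calc_mutants calculated shifts `(system, ddg)` for the mutant
#'   systems; default: the bundled mutant component table.
#' @param calc_short calculated shifts for the shorter peptides; default:
#'   the bundled short-peptide table.
#' @param exp_table experimental shifts; default: [run_kinetics()] on the
#'   bundled kinetics.
#' @param out_fit,out_grid optional output TSV paths for the fit and grid
#'   reports.
#' @return list with `experimental_fit` (the two experimental columns
#'   against each other), `grid` (a `protonation_grid`), `full`
#'   (10-point `correlation_fit`).
#' @export
run_correlation <- function(calc_mutants = NULL, calc_short = NULL,
                            exp_table = NULL, out_fit = NULL,
                            out_grid = NULL) {
  tabs <- reference_tables()
  if (is.null(calc_mutants)) calc_mutants <- tabs$mutant_components
  if (is.null(calc_short)) calc_short <- tabs$short_peptide_components
  if (is.null(exp_table)) exp_table <- run_kinetics(tabs$kinetics)
  exp_fit <- squared_pearson(exp_table$ddg_binding, exp_table$ddg_catalysis,
                             labels = exp_table$peptide)
  grid <- select_histidine_pair(calc_mutants, exp_table)
  full <- full_model(calc_mutants, calc_short, exp_table,
                     grid$best$his18[1L], grid$best$his19[1L])
  if (!is.null(out_grid)) {
    g <- expand.grid(his18 = histidine_tautomers(),
                     his19 = histidine_tautomers(),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    g$r_squared <- mapply(function(a, b) grid$grid[a, b], g$his18, g$his19)
    write_report(g, out_grid, list(stage = "tautomer-grid"))
  }
  if (!is.null(out_fit)) {
    f <- data.frame(
      model = c("experimental-columns", "best-tautomer-pair", "full"),
      r_squared = c(exp_fit$r_squared, grid$best$r_squared[1L],
                    full$r_squared),
      slope = c(exp_fit$slope, grid$best_fit$slope, full$slope),
      intercept = c(exp_fit$intercept, grid$best_fit$intercept,
                    full$intercept),
      n_points = c(exp_fit$n_points, grid$best_fit$n_points, full$n_points))
    write_report(f, out_fit,
                 list(stage = "correlation",
                      best_his18 = grid$best$his18[1L],
                      best_his19 = grid$best$his19[1L]))
  }
  list(experimental_fit = exp_fit, grid = grid, full = full)
}

#' End-to-end replay on bundled tables and synthetic systems
#'
#' Runs the kinetics and correlation stages on the bundled reference tables,
#' then exercises the full structural pipeline (toy complex, synthetic
#' ensemble, hydrogen bonds, RMSD, MM/GBSA) at desk scale, and returns a
#' consolidated report. Deterministic for a fixed seed.
#'
#' @param seed integer seed driving the synthetic stages.
#' @param out_dir optional directory for the stage reports.
#' @param n_frames synthetic ensemble length (default 60).
#' @param hb_target scheduled occupancy (%) for the synthetic contact pair.
#' @return list with `shifts`, `correlation`, `component_check`,
#'   `synthetic` (toy-system results: `mmgbsa` table, `hbonds`, `rmsd`,
#'   realised occupancy).
#' @export
run_replay <- function(seed = 1L, out_dir = NULL, n_frames = 60L,
                       hb_target = 70) {
  tabs <- reference_tables()
  paths <- function(f) if (is.null(out_dir)) NULL else file.path(out_dir, f)
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  shifts <- run_kinetics(tabs$kinetics, out = paths("kinetics.tsv"))
  corr <- run_correlation(exp_table = shifts,
                          out_fit = paths("correlation.tsv"),
                          out_grid = paths("tautomer_grid.tsv"))
  checks <- rbind(check_component_sums(tabs$mutant_components),
                  check_component_sums(tabs$short_peptide_components))
  # synthetic structural pipeline: one charged contact pair
  toy <- make_toy_complex(3, 2,
                          contacts = data.frame(distance = 2.9,
                                                receptor_charge = 0.8,
                                                ligand_charge = -0.8),
                          seed = seed)
  sched <- data.frame(i = toy$contact_atoms$receptor_idx,
                      j = toy$contact_atoms$ligand_idx,
                      occupancy = hb_target)
  ens <- make_ensemble(toy$system,
                       ensemble_recipe(n_frames, sigma = 0.12,
                                       hb_schedule = sched,
                                       seed = seed + 1L))
  hb <- hbond_occupancy(ens, sched[, c("i", "j")])
  rs <- run_rmsd(ens, out = paths("rmsd.tsv"))
  mm <- run_mmgbsa(list(toy = ens), toy$partition,
                   out = paths("mmgbsa.tsv"))
  list(shifts = shifts, correlation = corr, component_check = checks,
       synthetic = list(mmgbsa = mm, hbonds = hb, rmsd = rs,
                        realized_occupancy = hb$occupancy_pct[1L]))
}
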