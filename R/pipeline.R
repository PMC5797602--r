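# Report assembly: thin orchestration over the analysis modules, writing
# TSV/CSV reports whose headers carry package version, config hash and seed
# so that any run is reproducible from (config, seed).

config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  saveRDS(config[order(names(config))], tf)
  unname(tools::md5sum(tf))
}

report_header <- function(seed, config = list()) {
  c(sprintf("complexion %s", as.character(utils::packageVersion("complexion"))),
    sprintf("seed %s", format(seed)),
    sprintf("config %s", config_hash(config)))
}

#' Read a key = value run configuration file
#'
#' Flat TOML-style text: one `key = value` per line, `#` comments; values
#' are parsed as numbers, logicals (`true`/`false`) or strings. CLI flags
#' override file values.
#'
#' @param path config file path.
#' @return named list.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[grepl("=", lines)])
  out <- list()
  for (l in lines) {
    kv <- strsplit(l, "=", fixed = TRUE)[[1]]
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    val <- gsub('^"|"$', "", val)
    parsed <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(parsed)) parsed
      else if (tolower(val) %in% c("true", "false")) tolower(val) == "true"
      else val
  }
  out
}

as_traj <- function(x, dt = 1) {
  if (inherits(x, "trajectory")) x
  else if (inherits(x, "frame")) trajectory(list(x))
  else read_trajectory(x, dt = dt)
}

#' Contact report over a trajectory
#'
#' Writes `contacts.tsv` (time, CN, CN_n) and `contact_crossings.tsv` under
#' `out_dir`.
#'
#' @param x a [trajectory()], [frame()] or structure-file path.
#' @param out_dir output directory.
#' @param spec a [contact_spec()].
#' @param n_aa,n_nt residue counts (auto-counted when `NULL`).
#' @param seed seed recorded in the report header.
#' @return the contact series, invisibly.
#' @export
run_contacts <- function(x, out_dir, spec = contact_spec(), n_aa = NULL,
                         n_nt = NULL, seed = NA) {
  traj <- as_traj(x)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hdr <- report_header(seed, list(op = "contacts", d0 = spec$d0))
  if (!length(traj$frames)) {
    warning("empty trajectory: writing empty contact report", call. = FALSE)
    series <- contact_timeseries(traj, spec)
  } else {
    series <- contact_timeseries(traj, spec, n_aa = n_aa, n_nt = n_nt)
  }
  write_series_tsv(series, file.path(out_dir, "contacts.tsv"), hdr)
  write_series_tsv(attr(series, "crossings"),
                   file.path(out_dir, "contact_crossings.tsv"), hdr)
  invisible(series)
}

#' Ion-inventory report over a trajectory
#'
#' Writes `ions.tsv` (long format: frame, time, species, assignment, count)
#' and `ion_ledger.csv` (per-window shell occupancies with
#' adsorption-corrected charges, mirroring a salt-bridge bookkeeping table:
#' one row block per window of decreasing concentration stage).
#'
#' @inheritParams run_contacts
#' @param shells a [shell_spec()].
#' @param bare named bare charges `c(protein, rna)` for the ledger.
#' @param window window length in frames for stage statistics.
#' @return the inventory series, invisibly.
#' @export
run_ions <- function(x, out_dir, shells = shell_spec(), bare = NULL,
                     window = NULL, seed = NA) {
  traj <- as_traj(x)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hdr <- report_header(seed, list(op = "ions", d0 = shells$d0_adsorption))
  if (!length(traj$frames)) {
    warning("empty trajectory: writing empty ion report", call. = FALSE)
    write_series_tsv(data.frame(), file.path(out_dir, "ions.tsv"), hdr)
    return(invisible(NULL))
  }
  f1 <- traj$frames[[1]]
  sel_p <- build_selection(f1, "protein_all")
  sel_r <- build_selection(f1, "rna_all")
  inv <- inventory_timeseries(traj, sel_p, sel_r, shells, window = window)
  write_series_tsv(inv$series, file.path(out_dir, "ions.tsv"), hdr)
  led <- inv$window_stats
  if (!is.null(bare)) {
    rows <- list()
    for (w in sort(unique(led$window))) {
      sub <- led[led$window == w, ]
      cnt <- lapply(split(sub, sub$species), function(s) {
        stats::setNames(round(s$mean[match(.ASSIGNMENT_LEVELS, s$assignment)]),
                        .ASSIGNMENT_LEVELS)
      })
      mi <- manual_inventory(names(cnt),
                             protein_only = vapply(cnt, `[[`, 0, "protein_only"),
                             rna_only = vapply(cnt, `[[`, 0, "rna_only"),
                             bridging = vapply(cnt, `[[`, 0, "bridging"),
                             condensed = vapply(cnt, `[[`, 0, "condensed"),
                             bulk = vapply(cnt, `[[`, 0, "bulk"),
                             shells = shells)
      lg <- charge_ledger(mi, bare)
      rows[[w]] <- data.frame(window = w, mi$counts,
                              Q_a_protein = lg$Q_a_protein,
                              Q_a_rna = lg$Q_a_rna,
                              screening_percent = lg$screening_percent)
    }
    utils::write.csv(do.call(rbind, rows),
                     file.path(out_dir, "ion_ledger.csv"), row.names = FALSE)
  }
  invisible(inv)
}

#' Lennard-Jones energy report over a trajectory
#'
#' Writes `energy.tsv` (time, U_vdw, pair_count, threshold flags).
#'
#' @inheritParams run_contacts
#' @param params an [lj_table()].
#' @param thresholds flagged energy levels, kcal/mol.
#' @return the energy series, invisibly.
#' @export
run_energy <- function(x, out_dir, params = default_lj_table(),
                       thresholds = c(-50, -100), seed = NA) {
  traj <- as_traj(x)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hdr <- report_header(seed, list(op = "energy", cutoff = params$cutoff))
  if (!length(traj$frames)) {
    warning("empty trajectory: writing empty energy report", call. = FALSE)
    write_series_tsv(data.frame(), file.path(out_dir, "energy.tsv"), hdr)
    return(invisible(NULL))
  }
  f1 <- traj$frames[[1]]
  sel_p <- build_selection(f1, "protein_all")
  sel_r <- build_selection(f1, "rna_all")
  series <- energy_timeseries(traj, sel_p, sel_r, params, thresholds)
  write_series_tsv(series, file.path(out_dir, "energy.tsv"), hdr)
  invisible(series)
}

#' Structural-metric reports over a trajectory
#'
#' Writes one `metric_<name>.tsv` per requested metric.
#'
#' @inheritParams run_contacts
#' @param metrics subset of `c("rmsd_nm", "rg_nm", "sasa_nm2", "assembly_R")`.
#' @return named list of metric series, invisibly.
#' @export
run_metrics <- function(x, out_dir,
                        metrics = c("rmsd_nm", "rg_nm", "assembly_R"),
                        seed = NA) {
  traj <- as_traj(x)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hdr <- report_header(seed, list(op = "metrics"))
  f1 <- traj$frames[[1]]
  sel_p <- build_selection(f1, "protein_all")
  sel_r <- build_selection(f1, "rna_all")
  out <- list()
  for (m in metrics) {
    s <- metric_timeseries(traj, m, sel_protein = sel_p, sel_rna = sel_r)
    write_series_tsv(s, file.path(out_dir, paste0("metric_", m, ".tsv")), hdr)
    out[[m]] <- s
  }
  invisible(out)
}

#' Crystal-survey report
#'
#' Computes the residue ratio and normalized contact number for every entry,
#' applies the `[3, 15]` ratio filter, and writes `survey.csv` plus a
#' min/max summary line over the kept entries.
#'
#' @param frames named list of crystal [frame()]s (or PDB paths).
#' @param out_dir output directory.
#' @param spec a [contact_spec()].
#' @param seed recorded in the header.
#' @return the survey data.frame, invisibly.
#' @export
run_survey <- function(frames, out_dir, spec = contact_spec(), seed = NA) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (id in names(frames)) {
    f <- frames[[id]]
    if (is.character(f)) f <- read_structure(f)
    rep <- normalized_contact_number(f, spec)
    rows[[id]] <- data.frame(id = id, n_aa = rep$n_aa, n_nt = rep$n_nt,
                             CN = rep$CN, CN_n = rep$CN_n,
                             stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  df <- survey_filter(df)
  df <- df[, c("id", "n_aa", "n_nt", "residue_ratio", "CN", "CN_n", "kept")]
  utils::write.csv(df, file.path(out_dir, "survey.csv"), row.names = FALSE)
  kept <- df[df$kept, ]
  summary_line <- sprintf("kept %d/%d entries; CN_n min %.4g max %.4g",
                          nrow(kept), nrow(df),
                          min(kept$CN_n), max(kept$CN_n))
  writeLines(c(paste0("# ", report_header(seed, list(op = "survey"))),
               summary_line),
             file.path(out_dir, "survey_summary.txt"))
  invisible(df)
}

#' Build MC-RW first-contact samples and write them
#'
#' @param chain,partner see [mcrw_sample()].
#' @param out_dir output directory (numbered PDBs + JSON manifest).
#' @param config an [mcrw_config()].
#' @return the [mcrw_sample()] result, invisibly.
#' @export
run_mcrw <- function(chain, partner, out_dir, config = mcrw_config()) {
  res <- mcrw_sample(chain, partner, config)
  write_mcrw_samples(res, out_dir)
  invisible(res)
}

#' Generate synthetic fixtures and their truth files
#'
#' Emits a stem-loop + polyampholyte + planted-ion complex as PDB with a
#' JSON truth file recording the plant and seed.
#'
#' @param out_dir output directory.
#' @param n_nt,n_aa partner sizes.
#' @param plant planted ion counts (see [plant_ions()]).
#' @param seed RNG seed.
#' @return path of the PDB, invisibly.
#' @export
run_simulate <- function(out_dir, n_nt = 40, n_aa = 60,
                         plant = list(Mg = c(rna_only = 9),
                                      Na = c(condensed = 20)),
                         seed = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rna <- make_stemloop(n_nt, seed = seed)
  poly <- make_polyampholyte(n_aa,
                             composition_table(D = min(10, n_aa %/% 6), E = 0,
                                               K = 0, R = 0),
                             placement = list(n_acid_nterm = min(10, n_aa %/% 6),
                                              n_base_nterm = 0,
                                              nterm_span = max(10, n_aa %/% 3)),
                             seed = seed)
  pa <- poly$frame$atoms
  pa[, "x"] <- pa[, "x"] + max(rna$atoms$x) + 4
  pa$serial <- pa$serial + max(rna$atoms$serial)
  pa$resid <- pa$resid + max(rna$atoms$resid)
  cmplx <- frame(rbind(rna$atoms, pa))
  planted <- plant_ions(cmplx, plant, seed = seed + 1L)
  pdb <- file.path(out_dir, "synthetic_complex.pdb")
  write_structure(planted, pdb, "pdb")
  jsonlite::write_json(list(seed = seed, n_nt = n_nt, n_aa = n_aa,
                            plant = lapply(plant, as.list),
                            planted = attr(planted, "planted")),
                       file.path(out_dir, "synthetic_complex.truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(pdb)
}
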