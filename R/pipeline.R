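#' Read a cleavage time-course table
#'
#' Reads the delimited input schema for kinetics fitting: columns `label`,
#' `time_min`, and either `intensity` (raw densitometry) or `fraction`
#' (pre-normalized), plus `inhibitor_uM` and `lexa0_uM`. Each distinct
#' label becomes one [timecourse].
#'
#' @param path CSV file path.
#' @return List of `timecourse` objects.
#' @export
read_timecourse_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("label", "time_min", "inhibitor_uM", "lexa0_uM")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("schema error: missing column(s): ", paste(miss, collapse = ", "))
  has_int <- "intensity" %in% names(tab)
  has_frac <- "fraction" %in% names(tab)
  if (!has_int && !has_frac)
    stop("schema error: missing column(s): intensity (or fraction)")
  lapply(split(tab, tab$label), function(sub) {
    sub <- sub[order(sub$time_min), ]
    if (has_int)
      timecourse(sub$time_min, intensities = sub$intensity,
                 inhibitor_conc = sub$inhibitor_uM[1],
                 lexa0 = sub$lexa0_uM[1], label = sub$label[1])
    else
      timecourse(sub$time_min, fractions = sub$fraction,
                 inhibitor_conc = sub$inhibitor_uM[1],
                 lexa0 = sub$lexa0_uM[1], label = sub$label[1])
  })
}

#' Write simulated time courses as a kinetics-fit input CSV
#'
#' @param tcs List of `timecourse` objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_timecourse_csv <- function(tcs, path) {
  rows <- lapply(tcs, function(tc) {
    data.frame(label = tc$label, time_min = tc$times,
               intensity = tc$intensities, inhibitor_uM = tc$inhibitor_conc,
               lexa0_uM = tc$lexa0, stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' End-to-end beta-turn analysis of a structure
#'
#' Reads a PDB file, detects and classifies beta-turns in every chain, and
#' writes a TSV of all detected turns plus a JSON summary (input checksum,
#' parameters, per-type counts). The JSON echoes the package version so
#' outputs are traceable.
#'
#' @param pdb_path Path to a PDB file.
#' @param output_dir Directory for `turns.tsv` and `turns_summary.json`
#'   (created if needed); `NULL` writes nothing.
#' @param ca_cutoff CA(i)-CA(i+3) cutoff in angstroms (default 7.0).
#' @param exclude_helical Drop double-helical windows?
#' @param chain Optional chain id filter.
#' @param place_hydrogen Construct amide hydrogens for O...H distances?
#' @return List with `turns` (data.frame over all chains, with a `chain`
#'   column) and `summary` (the JSON payload as a list), invisibly when
#'   writing files.
#' @export
run_turn_analysis <- function(pdb_path, output_dir = NULL, ca_cutoff = 7.0,
                              exclude_helical = FALSE, chain = NULL,
                              place_hydrogen = TRUE) {
  if (!file.exists(pdb_path)) stop("input error: cannot read ", pdb_path)
  chains <- read_backbone(pdb_path)
  if (!is.null(chain))
    chains <- Filter(function(ch) ch$chain_id %in% chain, chains)
  turns <- do.call(rbind, lapply(chains, function(ch) {
    t <- detect_turns(ch, ca_cutoff = ca_cutoff,
                      exclude_helical = exclude_helical,
                      place_hydrogen = place_hydrogen)
    if (nrow(t)) cbind(chain = ch$chain_id, t, stringsAsFactors = FALSE)
    else cbind(chain = character(0), t)
  }))
  summary <- list(
    tool = "lexturn", version = as.character(utils::packageVersion("lexturn")),
    input = basename(pdb_path),
    input_md5 = unname(tools::md5sum(pdb_path)),
    parameters = list(ca_cutoff = ca_cutoff,
                      exclude_helical = exclude_helical,
                      chain = if (is.null(chain)) "all" else chain,
                      place_hydrogen = place_hydrogen),
    n_turns = nrow(turns),
    counts_by_type = as.list(table(turns$type)))
  res <- list(turns = turns, summary = summary)
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(turns, file.path(output_dir, "turns.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    jsonlite::write_json(summary, file.path(output_dir, "turns_summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(res))
  }
  res
}

#' End-to-end inhibitor effectiveness analysis
#'
#' Reads a time-course CSV, normalizes and fits each condition's
#' first-order rate constant, fits the effectiveness model across
#' inhibitor:protein ratios, converts the effectiveness to a dissociation
#' constant, and (optionally) attaches bootstrap confidence intervals.
#' Results go to a JSON report embedding version, seed and input checksum.
#'
#' @param csv_path Input CSV (see [read_timecourse_csv()] for the schema).
#' @param output_dir Directory for `effectiveness.json`; `NULL` writes
#'   nothing.
#' @param fix_k0 Optional fixed uninhibited rate constant.
#' @param n_boot Bootstrap replicates (0 disables the bootstrap).
#' @param seed Integer seed for the bootstrap.
#' @return List with `per_condition` (data.frame), `fit`
#'   (`effectiveness_fit`), `ci` (or `NULL`) and `report` (JSON payload).
#' @export
run_effectiveness <- function(csv_path, output_dir = NULL, fix_k0 = NULL,
                              n_boot = 0, seed = 1) {
  if (!file.exists(csv_path)) stop("input error: cannot read ", csv_path)
  tcs <- read_timecourse_csv(csv_path)
  per <- fit_timecourses(tcs)
  lexa0 <- unique(vapply(tcs, function(tc) tc$lexa0, numeric(1)))
  lexa0 <- if (length(lexa0) == 1 && is.finite(lexa0)) lexa0 else NULL
  fit <- fit_effectiveness(per$ratio, per$k, fix_k0 = fix_k0, lexa0 = lexa0)
  ci <- NULL
  if (n_boot > 0)
    ci <- bootstrap_effectiveness(per$ratio, per$k, n_boot = n_boot,
                                  seed = seed, fix_k0 = fix_k0, lexa0 = lexa0)
  report <- list(
    tool = "lexturn", version = as.character(utils::packageVersion("lexturn")),
    input = basename(csv_path), input_md5 = unname(tools::md5sum(csv_path)),
    seed = seed, n_boot = n_boot,
    per_condition = per,
    k0 = fit$k0, k0_se = fit$k0_se, phi = fit$phi, phi_se = fit$phi_se,
    kd_uM = fit$kd, lexa0_uM = fit$lexa0_used,
    converged = fit$converged, no_inhibition = fit$no_inhibition,
    ci = if (!is.null(ci)) as.data.frame(ci$ci) else NULL)
  res <- list(per_condition = per, fit = fit, ci = ci, report = report)
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report, file.path(output_dir, "effectiveness.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "rows")
    return(invisible(res))
  }
  res
}
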