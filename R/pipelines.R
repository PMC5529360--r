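#' End-to-end residue-stability pipeline
#'
#' For each labelled input trajectory: strip hydrogens, best-fit every
#' frame to the original structure (frame 1) on all protein heavy atoms,
#' build the average structure of the aligned frames, compute the
#' per-residue stability profile against it and the focal-distance
#' ordering, trim to the reporting residue range, and accumulate both
#' cumulative curves. Complexes are then ranked by [compare_mutants()].
#' Outputs are plain CSV/JSON (never plots), one `<label>_profile.csv` and
#' `<label>_curve.csv` per complex plus `comparison.json` and
#' `run_metadata.json`; identical inputs and configuration give identical
#' files.
#'
#' @param trajectories named list of [trajectory()] objects, multi-model
#'   PDB paths, or fixture prefixes ([write_fixture()]).
#' @param out_dir output directory (created if needed).
#' @param focal_residue_number focal residue (default 790, EGFR T790).
#' @param trim inclusive residue-number range reported (default
#'   `c(716, 976)`, first to last helix of the EGFR kinase domain).
#' @param statistic which stability component drives the comparison,
#'   `"mean"` (default) or `"std"`; both curves are always written.
#' @param k_window leading rank positions averaged by the comparison.
#' @param atom_mask optional fit mask of atom ids (default: all protein
#'   heavy atoms).
#' @return Invisibly, a list with per-label `profiles`, `orderings`,
#'   `curves` (mean and std) and the `comparison` data frame.
#' @export
run_stability_pipeline <- function(trajectories, out_dir,
                                   focal_residue_number = 790L,
                                   trim = c(716L, 976L),
                                   statistic = c("mean", "std"),
                                   k_window = 50L,
                                   atom_mask = NULL) {
  statistic <- match.arg(statistic)
  if (length(trajectories) == 0L) stop("no input trajectories",
                                       call. = FALSE)
  if (is.null(names(trajectories)) || any(names(trajectories) == "")) {
    stop("trajectories must be a named list", call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  profiles <- orderings <- curves_mean <- curves_std <- list()
  for (label in names(trajectories)) {
    traj <- load_trajectory_input(trajectories[[label]], label)
    heavy <- strip_hydrogens(traj)
    aligned <- align_trajectory(heavy, get_frame(heavy, 1L),
                                atom_mask = atom_mask)
    reference <- average_structure(aligned)
    profile <- stability_profile(aligned, reference)
    ordering <- focal_ordering(aligned, focal_residue_number)
    profile_t <- trim_to_range(profile, trim[1L], trim[2L])
    ordering_t <- trim_to_range(ordering, trim[1L], trim[2L])
    cm <- cumulative_average(profile_t, ordering_t, "mean")
    cs <- cumulative_average(profile_t, ordering_t, "std")
    profiles[[label]] <- profile_t
    orderings[[label]] <- ordering_t
    curves_mean[[label]] <- cm
    curves_std[[label]] <- cs
    prof_out <- merge(profile_t, ordering_t, by = "residue_number")
    prof_out <- prof_out[order(prof_out$rank),
                         c("residue_number", "residue_name", "K",
                           "stability_mean", "stability_std",
                           "dist_to_focal", "rank")]
    names(prof_out) <- c("residue_number", "residue_name", "K",
                         "stability_mean_A", "stability_std_A",
                         "dist_to_focal_A", "rank")
    utils::write.csv(prof_out,
                     file.path(out_dir, paste0(label, "_profile.csv")),
                     row.names = FALSE)
    curve_out <- data.frame(k = cm$k, residue_number = cm$residue_number,
                            cumulative_mean_A = cm$cumulative,
                            cumulative_std_A = cs$cumulative)
    utils::write.csv(curve_out,
                     file.path(out_dir, paste0(label, "_curve.csv")),
                     row.names = FALSE)
  }
  curves <- if (statistic == "mean") curves_mean else curves_std
  comparison <- compare_mutants(curves, k_window)
  jsonlite::write_json(
    list(statistic = statistic, k_window = attr(comparison, "k_window"),
         ordering_least_to_most_stable = comparison),
    file.path(out_dir, "comparison.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows")
  write_run_metadata(out_dir, list(
    pipeline = "stability", labels = names(trajectories),
    focal_residue_number = focal_residue_number, trim = trim,
    statistic = statistic, k_window = k_window))
  invisible(list(profiles = profiles, orderings = orderings,
                 curves_mean = curves_mean, curves_std = curves_std,
                 comparison = comparison))
}

load_trajectory_input <- function(x, label) {
  if (inherits(x, "Trajectory")) return(x)
  if (!is.character(x) || length(x) != 1L) {
    stop("input '", label, "' must be a Trajectory or a path",
         call. = FALSE)
  }
  if (file.exists(paste0(x, ".json"))) return(read_fixture(x))
  read_multimodel_pdb(x)
}

#' End-to-end cohort pipeline
#'
#' Validates the cohort, builds a contingency table per requested
#' attribute with exact and printed-style proportions (plus a two-sided
#' Fisher's exact p-value for the 2x2 case), tabulates outcome by
#' mutation class and TKI when exposure columns are present, and runs
#' every attribute evaluator. Writes `report.json`, one
#' `ranking_<evaluator>.csv` per evaluator, and `run_metadata.json`.
#'
#' @param cohort a cohort `data.frame` or CSV path ([load_cohort()]).
#' @param out_dir output directory.
#' @param table_attributes attributes to cross-tabulate against the
#'   outcome (default bone metastasis and initial mutation class).
#' @param evaluators ranking evaluators to run (default: all six).
#' @param relieff_k,seed passed to [rank_attributes()].
#' @return Invisibly, a list with `cohort`, `tables` (each with counts,
#'   proportions, and p-value where 2x2), `mutation_tki` (or `NULL`) and
#'   `rankings`.
#' @export
run_cohort_pipeline <- function(cohort, out_dir,
                                table_attributes = c("bone_met",
                                                     "initial_egfr_mutation"),
                                evaluators = RANKING_EVALUATORS,
                                relieff_k = 10L, seed = 1L) {
  if (is.character(cohort)) cohort <- load_cohort(cohort)
  else cohort <- validate_cohort(cohort)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tables <- lapply(table_attributes, function(a) {
    tab <- build_contingency(cohort, a)
    rows <- rownames(tab)
    props <- lapply(rows, function(r) proportion(tab, r, 1L))
    names(props) <- rows
    p <- if (all(dim(tab) == 2L)) fisher_exact_two_sided(tab) else NULL
    list(attribute = a, counts = tab, proportions = props,
         fisher_p = p)
  })
  names(tables) <- table_attributes
  mut_tki <- if (all(paste0("tki_", TKI_LEVELS) %in% names(cohort))) {
    mutation_tki_table(cohort)
  }
  rankings <- lapply(evaluators, function(ev) {
    rk <- rank_attributes(cohort, ev, relieff_k = relieff_k, seed = seed)
    utils::write.csv(rk, file.path(out_dir,
                                   paste0("ranking_", ev, ".csv")),
                     row.names = FALSE)
    rk
  })
  names(rankings) <- evaluators
  report <- list(
    n_patients = nrow(cohort),
    outcome_positive = sum(cohort$t790m),
    outcome_rate_pct = round_half_up(100 * mean(cohort$t790m), 1L),
    tables = lapply(tables, function(tb) list(
      attribute = tb$attribute,
      counts = as.data.frame(as.table(unclass(tb$counts))),
      proportions = tb$proportions,
      fisher_p = tb$fisher_p)),
    mutation_tki = mut_tki,
    ranking_top3 = lapply(rankings, function(rk)
      utils::head(rk$attribute, 3L))
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  write_run_metadata(out_dir, list(
    pipeline = "cohort", n_patients = nrow(cohort),
    table_attributes = table_attributes, evaluators = evaluators,
    relieff_k = relieff_k, seed = seed))
  invisible(list(cohort = cohort, tables = tables,
                 mutation_tki = mut_tki, rankings = rankings))
}

# provenance stamp shared by both pipelines: config echo, a deterministic
# config checksum, and the package version
write_run_metadata <- function(out_dir, config) {
  json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  bytes <- utf8ToInt(as.character(json))
  checksum <- sprintf("%08x",
                      sum(bytes * (seq_along(bytes) %% 997)) %% 2^31)
  jsonlite::write_json(
    list(config = config, config_checksum = checksum,
         package = "resiflex",
         version = as.character(utils::packageVersion("resiflex"))),
    file.path(out_dir, "run_metadata.json"),
    auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}
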