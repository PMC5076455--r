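# End-to-end workflows: the aging drug screen (expression -> age groups ->
# DE -> per-sample PAS -> filter -> GeroScore ranking -> shortlist) and the
# compound-perturbation pathway analysis with plate-matched vehicle controls.

#' Run configuration for the pipeline workflows
#'
#' @param expression,annotations,pathways,drugs paths to the four input TSVs
#'   (`drugs` may be `NULL` for perturbation-only runs).
#' @param alpha FDR significance threshold; default 0.05.
#' @param log_base PAS logarithm base; default 10.
#' @param epsilon CNR floor; default `1e-6`.
#' @param young_min,young_max,old_min donor-age group bounds in years;
#'   defaults 15, 30, 60.
#' @param shortlist_n size of the candidate shortlist; default 10.
#' @param aggregate GeroScore aggregation across samples, `"mean"` or
#'   `"median"`.
#' @param seed optional integer seed recorded in the manifest (the screen
#'   itself is deterministic).
#' @param out_dir output directory; created if absent.
#' @return a list of class `run_config`.
#' @export
run_config <- function(expression, annotations, pathways, drugs = NULL,
                       alpha = 0.05, log_base = 10, epsilon = 1e-6,
                       young_min = 15, young_max = 30, old_min = 60,
                       shortlist_n = 10, aggregate = "mean", seed = NULL,
                       out_dir = ".") {
  stopifnot(alpha >= 0, alpha < 1, log_base > 1, epsilon > 0)
  structure(list(expression = expression, annotations = annotations,
                 pathways = pathways, drugs = drugs, alpha = alpha,
                 log_base = log_base, epsilon = epsilon,
                 young_min = young_min, young_max = young_max,
                 old_min = old_min, shortlist_n = shortlist_n,
                 aggregate = aggregate, seed = seed, out_dir = out_dir),
            class = "run_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
}

log_stage <- function(name, ...) {
  message(sprintf("[%s] %s", name, paste0(...)))
}

write_manifest <- function(config, files, path) {
  inputs <- Filter(Negate(is.null),
                   config[c("expression", "annotations", "pathways", "drugs")])
  manifest <- list(
    parameters = config[setdiff(names(unclass(config)), names(inputs))],
    inputs = lapply(inputs, function(f)
      list(path = f, md5 = unname(tools::md5sum(f)))),
    outputs = files)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Run the aging drug screen
#'
#' Reads the four input tables, assigns old (case) vs young (reference)
#' donor groups, computes per-sample pathway activation profiles, drops
#' insignificantly perturbed samples, scores and ranks the drug database,
#' and writes the profile, filtered profile, score table, shortlist and a
#' reproducibility manifest (parameters plus input checksums) to
#' `config$out_dir`.
#'
#' @param config a `run_config` with a non-NULL `drugs` path.
#' @return invisibly, a list with `design`, `profile`, `filtered`, `table`
#'   and `shortlist`.
#' @export
run_aging_screen <- function(config) {
  if (is.null(config$drugs))
    stop("the aging screen needs a drug database (config$drugs)", call. = FALSE)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  mat <- stage("read", read_expression_table(config$expression))
  ann <- stage("read", read_sample_annotations(config$annotations))
  pdb <- stage("read", read_pathway_db(config$pathways))
  ddb <- stage("read", read_drug_db(config$drugs))
  design <- stage("age-groups",
                  assign_age_groups(ann, config$young_min, config$young_max,
                                    config$old_min))
  log_stage("age-groups", length(design$case_ids), " old vs ",
            length(design$reference_ids), " young samples")
  profile <- stage("pas", suppressWarnings(
    per_sample_pas_profile(mat, design, pdb, alpha = config$alpha,
                           log_base = config$log_base,
                           epsilon = config$epsilon)))
  filtered <- stage("filter", filter_zero_pas_samples(profile))
  tab <- stage("score", geroscore_table(ddb, filtered, pdb,
                                        aggregate = config$aggregate))
  top <- stage("shortlist",
               shortlist(tab, min(config$shortlist_n, nrow(tab))))
  out <- function(f) file.path(config$out_dir, f)
  files <- list(pas_profile = out("pas_profile.tsv"),
                pas_flags = out("pas_no_coverage.tsv"),
                pas_profile_filtered = out("pas_profile_filtered.tsv"),
                geroscore_table = out("geroscore_table.tsv"),
                shortlist = out("shortlist.tsv"))
  write_pas_profile(profile, files$pas_profile, files$pas_flags)
  write_pas_profile(filtered, files$pas_profile_filtered)
  write_geroscore_table(tab, files$geroscore_table)
  write_tsv(data.frame(rank = seq_along(top), drug_id = top), files$shortlist)
  write_manifest(config, files, out("manifest.json"))
  log_stage("done", "shortlist: ", paste(top, collapse = ", "))
  invisible(list(design = design, profile = profile, filtered = filtered,
                 table = tab, shortlist = top))
}

#' Run the compound-perturbation pathway analysis
#'
#' Builds a plate-matched case/vehicle design per compound, computes the
#' group-level pathway activation profile of each, and drops compounds whose
#' profile is all-zero (insignificantly perturbed). Compounds lacking case
#' wells or same-plate vehicle wells are skipped with a message.
#'
#' @param config a `run_config` (the `drugs` path is not used).
#' @param compounds character vector of perturbagen names to analyze.
#' @param dose,duration,vehicle,cell_type passed to
#'   [build_plate_matched_design()].
#' @return invisibly, a `pas_profile` with one row per retained compound.
#' @export
run_perturbation_analysis <- function(config, compounds, dose = NULL,
                                      duration = NULL, vehicle = "DMSO",
                                      cell_type = NULL) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  mat <- stage("read", read_expression_table(config$expression))
  ann <- stage("read", read_sample_annotations(config$annotations))
  pdb <- stage("read", read_pathway_db(config$pathways))
  designs <- stage("lincs-design",
                   build_all_designs(ann, compounds, dose = dose,
                                     duration = duration, vehicle = vehicle,
                                     cell_type = cell_type))
  rows <- lapply(designs, function(d) stage("pas", suppressWarnings(
    group_pas_profile(mat, d, pdb, alpha = config$alpha,
                      log_base = config$log_base, epsilon = config$epsilon))))
  values <- do.call(rbind, lapply(rows, unclass))
  flags <- do.call(rbind, lapply(rows, attr, "no_coverage"))
  rownames(values) <- rownames(flags) <- names(designs)
  profile <- new_pas_profile(values, flags)
  keep <- rowSums(profile != 0) > 0
  if (any(!keep))
    log_stage("filter", "excluding insignificantly perturbed compound(s): ",
              paste(rownames(profile)[!keep], collapse = ", "))
  if (!any(keep))
    stop("[filter] every compound has an all-zero pathway profile",
         call. = FALSE)
  profile <- new_pas_profile(values[keep, , drop = FALSE],
                             flags[keep, , drop = FALSE])
  write_pas_profile(profile,
                    file.path(config$out_dir, "perturbation_pas.tsv"),
                    file.path(config$out_dir, "perturbation_no_coverage.tsv"))
  write_designs(designs, file.path(config$out_dir, "perturbation_designs.tsv"))
  invisible(profile)
}

#' Write a simulated input bundle to disk
#'
#' Emits the four TSVs consumed by [run_aging_screen()] plus a ground-truth
#' JSON (planted pathways, planted drug, seed) for a simulated screen.
#'
#' @param config a `sim_config`.
#' @param n_decoys decoy drugs in the simulated database; default 30.
#' @param out_dir output directory.
#' @return invisibly, the named list of file paths written.
#' @export
write_simulated_bundle <- function(config, n_decoys = 30, out_dir = ".") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  db <- simulate_pathway_db(config)
  sim <- simulate_expression(config, db)
  drugs <- simulate_drug_db(db, config$planted_pathways, n_decoys = n_decoys,
                            seed = config$seed + 2L)
  # annotation ages mirror the planted case/reference contrast so that
  # assign_age_groups() reconstructs the simulated design
  ann <- data.frame(
    sample_id = colnames(sim$matrix),
    age = ifelse(colnames(sim$matrix) %in% sim$design$case_ids, 70, 25))
  files <- list(expression = file.path(out_dir, "expression.tsv"),
                annotations = file.path(out_dir, "annotations.tsv"),
                pathways = file.path(out_dir, "pathways.tsv"),
                drugs = file.path(out_dir, "drugs.tsv"),
                truth = file.path(out_dir, "truth.json"))
  write_expression_table(sim$matrix, files$expression)
  write_sample_annotations(ann, files$annotations)
  write_pathway_db(db, files$pathways)
  write_drug_db(drugs$drug_db, files$drugs)
  jsonlite::write_json(list(planted_pathways = as.list(config$planted_pathways),
                            planted_drug = drugs$planted_drug_id,
                            seed = config$seed),
                       files$truth, auto_unbox = TRUE, digits = NA)
  invisible(files)
}
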