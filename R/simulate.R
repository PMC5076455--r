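# Synthetic data with planted structure: log-normal expression intensities,
# disjoint pathway membership, a planted age-like contrast on selected
# pathways, and a drug database containing one ideal geroprotector among
# random decoys. Every generator is a pure function of its configuration
# (including the seed), so reruns are byte-identical.

#' Simulation configuration
#'
#' The defaults describe the package's standard recovery benchmark: 2000
#' genes, 10 disjoint pathways of 15 genes, 3 planted pro-aging pathways at
#' fold change 4, log-normal noise with sd 0.1 on the log10 scale, and 8
#' case vs 8 reference samples.
#'
#' @param n_genes total number of genes.
#' @param n_pathways number of pathways; membership is disjoint, so
#'   `n_pathways * genes_per_pathway <= n_genes` is required.
#' @param genes_per_pathway members per pathway.
#' @param n_reference,n_case samples per group.
#' @param planted_pathways named numeric vector mapping pathway ids (of the
#'   form `"PW01"`, `"PW02"`, ...) to fold changes > 0. The fold change is
#'   applied in the direction of each member's ARR sign, so a planted
#'   pathway's expected PAS is positive. Default: first three pathways at
#'   fold change 4.
#' @param noise_sd sd of the Gaussian noise on the log10 scale.
#' @param baseline_log10_mean mean log10 intensity; default 2 (intensities
#'   around 100).
#' @param seed integer RNG seed.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000, n_pathways = 10, genes_per_pathway = 15,
                       n_reference = 8, n_case = 8,
                       planted_pathways = c(PW01 = 4, PW02 = 4, PW03 = 4),
                       noise_sd = 0.1, baseline_log10_mean = 2, seed = 1) {
  stopifnot(n_genes >= 1, n_pathways >= 1, genes_per_pathway >= 1,
            n_reference >= 1, n_case >= 1, noise_sd >= 0)
  if (any(planted_pathways <= 0))
    stop("fold changes must be positive", call. = FALSE)
  structure(list(n_genes = as.integer(n_genes),
                 n_pathways = as.integer(n_pathways),
                 genes_per_pathway = as.integer(genes_per_pathway),
                 n_reference = as.integer(n_reference),
                 n_case = as.integer(n_case),
                 planted_pathways = planted_pathways,
                 noise_sd = noise_sd,
                 baseline_log10_mean = baseline_log10_mean,
                 seed = as.integer(seed)),
            class = "sim_config")
}

sim_gene_names <- function(n) sprintf("G%04d", seq_len(n))
sim_pathway_names <- function(n) sprintf("PW%02d", seq_len(n))

#' Simulate a pathway database
#'
#' Pathways get disjoint member sets; PAR is drawn uniformly from \{-1, +1\}
#' except for planted pathways, which are fixed to PAR = +1 (pro-aging) so
#' the planted contrast reads as an aging signature; member ARR weights are
#' drawn uniformly from \{+1, -1, +0.5, -0.5\}.
#'
#' @param config a `sim_config`.
#' @return a `pathway_db`.
#' @export
simulate_pathway_db <- function(config) {
  with(config, {
    if (n_pathways * genes_per_pathway > n_genes)
      stop("disjoint membership needs n_pathways * genes_per_pathway <= n_genes",
           call. = FALSE)
    missing_planted <- setdiff(names(planted_pathways),
                               sim_pathway_names(n_pathways))
    if (length(missing_planted) > 0L)
      stop("planted pathway id(s) outside the database: ",
           paste(missing_planted, collapse = ", "), call. = FALSE)
    set.seed(seed)
    genes <- sim_gene_names(n_genes)
    ids <- sim_pathway_names(n_pathways)
    par <- sample(c(-1L, 1L), n_pathways, replace = TRUE)
    par[ids %in% names(planted_pathways)] <- 1L
    pathways <- lapply(seq_len(n_pathways), function(i) {
      members_idx <- ((i - 1) * genes_per_pathway + 1):(i * genes_per_pathway)
      list(pathway_id = ids[i], name = ids[i], par = par[i],
           members = setNames(sample(c(1, -1, 0.5, -0.5), genes_per_pathway,
                                     replace = TRUE),
                              genes[members_idx]))
    })
    pathway_db(pathways)
  })
}

#' Simulate an expression matrix with a planted case/reference contrast
#'
#' Reference samples draw every gene from `10^(baseline + N(0, noise_sd))`.
#' Case samples use the same model, but members of planted pathways have
#' their mean multiplied by `fold_change^sign(ARR)`: activator members go up
#' and repressor members down by the same factor, so the pathway's expected
#' PAS is positive (the planted pathways behave as activated pro-aging
#' pathways in the old group).
#'
#' @param config a `sim_config`.
#' @param db the `pathway_db` from [simulate_pathway_db()] under the same
#'   config.
#' @return a list with elements `matrix` (expression matrix, case samples
#'   `CASE_1`, ... and reference samples `REF_1`, ...) and `design` (the
#'   corresponding `group_design`).
#' @export
simulate_expression <- function(config, db) {
  with(config, {
    set.seed(seed + 1L)
    genes <- sim_gene_names(n_genes)
    n_samples <- n_case + n_reference
    samples <- c(paste0("CASE_", seq_len(n_case)),
                 paste0("REF_", seq_len(n_reference)))
    log_mu <- matrix(baseline_log10_mean, nrow = n_genes, ncol = n_samples,
                     dimnames = list(genes, samples))
    for (pid in names(planted_pathways)) {
      members <- db$pathways[[pid]]$members
      shift <- sign(members) * log10(planted_pathways[[pid]])
      log_mu[names(members), seq_len(n_case)] <-
        log_mu[names(members), seq_len(n_case)] + shift
    }
    values <- 10^(log_mu + matrix(stats::rnorm(n_genes * n_samples,
                                               sd = noise_sd),
                                  nrow = n_genes))
    validate_expression_matrix(values)
    list(matrix = values,
         design = group_design("case_vs_reference",
                               case_ids = samples[seq_len(n_case)],
                               reference_ids = samples[-seq_len(n_case)]))
  })
}

#' Simulate a drug database with one planted ideal geroprotector
#'
#' The planted drug targets every member of the planted pro-aging
#' (PAR = +1) pathways with the DTI that opposes the planted activation:
#' it inhibits activator members (DTI +1 on ARR > 0) and activates
#' repressor members (DTI -1 on ARR < 0), so each of its targets
#' contributes positively to its GeroScore under the planted PAS sign.
#' Decoy drugs get the same number of targets, drawn uniformly from all
#' pathway member genes with uniform random DTI.
#'
#' @param db a `pathway_db`.
#' @param planted_pathways character vector of planted pathway ids (or a
#'   named fold-change vector; only the names are used).
#' @param n_decoys number of decoy drugs.
#' @param seed integer RNG seed.
#' @return a list with elements `drug_db` and `planted_drug_id`.
#' @export
simulate_drug_db <- function(db, planted_pathways, n_decoys, seed = 1) {
  ids <- if (is.null(names(planted_pathways))) as.character(planted_pathways)
         else names(planted_pathways)
  missing <- setdiff(ids, pathway_ids(db))
  if (length(missing) > 0L)
    stop("planted pathway(s) absent from the database: ",
         paste(missing, collapse = ", "), call. = FALSE)
  pro_aging <- ids[vapply(db$pathways[ids], function(p) p$par == 1L, logical(1))]
  if (length(pro_aging) == 0L)
    stop("no planted pro-aging (PAR = +1) pathway to build the ideal drug from",
         call. = FALSE)
  set.seed(seed)
  members <- unlist(lapply(db$pathways[pro_aging], function(p) p$members))
  names(members) <- unlist(lapply(db$pathways[pro_aging],
                                  function(p) names(p$members)))
  members <- members[!duplicated(names(members))]
  ideal <- list(drug_id = "GERO_IDEAL",
                targets = setNames(ifelse(members > 0, 1, -1), names(members)))
  all_genes <- unique(unlist(lapply(db$pathways, function(p) names(p$members))))
  n_targets <- length(ideal$targets)
  decoys <- lapply(seq_len(n_decoys), function(i) {
    k <- min(n_targets, length(all_genes))
    list(drug_id = sprintf("DECOY_%02d", i),
         targets = setNames(sample(c(-1, 1), k, replace = TRUE),
                            sample(all_genes, k)))
  })
  list(drug_db = drug_db(c(list(ideal), decoys)),
       planted_drug_id = "GERO_IDEAL")
}

#' End-to-end planted-geroprotector recovery benchmark
#'
#' For each replicate seed: simulate a pathway database, an expression
#' matrix with the planted contrast, and a drug database with one ideal
#' geroprotector among decoys; run differential expression, per-sample PAS,
#' the zero-PAS sample filter and GeroScore ranking; record whether the
#' planted drug ranks first. Replicates where the filter removes every
#' sample count as failures.
#'
#' @param config a `sim_config`; its `seed` offsets the replicate seeds.
#' @param n_decoys decoy drugs per replicate; default 30.
#' @param n_seeds number of replicates; default 100.
#' @param alpha FDR threshold of the differential expression; default 0.05.
#' @return the recovery rate in \[0, 1\] (fraction of replicates with the
#'   planted drug at rank 1), with the per-replicate ranks attached as
#'   attribute `ranks` (NA where scoring was impossible).
#' @export
run_recovery_benchmark <- function(config = sim_config(), n_decoys = 30,
                                   n_seeds = 100, alpha = 0.05) {
  ranks <- rep(NA_integer_, n_seeds)
  for (s in seq_len(n_seeds)) {
    cfg <- config
    cfg$seed <- config$seed + 1000L * s
    db <- simulate_pathway_db(cfg)
    sim <- simulate_expression(cfg, db)
    drugs <- simulate_drug_db(db, cfg$planted_pathways, n_decoys = n_decoys,
                              seed = cfg$seed + 2L)
    profile <- suppressWarnings(
      per_sample_pas_profile(sim$matrix, sim$design, db, alpha = alpha))
    filtered <- tryCatch(suppressMessages(filter_zero_pas_samples(profile)),
                         error = function(e) NULL)
    if (is.null(filtered)) next
    tab <- geroscore_table(drugs$drug_db, filtered, db)
    ranks[s] <- tab$rank[tab$drug_id == drugs$planted_drug_id]
  }
  structure(mean(!is.na(ranks) & ranks == 1L), ranks = ranks)
}
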