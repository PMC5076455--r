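# GeroScore: per-drug score summing, over drug targets t and pathways p,
# DTI_dt * NII_tp * ARR_tp * PAS_p * PAR_p. High scores mark drugs predicted
# to push an aged signalome toward the young state: inhibiting (DTI +1)
# activator members (ARR > 0) of activated (PAS > 0) pro-aging (PAR +1)
# pathways contributes positively.

#' Node involvement index
#'
#' 1 if the target gene is a member of the pathway, 0 otherwise. Matching is
#' case-insensitive.
#'
#' @param target_gene gene symbol.
#' @param pathway a single pathway record from a `pathway_db`.
#' @return integer 0 or 1.
#' @export
nii <- function(target_gene, pathway) {
  as.integer(norm_gene(target_gene) %in% names(pathway$members))
}

# Gene x pathway weight matrix: W[t, p] = ARR of gene t in pathway p when t
# is a member (NII = 1), 0 otherwise. Shared by geroscore() and
# geroscore_table() so scoring is a pair of matrix products.
pathway_weight_matrix <- function(db) {
  genes <- sort(unique(unlist(lapply(db$pathways, function(p) names(p$members)))))
  W <- matrix(0, nrow = length(genes), ncol = length(db$pathways),
              dimnames = list(genes, pathway_ids(db)))
  for (j in seq_along(db$pathways)) {
    members <- db$pathways[[j]]$members
    W[names(members), j] <- members
  }
  W
}

db_par_vector <- function(db) {
  vapply(db$pathways, function(p) as.numeric(p$par), numeric(1))
}

#' GeroScore of one drug for one case entity
#'
#' \deqn{GS_d = \sum_t DTI_{dt} \sum_p NII_{tp} \, ARR_{tp} \, PAS_p \, PAR_p}
#' where t runs over the drug's annotated targets and p over the pathway
#' database. Targets absent from every pathway contribute 0.
#'
#' @param drug a single drug record from a `drug_db`.
#' @param pas_row named numeric vector of PAS values covering every pathway
#'   of `db` (one case sample or group).
#' @param db `pathway_db`.
#' @return a scalar score.
#' @export
geroscore <- function(drug, pas_row, db) {
  missing <- setdiff(pathway_ids(db), names(pas_row))
  if (length(missing) > 0L)
    stop("PAS row lacks pathway(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (length(drug$targets) == 0L) return(0)
  W <- pathway_weight_matrix(db)
  weighted_pas <- as.numeric(pas_row[colnames(W)]) * db_par_vector(db)
  idx <- match(names(drug$targets), rownames(W))
  hit <- !is.na(idx)
  if (!all(hit))
    message(sprintf("drug '%s': %d target(s) absent from every pathway",
                    drug$drug_id, sum(!hit)))
  if (!any(hit)) return(0)
  sum(drug$targets[hit] * (W[idx[hit], , drop = FALSE] %*% weighted_pas))
}

#' Score and rank a drug database against a PAS profile
#'
#' Evaluates the GeroScore of every drug for every case sample of the
#' profile, aggregates across samples, and ranks drugs by descending
#' aggregate score with ties broken lexicographically by drug id.
#'
#' @param drug_db a `drug_db`.
#' @param profile a per-sample `pas_profile`, already passed through
#'   [filter_zero_pas_samples()].
#' @param db `pathway_db` the profile was computed against.
#' @param aggregate `"mean"` (default) or `"median"` across samples.
#' @return a data.frame of class `geroscore_table`, sorted by rank, with
#'   columns `drug_id`, `aggregate_score`, `rank`, then one column per
#'   sample.
#' @export
geroscore_table <- function(drug_db, profile, db, aggregate = c("mean", "median")) {
  aggregate <- match.arg(aggregate)
  if (length(drug_db$drugs) == 0L) stop("drug database is empty", call. = FALSE)
  missing <- setdiff(pathway_ids(db), colnames(profile))
  if (length(missing) > 0L)
    stop("profile lacks pathway(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  W <- pathway_weight_matrix(db)
  # drugs x genes DTI matrix
  D <- matrix(0, nrow = length(drug_db$drugs), ncol = nrow(W),
              dimnames = list(names(drug_db$drugs), rownames(W)))
  for (d in drug_db$drugs) {
    hit <- names(d$targets)[names(d$targets) %in% rownames(W)]
    D[d$drug_id, hit] <- d$targets[hit]
  }
  weighted_pas <- t(unclass(profile)[, colnames(W), drop = FALSE]) *
    db_par_vector(db)                      # pathways x samples, PAR applied
  scores <- D %*% W %*% weighted_pas       # drugs x samples
  agg <- switch(aggregate,
                mean = rowMeans(scores),
                median = apply(scores, 1, stats::median))
  ord <- order(-agg, rownames(scores))
  res <- data.frame(drug_id = rownames(scores)[ord],
                    aggregate_score = as.numeric(agg[ord]),
                    rank = seq_along(ord),
                    scores[ord, , drop = FALSE],
                    check.names = FALSE, row.names = NULL)
  class(res) <- c("geroscore_table", "data.frame")
  res
}

#' Shortlist the top-ranked drugs
#'
#' @param table a `geroscore_table`.
#' @param n number of drugs to keep; default 10.
#' @return character vector of the first `n` drug ids by rank.
#' @export
shortlist <- function(table, n = 10) {
  if (n > nrow(table))
    stop(sprintf("cannot shortlist %d drugs from a table of %d", n,
                 nrow(table)), call. = FALSE)
  table$drug_id[order(table$rank)][seq_len(n)]
}

#' Combine GeroScore tables from independently analyzed datasets
#'
#' When several expression datasets are screened separately (e.g. distinct
#' cell types or platforms), each produces its own score table. The combined
#' rating z-scores each table's aggregate scores (so datasets with different
#' score scales weigh equally) and averages the z-scores per drug across the
#' tables it appears in, re-ranking by the combined value.
#'
#' @param tables list of `geroscore_table` objects.
#' @return a data.frame with columns `drug_id`, `combined_score`,
#'   `n_datasets`, `rank`, sorted by rank (ties broken lexicographically).
#' @export
combine_geroscore_tables <- function(tables) {
  if (length(tables) == 0L) stop("no tables to combine", call. = FALSE)
  zs <- lapply(tables, function(tab) {
    s <- tab$aggregate_score
    z <- if (stats::sd(s) == 0) rep(0, length(s)) else (s - mean(s)) / stats::sd(s)
    setNames(z, tab$drug_id)
  })
  ids <- sort(unique(unlist(lapply(zs, names))))
  zmat <- vapply(zs, function(z) z[ids], numeric(length(ids)))
  zmat <- matrix(zmat, nrow = length(ids), dimnames = list(ids, NULL))
  combined <- rowMeans(zmat, na.rm = TRUE)
  n_ds <- rowSums(!is.na(zmat))
  ord <- order(-combined, ids)
  data.frame(drug_id = ids[ord], combined_score = as.numeric(combined[ord]),
             n_datasets = as.integer(n_ds[ord]), rank = seq_along(ord),
             row.names = NULL)
}

#' Write a GeroScore table as TSV
#' @param table a `geroscore_table`.
#' @param path output TSV path.
#' @export
write_geroscore_table <- function(table, path) {
  write_tsv(as.data.frame(table), path)
}
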