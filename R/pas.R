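# Pathway Activation Strength (PAS): a signed per-pathway statistic summing
# the activator/repressor-weighted log expression ratios of significantly
# changed member genes. Positive PAS marks an up-regulated pathway, negative
# a down-regulated one.

#' Pathway activation strength for one pathway
#'
#' \deqn{PAS_p = \sum_{n \in p} ARR_n \cdot BTIF_n \cdot \log_{b}(CNR_n)}
#' over the pathway's member genes measured in the data: ARR is the member's
#' signed activator/repressor weight, BTIF the binary significance flag of
#' the case-reference comparison, CNR the case-to-normal expression ratio,
#' and b the logarithm base (10 by default).
#'
#' @param de a `de_result` data.frame, or any list/data.frame carrying
#'   parallel `gene`, `cnr` and `btif` vectors (e.g. per-sample ratios paired
#'   with group-level flags).
#' @param pathway a single pathway record from a `pathway_db`.
#' @param log_base base of the logarithm; default 10.
#' @param warn_missing warn when member genes are absent from the data;
#'   default TRUE.
#' @return a scalar PAS. If no member gene is measured the score is 0 and
#'   carries attribute `no_coverage = TRUE` to distinguish "no data" from a
#'   measured 0.
#' @export
compute_pas <- function(de, pathway, log_base = 10, warn_missing = TRUE) {
  genes <- norm_gene(de$gene)
  idx <- match(names(pathway$members), genes)
  measured <- !is.na(idx)
  if (warn_missing && any(!measured))
    warning(sprintf("pathway '%s': %d member gene(s) not measured, skipped",
                    pathway$pathway_id, sum(!measured)), call. = FALSE)
  if (!any(measured)) return(structure(0, no_coverage = TRUE))
  arr <- pathway$members[measured]
  cnr <- de$cnr[idx[measured]]
  btif <- de$btif[idx[measured]]
  usable <- !is.na(cnr) & !is.na(btif)
  if (!any(usable)) return(structure(0, no_coverage = TRUE))
  sum(arr[usable] * btif[usable] * log(cnr[usable], base = log_base))
}

new_pas_profile <- function(values, no_coverage) {
  structure(values, no_coverage = no_coverage, class = "pas_profile")
}

#' @export
print.pas_profile <- function(x, ...) {
  cat(sprintf("<pas_profile: %d entities x %d pathways, %d no-coverage cell(s)>\n",
              nrow(x), ncol(x), sum(attr(x, "no_coverage"))))
  print(unclass(x)[, seq_len(min(ncol(x), 6L)), drop = FALSE], ...)
  invisible(x)
}

warn_uncovered_members <- function(matrix, db) {
  measured <- norm_gene(rownames(matrix))
  n_missing <- vapply(db$pathways, function(p)
    sum(!names(p$members) %in% measured), integer(1))
  if (any(n_missing > 0))
    warning(sprintf("%d pathway(s) have member genes absent from the matrix",
                    sum(n_missing > 0)), call. = FALSE)
}

#' Group-level pathway activation profile
#'
#' Runs case-reference differential expression for the design and scores
#' every pathway of the database, producing a single-row profile for the
#' case group as a whole.
#'
#' @param matrix validated expression matrix.
#' @param design `group_design`.
#' @param db `pathway_db`.
#' @param alpha FDR threshold for the significance flag; default 0.05.
#' @param log_base logarithm base of the PAS terms; default 10.
#' @param epsilon CNR floor; default `1e-6`.
#' @return a `pas_profile`: 1 x n_pathways numeric matrix (row named after
#'   the design) with a logical `no_coverage` attribute matrix marking
#'   pathways without any measured member.
#' @export
group_pas_profile <- function(matrix, design, db, alpha = 0.05,
                              log_base = 10, epsilon = 1e-6) {
  de <- differential_expression(matrix, design, alpha = alpha,
                                epsilon = epsilon)
  warn_uncovered_members(matrix, db)
  scores <- lapply(db$pathways, function(p)
    compute_pas(de, p, log_base = log_base, warn_missing = FALSE))
  values <- matrix(vapply(scores, as.numeric, numeric(1)), nrow = 1,
                   dimnames = list(design$name, pathway_ids(db)))
  flags <- matrix(vapply(scores, function(s)
    isTRUE(attr(s, "no_coverage")), logical(1)), nrow = 1,
    dimnames = dimnames(values))
  new_pas_profile(values, flags)
}

#' Per-sample pathway activation profile
#'
#' Scores every individual case sample against the reference group: the
#' significance flags (BTIF) come from the group-level case-reference
#' comparison — a single sample cannot support a t-test — while the ratios
#' are the sample's own per-gene CNRs against the reference mean.
#'
#' @inheritParams group_pas_profile
#' @return a `pas_profile` with one row per case sample.
#' @export
per_sample_pas_profile <- function(matrix, design, db, alpha = 0.05,
                                   log_base = 10, epsilon = 1e-6) {
  de <- differential_expression(matrix, design, alpha = alpha,
                                epsilon = epsilon)
  warn_uncovered_members(matrix, db)
  values <- matrix(NA_real_, nrow = length(design$case_ids),
                   ncol = length(db$pathways),
                   dimnames = list(design$case_ids, pathway_ids(db)))
  flags <- matrix(FALSE, nrow = nrow(values), ncol = ncol(values),
                  dimnames = dimnames(values))
  for (g in design$case_ids) {
    cnr_g <- per_sample_cnr(matrix, g, design$reference_ids, epsilon = epsilon)
    de_g <- list(gene = de$gene, cnr = as.numeric(cnr_g), btif = de$btif)
    for (j in seq_along(db$pathways)) {
      s <- compute_pas(de_g, db$pathways[[j]], log_base = log_base,
                       warn_missing = FALSE)
      values[g, j] <- as.numeric(s)
      flags[g, j] <- isTRUE(attr(s, "no_coverage"))
    }
  }
  new_pas_profile(values, flags)
}

#' Drop insignificantly perturbed samples
#'
#' Samples whose PAS is exactly zero for every pathway carry no significant
#' pathway signal and are excluded from downstream scoring. Removals are
#' reported via `message()`.
#'
#' @param profile a per-sample `pas_profile`.
#' @return the profile without its all-zero rows.
#' @export
filter_zero_pas_samples <- function(profile) {
  all_zero <- rowSums(profile != 0) == 0
  if (all(all_zero))
    stop("all samples have zero PAS for every pathway; nothing to analyze",
         call. = FALSE)
  if (any(all_zero))
    message(sprintf("excluding %d insignificantly perturbed sample(s): %s",
                    sum(all_zero),
                    paste(rownames(profile)[all_zero], collapse = ", ")))
  keep <- !all_zero
  new_pas_profile(unclass(profile)[keep, , drop = FALSE],
                  attr(profile, "no_coverage")[keep, , drop = FALSE])
}

#' Write a PAS profile (and its no-coverage flags) as TSV
#'
#' @param profile a `pas_profile`.
#' @param path output TSV path for the values; the companion no-coverage
#'   flag table goes to `flags_path` when given.
#' @param flags_path optional path for the logical no-coverage table.
#' @export
write_pas_profile <- function(profile, path, flags_path = NULL) {
  df <- data.frame(entity_id = rownames(profile), unclass(profile),
                   check.names = FALSE, row.names = NULL)
  write_tsv(df, path)
  if (!is.null(flags_path)) {
    fl <- data.frame(entity_id = rownames(profile),
                     attr(profile, "no_coverage") + 0L,
                     check.names = FALSE, row.names = NULL)
    write_tsv(fl, flags_path)
  }
  invisible(path)
}

#' Read a PAS profile written by [write_pas_profile()]
#' @param path values TSV path.
#' @param flags_path optional no-coverage flags TSV path.
#' @return a `pas_profile`.
#' @export
read_pas_profile <- function(path, flags_path = NULL) {
  df <- read_tsv_checked(path)
  values <- as.matrix(df[-1L])
  rownames(values) <- as.character(df[[1L]])
  flags <- if (is.null(flags_path)) {
    matrix(FALSE, nrow(values), ncol(values), dimnames = dimnames(values))
  } else {
    fl <- read_tsv_checked(flags_path)
    m <- as.matrix(fl[-1L]) > 0
    rownames(m) <- as.character(fl[[1L]])
    m
  }
  new_pas_profile(values, flags)
}
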