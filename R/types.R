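# Domain types: expression matrix, group design, pathway DB, drug DB.
# All gene symbols are matched case-insensitively by uppercasing on entry.

norm_gene <- function(x) toupper(trimws(x))

#' Validate an expression matrix
#'
#' An expression matrix is a base numeric matrix of linear-scale,
#' non-negative normalized intensities with unique gene symbols as row names
#' and unique sample ids as column names. Missing values (`NA`) are allowed;
#' negative values are not.
#'
#' @param x numeric matrix, genes in rows, samples in columns.
#' @return `x` invisibly, after stopping on any violated invariant.
#' @export
validate_expression_matrix <- function(x) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("expression matrix must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("expression matrix must carry gene row names and sample column names",
         call. = FALSE)
  if (anyDuplicated(norm_gene(rownames(x))))
    stop("duplicate gene symbols after case normalization", call. = FALSE)
  if (anyDuplicated(colnames(x)))
    stop("duplicate sample ids", call. = FALSE)
  if (any(x < 0, na.rm = TRUE))
    stop("expression values must be non-negative", call. = FALSE)
  invisible(x)
}

#' Construct a case/reference group design
#'
#' A design names the case-sample set and the reference-sample set of one
#' comparison, e.g. old vs young donors or compound-treated vs DMSO wells.
#'
#' @param name design label.
#' @param case_ids,reference_ids character vectors of sample ids; must be
#'   non-empty and disjoint.
#' @return an object of class `group_design`.
#' @export
group_design <- function(name, case_ids, reference_ids) {
  case_ids <- unique(as.character(case_ids))
  reference_ids <- unique(as.character(reference_ids))
  if (length(case_ids) == 0L) stop("case group is empty", call. = FALSE)
  if (length(reference_ids) == 0L) stop("reference group is empty", call. = FALSE)
  overlap <- intersect(case_ids, reference_ids)
  if (length(overlap) > 0L)
    stop("case and reference groups overlap: ",
         paste(overlap, collapse = ", "), call. = FALSE)
  structure(list(name = as.character(name)[1],
                 case_ids = case_ids,
                 reference_ids = reference_ids),
            class = "group_design")
}

#' @export
print.group_design <- function(x, ...) {
  cat(sprintf("<group_design '%s': %d case vs %d reference samples>\n",
              x$name, length(x$case_ids), length(x$reference_ids)))
  invisible(x)
}

# Check that every design id exists among the matrix columns.
check_design_in_matrix <- function(design, matrix) {
  missing <- setdiff(c(design$case_ids, design$reference_ids), colnames(matrix))
  if (length(missing) > 0L)
    stop("design '", design$name, "' references samples absent from the matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  invisible(TRUE)
}

#' Construct a pathway database
#'
#' Each pathway carries a pro-/anti-aging role PAR (+1 pro-aging, -1
#' anti-aging) and a member map from gene symbol to the gene's
#' activator/repressor role ARR, a signed weight in \[-1, 1\] excluding 0
#' (positive = pathway activator, negative = repressor; magnitudes below 1
#' mark weak roles).
#'
#' @param pathways list of pathway records, each a list with elements
#'   `pathway_id`, `name`, `par` and `members` (named numeric vector of ARR
#'   weights keyed by gene symbol).
#' @return an object of class `pathway_db`.
#' @export
pathway_db <- function(pathways) {
  ids <- vapply(pathways, function(p) as.character(p$pathway_id), character(1))
  if (anyDuplicated(ids)) stop("duplicate pathway ids", call. = FALSE)
  pathways <- lapply(pathways, function(p) {
    p$pathway_id <- as.character(p$pathway_id)
    p$name <- as.character(if (is.null(p$name)) p$pathway_id else p$name)
    p$par <- as.integer(p$par)
    if (!p$par %in% c(-1L, 1L))
      stop("pathway '", p$pathway_id, "': PAR must be +1 or -1", call. = FALSE)
    if (length(p$members) == 0L)
      stop("pathway '", p$pathway_id, "' has no members", call. = FALSE)
    names(p$members) <- norm_gene(names(p$members))
    if (anyDuplicated(names(p$members)))
      stop("pathway '", p$pathway_id, "': duplicate member genes", call. = FALSE)
    if (any(abs(p$members) > 1) || any(p$members == 0))
      stop("pathway '", p$pathway_id,
           "': ARR weights must lie in [-1, 1] and differ from 0", call. = FALSE)
    p
  })
  names(pathways) <- ids
  structure(list(pathways = pathways), class = "pathway_db")
}

#' @export
print.pathway_db <- function(x, ...) {
  n_genes <- length(unique(unlist(lapply(x$pathways,
                                         function(p) names(p$members)))))
  cat(sprintf("<pathway_db: %d pathways over %d genes>\n",
              length(x$pathways), n_genes))
  invisible(x)
}

#' @export
length.pathway_db <- function(x) length(x$pathways)

pathway_ids <- function(db) names(db$pathways)

#' Construct a drug-target database
#'
#' Each drug maps target gene symbols to a drug-target index DTI: -1 if the
#' drug activates the target protein, +1 if it inhibits it. Non-interacting
#' targets (DTI 0) are simply absent from the map.
#'
#' @param drugs list of drug records, each a list with elements `drug_id` and
#'   `targets` (named numeric vector of DTI values in \{-1, +1\} keyed by
#'   target gene symbol; may be empty).
#' @return an object of class `drug_db`.
#' @export
drug_db <- function(drugs) {
  ids <- vapply(drugs, function(d) as.character(d$drug_id), character(1))
  if (anyDuplicated(ids)) stop("duplicate drug ids", call. = FALSE)
  drugs <- lapply(drugs, function(d) {
    d$drug_id <- as.character(d$drug_id)
    d$targets <- as.numeric(d$targets) |> setNames(norm_gene(names(d$targets)))
    if (anyDuplicated(names(d$targets)))
      stop("drug '", d$drug_id, "': duplicate target genes", call. = FALSE)
    if (length(d$targets) > 0L && !all(d$targets %in% c(-1, 1)))
      stop("drug '", d$drug_id, "': DTI must be -1 or +1", call. = FALSE)
    d
  })
  names(drugs) <- ids
  structure(list(drugs = drugs), class = "drug_db")
}

#' @export
print.drug_db <- function(x, ...) {
  cat(sprintf("<drug_db: %d drugs, %d target annotations>\n",
              length(x$drugs),
              sum(vapply(x$drugs, function(d) length(d$targets), integer(1)))))
  invisible(x)
}

#' @export
length.drug_db <- function(x) length(x$drugs)
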