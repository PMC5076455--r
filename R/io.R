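# Tabular I/O. All formats are UTF-8 TSV with "." as decimal separator so
# that write/read round-trips are bit-exact.

read_tsv_checked <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (file.size(path) == 0L) stop("empty file: ", path, call. = FALSE)
  utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE, na.strings = c("NA", ""),
                    fileEncoding = "UTF-8")
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a gene-expression table
#'
#' Expects a TSV whose first column holds gene symbols and whose remaining
#' columns hold one sample each, with sample ids in the header. Values are
#' linear-scale, non-negative normalized intensities; `NA` marks a missing
#' measurement. Duplicate gene rows (e.g. multiple probes mapping to one
#' symbol) are collapsed by their per-sample mean with a warning.
#'
#' @param path path to the TSV file.
#' @return a validated numeric matrix, genes in rows (uppercased symbols),
#'   samples in columns.
#' @export
read_expression_table <- function(path) {
  df <- read_tsv_checked(path)
  if (ncol(df) < 2L)
    stop("expression table needs a gene column plus at least one sample: ",
         path, call. = FALSE)
  genes <- norm_gene(df[[1L]])
  body <- df[-1L]
  for (j in seq_along(body)) {
    if (is.logical(body[[j]]) && all(is.na(body[[j]])))
      body[[j]] <- as.numeric(body[[j]])   # an all-NA column parses as logical
    if (!is.numeric(body[[j]])) {
      bad <- which(!is.na(body[[j]]) & is.na(suppressWarnings(as.numeric(body[[j]]))))
      stop(sprintf("non-numeric value in column '%s', row %d of %s",
                   names(body)[j], if (length(bad)) bad[1] else NA_integer_,
                   path), call. = FALSE)
    }
  }
  m <- as.matrix(body)
  rownames(m) <- genes
  if (any(m < 0, na.rm = TRUE))
    stop("negative expression values in ", path, call. = FALSE)
  if (anyDuplicated(genes)) {
    dup <- unique(genes[duplicated(genes)])
    warning(sprintf("collapsing %d duplicated gene symbol(s) by mean: %s",
                    length(dup), paste(utils::head(dup, 5), collapse = ", ")),
            call. = FALSE)
    m <- rowsum(m, group = genes, na.rm = TRUE) /
      rowsum((!is.na(m)) + 0, group = genes)
    m[!is.finite(m)] <- NA_real_
  }
  validate_expression_matrix(m)
  m
}

#' Write a gene-expression table
#'
#' @param matrix validated expression matrix (see [read_expression_table()]).
#' @param path output TSV path.
#' @export
write_expression_table <- function(matrix, path) {
  validate_expression_matrix(matrix)
  df <- data.frame(gene_symbol = rownames(matrix), matrix,
                   check.names = FALSE, row.names = NULL)
  write_tsv(df, path)
}

#' Read sample annotations
#'
#' Expects a TSV with a mandatory `sample_id` column; recognized optional
#' columns are `age` (years), `cell_type`, `plate`, `perturbagen` (compound
#' name or the vehicle label, e.g. "DMSO"), `dose_um` (micromolar) and
#' `duration_h` (hours). Unknown columns are preserved untouched.
#'
#' @param path path to the TSV file.
#' @return a data.frame with one row per sample.
#' @export
read_sample_annotations <- function(path) {
  df <- read_tsv_checked(path)
  if (!"sample_id" %in% names(df))
    stop("annotation table lacks a 'sample_id' column: ", path, call. = FALSE)
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in ", path, ": ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "),
         call. = FALSE)
  if ("age" %in% names(df) && any(df$age < 0, na.rm = TRUE))
    stop("negative ages in ", path, call. = FALSE)
  df
}

#' Write sample annotations
#' @param annotations data.frame as returned by [read_sample_annotations()].
#' @param path output TSV path.
#' @export
write_sample_annotations <- function(annotations, path) {
  write_tsv(annotations, path)
}

#' Read a pathway database
#'
#' Expects a long-format TSV with columns `pathway_id`, `pathway_name`,
#' `par` and, per member gene, `gene_symbol` and `arr`. PAR must be constant
#' within a pathway and equal to +1 (pro-aging) or -1 (anti-aging); ARR
#' weights must lie in \[-1, 1\] and differ from 0.
#'
#' @param path path to the TSV file.
#' @return an object of class `pathway_db`.
#' @export
read_pathway_db <- function(path) {
  df <- read_tsv_checked(path)
  need <- c("pathway_id", "pathway_name", "par", "gene_symbol", "arr")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0L)
    stop("pathway table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  pieces <- split(df, df$pathway_id)
  pathways <- lapply(pieces, function(d) {
    if (length(unique(d$par)) != 1L)
      stop("conflicting PAR values for pathway '", d$pathway_id[1], "'",
           call. = FALSE)
    list(pathway_id = d$pathway_id[1],
         name = d$pathway_name[1],
         par = d$par[1],
         members = setNames(as.numeric(d$arr), d$gene_symbol))
  })
  # split() sorts by id; preserve first-appearance order of the file
  pathways <- pathways[unique(as.character(df$pathway_id))]
  pathway_db(pathways)
}

#' Write a pathway database
#' @param db object of class `pathway_db`.
#' @param path output TSV path.
#' @export
write_pathway_db <- function(db, path) {
  rows <- lapply(db$pathways, function(p) {
    data.frame(pathway_id = p$pathway_id, pathway_name = p$name, par = p$par,
               gene_symbol = names(p$members), arr = as.numeric(p$members))
  })
  write_tsv(do.call(rbind, c(rows, make.row.names = FALSE)), path)
}

#' Read a drug-target database
#'
#' Expects a TSV with columns `drug_id`, `target_gene`, `dti`. DTI encodes
#' the drug-target interaction: -1 the drug activates the target, +1 it
#' inhibits it, 0 no interaction. Rows with DTI 0 are dropped with a warning
#' since absence of a target already encodes non-interaction.
#'
#' @param path path to the TSV file.
#' @return an object of class `drug_db`.
#' @export
read_drug_db <- function(path) {
  df <- read_tsv_checked(path)
  need <- c("drug_id", "target_gene", "dti")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0L)
    stop("drug table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (!all(df$dti %in% c(-1, 0, 1)))
    stop("DTI values must be -1, 0 or +1", call. = FALSE)
  if (any(df$dti == 0)) {
    warning(sprintf("dropping %d drug-target row(s) with DTI 0 (no interaction)",
                    sum(df$dti == 0)), call. = FALSE)
    df <- df[df$dti != 0, , drop = FALSE]
  }
  pieces <- split(df, df$drug_id)
  drugs <- lapply(pieces, function(d) {
    list(drug_id = d$drug_id[1],
         targets = setNames(as.numeric(d$dti), d$target_gene))
  })
  drugs <- drugs[unique(as.character(df$drug_id))]
  drug_db(drugs)
}

#' Write a drug-target database
#' @param db object of class `drug_db`.
#' @param path output TSV path.
#' @export
write_drug_db <- function(db, path) {
  rows <- lapply(db$drugs, function(d) {
    if (length(d$targets) == 0L) return(NULL)
    data.frame(drug_id = d$drug_id, target_gene = names(d$targets),
               dti = as.integer(d$targets))
  })
  write_tsv(do.call(rbind, c(rows, make.row.names = FALSE)), path)
}

#' Write a group design (or a list of them) as TSV
#'
#' One row per sample with columns `design_name`, `role` (case/reference)
#' and `sample_id`.
#'
#' @param designs a `group_design` or list of them.
#' @param path output TSV path.
#' @export
write_designs <- function(designs, path) {
  if (inherits(designs, "group_design")) designs <- list(designs)
  rows <- lapply(designs, function(d) {
    data.frame(design_name = d$name,
               role = rep(c("case", "reference"),
                          c(length(d$case_ids), length(d$reference_ids))),
               sample_id = c(d$case_ids, d$reference_ids))
  })
  write_tsv(do.call(rbind, c(rows, make.row.names = FALSE)), path)
}

#' Read group designs from TSV
#' @param path TSV written by [write_designs()].
#' @return a list of `group_design` objects.
#' @export
read_designs <- function(path) {
  df <- read_tsv_checked(path)
  need <- c("design_name", "role", "sample_id")
  if (length(setdiff(need, names(df))) > 0L)
    stop("design table needs columns design_name, role, sample_id", call. = FALSE)
  lapply(split(df, df$design_name)[unique(as.character(df$design_name))],
         function(d) group_design(d$design_name[1],
                                  d$sample_id[d$role == "case"],
                                  d$sample_id[d$role == "reference"]))
}

#' Assign donors to old (case) and young (reference) groups by age
#'
#' Young donors span `young_min` to `young_max` years inclusive; old donors
#' are strictly older than `old_min`. Donors outside both windows, and
#' samples without an age, are excluded.
#'
#' @param annotations data.frame with `sample_id` and `age` columns.
#' @param young_min,young_max inclusive age bounds of the young (reference)
#'   group, in years; defaults 15 and 30.
#' @param old_min exclusive lower age bound of the old (case) group; default
#'   60 (i.e. strictly over 60).
#' @return a `group_design` with old donors as cases and young donors as the
#'   reference.
#' @export
assign_age_groups <- function(annotations, young_min = 15, young_max = 30,
                              old_min = 60) {
  if (!all(c("sample_id", "age") %in% names(annotations)))
    stop("annotations need sample_id and age columns", call. = FALSE)
  age <- annotations$age
  young <- annotations$sample_id[!is.na(age) & age >= young_min & age <= young_max]
  old <- annotations$sample_id[!is.na(age) & age > old_min]
  if (length(old) == 0L)
    stop(sprintf("no old (case) samples with age > %s", old_min), call. = FALSE)
  if (length(young) == 0L)
    stop(sprintf("no young (reference) samples with age in [%s, %s]",
                 young_min, young_max), call. = FALSE)
  group_design("old_vs_young", case_ids = old, reference_ids = young)
}
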