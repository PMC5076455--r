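# Case-reference differential expression: per-gene case/normal ratios (CNR),
# two-sided equal-variance Student's t-tests, Benjamini-Hochberg FDR, and the
# binary significance flag (BTIF) that gates PAS contributions.

#' Case-to-normal expression ratio (CNR) for one gene
#'
#' Ratio of the mean case intensity to the mean reference intensity, each
#' floored at `epsilon` to keep the ratio finite and positive on
#' zero-expression genes.
#'
#' @param case_values,reference_values non-negative intensities; `NA`s are
#'   dropped.
#' @param epsilon positive floor applied to both means; default `1e-6`.
#' @return a positive scalar.
#' @export
gene_cnr <- function(case_values, reference_values, epsilon = 1e-6) {
  case_values <- case_values[!is.na(case_values)]
  reference_values <- reference_values[!is.na(reference_values)]
  if (length(case_values) == 0L) stop("no case values", call. = FALSE)
  if (length(reference_values) == 0L) stop("no reference values", call. = FALSE)
  max(mean(case_values), epsilon) / max(mean(reference_values), epsilon)
}

#' Two-sided equal-variance Student's t-test p-value for one gene
#'
#' Classic pooled-variance two-sample t-test. When both groups are constant
#' with equal means the p-value is 1 (no evidence of change); constant groups
#' with unequal means give p = 0. With fewer than two observations on either
#' side the gene is untestable and `NA` is returned.
#'
#' @param case_values,reference_values numeric vectors; `NA`s are dropped.
#' @return p-value in \[0, 1\], or `NA` if untestable.
#' @export
gene_ttest <- function(case_values, reference_values) {
  case_values <- case_values[!is.na(case_values)]
  reference_values <- reference_values[!is.na(reference_values)]
  drop(row_student_t(matrix(case_values, nrow = 1),
                     matrix(reference_values, nrow = 1)))
}

# Row-wise pooled-variance Student's t p-values for a genes x samples split.
# Vectorized so that genome-scale screens and many-seed benchmarks stay fast;
# agreement with stats::t.test(var.equal = TRUE) is asserted in the tests.
row_student_t <- function(case_mat, ref_mat) {
  n1 <- rowSums(!is.na(case_mat))
  n2 <- rowSums(!is.na(ref_mat))
  m1 <- rowMeans(case_mat, na.rm = TRUE)
  m2 <- rowMeans(ref_mat, na.rm = TRUE)
  ss1 <- rowSums((case_mat - m1)^2, na.rm = TRUE)
  ss2 <- rowSums((ref_mat - m2)^2, na.rm = TRUE)
  df <- n1 + n2 - 2
  sp2 <- ifelse(df > 0, (ss1 + ss2) / df, NA_real_)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  p <- 2 * stats::pt(-abs((m1 - m2) / se), df)
  # zero pooled variance: equal means carry no evidence, unequal means are
  # infinitely significant in the Student model
  degen <- !is.na(sp2) & sp2 == 0
  p[degen] <- ifelse(m1[degen] == m2[degen], 1, 0)
  p[n1 < 2 | n2 < 2] <- NA_real_
  p
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted q-values, order-preserving with the input. `NA` entries
#' (untestable genes) are excluded from the family size and returned as `NA`.
#'
#' @param pvalues numeric vector of p-values in \[0, 1\] (NAs allowed).
#' @return numeric vector of q-values of the same length and order.
#' @export
bh_adjust <- function(pvalues) {
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  q <- rep(NA_real_, length(pvalues))
  q[ok] <- stats::p.adjust(pvalues[ok], method = "BH")
  q
}

#' Case-reference differential expression over a matrix
#'
#' For every gene: the case-to-normal ratio (CNR) of group means, the
#' two-sided equal-variance Student's t p-value, the Benjamini-Hochberg
#' q-value, and the binary significance flag BTIF = 1 iff q < `alpha`.
#' Genes with fewer than two usable values on either side are untestable:
#' they keep their CNR but get `NA` p and q, BTIF 0, and do not count
#' towards the FDR family.
#'
#' @param matrix validated expression matrix.
#' @param design `group_design` whose ids are columns of `matrix`.
#' @param alpha FDR significance threshold; default 0.05.
#' @param epsilon positive floor used in the CNR; default `1e-6`.
#' @return a data.frame of class `de_result` with columns `gene`, `cnr`,
#'   `p`, `q`, `btif`, one row per gene in matrix order.
#' @export
differential_expression <- function(matrix, design, alpha = 0.05,
                                    epsilon = 1e-6) {
  validate_expression_matrix(matrix)
  check_design_in_matrix(design, matrix)
  if (nrow(matrix) == 0L) stop("expression matrix has no genes", call. = FALSE)
  case_mat <- matrix[, design$case_ids, drop = FALSE]
  ref_mat <- matrix[, design$reference_ids, drop = FALSE]
  m_case <- pmax(rowMeans(case_mat, na.rm = TRUE), epsilon)
  m_ref <- pmax(rowMeans(ref_mat, na.rm = TRUE), epsilon)
  cnr <- m_case / m_ref
  # all-NA rows have NaN means; they are untestable and ratio-less
  cnr[is.nan(cnr)] <- NA_real_
  p <- row_student_t(case_mat, ref_mat)
  q <- bh_adjust(p)
  res <- data.frame(gene = rownames(matrix), cnr = cnr, p = p, q = q,
                    btif = as.integer(!is.na(q) & q < alpha),
                    row.names = NULL)
  class(res) <- c("de_result", "data.frame")
  res
}

#' Per-sample case-to-normal ratios
#'
#' CNR of one individual case sample against the mean of a reference group,
#' per gene: `max(value, epsilon) / max(mean(reference), epsilon)`. This is
#' the ratio feeding individual-sample pathway activation profiles.
#'
#' @param matrix validated expression matrix.
#' @param sample_id a column of `matrix`, not part of the reference set.
#' @param reference_ids reference sample columns.
#' @param epsilon positive floor; default `1e-6`.
#' @return named numeric vector of per-gene ratios (NA where unmeasured).
#' @export
per_sample_cnr <- function(matrix, sample_id, reference_ids, epsilon = 1e-6) {
  if (!sample_id %in% colnames(matrix))
    stop("unknown sample id: ", sample_id, call. = FALSE)
  if (sample_id %in% reference_ids)
    stop("sample '", sample_id, "' is part of the reference set", call. = FALSE)
  missing <- setdiff(reference_ids, colnames(matrix))
  if (length(missing) > 0L)
    stop("unknown reference ids: ", paste(missing, collapse = ", "),
         call. = FALSE)
  ref_mean <- rowMeans(matrix[, reference_ids, drop = FALSE], na.rm = TRUE)
  value <- matrix[, sample_id]
  cnr <- pmax(value, epsilon) / pmax(ref_mean, epsilon)
  cnr[is.na(value) | is.nan(ref_mean)] <- NA_real_
  setNames(cnr, rownames(matrix))
}

#' Write a differential-expression result table
#' @param de `de_result` data.frame.
#' @param path output TSV path.
#' @export
write_de_result <- function(de, path) {
  write_tsv(as.data.frame(de), path)
}
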