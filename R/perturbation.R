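# Case/reference designs for compound-perturbation expression data: each
# compound's case wells are compared against vehicle (DMSO) wells drawn from
# the same RNA plate(s), so plate effects cancel in the ratio.

dose_matches <- function(dose, target, rel_tol = 0.01) {
  !is.na(dose) & abs(dose - target) <= rel_tol * abs(target)
}

#' Build a plate-matched case/vehicle design for one compound
#'
#' Case samples are those annotated with the compound at the given dose and
#' duration; the reference consists of vehicle-treated samples from the same
#' plate(s) as the case samples. Doses are matched with a 1% relative
#' tolerance to absorb rounding in annotation files.
#'
#' @param annotations data.frame with `sample_id`, `perturbagen`, `plate`
#'   and, when dose/duration filters are used, `dose_um` / `duration_h`.
#' @param compound perturbagen name of the case group.
#' @param dose dose in micromolar; `NULL` skips dose filtering.
#' @param duration treatment duration in hours; `NULL` skips the filter.
#' @param vehicle vehicle label of the reference wells; default `"DMSO"`.
#' @param cell_type optional cell-line filter applied to both groups.
#' @return a `group_design` named after the compound.
#' @export
build_plate_matched_design <- function(annotations, compound, dose = NULL,
                                       duration = NULL, vehicle = "DMSO",
                                       cell_type = NULL) {
  need <- c("sample_id", "perturbagen", "plate")
  missing <- setdiff(need, names(annotations))
  if (length(missing) > 0L)
    stop("annotations lack column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  ann <- annotations
  if (!is.null(cell_type)) ann <- ann[!is.na(ann$cell_type) &
                                        ann$cell_type == cell_type, , drop = FALSE]
  is_case <- !is.na(ann$perturbagen) & ann$perturbagen == compound
  if (!is.null(dose)) is_case <- is_case & dose_matches(ann$dose_um, dose)
  if (!is.null(duration))
    is_case <- is_case & !is.na(ann$duration_h) & ann$duration_h == duration
  if (!any(is_case))
    stop("no case samples for compound '", compound, "'", call. = FALSE)
  case_plates <- unique(ann$plate[is_case])
  is_ref <- !is.na(ann$perturbagen) & ann$perturbagen == vehicle &
    ann$plate %in% case_plates
  if (!any(is_ref))
    stop("no '", vehicle, "' reference samples on plate(s) ",
         paste(case_plates, collapse = ", "), " for compound '", compound, "'",
         call. = FALSE)
  group_design(compound, ann$sample_id[is_case], ann$sample_id[is_ref])
}

#' Build plate-matched designs for a list of compounds
#'
#' Maps [build_plate_matched_design()] over the compounds; compounds that
#' cannot be resolved (no case wells, or no same-plate vehicle wells) are
#' skipped with a message.
#'
#' @inheritParams build_plate_matched_design
#' @param compounds character vector of perturbagen names.
#' @return a named list of `group_design` objects (possibly shorter than
#'   `compounds`).
#' @export
build_all_designs <- function(annotations, compounds, dose = NULL,
                              duration = NULL, vehicle = "DMSO",
                              cell_type = NULL) {
  designs <- list()
  for (cmp in compounds) {
    d <- tryCatch(
      build_plate_matched_design(annotations, cmp, dose = dose,
                                 duration = duration, vehicle = vehicle,
                                 cell_type = cell_type),
      error = function(e) {
        message("skipping compound '", cmp, "': ", conditionMessage(e))
        NULL
      })
    if (!is.null(d)) designs[[cmp]] <- d
  }
  if (length(designs) == 0L)
    stop("no compound could be resolved into a design", call. = FALSE)
  designs
}
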