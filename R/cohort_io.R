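#' Write a cohort to CSV
#'
#' Plain comma-separated UTF-8 with a header row, `.` decimal separator
#' and empty cells for missing values: `id, age, prior_falls,
#' future_faller`, one column per metric (analysis scale), then
#' `<metric>_dt` columns for dual-task values where present.
#'
#' @param cohort A cohort data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read and validate a cohort CSV
#'
#' Validates the file against the metric registry: every metric column
#' must be present and numeric, ids unique, `future_faller` coded 0/1
#' with blanks meaning indeterminate prospective status.
#'
#' @param path CSV file path.
#' @param registry Metric registry ([isaw_metrics()] by default).
#' @return A validated cohort data frame; rows with indeterminate fall
#'   status are retained with `future_faller = NA`.
#' @export
read_cohort <- function(path, registry = isaw_metrics()) {
  registry <- as_registry(registry)
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = c("", "NA"))
  required <- c("id", "age", "prior_falls", "future_faller", registry$name)
  missing <- setdiff(required, names(raw))
  if (length(missing)) {
    stop("cohort file is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  num_cols <- c("age", "prior_falls", registry$name,
                intersect(paste0(registry$name, "_dt"), names(raw)))
  for (cl in num_cols) {
    if (!is.numeric(raw[[cl]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(raw[[cl]]))) &
                     !is.na(raw[[cl]]))
      stop("non-numeric value in column '", cl, "' at row ",
           paste(utils::head(bad, 5), collapse = ", "))
    }
  }
  raw$id <- as.character(raw$id)
  if (anyDuplicated(raw$id)) {
    stop("duplicate participant ids: ",
         paste(unique(raw$id[duplicated(raw$id)]), collapse = ", "))
  }
  if (!all(raw$future_faller %in% c(0L, 1L, NA))) {
    stop("future_faller must be coded 0, 1, or blank (indeterminate)")
  }
  if (any(!is.finite(as.matrix(raw[registry$name])))) {
    stop("non-finite metric values in cohort")
  }
  class(raw) <- c("cohort", class(raw))
  raw
}

#' Restrict a cohort to records with determinate prospective fall status
#'
#' Participants whose fall status over the follow-up window could not be
#' determined are excluded from modelling; the number removed is
#' reported.
#'
#' @param cohort A cohort data frame.
#' @return The cohort with indeterminate rows removed.  Idempotent.
#' @export
analysis_subset <- function(cohort) {
  drop <- is.na(cohort$future_faller)
  if (any(drop)) {
    message(sum(drop), " record(s) with indeterminate fall status removed; ",
            sum(!drop), " retained")
  }
  out <- cohort[!drop, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0) warning("analysis subset is empty")
  out
}
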