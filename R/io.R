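# NONMEM-style CSV reader/writer. Comma separated, "." as the missing
# marker, header required.

dataset_cols <- c("ID", "TIME", "AMT", "DV", "EVID", "MDV", "OCC", "SS",
                  "BLQ", "ARM", "ASAT", "ALAT", "ALB", "CREAT", "AGE",
                  "SEX", "FOOD", "DOSE_DAILY")

#' Write a cohort dataset to NONMEM-style CSV
#'
#' Comma-separated with a header row; missing values are written as ".".
#'
#' @param data Cohort tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_pazo_dataset <- function(data, path) {
  cols <- intersect(dataset_cols, names(data))
  extra <- setdiff(names(data), dataset_cols)
  readr::write_csv(data[, c(cols, extra)], path, na = ".")
  invisible(path)
}

#' Read a NONMEM-style CSV cohort dataset
#'
#' Validates the mandatory columns (ID, TIME, AMT, DV, EVID, MDV, OCC,
#' BLQ), that TIME is non-negative and non-decreasing within subject, and
#' that every subject has a dose row before its first observation.
#' Malformed rows are reported with their line numbers.
#'
#' @param path CSV file.
#' @return A `pazo_cohort` tibble (without simulation ground truth).
#' @export
read_pazo_dataset <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  out <- readr::read_csv(path, na = ".", show_col_types = FALSE,
                         progress = FALSE)
  miss <- setdiff(c("ID", "TIME", "AMT", "DV", "EVID", "MDV", "OCC", "BLQ"),
                  names(out))
  if (length(miss) > 0) {
    stop(sprintf("dataset is missing mandatory column(s): %s",
                 paste(miss, collapse = ", ")))
  }
  probs <- readr::problems(out)
  if (nrow(probs) > 0) {
    stop(sprintf("malformed rows at line(s): %s",
                 paste(utils::head(probs$row, 10), collapse = ", ")))
  }
  if (any(out$TIME < 0)) {
    stop(sprintf("negative TIME at row(s): %s",
                 paste(utils::head(which(out$TIME < 0), 10), collapse = ", ")))
  }
  for (id in unique(out$ID)) {
    tt <- out$TIME[out$ID == id]
    if (is.unsorted(tt)) {
      stop(sprintf("non-monotone TIME within subject %s", id))
    }
    d <- out[out$ID == id, ]
    if (!any(d$EVID == 1) ||
        (any(d$EVID == 0) &&
         min(d$TIME[d$EVID == 1]) > min(d$TIME[d$EVID == 0]))) {
      stop(sprintf("subject %s has no dose row before its first observation", id))
    }
  }
  obs <- out$EVID == 0
  if (any(obs & is.na(out$DV) & out$BLQ != 1)) {
    stop("observation rows must carry DV or be flagged BLQ")
  }
  tibble::new_tibble(out, nrow = nrow(out), class = "pazo_cohort")
}
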