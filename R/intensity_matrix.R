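#' Labelled intensity matrix of replicate spectra
#'
#' The central container of the package: a non-negative matrix of binned
#' spectral intensities with one row per replicate spectrum and one column per
#' nominal m/z channel, carrying patient identity, replicate number and class
#' label for every row.
#'
#' @param values numeric matrix, rows = replicate spectra, columns = m/z
#'   channels; all entries must be non-negative and finite.
#' @param mz integer vector of nominal m/z labels, strictly increasing, one
#'   per column.
#' @param patient character vector of patient identifiers, one per row.
#' @param replicate integer vector of replicate numbers, one per row;
#'   `(patient, replicate)` pairs must be unique.
#' @param class factor or character vector of class labels per row, values
#'   `"case"` (positive) or `"control"` (negative); all rows of one patient
#'   must share one class.
#' @param normalized logical flag; `TRUE` once each row has been divided by
#'   its own maximum (see [normalize_rows()]).
#'
#' @return An object of class `intensity_matrix`.
#' @seealso [normalize_rows()], [read_feature_table()], [bin_peaks()]
#' @export
intensity_matrix <- function(values, mz, patient, replicate, class,
                             normalized = FALSE) {
  values <- as.matrix(values)
  mz <- as.integer(mz)
  patient <- as.character(patient)
  replicate <- as.integer(replicate)
  class <- factor(as.character(class), levels = c("control", "case"))
  if (ncol(values) != length(mz)) {
    stop("`mz` must have one label per column of `values`", call. = FALSE)
  }
  if (any(diff(mz) <= 0)) {
    stop("`mz` labels must be strictly increasing", call. = FALSE)
  }
  n <- nrow(values)
  if (length(patient) != n || length(replicate) != n || length(class) != n) {
    stop("row metadata must have one entry per row of `values`", call. = FALSE)
  }
  if (anyNA(class)) {
    stop("class labels must be 'case' or 'control'", call. = FALSE)
  }
  if (anyNA(values) || any(!is.finite(values))) {
    stop("intensities must be finite and non-missing", call. = FALSE)
  }
  if (any(values < 0)) {
    stop("intensities must be non-negative", call. = FALSE)
  }
  key <- paste(patient, replicate, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (patient, replicate) keys: ",
         paste(unique(gsub("\r", "/", key[duplicated(key)])), collapse = ", "),
         call. = FALSE)
  }
  cls_by_pat <- tapply(as.character(class), patient,
                       function(v) length(unique(v)))
  if (any(cls_by_pat > 1)) {
    stop("patients with conflicting class labels: ",
         paste(names(cls_by_pat)[cls_by_pat > 1], collapse = ", "),
         call. = FALSE)
  }
  colnames(values) <- paste0("mz_", mz)
  rownames(values) <- paste0(patient, "_r", replicate)
  structure(
    list(values = values, mz = mz, patient = patient, replicate = replicate,
         class = class, normalized = isTRUE(normalized)),
    class = "intensity_matrix"
  )
}

#' @export
print.intensity_matrix <- function(x, ...) {
  cat(sprintf(
    "<intensity_matrix> %d spectra x %d channels (m/z %d-%d), %d patients (%d case / %d control)%s\n",
    nrow(x$values), ncol(x$values), min(x$mz), max(x$mz),
    length(unique(x$patient)),
    length(unique(x$patient[x$class == "case"])),
    length(unique(x$patient[x$class == "control"])),
    if (x$normalized) ", row-max normalized" else ""
  ))
  invisible(x)
}

#' @export
dim.intensity_matrix <- function(x) dim(x$values)

#' Patient-level class table
#'
#' @param x an `intensity_matrix`.
#' @return data.frame with one row per patient and columns `patient`, `class`.
#' @export
patient_table <- function(x) {
  stopifnot(inherits(x, "intensity_matrix"))
  keep <- !duplicated(x$patient)
  data.frame(patient = x$patient[keep], class = x$class[keep],
             stringsAsFactors = FALSE)
}

#' Subset an intensity matrix by rows and/or channels
#'
#' @param x an `intensity_matrix`.
#' @param rows integer or logical row index, or `NULL` to keep all rows.
#' @param mz_keep integer vector of m/z labels to retain, or `NULL`.
#' @return A new `intensity_matrix`.
#' @export
subset_spectra <- function(x, rows = NULL, mz_keep = NULL) {
  stopifnot(inherits(x, "intensity_matrix"))
  if (is.null(rows)) rows <- seq_len(nrow(x$values))
  cols <- if (is.null(mz_keep)) {
    seq_along(x$mz)
  } else {
    idx <- match(mz_keep, x$mz)
    if (anyNA(idx)) {
      stop("unknown m/z channels: ",
           paste(mz_keep[is.na(idx)], collapse = ", "), call. = FALSE)
    }
    sort(idx)
  }
  intensity_matrix(x$values[rows, cols, drop = FALSE], x$mz[cols],
                   x$patient[rows], x$replicate[rows], x$class[rows],
                   normalized = x$normalized)
}

#' Row indices belonging to a set of patients
#'
#' @param x an `intensity_matrix`.
#' @param patients character vector of patient ids.
#' @return integer vector of row indices.
#' @export
rows_for_patients <- function(x, patients) {
  stopifnot(inherits(x, "intensity_matrix"))
  which(x$patient %in% patients)
}
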