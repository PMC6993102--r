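#' Write a feature table to delimited text
#'
#' Serialises an [intensity_matrix()] as UTF-8 delimited text with the header
#' `patient_id,class,replicate,mz_<first>,...`; one row per replicate
#' spectrum. The companion reader is [read_feature_table()].
#'
#' @param x an `intensity_matrix`.
#' @param path output file path.
#' @param sep field separator, `","` (default) or `"\t"`.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(x, path, sep = ",") {
  stopifnot(inherits(x, "intensity_matrix"))
  df <- data.frame(patient_id = x$patient,
                   class = as.character(x$class),
                   replicate = x$replicate,
                   x$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a feature table from delimited text
#'
#' Expects a header row `patient_id,class,replicate` followed by m/z channel
#' columns named `mz_<value>` (or bare integers). Channel order is preserved.
#' Malformed input -- non-numeric intensity cells, negative intensities, or
#' duplicate `(patient, replicate)` keys -- raises an error naming the
#' offending row and column.
#'
#' @param path input file path.
#' @param sep field separator; `NULL` (default) sniffs comma vs tab from the
#'   header line.
#' @return An [intensity_matrix()]; the `normalized` flag is set when every
#'   nonzero row has maximum 1 (within 1e-12).
#' @export
read_feature_table <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1L, encoding = "UTF-8")
  if (is.null(sep)) {
    sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  }
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "",
                          colClasses = "character", check.names = FALSE,
                          fileEncoding = "UTF-8", comment.char = "")
  need <- c("patient_id", "class", "replicate")
  if (!all(need %in% names(df)[1:3])) {
    stop("header must start with patient_id, class, replicate", call. = FALSE)
  }
  mz_cols <- setdiff(names(df), need)
  if (!length(mz_cols)) stop("no m/z channel columns found", call. = FALSE)
  mz <- suppressWarnings(as.integer(sub("^mz_", "", mz_cols)))
  if (anyNA(mz)) {
    stop("channel columns must be named mz_<integer> or <integer>; offending: ",
         paste(mz_cols[is.na(mz)], collapse = ", "), call. = FALSE)
  }
  vals <- matrix(NA_real_, nrow(df), length(mz_cols))
  for (j in seq_along(mz_cols)) {
    v <- suppressWarnings(as.numeric(df[[mz_cols[j]]]))
    bad <- which(is.na(v))
    if (length(bad)) {
      stop(sprintf("non-numeric intensity at data row %d, column %s",
                   bad[1], mz_cols[j]), call. = FALSE)
    }
    neg <- which(v < 0)
    if (length(neg)) {
      stop(sprintf("negative intensity at data row %d, column %s",
                   neg[1], mz_cols[j]), call. = FALSE)
    }
    vals[, j] <- v
  }
  key <- paste(df$patient_id, df$replicate, sep = "/")
  if (anyDuplicated(key)) {
    stop("duplicate (patient, replicate) keys: ",
         paste(unique(key[duplicated(key)]), collapse = ", "), call. = FALSE)
  }
  rmax <- apply(vals, 1, max)
  normalized <- all(abs(rmax[rmax > 0] - 1) < 1e-12)
  intensity_matrix(vals, mz, df$patient_id, as.integer(df$replicate),
                   df$class, normalized = normalized)
}

#' Bin centroided peak lists to nominal m/z channels
#'
#' Each channel `c` holds the summed intensity of all peaks falling in the
#' half-open bin `[c, c + width)`. The number of channels is
#' `ceiling((mz_end - mz_start) / width)`. Peaks outside `[mz_start, mz_end)`
#' are dropped, counted, and reported in a warning.
#'
#' @param peak_lists list of per-spectrum peak matrices/data.frames with two
#'   columns, m/z and intensity.
#' @param mz_start,mz_end acquisition range, left-closed right-open.
#' @param width bin width in m/z units (default 1, nominal mass binning).
#' @param patient,replicate,class per-spectrum row metadata (recycled rules
#'   as in [intensity_matrix()]).
#' @return An [intensity_matrix()] of binned intensities.
#' @export
bin_peaks <- function(peak_lists, mz_start = 250, mz_end = 2002, width = 1,
                      patient = NULL, replicate = NULL, class = NULL) {
  stopifnot(is.list(peak_lists), mz_end > mz_start, width > 0)
  n <- length(peak_lists)
  n_chan <- as.integer(ceiling((mz_end - mz_start) / width))
  mz <- as.integer(mz_start + width * (seq_len(n_chan) - 1L))
  vals <- matrix(0, n, n_chan)
  dropped <- 0L
  for (i in seq_len(n)) {
    pk <- peak_lists[[i]]
    if (is.null(pk) || !NROW(pk)) next
    pk <- as.matrix(pk)
    if (ncol(pk) < 2) stop("peak list ", i, " must have m/z and intensity columns",
                           call. = FALSE)
    m <- as.numeric(pk[, 1]); y <- as.numeric(pk[, 2])
    inside <- m >= mz_start & m < mz_end
    dropped <- dropped + sum(!inside)
    if (!any(inside)) next
    idx <- floor((m[inside] - mz_start) / width) + 1L
    acc <- tapply(y[inside], idx, sum)
    vals[i, as.integer(names(acc))] <- as.numeric(acc)
  }
  if (dropped > 0) {
    warning(dropped, " peak(s) outside [", mz_start, ", ", mz_end,
            ") were dropped", call. = FALSE)
  }
  if (is.null(patient)) patient <- sprintf("S%03d", seq_len(n))
  if (is.null(replicate)) replicate <- rep(1L, n)
  if (is.null(class)) class <- rep("control", n)
  intensity_matrix(vals, mz, patient, replicate, class)
}

#' Per-vector maximum normalization
#'
#' Divides every replicate spectrum (row) by its own maximum intensity so the
#' largest channel of each nonzero vector equals exactly 1. All-zero rows are
#' left as zeros and reported in a warning, never dropped: removing them would
#' silently unbalance per-patient replicate counts. The operation is
#' idempotent.
#'
#' @param x an `intensity_matrix`.
#' @return The normalized `intensity_matrix` with the `normalized` flag set.
#' @export
normalize_rows <- function(x) {
  stopifnot(inherits(x, "intensity_matrix"))
  rmax <- apply(x$values, 1, max)
  zero <- rmax == 0
  if (any(zero)) {
    warning(sum(zero), " all-zero row(s) left unnormalized: ",
            paste(utils::head(rownames(x$values)[zero], 5), collapse = ", "),
            call. = FALSE)
    rmax[zero] <- 1
  }
  x$values <- x$values / rmax
  x$normalized <- TRUE
  x
}
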