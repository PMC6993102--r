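#' Detect linearly dependent channels by Gauss-Jordan elimination
#'
#' Groups of linearly dependent m/z channels carry no more information than a
#' single representative, so before feature ranking the matrix is reduced to a
#' linearly independent channel set. Columns are processed in ascending m/z
#' order with partial pivoting on rows; a column whose remaining entries are
#' all below `pivot_tolerance * max(abs(column))` after elimination against
#' the pivots found so far is declared dependent. Because the pivot block is
#' reduced to the identity, the entries of a dependent column in the pivot
#' rows are exactly its expansion coefficients on the pivot channels; each
#' dependent column is assigned to the group of its lowest-m/z supporting
#' pivot (the first pivot with a non-negligible coefficient). Groups partition
#' the channel set and each group is then represented by its member with the
#' maximum median intensity across all vectors, ties broken by lower m/z.
#'
#' When the matrix has fewer rows than channels its column rank is bounded by
#' the row count, so channels beyond that bound are necessarily dependent on
#' earlier ones and the reduction retains at most `nrow` representatives;
#' exactly rank-many groups are produced at the stated tolerance.
#'
#' @param x an [intensity_matrix()] (normalize first, see [normalize_rows()])
#'   or a plain numeric matrix; for a plain matrix channels are labelled by
#'   column index.
#' @param pivot_tolerance relative pivot threshold, must be > 0;
#'   default `1e-8`.
#' @param rows optional integer row subset that feeds the elimination (e.g.
#'   fit-partition rows only, to keep test vectors out of feature grouping);
#'   medians for representative selection always use all rows of `x`.
#' @return An object of class `dependency_reduction` with elements
#'   `representatives` (retained channel labels, ascending), `groups` (named
#'   list mapping each representative to all member channels including
#'   itself), `pivots` (the Gauss-Jordan pivot channels), `pivot_tolerance`,
#'   `n_rows_used` and `labels` (all channel labels in input order).
#' @export
find_dependent_groups <- function(x, pivot_tolerance = 1e-8, rows = NULL) {
  if (!is.null(pivot_tolerance) &&
      (!is.numeric(pivot_tolerance) || length(pivot_tolerance) != 1 ||
       pivot_tolerance <= 0)) {
    stop("`pivot_tolerance` must be a single positive number", call. = FALSE)
  }
  if (inherits(x, "intensity_matrix")) {
    if (!x$normalized) {
      warning("matrix is not row-max normalized; reducing as-is", call. = FALSE)
    }
    vals <- x$values
    labels <- x$mz
  } else {
    vals <- as.matrix(x)
    labels <- seq_len(ncol(vals))
  }
  if (nrow(vals) < 1) stop("matrix must have at least one row", call. = FALSE)
  elim_rows <- if (is.null(rows)) seq_len(nrow(vals)) else rows
  A <- vals[elim_rows, , drop = FALSE]
  n <- nrow(A); p <- ncol(A)
  colscale <- apply(abs(A), 2, max)

  avail <- rep(TRUE, n)
  pivot_row_of <- integer(0)   # row index of k-th pivot
  pivot_col_of <- integer(0)   # column index of k-th pivot
  owner <- integer(p)          # for each column, index of its group's pivot col
  coef_tol <- 1e-6             # relative cutoff for "supporting" coefficients

  for (j in seq_len(p)) {
    piv_found <- FALSE
    if (any(avail)) {
      cand <- which(avail)
      r <- cand[which.max(abs(A[cand, j]))]
      if (abs(A[r, j]) > pivot_tolerance * max(colscale[j], .Machine$double.eps)) {
        A[r, ] <- A[r, ] / A[r, j]
        f <- A[, j]
        f[r] <- 0
        A <- A - outer(f, A[r, ])
        avail[r] <- FALSE
        pivot_row_of <- c(pivot_row_of, r)
        pivot_col_of <- c(pivot_col_of, j)
        owner[j] <- j
        piv_found <- TRUE
      }
    }
    if (!piv_found) {
      # dependent column: its entries in the pivot rows are the expansion
      # coefficients on the pivot columns found so far
      if (length(pivot_row_of)) {
        coefs <- A[pivot_row_of, j]
        supp <- which(abs(coefs) > coef_tol * max(abs(coefs), .Machine$double.eps))
        owner[j] <- if (length(supp)) pivot_col_of[min(supp)] else pivot_col_of[1L]
      } else {
        owner[j] <- 0L  # all-zero matrix so far: grouped later
      }
    }
  }

  if (!length(pivot_col_of)) {
    # degenerate all-zero input: one group holding every channel
    groups <- list(as.vector(labels))
    names(groups) <- as.character(labels[1])
    return(structure(
      list(representatives = labels[1], groups = groups, pivots = integer(0),
           pivot_tolerance = pivot_tolerance, n_rows_used = n,
           labels = labels),
      class = "dependency_reduction"))
  }
  owner[owner == 0L] <- pivot_col_of[1L]

  med <- apply(vals, 2, stats::median)
  groups <- split(seq_len(p), owner)
  rep_of <- vapply(groups, function(members) {
    members[order(-med[members], labels[members])][1L]
  }, integer(1))
  ord <- order(labels[rep_of])
  groups <- groups[ord]
  rep_of <- rep_of[ord]
  out_groups <- lapply(groups, function(members) as.vector(labels[members]))
  names(out_groups) <- as.character(labels[rep_of])

  structure(
    list(representatives = as.vector(labels[sort(rep_of)]),
         groups = out_groups,
         pivots = as.vector(labels[pivot_col_of]),
         pivot_tolerance = pivot_tolerance,
         n_rows_used = n,
         labels = labels),
    class = "dependency_reduction")
}

#' @export
print.dependency_reduction <- function(x, ...) {
  n_grp <- sum(lengths(x$groups) > 1)
  cat(sprintf(
    "<dependency_reduction> %d of %d channels retained (tolerance %g, %d rows); %d non-singleton group(s)\n",
    length(x$representatives), length(x$labels), x$pivot_tolerance,
    x$n_rows_used, n_grp))
  invisible(x)
}

#' Reduce a matrix to its independent representative channels
#'
#' Retains only the representative channel of every dependency group; original
#' m/z labels and row metadata are preserved.
#'
#' @param x an [intensity_matrix()] with the same channel labels the
#'   reduction was computed on.
#' @param reduction a `dependency_reduction` from [find_dependent_groups()].
#' @return The reduced `intensity_matrix`.
#' @export
reduce_channels <- function(x, reduction) {
  stopifnot(inherits(x, "intensity_matrix"),
            inherits(reduction, "dependency_reduction"))
  if (length(x$mz) != length(reduction$labels) ||
      any(x$mz != reduction$labels)) {
    stop("channel labels of `x` do not match those the reduction was computed on",
         call. = FALSE)
  }
  subset_spectra(x, mz_keep = reduction$representatives)
}

#' Expand a representative channel to its dependency group
#'
#' Dependent channels are reused at the annotation stage: every ion in the
#' group may correspond to the molecule behind the retained representative.
#'
#' @param reduction a `dependency_reduction`.
#' @param channel a representative channel label.
#' @return Vector of all member channels of the group (including the
#'   representative itself).
#' @export
expand_to_group <- function(reduction, channel) {
  stopifnot(inherits(reduction, "dependency_reduction"))
  key <- as.character(channel)
  if (!key %in% names(reduction$groups)) {
    stop("channel ", channel, " is not a representative", call. = FALSE)
  }
  reduction$groups[[key]]
}

#' Serialize / restore a dependency reduction as JSON
#'
#' @param reduction a `dependency_reduction`.
#' @param path file path.
#' @return `write_reduction()` returns `path` invisibly; `read_reduction()`
#'   returns the restored `dependency_reduction`.
#' @export
write_reduction <- function(reduction, path) {
  stopifnot(inherits(reduction, "dependency_reduction"))
  jsonlite::write_json(
    list(representatives = reduction$representatives,
         groups = reduction$groups,
         pivots = reduction$pivots,
         pivot_tolerance = reduction$pivot_tolerance,
         n_rows_used = reduction$n_rows_used,
         labels = reduction$labels),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_reduction
#' @export
read_reduction <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  groups <- lapply(obj$groups, as.vector)
  structure(
    list(representatives = as.vector(obj$representatives), groups = groups,
         pivots = as.vector(obj$pivots),
         pivot_tolerance = obj$pivot_tolerance,
         n_rows_used = obj$n_rows_used, labels = as.vector(obj$labels)),
    class = "dependency_reduction")
}
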