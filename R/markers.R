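#' Empirical cumulative distribution function
#'
#' Right-continuous step function: `F(x)` is the fraction of values `<= x`.
#' Thin wrapper over [stats::ecdf()] that rejects empty input.
#'
#' @param values numeric vector, at least one value.
#' @return A function of class `ecdf`.
#' @export
empirical_cdf <- function(values) {
  values <- as.numeric(values)
  if (!length(values) || anyNA(values)) {
    stop("`values` must be a non-empty numeric vector", call. = FALSE)
  }
  stats::ecdf(values)
}

#' CDF-difference marker criterion for one feature
#'
#' A discriminant channel is called a *marker* when the ion is systematically
#' more intense in the positive class: writing `m_j` for the median of the
#' positive-class values, `P` for the positive-class CDF and `Q` for the
#' negative-class CDF, the criterion requires the CDF gap
#' `delta_j = Q(m_j) - P(m_j)` to exceed the threshold `beta` *and* `Q` to
#' dominate `P` everywhere above `m_j`. Dominance is checked at every
#' observed sample value above `m_j`, which is exact for step CDFs. `beta`
#' must lie in (0, 0.5); 0.4 is the conventional default.
#'
#' @param pos_values feature values of positive-class (case) vectors.
#' @param neg_values feature values of negative-class (control) vectors.
#' @param beta marker threshold in (0, 0.5).
#' @return Object of class `marker_decision`: `m_j`, `delta_j`, `dominance`,
#'   `beta`, `is_marker`.
#' @export
marker_delta <- function(pos_values, neg_values, beta = 0.4) {
  if (!length(pos_values) || !length(neg_values)) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  if (!is.numeric(beta) || length(beta) != 1 || beta <= 0 || beta >= 0.5) {
    stop("`beta` must lie strictly between 0 and 0.5", call. = FALSE)
  }
  P <- empirical_cdf(pos_values)
  Q <- empirical_cdf(neg_values)
  m_j <- stats::median(pos_values)
  delta_j <- Q(m_j) - P(m_j)
  pts <- sort(unique(c(pos_values, neg_values)))
  pts <- pts[pts > m_j]
  dominance <- !length(pts) || all(Q(pts) >= P(pts) - 1e-12)
  structure(list(m_j = m_j, delta_j = delta_j, dominance = dominance,
                 beta = beta, is_marker = (delta_j > beta) && dominance),
            class = "marker_decision")
}

#' @export
print.marker_decision <- function(x, ...) {
  cat(sprintf("m_j = %.4g, delta_j = %.3f, dominance %s, beta = %.2f -> %s\n",
              x$m_j, x$delta_j, if (x$dominance) "yes" else "no", x$beta,
              if (x$is_marker) "MARKER" else "not a marker"))
  invisible(x)
}

#' Apply the marker criterion to a set of channels
#'
#' Values are pooled across replicate vectors (each vector contributes one
#' value per channel). By default only fit-partition rows should be supplied
#' through `rows`, keeping test vectors out of the marker decision.
#'
#' @param x an [intensity_matrix()].
#' @param channels channel labels to test, in ranking order (preserved in the
#'   output).
#' @param beta marker threshold in (0, 0.5).
#' @param rows optional row subset (e.g. fit-partition rows); default all.
#' @return data.frame with one row per channel: `channel`, `m_j`, `delta_j`,
#'   `dominance`, `is_marker`.
#' @export
detect_markers <- function(x, channels, beta = 0.4, rows = NULL) {
  stopifnot(inherits(x, "intensity_matrix"))
  if (!length(channels)) stop("`channels` must be non-empty", call. = FALSE)
  cols <- .channel_cols(x, channels)
  if (is.null(rows)) rows <- seq_len(nrow(x$values))
  cls <- x$class[rows]
  out <- lapply(seq_along(cols), function(i) {
    v <- x$values[rows, cols[i]]
    d <- marker_delta(v[cls == "case"], v[cls == "control"], beta)
    data.frame(channel = channels[i], m_j = d$m_j, delta_j = d$delta_j,
               dominance = d$dominance, is_marker = d$is_marker)
  })
  res <- do.call(rbind, out)
  attr(res, "beta") <- beta
  res
}

#' Per-class distribution report for one channel
#'
#' Tabular per-class histogram and CDF values for plotting a feature's
#' distribution analysis, annotated with the marker statistic.
#'
#' @param x an [intensity_matrix()].
#' @param channel a single channel label.
#' @param n_bins number of histogram bins over the pooled value range.
#' @param beta marker threshold for the annotation.
#' @param rows optional row subset.
#' @return List with `histogram` (class, bin midpoint, count, density),
#'   `cdf` (value grid with `P` and `Q`), and the `marker_decision`.
#' @export
distribution_report <- function(x, channel, n_bins = 30, beta = 0.4,
                                rows = NULL) {
  stopifnot(inherits(x, "intensity_matrix"), length(channel) == 1)
  col <- .channel_cols(x, channel)
  if (is.null(rows)) rows <- seq_len(nrow(x$values))
  v <- x$values[rows, col]
  cls <- x$class[rows]
  pos <- v[cls == "case"]; neg <- v[cls == "control"]
  decision <- marker_delta(pos, neg, beta)
  rng <- range(v)
  if (diff(rng) == 0) {
    breaks <- c(rng[1] - 0.5, rng[1] + 0.5)
  } else {
    breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  }
  hist_one <- function(vals, class) {
    h <- graphics::hist(vals, breaks = breaks, plot = FALSE)
    data.frame(class = class, mid = h$mids, count = h$counts,
               density = h$density)
  }
  histogram <- rbind(hist_one(pos, "case"), hist_one(neg, "control"))
  grid <- sort(unique(v))
  P <- empirical_cdf(pos); Q <- empirical_cdf(neg)
  cdf <- data.frame(value = grid, P = P(grid), Q = Q(grid))
  list(histogram = histogram, cdf = cdf, decision = decision,
       channel = channel)
}
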