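#' Body mass index
#'
#' BMI in kg/m^2: weight in kilograms divided by height in meters squared.
#'
#' @param weight body weight in kg, > 0.
#' @param height body height in m, > 0.
#' @return Numeric BMI, vectorized.
#' @export
compute_bmi <- function(weight, height) {
  if (any(!is.finite(weight)) || any(weight <= 0)) {
    stop("`weight` must be positive", call. = FALSE)
  }
  if (any(!is.finite(height)) || any(height <= 0)) {
    stop("`height` must be positive", call. = FALSE)
  }
  weight / height^2
}

#' WHO BMI category
#'
#' Standard WHO cut points: eutrophic (normal weight) `[18, 25)`, overweight
#' `[25, 30)`, class I obesity `[30, 35)`, class II obesity `[35, 40)`, class
#' III obesity `>= 40`. Values below the eutrophic floor are labelled
#' `"underweight"` (out of study), never silently folded into eutrophic.
#'
#' @param bmi numeric BMI in kg/m^2, > 0.
#' @return Ordered factor with levels `underweight < eutrophic < overweight <
#'   obese_1 < obese_2 < obese_3`.
#' @export
who_category <- function(bmi) {
  if (any(!is.finite(bmi)) || any(bmi <= 0)) {
    stop("`bmi` must be positive", call. = FALSE)
  }
  cut(bmi, breaks = c(0, 18, 25, 30, 35, 40, Inf),
      labels = c("underweight", "eutrophic", "overweight",
                 "obese_1", "obese_2", "obese_3"),
      right = FALSE, ordered_result = TRUE)
}

#' Case/control label from BMI
#'
#' Case (positive class, weight gain) is any WHO category at or above
#' overweight; eutrophic subjects are controls; underweight subjects fall
#' outside the study design and map to `NA`.
#'
#' @param bmi numeric BMI in kg/m^2.
#' @return Factor with levels `control`, `case` (NA for underweight).
#' @export
bmi_class <- function(bmi) {
  cat <- who_category(bmi)
  out <- ifelse(cat >= "overweight", "case",
                ifelse(cat == "eutrophic", "control", NA_character_))
  factor(out, levels = c("control", "case"))
}

#' Specification of a synthetic MALDI cohort
#'
#' Describes the statistical structure of a simulated two-class plasma MALDI
#' feature table: balanced patient groups with replicate spectra, log-normal
#' per-channel baseline intensities with patient- and replicate-level noise, a
#' stable high-intensity base-peak channel (so per-vector maximum
#' normalization has a steady anchor, as the matrix peak does in real
#' spectra), planted marker channels whose case-patient intensities are
#' location-shifted upward on the log scale, and planted linearly dependent
#' channel groups whose member columns are exact scalar multiples of their
#' generator column (before optional jitter).
#'
#' Defaults emulate the acquisition design the package targets: 90 + 90
#' patients, quintuplicate spectra, 1,752 unit-width channels starting at
#' nominal m/z 250, five markers at paper-typical low m/z positions with a
#' 3-sigma shift, and ten dependency groups contributing 20 dependent member
#' channels.
#'
#' @param n_per_class patients per class (default 90).
#' @param replicates_per_patient replicate spectra per patient (default 5).
#' @param n_channels number of unit-width m/z channels (default 1752).
#' @param channel_mz_start first nominal m/z (default 250).
#' @param marker_channels data.frame with columns `mz` and `shift` (location
#'   shift for case patients in units of the channel's total log-scale
#'   baseline sd); `shift > 0` shifts the positive class upward.
#' @param dependent_groups data.frame with columns `generator_mz`,
#'   `member_mz`, `coefficient`; each member column is
#'   `coefficient * generator` column. Coefficients below 1 keep the
#'   generator as the max-median representative of its group.
#' @param patient_sd,replicate_sd log-scale sd of patient-level (biological)
#'   and replicate-level (technical) intensity noise. Defaults 0.40 and 0.15,
#'   i.e. roughly 40% between-patient CV -- typical of plasma metabolite
#'   inter-individual variation -- and 15% technical replicate CV.
#' @param channel_mean_sd sd of per-channel baseline log-mean heterogeneity.
#' @param member_jitter_sd relative jitter applied to dependent member
#'   columns (default 0 = exact linear dependence).
#' @param missing_rate probability of dropping any replicate row, to mimic
#'   incomplete replicate acquisition (default 0, fully balanced).
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_per_class = 90,
                           replicates_per_patient = 5,
                           n_channels = 1752,
                           channel_mz_start = 250,
                           marker_channels = NULL,
                           dependent_groups = NULL,
                           patient_sd = 0.40,
                           replicate_sd = 0.15,
                           channel_mean_sd = 0.8,
                           member_jitter_sd = 0,
                           missing_rate = 0) {
  mz <- channel_mz_start + seq_len(n_channels) - 1L
  if (is.null(marker_channels)) {
    mk <- c(263L, 278L, 299L, 308L, 389L)
    mk <- mk[mk %in% mz]
    marker_channels <- data.frame(mz = mk, shift = rep(3, length(mk)))
  }
  if (is.null(dependent_groups)) {
    gen <- seq(500L, 680L, by = 20L)
    gen <- gen[gen %in% mz]
    dependent_groups <- data.frame(
      generator_mz = rep(gen, each = 2),
      member_mz = as.integer(c(rbind(900L + 10L * seq_along(gen),
                                     1300L + 10L * seq_along(gen)))),
      coefficient = rep(c(0.6, 0.35), times = length(gen)))
    dependent_groups <-
      dependent_groups[dependent_groups$member_mz %in% mz, , drop = FALSE]
  }
  marker_channels <- as.data.frame(marker_channels)
  dependent_groups <- as.data.frame(dependent_groups)
  stopifnot(all(c("mz", "shift") %in% names(marker_channels)),
            all(c("generator_mz", "member_mz", "coefficient") %in%
                  names(dependent_groups)))
  if (n_per_class < 1 || replicates_per_patient < 1 || n_channels < 2) {
    stop("cohort dimensions must be positive", call. = FALSE)
  }
  bad_mz <- setdiff(c(marker_channels$mz, dependent_groups$generator_mz,
                      dependent_groups$member_mz), mz)
  if (length(bad_mz)) {
    stop("channels outside the m/z grid: ", paste(bad_mz, collapse = ", "),
         call. = FALSE)
  }
  members <- dependent_groups$member_mz
  if (anyDuplicated(members)) {
    stop("a channel may be a member of only one dependency group",
         call. = FALSE)
  }
  overlap <- intersect(marker_channels$mz,
                       c(dependent_groups$generator_mz, members))
  if (length(overlap) || length(intersect(members,
                                          dependent_groups$generator_mz))) {
    stop("marker channels, generators and dependent members must be disjoint",
         call. = FALSE)
  }
  if (missing_rate < 0 || missing_rate >= 1) {
    stop("`missing_rate` must be in [0, 1)", call. = FALSE)
  }
  structure(
    list(n_per_class = n_per_class,
         replicates_per_patient = replicates_per_patient,
         n_channels = n_channels, channel_mz_start = channel_mz_start,
         mz = mz, marker_channels = marker_channels,
         dependent_groups = dependent_groups,
         patient_sd = patient_sd, replicate_sd = replicate_sd,
         channel_mean_sd = channel_mean_sd,
         member_jitter_sd = member_jitter_sd,
         missing_rate = missing_rate),
    class = "synthetic_spec")
}

#' Generate a synthetic labelled cohort
#'
#' Draws a cohort according to a [synthetic_spec()]: subject anthropometrics
#' (height, BMI per class, weight back-computed, class label assigned through
#' the WHO cut points), then the intensity matrix. Per channel `c` the
#' log-intensity of patient `i`, replicate `r` is
#' `mu_c + shift_c[class_i] + a_ic + e_icr` with `a_ic ~ N(0, patient_sd)`
#' and `e_icr ~ N(0, replicate_sd)`; intensities are `exp()` of that, hence
#' strictly positive. Dependent member columns are overwritten with
#' `coefficient * generator` after noise, so their linear dependence is exact
#' (up to optional jitter). The raw matrix is *not* normalized: per-vector
#' normalization is the pipeline's first step, not the generator's.
#'
#' @param spec a [synthetic_spec()].
#' @param seed integer seed; the draw is fully reproducible given
#'   `(spec, seed)`.
#' @return List with elements `matrix` (an [intensity_matrix()]), `subjects`
#'   (data.frame of patient anthropometrics and class) and `truth` (planted
#'   marker channels and dependency groups, plus the seed).
#' @export
generate_cohort <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(as.integer(seed))
  n_pat <- 2L * spec$n_per_class
  class <- rep(c("control", "case"), each = spec$n_per_class)
  patient <- sprintf("S%03d", seq_len(n_pat))

  height <- pmin(pmax(stats::rnorm(n_pat, 1.66, 0.08), 1.45), 1.95)
  bmi <- ifelse(class == "control",
                pmin(pmax(stats::rnorm(n_pat, 22.3, 1.9), 18.5), 24.7),
                pmin(pmax(stats::rnorm(n_pat, 33.3, 6.0), 25.2), 55))
  weight <- bmi * height^2
  subjects <- data.frame(patient = patient, class = class,
                         weight = weight, height = height,
                         bmi = compute_bmi(weight, height),
                         category = who_category(bmi),
                         stringsAsFactors = FALSE)
  stopifnot(identical(as.character(bmi_class(subjects$bmi)), class))

  p <- spec$n_channels
  mz <- spec$mz
  # per-channel baseline: gentle decay with m/z plus heterogeneity, and a
  # stable base-peak channel right after the range start
  mu <- log(500) - 1.5 * (seq_len(p) - 1) / p +
    stats::rnorm(p, 0, spec$channel_mean_sd)
  s_pat <- rep(spec$patient_sd, p)
  s_rep <- rep(spec$replicate_sd, p)
  base_idx <- 2L
  mu[base_idx] <- log(5e4)
  s_pat[base_idx] <- 0.04
  s_rep[base_idx] <- 0.03
  sigma_tot <- sqrt(s_pat^2 + s_rep^2)

  shift <- numeric(p)
  mk_idx <- match(spec$marker_channels$mz, mz)
  shift[mk_idx] <- spec$marker_channels$shift * sigma_tot[mk_idx]

  n_rep <- spec$replicates_per_patient
  n_rows <- n_pat * n_rep
  pat_eff <- matrix(stats::rnorm(n_pat * p), n_pat, p) *
    rep(s_pat, each = n_pat)
  pat_mean <- rep(mu, each = n_pat) + pat_eff
  pat_mean[class == "case", ] <- pat_mean[class == "case", ] +
    rep(shift, each = spec$n_per_class)

  row_pat <- rep(seq_len(n_pat), each = n_rep)
  loga <- pat_mean[row_pat, ] +
    matrix(stats::rnorm(n_rows * p), n_rows, p) * rep(s_rep, each = n_rows)
  vals <- exp(loga)

  # exact linear dependence, planted after noise
  dg <- spec$dependent_groups
  if (nrow(dg)) {
    gi <- match(dg$generator_mz, mz)
    mi <- match(dg$member_mz, mz)
    for (k in seq_len(nrow(dg))) {
      col <- dg$coefficient[k] * vals[, gi[k]]
      if (spec$member_jitter_sd > 0) {
        col <- col * exp(stats::rnorm(n_rows, 0, spec$member_jitter_sd))
      }
      vals[, mi[k]] <- col
    }
  }

  keep <- rep(TRUE, n_rows)
  if (spec$missing_rate > 0) {
    keep <- stats::runif(n_rows) >= spec$missing_rate
    # never drop all replicates of a patient
    for (i in seq_len(n_pat)) {
      idx <- which(row_pat == i)
      if (!any(keep[idx])) keep[idx[1]] <- TRUE
    }
  }

  mat <- intensity_matrix(vals[keep, , drop = FALSE], mz,
                          patient[row_pat][keep],
                          rep(seq_len(n_rep), times = n_pat)[keep],
                          class[row_pat][keep])
  truth <- list(marker_channels = spec$marker_channels,
                dependent_groups = spec$dependent_groups,
                base_peak_mz = mz[base_idx],
                seed = as.integer(seed))
  list(matrix = mat, subjects = subjects, truth = truth)
}

#' Write a cohort's ground truth as a JSON sidecar
#'
#' @param truth the `truth` element of [generate_cohort()]'s result.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
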