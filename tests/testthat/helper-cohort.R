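# Small planted-truth cohorts used across the unit tests. Dimensions are kept
# well below the channel count so the dependence structure is fully
# identifiable (rows > channels).

tiny_spec <- function(marker_channels = data.frame(mz = c(255L, 270L),
                                                   shift = 3),
                      dependent_groups = data.frame(
                        generator_mz = c(260L, 260L, 265L),
                        member_mz = c(280L, 281L, 290L),
                        coefficient = c(0.5, 0.3, 0.6)),
                      ...) {
  synthetic_spec(
    n_per_class = 12, replicates_per_patient = 3, n_channels = 60,
    marker_channels = marker_channels, dependent_groups = dependent_groups,
    ...)
}

tiny_cohort <- function(seed = 7, ...) generate_cohort(tiny_spec(...), seed)

# a larger, still fast cohort for learning-stage tests
small_learning_cohort <- function(seed = 7) {
  spec <- synthetic_spec(
    n_per_class = 20, replicates_per_patient = 3, n_channels = 80,
    marker_channels = data.frame(mz = c(255L, 270L, 300L), shift = 3),
    dependent_groups = data.frame(
      generator_mz = c(260L, 265L), member_mz = c(310L, 320L),
      coefficient = c(0.5, 0.6)))
  generate_cohort(spec, seed)
}

make_matrix <- function(values, mz = NULL, class = NULL) {
  n <- nrow(values)
  if (is.null(mz)) mz <- 250L + seq_len(ncol(values)) - 1L
  if (is.null(class)) class <- rep(c("case", "control"), length.out = n)
  intensity_matrix(values, mz,
                   patient = sprintf("P%02d", seq_len(n)),
                   replicate = rep(1L, n), class = class)
}
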