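#' Patient-grouped fit/test split
#'
#' Splits patients (never individual replicate spectra) into an untouched
#' test partition and a fit partition, stratified by class: per class,
#' `floor(test_fraction * n)` patients go to test and the remainder to fit.
#' All replicate vectors of a patient follow their patient, so train/test
#' contamination through technical replicates is impossible by construction.
#'
#' @param patients character vector of patient ids.
#' @param classes class label per patient (`"case"`/`"control"`).
#' @param test_fraction fraction of patients per class reserved for the final
#'   test, in (0, 1); default 0.2.
#' @param seed integer seed; the split is deterministic given the seed.
#' @return An object of class `partition_plan` with per-class `test` and
#'   `fit` patient sets (`experiments` empty until [make_experiments()]).
#' @export
split_fit_test <- function(patients, classes, test_fraction = 0.2, seed = 1L) {
  patients <- as.character(patients)
  classes <- as.character(classes)
  stopifnot(length(patients) == length(classes), !anyDuplicated(patients))
  if (test_fraction <= 0 || test_fraction >= 1) {
    stop("`test_fraction` must be in (0, 1)", call. = FALSE)
  }
  lv <- sort(unique(classes))
  if (!setequal(lv, c("case", "control"))) {
    stop("both classes ('case', 'control') must be present", call. = FALSE)
  }
  set.seed(as.integer(seed))
  test <- list(); fit <- list()
  for (cl in c("control", "case")) {
    pats <- patients[classes == cl]
    n_test <- floor(test_fraction * length(pats))
    if (n_test < 1 || n_test >= length(pats)) {
      stop("class ", cl, " has too few patients for a ", test_fraction,
           " test split", call. = FALSE)
    }
    idx <- sample(length(pats), n_test)
    test[[cl]] <- sort(pats[idx])
    fit[[cl]] <- sort(pats[-idx])
  }
  structure(list(test = test, fit = fit, experiments = list(),
                 test_fraction = test_fraction, seed = as.integer(seed)),
            class = "partition_plan")
}

#' Shuffle the fit partition into repeated train/validation experiments
#'
#' The fit patients of each class are independently reshuffled
#' `n_experiments` times into `floor((1 - val_fraction) * n)` training
#' patients and the remaining validation patients (so an 82-patient class at
#' `val_fraction = 0.2` yields 65 training and 17 validation patients).
#'
#' @param plan a `partition_plan` from [split_fit_test()].
#' @param n_experiments number of independent shuffles (default 10).
#' @param val_fraction validation fraction per class, in (0, 1); default 0.2.
#' @param seed integer seed.
#' @return The completed `partition_plan`, with `experiments` a list of
#'   `list(train = , val = )` per-class patient sets.
#' @export
make_experiments <- function(plan, n_experiments = 10, val_fraction = 0.2,
                             seed = 1L) {
  stopifnot(inherits(plan, "partition_plan"))
  if (!length(plan$fit)) stop("plan has no fit partition", call. = FALSE)
  if (val_fraction <= 0 || val_fraction >= 1) {
    stop("`val_fraction` must be in (0, 1)", call. = FALSE)
  }
  set.seed(as.integer(seed))
  exps <- vector("list", n_experiments)
  for (e in seq_len(n_experiments)) {
    train <- list(); val <- list()
    for (cl in names(plan$fit)) {
      pats <- plan$fit[[cl]]
      n_train <- floor((1 - val_fraction) * length(pats))
      n_val <- length(pats) - n_train
      if (n_val < 1) {
        stop("`val_fraction` leaves no validation patients for class ", cl,
             call. = FALSE)
      }
      if (n_train < 1) {
        stop("`val_fraction` leaves no training patients for class ", cl,
             call. = FALSE)
      }
      idx <- sample(length(pats), n_train)
      train[[cl]] <- sort(pats[idx])
      val[[cl]] <- sort(pats[setdiff(seq_along(pats), idx)])
    }
    exps[[e]] <- list(train = train, val = val)
  }
  plan$experiments <- exps
  assert_no_leakage(plan)
  plan
}

#' Assert pairwise disjointness of all patient partitions
#'
#' Verifies that test and fit patient sets are disjoint and that every
#' experiment's train and validation sets partition the fit set exactly.
#' Called automatically whenever experiments are built; exported so analyses
#' can re-assert it on every run.
#'
#' @param plan a `partition_plan`.
#' @return `TRUE` invisibly; otherwise an error.
#' @export
assert_no_leakage <- function(plan) {
  stopifnot(inherits(plan, "partition_plan"))
  test_all <- unlist(plan$test, use.names = FALSE)
  fit_all <- unlist(plan$fit, use.names = FALSE)
  if (length(intersect(test_all, fit_all))) {
    stop("test and fit patient sets overlap", call. = FALSE)
  }
  for (e in seq_along(plan$experiments)) {
    ex <- plan$experiments[[e]]
    for (cl in names(plan$fit)) {
      tr <- ex$train[[cl]]; va <- ex$val[[cl]]
      if (length(intersect(tr, va))) {
        stop("experiment ", e, ": train and validation overlap for ", cl,
             call. = FALSE)
      }
      if (!setequal(c(tr, va), plan$fit[[cl]])) {
        stop("experiment ", e, ": train + validation != fit for ", cl,
             call. = FALSE)
      }
      if (length(intersect(c(tr, va), test_all))) {
        stop("experiment ", e, ": test patients leaked into fit for ", cl,
             call. = FALSE)
      }
    }
  }
  invisible(TRUE)
}

#' @export
print.partition_plan <- function(x, ...) {
  cat(sprintf(
    "<partition_plan> test %s | fit %s | %d experiment(s)\n",
    paste(vapply(x$test, length, 1L), collapse = "+"),
    paste(vapply(x$fit, length, 1L), collapse = "+"),
    length(x$experiments)))
  invisible(x)
}
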