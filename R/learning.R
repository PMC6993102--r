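# Random-Forest ranking machinery: grid search for the tree count, iterative
# importance-based feature elimination, final diagnosis classifier, and the
# cross-classifier comparison harness. All randomness flows from one master
# seed through derived substreams.

derive_seeds <- function(seed, n) {
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

.metric_names <- c("sensitivity", "specificity", "precision", "f1", "accuracy")

.channel_cols <- function(x, channels) {
  idx <- match(channels, x$mz)
  if (anyNA(idx)) {
    stop("unseen channel(s): ", paste(channels[is.na(idx)], collapse = ", "),
         call. = FALSE)
  }
  idx
}

.train_learner <- function(learner, X, y, num_trees, seed) {
  switch(
    learner,
    random_forest = ranger::ranger(
      x = X, y = y, num.trees = num_trees, importance = "impurity",
      num.threads = 1, seed = seed),
    svm_smo = {
      set.seed(seed)
      has_var <- apply(X, 2, function(v) stats::sd(v) > 0)
      e1071::svm(x = X, y = y, kernel = "linear", scale = has_var)
    },
    svm_isda = {
      set.seed(seed)
      kernlab::ksvm(x = X, y = y, kernel = "vanilladot",
                    scaled = apply(X, 2, function(v) stats::sd(v) > 0),
                    kpar = list())
    },
    tree = {
      set.seed(seed)
      df <- data.frame(.class = y, X, check.names = FALSE)
      rpart::rpart(.class ~ ., data = df, method = "class")
    },
    stop("unknown learner: ", learner, call. = FALSE)
  )
}

.predict_learner <- function(learner, fit, X) {
  out <- switch(
    learner,
    random_forest = stats::predict(fit, data = X, num.threads = 1)$predictions,
    svm_smo = stats::predict(fit, X),
    svm_isda = kernlab::predict(fit, X),
    tree = stats::predict(fit, newdata = data.frame(X, check.names = FALSE),
                          type = "class"),
    stop("unknown learner: ", learner, call. = FALSE)
  )
  factor(as.character(out), levels = c("control", "case"))
}

# aggregate per-vector predictions to patient level; ties in the majority
# vote go to the positive class (screening bias)
.patient_votes <- function(pred, patient) {
  tab <- table(patient, pred)
  if (any(rowSums(tab) == 0)) {
    stop("patient with zero vectors in evaluation set", call. = FALSE)
  }
  case_votes <- tab[, "case"]
  total <- rowSums(tab)
  pred_pat <- ifelse(case_votes * 2 >= total, "case", "control")
  factor(pred_pat, levels = c("control", "case"))
}

.confusion_from_preds <- function(pred, truth) {
  confusion_counts(tp = sum(pred == "case" & truth == "case"),
                   tn = sum(pred == "control" & truth == "control"),
                   fp = sum(pred == "case" & truth == "control"),
                   fn = sum(pred == "control" & truth == "case"))
}

# train on the train patients, score the evaluation patients, return metrics
# (at the requested aggregation level) and, for forests, normalized
# per-channel importance
.eval_split <- function(x, channels, train_patients, eval_patients, learner,
                        num_trees, seed, aggregation) {
  cols <- .channel_cols(x, channels)
  rows_tr <- rows_for_patients(x, train_patients)
  rows_ev <- rows_for_patients(x, eval_patients)
  Xtr <- x$values[rows_tr, cols, drop = FALSE]
  fit <- .train_learner(learner, Xtr, droplevels0(x$class[rows_tr]),
                        num_trees, seed)
  pred <- .predict_learner(learner, fit, x$values[rows_ev, cols, drop = FALSE])
  if (aggregation == "patient") {
    pred_u <- .patient_votes(pred, x$patient[rows_ev])
    truth_u <- x$class[rows_ev][!duplicated(x$patient[rows_ev])]
    names(truth_u) <- x$patient[rows_ev][!duplicated(x$patient[rows_ev])]
    truth_u <- truth_u[names(pred_u)]
  } else {
    pred_u <- pred
    truth_u <- x$class[rows_ev]
  }
  counts <- .confusion_from_preds(pred_u, truth_u)
  imp <- NULL
  if (learner == "random_forest") {
    raw <- ranger::importance(fit)
    s <- sum(raw)
    imp <- if (s > 0) raw / s else rep(1 / length(raw), length(raw))
    names(imp) <- as.character(channels)
  }
  list(metrics = compute_metrics(counts), counts = counts, importance = imp)
}

droplevels0 <- function(f) factor(as.character(f), levels = c("control", "case"))

.summarise_experiments <- function(metric_list) {
  m <- do.call(rbind, lapply(metric_list, function(mm) unlist(mm)))
  means <- colMeans(m, na.rm = TRUE)
  sds <- apply(m, 2, stats::sd, na.rm = TRUE)
  rsd <- ifelse(is.finite(means) & means != 0, 100 * sds / means, NA_real_)
  list(mean = means, rsd = rsd)
}

# run every experiment of the plan at a fixed channel set and tree count
.run_experiments <- function(x, channels, plan, num_trees, seeds,
                             aggregation, learner = "random_forest") {
  n_exp <- length(plan$experiments)
  metrics <- vector("list", n_exp)
  imps <- matrix(0, n_exp, length(channels))
  for (e in seq_len(n_exp)) {
    ex <- plan$experiments[[e]]
    res <- .eval_split(x, channels,
                       unlist(ex$train, use.names = FALSE),
                       unlist(ex$val, use.names = FALSE),
                       learner, num_trees, seeds[e], aggregation)
    metrics[[e]] <- res$metrics
    if (!is.null(res$importance)) imps[e, ] <- res$importance
  }
  summ <- .summarise_experiments(metrics)
  list(mean = summ$mean, rsd = summ$rsd,
       importance = stats::setNames(colMeans(imps), as.character(channels)),
       per_experiment = metrics)
}

#' Grid search for the Random-Forest tree count as a function of vector length
#'
#' Evaluates every (vector length, tree count) grid cell by training one
#' forest per experiment on the top-`length` channels of a pilot importance
#' ranking (one full-length forest per experiment) and averaging validation
#' f1-score and balanced accuracy over the experiments. Per length, the tree
#' count maximising mean f1 is selected (ties: higher accuracy, then fewer
#' trees). Lengths not visited by the grid are mapped to the nearest visited
#' length (ties toward the smaller length).
#'
#' @param x fit-partition [intensity_matrix()], normalized and reduced.
#' @param plan a completed [make_experiments()] plan.
#' @param lengths integer vector of vector lengths to visit (clipped to the
#'   number of channels).
#' @param trees integer vector of candidate tree counts, all >= 1.
#' @param seed master seed for this stage.
#' @param aggregation `"patient"` (default, majority vote over replicates) or
#'   `"vector"`.
#' @return An object of class `trees_function`: `grid` (per-cell mean f1 and
#'   accuracy), `mapping` (selected tree count per visited length), and the
#'   pilot importance ranking.
#' @seealso [trees_for_length()]
#' @export
grid_search_trees <- function(x, plan, lengths, trees, seed = 1L,
                              aggregation = c("patient", "vector")) {
  aggregation <- match.arg(aggregation)
  stopifnot(inherits(x, "intensity_matrix"), inherits(plan, "partition_plan"))
  if (!length(lengths) || !length(trees)) {
    stop("`lengths` and `trees` grids must be non-empty", call. = FALSE)
  }
  if (any(trees < 1)) stop("tree counts must be >= 1", call. = FALSE)
  lengths <- sort(unique(pmin(as.integer(lengths), length(x$mz))),
                  decreasing = TRUE)
  trees <- sort(unique(as.integer(trees)))
  n_exp <- length(plan$experiments)
  seeds <- derive_seeds(seed, n_exp * (1 + length(lengths) * length(trees)))
  pilot <- .run_experiments(x, x$mz, plan, max(trees), seeds[seq_len(n_exp)],
                            aggregation)
  base_rank <- x$mz[order(-pilot$importance, x$mz)]

  grid <- expand.grid(length = lengths, num_trees = trees,
                      KEEP.OUT.ATTRS = FALSE)
  grid$mean_f1 <- NA_real_
  grid$mean_accuracy <- NA_real_
  off <- n_exp
  for (i in seq_len(nrow(grid))) {
    chans <- base_rank[seq_len(grid$length[i])]
    res <- .run_experiments(x, chans, plan, grid$num_trees[i],
                            seeds[off + seq_len(n_exp)], aggregation)
    off <- off + n_exp
    grid$mean_f1[i] <- res$mean["f1"]
    grid$mean_accuracy[i] <- res$mean["accuracy"]
  }
  mapping <- do.call(rbind, lapply(lengths, function(L) {
    g <- grid[grid$length == L, ]
    g <- g[order(-g$mean_f1, -g$mean_accuracy, g$num_trees), ]
    g[1, c("length", "num_trees")]
  }))
  rownames(mapping) <- NULL
  structure(list(grid = grid, mapping = mapping,
                 pilot_ranking = base_rank, aggregation = aggregation),
            class = "trees_function")
}

#' Tree count for a given vector length
#'
#' @param trees_fn a `trees_function` from [grid_search_trees()], or a single
#'   number used as a constant tree count.
#' @param length vector length.
#' @return Integer tree count (nearest visited grid length; ties toward the
#'   smaller length).
#' @export
trees_for_length <- function(trees_fn, length) {
  if (is.numeric(trees_fn) && base::length(trees_fn) == 1) {
    return(as.integer(trees_fn))
  }
  stopifnot(inherits(trees_fn, "trees_function"))
  map <- trees_fn$mapping
  d <- abs(map$length - length)
  cand <- which(d == min(d))
  pick <- cand[which.min(map$length[cand])]
  as.integer(map$num_trees[pick])
}

#' @export
print.trees_function <- function(x, ...) {
  cat("<trees_function> selected tree counts by vector length:\n")
  print(x$mapping, row.names = FALSE)
  invisible(x)
}

#' Iterative Random-Forest feature ranking
#'
#' Starting from all channels of the (reduced, normalized) fit matrix, each
#' iteration trains one forest per experiment, records the mean and relative
#' standard deviation of the validation metrics, aggregates per-channel
#' importance as the arithmetic mean of per-forest importances (each
#' normalized to sum 1), and keeps the top `max(1, floor(reduction_factor *
#' length))` channels (ties: higher importance, then lower m/z) until a
#' single channel remains.
#'
#' @param x fit-partition [intensity_matrix()].
#' @param plan a completed `partition_plan`.
#' @param trees_fn a `trees_function` or constant tree count.
#' @param reduction_factor per-iteration survival factor in (0, 1);
#'   default 0.9.
#' @param seed master seed for this stage.
#' @param aggregation `"patient"` or `"vector"`.
#' @return An object of class `ranking_trace`; see [as.data.frame.ranking_trace()]
#'   for the tabular summary and [select_optimal()] for peak selection.
#' @export
iterate_ranking <- function(x, plan, trees_fn, reduction_factor = 0.9,
                            seed = 1L, aggregation = c("patient", "vector")) {
  aggregation <- match.arg(aggregation)
  stopifnot(inherits(x, "intensity_matrix"), inherits(plan, "partition_plan"))
  if (reduction_factor <= 0 || reduction_factor >= 1) {
    stop("`reduction_factor` must be in (0, 1)", call. = FALSE)
  }
  lens <- integer(0)
  L <- length(x$mz)
  while (TRUE) {
    lens <- c(lens, L)
    if (L == 1L) break
    L <- max(1L, as.integer(floor(reduction_factor * L)))
  }
  n_exp <- length(plan$experiments)
  seeds <- matrix(derive_seeds(seed, length(lens) * n_exp), nrow = length(lens))
  channels <- x$mz
  iterations <- vector("list", length(lens))
  for (k in seq_along(lens)) {
    res <- .run_experiments(x, channels, plan, trees_for_length(trees_fn, lens[k]),
                            seeds[k, ], aggregation)
    iterations[[k]] <- list(
      length = lens[k],
      num_trees = trees_for_length(trees_fn, lens[k]),
      channels = channels,
      importance = res$importance,
      mean = res$mean,
      rsd = res$rsd)
    if (lens[k] > 1L) {
      keep <- order(-res$importance, channels)[seq_len(lens[k + 1L])]
      channels <- sort(channels[keep])
    }
  }
  structure(list(iterations = iterations,
                 reduction_factor = reduction_factor,
                 aggregation = aggregation, seed = as.integer(seed)),
            class = "ranking_trace")
}

#' @export
#' @rdname iterate_ranking
#' @param row.names,optional,... passed through (see [base::as.data.frame()]).
as.data.frame.ranking_trace <- function(x, row.names = NULL, optional = FALSE,
                                        ...) {
  rows <- lapply(x$iterations, function(it) {
    out <- data.frame(length = it$length, num_trees = it$num_trees)
    for (m in .metric_names) {
      out[[paste0("mean_", m)]] <- unname(it$mean[m])
      out[[paste0("rsd_", m)]] <- unname(it$rsd[m])
    }
    out
  })
  do.call(rbind, rows)
}

#' @export
print.ranking_trace <- function(x, ...) {
  df <- as.data.frame(x)
  cat(sprintf("<ranking_trace> %d iterations, lengths %d -> 1\n",
              nrow(df), df$length[1]))
  best <- select_optimal(x)
  cat(sprintf("  f1 peak: %.3f at length %d\n", best$mean_f1, best$length))
  invisible(x)
}

#' Optimal channel set from a ranking trace
#'
#' The surviving channel set at the iteration with the maximum mean
#' validation f1-score; ties resolve to the smaller vector length.
#'
#' @param trace a `ranking_trace`.
#' @return List with `channels`, `length`, `num_trees`, `mean_f1` and the
#'   trace `iteration` index.
#' @export
select_optimal <- function(trace) {
  stopifnot(inherits(trace, "ranking_trace"), length(trace$iterations) > 0)
  f1 <- vapply(trace$iterations, function(it) {
    v <- it$mean["f1"]; if (is.na(v)) -Inf else v
  }, numeric(1))
  lens <- vapply(trace$iterations, function(it) it$length, numeric(1))
  best <- which(f1 == max(f1))
  pick <- best[which.min(lens[best])]
  it <- trace$iterations[[pick]]
  list(channels = it$channels, length = it$length, num_trees = it$num_trees,
       mean_f1 = unname(it$mean["f1"]), iteration = pick)
}

#' Train the final diagnosis classifier
#'
#' One Random Forest trained on every fit-partition vector restricted to the
#' selected channels.
#'
#' @param x fit-partition [intensity_matrix()].
#' @param channels selected channel set (must all exist in `x`).
#' @param num_trees tree count (e.g. from [trees_for_length()]).
#' @param seed integer seed.
#' @return Object of class `diagnosis_classifier`.
#' @export
train_diagnosis_classifier <- function(x, channels, num_trees, seed = 1L) {
  stopifnot(inherits(x, "intensity_matrix"))
  cols <- .channel_cols(x, channels)
  fit <- ranger::ranger(x = x$values[, cols, drop = FALSE],
                        y = droplevels0(x$class),
                        num.trees = num_trees, importance = "impurity",
                        num.threads = 1, seed = as.integer(seed),
                        probability = FALSE)
  structure(list(model = fit, channels = channels,
                 num_trees = num_trees, seed = as.integer(seed)),
            class = "diagnosis_classifier")
}

#' Evaluate the diagnosis classifier on held-out test patients
#'
#' Per-vector predictions are aggregated to patient level by majority vote
#' (default; ties with even replicate counts go to the positive class) before
#' computing metrics; `aggregation = "vector"` scores each replicate
#' spectrum independently.
#'
#' @param classifier a `diagnosis_classifier`.
#' @param test_x test-partition [intensity_matrix()] (patients disjoint from
#'   the fit partition).
#' @param aggregation `"patient"` (default) or `"vector"`.
#' @return List with `metrics` ([compute_metrics()]), `counts`
#'   ([confusion_counts()]) and per-unit `predictions`.
#' @export
evaluate_on_test <- function(classifier, test_x,
                             aggregation = c("patient", "vector")) {
  aggregation <- match.arg(aggregation)
  stopifnot(inherits(classifier, "diagnosis_classifier"),
            inherits(test_x, "intensity_matrix"))
  cols <- .channel_cols(test_x, classifier$channels)
  pred <- .predict_learner("random_forest", classifier$model,
                           test_x$values[, cols, drop = FALSE])
  if (aggregation == "patient") {
    pred_u <- .patient_votes(pred, test_x$patient)
    first <- !duplicated(test_x$patient)
    truth_u <- stats::setNames(test_x$class[first], test_x$patient[first])
    truth_u <- truth_u[names(pred_u)]
    predictions <- data.frame(unit = names(pred_u), truth = truth_u,
                              predicted = pred_u, row.names = NULL)
  } else {
    pred_u <- pred
    truth_u <- test_x$class
    predictions <- data.frame(unit = rownames(test_x$values), truth = truth_u,
                              predicted = pred_u, row.names = NULL)
  }
  counts <- .confusion_from_preds(pred_u, truth_u)
  list(metrics = compute_metrics(counts), counts = counts,
       predictions = predictions)
}

#' Compare classifiers on identical partitions and channels
#'
#' Feeds the same experiments and the same selected channel set to a Random
#' Forest, two support-vector-machine variants (libsvm's sequential-minimal
#' optimizer via e1071 and kernlab's implementation, both linear kernel) and
#' a single Gini decision tree, and reports the mean and relative standard
#' deviation of each validation metric over the experiments.
#'
#' @param x fit-partition [intensity_matrix()].
#' @param channels channel set to use for every learner.
#' @param plan completed `partition_plan`.
#' @param learners subset of `c("random_forest", "svm_smo", "svm_isda",
#'   "tree")`; duplicates allowed (and produce identical rows).
#' @param num_trees tree count for the forest learner.
#' @param seed master seed.
#' @param aggregation `"patient"` or `"vector"`.
#' @return Long data.frame with columns `learner`, `metric`, `mean`, `rsd`.
#' @export
compare_classifiers <- function(x, channels, plan,
                                learners = c("random_forest", "svm_smo",
                                             "svm_isda", "tree"),
                                num_trees = 58, seed = 1L,
                                aggregation = c("patient", "vector")) {
  aggregation <- match.arg(aggregation)
  known <- c("random_forest", "svm_smo", "svm_isda", "tree")
  bad <- setdiff(learners, known)
  if (length(bad)) stop("unknown learner: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  n_exp <- length(plan$experiments)
  seeds <- derive_seeds(seed, n_exp)
  out <- list()
  for (lr in learners) {
    res <- .run_experiments(x, channels, plan, num_trees, seeds,
                            aggregation, learner = lr)
    out[[length(out) + 1L]] <- data.frame(
      learner = lr, metric = .metric_names,
      mean = unname(res$mean[.metric_names]),
      rsd = unname(res$rsd[.metric_names]))
  }
  do.call(rbind, out)
}
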