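# shared small fit/plan setup for the learning-stage tests
learning_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      coh <- small_learning_cohort(seed = 7)
      x <- normalize_rows(coh$matrix)
      pt <- patient_table(x)
      plan <- split_fit_test(pt$patient, pt$class, 0.2, seed = 1)
      plan <- make_experiments(plan, n_experiments = 4, seed = 2)
      fit_x <- subset_spectra(x, rows_for_patients(x, unlist(plan$fit)))
      test_x <- subset_spectra(x, rows_for_patients(x, unlist(plan$test)))
      cache <<- list(coh = coh, plan = plan, fit_x = fit_x, test_x = test_x)
    }
    cache
  }
})

test_that("grid search selects by f1 with ties resolved toward fewer trees", {
  fx <- learning_fixture()
  tf <- grid_search_trees(fx$fit_x, fx$plan, lengths = 8, trees = c(10, 20),
                          seed = 3)
  expect_s3_class(tf, "trees_function")
  expect_equal(nrow(tf$grid), 2)
  g <- tf$grid
  # separable cohort: both tree counts reach the same f1, so the tie rule
  # must pick the smaller count
  if (g$mean_f1[g$num_trees == 10] == g$mean_f1[g$num_trees == 20]) {
    expect_equal(tf$mapping$num_trees, 10)
  }
  # single-cell grid selects that cell
  tf1 <- grid_search_trees(fx$fit_x, fx$plan, lengths = 8, trees = 30,
                           seed = 3)
  expect_equal(tf1$mapping$num_trees, 30)
  expect_equal(tf1$mapping$length, 8)

  expect_error(grid_search_trees(fx$fit_x, fx$plan, lengths = 8, trees = 0),
               ">= 1")
  expect_error(grid_search_trees(fx$fit_x, fx$plan, lengths = integer(0),
                                 trees = 10), "non-empty")
})

test_that("tree-count mapping extends to unvisited lengths by nearest visited length", {
  tf <- structure(list(
    grid = data.frame(),
    mapping = data.frame(length = c(50, 10), num_trees = c(80, 20))),
    class = "trees_function")
  expect_equal(trees_for_length(tf, 50), 80)
  expect_equal(trees_for_length(tf, 45), 80)
  expect_equal(trees_for_length(tf, 12), 20)
  # equidistant: the smaller length wins
  expect_equal(trees_for_length(tf, 30), 20)
  # constant fallback
  expect_equal(trees_for_length(58, 123), 58)
})

test_that("iterative ranking visits the floor(0.9 L) length sequence down to 1", {
  fx <- learning_fixture()
  small <- subset_spectra(fx$fit_x, mz_keep = fx$fit_x$mz[1:10])
  trace <- iterate_ranking(small, fx$plan, trees_fn = 20,
                           reduction_factor = 0.9, seed = 5)
  df <- as.data.frame(trace)
  expect_equal(df$length, c(10, 9, 8, 7, 6, 5, 4, 3, 2, 1))
  # surviving channel sets are nested across iterations
  for (k in 2:length(trace$iterations)) {
    expect_true(all(trace$iterations[[k]]$channels %in%
                      trace$iterations[[k - 1]]$channels))
  }
  expect_true(all(df$mean_f1 >= 0 & df$mean_f1 <= 1, na.rm = TRUE))
  expect_error(iterate_ranking(small, fx$plan, 20, reduction_factor = 1),
               "0, 1")
})

test_that("ranking is reproducible given the master seed", {
  fx <- learning_fixture()
  small <- subset_spectra(fx$fit_x, mz_keep = fx$fit_x$mz[1:12])
  t1 <- iterate_ranking(small, fx$plan, 15, seed = 11)
  t2 <- iterate_ranking(small, fx$plan, 15, seed = 11)
  expect_equal(as.data.frame(t1), as.data.frame(t2))
  expect_identical(select_optimal(t1)$channels, select_optimal(t2)$channels)
})

test_that("select_optimal picks the f1 peak and breaks ties toward shorter vectors", {
  mk_iter <- function(len, f1) {
    list(length = len, num_trees = 10, channels = seq_len(len),
         importance = NULL,
         mean = c(sensitivity = NA, specificity = NA, precision = NA,
                  f1 = f1, accuracy = NA),
         rsd = rep(NA_real_, 5))
  }
  trace <- structure(list(iterations = list(
    mk_iter(20, 0.90), mk_iter(18, 0.95), mk_iter(16, 0.95),
    mk_iter(14, 0.80), mk_iter(1, 0.70))), class = "ranking_trace")
  best <- select_optimal(trace)
  expect_equal(best$length, 16)
  expect_equal(best$mean_f1, 0.95)

  # monotone improvement toward length 1 selects the single-channel set
  tr2 <- structure(list(iterations = list(
    mk_iter(4, 0.7), mk_iter(3, 0.8), mk_iter(2, 0.9), mk_iter(1, 0.95))),
    class = "ranking_trace")
  expect_equal(select_optimal(tr2)$length, 1)
})

test_that("planted markers dominate the optimal set of a separable cohort", {
  fx <- learning_fixture()
  tf <- grid_search_trees(fx$fit_x, fx$plan, lengths = c(16, 8),
                          trees = c(20, 40), seed = 4)
  trace <- iterate_ranking(fx$fit_x, fx$plan, tf, seed = 6)
  best <- select_optimal(trace)
  planted <- fx$coh$truth$marker_channels$mz
  # survivors at length 4 are dominated by the planted markers; the optimal
  # set may be smaller when f1 saturates (ties resolve to shorter vectors)
  lens <- vapply(trace$iterations, function(it) it$length, numeric(1))
  at4 <- trace$iterations[[which(lens == 4)]]$channels
  expect_gte(length(intersect(at4, planted)), 2)
  expect_true(all(best$channels %in% at4))
  expect_gte(best$mean_f1, 0.9)
})

test_that("the diagnosis classifier is deterministic and optimistic on its training data", {
  fx <- learning_fixture()
  planted <- fx$coh$truth$marker_channels$mz
  clf <- train_diagnosis_classifier(fx$fit_x, planted, num_trees = 30,
                                    seed = 9)
  clf2 <- train_diagnosis_classifier(fx$fit_x, planted, num_trees = 30,
                                     seed = 9)
  test_res <- evaluate_on_test(clf, fx$test_x)
  expect_identical(test_res$predictions,
                   evaluate_on_test(clf2, fx$test_x)$predictions)
  train_res <- evaluate_on_test(clf, fx$fit_x)
  expect_gte(train_res$metrics$f1, test_res$metrics$f1 - 1e-9)
  expect_gte(test_res$metrics$accuracy, 0.8)
  expect_error(train_diagnosis_classifier(fx$fit_x, c(255L, 9999L), 10, 1),
               "unseen channel")
  expect_error(evaluate_on_test(clf, subset_spectra(fx$test_x,
                                                    mz_keep = 250:254)),
               "unseen channel")
})

test_that("majority vote aggregates replicate vectors with ties to the positive class", {
  votes <- maldimarkers:::.patient_votes
  pred <- factor(c("case", "case", "case", "control", "control",
                   "case", "control"),
                 levels = c("control", "case"))
  pat <- c(rep("A", 5), rep("B", 2))
  out <- votes(pred, pat)
  expect_equal(as.character(out[["A"]]), "case")    # 3 of 5
  expect_equal(as.character(out[["B"]]), "case")    # 1-1 tie -> positive
  out2 <- votes(factor(rep("control", 3), levels = c("control", "case")),
                rep("C", 3))
  expect_equal(as.character(out2[["C"]]), "control")
})

test_that("classifier comparison feeds identical partitions to every learner", {
  fx <- learning_fixture()
  planted <- fx$coh$truth$marker_channels$mz
  cmp <- compare_classifiers(fx$fit_x, planted, fx$plan,
                             learners = c("random_forest", "svm_smo",
                                          "svm_isda", "tree"),
                             num_trees = 20, seed = 10)
  expect_setequal(unique(cmp$learner),
                  c("random_forest", "svm_smo", "svm_isda", "tree"))
  expect_setequal(unique(cmp$metric),
                  c("sensitivity", "specificity", "precision", "f1",
                    "accuracy"))
  expect_true(all(cmp$mean >= 0 & cmp$mean <= 1, na.rm = TRUE))
  # a separable cohort is easy for every learner
  f1s <- cmp$mean[cmp$metric == "f1"]
  expect_true(all(f1s >= 0.9))

  # the same learner listed twice produces identical rows
  dup <- compare_classifiers(fx$fit_x, planted, fx$plan,
                             learners = c("tree", "tree"), seed = 10)
  expect_equal(dup$mean[dup$learner == "tree"][1:5],
               dup$mean[dup$learner == "tree"][6:10])

  # degenerate single-feature input still yields a well-formed table
  one <- compare_classifiers(fx$fit_x, planted[1], fx$plan,
                             learners = c("random_forest", "tree"),
                             num_trees = 10, seed = 10)
  expect_equal(nrow(one), 10)
  expect_error(compare_classifiers(fx$fit_x, planted, fx$plan,
                                   learners = "boosting"), "unknown learner")
})

test_that("the pipeline driver chains the stages and logs its decisions", {
  coh <- small_learning_cohort(seed = 19)
  res <- run_discovery_pipeline(coh$matrix, seed = 21,
                                lengths_grid = c(32, 8),
                                trees_grid = c(20, 40))
  expect_s3_class(res, "discovery_result")
  expect_true(all(coh$truth$dependent_groups$member_mz %in%
                    setdiff(coh$matrix$mz, res$reduction$representatives)))
  expect_true(res$optimal$length >= 1)
  expect_equal(nrow(res$markers), length(res$optimal$channels))
  expect_named(res$log$stage_seeds,
               c("split", "experiments", "grid", "ranking", "final"))
  expect_equal(res$log$reduction_rows, "fit")
  # dataset-reproduction mode feeds all vectors to the elimination
  res_all <- run_discovery_pipeline(coh$matrix, seed = 21,
                                    lengths_grid = 8, trees_grid = 20,
                                    reduction_rows = "all")
  expect_equal(res_all$reduction$n_rows_used, nrow(coh$matrix$values))
})
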