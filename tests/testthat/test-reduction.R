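test_that("an exact scalar multiple forms one group represented by its max-median member", {
  set.seed(1)
  X <- matrix(rexp(30 * 4), 30, 4)
  X[, 3] <- 3 * X[, 1]
  red <- find_dependent_groups(X)
  expect_equal(length(red$representatives), 3)
  grp <- red$groups[[which(vapply(red$groups, length, 1L) == 2)]]
  expect_setequal(grp, c(1, 3))
  # column 3 = 3 * column 1 has three times the median, so it represents
  expect_true(3 %in% red$representatives)
  expect_false(1 %in% red$representatives)
})

test_that("independent columns give singleton groups and nothing is eliminated", {
  set.seed(2)
  X <- matrix(rnorm(50 * 8), 50, 8)
  red <- find_dependent_groups(X)
  expect_equal(red$representatives, 1:8)
  expect_true(all(lengths(red$groups) == 1))
})

test_that("representative count equals the numerical rank of low-rank constructions", {
  for (s in 1:10) {
    set.seed(s)
    r <- sample(5:30, 1)
    X <- matrix(rnorm(40 * r), 40, r) %*% matrix(rnorm(r * 60), r, 60)
    red <- find_dependent_groups(X, pivot_tolerance = 1e-8)
    sv <- svd(X, nu = 0, nv = 0)$d
    rank_svd <- sum(sv > 1e-8 * sv[1])
    expect_equal(length(red$representatives), rank_svd)
    expect_equal(rank_svd, r)
  }
})

test_that("eliminated columns are reconstructible from the retained ones", {
  set.seed(4)
  X <- matrix(rnorm(40 * 10), 40, 10) %*% matrix(rnorm(10 * 25), 10, 25)
  red <- find_dependent_groups(X)
  keep <- red$representatives
  drop <- setdiff(seq_len(ncol(X)), keep)
  expect_gt(length(drop), 0)
  B <- X[, keep, drop = FALSE]
  for (j in drop) {
    resid <- stats::lsfit(B, X[, j], intercept = FALSE)$residuals
    expect_lt(sqrt(sum(resid^2)), 1e-6 * sqrt(sum(X[, j]^2)))
  }
})

test_that("group contents are invariant under row permutation", {
  coh <- tiny_cohort(seed = 5)
  x <- normalize_rows(coh$matrix)
  red1 <- find_dependent_groups(x)
  set.seed(99)
  perm <- sample(nrow(x$values))
  xp <- intensity_matrix(x$values[perm, ], x$mz, x$patient[perm],
                         x$replicate[perm], x$class[perm],
                         normalized = TRUE)
  red2 <- find_dependent_groups(xp)
  norm_groups <- function(r) lapply(r$groups, sort)[order(names(r$groups))]
  expect_identical(norm_groups(red1), norm_groups(red2))
})

test_that("planted dependency groups are recovered from a generated cohort", {
  coh <- tiny_cohort(seed = 8)
  x <- normalize_rows(coh$matrix)
  red <- find_dependent_groups(x)
  dg <- coh$truth$dependent_groups
  removed <- setdiff(x$mz, red$representatives)
  expect_setequal(removed, dg$member_mz)
  expect_setequal(expand_to_group(red, 260L), c(260L, 280L, 281L))
  expect_setequal(expand_to_group(red, 265L), c(265L, 290L))
})

test_that("reduce_channels keeps representatives, metadata and label order", {
  coh <- tiny_cohort(seed = 8)
  x <- normalize_rows(coh$matrix)
  red <- find_dependent_groups(x)
  xr <- reduce_channels(x, red)
  expect_equal(xr$mz, sort(red$representatives))
  expect_identical(xr$patient, x$patient)
  expect_equal(ncol(xr$values), 60 - 3)

  # identity when nothing is dependent
  set.seed(1)
  ind <- make_matrix(matrix(rexp(40 * 6), 40, 6))
  red_i <- find_dependent_groups(ind$values)
  expect_equal(length(red_i$representatives), 6)

  # label mismatch is an error
  other <- subset_spectra(x, mz_keep = x$mz[-1])
  expect_error(reduce_channels(other, red), "labels")
})

test_that("expand_to_group rejects non-representatives and unknown channels", {
  coh <- tiny_cohort(seed = 8)
  red <- find_dependent_groups(normalize_rows(coh$matrix))
  expect_setequal(expand_to_group(red, 255L), 255L)
  expect_error(expand_to_group(red, 280L), "not a representative")
  expect_error(expand_to_group(red, 9999L), "not a representative")
})

test_that("pivot tolerance must be positive and reductions serialize to JSON", {
  X <- matrix(1:20, 5, 4)
  expect_error(find_dependent_groups(X, pivot_tolerance = 0), "positive")
  expect_error(find_dependent_groups(X, pivot_tolerance = -1), "positive")

  coh <- tiny_cohort(seed = 8)
  red <- find_dependent_groups(normalize_rows(coh$matrix))
  path <- withr::local_tempfile(fileext = ".json")
  write_reduction(red, path)
  back <- read_reduction(path)
  expect_equal(back$representatives, red$representatives)
  expect_equal(lapply(back$groups, sort), lapply(red$groups, sort))
  expect_equal(back$pivot_tolerance, red$pivot_tolerance)
})

test_that("reduction restricted to a row subset still reduces the full matrix", {
  coh <- tiny_cohort(seed = 12)
  x <- normalize_rows(coh$matrix)
  rows <- which(x$patient %in% unique(x$patient)[1:16])
  red <- find_dependent_groups(x, rows = rows)
  expect_equal(red$n_rows_used, length(rows))
  removed <- setdiff(x$mz, red$representatives)
  expect_true(all(coh$truth$dependent_groups$member_mz %in%
                    c(removed, red$representatives)))
  xr <- reduce_channels(x, red)
  expect_equal(nrow(xr$values), nrow(x$values))
})
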